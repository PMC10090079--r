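#' Read genome records from a FASTA file
#'
#' Sequences are uppercased on read; IUPAC ambiguity characters outside
#' A/C/G/T/N are collapsed to N with a warning, so that all downstream
#' pairing and k-mer logic operates over a five-letter alphabet.
#'
#' @param path FASTA file (wrapped or unwrapped, one or more records).
#' @return named character vector of sequences; names are record ids
#'   (first whitespace-delimited token of the header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) stop("FASTA format error: no records in ", path,
                             call. = FALSE)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicate record ids in ", path, call. = FALSE)
  }
  if (any(nchar(seqs) == 0)) {
    stop("FASTA format error: empty sequence in ", path, call. = FALSE)
  }
  cleaned <- gsub("[^ACGTN]", "N", seqs)
  if (any(cleaned != seqs)) {
    warning(sum(cleaned != seqs),
            " record(s) contained non-ACGTN characters; collapsed to N",
            call. = FALSE)
  }
  names(cleaned) <- ids
  cleaned
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector (uppercased), ids from the first header
#'   token.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("FASTA format error: no records in ", path,
                             call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) {
    stop("FASTA format error: duplicate record ids in ", path, call. = FALSE)
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector (DNA, RNA or protein).
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Phred+33) as a named character vector
#'
#' Qualities are not retained; the toolkit's classifiers operate on base
#' calls only.
#'
#' @param path FASTQ file.
#' @return named character vector of uppercased read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("FASTQ format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  reads <- toupper(as.character(set))
  names(reads) <- sub("\\s.*$", "", names(set))
  reads
}

#' Write reads to a FASTQ file with constant quality
#'
#' @param reads named character vector of DNA reads.
#' @param path output path.
#' @param qual_char single quality character applied to every base
#'   (default "I", Phred 40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  stopifnot(!is.null(names(reads)))
  set <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
    strrep(qual_char, n)
  }, ""))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Reverse complement a DNA string
#'
#' @param dna string over A/C/G/T/N.
#' @return reverse complement; N maps to N.
#' @examples
#' revcomp("AAAC")
#' @export
revcomp <- function(dna) {
  dna <- check_alphabet(dna, what = "DNA")
  paste(rev(seq_chars(chartr("ACGTN", "TGCAN", dna))), collapse = "")
}

#' Transcribe DNA to RNA (T -> U)
#'
#' @param dna string over A/C/G/T/N, read as the transcript-strand sequence.
#' @return RNA string over A/C/G/U/N.
#' @export
transcribe <- function(dna) {
  chartr("T", "U", check_alphabet(dna, what = "DNA"))
}

#' Reverse transcribe RNA to DNA (U -> T)
#' @param rna string over A/C/G/U/N.
#' @return DNA string.
#' @export
rna_to_dna <- function(rna) {
  chartr("U", "T", check_alphabet(rna, alphabet = c("A", "C", "G", "U", "N"),
                                  what = "RNA"))
}

#' Translate DNA under the bacterial genetic code
#'
#' A terminal stop codon is dropped; internal stops are rendered "*".
#' Codons containing N translate to "X".
#'
#' @param dna coding-strand DNA; length must be divisible by 3.
#' @param table genetic code table id (11, bacterial; codon assignments are
#'   identical to the standard code).
#' @return amino-acid string.
#' @examples
#' translate_dna("ATGGCT")
#' @export
translate_dna <- function(dna, table = 11) {
  dna <- check_alphabet(dna, what = "DNA")
  if (nchar(dna) %% 3 != 0) {
    stop("sequence length not divisible by 3", call. = FALSE)
  }
  if (nchar(dna) == 0) return("")
  gc <- codon_table(table)
  starts <- seq(1, nchar(dna), 3)
  aa <- unname(gc[substring(dna, starts, starts + 2)])
  aa[is.na(aa)] <- "X"                      # codons containing N
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# cached genetic-code lookup (codon -> amino acid, stops as "*")
.codon_cache <- new.env(parent = emptyenv())
codon_table <- function(table = 11) {
  key <- as.character(table)
  if (is.null(.codon_cache[[key]])) {
    .codon_cache[[key]] <- Biostrings::getGeneticCode(key)
  }
  .codon_cache[[key]]
}

#' Find open reading frames on both strands
#'
#' ORFs are maximal: each runs from the first start codon (ATG, or the
#' bacterial alternatives GTG/TTG) after the previous in-frame stop, to the
#' next in-frame stop (interval includes the stop codon) or, when no stop
#' follows, to the last complete codon of the contig (reported with
#' `partial = TRUE`).
#'
#' @param record single DNA string, or a named length-1 character vector
#'   whose name supplies the contig id.
#' @param min_len_aa minimum protein length in amino acids (stop excluded).
#' @param start_codons allowed start codons.
#' @param contig_id contig id used in the output when `record` is unnamed.
#' @return data.frame with columns contig_id, start, end, strand (interval in
#'   0-based half-open forward coordinates), start_codon, protein, partial;
#'   sorted by start, then end, then strand.
#' @export
find_orfs <- function(record, min_len_aa = 1L,
                      start_codons = c("ATG", "GTG", "TTG"),
                      contig_id = NULL) {
  stopifnot(min_len_aa >= 1)
  if (is.null(contig_id)) {
    contig_id <- if (!is.null(names(record))) names(record)[1] else "contig"
  }
  seq_fwd <- check_alphabet(unname(record[1]), what = "contig")
  len <- nchar(seq_fwd)

  scan_strand <- function(s, strand) {
    out <- list()
    emit <- function(s0, e0, start_codon, partial) {
      prot <- translate_dna(substr(s, s0 + 1, e0))
      if (nchar(prot) >= min_len_aa) {
        out[[length(out) + 1]] <<- list(s0 = s0, e0 = e0, strand = strand,
                                        start_codon = start_codon,
                                        protein = prot, partial = partial)
      }
    }
    for (frame in 0:2) {
      n_codon <- (nchar(s) - frame) %/% 3
      if (n_codon < 1) next
      starts_nt <- frame + 3 * (seq_len(n_codon) - 1)  # 0-based codon starts
      codons <- substring(s, starts_nt + 1, starts_nt + 3)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_start <- codons %in% start_codons
      seg_begin <- 1L  # codon index opening the current segment
      for (ci in which(is_stop)) {
        if (seg_begin <= ci - 1) {
          seg <- seg_begin:(ci - 1)
          ai <- seg[is_start[seg]][1]
          if (!is.na(ai)) {
            emit(starts_nt[ai], starts_nt[ci] + 3L, codons[ai],
                 partial = FALSE)
          }
        }
        seg_begin <- ci + 1L
      }
      if (seg_begin <= n_codon) {  # trailing segment running to contig end
        seg <- seg_begin:n_codon
        ai <- seg[is_start[seg]][1]
        if (!is.na(ai)) {
          emit(starts_nt[ai], starts_nt[n_codon] + 3L, codons[ai],
               partial = TRUE)
        }
      }
    }
    out
  }

  fwd <- scan_strand(seq_fwd, "+")
  rev <- scan_strand(revcomp(seq_fwd), "-")
  rows <- c(
    lapply(fwd, function(o) {
      data.frame(contig_id = contig_id, start = o$s0, end = o$e0,
                 strand = "+", start_codon = o$start_codon,
                 protein = o$protein, partial = o$partial,
                 stringsAsFactors = FALSE)
    }),
    lapply(rev, function(o) {
      data.frame(contig_id = contig_id, start = len - o$e0, end = len - o$s0,
                 strand = "-", start_codon = o$start_codon,
                 protein = o$protein, partial = o$partial,
                 stringsAsFactors = FALSE)
    })
  )
  if (length(rows) == 0) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      start_codon = character(), protein = character(),
                      partial = logical(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}
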