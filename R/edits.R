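#' Describe an amplicon reference with its expected cut site
#'
#' The expected cut defaults to 23 bp downstream of the PAM 3' end, the
#' midpoint of the 21-25 bp run-off cleavage range these effectors show;
#' edits are quantified inside a `window_width`-bp window centered on the
#' cut.
#'
#' @param sequence amplicon DNA.
#' @param pam_start,pam_end PAM interval (0-based half-open; PAM 5' of the
#'   protospacer).
#' @param spacer_len protospacer length (abuts the PAM 3' end).
#' @param cut_offset expected cut, bp downstream of the PAM 3' end.
#' @param window_width quantification window width (bp).
#' @return list of class `amplicon_ref`.
#' @export
amplicon_ref <- function(sequence, pam_start, pam_end, spacer_len = 20L,
                         cut_offset = 23L, window_width = 10L) {
  sequence <- check_alphabet(sequence, what = "amplicon")
  stopifnot(pam_start >= 0, pam_end > pam_start,
            pam_end + spacer_len <= nchar(sequence))
  structure(list(
    sequence = sequence,
    pam_start = as.integer(pam_start), pam_end = as.integer(pam_end),
    protospacer_start = as.integer(pam_end),
    protospacer_end = as.integer(pam_end + spacer_len),
    expected_cut = as.integer(pam_end + cut_offset),
    window_width = as.integer(window_width)
  ), class = "amplicon_ref")
}

# left-normalize one indel against the reference so homopolymer placement
# is deterministic. pos is the 0-based reference coordinate where the
# event begins (deletion: first deleted base; insertion: insertion point,
# i.e. inserted bases precede ref position pos).
left_normalize_indel <- function(ref_chars, pos, len, kind, inserted = "") {
  if (kind == "del") {
    while (pos > 0 && ref_chars[pos] == ref_chars[pos + len]) {
      pos <- pos - 1L
    }
    list(pos = pos, len = len, kind = kind, seq = "")
  } else {
    ins <- seq_chars(inserted)
    while (pos > 0 && ref_chars[pos] == ins[length(ins)]) {
      ins <- c(ref_chars[pos], ins[-length(ins)])
      pos <- pos - 1L
    }
    list(pos = pos, len = len, kind = kind,
         seq = paste(ins, collapse = ""))
  }
}

#' Align a read to an amplicon reference
#'
#' Global-in-read alignment with affine gaps (match +2, mismatch -2, gap
#' open -6, gap extend -1, mirroring the scaled semantics of a
#' `bwa mem -A2 -O3 -E1` alignment); both the read and its reverse
#' complement are tried and the better score kept, so classification is
#' orientation-invariant. Indels are left-normalized against the
#' reference. Reads aligning below 60 percent identity are flagged
#' unaligned.
#'
#' @param read read sequence.
#' @param ref an [amplicon_ref()].
#' @param min_identity identity floor (fraction of alignment columns).
#' @return list: status ("aligned"/"unaligned"), indels (data.frame pos,
#'   len, kind, seq in 0-based reference coordinates, left-normalized),
#'   ref_start/ref_end (aligned reference span), identity, orientation,
#'   aligned_read (read characters per alignment column).
#' @export
align_read <- function(read, ref, min_identity = 0.6) {
  align_reads_batch(read, ref, min_identity)[[1]]
}

.align_cache <- new.env(parent = emptyenv())
nuc_submat <- function() {
  if (is.null(.align_cache$mat)) {
    .align_cache$mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -2, baseOnly = FALSE)
  }
  .align_cache$mat
}

#' Align a batch of reads to an amplicon reference
#'
#' Vectorized form of [align_read()] (one alignment call per orientation
#' for the whole batch); identical per-read results.
#'
#' @param reads character vector of reads.
#' @param ref an [amplicon_ref()].
#' @param min_identity identity floor.
#' @return list of per-read alignment results (see [align_read()]).
#' @export
align_reads_batch <- function(reads, ref, min_identity = 0.6) {
  reads <- toupper(reads)
  if (any(nchar(reads) < 30)) stop("read shorter than 30 bp", call. = FALSE)
  refseq <- ref$sequence
  subj <- Biostrings::DNAString(refseq)
  fwd <- Biostrings::DNAStringSet(reads)
  rev <- Biostrings::reverseComplement(fwd)
  do_align <- function(set) {
    Biostrings::pairwiseAlignment(
      set, subj, type = "global-local", substitutionMatrix = nuc_submat(),
      gapOpening = 5, gapExtension = 1)
  }
  al_f <- do_align(fwd)
  al_r <- do_align(rev)
  use_rev <- Biostrings::score(al_r) > Biostrings::score(al_f)
  pat_str <- ifelse(use_rev,
                    as.character(Biostrings::pattern(al_r)),
                    as.character(Biostrings::pattern(al_f)))
  sub_str <- ifelse(use_rev,
                    as.character(Biostrings::subject(al_r)),
                    as.character(Biostrings::subject(al_f)))
  off <- ifelse(use_rev,
                BiocGenerics::start(Biostrings::subject(al_r)),
                BiocGenerics::start(Biostrings::subject(al_f))) - 1L
  ref_chars <- seq_chars(refseq)
  lapply(seq_along(reads), function(i) {
    parse_alignment(pat_str[i], sub_str[i], off[i], ref_chars,
                    min_identity,
                    orientation = if (use_rev[i]) "-" else "+")
  })
}

# walk one gapped alignment, emitting left-normalized indels
parse_alignment <- function(pat_str, sub_str, ref_offset, ref_chars,
                            min_identity, orientation) {
  pat <- seq_chars(pat_str)
  sub <- seq_chars(sub_str)
  ident <- sum(pat == sub & pat != "-") / length(pat)
  if (ident < min_identity) {
    return(list(status = "unaligned", indels = NULL, identity = ident,
                orientation = orientation))
  }
  ref_pos <- ref_offset + cumsum(sub != "-")  # 1-based ref residue per col
  indels <- list()
  i <- 1
  ncol <- length(pat)
  while (i <= ncol) {
    if (sub[i] == "-") {            # insertion in read
      j <- i
      while (j < ncol && sub[j + 1] == "-") j <- j + 1
      ins_seq <- paste(pat[i:j], collapse = "")
      pos0 <- ref_pos[i]            # 0-based insertion point
      indels[[length(indels) + 1]] <-
        left_normalize_indel(ref_chars, pos0, j - i + 1L, "ins", ins_seq)
      i <- j + 1
    } else if (pat[i] == "-") {     # deletion from reference
      j <- i
      while (j < ncol && pat[j + 1] == "-") j <- j + 1
      pos0 <- ref_pos[i] - 1L       # 0-based first deleted base
      indels[[length(indels) + 1]] <-
        left_normalize_indel(ref_chars, pos0, j - i + 1L, "del")
      i <- j + 1
    } else i <- i + 1
  }
  indel_df <- if (length(indels) == 0) {
    data.frame(pos = integer(), len = integer(), kind = character(),
               seq = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(indels, function(x) {
      data.frame(pos = x$pos, len = x$len, kind = x$kind, seq = x$seq,
                 stringsAsFactors = FALSE)
    }))
  }
  list(status = "aligned", indels = indel_df,
       ref_start = ref_offset, ref_end = ref_offset + sum(sub != "-"),
       identity = ident, orientation = orientation,
       columns = list(pat = pat, sub = sub, ref_pos = ref_pos))
}

# does an indel overlap the half-open window [a, b)?
indel_in_window <- function(pos, len, kind, a, b) {
  if (kind == "del") pos < b && (pos + len) > a
  else pos >= a && pos < b        # insertion: point event at its ref pos
}

#' Classify an aligned read as edited or unedited
#'
#' Nuclease rule: a read is edited when at least one indel overlaps the
#' quantification window `[cut - w/2, cut + w/2)`; substitutions alone
#' never count (sequencing-error tolerance). The allele key is the
#' read's base string over the reference window (insertions inside the
#' window included), so unedited reads key to the reference window
#' sequence.
#'
#' @param alignment result of [align_read()].
#' @param ref the [amplicon_ref()].
#' @param read_id read identifier carried into the call.
#' @return list of class `read_call`: read_id, status ("edited",
#'   "unedited", "unaligned"), indels, allele_key.
#' @export
classify_read <- function(alignment, ref, read_id = NA_character_) {
  w <- ref$window_width
  a <- ref$expected_cut - w %/% 2
  b <- a + w
  if (alignment$status == "unaligned") {
    return(structure(list(read_id = read_id, status = "unaligned",
                          indels = NULL, allele_key = NA_character_),
                     class = "read_call"))
  }
  ind <- alignment$indels
  hit <- FALSE
  if (nrow(ind) > 0) {
    hit <- any(vapply(seq_len(nrow(ind)), function(i) {
      indel_in_window(ind$pos[i], ind$len[i], ind$kind[i], a, b)
    }, logical(1)))
  }
  # window-local allele string from alignment columns
  cols <- alignment$columns
  ref0 <- cols$ref_pos - 1                     # 0-based ref base per column
  in_win <- (cols$sub != "-" & ref0 >= a & ref0 < b) |
    (cols$sub == "-" & cols$ref_pos >= a & cols$ref_pos < b)
  key_chars <- cols$pat[in_win]
  allele_key <- paste(key_chars[key_chars != "-"], collapse = "")
  structure(list(read_id = read_id,
                 status = if (hit) "edited" else "unedited",
                 indels = ind, allele_key = allele_key),
            class = "read_call")
}

#' Summarize editing outcomes over a set of read calls
#'
#' The indel frequency is `100 * n_edited / (n_total - n_unaligned)`.
#' The allele table reports the top `top_n` window-local alleles among
#' aligned reads; deletion centers are the midpoints of deletions,
#' re-expressed in bp downstream of the PAM 3' end (the effectors this
#' toolkit targets cut PAM-distal, so centers typically fall beyond the
#' protospacer end).
#'
#' @param read_calls list of `read_call` objects.
#' @param ref the [amplicon_ref()].
#' @param top_n alleles reported.
#' @return list of class `editing_summary`: n_total, n_unaligned, n_edited,
#'   indel_frequency (percent), allele_table (data.frame allele, n, pct,
#'   edited), deletion_centers (table), deletion_sizes (table).
#' @export
summarize_edits <- function(read_calls, ref, top_n = 10L) {
  n_total <- length(read_calls)
  status <- vapply(read_calls, function(x) x$status, "")
  n_unaligned <- sum(status == "unaligned")
  n_aligned <- n_total - n_unaligned
  if (n_aligned == 0) stop("zero aligned reads", call. = FALSE)
  n_edited <- sum(status == "edited")

  aligned <- read_calls[status != "unaligned"]
  keys <- vapply(aligned, function(x) x$allele_key, "")
  edited_flag <- vapply(aligned, function(x) x$status == "edited",
                        logical(1))
  tab <- sort(table(keys), decreasing = TRUE)
  allele_table <- data.frame(
    allele = names(tab), n = as.integer(tab),
    pct = 100 * as.integer(tab) / n_aligned,
    edited = vapply(names(tab), function(k) {
      any(edited_flag[keys == k])
    }, logical(1)),
    stringsAsFactors = FALSE)
  rownames(allele_table) <- NULL
  allele_table <- head(allele_table, top_n)

  centers <- numeric(); sizes <- integer()
  for (x in aligned) {
    ind <- x$indels
    if (is.null(ind) || nrow(ind) == 0) next
    del <- ind[ind$kind == "del", , drop = FALSE]
    if (nrow(del) == 0) next
    centers <- c(centers, del$pos + del$len / 2 - ref$pam_end)
    sizes <- c(sizes, del$len)
  }
  structure(list(
    n_total = n_total, n_unaligned = n_unaligned, n_edited = n_edited,
    indel_frequency = 100 * n_edited / n_aligned,
    allele_table = allele_table,
    deletion_centers = table(centers), deletion_sizes = table(sizes)
  ), class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat("Editing summary:", x$n_total, "reads (", x$n_unaligned,
      "unaligned )\n")
  cat(sprintf("  indel frequency: %.1f%% (%d edited / %d aligned)\n",
              x$indel_frequency, x$n_edited, x$n_total - x$n_unaligned))
  cat("  top alleles:\n")
  print(head(x$allele_table, 5), row.names = FALSE)
  invisible(x)
}

#' Quantify editing outcomes from reads against an amplicon reference
#'
#' Convenience wrapper: align, classify, summarize.
#'
#' @param reads named character vector of reads, or a FASTQ path.
#' @param ref an [amplicon_ref()].
#' @param top_n alleles reported.
#' @param min_identity passed to [align_read()].
#' @return an `editing_summary`; per-read calls in attribute `calls`.
#' @export
quantify_edits <- function(reads, ref, top_n = 10L, min_identity = 0.6) {
  if (length(reads) == 1 && file.exists(reads)) reads <- read_fastq(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  alns <- align_reads_batch(unname(reads), ref, min_identity)
  calls <- lapply(seq_along(reads), function(i) {
    classify_read(alns[[i]], ref, names(reads)[i])
  })
  out <- summarize_edits(calls, ref, top_n)
  attr(out, "calls") <- calls
  out
}
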