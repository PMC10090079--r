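# Karlin-Altschul parameters for gapped BLOSUM62 (gap open 11, extend 1),
# the standard constants used by gapped protein BLAST.
KA_LAMBDA <- 0.267
KA_K <- 0.041

# shared k-mer seed: TRUE if query and subject proteins share any k-mer
shares_kmer <- function(a, b, k = 4L) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  ka <- unique(substring(a, seq_len(nchar(a) - k + 1),
                         seq_len(nchar(a) - k + 1) + k - 1))
  kb <- unique(substring(b, seq_len(nchar(b) - k + 1),
                         seq_len(nchar(b) - k + 1) + k - 1))
  any(ka %in% kb)
}

#' Score protein homology with a Karlin-Altschul E-value
#'
#' Built-in homology gate: a shared 4-mer seed followed by local alignment
#' (BLOSUM62, affine gaps 11/1), converted to an E-value with the standard
#' Karlin-Altschul formula E = K m n exp(-lambda S) using gapped BLOSUM62
#' constants. Pairs without a shared seed k-mer score E = Inf.
#'
#' @param query,subject amino-acid strings.
#' @param seed_k seed k-mer length.
#' @return list with `score` (alignment bit-less raw score) and `evalue`.
#' @export
protein_evalue <- function(query, subject, seed_k = 4L) {
  if (!shares_kmer(query, subject, seed_k)) {
    return(list(score = 0, evalue = Inf))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  s <- Biostrings::score(al)
  e <- KA_K * nchar(query) * nchar(subject) * exp(-KA_LAMBDA * s)
  list(score = s, evalue = e)
}

#' Scan a genome for Cas12f candidate genes
#'
#' Applies the two gates used for compact type V-F effector mining: a
#' translated-homology gate against reference Cas12f proteins (default
#' E <= 1e-10) and a protein size gate (default 400-700 aa). Only ORFs
#' passing both gates are returned.
#'
#' @param genome named character vector of contigs (as from [read_fasta()]).
#' @param reference_proteins named character vector of reference Cas12f
#'   amino-acid sequences.
#' @param gate_threshold maximum E-value.
#' @param size_range protein length bounds in aa, inclusive.
#' @param min_scan_aa minimum ORF length (aa) considered at all.
#' @param homology_fn pluggable gate: function(query_protein,
#'   reference_protein) returning list(score, evalue). Defaults to the
#'   built-in [protein_evalue()]; see [tblastn_gate()] for an external
#'   translated-search adapter.
#' @return data.frame of candidates, sorted by contig then start, with
#'   columns contig_id, start, end, strand, protein, protein_len,
#'   best_reference_id, evalue, passed_size_gate.
#' @export
scan_cas_candidates <- function(genome, reference_proteins,
                                gate_threshold = 1e-10,
                                size_range = c(400L, 700L),
                                min_scan_aa = 100L,
                                homology_fn = protein_evalue) {
  if (length(reference_proteins) == 0) {
    stop("config error: no reference proteins supplied", call. = FALSE)
  }
  if (is.null(names(reference_proteins))) {
    names(reference_proteins) <- paste0("ref", seq_along(reference_proteins))
  }
  rows <- list()
  for (cid in names(genome)) {
    orfs <- find_orfs(genome[cid], min_len_aa = min_scan_aa, contig_id = cid)
    if (nrow(orfs) == 0) next
    for (i in seq_len(nrow(orfs))) {
      prot <- orfs$protein[i]
      best_e <- Inf; best_ref <- NA_character_
      for (rid in names(reference_proteins)) {
        h <- homology_fn(prot, reference_proteins[[rid]])
        if (h$evalue < best_e) { best_e <- h$evalue; best_ref <- rid }
      }
      size_ok <- nchar(prot) >= size_range[1] && nchar(prot) <= size_range[2]
      if (best_e <= gate_threshold && size_ok) {
        rows[[length(rows) + 1]] <- data.frame(
          contig_id = cid, start = orfs$start[i], end = orfs$end[i],
          strand = orfs$strand[i], protein = prot,
          protein_len = nchar(prot), best_reference_id = best_ref,
          evalue = best_e, passed_size_gate = size_ok,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      protein = character(), protein_len = integer(),
                      best_reference_id = character(), evalue = numeric(),
                      passed_size_gate = logical(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$contig_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Check conserved RuvC catalytic aspartates by alignment position mapping
#'
#' Globally aligns a candidate protein to a reference (BLOSUM62, affine
#' gaps) and maps each catalytic reference position through the alignment;
#' a position is `present` when the candidate carries an aspartate (D) at
#' the mapped column. `ruvc_ok` requires all positions present. Alignments
#' covering less than half of the reference are reported with
#' `low_coverage = TRUE` and `ruvc_ok = FALSE`.
#'
#' For the two compact effectors characterized in this toolkit's domain the
#' catalytic pairs are D228/D406 (433-aa Oscillibacter-type) and D210/D388
#' (415-aa Ruminiclostridium-type); alanine substitution at any of these
#' abolishes nuclease activity.
#'
#' @param candidate_protein amino-acid string to check.
#' @param reference_protein reference amino-acid string.
#' @param catalytic_positions integer vector of 1-based reference positions.
#' @param znf_motif optional regular expression for a C4-type zinc-finger
#'   motif scan (experimental); NULL skips the scan.
#' @return list with elements positions (data.frame reference_position,
#'   candidate_position, residue, present), ruvc_ok, znf_ok, low_coverage,
#'   coverage.
#' @export
check_ruvc_motif <- function(candidate_protein, reference_protein,
                             catalytic_positions,
                             znf_motif = "C..C.{8,40}C..C") {
  stopifnot(length(catalytic_positions) >= 1)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(candidate_protein),
    Biostrings::AAString(reference_protein),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  pat <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  sub <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  ref_pos <- cumsum(sub != "-")      # reference residue index per column
  cand_pos <- cumsum(pat != "-")
  aligned_ref <- sum(sub != "-" & pat != "-")
  coverage <- aligned_ref / nchar(reference_protein)

  rows <- lapply(sort(catalytic_positions), function(p) {
    col <- which(sub != "-" & ref_pos == p)
    if (length(col) == 0 || pat[col] == "-") {
      data.frame(reference_position = p, candidate_position = NA_integer_,
                 residue = NA_character_, present = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(reference_position = p, candidate_position = cand_pos[col],
                 residue = pat[col], present = pat[col] == "D",
                 stringsAsFactors = FALSE)
    }
  })
  positions <- do.call(rbind, rows)
  low_coverage <- coverage < 0.5
  znf_ok <- if (is.null(znf_motif)) NA else
    grepl(znf_motif, candidate_protein)
  list(positions = positions,
       ruvc_ok = all(positions$present) && !low_coverage,
       znf_ok = znf_ok, low_coverage = low_coverage, coverage = coverage)
}

#' Detect CRISPR repeat-spacer arrays
#'
#' Seed-and-extend detector in the CRT family: an exact seed k-mer repeated
#' within a bounded lookahead is extended to the maximal exact repeat of the
#' first two copies, then further copies are chained up- and downstream
#' under spacer-length and mismatch constraints. The consensus repeat is the
#' column-majority over aligned copies (ties broken toward the
#' lexicographically smallest base). Arrays are reported
#' orientation-agnostic (`orientation_resolved = FALSE`); polarity is
#' resolved downstream by the anti-repeat scan.
#'
#' @param record contig sequence (named or plain character).
#' @param repeat_len allowed repeat-unit length range (bp).
#' @param spacer_len allowed spacer length range (bp).
#' @param min_repeats minimum number of repeat copies.
#' @param max_mismatch_frac per-copy mismatch budget against the consensus.
#' @param seed_len exact seed length.
#' @param lookahead allowed distance range between seed start positions.
#' @param contig_id contig id used in output.
#' @return list of arrays; each is a list with contig_id, start, end,
#'   repeats (data.frame start, end, sequence), spacers (data.frame),
#'   consensus_repeat, n_repeats, orientation_resolved.
#' @export
find_crispr_arrays <- function(record,
                               repeat_len = c(18L, 45L),
                               spacer_len = c(15L, 60L),
                               min_repeats = 2L,
                               max_mismatch_frac = 0.2,
                               seed_len = 8L,
                               lookahead = c(16L, 105L),
                               contig_id = NULL) {
  if (is.null(contig_id)) {
    contig_id <- if (!is.null(names(record))) names(record)[1] else "contig"
  }
  s <- check_alphabet(unname(record[1]), what = "contig")
  ch <- seq_chars(s)
  L <- length(ch)
  if (L < 2 * repeat_len[1] + spacer_len[1]) return(list())

  # enumerate exact seed pairs (i, j), 0-based starts, j - i within lookahead
  n_seed_pos <- L - seed_len + 1
  if (n_seed_pos < 2) return(list())
  kmers <- substring(s, 1:n_seed_pos, 1:n_seed_pos + seed_len - 1)
  seeds <- list()
  by_kmer <- split(0:(n_seed_pos - 1), kmers)
  for (pos in by_kmer) {
    if (length(pos) < 2) next
    prs <- combn(pos, 2)
    d <- prs[2, ] - prs[1, ]
    keep <- d >= lookahead[1] & d <= lookahead[2]
    if (any(keep)) seeds[[length(seeds) + 1]] <- prs[, keep, drop = FALSE]
  }
  if (length(seeds) == 0) return(list())
  seeds <- do.call(cbind, seeds)
  ord <- order(seeds[1, ], seeds[2, ])
  seeds <- seeds[, ord, drop = FALSE]

  hamming <- function(a0, b0, len) {
    sum(ch[(a0 + 1):(a0 + len)] != ch[(b0 + 1):(b0 + len)])
  }

  arrays <- list()
  seen_keys <- character()
  for (si in seq_len(ncol(seeds))) {
    i <- seeds[1, si]; j <- seeds[2, si]
    # extend the exact match of the first two copies
    l <- 0L
    while (i - l - 1 >= 0 && ch[i - l] == ch[j - l]) l <- l + 1L
    r <- seed_len
    while (i + r < j - l && j + r < L && ch[i + r + 1] == ch[j + r + 1]) {
      r <- r + 1L
    }
    u_start <- i - l; u_len <- l + r
    if (u_len < repeat_len[1] || u_len > repeat_len[2]) next
    v_start <- j - l
    spc <- v_start - (u_start + u_len)
    if (spc < spacer_len[1] || spc > spacer_len[2]) next
    unit <- substr(s, u_start + 1, u_start + u_len)
    budget <- floor(max_mismatch_frac * u_len)

    copies <- c(u_start, v_start)
    # chain downstream
    repeat {
      last <- copies[length(copies)]
      lo <- last + u_len + spacer_len[1]
      hi <- min(last + u_len + spacer_len[2], L - u_len)
      if (lo > hi) break
      cand <- lo:hi
      dists <- vapply(cand, function(q) hamming(q, u_start, u_len), 0)
      ok <- which(dists <= budget)
      if (length(ok) == 0) break
      best <- ok[which.min(dists[ok])]  # min mismatches, tie -> leftmost
      copies <- c(copies, cand[best])
    }
    # chain upstream
    repeat {
      first <- copies[1]
      hi <- first - u_len - spacer_len[1]
      lo <- max(first - u_len - spacer_len[2], 0L)
      if (hi < lo) break
      cand <- lo:hi
      dists <- vapply(cand, function(q) hamming(q, u_start, u_len), 0)
      ok <- which(dists <= budget)
      if (length(ok) == 0) break
      best <- ok[which.min(dists[ok])]
      copies <- c(cand[best], copies)
    }
    if (length(copies) < min_repeats) next
    key <- paste(c(u_len, copies), collapse = ",")
    if (key %in% seen_keys) next
    seen_keys <- c(seen_keys, key)
    arrays[[length(arrays) + 1]] <- list(copies = copies, u_len = u_len)
  }
  if (length(arrays) == 0) return(list())

  # rank candidate arrays: more copies, then longer repeat, then leftmost;
  # select greedily non-overlapping
  score <- vapply(arrays, function(a) {
    length(a$copies) * 1e9 + a$u_len * 1e4 - a$copies[1] / L
  }, 0)
  ord <- order(-score)
  chosen <- list()
  occupied <- integer(0)
  for (k in ord) {
    a <- arrays[[k]]
    span <- (a$copies[1] + 1):(a$copies[length(a$copies)] + a$u_len)
    if (length(intersect(span, occupied)) > 0) next
    occupied <- c(occupied, span)
    chosen[[length(chosen) + 1]] <- a
  }
  chosen <- chosen[order(vapply(chosen, function(a) a$copies[1], 0))]

  lapply(chosen, function(a) {
    rep_seqs <- substring(s, a$copies + 1, a$copies + a$u_len)
    cons <- consensus_majority(rep_seqs)
    n <- length(a$copies)
    sp_start <- a$copies[-n] + a$u_len
    sp_end <- a$copies[-1]
    structure(list(
      contig_id = contig_id,
      start = a$copies[1],
      end = a$copies[n] + a$u_len,
      repeats = data.frame(start = a$copies, end = a$copies + a$u_len,
                           sequence = rep_seqs, stringsAsFactors = FALSE),
      spacers = data.frame(start = sp_start, end = sp_end,
                           sequence = substring(s, sp_start + 1, sp_end),
                           stringsAsFactors = FALSE),
      consensus_repeat = cons,
      n_repeats = n,
      orientation_resolved = FALSE,
      strand = NA_character_
    ), class = "crispr_array")
  })
}

# column-majority consensus over equal-length strings; ties to the
# lexicographically smallest base
consensus_majority <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  paste(apply(m, 2, function(col) {
    tab <- table(col)
    names(tab)[tab == max(tab)][1]  # table() is alphabetical
  }), collapse = "")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat("CRISPR array on", x$contig_id,
      sprintf("[%d,%d)", x$start, x$end), "\n")
  cat("  ", x$n_repeats, "repeats,", nrow(x$spacers), "spacers;",
      "consensus repeat:", x$consensus_repeat, "\n")
  invisible(x)
}

#' Pair Cas12f candidates with nearby CRISPR arrays into locus models
#'
#' Each candidate is paired with the nearest array on the same contig within
#' `max_distance` of the gene boundary (native compact-system gene
#' organization: effector gene adjacent to its array). The noncoding region
#' between gene and array - minus any intervening ORF of at least
#' `min_orf_excise_aa` codons - is retained for the anti-repeat scan.
#'
#' @param candidates data.frame from [scan_cas_candidates()].
#' @param arrays list of arrays from [find_crispr_arrays()] (all contigs).
#' @param genome named contig vector (needed for intervening-ORF excision).
#' @param max_distance maximum gene-to-array distance in bp.
#' @param min_orf_excise_aa intervening ORFs at least this long (codons) are
#'   excised from the noncoding region.
#' @return list of locus models: cas (one-row data.frame), array,
#'   cas_array_distance, noncoding_regions (data.frame start/end, forward
#'   contig coordinates).
#' @export
pair_locus <- function(candidates, arrays, genome,
                       max_distance = 10000L, min_orf_excise_aa = 100L) {
  loci <- list()
  if (nrow(candidates) == 0 || length(arrays) == 0) return(loci)
  arr_contigs <- vapply(arrays, function(a) a$contig_id, "")
  for (i in seq_len(nrow(candidates))) {
    cas <- candidates[i, , drop = FALSE]
    same <- which(arr_contigs == cas$contig_id)
    if (length(same) == 0) {
      toolkit_log("candidate at ", cas$contig_id, ":", cas$start,
                  " has no array on its contig; dropped",
                  module = "locus_miner")
      next
    }
    dists <- vapply(same, function(k) {
      a <- arrays[[k]]
      if (a$start >= cas$end) as.integer(a$start - cas$end)
      else if (cas$start >= a$end) as.integer(cas$start - a$end)
      else 0L
    }, 0L)
    best <- same[which.min(dists)]
    d <- min(dists)
    if (d > max_distance) {
      toolkit_log("candidate at ", cas$contig_id, ":", cas$start,
                  " nearest array is ", d, " bp away (> max_distance); dropped",
                  module = "locus_miner")
      next
    }
    a <- arrays[[best]]
    gap <- if (a$start >= cas$end) c(cas$end, a$start) else c(a$end, cas$start)
    nc <- data.frame(start = gap[1], end = gap[2])
    if (nc$end > nc$start) {
      contig_seq <- genome[[cas$contig_id]]
      region <- substr(contig_seq, nc$start + 1, nc$end)
      orfs <- find_orfs(region, min_len_aa = min_orf_excise_aa,
                        contig_id = cas$contig_id)
      if (nrow(orfs) > 0) {
        cut <- IRanges::IRanges(start = orfs$start + nc$start + 1,
                                end = orfs$end + nc$start)
        full <- IRanges::IRanges(start = nc$start + 1, end = nc$end)
        kept <- IRanges::setdiff(full, IRanges::reduce(cut))
        nc <- data.frame(start = IRanges::start(kept) - 1,
                         end = IRanges::end(kept))
      }
    } else {
      nc <- data.frame(start = integer(), end = integer())
    }
    loci[[length(loci) + 1]] <- structure(list(
      cas = cas, array = a, cas_array_distance = d,
      noncoding_regions = nc
    ), class = "locus_model")
  }
  loci
}

#' @export
print.locus_model <- function(x, ...) {
  cat("Cas12f locus model on", x$cas$contig_id, "\n")
  cat(sprintf("  cas gene [%d,%d) %s, %d aa, E=%.3g (ref %s)\n",
              x$cas$start, x$cas$end, x$cas$strand, x$cas$protein_len,
              x$cas$evalue, x$cas$best_reference_id))
  cat(sprintf("  array [%d,%d), %d repeats; distance %d bp\n",
              x$array$start, x$array$end, x$array$n_repeats,
              x$cas_array_distance))
  invisible(x)
}

#' External translated-homology adapter (TBLASTN)
#'
#' Runs `tblastn` (must be on PATH) with the reference proteins as queries
#' against a nucleotide FASTA, returning the tabular fields the pipeline's
#' homology-gate contract expects. Intended for production-scale mining;
#' all tests use the built-in gate.
#'
#' @param reference_faa path to reference protein FASTA.
#' @param genome_fna path to nucleotide FASTA.
#' @param evalue E-value cutoff passed to tblastn.
#' @return data.frame with columns qid, sid, evalue, sstart, send (1-based,
#'   as reported by BLAST).
#' @export
tblastn_gate <- function(reference_faa, genome_fna, evalue = 1e-10) {
  if (Sys.which("tblastn") == "") {
    stop("tblastn not found on PATH", call. = FALSE)
  }
  out <- system2("tblastn",
                 c("-query", shQuote(reference_faa),
                   "-subject", shQuote(genome_fna),
                   "-evalue", format(evalue, scientific = TRUE),
                   "-outfmt", shQuote("6 qseqid sseqid evalue sstart send")),
                 stdout = TRUE)
  if (length(out) == 0) {
    return(data.frame(qid = character(), sid = character(),
                      evalue = numeric(), sstart = integer(),
                      send = integer(), stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(text = paste(out, collapse = "\n"), header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("qid", "sid", "evalue", "sstart", "send")
  df
}
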