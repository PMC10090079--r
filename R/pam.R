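#' Configuration for a randomized-PAM library
#'
#' Describes where the randomized block sits in each read: the fixed
#' upstream flank that anchors the read, the offset from the flank's 3' end
#' to the randomized block, and the library readout mode. The default
#' models a 7-bp randomized block immediately downstream of the anchor
#' (upstream of the fixed protospacer), read out from cleaved products.
#'
#' @param k randomized block length.
#' @param flank fixed anchoring sequence (upstream of the block), >= 8 bp.
#' @param offset distance from flank 3' end to the block start.
#' @param max_mismatch mismatches tolerated when locating the flank.
#' @param mode "product_enriched" (cleaved products sequenced) or
#'   "survivor_depleted" (uncut library sequenced; active PAMs deplete).
#' @return list of class `pam_library_config`.
#' @export
pam_library_config <- function(k = 7L, flank = "GGTCTCTACCT", offset = 0L,
                               max_mismatch = 1L,
                               mode = c("product_enriched",
                                        "survivor_depleted")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1, nchar(flank) >= 8, offset >= 0)
  structure(list(k = as.integer(k), flank = toupper(flank),
                 offset = as.integer(offset),
                 max_mismatch = as.integer(max_mismatch), mode = mode),
            class = "pam_library_config")
}

#' Tally randomized PAM k-mers from anchored reads
#'
#' Locates the fixed flank in each read (tolerating `max_mismatch`
#' mismatches; first match wins) and tallies the k-mer at the anchored
#' offset. Reads without the anchor are skipped and counted; k-mers
#' containing N are skipped and counted.
#'
#' @param reads character vector of reads, or a FASTQ path.
#' @param config a [pam_library_config()].
#' @return list of class `pam_counts`: counts (named integer vector),
#'   total, skipped_no_anchor, skipped_n.
#' @export
count_pam_kmers <- function(reads, config = pam_library_config()) {
  if (length(reads) == 1 && file.exists(reads)) reads <- read_fastq(reads)
  reads <- toupper(reads)
  k <- config$k
  fl <- nchar(config$flank)
  # exact anchor first (fast path); mismatch-tolerant search only on the rest
  anchor_at <- regexpr(config$flank, reads, fixed = TRUE)
  misses <- which(anchor_at < 0)
  if (length(misses) > 0 && config$max_mismatch > 0) {
    hits <- Biostrings::vmatchPattern(config$flank,
                                      Biostrings::DNAStringSet(reads[misses]),
                                      max.mismatch = config$max_mismatch)
    for (ii in seq_along(misses)) {
      st <- BiocGenerics::start(hits[[ii]])
      if (length(st) > 0) anchor_at[misses[ii]] <- st[1]
    }
  }
  p <- as.integer(anchor_at) + fl + config$offset  # 1-based k-mer start
  anchored <- anchor_at > 0 & p + k - 1 <= nchar(reads)
  skipped_anchor <- sum(!anchored)
  kmers <- substr(reads, p, p + k - 1)
  has_n <- grepl("N", kmers, fixed = TRUE)
  skipped_n <- sum(anchored & has_n)
  keep <- anchored & !has_n
  counts <- table(kmers[keep])
  counts <- setNames(as.integer(counts), names(counts))
  if (sum(keep) == 0) {
    warning("no anchored reads; empty PAM counts", call. = FALSE)
  }
  structure(list(counts = counts, total = sum(counts),
                 skipped_no_anchor = skipped_anchor, skipped_n = skipped_n),
            class = "pam_counts")
}

#' Rank PAM k-mers by treated/control enrichment
#'
#' Enrichment of k-mer x is the pseudocounted frequency ratio
#' ((treated_x + p) / treated_total) / ((control_x + p) / control_total),
#' sorted descending with lexicographic tie-break. In
#' `survivor_depleted` mode the ratio is inverted, so active PAMs (depleted
#' from survivors) still rank first. The two modes produce reciprocal
#' rankings on the same data.
#'
#' @param treated,control `pam_counts` objects.
#' @param pseudocount additive pseudocount p > 0.
#' @param mode see [pam_library_config()].
#' @return data.frame with columns kmer, score, treated_count,
#'   control_count, in rank order.
#' @export
pam_enrich <- function(treated, control, pseudocount = 0.5,
                       mode = c("product_enriched", "survivor_depleted")) {
  mode <- match.arg(mode)
  stopifnot(pseudocount > 0)
  if (treated$total == 0 && control$total == 0) {
    stop("both libraries are empty", call. = FALSE)
  }
  kmers <- sort(union(names(treated$counts), names(control$counts)))
  tc <- ifelse(kmers %in% names(treated$counts),
               treated$counts[kmers], 0L)
  cc <- ifelse(kmers %in% names(control$counts),
               control$counts[kmers], 0L)
  tc[is.na(tc)] <- 0L; cc[is.na(cc)] <- 0L
  score <- ((tc + pseudocount) / max(treated$total, 1)) /
    ((cc + pseudocount) / max(control$total, 1))
  if (mode == "survivor_depleted") score <- 1 / score
  df <- data.frame(kmer = kmers, score = score, treated_count = as.integer(tc),
                   control_count = as.integer(cc), stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$kmer), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Restrict a PAM ranking to supported, enriched k-mers
#'
#' A k-mer observed a single time in the product library can be carryover
#' or sequencing noise; this filter keeps k-mers with at least
#' `min_treated` product reads and at least `min_score`-fold enrichment
#' before profile building. With sparse PAM preferences (few truly active
#' k-mers) this prevents the fixed top-K window from padding the profile
#' with background.
#'
#' @param ranked data.frame from [pam_enrich()].
#' @param min_score minimum enrichment score.
#' @param min_treated minimum treated (product) read count.
#' @return the filtered ranking, order preserved.
#' @export
enriched_kmers <- function(ranked, min_score = 2, min_treated = 2L) {
  ranked[ranked$score >= min_score & ranked$treated_count >= min_treated, ,
         drop = FALSE]
}

#' Build a PAM profile from the top-ranked k-mers
#'
#' The top `top_k` k-mers (default 1000, matching the convention of drawing
#' PAM logos from the top 1000 enriched sequences) contribute unweighted to
#' a position frequency matrix; per-position information content is
#' 2 + sum_b f log2 f (bits), and the IUPAC consensus comes from
#' [call_consensus()]. A count-weighted PFM is available via `weighted`.
#'
#' @param ranked data.frame from [pam_enrich()].
#' @param top_k number of top k-mers used.
#' @param weighted weight k-mers by treated counts instead of equally.
#' @param include_fraction,trim_ic passed to [call_consensus()].
#' @return list of class `pam_profile`: ranked (the rows used), pfm (4 x k
#'   matrix, columns sum to 1), information_content, consensus, top_k.
#' @export
build_pam_profile <- function(ranked, top_k = 1000L, weighted = FALSE,
                              include_fraction = 0.5, trim_ic = 0.3) {
  if (nrow(ranked) == 0) stop("empty ranking", call. = FALSE)
  if (top_k > nrow(ranked)) {
    toolkit_log("only ", nrow(ranked), " distinct k-mers available; ",
                "using all", module = "pam_profiler")
    top_k <- nrow(ranked)
  }
  use <- ranked[seq_len(top_k), , drop = FALSE]
  k <- nchar(use$kmer[1])
  m <- do.call(rbind, strsplit(use$kmer, "", fixed = TRUE))
  w <- if (weighted) use$treated_count else rep(1, nrow(use))
  pfm <- sapply(seq_len(k), function(j) {
    f <- vapply(c("A", "C", "G", "T"),
                function(b) sum(w[m[, j] == b]), 0)
    f / sum(f)
  })
  rownames(pfm) <- c("A", "C", "G", "T")
  ic <- apply(pfm, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  structure(list(
    ranked = use, pfm = pfm, information_content = ic,
    consensus = call_consensus(pfm, include_fraction, trim_ic),
    top_k = top_k
  ), class = "pam_profile")
}

#' @export
print.pam_profile <- function(x, ...) {
  cat("PAM profile over top", x$top_k, "k-mers\n")
  cat("  consensus:", x$consensus, "\n")
  cat("  information content (bits):",
      paste(sprintf("%.2f", x$information_content), collapse = " "), "\n")
  invisible(x)
}

#' Call an IUPAC consensus from a position frequency matrix
#'
#' At each position, bases with frequency at least `include_fraction` times
#' the maximum base frequency are kept and collapsed to their IUPAC code.
#' Leading and trailing positions with information content below `trim_ic`
#' bits are rendered N (reported but flagged uninformative via the
#' `uninformative` attribute).
#'
#' @param pfm 4 x k matrix with rows A, C, G, T, columns summing to 1.
#' @param include_fraction inclusion threshold relative to the max base.
#' @param trim_ic information-content floor (bits) for edge positions.
#' @return IUPAC string with attribute `uninformative` (logical vector).
#' @export
call_consensus <- function(pfm, include_fraction = 0.5, trim_ic = 0.3) {
  if (length(pfm) == 0 || ncol(pfm) == 0) stop("empty pfm", call. = FALSE)
  codes <- apply(pfm, 2, function(f) {
    keep <- names(f)[f >= include_fraction * max(f)]
    bases_to_iupac(keep)
  })
  ic <- apply(pfm, 2, function(f) { f <- f[f > 0]; 2 + sum(f * log2(f)) })
  uninformative <- rep(FALSE, length(codes))
  for (i in seq_along(codes)) {            # leading low-IC run
    if (ic[i] < trim_ic) uninformative[i] <- TRUE else break
  }
  for (i in rev(seq_along(codes))) {       # trailing low-IC run
    if (ic[i] < trim_ic) uninformative[i] <- TRUE else break
  }
  codes[uninformative] <- "N"
  structure(paste(codes, collapse = ""), uninformative = uninformative)
}

#' Profile cleavage positions from run-off read ends
#'
#' Re-expresses per-strand read-end (cut) positions as bp downstream of the
#' PAM 3' boundary and summarizes: per-strand histograms, modal positions,
#' modal overhang (absolute difference of strand modes; 0 means blunt), and
#' the overall position range. A strand with no observations yields an
#' empty histogram and an undefined (NA) overhang, flagged.
#'
#' @param nt_positions cut positions on the non-target strand (reference
#'   coordinates, 0-based).
#' @param t_positions cut positions on the target strand.
#' @param pam_end reference coordinate of the PAM 3' boundary (0-based,
#'   exclusive end of the PAM).
#' @return list of class `cut_site_profile`: nt_hist, t_hist (tables over
#'   bp-downstream-of-PAM), nt_mode, t_mode, modal_overhang,
#'   position_range, incomplete.
#' @export
infer_cut_sites <- function(nt_positions, t_positions, pam_end) {
  rel_nt <- nt_positions - pam_end
  rel_t <- t_positions - pam_end
  if (length(c(rel_nt, rel_t)) > 0 && any(c(rel_nt, rel_t) < 0)) {
    stop("cut positions upstream of the PAM 3' end", call. = FALSE)
  }
  mode_of <- function(x) {
    if (length(x) == 0) return(NA_integer_)
    tab <- table(x)
    as.integer(names(tab)[which.max(tab)])  # tie -> smallest position
  }
  nt_mode <- mode_of(rel_nt); t_mode <- mode_of(rel_t)
  incomplete <- length(rel_nt) == 0 || length(rel_t) == 0
  if (incomplete) {
    toolkit_log("a strand has zero cut observations; overhang undefined",
                module = "pam_profiler")
  }
  all_pos <- c(rel_nt, rel_t)
  structure(list(
    nt_hist = table(rel_nt), t_hist = table(rel_t),
    nt_mode = nt_mode, t_mode = t_mode,
    modal_overhang = if (incomplete) NA_integer_ else abs(nt_mode - t_mode),
    position_range = if (length(all_pos) == 0) c(NA_integer_, NA_integer_)
      else range(all_pos),
    incomplete = incomplete
  ), class = "cut_site_profile")
}

#' @export
print.cut_site_profile <- function(x, ...) {
  cat("Run-off cut-site profile (bp downstream of the 5' PAM)\n")
  cat("  non-target strand mode:", x$nt_mode,
      " target strand mode:", x$t_mode, "\n")
  cat("  modal overhang:", x$modal_overhang, "nt;  range:",
      paste(x$position_range, collapse = "-"), "\n")
  invisible(x)
}

#' Write a logo count matrix consumable by standard logo renderers
#'
#' @param profile a `pam_profile`.
#' @param path output TSV path (positions x A/C/G/T counts over the top-k
#'   set).
#' @return `path`, invisibly.
#' @export
write_logo_matrix <- function(profile, path) {
  counts <- round(profile$pfm * profile$top_k)
  df <- as.data.frame(t(counts))
  df <- cbind(position = seq_len(nrow(df)), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
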