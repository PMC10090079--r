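#' Default anti-repeat pairing parameters
#'
#' The anti-repeat rule used for compact type V-F tracrRNA prediction:
#' within a 22-nt window matched against the 22-nt 3' end of the direct
#' repeat, require at least 9 Watson-Crick (A-U / C-G) pairs and at least
#' 65 percent of positions paired counting wobble (A-U / C-G / G-U);
#' accepted anti-repeats are extended 150 nt upstream to the putative
#' tracrRNA transcript.
#'
#' @param window pairing window length (nt).
#' @param wc_min minimum Watson-Crick pair count.
#' @param paired_fraction_min minimum fraction (WC + wobble) / window.
#' @param extension upstream extension (nt).
#' @return list of class `pairing_params`.
#' @export
pairing_params <- function(window = 22L, wc_min = 9L,
                           paired_fraction_min = 0.65, extension = 150L) {
  stopifnot(wc_min <= window, paired_fraction_min > 0,
            paired_fraction_min <= 1, extension >= 0)
  structure(list(window = as.integer(window), wc_min = as.integer(wc_min),
                 paired_fraction_min = paired_fraction_min,
                 extension = as.integer(extension)),
            class = "pairing_params")
}

#' Extract the mature-repeat 3' suffix of a direct repeat, as RNA
#'
#' The repeat portion of the mature crRNA derives from the 3' end of the
#' direct repeat (about 22 nt for compact type V systems); this suffix is
#' the query for the anti-repeat scan.
#'
#' @param consensus_repeat DNA consensus repeat.
#' @param window suffix length (nt).
#' @return RNA string of length `window`.
#' @export
dr_suffix <- function(consensus_repeat, window = 22L) {
  consensus_repeat <- check_alphabet(consensus_repeat, what = "repeat")
  if (nchar(consensus_repeat) < window) {
    stop("consensus repeat shorter than the pairing window", call. = FALSE)
  }
  transcribe(substr(consensus_repeat, nchar(consensus_repeat) - window + 1,
                    nchar(consensus_repeat)))
}

# pair class lookup for an antiparallel RNA duplex:
# 2 = Watson-Crick (A-U, C-G), 1 = wobble (G-U), 0 = unpaired/N
RNA_BASES <- c("A", "C", "G", "U", "N")
PAIR_CLASS <- matrix(0L, 5, 5, dimnames = list(RNA_BASES, RNA_BASES))
PAIR_CLASS["A", "U"] <- PAIR_CLASS["U", "A"] <- 2L
PAIR_CLASS["C", "G"] <- PAIR_CLASS["G", "C"] <- 2L
PAIR_CLASS["G", "U"] <- PAIR_CLASS["U", "G"] <- 1L

# count (wc, wobble) for dr (5'->3') paired antiparallel against a window
# given as the window's reverse (3'->5') base vector
pairing_counts <- function(dr_vec, win_rev_vec) {
  cls <- PAIR_CLASS[cbind(dr_vec, win_rev_vec)]
  c(wc = sum(cls == 2L), wobble = sum(cls == 1L))
}

#' Scan a noncoding region for anti-repeat hits
#'
#' Both strands are scanned. At every offset an ungapped antiparallel RNA
#' duplex is formed between the DR suffix and the candidate window; A-U and
#' C-G count as Watson-Crick, G-U as wobble, N pairs with nothing. A hit
#' requires `wc >= wc_min` and `(wc + wobble) / window >=
#' paired_fraction_min`. With `merge = TRUE` overlapping hits on the same
#' strand are resolved keeping the max-(wc, then total) hit, ties to the
#' leftmost.
#'
#' @param region_seq noncoding DNA (forward contig orientation).
#' @param dr_suffix_rna RNA query from [dr_suffix()].
#' @param params a [pairing_params()] object.
#' @param merge resolve overlapping hits (default TRUE).
#' @return data.frame with columns start, end (region-forward 0-based
#'   half-open), strand (transcript strand), wc_pairs, wobble_pairs,
#'   total_pairs, paired_fraction; ordered by start then strand.
#' @export
scan_anti_repeat <- function(region_seq, dr_suffix_rna,
                             params = pairing_params(), merge = TRUE) {
  region_seq <- check_alphabet(region_seq, what = "region")
  W <- params$window
  if (nchar(dr_suffix_rna) != W) {
    stop("dr_suffix_rna length must equal params$window", call. = FALSE)
  }
  L <- nchar(region_seq)
  if (L < W) return(empty_hits())
  dr_vec <- seq_chars(check_alphabet(dr_suffix_rna,
                                     alphabet = c("A", "C", "G", "U", "N"),
                                     what = "DR suffix"))
  dri <- match(dr_vec, RNA_BASES)
  hits <- list()
  for (strand in c("+", "-")) {
    tx <- if (strand == "+") transcribe(region_seq) else
      transcribe(revcomp(region_seq))
    tvi <- match(seq_chars(tx), RNA_BASES)
    n_off <- L - W + 1
    # one row per offset; column c holds the partner of DR position c in
    # the antiparallel duplex (window read 3'->5')
    pos <- outer(0:(L - W), W:1, "+")          # 1-based transcript positions
    cls <- matrix(PAIR_CLASS[cbind(rep(dri, each = n_off),
                                   tvi[as.vector(pos)])], nrow = n_off)
    wc <- as.integer(rowSums(cls == 2L))
    wob <- as.integer(rowSums(cls == 1L))
    total <- wc + wob
    pass <- which(wc >= params$wc_min & total / W >= params$paired_fraction_min)
    if (length(pass) > 0) {
      o <- pass - 1L                            # 0-based transcript offsets
      fs <- if (strand == "+") o else L - o - W # forward region coordinates
      hits[[length(hits) + 1]] <- data.frame(
        start = fs, end = fs + W, strand = strand,
        wc_pairs = wc[pass], wobble_pairs = wob[pass],
        total_pairs = total[pass], paired_fraction = total[pass] / W,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) return(empty_hits())
  df <- do.call(rbind, hits)
  if (merge) df <- merge_hits(df)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_hits <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             wc_pairs = integer(), wobble_pairs = integer(),
             total_pairs = integer(), paired_fraction = numeric(),
             stringsAsFactors = FALSE)
}

# per strand: greedy selection by (wc desc, total desc, start asc) dropping
# hits overlapping an already-kept one
merge_hits <- function(df) {
  out <- list()
  for (strand in unique(df$strand)) {
    sub <- df[df$strand == strand, , drop = FALSE]
    sub <- sub[order(-sub$wc_pairs, -sub$total_pairs, sub$start), ,
               drop = FALSE]
    kept <- sub[0, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      overlaps <- any(sub$start[i] < kept$end & sub$end[i] > kept$start)
      if (!overlaps) kept <- rbind(kept, sub[i, , drop = FALSE])
    }
    out[[strand]] <- kept
  }
  do.call(rbind, out)
}

#' Extend an anti-repeat hit upstream to a tracrRNA candidate transcript
#'
#' Upstream means 5' on the tracrRNA transcript; the extension is clamped at
#' the region boundary (clamping is reported).
#'
#' @param hit one-row data.frame from [scan_anti_repeat()].
#' @param region_seq the scanned noncoding DNA (forward orientation).
#' @param extension upstream extension in nt.
#' @return list of class `tracr_candidate` with transcript (RNA),
#'   anti_repeat (the hit), extended_start/extended_end (region-forward
#'   coordinates), strand, clamped; structure fields unset.
#' @export
extend_tracr <- function(hit, region_seq, extension = 150L) {
  region_seq <- check_alphabet(region_seq, what = "region")
  L <- nchar(region_seq)
  stopifnot(hit$start >= 0, hit$end <= L)
  if (hit$strand == "+") {
    ext_start <- max(0L, hit$start - extension)
    ext_end <- hit$end
    clamped <- hit$start - extension < 0
    dna <- substr(region_seq, ext_start + 1, ext_end)
  } else {
    ext_start <- hit$start
    ext_end <- min(L, hit$end + extension)
    clamped <- hit$end + extension > L
    dna <- revcomp(substr(region_seq, ext_start + 1, ext_end))
  }
  if (clamped) {
    toolkit_log("upstream extension clamped at region boundary",
                module = "tracr_predictor")
  }
  structure(list(
    transcript = transcribe(dna),
    anti_repeat = hit,
    extended_start = ext_start, extended_end = ext_end,
    strand = hit$strand, clamped = clamped,
    structure = NULL, mfe_like_score = NA_real_,
    hairpin_count = NA_integer_, passed_structure_screen = NA
  ), class = "tracr_candidate")
}

#' @export
print.tracr_candidate <- function(x, ...) {
  cat("tracrRNA candidate,", nchar(x$transcript), "nt, strand", x$strand,
      sprintf("[%d,%d)", x$extended_start, x$extended_end), "\n")
  cat(sprintf("  anti-repeat: %d WC + %d wobble (%.1f%% paired)\n",
              x$anti_repeat$wc_pairs, x$anti_repeat$wobble_pairs,
              100 * x$anti_repeat$paired_fraction))
  if (!is.null(x$structure)) {
    cat("  structure:", x$structure, "\n")
    cat(sprintf("  score %.1f, %d hairpin(s), screen %s\n",
                x$mfe_like_score, x$hairpin_count,
                ifelse(isTRUE(x$passed_structure_screen), "PASS", "fail")))
  }
  invisible(x)
}

#' Screen a tracrRNA candidate by predicted secondary structure
#'
#' The folder is a pluggable contract: RNA string in, list(structure =
#' dot-bracket, score) out. The default is the built-in maximum
#' base-pairing dynamic program ([fold_nussinov()]); [fold_rnafold()]
#' adapts an external thermodynamic folder. The screen counts hairpin
#' loops closed by a stacked stem of at least `min_stem` pairs and passes
#' candidates with at least `min_hairpins` such hairpins. The numeric
#' thresholds are a declared heuristic for "conserved" tracrRNA
#' architecture; no quantitative community standard exists.
#'
#' @param candidate a `tracr_candidate` from [extend_tracr()].
#' @param folder folding function.
#' @param min_stem minimum stacked stem length closing a hairpin.
#' @param min_hairpins minimum qualifying hairpin count to pass.
#' @return the candidate with structure, mfe_like_score, hairpin_count and
#'   passed_structure_screen set (or failure reason in `failed_reason`).
#' @export
screen_structure <- function(candidate, folder = fold_nussinov,
                             min_stem = 4L, min_hairpins = 2L) {
  res <- tryCatch(folder(candidate$transcript), error = function(e) e)
  if (inherits(res, "error")) {
    candidate$passed_structure_screen <- FALSE
    candidate$failed_reason <- conditionMessage(res)
    return(candidate)
  }
  candidate$structure <- res$structure
  candidate$mfe_like_score <- res$score
  candidate$hairpin_count <- count_hairpins(res$structure,
                                            min_stem = min_stem)
  candidate$passed_structure_screen <-
    candidate$hairpin_count >= min_hairpins
  candidate
}

#' Predict tracrRNA candidates for a locus model
#'
#' Runs the anti-repeat scan over every noncoding region of the locus,
#' extends accepted hits upstream, screens structures, and resolves the
#' array orientation from the strand of the best anti-repeat (the DR
#' polarity is defined by the anti-repeat, not guessed from the array).
#'
#' @param locus a locus model from [pair_locus()].
#' @param genome named contig vector.
#' @param params [pairing_params()].
#' @param folder structure folder (see [screen_structure()]).
#' @param min_stem,min_hairpins structure screen thresholds.
#' @return the locus with `$tracr_candidates` (list of screened candidates,
#'   coordinates lifted to contig-forward) and the array's
#'   orientation_resolved/strand updated when a hit exists.
#' @export
predict_tracr <- function(locus, genome, params = pairing_params(),
                          folder = fold_nussinov, min_stem = 4L,
                          min_hairpins = 2L) {
  contig <- genome[[locus$cas$contig_id]]
  cands <- list()
  nc <- locus$noncoding_regions
  # the DR polarity is unknown until an anti-repeat is found: scan with the
  # 3' suffix of both readings of the consensus repeat; the reading that
  # pairs defines the array orientation
  for (dr_strand in c("+", "-")) {
    cons <- if (dr_strand == "+") locus$array$consensus_repeat else
      revcomp(locus$array$consensus_repeat)
    if (nchar(cons) < params$window) next
    drs <- dr_suffix(cons, params$window)
    for (i in seq_len(nrow(nc))) {
      region <- substr(contig, nc$start[i] + 1, nc$end[i])
      if (nchar(region) < params$window) next
      hits <- scan_anti_repeat(region, drs, params)
      for (j in seq_len(nrow(hits))) {
        cand <- extend_tracr(hits[j, , drop = FALSE], region,
                             params$extension)
        cand <- screen_structure(cand, folder, min_stem, min_hairpins)
        cand$dr_strand <- dr_strand
        # lift region-local coordinates to contig coordinates
        cand$extended_start <- cand$extended_start + nc$start[i]
        cand$extended_end <- cand$extended_end + nc$start[i]
        cand$anti_repeat$start <- cand$anti_repeat$start + nc$start[i]
        cand$anti_repeat$end <- cand$anti_repeat$end + nc$start[i]
        cands[[length(cands) + 1]] <- cand
      }
    }
  }
  if (length(cands) > 0) {
    best <- cands[[order(-vapply(cands, function(x) x$anti_repeat$wc_pairs, 0),
                         -vapply(cands, function(x) x$anti_repeat$total_pairs,
                                 0))[1]]]
    locus$array$orientation_resolved <- TRUE
    locus$array$strand <- best$dr_strand
  }
  locus$tracr_candidates <- cands
  locus
}
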