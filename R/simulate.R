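# deterministic reverse translation: seeded uniform codon draw per residue,
# with M forced to ATG at the first position
reverse_translate <- function(protein) {
  gc <- Biostrings::getGeneticCode("11")
  by_aa <- split(names(gc), gc)
  aas <- seq_chars(protein)
  codons <- vapply(aas, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue: ", a,
                            call. = FALSE)
    opts[sample.int(length(opts), 1)]
  }, "")
  if (aas[1] == "M") codons[1] <- "ATG"
  paste(codons, collapse = "")
}

# mismatch base for an RNA base: pairs with nothing (neither WC nor wobble)
MISMATCH_FOR <- c(A = "C", C = "A", G = "A", U = "C")
WC_FOR <- c(A = "U", C = "G", G = "C", U = "A")

# build the anti-repeat window (region-forward DNA) pairing the DR suffix
# with exactly wc WC and wobble G-U pairs; wobble positions require the DR
# base to be G or U
plant_anti_repeat <- function(dr_suffix_rna, wc, wobble) {
  drv <- seq_chars(dr_suffix_rna)
  W <- length(drv)
  if (wc + wobble > W) stop("infeasible pairing counts", call. = FALSE)
  wobble_ok <- which(drv %in% c("G", "U"))   # wobble needs a G or U on the DR
  wob_pos <- head(wobble_ok, wobble)
  if (length(wob_pos) < wobble) {
    stop("infeasible pairing counts: DR suffix has too few G/U for ",
         wobble, " wobble pairs", call. = FALSE)
  }
  wc_pos <- head(setdiff(seq_len(W), wob_pos), wc)
  if (length(wc_pos) < wc) stop("infeasible pairing counts", call. = FALSE)
  partner <- character(W)
  for (p in seq_len(W)) {
    partner[p] <- if (p %in% wc_pos) WC_FOR[[drv[p]]]
    else if (p %in% wob_pos) {
      if (drv[p] == "G") "U" else "G"     # G-U wobble partner
    } else MISMATCH_FOR[[drv[p]]]
  }
  # antiparallel: DR position p pairs with window position W - 1 - p
  window_rna <- paste(rev(partner), collapse = "")
  rna_to_dna(window_rna)
}

# Deterministically clean the noncoding gap: mutate bases (never inside the
# planted window) until the scanned region reports exactly the planted
# anti-repeat hit (or none when below threshold) under both DR readings and
# contains no ORF of >= 100 codons. Draws replacement bases from the seeded
# stream, so the result is reproducible.
sanitize_gap <- function(gap, guard, p_start, p_end, keep_planted,
                         drs, drs_rc, params, wc, wobble,
                         max_iter = 400L) {
  v <- seq_chars(gap)
  protected <- (p_start + 1):p_end            # 1-based planted window
  bases <- c("A", "C", "G", "T")
  for (iter in seq_len(max_iter)) {
    region <- paste0(paste(v, collapse = ""), guard)
    offenders <- list()
    for (qi in 1:2) {
      q <- if (qi == 1) drs else drs_rc
      h <- scan_anti_repeat(region, q, params)
      for (r in seq_len(nrow(h))) {
        is_planted <- qi == 1 && h$strand[r] == "+" &&
          h$start[r] == p_start && h$wc_pairs[r] == wc &&
          h$wobble_pairs[r] == wobble
        if (!(keep_planted && is_planted)) {
          offenders[[length(offenders) + 1]] <- h[r, , drop = FALSE]
        }
      }
    }
    orfs <- find_orfs(region, min_len_aa = 100L)
    if (length(offenders) == 0 && nrow(orfs) == 0) {
      return(paste(v, collapse = ""))
    }
    if (length(offenders) > 0) {
      o <- offenders[[1]]
      win <- (o$start + 1):min(o$end, length(v))
      mutable <- setdiff(win, protected)
      if (length(mutable) == 0) stop("cannot sanitize planted overlap",
                                     call. = FALSE)
      pick <- mutable[unique(round(seq(1, length(mutable),
                                       length.out = min(6, length(mutable)))))]
      for (p in pick) v[p] <- sample(setdiff(bases, v[p]), 1)
    } else {
      # stomp an in-frame stop into the middle of the offending ORF
      o <- orfs[1, , drop = FALSE]
      mid <- o$start + 3 * ((o$end - o$start) %/% 6)  # codon-aligned, 0-based
      stop_codon <- if (o$strand == "+") c("T", "A", "A") else
        c("T", "T", "A")                               # revcomp of TAA
      tgt <- (mid + 1):(mid + 3)
      tgt <- tgt[tgt <= length(v)]
      free <- setdiff(tgt, protected)
      if (length(free) == length(tgt)) {
        v[tgt] <- stop_codon[seq_along(tgt)]
      } else {
        # fall back to scrambling any free base of the ORF
        span <- setdiff((o$start + 1):min(o$end, length(v)), protected)
        if (length(span) == 0) stop("cannot sanitize planted overlap",
                                    call. = FALSE)
        p <- span[ceiling(length(span) / 2)]
        v[p] <- sample(setdiff(bases, v[p]), 1)
      }
    }
  }
  stop("could not generate a clean locus", call. = FALSE)
}

#' Simulate a compact Cas12f locus with a planted tracrRNA anti-repeat
#'
#' Generates a contig laying out: random flank, an in-frame stop, the
#' reverse-translated cas ORF, a noncoding gap carrying an anti-repeat
#' constructed to pair with the DR 22-nt suffix at exactly the requested
#' (WC, wobble) counts, the repeat-spacer array, and a trailing flank.
#' The noncoding gap is deterministically sanitized (bases mutated from
#' the seeded stream, never inside the planted window) until the scanner
#' reports exactly the planted hit - or none when the planted counts are
#' below threshold - so truth annotations are sharp. Spacer boundary
#' bases are chosen so repeat extension stops exactly at the planted
#' boundaries (for up to 4 repeat copies).
#'
#' @param cas_protein amino-acid sequence for the planted ORF (start M).
#' @param repeat_seq direct repeat DNA (>= 22 nt).
#' @param n_repeats number of repeat copies (2-4 keep boundaries exact).
#' @param spacer_len spacer length.
#' @param anti_repeat_wc,anti_repeat_wobble planted pairing counts.
#' @param cas_array_gap noncoding gap between cas ORF and array (bp).
#' @param anti_repeat_offset offset of the planted window inside the gap.
#' @param flanking_random flank length on each side (bp).
#' @param seed RNG seed.
#' @param params [pairing_params()] used for the cleanliness scan.
#' @return list: genome (named contig vector), truth (list with cas
#'   interval, array interval, repeat starts, anti-repeat interval in
#'   contig coordinates, planted counts, dr_suffix).
#' @export
simulate_locus <- function(cas_protein, repeat_seq, n_repeats = 4L,
                           spacer_len = 30L, anti_repeat_wc = 22L,
                           anti_repeat_wobble = 0L, cas_array_gap = 500L,
                           anti_repeat_offset = 200L,
                           flanking_random = 150L, seed = 1L,
                           params = pairing_params()) {
  stopifnot(anti_repeat_offset + params$window <= cas_array_gap,
            nchar(repeat_seq) >= params$window)
  repeat_seq <- check_alphabet(repeat_seq, what = "repeat")
  with_seed(seed, {
    cas_dna <- paste0(reverse_translate(cas_protein), "TAA")
    drs <- dr_suffix(repeat_seq, params$window)
    planted <- plant_anti_repeat(drs, anti_repeat_wc, anti_repeat_wobble)
    thresholds_met <- anti_repeat_wc >= params$wc_min &&
      (anti_repeat_wc + anti_repeat_wobble) / params$window >=
        params$paired_fraction_min

    # spacers with boundary-guard bases so repeat extension is exact
    bases <- c("A", "C", "G", "T")
    spacers <- vapply(seq_len(n_repeats - 1), function(i) {
      body <- random_dna(spacer_len - 2)
      paste0(bases[(i - 1) %% 4 + 1], body, bases[i %% 4 + 1])
    }, "")
    arr_parts <- character(0)
    for (i in seq_len(n_repeats)) {
      arr_parts <- c(arr_parts, repeat_seq)
      if (i < n_repeats) arr_parts <- c(arr_parts, spacers[i])
    }
    array_seq <- paste(arr_parts, collapse = "")
    # guard bases flanking the array so repeat extension stops exactly
    left_guard <- bases[(n_repeats - 1) %% 4 + 1]
    right_guard <- bases[n_repeats %% 4 + 1]

    # the noncoding region the pipeline will see (gap + guard base) must
    # report the planted window as its only anti-repeat hit (or none at
    # all when below threshold) under both DR readings, and carry no
    # intervening ORF long enough to be excised; spurious features are
    # mutated away deterministically from the seeded stream
    drs_rc <- dr_suffix(revcomp(repeat_seq), params$window)
    gap <- paste0(random_dna(anti_repeat_offset), planted,
                  random_dna(cas_array_gap - anti_repeat_offset -
                               nchar(planted)))
    gap <- sanitize_gap(gap, left_guard,
                        p_start = anti_repeat_offset,
                        p_end = anti_repeat_offset + params$window,
                        keep_planted = thresholds_met,
                        drs = drs, drs_rc = drs_rc, params = params,
                        wc = anti_repeat_wc, wobble = anti_repeat_wobble)

    left <- random_dna(flanking_random - 1)
    right <- random_dna(flanking_random - 1)
    contig <- paste0(left, "TAA", cas_dna, gap, left_guard, array_seq,
                     right_guard, right)
    cas_start <- nchar(left) + 3L
    cas_end <- cas_start + nchar(cas_dna)
    gap_start <- cas_end
    array_start <- gap_start + nchar(gap) + 1L  # +1 for left guard base
    repeat_starts <- array_start +
      cumsum(c(0L, rep(nchar(repeat_seq) + spacer_len, n_repeats - 1)))
    truth <- list(
      cas_start = cas_start, cas_end = cas_end,
      cas_protein = cas_protein,
      array_start = array_start,
      array_end = array_start + nchar(array_seq),
      repeat_starts = repeat_starts,
      repeat_len = nchar(repeat_seq),
      consensus_repeat = repeat_seq,
      anti_repeat_start = gap_start + anti_repeat_offset,
      anti_repeat_end = gap_start + anti_repeat_offset + params$window,
      wc = anti_repeat_wc, wobble = anti_repeat_wobble,
      thresholds_met = thresholds_met,
      dr_suffix = drs
    )
    list(genome = c(contig1 = contig), truth = truth)
  })
}

#' Simulate a randomized-PAM cleavage library
#'
#' Control reads carry uniform random k-mers in the anchored construct
#' (flank + randomized block + protospacer). Treated reads are the control
#' reads retained with probability `p_match` when the k-mer matches the
#' activity motif and `p_background` otherwise (product-enriched readout).
#' Byte-reproducible under a fixed seed.
#'
#' @param motif IUPAC activity motif of length k.
#' @param p_match,p_background retention probabilities.
#' @param n_reads control library size.
#' @param config a [pam_library_config()].
#' @param protospacer fixed sequence downstream of the randomized block.
#' @param seed RNG seed.
#' @return list: treated, control (named read vectors), truth (list with
#'   control_tally, treated_tally, motif).
#' @export
simulate_pam_library <- function(motif, p_match = 0.9, p_background = 0.01,
                                 n_reads = 100000L,
                                 config = pam_library_config(),
                                 protospacer = "CCATTACAGTAGGAGCATAC",
                                 seed = 1L) {
  stopifnot(p_background >= 0, p_match <= 1, p_background < p_match)
  k <- config$k
  if (nchar(motif) != k) stop("motif length must equal config$k",
                              call. = FALSE)
  if (n_reads < 1000) {
    warning("fewer than 1000 reads; motif recovery not guaranteed",
            call. = FALSE)
  }
  with_seed(seed, {
    km_mat <- matrix(sample(c("A", "C", "G", "T"), n_reads * k,
                            replace = TRUE), ncol = k)
    kmers <- do.call(paste0, as.data.frame(km_mat, stringsAsFactors = FALSE))
    matches <- rep(TRUE, n_reads)
    mot <- seq_chars(toupper(motif))
    for (j in seq_len(k)) {
      matches <- matches & km_mat[, j] %in% iupac_to_bases(mot[j])
    }
    p <- ifelse(matches, p_match, p_background)
    retained <- runif(n_reads) < p
    reads <- paste0(config$flank, kmers, protospacer)
    control <- setNames(reads, paste0("ctrl", seq_len(n_reads)))
    treated <- setNames(reads[retained],
                        paste0("trt", seq_len(sum(retained))))
    truth <- list(
      control_tally = table(kmers),
      treated_tally = table(kmers[retained]),
      motif = toupper(motif), n_treated = sum(retained)
    )
    list(treated = treated, control = control, truth = truth)
  })
}

# apply one edit description to an amplicon sequence
apply_edit <- function(refseq, edit) {
  if (edit$type == "wt") return(refseq)
  if (edit$type == "del") {
    paste0(substr(refseq, 1, edit$pos),
           substr(refseq, edit$pos + edit$len + 1, nchar(refseq)))
  } else if (edit$type == "ins") {
    paste0(substr(refseq, 1, edit$pos), edit$seq,
           substr(refseq, edit$pos + 1, nchar(refseq)))
  } else stop("unknown edit type: ", edit$type, call. = FALSE)
}

#' Simulate amplicon sequencing reads with planted allele proportions
#'
#' Read counts per allele are allocated by largest remainder, so small
#' fixtures carry exact expected counts (a multinomial mode is available
#' for statistical tests). Substitution errors are injected per base at
#' `error_rate`; indel errors are not modeled.
#'
#' @param ref an [amplicon_ref()].
#' @param alleles list of allele specs: each a list with `name`,
#'   `proportion`, and an edit (`type` = "wt", "del" or "ins", with `pos`
#'   (0-based), `len`, `seq` as applicable).
#' @param n_reads total reads.
#' @param error_rate per-base substitution probability.
#' @param allocation "largest_remainder" (deterministic counts) or
#'   "multinomial".
#' @param seed RNG seed.
#' @return list: reads (named vector), truth (data.frame read_id, allele).
#' @export
simulate_amplicon_reads <- function(ref, alleles, n_reads = 100L,
                                    error_rate = 0,
                                    allocation = c("largest_remainder",
                                                   "multinomial"),
                                    seed = 1L) {
  allocation <- match.arg(allocation)
  props <- vapply(alleles, function(a) a$proportion, 0)
  if (abs(sum(props) - 1) > 1e-9) {
    stop("allele proportions must sum to 1", call. = FALSE)
  }
  with_seed(seed, {
    counts <- if (allocation == "largest_remainder") {
      raw <- props * n_reads
      base <- floor(raw)
      rem <- n_reads - sum(base)
      extra <- order(-(raw - base))[seq_len(rem)]
      base[extra] <- base[extra] + 1
      as.integer(base)
    } else {
      as.integer(stats::rmultinom(1, n_reads, props))
    }
    seqs <- vapply(alleles, function(a) apply_edit(ref$sequence, a), "")
    read_seqs <- rep(seqs, counts)
    read_alleles <- rep(vapply(alleles, function(a) a$name, ""), counts)
    if (error_rate > 0) {
      read_seqs <- vapply(read_seqs, function(s) {
        v <- seq_chars(s)
        hit <- runif(length(v)) < error_rate
        if (any(hit)) {
          v[hit] <- vapply(v[hit], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, "")
        }
        paste(v, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    ids <- paste0("read", seq_along(read_seqs))
    list(reads = setNames(read_seqs, ids),
         truth = data.frame(read_id = ids, allele = read_alleles,
                            stringsAsFactors = FALSE))
  })
}
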