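#' Build a hierarchical run configuration
#'
#' Collects every tunable threshold of the pipeline under module-named
#' keys, merged over defaults; unknown keys are rejected. The effective
#' configuration is echoed into each run's output directory so reruns are
#' reproducible from the echo alone.
#'
#' @param ... named overrides, e.g. `locus_miner = list(max_distance =
#'   5000)`.
#' @return nested list of class `run_config`.
#' @export
cas12f_config <- function(...) {
  defaults <- list(
    locus_miner = list(
      gate_threshold = 1e-10, size_range = c(400L, 700L),
      min_scan_aa = 100L, repeat_len = c(18L, 45L),
      spacer_len = c(15L, 60L), min_repeats = 2L,
      max_mismatch_frac = 0.2, seed_len = 8L, lookahead = c(16L, 105L),
      max_distance = 10000L, min_orf_excise_aa = 100L
    ),
    tracr_predictor = list(
      window = 22L, wc_min = 9L, paired_fraction_min = 0.65,
      extension = 150L, min_stem = 4L, min_hairpins = 2L
    ),
    sgrna_designer = list(spacer_len = 20L, tetraloop = "GAAA"),
    pam_profiler = list(
      k = 7L, top_k = 1000L, pseudocount = 0.5,
      include_fraction = 0.5, trim_ic = 0.3, mode = "product_enriched",
      flank = "GGTCTCTACCT", max_mismatch = 1L
    ),
    edit_outcomes = list(
      cut_offset = 23L, window_width = 10L, top_n = 10L,
      min_identity = 0.6
    ),
    seed = 1L, verbosity = 1L
  )
  overrides <- list(...)
  merge_cfg <- function(base, over, path = "") {
    for (nm in names(over)) {
      if (!nm %in% names(base)) {
        stop("unknown config key: ", paste0(path, nm), call. = FALSE)
      }
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]],
                                paste0(path, nm, "$"))
      } else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_cfg(defaults, overrides), class = "run_config")
}

echo_config <- function(config, outdir) {
  yaml::write_yaml(unclass(config), file.path(outdir, "effective_config.yaml"))
}

#' Export locus models as GFF3
#'
#' Features: cas12f_candidate, CRISPR_array, repeat_unit, spacer, and
#' tracrRNA_candidate; coordinates converted to the 1-based inclusive GFF3
#' convention at this boundary only.
#'
#' @param loci list of locus models (after [predict_tracr()]).
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
export_loci_gff3 <- function(loci, path) {
  grs <- list()
  add <- function(contig, start0, end0, strand, type, id) {
    GenomicRanges::GRanges(
      seqnames = contig,
      ranges = IRanges::IRanges(start = start0 + 1, end = end0),
      strand = if (is.na(strand)) "*" else strand,
      type = type, ID = id)
  }
  for (li in seq_along(loci)) {
    locus <- loci[[li]]
    cas <- locus$cas
    grs[[length(grs) + 1]] <- add(cas$contig_id, cas$start, cas$end,
                                  cas$strand, "cas12f_candidate",
                                  paste0("cas", li))
    a <- locus$array
    grs[[length(grs) + 1]] <- add(a$contig_id, a$start, a$end, a$strand,
                                  "CRISPR_array", paste0("array", li))
    for (ri in seq_len(nrow(a$repeats))) {
      grs[[length(grs) + 1]] <- add(a$contig_id, a$repeats$start[ri],
                                    a$repeats$end[ri], a$strand,
                                    "repeat_unit",
                                    paste0("array", li, "_rep", ri))
    }
    for (si in seq_len(nrow(a$spacers))) {
      grs[[length(grs) + 1]] <- add(a$contig_id, a$spacers$start[si],
                                    a$spacers$end[si], a$strand, "spacer",
                                    paste0("array", li, "_spc", si))
    }
    for (ti in seq_along(locus$tracr_candidates)) {
      tc <- locus$tracr_candidates[[ti]]
      grs[[length(grs) + 1]] <- add(cas$contig_id, tc$extended_start,
                                    tc$extended_end, tc$strand,
                                    "tracrRNA_candidate",
                                    paste0("tracr", li, "_", ti))
    }
  }
  gr <- if (length(grs) == 0) GenomicRanges::GRanges() else
    do.call(c, grs)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Run the mining pipeline: Cas gene + array + tracrRNA prediction
#'
#' Chains ORF calling, the homology/size gates, array detection, locus
#' pairing, and anti-repeat tracrRNA prediction; writes GFF3, a TSV locus
#' summary, a tracr-candidate FASTA, and the effective config echo.
#'
#' @param input_fasta contigs FASTA path.
#' @param reference_faa reference Cas12f protein FASTA path.
#' @param outdir output directory (created).
#' @param config a [cas12f_config()].
#' @return list of locus models (with tracr candidates), invisibly.
#' @export
run_mine <- function(input_fasta, reference_faa, outdir,
                     config = cas12f_config()) {
  if (!file.exists(reference_faa)) {
    stop("config error: reference protein FASTA not found: ", reference_faa,
         call. = FALSE)
  }
  genome <- read_fasta(input_fasta)
  refs <- read_protein_fasta(reference_faa)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  lm <- config$locus_miner
  tp <- config$tracr_predictor
  cands <- scan_cas_candidates(genome, refs,
                               gate_threshold = lm$gate_threshold,
                               size_range = lm$size_range,
                               min_scan_aa = lm$min_scan_aa)
  arrays <- list()
  for (cid in names(genome)) {
    arrays <- c(arrays, find_crispr_arrays(
      genome[cid], repeat_len = lm$repeat_len, spacer_len = lm$spacer_len,
      min_repeats = lm$min_repeats,
      max_mismatch_frac = lm$max_mismatch_frac, seed_len = lm$seed_len,
      lookahead = lm$lookahead, contig_id = cid))
  }
  loci <- pair_locus(cands, arrays, genome,
                     max_distance = lm$max_distance,
                     min_orf_excise_aa = lm$min_orf_excise_aa)
  params <- pairing_params(tp$window, tp$wc_min, tp$paired_fraction_min,
                           tp$extension)
  loci <- lapply(loci, predict_tracr, genome = genome, params = params,
                 min_stem = tp$min_stem, min_hairpins = tp$min_hairpins)

  export_loci_gff3(loci, file.path(outdir, "loci.gff3"))
  summ <- do.call(rbind, lapply(seq_along(loci), function(i) {
    l <- loci[[i]]
    data.frame(locus = i, contig = l$cas$contig_id,
               cas_start = l$cas$start, cas_end = l$cas$end,
               cas_len_aa = l$cas$protein_len, evalue = l$cas$evalue,
               array_start = l$array$start, array_end = l$array$end,
               n_repeats = l$array$n_repeats,
               consensus_repeat = l$array$consensus_repeat,
               distance = l$cas_array_distance,
               n_tracr = length(l$tracr_candidates),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summ)) summ <- data.frame()
  write.table(summ, file.path(outdir, "loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr_seqs <- character(); nm <- character()
  for (i in seq_along(loci)) {
    for (j in seq_along(loci[[i]]$tracr_candidates)) {
      tr_seqs <- c(tr_seqs, loci[[i]]$tracr_candidates[[j]]$transcript)
      nm <- c(nm, paste0("locus", i, "_tracr", j))
    }
  }
  if (length(tr_seqs) > 0) {
    write_fasta(setNames(tr_seqs, nm), file.path(outdir, "tracr.fasta"))
  }
  echo_config(config, outdir)
  invisible(loci)
}

#' Run PAM inference from treated/control libraries
#'
#' @param treated_fastq treated (product) FASTQ path or read vector.
#' @param control_fastq control FASTQ path or read vector; required in
#'   survivor-depleted mode.
#' @param outdir output directory.
#' @param config a [cas12f_config()].
#' @return the `pam_profile`, invisibly.
#' @export
run_pam <- function(treated_fastq, control_fastq = NULL, outdir,
                    config = cas12f_config()) {
  pp <- config$pam_profiler
  if (is.null(control_fastq) && pp$mode == "survivor_depleted") {
    stop("config error: survivor-depleted mode requires a control library",
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  libcfg <- pam_library_config(k = pp$k, flank = pp$flank,
                               max_mismatch = pp$max_mismatch,
                               mode = pp$mode)
  treated <- count_pam_kmers(treated_fastq, libcfg)
  if (treated$total == 0) stop("zero anchored treated reads", call. = FALSE)
  control <- if (is.null(control_fastq)) {
    # raw-count mode: uniform pseudo-control over the observed k-mers
    structure(list(counts = setNames(rep(1L, length(treated$counts)),
                                     names(treated$counts)),
                   total = length(treated$counts),
                   skipped_no_anchor = 0L, skipped_n = 0L),
              class = "pam_counts")
  } else count_pam_kmers(control_fastq, libcfg)
  ranked <- pam_enrich(treated, control, pp$pseudocount, pp$mode)
  profile <- build_pam_profile(ranked, top_k = pp$top_k,
                               include_fraction = pp$include_fraction,
                               trim_ic = pp$trim_ic)
  write.table(ranked, file.path(outdir, "ranked_kmers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pfm_df <- cbind(base = rownames(profile$pfm), as.data.frame(profile$pfm))
  write.table(pfm_df, file.path(outdir, "pfm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(position = seq_along(profile$information_content),
                         ic_bits = profile$information_content,
                         consensus = seq_chars(profile$consensus)),
              file.path(outdir, "information_content.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_logo_matrix(profile, file.path(outdir, "logo_matrix.tsv"))
  echo_config(config, outdir)
  invisible(profile)
}

#' Run indel quantification from amplicon reads
#'
#' @param reads_fastq FASTQ path or read vector.
#' @param ref an [amplicon_ref()] (or amplicon FASTA path plus
#'   `pam_start`/`pam_end`).
#' @param outdir output directory.
#' @param config a [cas12f_config()].
#' @param pam_start,pam_end PAM interval when `ref` is a FASTA path.
#' @return the `editing_summary`, invisibly.
#' @export
run_indel <- function(reads_fastq, ref, outdir, config = cas12f_config(),
                      pam_start = NULL, pam_end = NULL) {
  eo <- config$edit_outcomes
  if (is.character(ref)) {
    seqs <- read_fasta(ref)
    ref <- amplicon_ref(seqs[[1]], pam_start, pam_end,
                        cut_offset = eo$cut_offset,
                        window_width = eo$window_width)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summ <- quantify_edits(reads_fastq, ref, top_n = eo$top_n,
                         min_identity = eo$min_identity)
  write.table(data.frame(
    n_total = summ$n_total, n_unaligned = summ$n_unaligned,
    n_edited = summ$n_edited, indel_frequency = summ$indel_frequency),
    file.path(outdir, "summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write.table(summ$allele_table, file.path(outdir, "alleles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- attr(summ, "calls")
  per_read <- do.call(rbind, lapply(calls, function(x) {
    data.frame(read_id = x$read_id, status = x$status,
               n_indels = if (is.null(x$indels)) 0L else nrow(x$indels),
               allele_key = x$allele_key, stringsAsFactors = FALSE)
  }))
  write.table(per_read, file.path(outdir, "read_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  echo_config(config, outdir)
  invisible(summ)
}
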