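test_that("DR suffix takes the transcribed 3' end of the repeat", {
  rep36 <- paste0(strrep("A", 14), "GTTTCAATCCACGCGCCCATAG")
  s <- dr_suffix(rep36, 22)
  expect_equal(nchar(s), 22)
  expect_identical(s, "GUUUCAAUCCACGCGCCCAUAG")
  rep22 <- "GTTTCAATCCACGCGCCCATAG"
  expect_identical(dr_suffix(rep22, 22), "GUUUCAAUCCACGCGCCCAUAG")
  expect_error(dr_suffix("GTTTCAATCCACGCGCCCAT", 22), "shorter")
})

test_that("pairing thresholds act as sharp boundaries", {
  drs <- dr_suffix(fixture_repeat)
  scan_one <- function(wc, wobble) {
    win <- planted_window(drs, wc, wobble)
    nrow(scan_anti_repeat(win, drs))
  }
  expect_equal(scan_one(22, 0), 1)   # perfect complement
  expect_equal(scan_one(9, 6), 1)    # wc 9, total 15: both minima met
  expect_equal(scan_one(8, 8), 0)    # 16 paired but wc 8 < 9
  expect_equal(scan_one(9, 5), 0)    # wc ok but 14/22 < 65%
  win <- planted_window(drs, 22, 0)
  h <- scan_anti_repeat(win, drs)
  expect_equal(h$wc_pairs, 22)
  expect_equal(h$paired_fraction, 1.0)
})

test_that("anti-repeat scan matches brute-force enumeration", {
  drs <- dr_suffix(fixture_repeat)
  set.seed(5)
  for (i in 1:50) {
    region <- random_dna_str(sample(60:300, 1))
    if (i %% 4 == 0) {  # plant a window in every fourth region
      w <- planted_window(drs, sample(9:22, 1), 0)
      at <- sample(0:(nchar(region) - 22), 1)
      region <- paste0(substr(region, 1, at), w,
                       substr(region, at + 23, nchar(region)))
    }
    got <- scan_anti_repeat(region, drs, merge = FALSE)
    want <- oracle_anti_repeat(region, drs)
    expect_equal(got[, c("start", "end", "strand", "wc_pairs",
                         "wobble_pairs", "total_pairs")],
                 want, ignore_attr = TRUE)
  }
})

test_that("overlap merging keeps the max-(wc, total) hit, ties leftmost", {
  drs <- dr_suffix(fixture_repeat)
  strong <- planted_window(drs, 22, 0)
  weak <- planted_window(drs, 10, 5)
  # overlapping placement: weak window starts 10 nt into the strong one
  region <- paste0(substr(strong, 1, 10), weak, strrep("A", 30))
  all_hits <- scan_anti_repeat(region, drs, merge = FALSE)
  merged <- scan_anti_repeat(region, drs, merge = TRUE)
  for (strand in unique(merged$strand)) {
    m <- merged[merged$strand == strand, ]
    a <- all_hits[all_hits$strand == strand, ]
    expect_equal(max(a$wc_pairs), max(m$wc_pairs))
  }
  # merged hits never overlap within a strand
  for (strand in unique(merged$strand)) {
    m <- merged[merged$strand == strand, ]
    if (nrow(m) > 1) {
      m <- m[order(m$start), ]
      expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
    }
  }
})

test_that("upstream extension is 150 nt on the transcript, clamped at
           region bounds", {
  drs <- dr_suffix(fixture_repeat)
  win <- planted_window(drs, 22, 0)
  region <- paste0(random_dna_str(200), win, random_dna_str(80))
  hits <- scan_anti_repeat(region, drs)
  hit <- hits[hits$start == 200 & hits$strand == "+", ]
  cand <- extend_tracr(hit, region, 150)
  expect_equal(cand$extended_start, 50)
  expect_equal(cand$extended_end, 222)
  expect_equal(nchar(cand$transcript), 172)
  expect_false(cand$clamped)
  expect_true(all(strsplit(cand$transcript, "")[[1]] %in%
                    c("A", "C", "G", "U", "N")))

  # anti-repeat close to the region start clamps
  region2 <- paste0(substr(region, 161, 200), win, random_dna_str(40))
  hit2 <- scan_anti_repeat(region2, drs)
  hit2 <- hit2[hit2$start == 40 & hit2$strand == "+", ]
  cand2 <- extend_tracr(hit2, region2, 150)
  expect_equal(cand2$extended_start, 0)
  expect_equal(cand2$extended_end, 62)
  expect_true(cand2$clamped)

  cand3 <- extend_tracr(hit, region, 0)
  expect_equal(nchar(cand3$transcript), 22)
})

test_that("extension never exceeds region bounds on either strand", {
  drs <- dr_suffix(fixture_repeat)
  set.seed(8)
  for (i in 1:20) {
    region <- random_dna_str(120)
    hits <- scan_anti_repeat(region, drs,
                             pairing_params(wc_min = 4,
                                            paired_fraction_min = 0.3))
    if (nrow(hits) == 0) next
    for (j in seq_len(min(3, nrow(hits)))) {
      cand <- extend_tracr(hits[j, ], region, 150)
      expect_gte(cand$extended_start, 0)
      expect_lte(cand$extended_end, 120)
    }
  }
})

test_that("built-in folder matches exhaustive max-pairing recursion", {
  set.seed(12)
  for (i in 1:25) {
    rna <- paste(sample(c("A", "C", "G", "U"), sample(8:16, 1), TRUE),
                 collapse = "")
    got <- fold_nussinov(rna)
    expect_equal(-got$score, oracle_max_pairs(rna))
    expect_equal(nchar(got$structure), nchar(rna))
    # dot-bracket is balanced
    v <- strsplit(got$structure, "")[[1]]
    expect_equal(sum(v == "("), sum(v == ")"))
  }
})

test_that("structure screen counts stacked hairpins", {
  r1 <- screen_structure(list(transcript = "GGGGAAAACCCC"))
  expect_equal(r1$hairpin_count, 1)
  expect_false(r1$passed_structure_screen)

  r2 <- screen_structure(list(transcript = "AAAAAAAAAAAA"))
  expect_equal(r2$hairpin_count, 0)
  expect_false(r2$passed_structure_screen)

  # two stable stem-loops pass the default screen
  two_hp <- paste0("GGGGGAAAACCCCC", "AAAAAAAA", "CCCCUUUUU")
  r3 <- screen_structure(list(transcript = two_hp))
  expect_gte(r3$hairpin_count, 2)
  expect_true(r3$passed_structure_screen)

  # a failing folder marks the candidate failed with a reason
  bad_folder <- function(rna) stop("boom")
  r4 <- screen_structure(list(transcript = "ACGU"), folder = bad_folder)
  expect_false(r4$passed_structure_screen)
  expect_match(r4$failed_reason, "boom")
})

test_that("full pipeline recovers exactly the planted tracrRNA", {
  prots <- standin_proteins()
  os <- unname(prots[1])
  sim <- simulate_locus(os, fixture_repeat, anti_repeat_wc = 12,
                        anti_repeat_wobble = 3, seed = 42)
  g <- sim$genome
  loci <- pair_locus(scan_cas_candidates(g, c(Os = os)),
                     find_crispr_arrays(g), g)
  loci <- lapply(loci, predict_tracr, genome = g)
  expect_length(loci, 1)
  tc <- loci[[1]]$tracr_candidates
  expect_length(tc, 1)
  expect_equal(tc[[1]]$anti_repeat$start, sim$truth$anti_repeat_start)
  expect_equal(tc[[1]]$anti_repeat$end, sim$truth$anti_repeat_end)
  expect_equal(tc[[1]]$anti_repeat$wc_pairs, 12)
  expect_equal(tc[[1]]$anti_repeat$wobble_pairs, 3)
  expect_true(loci[[1]]$array$orientation_resolved)
  # the planted interval lies inside the extended transcript interval
  expect_lte(tc[[1]]$extended_start, sim$truth$anti_repeat_start)
  expect_gte(tc[[1]]$extended_end, sim$truth$anti_repeat_end)
})
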