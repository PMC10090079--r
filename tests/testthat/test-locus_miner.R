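make_contig_with_orf <- function(protein, flank = 200, seed = 1) {
  set.seed(seed)
  dna <- cas12ftools:::with_seed(seed,
                                 cas12ftools:::reverse_translate(protein))
  c(ctg = paste0(random_dna_str(flank), "TAA", dna, "TAA",
                 random_dna_str(flank)))
}

test_that("homology + size gates recover a planted reference ORF", {
  prots <- standin_proteins()
  os <- unname(prots[1])
  g <- make_contig_with_orf(os, seed = 3)
  got <- scan_cas_candidates(g, c(Os = os))
  expect_equal(nrow(got), 1)
  expect_lt(got$evalue, 1e-100)
  expect_equal(got$protein_len, 433)
  expect_identical(got$protein, os)
  expect_true(got$passed_size_gate)
})

test_that("size gate rejects a 350-aa homolog of the reference", {
  prots <- standin_proteins()
  os <- unname(prots[1])
  short <- substr(os, 1, 350)
  g <- make_contig_with_orf(short, seed = 5)
  got <- scan_cas_candidates(g, c(Os = os))
  expect_equal(nrow(got), 0)
  # same ORF passes once the size floor admits it
  got2 <- scan_cas_candidates(g, c(Os = os), size_range = c(300, 700))
  expect_equal(nrow(got2), 1)
})

test_that("homology gate rejects random proteins; shuffling kills the hit", {
  prots <- standin_proteins()
  os <- unname(prots[1])
  set.seed(9)
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  rand450 <- paste0("M", paste(sample(aa, 449, TRUE), collapse = ""))
  g <- make_contig_with_orf(rand450, seed = 13)
  expect_equal(nrow(scan_cas_candidates(g, c(Os = os))), 0)
  # a shuffled copy of the reference scores like a random protein
  shuf <- paste(sample(strsplit(os, "")[[1]]), collapse = "")
  expect_gt(protein_evalue(shuf, os)$evalue, 1e-10)
  expect_lt(protein_evalue(os, os)$evalue, 1e-200)
})

test_that("candidate set shrinks monotonically as the gate tightens", {
  prots <- standin_proteins()
  os <- unname(prots[1])
  g <- make_contig_with_orf(os, seed = 3)
  n <- vapply(c(1e-5, 1e-10, 1e-50, 1e-300),
              function(th) nrow(scan_cas_candidates(g, c(Os = os),
                                                    gate_threshold = th)),
              0)
  expect_true(all(diff(n) <= 0))
})

test_that("catalytic aspartate check maps reference positions through
           alignment", {
  prots <- standin_proteins()
  os <- unname(prots[1]); rh <- unname(prots[2])
  r1 <- check_ruvc_motif(os, os, c(228, 406))
  expect_true(all(r1$positions$present))
  expect_true(r1$ruvc_ok)
  expect_identical(r1$positions$residue, c("D", "D"))
  r2 <- check_ruvc_motif(rh, rh, c(210, 388))
  expect_true(r2$ruvc_ok)

  # alanine substitution at a catalytic site is detected
  mut <- os
  substr(mut, 228, 228) <- "A"
  r3 <- check_ruvc_motif(mut, os, c(228, 406))
  expect_false(r3$positions$present[r3$positions$reference_position == 228])
  expect_true(r3$positions$present[r3$positions$reference_position == 406])
  expect_false(r3$ruvc_ok)

  # indels upstream still map the catalytic column correctly
  ins <- paste0(substr(os, 1, 100), "GGSGG", substr(os, 101, nchar(os)))
  r4 <- check_ruvc_motif(ins, os, c(228, 406))
  expect_true(r4$ruvc_ok)
  expect_equal(r4$positions$candidate_position, c(233, 411))
})

test_that("self-alignment reports present at every aspartate position", {
  set.seed(21)
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:5) {
    p <- paste(sample(aa, 150, TRUE), collapse = "")
    dpos <- which(strsplit(p, "")[[1]] == "D")
    if (length(dpos) == 0) next
    r <- check_ruvc_motif(p, p, dpos)
    expect_true(all(r$positions$present))
  }
})

test_that("low-coverage alignments are flagged and fail the check", {
  prots <- standin_proteins()
  os <- unname(prots[1])
  frag <- substr(os, 300, 433)   # < 50% of the reference
  r <- check_ruvc_motif(frag, os, c(228, 406))
  expect_true(r$low_coverage)
  expect_false(r$ruvc_ok)
})

test_that("planted repeat-spacer arrays are found with exact boundaries", {
  set.seed(2)
  rep36 <- random_dna_str(36)
  sp <- function(a, b) paste0(a, random_dna_str(28), b)
  contig <- paste0(random_dna_str(100), "T",
                   rep36, sp("A", "C"), rep36, sp("C", "G"), rep36,
                   sp("G", "T"), rep36, "A", random_dna_str(100))
  arr <- find_crispr_arrays(contig)
  expect_length(arr, 1)
  a <- arr[[1]]
  expect_equal(a$n_repeats, 4)
  expect_equal(nrow(a$spacers), 3)
  expect_equal(a$start, 101)
  expect_equal(a$end, 101 + 4 * 36 + 3 * 30)
  expect_identical(a$consensus_repeat, rep36)
  expect_false(a$orientation_resolved)

  # two mismatches in one copy stay within the 20% budget
  v <- strsplit(contig, "")[[1]]
  second_rep <- 101 + 36 + 30
  v[second_rep + 3] <- setdiff(c("A", "C", "G", "T"), v[second_rep + 3])[1]
  v[second_rep + 9] <- setdiff(c("A", "C", "G", "T"), v[second_rep + 9])[1]
  arr2 <- find_crispr_arrays(paste(v, collapse = ""))
  expect_length(arr2, 1)
  expect_equal(arr2[[1]]$n_repeats, 4)
})

test_that("array detection matches the exhaustive seed-and-extend oracle", {
  set.seed(31)
  to_df <- function(arrs) {
    do.call(rbind, c(list(data.frame(start = integer(), len = integer(),
                                     n = integer())),
                     lapply(arrs, function(a) {
      if (!is.null(a$repeats)) {
        data.frame(start = a$repeats$start[1],
                   len = a$repeats$end[1] - a$repeats$start[1],
                   n = nrow(a$repeats))
      } else {
        data.frame(start = a$copies[1], len = a$u_len,
                   n = length(a$copies))
      }
    })))
  }
  for (i in 1:50) {
    s <- random_dna_str(sample(800:2000, 1))
    if (i %% 5 == 0) {  # plant an array in every fifth instance
      ru <- random_dna_str(sample(20:40, 1))
      n_sp <- sample(15:55, 2)
      s <- paste0(substr(s, 1, 300), ru, random_dna_str(n_sp[1]), ru,
                  random_dna_str(n_sp[2]), ru,
                  substr(s, 301, nchar(s)))
    }
    expect_equal(to_df(find_crispr_arrays(s)), to_df(oracle_arrays(s)),
                 ignore_attr = TRUE)
  }
})

test_that("locus pairing computes distance and excises intervening ORFs", {
  # cas at [1000,2300), array at [3000,3500): distance 700
  set.seed(17)
  cands <- data.frame(contig_id = "c", start = 1000L, end = 2300L,
                      strand = "+", protein = "M", protein_len = 433L,
                      best_reference_id = "r", evalue = 0,
                      passed_size_gate = TRUE, stringsAsFactors = FALSE)
  arr <- list(structure(list(contig_id = "c", start = 3000L, end = 3500L,
                             repeats = data.frame(), spacers = data.frame(),
                             consensus_repeat = "G", n_repeats = 2,
                             orientation_resolved = FALSE,
                             strand = NA_character_),
                        class = "crispr_array"))
  genome <- c(c = random_dna_str(4000))
  loci <- pair_locus(cands, arr, genome)
  expect_length(loci, 1)
  expect_equal(loci[[1]]$cas_array_distance, 700)
  expect_equal(loci[[1]]$noncoding_regions$start, 2300)
  expect_equal(loci[[1]]$noncoding_regions$end, 3000)

  # array on a different contig pairs nothing
  arr2 <- arr
  arr2[[1]]$contig_id <- "other"
  expect_length(suppressMessages(pair_locus(cands, arr2, genome)), 0)

  # an intervening 150-codon ORF is excised from the noncoding region
  orf_dna <- paste0("ATG", strrep("GCT", 149), "TAA")
  g2 <- c(c = paste0(substr(genome[["c"]], 1, 2400), "TAA", orf_dna,
                     substr(genome[["c"]], 2858, 4000)))
  loci2 <- pair_locus(cands, arr, g2)
  nc <- loci2[[1]]$noncoding_regions
  expect_gt(nrow(nc), 1)
  total <- sum(nc$end - nc$start)
  expect_lt(total, 700 - 400)
})
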