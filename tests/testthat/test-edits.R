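test_that("amplicon reference places the expected cut downstream of PAM", {
  ref <- fixture_amplicon()
  expect_equal(ref$protospacer_start, 84)
  expect_equal(ref$protospacer_end, 104)
  expect_equal(ref$expected_cut, 84 + 23)
  expect_equal(ref$window_width, 10)
})

test_that("alignment recovers planted indels, left-normalized", {
  ref <- fixture_amplicon()
  # identity read: no indels
  a <- align_read(ref$sequence, ref)
  expect_equal(a$status, "aligned")
  expect_equal(nrow(a$indels), 0)
  expect_equal(a$identity, 1)

  # single 3-bp deletion
  r_del <- paste0(substr(ref$sequence, 1, 100),
                  substr(ref$sequence, 104, nchar(ref$sequence)))
  a2 <- align_read(r_del, ref)
  expect_equal(nrow(a2$indels), 1)
  expect_equal(a2$indels$kind, "del")
  expect_equal(a2$indels$len, 3)

  # deletion inside a homopolymer is left-aligned
  hp <- paste0(strrep("C", 30), "AAAAAA", strrep("G", 30),
               "TTTA", "CCATTACAGTAGGAGCATAC", strrep("T", 30))
  href <- amplicon_ref(hp, pam_start = 66, pam_end = 70)
  r_hp <- paste0(substr(hp, 1, 33), substr(hp, 36, nchar(hp)))  # del 2 A's
  a3 <- align_read(r_hp, href)
  expect_equal(a3$indels$kind, "del")
  expect_equal(a3$indels$len, 2)
  expect_equal(a3$indels$pos, 30)  # shifted to the start of the A-run

  # unalignable read is flagged
  set.seed(23)
  junk <- random_dna_str(60)
  a4 <- align_read(junk, ref)
  expect_equal(a4$status, "unaligned")
})

test_that("simulated gap placements are recovered after left-normalization", {
  ref <- fixture_amplicon()
  L <- nchar(ref$sequence)
  set.seed(29)
  for (i in 1:200) {
    kind <- sample(c("del", "ins"), 1)
    pos <- sample(30:(L - 40), 1)
    len <- sample(1:8, 1)
    if (kind == "del") {
      read <- paste0(substr(ref$sequence, 1, pos),
                     substr(ref$sequence, pos + len + 1, L))
    } else {
      ins <- random_dna_str(len)
      read <- paste0(substr(ref$sequence, 1, pos), ins,
                     substr(ref$sequence, pos + 1, L))
    }
    a <- align_read(read, ref)
    expect_equal(nrow(a$indels), 1)
    expect_equal(a$indels$kind, kind)
    expect_equal(a$indels$len, len)
    # truth, left-normalized the same way
    rc <- strsplit(ref$sequence, "")[[1]]
    truth <- if (kind == "del") {
      cas12ftools:::left_normalize_indel(rc, pos, len, "del")
    } else {
      cas12ftools:::left_normalize_indel(rc, pos, len, "ins", ins)
    }
    expect_equal(a$indels$pos, truth$pos)
  }
})

test_that("window classification follows the indel-overlap rule", {
  ref <- fixture_amplicon()
  cut <- ref$expected_cut
  del_read <- function(pos, len) {
    paste0(substr(ref$sequence, 1, pos),
           substr(ref$sequence, pos + len + 1, nchar(ref$sequence)))
  }
  # 3-bp deletion centered at the cut -> edited
  cl <- classify_read(align_read(del_read(cut - 1, 3), ref), ref)
  expect_equal(cl$status, "edited")
  # 1-bp insertion 12 bp away -> outside the 10-bp window, unedited
  ins_far <- paste0(substr(ref$sequence, 1, cut + 12), "A",
                    substr(ref$sequence, cut + 13, nchar(ref$sequence)))
  cl2 <- classify_read(align_read(ins_far, ref), ref)
  expect_equal(cl2$status, "unedited")
  # substitutions alone never count as edits
  sub_read <- ref$sequence
  substr(sub_read, cut, cut + 2) <- "AAA"
  cl3 <- classify_read(align_read(sub_read, ref), ref)
  expect_equal(cl3$status, "unedited")
})

test_that("classification flips exactly when the window reaches the indel", {
  base <- fixture_amplicon()
  cut <- base$expected_cut
  for (d in c(2, 4, 6)) {
    # 1-bp deletion at distance d downstream of the cut
    read <- paste0(substr(base$sequence, 1, cut + d),
                   substr(base$sequence, cut + d + 2,
                          nchar(base$sequence)))
    for (w in seq(2, 16, 2)) {
      ref_w <- base
      ref_w$window_width <- as.integer(w)
      cl <- classify_read(align_read(read, ref_w), ref_w)
      expected <- if (w > 2 * d) "edited" else "unedited"
      expect_equal(cl$status, expected,
                   label = sprintf("d=%d w=%d -> %s", d, w, cl$status))
    }
  }
})

test_that("classification is invariant to read orientation", {
  ref <- fixture_amplicon()
  sim <- simulate_amplicon_reads(ref, alleles = list(
    list(name = "WT", proportion = 0.5, type = "wt"),
    list(name = "del4", proportion = 0.5, type = "del",
         pos = ref$expected_cut - 2, len = 4)), n_reads = 20, seed = 2)
  for (r in sim$reads) {
    c1 <- classify_read(align_read(r, ref), ref)
    c2 <- classify_read(align_read(revcomp(r), ref), ref)
    expect_identical(c1$status, c2$status)
    expect_identical(c1$allele_key, c2$allele_key)
  }
})

test_that("summary reports exact frequency on the planted 30% fixture", {
  ref <- fixture_amplicon()
  sim <- simulate_amplicon_reads(ref, alleles = list(
    list(name = "WT", proportion = 0.7, type = "wt"),
    list(name = "del3", proportion = 0.3, type = "del",
         pos = ref$expected_cut - 1, len = 3)), n_reads = 100, seed = 5)
  summ <- quantify_edits(sim$reads, ref)
  expect_equal(summ$indel_frequency, 30.0)
  expect_equal(summ$n_edited, 30)
  # allele percentages + unedited account for all aligned reads
  expect_lte(sum(summ$allele_table$pct), 100 + 1e-9)
  expect_equal(sum(summ$allele_table$n), 100)
})

test_that("allele mix is recovered within 2% at n = 2000", {
  ref <- fixture_amplicon()
  sim <- simulate_amplicon_reads(ref, alleles = list(
    list(name = "WT", proportion = 0.6, type = "wt"),
    list(name = "del3", proportion = 0.25, type = "del",
         pos = ref$expected_cut - 1, len = 3),
    list(name = "del7", proportion = 0.15, type = "del",
         pos = ref$expected_cut - 3, len = 7)), n_reads = 2000, seed = 11)
  summ <- quantify_edits(sim$reads, ref)
  top3 <- summ$allele_table[1:3, ]
  expect_true(all(abs(sort(top3$pct, decreasing = TRUE) -
                        c(60, 25, 15)) <= 2))
  expect_true(abs(summ$indel_frequency - 40) <= 2)
})

test_that("deletion centers land PAM-distal, beyond the protospacer", {
  ref <- fixture_amplicon()
  sim <- simulate_amplicon_reads(ref, alleles = list(
    list(name = "WT", proportion = 0.4, type = "wt"),
    list(name = "del4", proportion = 0.6, type = "del",
         pos = ref$pam_end + 22, len = 4)), n_reads = 200, seed = 13)
  summ <- quantify_edits(sim$reads, ref)
  centers <- as.numeric(names(summ$deletion_centers))
  mode_center <- centers[which.max(summ$deletion_centers)]
  expect_equal(mode_center, 24)
  proto_len <- ref$protospacer_end - ref$protospacer_start
  expect_gt(mode_center, proto_len)
})

test_that("indel frequency is unbiased over seeded binomial replicates", {
  ref <- fixture_amplicon()
  rate <- 0.3
  est <- vapply(1:50, function(s) {
    sim <- simulate_amplicon_reads(ref, alleles = list(
      list(name = "WT", proportion = 1 - rate, type = "wt"),
      list(name = "del3", proportion = rate, type = "del",
           pos = ref$expected_cut - 1, len = 3)),
      n_reads = 60, allocation = "multinomial", seed = s)
    quantify_edits(sim$reads, ref)$indel_frequency
  }, 0)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 100 * rate), 3 * se + 1e-9)
})
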