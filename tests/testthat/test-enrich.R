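test_that("tabulate counts accepted records per sample and flags unassigned barcodes", {
  rec <- data.frame(
    read_id = sprintf("r%d", 1:5),
    barcode = c("ACT", "ACT", "AAA", "TTT", "ACT"),
    orientation = "forward",
    raw_insert = NA, insert_nt = NA,
    peptide = c("P1P1P1P1P1P1", "P1P1P1P1P1P1", "P2P2P2P2P2P2",
                "P1P1P1P1P1P1", NA),
    fate = c("accepted", "accepted", "accepted", "accepted", "discarded"),
    discard_reason = c(NA, NA, NA, NA, "stop_codon"),
    assigned = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  tab <- tabulate_peptides(rec, fixture_sheet)
  expect_equal(tab$counts["P1P1P1P1P1P1", "ACT"], 2L)
  expect_equal(tab$counts["P2P2P2P2P2P2", "AAA"], 1L)
  expect_equal(tab$counts["P1P1P1P1P1P1", "unassigned"], 1L)
  expect_equal(tab$samples$target[tab$samples$barcode == "unassigned"],
               "unassigned")
  # column sums equal accepted reads per sample
  expect_equal(sum(tab$counts), 4L)

  empty <- tabulate_peptides(rec[rec$fate == "none", ], fixture_sheet)
  expect_equal(nrow(empty$counts), 0L)
})

test_that("sample fractions reproduce the parental worked example (98 / 2,732)", {
  # a parental column whose 2,732 reads contain ALWPPNLHAWVP 98 times
  counts <- cbind(AAA = c(98L, 2000L, 634L), ACT = c(0L, 10L, 5L))
  rownames(counts) <- c("ALWPPNLHAWVP", "OTHERPEPTIDE", "THIRDPEPTIDE")
  samples <- data.frame(
    barcode = c("AAA", "ACT"), target = c("parental", "ubiquitin"),
    round = c(0L, 3L), wash = c("none", "slow"), amplified = FALSE,
    stringsAsFactors = FALSE
  )
  tab <- count_table(counts, samples)
  frac <- sample_fraction(tab, "ALWPPNLHAWVP", "AAA")
  expect_equal(frac, 98 / 2732)
  expect_gte(100 * frac, 3.5)
  expect_equal(sample_fraction(tab, "ALWPPNLHAWVP", "ACT"), 0)
  expect_warning(f0 <- sample_fraction(tab, "NOSUCHPEPTIDE", "AAA"), "not in table")
  expect_equal(f0, 0)
})

test_that("fractions within a sample sum to 1 and are scale-invariant", {
  for (seed in 1:10) {
    tab <- random_count_table(n_pep = 10, seed = seed)
    for (bc in colnames(tab$counts)) {
      fr <- vapply(rownames(tab$counts),
                   function(p) sample_fraction(tab, p, bc), numeric(1))
      csum <- sum(tab$counts[, bc])
      if (csum > 0) expect_equal(sum(fr), 1)
    }
    doubled <- count_table(tab$counts * 2L, tab$samples)
    p1 <- rownames(tab$counts)[1]
    expect_equal(sample_fraction(doubled, p1, "ACT"),
                 sample_fraction(tab, p1, "ACT"))
  }
})

test_that("round trajectories report per-round counts and fractions in order", {
  # constructed table where the binder holds 0%, 73% and 99% of rounds 1-3
  counts <- rbind(
    FIPAQLHFHWRS = c(0L, 0L, 730L, 990L, 0L),
    FILLERPEPTID = c(100L, 500L, 270L, 10L, 50L)
  )
  colnames(counts) <- fixture_sheet$barcode
  tab <- count_table(counts, as.data.frame(fixture_sheet))
  tr <- round_trajectory(tab, "FIPAQLHFHWRS", target = "ubiquitin",
                         wash = "slow", amplified = FALSE)
  expect_equal(tr$round, 1:3)
  expect_equal(tr$fraction, c(0, 0.73, 0.99))
  expect_equal(tr$count, c(0L, 730L, 990L))

  # absent peptide: all-zero trajectory of the same shape
  tr0 <- round_trajectory(tab, "NOTINTHETABLE", target = "ubiquitin",
                          wash = "slow", amplified = FALSE)
  expect_equal(tr0$fraction, c(0, 0, 0))

  # single-round selector
  tr1 <- round_trajectory(tab, "FIPAQLHFHWRS", target = "ubiquitin",
                          amplified = TRUE)
  expect_equal(nrow(tr1), 1L)
  expect_warning(round_trajectory(tab, "FIPAQLHFHWRS", target = "nedd8"),
                 "no sample")
})

test_that("target overlap computes jaccard and min-denominator metrics", {
  a <- c("a", "b", "c", "d")
  b <- c("a", "e", "f")
  expect_equal(target_overlap(a, b, "jaccard"), 1 / 6)
  expect_equal(target_overlap(a, b, "min"), 1 / 3)
  both <- target_overlap(a, b)
  expect_equal(both[["jaccard"]], 1 / 6)
  expect_equal(both[["min"]], 1 / 3)
  expect_equal(target_overlap(a, a), c(jaccard = 1, min = 1))
  expect_equal(target_overlap(a, c("x", "y")), c(jaccard = 0, min = 0))
  # symmetry of jaccard
  expect_equal(target_overlap(a, b, "jaccard"), target_overlap(b, a, "jaccard"))
  expect_error(target_overlap(character(0), character(0)), "empty")
})

test_that("position frequency matrices give normalized columns and majority consensus", {
  single <- position_frequency_matrix("FIPAQLHFHWRS")
  expect_equal(pfm_consensus(single), "FIPAQLHFHWRS")
  expect_true(all(abs(colSums(single) - 1) < 1e-12))
  expect_true(all(apply(single, 2, max) == 1))

  pair <- position_frequency_matrix(c("FIPAQLHFHWRS", "FIAAQLAFHWRS"))
  expect_equal(pfm_consensus(pair), "FIxAQLxFHWRS")
  expect_true(all(abs(colSums(pair) - 1) < 1e-12))

  expect_error(position_frequency_matrix(c("ABC", "ABCD")), "same length")
})

test_that("enrichment report covers every peptide-sample pair", {
  tab <- random_count_table(n_pep = 5, seed = 2)
  enr <- enrichment_report(tab)
  expect_equal(nrow(enr), nrow(tab$counts) * ncol(tab$counts))
  expect_true(all(enr$fraction >= 0 & enr$fraction <= 1))
  agg <- tapply(enr$fraction, enr$barcode, sum)
  expect_true(all(abs(agg[colSums(tab$counts) > 0] - 1) < 1e-12))
})
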