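test_that("reverse_complement is a Watson-Crick involution and matches Biostrings", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement("ANT"), "ANT")
  expect_error(reverse_complement("ACGU"), "non-nucleotide")
  set.seed(3)
  for (i in 1:25) {
    s <- random_nt(sample(1:60, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(reverse_complement(s),
                 as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
})

test_that("length prefilter discards reads too short for the variable region", {
  layout <- fixture_layout
  expect_equal(length_prefilter(strrep("A", 10), layout), "too_short")
  thr <- min_read_length(layout)
  expect_equal(length_prefilter(strrep("A", thr), layout), "pass")
  expect_equal(length_prefilter(strrep("A", thr - 1L), layout), "too_short")
})

test_that("anchor search sets orientation and extracts the adjacent barcode", {
  layout <- fixture_layout
  ins <- encode_peptide_nnk("FIPAQLHFHWRS")
  fwd <- make_clean_read(ins, "ACT")
  ob <- orient_and_barcode(fwd, layout)
  expect_equal(ob$orientation, "forward")
  expect_equal(ob$barcode, "ACT")

  rev <- make_clean_read(ins, "AAA", strand = "reverse")
  ob2 <- orient_and_barcode(rev, layout)
  expect_equal(ob2$orientation, "reverse")
  expect_equal(ob2$barcode, "AAA")

  expect_equal(orient_and_barcode(strrep("G", 80), layout)$reason,
               "no_anchor_match")
  # a read ending inside the barcode slot has an incomplete barcode
  short_bc <- paste0(strrep("C", 8), layout$fwd_anchor, "AC")
  expect_equal(orient_and_barcode(short_bc, layout)$reason, "incomplete_barcode")
  # N inside the barcode is an incomplete barcode
  n_bc <- sub("ACT", "ANT", make_clean_read(ins, "ACT"), fixed = TRUE)
  expect_equal(orient_and_barcode(n_bc, layout)$reason, "incomplete_barcode")
  # both anchors inside the search window is ambiguous (short-anchor layout,
  # since two 12-nt anchors cannot co-occur in the fixture's window)
  shorty <- construct_layout("AAGGCC", "TTCCGG", left_border = "TATTCTCACTCT",
                             right_border = "GGTGGAGGTTCG",
                             anchor_min_length = 6L)
  both <- paste0("AAGGCC", "TTCCGG", "ACT", strrep("A", 80))
  expect_equal(orient_and_barcode(both, shorty)$reason, "ambiguous_orientation")
})

test_that("insert extraction is border-delimited and strand-aware", {
  layout <- fixture_layout
  ins <- encode_peptide_nnk("AKFDMHIATRLS")
  fwd <- make_clean_read(ins, "ACT")
  q <- seq_len(nchar(fwd))
  ob <- orient_and_barcode(fwd, layout)
  ex <- extract_insert(fwd, q, "forward", layout, from = ob$barcode_end)
  expect_equal(ex$raw_insert, ins)
  expect_length(ex$raw_quals, 36L)

  # the reverse complement of the same amplicon yields the identical insert
  # with the quality slice reversed
  rev <- reverse_complement(fwd)
  qr <- rev(q)
  ob2 <- orient_and_barcode(rev, layout)
  ex2 <- extract_insert(rev, qr, "reverse", layout, from = ob2$barcode_end)
  expect_equal(ex2$raw_insert, ins)
  expect_equal(ex2$raw_quals, ex$raw_quals)

  no_rb <- paste0(layout$fwd_anchor, "ACT", layout$left_border, ins, "GGGAAA")
  expect_equal(extract_insert(no_rb, NULL, "forward", layout, from = 15L)$reason,
               "border_not_found")
})

test_that("repair removes lowest-quality bases, 3'-most first on ties", {
  layout <- fixture_layout
  ins36 <- encode_peptide_nnk("GAVTLSNQWKRD")
  expect_equal(repair_insert(ins36, rep(30L, 36), layout)$insert_nt, ins36)
  expect_equal(repair_insert(substr(ins36, 1, 30), rep(30L, 30), layout)$reason,
               "under_length")
  expect_equal(repair_insert(paste0(ins36, "AA"), NULL, layout)$reason,
               "repair_failed")

  # 38-nt input with its two strictly lowest qualities at positions 5 and 20
  padded <- paste0(substr(ins36, 1, 4), "A", substr(ins36, 5, 18), "C",
                   substr(ins36, 19, 36))
  q <- rep(30L, 38); q[5] <- 3L; q[20] <- 7L
  expect_equal(repair_insert(padded, q, layout)$insert_nt, ins36)

  # tie rule: equal minimal quality removes the 3'-most base first
  two_extra <- paste0("GG", ins36)
  q2 <- rep(10L, 38); q2[1] <- 10L
  got <- repair_insert(two_extra, q2, layout, tie = "right")$insert_nt
  expect_equal(got, substr(two_extra, 1, 36))
  got_left <- repair_insert(two_extra, q2, layout, tie = "left")$insert_nt
  expect_equal(got_left, ins36)
})

test_that("repair equals the brute-force lowest-quality-multiset oracle", {
  layout <- fixture_layout
  # oracle: one-shot removal of the (L - 36) positions ranked by
  # (quality ascending, position descending)
  oracle <- function(insert, q) {
    k <- nchar(insert) - 36L
    ch <- strsplit(insert, "")[[1]]
    if (k > 0L) ch <- ch[-order(q, -seq_along(q))[seq_len(k)]]
    paste(ch, collapse = "")
  }
  set.seed(99)
  for (i in 1:300) {
    len <- sample(36:45, 1)
    ins <- random_nt(len)
    q <- sample(0:40, len, replace = TRUE)
    expect_equal(repair_insert(ins, q, layout)$insert_nt, oracle(ins, q))
  }
})

test_that("NNK validation equals brute-force membership for all 64 codons", {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases, paste0))
  nnk_set <- all64[substr(all64, 3, 3) %in% c("G", "T")]
  expect_length(nnk_set, 32L)
  pad <- strrep("GCT", 11)  # 11 valid Ala codons as context
  for (codon in all64) {
    got <- validate_codons(paste0(pad, codon), amber = "reject")
    want <- if (codon %in% c("TAA", "TGA", "TAG")) {
      "stop_codon"
    } else if (codon %in% nnk_set) "pass" else "codon_invalid"
    expect_equal(got, want, label = codon)
  }
})

test_that("amber policy controls the fate of TAG codons", {
  tag_insert <- paste0(strrep("GCT", 11), "TAG")
  expect_equal(validate_codons(tag_insert, amber = "reject"), "stop_codon")
  expect_equal(validate_codons(tag_insert, amber = "suppress"), "pass")
  expect_equal(translate_insert(tag_insert, amber = "suppress"),
               paste0(strrep("A", 11), "Q"))
  expect_equal(validate_codons(paste0(strrep("GCT", 11), "AAA")), "codon_invalid")
  expect_equal(validate_codons(paste0(strrep("GCT", 11), "TNG")), "codon_invalid")
})

test_that("translation inverts the NNK encoder for known binder peptides", {
  expect_equal(translate_insert(strrep("GGT", 12)), strrep("G", 12))
  set.seed(8)
  for (pep in c("FIPAQLHFHWRS", "AKFDMHIATRLS", "HMGRHMHEGASS")) {
    for (i in 1:5) {
      enc <- encode_peptide_nnk(pep)
      expect_equal(validate_codons(enc), "pass")
      expect_equal(translate_insert(enc), pep)
    }
  }
})

test_that("deconvolve_read composes the steps and reports first failure", {
  layout <- fixture_layout
  ins <- encode_peptide_nnk("FIPAQLHFHWRS")
  r <- make_clean_read(ins, "ACT")
  rec <- deconvolve_read(r, flat_quals(r), layout, fixture_sheet, read_id = "ok")
  expect_equal(rec$fate, "accepted")
  expect_equal(rec$barcode, "ACT")
  expect_equal(rec$peptide, "FIPAQLHFHWRS")
  expect_true(rec$assigned)

  # unknown barcode is retained but flagged unassigned
  rec_un <- deconvolve_read(make_clean_read(ins, "TTT"), NULL, layout, fixture_sheet)
  expect_equal(rec_un$fate, "accepted")
  expect_false(rec_un$assigned)

  # an extra low-quality base inside the variable region is repaired away
  bad <- paste0(layout$fwd_anchor, "ACT", layout$left_border,
                substr(ins, 1, 17), "A", substr(ins, 18, 36),
                layout$right_border, "CATCATACGATCGTTACAGCTAGCTAAGTC",
                reverse_complement("ACT"), reverse_complement(layout$rev_anchor))
  q <- flat_quals(bad)
  q[nchar(layout$fwd_anchor) + 3L + nchar(layout$left_border) + 18L] <- 2L
  rec2 <- deconvolve_read(bad, q, layout, fixture_sheet)
  expect_equal(rec2$fate, "accepted")
  expect_equal(rec2$peptide, "FIPAQLHFHWRS")

  # a stop codon in the insert is discarded as stop_codon
  stop_ins <- paste0(substr(ins, 1, 33), "TAG")
  rec3 <- deconvolve_read(make_clean_read(stop_ins), flat_quals(make_clean_read(stop_ins)),
                          layout, fixture_sheet)
  expect_equal(rec3$discard_reason, "stop_codon")
})

test_that("strand equivalence: a read and its reverse complement deconvolve identically", {
  layout <- fixture_layout
  set.seed(21)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:50) {
    pep <- paste(sample(aa, 12, replace = TRUE), collapse = "")
    r <- make_clean_read(encode_peptide_nnk(pep), "AGG")
    fwd <- deconvolve_read(r, flat_quals(r), layout, fixture_sheet)
    rc <- reverse_complement(r)
    rev <- deconvolve_read(rc, rev(flat_quals(r)), layout, fixture_sheet)
    expect_equal(fwd$fate, "accepted")
    expect_equal(rev$orientation, "reverse")
    expect_equal(rev$insert_nt, fwd$insert_nt)
    expect_equal(rev$peptide, fwd$peptide)
  }
})

test_that("batch deconvolution agrees with the per-read reference path", {
  layout <- fixture_layout
  cfg <- sim_config(fixture_layout, fixture_sheet,
                    example_spectra()[c(1, 3, 11), , drop = FALSE],
                    wt_rate = 0.08, sub_rate = 0.01, hp_indel_rate = 0.01,
                    seed = 17)
  gt <- simulate_reads(cfg)
  batch <- deconvolve_reads(gt$reads, layout, fixture_sheet)
  single <- lapply(seq_len(nrow(gt$reads)), function(i) {
    deconvolve_read(gt$reads$bases[i], gt$reads$quals[[i]], layout,
                    fixture_sheet, read_id = gt$reads$read_id[i])
  })
  single <- do.call(rbind, lapply(single, function(x) {
    as.data.frame(x, stringsAsFactors = FALSE)
  }))
  for (col in c("barcode", "orientation", "insert_nt", "peptide", "fate",
                "discard_reason", "assigned")) {
    expect_equal(batch[[col]], single[[col]], label = col)
  }
})

test_that("every read yields exactly one record and reasons partition the input", {
  cfg <- sim_config(fixture_layout, fixture_sheet,
                    example_spectra()[1:5, , drop = FALSE],
                    wt_rate = 0.1, sub_rate = 0.02, hp_indel_rate = 0.02,
                    seed = 5)
  gt <- simulate_reads(cfg)
  rec <- deconvolve_reads(gt$reads, fixture_layout, fixture_sheet)
  expect_equal(nrow(rec), nrow(gt$reads))
  ds <- discard_summary(rec)
  expect_equal(sum(ds$reads), nrow(gt$reads))
  expect_true(all(rec$fate[!is.na(rec$peptide)] == "accepted"))
  expect_true(all(is.na(rec$peptide[rec$fate == "discarded"])))
  expect_true(all(!is.na(rec$discard_reason[rec$fate == "discarded"])))
})
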