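# Shared fixtures: a clean-read builder independent of the simulator's
# internals, plus small random-table generators.

fixture_layout <- phagedeconv::example_layout()
fixture_sheet <- phagedeconv::example_sample_sheet()

# Hand-assembled amplicon read: anchor + barcode + left border + insert +
# right border + filler + revcomp(barcode + rev anchor). `insert` is given
# as nucleotides so tests control codon content exactly.
make_clean_read <- function(insert, barcode = "ACT", layout = fixture_layout,
                            strand = c("forward", "reverse"),
                            filler = "CATCATACGATCGTTACAGCTAGCTAAGTC") {
  strand <- match.arg(strand)
  amp <- paste0(layout$fwd_anchor, barcode, layout$left_border, insert,
                layout$right_border, filler,
                phagedeconv::reverse_complement(barcode),
                phagedeconv::reverse_complement(layout$rev_anchor))
  if (strand == "reverse") amp <- phagedeconv::reverse_complement(amp)
  amp
}

# Uniform qualities for a read.
flat_quals <- function(bases, q = 30L) rep(q, nchar(bases))

# A small random count table over random peptide strings.
random_count_table <- function(n_pep = 8, seed = 1) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  peps <- unique(replicate(n_pep, paste(sample(aa, 12, replace = TRUE), collapse = "")))
  counts <- matrix(rpois(length(peps) * nrow(fixture_sheet), 5),
                   nrow = length(peps),
                   dimnames = list(peps, fixture_sheet$barcode))
  phagedeconv::count_table(counts, as.data.frame(fixture_sheet))
}

# Random NNK insert of a given codon count (nucleotide level, no stops
# guaranteed -- callers that need validity should use encode_peptide_nnk).
random_nt <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
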