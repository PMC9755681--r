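# Reference fixture: the Ph.D.-12 style experiment the simulator replays.
# Anchors and borders are invented (the original primer sequences are not
# machine-readable); the right border is a plausible Gly-Gly-Gly-Ser
# spacer-coding sequence so the construct stays biologically coherent.
# The same fixture ships as text under inst/extdata/.

#' Reference Ph.D.-12 construct layout
#'
#' A 12-codon NNK insert flanked by fixed borders, trinucleotide inline
#' barcodes behind 12-nt primer anchors, a 4-codon Gly-Gly-Gly-Ser spacer and
#' a 381-nt wild-type amplicon.
#'
#' @return A [construct_layout()].
#' @export
example_layout <- function() {
  construct_layout(
    fwd_anchor = "GCCTTGCTAGCG",
    rev_anchor = "TCAGGTCACGTT",
    barcode_length = 3L,
    left_border = "TATTCTCACTCT",
    right_border = "GGTGGAGGTTCG",  # GGT GGA GGT TCG: Gly-Gly-Gly-Ser
    insert_codons = 12L,
    spacer_codons = 4L,
    wt_amplicon_length = 381L,
    anchor_min_length = 12L
  )
}

#' Reference sample sheet
#'
#' The five-barcode design: AAA tags the unpanned parental library; ACT, ATC
#' and AGG tag ubiquitin rounds 3, 1 and 2 under high-stringency (slow)
#' washes with unamplified phage; ACG tags round 1 with amplified phage.
#'
#' @return A [sample_sheet()].
#' @export
example_sample_sheet <- function() {
  sample_sheet(
    barcode = c("AAA", "ATC", "AGG", "ACT", "ACG"),
    target = c("parental", "ubiquitin", "ubiquitin", "ubiquitin", "ubiquitin"),
    round = c(0L, 1L, 2L, 3L, 1L),
    wash = c("none", "slow", "slow", "slow", "slow"),
    amplified = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    layout = example_layout()
  )
}

#' Reference peptide spectra (true counts per sample)
#'
#' Twenty 12-mers over five samples at depth 2,000 reads per sample. The
#' composition emulates the enrichment pattern of the experiment: the
#' high-affinity binder FIPAQLHFHWRS is absent from round 1, dominant by
#' round 3; parental-biased background peptides (headed by ALWPPNLHAWVP at
#' 3.6% of the parental pool) fade under stringent washing; binder-class
#' peptides are rare (count <= 2) in the parental library so they survive
#' the parental filter. Consecutive per-sample counts are separated widely
#' enough that read loss at the default error rates leaves the top-5 rank
#' order intact.
#'
#' @return An integer matrix, 20 peptides x 5 barcodes, each column summing
#'   to 2,000.
#' @export
example_spectra <- function() {
  peptides <- c(
    # binder class (rare in the parental pool)
    "FIPAQLHFHWRS", "HMGRHMHEGASS", "WPLFHFHERGSH", "HYTHTHQYTYSM",
    "QHFHIGESGSLL", "KLWVIPQSGRTA", "NDVRSGWQTYLK", "SMTWNAKEPGVQ",
    "RQEYWSLGNKAV", "GAVTLSNQWKRD",
    # propagation-biased background (abundant in the parental pool)
    "ALWPPNLHAWVP", "AHSANNFDVKGI", "TPMVERNYNAAD", "MPLMSEPALEML",
    "YSAHNYIGDSGP", "LNTPQGAWSVKE", "EKSGVYWPQLNT", "VWGKQNSLTAEP",
    "TQNPSGLWVAKE", "GQDFVSNLWTAK"
  )
  m <- cbind(
    AAA = c(0L, 2L, 2L, 1L, 2L, 1L, 1L, 0L, 0L, 0L,
            72L, 470L, 340L, 265L, 215L, 175L, 145L, 120L, 100L, 89L),
    ATC = c(0L, 140L, 500L, 260L, 190L, 85L, 60L, 50L, 32L, 25L,
            360L, 100L, 70L, 40L, 30L, 20L, 15L, 10L, 8L, 5L),
    AGG = c(1400L, 180L, 80L, 52L, 34L, 24L, 15L, 10L, 6L, 4L,
            120L, 30L, 20L, 12L, 8L, 3L, 2L, 0L, 0L, 0L),
    ACT = c(1800L, 80L, 48L, 30L, 20L, 10L, 5L, 3L, 2L, 2L,
            0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    ACG = c(700L, 115L, 380L, 250L, 78L, 52L, 36L, 30L, 15L, 10L,
            170L, 62L, 44L, 25L, 20L, 6L, 4L, 2L, 1L, 0L)
  )
  rownames(m) <- peptides
  stopifnot(all(colSums(m) == 2000L))
  m
}

#' Reference simulation config
#'
#' The full fixture: [example_layout()], [example_sample_sheet()] and
#' [example_spectra()] with the default 454-style error model (5% wild-type
#' contamination, 0.5% substitutions, 0.5% homopolymer indels).
#'
#' @param seed integer seed.
#' @param wt_rate,sub_rate,hp_indel_rate overrides of the default error
#'   model (set all to 0 for an error-free run).
#' @return A [sim_config()].
#' @export
example_sim_config <- function(seed = 1L, wt_rate = 0.05, sub_rate = 0.005,
                               hp_indel_rate = 0.005) {
  sim_config(example_layout(), example_sample_sheet(), example_spectra(),
             wt_rate = wt_rate, sub_rate = sub_rate,
             hp_indel_rate = hp_indel_rate, seed = seed)
}
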