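# End-to-end orchestration: deconvolve -> filter -> enrich, with a JSON run
# manifest whose read accounting always balances.

write_tsv <- function(df, file) {
  con <- file(file, "wb")
  lines <- paste(names(df), collapse = "\t")
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(file)
}

pkg_version <- function() {
  as.character(utils::packageVersion("phagedeconv"))
}

#' Run the full deconvolution pipeline on sequencing input
#'
#' Reads FASTA+QUAL or FASTQ input, deconvolutes every read, tabulates
#' accepted peptides per barcode, applies the background filters and writes:
#' `records.tsv` (one row per read), `discard_summary.tsv`, `counts_raw.csv`,
#' `counts_filtered.csv`, `filter_report.tsv`, `enrichment.tsv` (per-peptide
#' per-sample fractions on the filtered table) and `manifest.json`.
#'
#' @param fasta_file,qual_file paired 454-style input (both or neither).
#' @param fastq_file FASTQ input (alternative to the pair).
#' @param layout a [construct_layout()] or path to a layout config file.
#' @param sheet a [sample_sheet()] or path to a sample sheet table.
#' @param out_dir output directory (created if missing).
#' @param policy a [filter_policy()].
#' @param amber,repair_tie see [deconvolve_read()].
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(fasta_file = NULL, qual_file = NULL,
                         fastq_file = NULL, layout, sheet, out_dir,
                         policy = filter_policy(), amber = "reject",
                         repair_tie = "right") {
  if (is.character(layout)) layout <- read_layout_config(layout)
  if (is.character(sheet)) sheet <- load_sample_sheet(sheet, layout)
  if (!is.null(fastq_file)) {
    reads <- read_fastq(fastq_file)
    inputs <- list(fastq = fastq_file)
  } else if (!is.null(fasta_file)) {
    if (is.null(qual_file)) {
      reads <- seq_reads(
        sub("\\s.*$", "", names(Biostrings::readBStringSet(fasta_file))),
        as.character(Biostrings::readBStringSet(fasta_file))
      )
    } else {
      reads <- read_fasta_qual(fasta_file, qual_file)
    }
    inputs <- list(fasta = fasta_file, qual = qual_file)
  } else {
    stop("provide fasta_file (+ qual_file) or fastq_file")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  records <- deconvolve_reads(reads, layout, sheet, amber = amber,
                              repair_tie = repair_tie)
  dsum <- discard_summary(records)
  raw_table <- tabulate_peptides(records, sheet)
  filt <- apply_filters(raw_table, policy,
                        require_parental = any(sheet$target == "parental"))
  enr <- enrichment_report(filt$table)

  write_tsv(records, file.path(out_dir, "records.tsv"))
  write_tsv(dsum, file.path(out_dir, "discard_summary.tsv"))
  write_count_csv(raw_table, file.path(out_dir, "counts_raw.csv"))
  write_count_csv(filt$table, file.path(out_dir, "counts_filtered.csv"))
  write_tsv(filt$report, file.path(out_dir, "filter_report.tsv"))
  write_tsv(enr, file.path(out_dir, "enrichment.tsv"))

  by_reason <- dsum$reads[dsum$outcome != "accepted"]
  names(by_reason) <- dsum$outcome[dsum$outcome != "accepted"]
  manifest <- list(
    tool = "phagedeconv", version = pkg_version(),
    inputs = inputs,
    layout = unclass(layout),
    n_samples = nrow(sheet),
    policy = list(his_mode = policy$his_mode,
                  parental_max = policy$parental_max,
                  amber = amber, repair_tie = repair_tie),
    reads_in = nrow(reads),
    accepted = sum(records$fate == "accepted"),
    discarded = as.list(by_reason),
    peptides_raw = nrow(raw_table$counts),
    peptides_filtered = nrow(filt$table$counts),
    peptides_removed = nrow(filt$report)
  )
  stopifnot(manifest$accepted + sum(by_reason) == manifest$reads_in)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf(
    "phagedeconv: %d reads in, %d accepted, %d peptides (%d after filtering)",
    manifest$reads_in, manifest$accepted, manifest$peptides_raw,
    manifest$peptides_filtered
  ))
  invisible(manifest)
}

#' Run the simulator and write its outputs plus a manifest
#'
#' @param config a [sim_config()].
#' @param out_dir output directory; receives `reads.fasta`, `reads.qual`,
#'   `reads.fastq`, `truth.tsv` and `manifest.json`.
#' @return Invisibly, the `ground_truth` object.
#' @export
run_simulation <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gt <- simulate_reads(
    config,
    fasta_file = file.path(out_dir, "reads.fasta"),
    qual_file = file.path(out_dir, "reads.qual"),
    fastq_file = file.path(out_dir, "reads.fastq"),
    truth_file = file.path(out_dir, "truth.tsv")
  )
  manifest <- list(
    tool = "phagedeconv simulate", version = pkg_version(),
    seed = config$seed,
    rates = list(wt = config$wt_rate, sub = config$sub_rate,
                 hp_indel = config$hp_indel_rate),
    n_reads = nrow(gt$reads),
    n_samples = ncol(config$spectra),
    n_peptides = nrow(config$spectra)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("phagedeconv simulate: wrote %d reads to %s",
                  nrow(gt$reads), out_dir))
  invisible(gt)
}
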