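# Peptide x sample count tables and enrichment summaries: per-sample
# fractions, round trajectories, cross-target overlap, and a
# position-frequency consensus.

#' Construct a peptide x sample count table
#'
#' Rows are peptides sorted by total count (descending, ties lexicographic);
#' columns are samples in sample-sheet order. Column sums equal the number of
#' accepted reads assigned to each sample.
#'
#' @param counts nonnegative integer matrix with peptide rownames and one
#'   column per sample barcode.
#' @param samples `data.frame` with columns `barcode`, `target`, `round`,
#'   `wash`, `amplified`, one row per column of `counts`.
#' @return A list of class `count_table` with elements `counts`, `samples`,
#'   `totals`.
#' @export
count_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (anyNA(counts) || any(counts < 0L)) stop("counts must be nonnegative integers")
  if (ncol(counts) != nrow(samples)) {
    stop("counts must have one column per sample")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  colnames(counts) <- samples$barcode
  if (nrow(counts) && is.null(rownames(counts))) stop("counts needs peptide rownames")
  totals <- as.integer(rowSums(counts))
  if (nrow(counts)) {
    ord <- order(-totals, rownames(counts))
    counts <- counts[ord, , drop = FALSE]
    totals <- totals[ord]
  }
  structure(list(counts = counts, samples = samples, totals = totals),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d peptides x %d samples (%d reads)\n",
              nrow(x$counts), ncol(x$counts), sum(x$totals)))
  if (nrow(x$counts)) {
    print(utils::head(cbind(total = x$totals, x$counts), 10))
    if (nrow(x$counts) > 10) cat(sprintf("... %d more peptides\n", nrow(x$counts) - 10))
  }
  invisible(x)
}

#' Tabulate accepted reads into a count table
#'
#' Counts each accepted record's peptide under its sample barcode. All sample
#' sheet barcodes appear as columns (zero-filled when unseen); accepted reads
#' whose barcode is not in the sheet are aggregated into one flagged
#' `unassigned` pseudo-sample.
#'
#' @param records an `insert_records` table from [deconvolve_reads()].
#' @param sheet a [sample_sheet()].
#' @return A [count_table()].
#' @export
tabulate_peptides <- function(records, sheet) {
  stopifnot(inherits(sheet, "sample_sheet"))
  acc <- records[records$fate == "accepted", , drop = FALSE]
  bc <- ifelse(acc$barcode %in% sheet$barcode, acc$barcode, "unassigned")
  has_unassigned <- any(bc == "unassigned")
  samples <- as.data.frame(sheet, stringsAsFactors = FALSE)
  class(samples) <- "data.frame"
  if (has_unassigned) {
    samples <- rbind(samples, data.frame(
      barcode = "unassigned", target = "unassigned", round = NA_integer_,
      wash = "none", amplified = FALSE, stringsAsFactors = FALSE
    ))
  }
  peptides <- sort(unique(acc$peptide))
  counts <- matrix(0L, length(peptides), nrow(samples),
                   dimnames = list(peptides, samples$barcode))
  if (nrow(acc)) {
    t2 <- table(factor(acc$peptide, levels = peptides),
                factor(bc, levels = samples$barcode))
    counts <- matrix(as.integer(t2), nrow(t2),
                     dimnames = list(peptides, samples$barcode))
  }
  count_table(counts, samples)
}

#' Fraction of a sample's reads carrying a peptide
#'
#' @param table a [count_table()].
#' @param peptide peptide string.
#' @param barcode sample barcode (column) to evaluate.
#' @return `count / column sum`, 0 when the column is empty; an unknown
#'   peptide returns 0 with a warning.
#' @export
sample_fraction <- function(table, peptide, barcode) {
  stopifnot(inherits(table, "count_table"))
  if (!barcode %in% colnames(table$counts)) {
    stop(sprintf("unknown sample barcode '%s'", barcode))
  }
  csum <- sum(table$counts[, barcode])
  if (csum == 0L) return(0)
  if (!peptide %in% rownames(table$counts)) {
    warning(sprintf("peptide '%s' not in table; fraction is 0", peptide))
    return(0)
  }
  table$counts[peptide, barcode] / csum
}

#' Enrichment trajectory of a peptide across panning rounds
#'
#' For the samples matching a (target, wash, amplified) selector, reports the
#' peptide's count and its share of each round's accepted reads, rounds in
#' ascending order.
#'
#' @param table a [count_table()].
#' @param peptide peptide string.
#' @param target,wash,amplified selector; a `NULL` field matches anything.
#' @return `data.frame` with columns `round`, `count`, `fraction`.
#' @export
round_trajectory <- function(table, peptide, target = NULL, wash = NULL,
                             amplified = NULL) {
  stopifnot(inherits(table, "count_table"))
  s <- table$samples
  sel <- rep(TRUE, nrow(s))
  if (!is.null(target)) sel <- sel & s$target == target
  if (!is.null(wash)) sel <- sel & s$wash == wash
  if (!is.null(amplified)) sel <- sel & s$amplified == amplified
  sel <- sel & !is.na(s$round)
  if (!any(sel)) {
    warning("selector matches no sample; empty trajectory")
    return(data.frame(round = integer(0), count = integer(0),
                      fraction = numeric(0)))
  }
  rounds <- sort(unique(s$round[sel]))
  cnt <- integer(length(rounds))
  frac <- numeric(length(rounds))
  pep_row <- match(peptide, rownames(table$counts))
  for (i in seq_along(rounds)) {
    cols <- which(sel & s$round == rounds[i])
    csum <- sum(table$counts[, cols])
    cnt[i] <- if (is.na(pep_row)) 0L else sum(table$counts[pep_row, cols])
    frac[i] <- if (csum == 0L) 0 else cnt[i] / csum
  }
  data.frame(round = rounds, count = cnt, fraction = frac)
}

#' Overlap between two targets' peptide sets
#'
#' @param peptides_a,peptides_b character vectors (treated as sets).
#' @param metric `"jaccard"` (intersection over union), `"min"`
#'   (intersection over the smaller set) or `"both"` (default: a named
#'   vector with both).
#' @return Overlap fraction(s) in `[0, 1]`.
#' @export
target_overlap <- function(peptides_a, peptides_b,
                           metric = c("both", "jaccard", "min")) {
  metric <- match.arg(metric)
  a <- unique(peptides_a)
  b <- unique(peptides_b)
  if (!length(a) && !length(b)) {
    stop("target_overlap is undefined for two empty peptide sets")
  }
  inter <- length(intersect(a, b))
  jac <- inter / length(union(a, b))
  if (metric == "jaccard") return(jac)
  if (!length(a) || !length(b)) {
    stop("the min-denominator overlap needs two nonempty peptide sets")
  }
  mn <- inter / min(length(a), length(b))
  if (metric == "min") return(mn)
  c(jaccard = jac, min = mn)
}

#' Position frequency matrix over equal-length peptides
#'
#' A lightweight consensus summary: per-position residue frequencies and a
#' consensus string reporting the strict-majority residue per column, with
#' `x` where no residue exceeds half the sequences.
#'
#' @param peptides character vector of equal-length amino-acid strings.
#' @return A 20 x k matrix of class `pfm` (rows: residues, columns sum to 1)
#'   with the consensus string in `attr(, "consensus")`.
#' @export
position_frequency_matrix <- function(peptides) {
  if (!length(peptides)) stop("need at least one peptide")
  k <- unique(nchar(peptides))
  if (length(k) != 1L) stop("peptides must all have the same length")
  bad <- grepl(sprintf("[^%s]", paste(AA_LETTERS, collapse = "")), peptides)
  if (any(bad)) stop(sprintf("non-amino-acid character in '%s'", peptides[bad][1]))
  chars <- do.call(rbind, strsplit(peptides, "", fixed = TRUE))
  pfm <- vapply(seq_len(k), function(j) {
    as.vector(table(factor(chars[, j], levels = AA_LETTERS))) / length(peptides)
  }, numeric(length(AA_LETTERS)))
  dimnames(pfm) <- list(AA_LETTERS, seq_len(k))
  cons <- vapply(seq_len(k), function(j) {
    top <- which.max(pfm[, j])
    if (pfm[top, j] > 0.5) AA_LETTERS[top] else "x"
  }, character(1))
  structure(pfm, consensus = paste(cons, collapse = ""), class = c("pfm", "matrix"))
}

#' Consensus string of a position frequency matrix
#' @param pfm a matrix from [position_frequency_matrix()].
#' @return The consensus string (strict-majority residue per column, else `x`).
#' @export
pfm_consensus <- function(pfm) {
  attr(pfm, "consensus")
}

#' Per-peptide per-sample enrichment fractions
#'
#' @param table a [count_table()].
#' @return `data.frame` with one row per (peptide, sample): `peptide`,
#'   `barcode`, `count`, `fraction` of that sample's reads.
#' @export
enrichment_report <- function(table) {
  stopifnot(inherits(table, "count_table"))
  csums <- colSums(table$counts)
  n <- nrow(table$counts)
  m <- ncol(table$counts)
  frac <- sweep(table$counts, 2, pmax(csums, 1L), "/")
  frac[, csums == 0L] <- 0
  data.frame(
    peptide = rep(rownames(table$counts), times = m),
    barcode = rep(colnames(table$counts), each = n),
    count = as.integer(table$counts),
    fraction = as.numeric(frac),
    stringsAsFactors = FALSE
  )
}
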