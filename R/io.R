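#' Construct a table of sequencing reads
#'
#' The per-read unit of the pipeline: an identifier, a nucleotide string and
#' (optionally) one Phred-scaled integer quality per base. Bases are
#' case-normalized to upper case, `U` is normalized to `T` and any other
#' non-IUPAC-core character becomes `N`; strictness about `N` is applied
#' downstream, not at ingestion.
#'
#' @param read_id character vector of read identifiers.
#' @param bases character vector of nucleotide strings.
#' @param quals `NULL` (quality-less FASTA input) or a list of integer
#'   vectors, one per read, each the same length as its read and with values
#'   in `[0, 93]`.
#' @return A `data.frame` of class `seq_reads` with columns `read_id`,
#'   `bases` and a list column `quals` (entries `NULL` when absent).
#' @export
seq_reads <- function(read_id, bases, quals = NULL) {
  read_id <- as.character(read_id)
  bases <- normalize_bases(as.character(bases))
  n <- length(read_id)
  if (length(bases) != n) {
    stop("read_id and bases must have equal length")
  }
  if (is.null(quals)) {
    quals <- rep(list(NULL), n)
  } else {
    if (!is.list(quals) || length(quals) != n) {
      stop("quals must be a list with one entry per read")
    }
    has_q <- !vapply(quals, is.null, logical(1))
    qlen <- integer(n)
    qlen[has_q] <- lengths(quals[has_q])
    bad <- which(has_q & qlen != nchar(bases))
    if (length(bad)) {
      i <- bad[1]
      stop(sprintf("record '%s': %d quality values for %d bases",
                   read_id[i], qlen[i], nchar(bases[i])))
    }
    flat <- unlist(quals[has_q], use.names = FALSE)
    if (length(flat)) {
      flat <- as.integer(flat)
      if (anyNA(flat) || any(flat < 0L) || any(flat > 93L)) {
        bad_rec <- which(has_q)[findInterval(
          which(is.na(flat) | flat < 0L | flat > 93L)[1] - 1L,
          cumsum(qlen[has_q])) + 1L]
        stop(sprintf("record '%s': quality values must be integers in [0, 93]",
                     read_id[bad_rec]))
      }
      quals[has_q] <- split_by_lengths(flat, qlen[has_q])
    }
  }
  out <- data.frame(read_id = read_id, bases = bases, stringsAsFactors = FALSE)
  out$quals <- quals
  class(out) <- c("seq_reads", "data.frame")
  out
}

# Re-chunk a flat vector into pieces of the given lengths.
split_by_lengths <- function(x, lens) {
  f <- factor(rep(seq_along(lens), lens), levels = seq_along(lens))
  unname(split(x, f))
}

# Upper-case, U -> T, anything outside {A,C,G,T,N} -> N.
normalize_bases <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[^ACGTN]", "N", x)
}

#' Read paired FASTA and 454-style QUAL files
#'
#' Reads a sequence FASTA file and its companion quality file in the classic
#' Roche 454 convention: same record IDs in the same order, each QUAL record
#' a (possibly line-wrapped) whitespace-separated list of integer Phred
#' scores, one per base.
#'
#' @param fasta_file path to the FASTA file.
#' @param qual_file path to the QUAL file.
#' @return A [seq_reads()] table with qualities attached.
#' @export
read_fasta_qual <- function(fasta_file, qual_file) {
  seqs <- Biostrings::readBStringSet(fasta_file)
  ids <- sub("\\s.*$", "", names(seqs))
  bases <- as.character(seqs)
  qrec <- parse_qual_file(qual_file)
  if (length(qrec$ids) != length(ids)) {
    stop(sprintf(
      "FASTA has %d records but QUAL has %d", length(ids), length(qrec$ids)
    ))
  }
  mism <- which(ids != qrec$ids)
  if (length(mism)) {
    i <- mism[1]
    stop(sprintf(
      "record ID mismatch at position %d: FASTA '%s' vs QUAL '%s'",
      i, ids[i], qrec$ids[i]
    ))
  }
  seq_reads(ids, bases, qrec$quals)
}

# 454 QUAL dialect: ">" headers delimit records; integer scores are
# whitespace-separated and may be wrapped over several lines.
parse_qual_file <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) {
    if (all(!nzchar(trimws(lines)))) return(list(ids = character(0), quals = list()))
    stop(sprintf("'%s': not a QUAL file (no '>' header found)", path))
  }
  rec <- cumsum(hdr)
  if (any(rec == 0 & nzchar(trimws(lines)))) {
    stop(sprintf("'%s': quality values before first '>' header", path))
  }
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  body <- split(lines[!hdr], rec[!hdr])
  quals <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    txt <- body[[as.character(i)]]
    vals <- if (is.null(txt)) character(0) else unlist(strsplit(trimws(txt), "\\s+"))
    vals <- vals[nzchar(vals)]
    q <- suppressWarnings(as.integer(vals))
    if (anyNA(q)) {
      stop(sprintf("record '%s': non-integer quality value in '%s'", ids[i], path))
    }
    quals[[i]] <- q
  }
  list(ids = ids, quals = quals)
}

#' Read a FASTQ file (Phred+33)
#'
#' Same contract as [read_fasta_qual()] for the modern single-file dialect.
#'
#' @param fastq_file path to a 4-line-per-record FASTQ file.
#' @return A [seq_reads()] table with qualities attached.
#' @export
read_fastq <- function(fastq_file) {
  lines <- readLines(fastq_file)
  lines <- lines[seq_len(length(lines))]
  if (length(lines) %% 4L != 0L) {
    stop(sprintf(
      "'%s': truncated FASTQ record at record %d",
      fastq_file, length(lines) %/% 4L + 1L
    ))
  }
  n <- length(lines) %/% 4L
  if (n == 0) return(seq_reads(character(0), character(0), list()))
  at <- lines[seq(1, length(lines), by = 4)]
  sq <- lines[seq(2, length(lines), by = 4)]
  pl <- lines[seq(3, length(lines), by = 4)]
  qs <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(at, "@") | !startsWith(pl, "+"))
  if (length(bad)) {
    stop(sprintf("'%s': malformed FASTQ record %d", fastq_file, bad[1]))
  }
  ids <- sub("\\s.*$", "", sub("^@", "", at))
  quals <- vector("list", n)
  for (i in seq_len(n)) {
    if (nchar(qs[i]) != nchar(sq[i])) {
      stop(sprintf(
        "record '%s' (ordinal %d): %d quality characters for %d bases",
        ids[i], i, nchar(qs[i]), nchar(sq[i])
      ))
    }
    q <- utf8ToInt(qs[i]) - 33L
    if (any(q < 0L) || any(q > 93L)) {
      stop(sprintf(
        "record '%s' (ordinal %d): quality character outside Phred+33 range",
        ids[i], i
      ))
    }
    quals[[i]] <- q
  }
  seq_reads(ids, sq, quals)
}

#' Write sequencing reads as FASTA + QUAL (and optionally FASTQ)
#'
#' @param reads a [seq_reads()] table; all reads must carry qualities when a
#'   QUAL or FASTQ destination is given.
#' @param fasta_file,qual_file,fastq_file output paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_reads <- function(reads, fasta_file = NULL, qual_file = NULL, fastq_file = NULL) {
  written <- character(0)
  if (!is.null(fasta_file)) {
    con <- file(fasta_file, "wb")
    writeLines(paste0(">", reads$read_id, "\n", reads$bases), con, sep = "\n")
    close(con)
    written <- c(written, fasta_file)
  }
  if (!is.null(qual_file)) {
    qtxt <- vapply(reads$quals, function(q) paste(q, collapse = " "), character(1))
    con <- file(qual_file, "wb")
    writeLines(paste0(">", reads$read_id, "\n", qtxt), con, sep = "\n")
    close(con)
    written <- c(written, qual_file)
  }
  if (!is.null(fastq_file)) {
    qtxt <- vapply(reads$quals, function(q) intToUtf8(q + 33L), character(1))
    con <- file(fastq_file, "wb")
    writeLines(paste0("@", reads$read_id, "\n", reads$bases, "\n+\n", qtxt),
               con, sep = "\n")
    close(con)
    written <- c(written, fastq_file)
  }
  invisible(written)
}

# Serialized sample column header: barcode|target|round|wash|amplified
sample_col_labels <- function(samples) {
  paste(samples$barcode, samples$target, samples$round, samples$wash,
        ifelse(samples$amplified, "true", "false"), sep = "|")
}

parse_sample_col_labels <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad)) {
    stop(sprintf("malformed sample column header '%s'", labels[bad[1]]))
  }
  m <- do.call(rbind, parts)
  data.frame(
    barcode = m[, 1], target = m[, 2],
    round = suppressWarnings(as.integer(m[, 3])),
    wash = m[, 4], amplified = m[, 5] == "true",
    stringsAsFactors = FALSE
  )
}

#' Export a peptide count table as CSV
#'
#' One row per peptide (descending by total count, ties lexicographic — the
#' order the table already holds), a `total` column, and one column per
#' sample whose header packs the sample metadata as
#' `barcode|target|round|wash|amplified`. The format round-trips exactly
#' through [read_count_csv()].
#'
#' @param table a [count_table()].
#' @param file destination path.
#' @return Invisibly, `file`.
#' @export
write_count_csv <- function(table, file) {
  stopifnot(inherits(table, "count_table"))
  header <- paste(c("peptide", "total", sample_col_labels(table$samples)),
                  collapse = ",")
  rows <- character(nrow(table$counts))
  if (nrow(table$counts)) {
    body <- apply(table$counts, 1, paste, collapse = ",")
    rows <- paste(rownames(table$counts), table$totals, body, sep = ",")
  }
  con <- file(file, "wb")
  writeLines(c(header, rows), con, sep = "\n")
  close(con)
  invisible(file)
}

#' Read a peptide count table written by [write_count_csv()]
#'
#' @param file path to the CSV.
#' @return A [count_table()].
#' @export
read_count_csv <- function(file) {
  lines <- readLines(file)
  if (!length(lines)) stop(sprintf("'%s': empty count CSV", file))
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "peptide" || header[2] != "total") {
    stop(sprintf("'%s': not a count CSV (bad header)", file))
  }
  samples <- parse_sample_col_labels(header[-(1:2)])
  body <- lines[-1]
  if (!length(body)) {
    return(count_table(matrix(0L, 0, nrow(samples),
                              dimnames = list(NULL, samples$barcode)), samples))
  }
  cells <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad)) stop(sprintf("'%s': ragged row %d", file, bad[1] + 1L))
  m <- do.call(rbind, cells)
  counts <- matrix(as.integer(m[, -(1:2), drop = FALSE]), nrow = nrow(m),
                   dimnames = list(m[, 1], samples$barcode))
  count_table(counts, samples)
}
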