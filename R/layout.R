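#' Describe the amplicon architecture of a display-library construct
#'
#' Models a Ph.D.-12-style amplicon: a forward/reverse primer anchor directly
#' 5' of an inline sample barcode, fixed border sequences flanking the
#' variable region, a k-codon random insert, and the Gly-Gly-Gly-Ser spacer
#' that joins the peptide to the pIII coat protein. A read (forward or
#' reverse) starts at its primer, so the barcode is defined positionally as
#' the `barcode_length` bases immediately following the matched anchor.
#'
#' @param fwd_anchor exact-match fragment of the forward primer immediately
#'   preceding the barcode slot.
#' @param rev_anchor same role for reverse reads (as it appears at the start
#'   of a reverse read).
#' @param barcode_length inline barcode length in nt (3 for the trinucleotide
#'   scheme).
#' @param left_border fixed sequence directly 5' of the variable region.
#' @param right_border fixed sequence directly 3' of the variable region
#'   (start of the spacer-coding sequence).
#' @param insert_codons number of randomized codons (12 for Ph.D.-12).
#' @param spacer_codons codons in the spacer (4: Gly-Gly-Gly-Ser).
#' @param wt_amplicon_length length in nt of the amplicon from insert-less
#'   wild-type phage (381 for the Ph.D.-12 primer set).
#' @param anchor_min_length exact-match length used for anchor search; when
#'   an anchor is longer, its 3'-terminal `anchor_min_length` bases (those
#'   adjacent to the barcode) are matched.
#' @return An object of class `construct_layout`.
#' @export
construct_layout <- function(fwd_anchor, rev_anchor, barcode_length = 3L,
                             left_border, right_border, insert_codons = 12L,
                             spacer_codons = 4L, wt_amplicon_length = 381L,
                             anchor_min_length = 12L) {
  layout <- list(
    fwd_anchor = normalize_bases(fwd_anchor),
    rev_anchor = normalize_bases(rev_anchor),
    barcode_length = as.integer(barcode_length),
    left_border = normalize_bases(left_border),
    right_border = normalize_bases(right_border),
    insert_codons = as.integer(insert_codons),
    spacer_codons = as.integer(spacer_codons),
    wt_amplicon_length = as.integer(wt_amplicon_length),
    anchor_min_length = as.integer(anchor_min_length)
  )
  for (f in c("fwd_anchor", "rev_anchor", "left_border", "right_border")) {
    s <- layout[[f]]
    if (!nzchar(s) || grepl("[^ACGT]", s)) {
      stop(sprintf("%s must be a nonempty string over {A,C,G,T}", f))
    }
  }
  if (layout$insert_codons < 1L) stop("insert_codons must be >= 1")
  if (layout$barcode_length < 1L) stop("barcode_length must be >= 1")
  if (layout$spacer_codons < 0L) stop("spacer_codons must be >= 0")
  if (layout$anchor_min_length < 1L) stop("anchor_min_length must be >= 1")
  if (grepl(layout$left_border, layout$right_border, fixed = TRUE) ||
      grepl(layout$right_border, layout$left_border, fixed = TRUE)) {
    stop("left_border and right_border must not contain each other")
  }
  class(layout) <- "construct_layout"
  layout
}

# The anchor fragment actually matched: 3'-terminal anchor_min_length bases
# (adjacent to the barcode) when the configured anchor is longer.
anchor_used <- function(anchor, min_len) {
  n <- nchar(anchor)
  if (n <= min_len) anchor else substr(anchor, n - min_len + 1L, n)
}

#' Expected amplicon length for a layout
#'
#' @param layout a [construct_layout()].
#' @param with_insert `TRUE` for a library clone carrying the insert and
#'   spacer, `FALSE` for insert-less wild-type phage.
#' @return Length in nt: the wild-type amplicon length, plus
#'   `3 * (insert_codons + spacer_codons)` when `with_insert` is `TRUE`.
#' @export
amplicon_length <- function(layout, with_insert = TRUE) {
  stopifnot(inherits(layout, "construct_layout"))
  n <- layout$wt_amplicon_length
  if (with_insert) n <- n + 3L * (layout$insert_codons + layout$spacer_codons)
  n
}

#' Nucleotide length of the variable region
#'
#' @param layout a [construct_layout()].
#' @return `3 * insert_codons` (36 for a 12-mer library).
#' @export
insert_nt_length <- function(layout) {
  stopifnot(inherits(layout, "construct_layout"))
  3L * layout$insert_codons
}

#' Load a construct layout from a flat key=value config file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and blank
#' lines ignored. Keys are the arguments of [construct_layout()].
#'
#' @param file path to the config file.
#' @return A [construct_layout()].
#' @export
read_layout_config <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(\\S+)$", lines))
  bad <- which(lengths(m) != 3L)
  if (length(bad)) stop(sprintf("'%s': cannot parse config line '%s'", file, lines[bad[1]]))
  kv <- stats::setNames(vapply(m, `[`, character(1), 3L),
                        vapply(m, `[`, character(1), 2L))
  need <- c("fwd_anchor", "rev_anchor", "left_border", "right_border")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop(sprintf("'%s': missing layout key '%s'", file, miss[1]))
  num <- function(key, default) {
    if (key %in% names(kv)) as.integer(kv[[key]]) else default
  }
  construct_layout(
    fwd_anchor = kv[["fwd_anchor"]], rev_anchor = kv[["rev_anchor"]],
    barcode_length = num("barcode_length", 3L),
    left_border = kv[["left_border"]], right_border = kv[["right_border"]],
    insert_codons = num("insert_codons", 12L),
    spacer_codons = num("spacer_codons", 4L),
    wt_amplicon_length = num("wt_amplicon_length", 381L),
    anchor_min_length = num("anchor_min_length", 12L)
  )
}

#' Write a construct layout as a flat key=value config file
#'
#' @param layout a [construct_layout()].
#' @param file destination path.
#' @return Invisibly, `file`.
#' @export
write_layout_config <- function(layout, file) {
  stopifnot(inherits(layout, "construct_layout"))
  con <- file(file, "wb")
  writeLines(paste(names(unclass(layout)), unlist(layout, use.names = FALSE),
                   sep = " = "), con, sep = "\n")
  close(con)
  invisible(file)
}

#' Build a validated sample sheet
#'
#' Maps inline barcodes to sample metadata: target protein, panning round
#' (0 = unpanned parental library), wash stringency and whether the phage
#' pool was amplified in bacteria before sequencing.
#'
#' @param barcode character vector of barcodes.
#' @param target character vector of target labels (`"parental"` marks the
#'   unpanned library; at most one entry may carry it).
#' @param round integer vector of panning rounds (0-3).
#' @param wash one of `"fast"`, `"slow"`, `"none"` per sample.
#' @param amplified logical vector.
#' @param layout optional [construct_layout()] used to validate barcode
#'   length.
#' @return A `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(barcode, target, round, wash, amplified, layout = NULL) {
  sheet <- data.frame(
    barcode = normalize_bases(as.character(barcode)),
    target = as.character(target),
    round = as.integer(round),
    wash = as.character(wash),
    amplified = as.logical(amplified),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sheet$barcode)) {
    dup <- sheet$barcode[duplicated(sheet$barcode)][1]
    stop(sprintf("duplicate barcode '%s' in sample sheet", dup))
  }
  if (any(grepl("[^ACGT]", sheet$barcode))) {
    stop("barcodes must be over {A,C,G,T}")
  }
  if (!is.null(layout)) {
    bad <- which(nchar(sheet$barcode) != layout$barcode_length)
    if (length(bad)) {
      stop(sprintf(
        "barcode '%s' has length %d; layout expects %d",
        sheet$barcode[bad[1]], nchar(sheet$barcode[bad[1]]), layout$barcode_length
      ))
    }
  }
  if (!all(sheet$wash %in% c("fast", "slow", "none"))) {
    bad <- setdiff(unique(sheet$wash), c("fast", "slow", "none"))[1]
    stop(sprintf("unknown wash label '%s' (use fast, slow or none)", bad))
  }
  if (sum(sheet$target == "parental") > 1L) {
    stop("at most one sample may be marked target = 'parental'")
  }
  if (anyNA(sheet$round) || any(sheet$round < 0L)) {
    stop("round must be a nonnegative integer (0 = parental library)")
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Load a sample sheet from CSV or TSV
#'
#' Delimiter is auto-detected from the header line. Required columns:
#' `barcode,target,round,wash,amplified`.
#'
#' @param file path to the table.
#' @param layout optional [construct_layout()] for barcode-length validation.
#' @return A [sample_sheet()].
#' @export
load_sample_sheet <- function(file, layout = NULL) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("barcode", "target", "round", "wash", "amplified")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("'%s': sample sheet is missing column '%s'", file, miss[1]))
  }
  amp <- df$amplified
  if (is.character(amp)) amp <- tolower(amp) %in% c("true", "t", "yes", "1")
  sample_sheet(df$barcode, df$target, df$round, df$wash, amp, layout)
}

#' Write a sample sheet as CSV
#' @param sheet a [sample_sheet()].
#' @param file destination path.
#' @return Invisibly, `file`.
#' @export
write_sample_sheet <- function(sheet, file) {
  stopifnot(inherits(sheet, "sample_sheet"))
  con <- file(file, "wb")
  writeLines(c(
    "barcode,target,round,wash,amplified",
    paste(sheet$barcode, sheet$target, sheet$round, sheet$wash,
          ifelse(sheet$amplified, "true", "false"), sep = ",")
  ), con, sep = "\n")
  close(con)
  invisible(file)
}
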