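# Per-read extraction: orientation, barcode, insert, quality repair, NNK
# codon validation, translation. Per-read functions are the reference
# implementation of each step; deconvolve_reads() is a vectorized batch
# engine over the same rules (tested for equivalence against the per-read
# path).

DISCARD_REASONS <- c(
  "too_short", "no_anchor_match", "incomplete_barcode", "border_not_found",
  "under_length", "repair_failed", "codon_invalid", "stop_codon",
  "ambiguous_orientation"
)

#' Reverse complement of a nucleotide string
#'
#' Watson-Crick complement, reversed; `N` maps to `N`.
#'
#' @param seq character vector of sequences over `{A,C,G,T,N}`.
#' @return The reverse complement(s).
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) {
    stop("reverse_complement: sequence contains non-nucleotide characters")
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Minimum read length able to contain the variable region
#'
#' A read shorter than (shorter anchor) + barcode + left border + insert +
#' right border cannot contain the full 36-nt variable region and is
#' discarded before any matching.
#'
#' @param layout a [construct_layout()].
#' @return Threshold length in nt.
#' @export
min_read_length <- function(layout) {
  fa <- anchor_used(layout$fwd_anchor, layout$anchor_min_length)
  ra <- anchor_used(layout$rev_anchor, layout$anchor_min_length)
  min(nchar(fa), nchar(ra)) + layout$barcode_length +
    nchar(layout$left_border) + insert_nt_length(layout) +
    nchar(layout$right_border)
}

#' Length prefilter (step 1)
#'
#' @param bases read sequence.
#' @param layout a [construct_layout()].
#' @return `"pass"` or `"too_short"`.
#' @export
length_prefilter <- function(bases, layout) {
  if (nchar(bases) >= min_read_length(layout)) "pass" else "too_short"
}

# 5' search window for anchors: anchor + barcode + 8 nt of slack.
anchor_window <- function(layout) {
  fa <- anchor_used(layout$fwd_anchor, layout$anchor_min_length)
  ra <- anchor_used(layout$rev_anchor, layout$anchor_min_length)
  max(nchar(fa), nchar(ra)) + layout$barcode_length + 8L
}

#' Orient a read and extract its inline barcode (step 2)
#'
#' Scans a bounded window at the 5' end for an exact occurrence of the
#' forward or reverse primer anchor; the barcode is the `barcode_length`
#' bases immediately 3' of the matched anchor.
#'
#' @param bases read sequence (must have passed [length_prefilter()]).
#' @param layout a [construct_layout()].
#' @return A list with `orientation` (`"forward"`/`"reverse"`), `barcode` and
#'   `barcode_end` (position of the last barcode base) on success; otherwise
#'   a list with `reason` one of `no_anchor_match`, `incomplete_barcode`,
#'   `ambiguous_orientation`.
#' @export
orient_and_barcode <- function(bases, layout) {
  fa <- anchor_used(layout$fwd_anchor, layout$anchor_min_length)
  ra <- anchor_used(layout$rev_anchor, layout$anchor_min_length)
  win <- substr(bases, 1L, anchor_window(layout))
  pf <- regexpr(fa, win, fixed = TRUE)
  pr <- regexpr(ra, win, fixed = TRUE)
  if (pf > 0L && pr > 0L) return(list(reason = "ambiguous_orientation"))
  if (pf < 0L && pr < 0L) return(list(reason = "no_anchor_match"))
  if (pf > 0L) {
    orientation <- "forward"; pos <- pf; alen <- nchar(fa)
  } else {
    orientation <- "reverse"; pos <- pr; alen <- nchar(ra)
  }
  bstart <- pos + alen
  bend <- bstart + layout$barcode_length - 1L
  bc <- substr(bases, bstart, bend)
  if (nchar(bc) < layout$barcode_length || grepl("N", bc, fixed = TRUE)) {
    return(list(reason = "incomplete_barcode"))
  }
  list(orientation = orientation, barcode = bc, barcode_end = bend)
}

#' Extract the variable-region insert between its border sequences (step 3)
#'
#' For forward reads, returns the substring strictly between the first
#' occurrence of the left border (after the barcode) and the next occurrence
#' of the right border. For reverse reads the same search runs with the
#' reverse-complemented borders, and the extracted substring is returned
#' reverse-complemented (message sense) with its quality slice reversed.
#'
#' @param bases read sequence.
#' @param quals integer quality vector or `NULL`.
#' @param orientation `"forward"` or `"reverse"`.
#' @param layout a [construct_layout()].
#' @param from 1-based position after which to search (typically the last
#'   barcode base).
#' @return A list with `raw_insert` and `raw_quals` (message sense), or a
#'   list with `reason = "border_not_found"`.
#' @export
extract_insert <- function(bases, quals, orientation, layout, from = 0L) {
  if (orientation == "forward") {
    lb <- layout$left_border; rb <- layout$right_border
  } else {
    lb <- reverse_complement(layout$right_border)
    rb <- reverse_complement(layout$left_border)
  }
  tail_str <- substr(bases, from + 1L, nchar(bases))
  p1 <- regexpr(lb, tail_str, fixed = TRUE)
  if (p1 < 0L) return(list(reason = "border_not_found"))
  ins_start <- from + p1 + nchar(lb)            # 1-based start of insert
  rest <- substr(bases, ins_start, nchar(bases))
  p2 <- regexpr(rb, rest, fixed = TRUE)
  if (p2 < 0L) return(list(reason = "border_not_found"))
  ins_end <- ins_start + p2 - 2L                # last base before right border
  raw <- if (ins_end >= ins_start) substr(bases, ins_start, ins_end) else ""
  rq <- if (is.null(quals)) NULL else quals[seq_len(ins_end - ins_start + 1L) + ins_start - 1L]
  if (orientation == "reverse") {
    raw <- if (nzchar(raw)) reverse_complement(raw) else ""
    if (!is.null(rq)) rq <- rev(rq)
  }
  list(raw_insert = raw, raw_quals = rq)
}

#' Quality-guided repair of an over-length insert (step 4)
#'
#' An insert of exactly `3 * insert_codons` nt is returned unchanged; a
#' shorter one is discarded. A longer one is repaired by iteratively removing
#' the single base with the current minimum quality (ties: the 3'-most
#' minimal base, where 454 quality is poorest; `tie = "left"` selects the
#' 5'-most) until the target length is reached. Without qualities repair is
#' impossible.
#'
#' @param raw_insert extracted insert (message sense).
#' @param raw_quals aligned integer qualities or `NULL`.
#' @param layout a [construct_layout()].
#' @param tie `"right"` (default) or `"left"`.
#' @return A list with `insert_nt` on success, or `reason` one of
#'   `under_length`, `repair_failed`.
#' @export
repair_insert <- function(raw_insert, raw_quals, layout, tie = c("right", "left")) {
  tie <- match.arg(tie)
  target <- insert_nt_length(layout)
  n <- nchar(raw_insert)
  if (n == target) return(list(insert_nt = raw_insert))
  if (n < target) return(list(reason = "under_length"))
  if (is.null(raw_quals)) return(list(reason = "repair_failed"))
  stopifnot(length(raw_quals) == n)
  ch <- strsplit(raw_insert, "", fixed = TRUE)[[1]]
  q <- as.numeric(raw_quals)
  while (length(ch) > target) {
    mins <- which(q == min(q))
    drop <- if (tie == "right") mins[length(mins)] else mins[1]
    ch <- ch[-drop]
    q <- q[-drop]
  }
  list(insert_nt = paste(ch, collapse = ""))
}

# The 32 NNK codons: any base at positions 1-2, G or T at position 3.
nnk_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(as.vector(outer(b, b, paste0)), c("G", "T"), paste0))
}

#' Validate the codon structure of an insert (step 4, codon check)
#'
#' Partitions the insert into codons and checks each against the NNK scheme
#' (third base G or T) and the no-stop rule. TAA and TGA are always stops;
#' TAG is a stop under `amber = "reject"` (default) and a glutamine codon
#' under `amber = "suppress"` (supE host behaviour). Any `N` in the insert
#' fails the check.
#'
#' @param insert_nt insert of length `3 * k`.
#' @param amber `"reject"` or `"suppress"`.
#' @param scheme codon scheme; only `"NNK"` is implemented.
#' @return `"pass"`, `"codon_invalid"` or `"stop_codon"`.
#' @export
validate_codons <- function(insert_nt, amber = c("reject", "suppress"),
                            scheme = "NNK") {
  amber <- match.arg(amber)
  if (scheme != "NNK") stop("only the NNK codon scheme is implemented")
  n <- nchar(insert_nt)
  if (n %% 3L != 0L) stop("insert length is not a multiple of 3")
  if (grepl("N", insert_nt, fixed = TRUE)) return("codon_invalid")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(insert_nt, starts, starts + 2L)
  stops <- c("TAA", "TGA", if (amber == "reject") "TAG")
  if (any(codons %in% stops)) return("stop_codon")
  third <- substring(codons, 3L, 3L)
  if (any(!third %in% c("G", "T"))) return("codon_invalid")
  "pass"
}

# Codon -> amino acid lookup from the standard genetic code; under amber
# suppression TAG reads through as Gln.
codon_table <- function(amber = "reject") {
  tab <- Biostrings::GENETIC_CODE
  if (amber == "suppress") tab[["TAG"]] <- "Q"
  tab
}

#' Translate a validated insert (step 5)
#'
#' @param insert_nt insert that passed [validate_codons()].
#' @param amber `"reject"` or `"suppress"` (under suppression TAG translates
#'   to Q).
#' @return The peptide string.
#' @export
translate_insert <- function(insert_nt, amber = c("reject", "suppress")) {
  amber <- match.arg(amber)
  n <- nchar(insert_nt)
  if (n %% 3L != 0L) stop("insert length is not a multiple of 3")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(insert_nt, starts, starts + 2L)
  tab <- codon_table(amber)
  aa <- unname(tab[codons])
  if (anyNA(aa) || any(aa == "*")) {
    stop(sprintf("untranslatable codon in '%s'", insert_nt))
  }
  paste(aa, collapse = "")
}

empty_record <- function(read_id) {
  list(read_id = read_id, barcode = NA_character_, orientation = NA_character_,
       raw_insert = NA_character_, insert_nt = NA_character_,
       peptide = NA_character_, fate = "discarded",
       discard_reason = NA_character_, assigned = NA)
}

#' Deconvolute a single read (steps 1-5 composed)
#'
#' Applies, in order: length prefilter, anchor/barcode match, border-delimited
#' insert extraction (reverse reads are re-oriented to message sense),
#' quality repair, NNK codon validation and translation. The first failing
#' step fixes the record's fate and discard reason.
#'
#' @param bases read sequence.
#' @param quals integer quality vector or `NULL`.
#' @param layout a [construct_layout()].
#' @param sheet optional [sample_sheet()]; barcodes absent from it are
#'   retained but flagged `assigned = FALSE`.
#' @param read_id identifier carried into the record.
#' @param amber amber-codon policy, see [validate_codons()].
#' @param repair_tie tie rule for [repair_insert()].
#' @return A one-record list with fields `read_id`, `barcode`, `orientation`,
#'   `raw_insert`, `insert_nt`, `peptide`, `fate`, `discard_reason`,
#'   `assigned`.
#' @export
deconvolve_read <- function(bases, quals = NULL, layout, sheet = NULL,
                            read_id = "read", amber = "reject",
                            repair_tie = "right") {
  rec <- empty_record(read_id)
  bases <- normalize_bases(bases)
  if (length_prefilter(bases, layout) == "too_short") {
    rec$discard_reason <- "too_short"
    return(rec)
  }
  ob <- orient_and_barcode(bases, layout)
  if (!is.null(ob$reason)) {
    rec$discard_reason <- ob$reason
    return(rec)
  }
  rec$orientation <- ob$orientation
  rec$barcode <- ob$barcode
  rec$assigned <- if (is.null(sheet)) NA else ob$barcode %in% sheet$barcode
  ex <- extract_insert(bases, quals, ob$orientation, layout, from = ob$barcode_end)
  if (!is.null(ex$reason)) {
    rec$discard_reason <- ex$reason
    return(rec)
  }
  rec$raw_insert <- ex$raw_insert
  rp <- repair_insert(ex$raw_insert, ex$raw_quals, layout, tie = repair_tie)
  if (!is.null(rp$reason)) {
    rec$discard_reason <- rp$reason
    return(rec)
  }
  vc <- validate_codons(rp$insert_nt, amber = amber)
  if (vc != "pass") {
    rec$discard_reason <- vc
    return(rec)
  }
  rec$insert_nt <- rp$insert_nt
  rec$peptide <- translate_insert(rp$insert_nt, amber = amber)
  rec$fate <- "accepted"
  rec$discard_reason <- NA_character_
  rec
}

#' Deconvolute a table of reads
#'
#' Vectorized batch version of [deconvolve_read()]: every input read yields
#' exactly one record, so fates and discard reasons partition the input.
#'
#' @param reads a [seq_reads()] table.
#' @param layout a [construct_layout()].
#' @param sheet optional [sample_sheet()].
#' @param amber,repair_tie as in [deconvolve_read()].
#' @return A `data.frame` of class `insert_records`, one row per read.
#' @export
deconvolve_reads <- function(reads, layout, sheet = NULL, amber = "reject",
                             repair_tie = "right") {
  n <- nrow(reads)
  bases <- reads$bases
  read_id <- reads$read_id
  barcode <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  raw_insert <- rep(NA_character_, n)
  insert_nt <- rep(NA_character_, n)
  peptide <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  if (n > 0) {
    live <- rep(TRUE, n)

    # step 1: length
    short <- nchar(bases) < min_read_length(layout)
    reason[short] <- "too_short"
    live <- live & !short

    # step 2: anchor + barcode
    fa <- anchor_used(layout$fwd_anchor, layout$anchor_min_length)
    ra <- anchor_used(layout$rev_anchor, layout$anchor_min_length)
    win <- substr(bases, 1L, anchor_window(layout))
    pf <- regexpr(fa, win, fixed = TRUE)
    pr <- regexpr(ra, win, fixed = TRUE)
    amb <- live & pf > 0L & pr > 0L
    none <- live & pf < 0L & pr < 0L
    reason[amb] <- "ambiguous_orientation"
    reason[none] <- "no_anchor_match"
    live <- live & !amb & !none
    is_fwd <- pf > 0L
    orientation[live] <- ifelse(is_fwd[live], "forward", "reverse")
    apos <- ifelse(is_fwd, pf, pr)
    alen <- ifelse(is_fwd, nchar(fa), nchar(ra))
    bstart <- apos + alen
    bend <- bstart + layout$barcode_length - 1L
    bc <- substr(bases, bstart, bend)
    inc <- live & (nchar(bc) < layout$barcode_length | grepl("N", bc, fixed = TRUE))
    reason[inc] <- "incomplete_barcode"
    live <- live & !inc
    barcode[live] <- bc[live]

    # step 3: borders (forward and reverse lanes share the slicing code)
    ins_start <- rep(NA_integer_, n)
    ins_end <- rep(NA_integer_, n)
    for (ori in c("forward", "reverse")) {
      lane <- live & orientation == ori
      if (!any(lane, na.rm = TRUE)) next
      lane[is.na(lane)] <- FALSE
      if (ori == "forward") {
        lb <- layout$left_border; rb <- layout$right_border
      } else {
        lb <- reverse_complement(layout$right_border)
        rb <- reverse_complement(layout$left_border)
      }
      tail_str <- substr(bases[lane], bend[lane] + 1L, nchar(bases[lane]))
      p1 <- regexpr(lb, tail_str, fixed = TRUE)
      st <- ifelse(p1 > 0L, bend[lane] + p1 + nchar(lb), NA_integer_)
      rest <- ifelse(p1 > 0L, substr(bases[lane], st, nchar(bases[lane])), "")
      p2 <- regexpr(rb, rest, fixed = TRUE)
      en <- ifelse(p2 > 0L, st + p2 - 2L, NA_integer_)
      ok <- p1 > 0L & p2 > 0L
      idx <- which(lane)
      reason[idx[!ok]] <- "border_not_found"
      ins_start[idx[ok]] <- st[ok]
      ins_end[idx[ok]] <- en[ok]
    }
    live <- live & is.na(reason)
    raw <- ifelse(live & ins_end >= ins_start,
                  substr(bases, ins_start, ins_end), "")
    rev_lane <- live & orientation == "reverse" & nzchar(raw)
    raw[rev_lane] <- reverse_complement(raw[rev_lane])
    raw_insert[live] <- raw[live]

    # step 4a: repair (per-read; only the over-length minority loops)
    target <- insert_nt_length(layout)
    rawlen <- ifelse(live, nchar(raw), NA_integer_)
    under <- live & rawlen < target
    reason[under] <- "under_length"
    live <- live & !under
    over <- which(live & rawlen > target)
    fixed <- raw
    for (i in over) {
      q <- reads$quals[[i]]
      if (is.null(q)) {
        reason[i] <- "repair_failed"
        next
      }
      qs <- q[ins_start[i]:ins_end[i]]
      if (orientation[i] == "reverse") qs <- rev(qs)
      rp <- repair_insert(raw[i], qs, layout, tie = repair_tie)
      if (!is.null(rp$reason)) reason[i] <- rp$reason else fixed[i] <- rp$insert_nt
    }
    live <- live & is.na(reason)

    # step 4b + 5: codon check and translation, vectorized over codon slots
    idx <- which(live)
    if (length(idx)) {
      ins <- fixed[idx]
      k <- layout$insert_codons
      codm <- matrix("", length(idx), k)
      for (j in seq_len(k)) {
        codm[, j] <- substr(ins, 3L * j - 2L, 3L * j)
      }
      stops <- c("TAA", "TGA", if (amber == "reject") "TAG")
      has_n <- grepl("N", ins, fixed = TRUE)
      has_stop <- rowSums(matrix(codm %in% stops, nrow(codm))) > 0L
      bad_third <- rowSums(matrix(!substr(codm, 3L, 3L) %in% c("G", "T"),
                                  nrow(codm))) > 0L
      verdict <- ifelse(has_n, "codon_invalid",
                 ifelse(has_stop, "stop_codon",
                 ifelse(bad_third, "codon_invalid", NA_character_)))
      reason[idx[!is.na(verdict)]] <- verdict[!is.na(verdict)]
      ok <- is.na(verdict)
      if (any(ok)) {
        tab <- codon_table(amber)
        aam <- matrix(tab[codm[ok, , drop = FALSE]], sum(ok))
        pep <- do.call(paste0, as.data.frame(aam, stringsAsFactors = FALSE))
        insert_nt[idx[ok]] <- ins[ok]
        peptide[idx[ok]] <- pep
      }
    }
  }
  fate <- ifelse(is.na(reason) & !is.na(peptide), "accepted", "discarded")
  assigned <- if (is.null(sheet)) rep(NA, n) else barcode %in% sheet$barcode
  assigned[is.na(barcode)] <- NA
  out <- data.frame(
    read_id = read_id, barcode = barcode, orientation = orientation,
    raw_insert = raw_insert, insert_nt = insert_nt, peptide = peptide,
    fate = fate, discard_reason = reason, assigned = assigned,
    stringsAsFactors = FALSE
  )
  class(out) <- c("insert_records", "data.frame")
  out
}

#' Summarize discard reasons of a record table
#'
#' @param records an `insert_records` table from [deconvolve_reads()].
#' @return A `data.frame` with one row per fate/reason and its read count;
#'   counts sum to the number of input reads.
#' @export
discard_summary <- function(records) {
  key <- ifelse(records$fate == "accepted", "accepted", records$discard_reason)
  tab <- table(factor(key, levels = c("accepted", DISCARD_REASONS)))
  data.frame(outcome = names(tab), reads = as.integer(tab),
             stringsAsFactors = FALSE)
}
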