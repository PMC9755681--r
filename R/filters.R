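# Background removal: nickel-plate poly-His binders and peptides whose
# abundance in the unpanned parental library marks a bacterial propagation
# advantage rather than target binding.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Bundle the background-filter settings
#'
#' @param his_mode `"run3"` (remove peptides containing a contiguous `HHH`
#'   run, the default) or `"total3"` (remove peptides with three or more
#'   histidines anywhere).
#' @param parental_max maximum allowed count in the parental-library sample;
#'   peptides observed *more* often than this are removed from every sample.
#'   The default 2 keeps peptides seen at most twice; 1 gives the stricter
#'   more-than-once rule.
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(his_mode = c("run3", "total3"), parental_max = 2L) {
  his_mode <- match.arg(his_mode)
  parental_max <- as.integer(parental_max)
  if (is.na(parental_max) || parental_max < 0L) stop("parental_max must be >= 0")
  structure(list(his_mode = his_mode, parental_max = parental_max),
            class = "filter_policy")
}

#' Remove poly-histidine plate binders
#'
#' His-tagged targets are captured on nickel plates, so histidine-rich
#' peptides bind the plate rather than the target.
#'
#' @param peptides character vector of amino-acid strings.
#' @param his_mode see [filter_policy()].
#' @return A list with `kept` and `removed` character vectors (a disjoint,
#'   exhaustive partition of the input).
#' @export
his_filter <- function(peptides, his_mode = c("run3", "total3")) {
  his_mode <- match.arg(his_mode)
  bad <- grepl(sprintf("[^%s]", paste(AA_LETTERS, collapse = "")), peptides)
  if (any(bad)) {
    stop(sprintf("non-amino-acid character in peptide '%s'", peptides[bad][1]))
  }
  hit <- if (his_mode == "run3") {
    grepl("HHH", peptides, fixed = TRUE)
  } else {
    vapply(gregexpr("H", peptides, fixed = TRUE),
           function(m) sum(m > 0L), integer(1)) >= 3L
  }
  list(kept = peptides[!hit], removed = peptides[hit])
}

#' Remove parental-library propagation artifacts
#'
#' Any peptide observed more than `parental_max` times in the parental
#' (round 0) sample is removed from every sample of the table, since its
#' abundance reflects phage amplification advantage in bacteria, not binding.
#'
#' @param table a [count_table()] containing a sample with
#'   `target == "parental"`.
#' @param parental_max see [filter_policy()].
#' @return A list with `kept_table` (a [count_table()]) and `removed` (a
#'   `data.frame` of removed peptides and their parental counts).
#' @export
parental_filter <- function(table, parental_max = 2L) {
  stopifnot(inherits(table, "count_table"))
  parental_max <- as.integer(parental_max)
  pcol <- which(table$samples$target == "parental")
  if (!length(pcol)) {
    stop(paste(
      "no parental sample in the table; mark one sample with",
      "target = 'parental' (round 0) or skip the parental filter"
    ))
  }
  pcount <- table$counts[, pcol[1]]
  drop <- pcount > parental_max
  removed <- data.frame(
    peptide = rownames(table$counts)[drop],
    parental_count = unname(pcount[drop]),
    stringsAsFactors = FALSE
  )
  kept <- count_table(table$counts[!drop, , drop = FALSE], table$samples)
  list(kept_table = kept, removed = removed)
}

#' Apply the full background-filter policy to a count table
#'
#' Runs the poly-His filter on the peptide list and the parental-abundance
#' filter on the counts (the two commute). When the table has no parental
#' sample and `require_parental` is `FALSE`, only the His filter runs.
#'
#' @param table a [count_table()].
#' @param policy a [filter_policy()].
#' @param require_parental error (default) or skip when no parental sample
#'   is present.
#' @return A list with `table` (filtered [count_table()]) and `report`
#'   (`data.frame` with columns `peptide`, `rule`, `parental_count`).
#' @export
apply_filters <- function(table, policy = filter_policy(),
                          require_parental = TRUE) {
  stopifnot(inherits(table, "count_table"), inherits(policy, "filter_policy"))
  hf <- his_filter(rownames(table$counts), policy$his_mode)
  report <- data.frame(peptide = hf$removed,
                       rule = rep(sprintf("his_%s", policy$his_mode),
                                  length(hf$removed)),
                       parental_count = rep(NA_integer_, length(hf$removed)),
                       stringsAsFactors = FALSE)
  keep <- !rownames(table$counts) %in% hf$removed
  table <- count_table(table$counts[keep, , drop = FALSE], table$samples)
  has_parental <- any(table$samples$target == "parental")
  if (has_parental) {
    pf <- parental_filter(table, policy$parental_max)
    if (nrow(pf$removed)) {
      report <- rbind(report, data.frame(
        peptide = pf$removed$peptide,
        rule = sprintf("parental_gt%d", policy$parental_max),
        parental_count = pf$removed$parental_count,
        stringsAsFactors = FALSE
      ))
    }
    table <- pf$kept_table
  } else if (require_parental) {
    stop(paste(
      "no parental sample in the table; mark one sample with",
      "target = 'parental' or call with require_parental = FALSE"
    ))
  }
  list(table = table, report = report)
}
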