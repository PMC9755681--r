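# 454-style amplicon read simulator with ground truth. Reads take the form
#   fwd_anchor + barcode + left_border + insert(3k) + right_border(spacer) +
#   downstream stuffer + revcomp(barcode) + revcomp(rev_anchor)
# (or the reverse complement of the whole amplicon for reverse-strand
# reads); wild-type contaminant reads lack insert, spacer and borders.
# Errors are substitutions and homopolymer +/-1 indels, with conspicuously
# low quality at error positions so the quality-repair step is exercised.

#' Random NNK encoding of a peptide
#'
#' Each residue is encoded by a uniformly chosen NNK codon (third base G or
#' T); the result always passes [validate_codons()] under the amber-reject
#' policy. Encoding consumes the R random stream.
#'
#' @param peptide string over the 20 standard residues.
#' @return A nucleotide string of length `3 * nchar(peptide)`.
#' @export
encode_peptide_nnk <- function(peptide) {
  encode_peptides_nnk(peptide)
}

# Vectorized encoder used by the simulator.
encode_peptides_nnk <- function(peptides) {
  tab <- nnk_by_residue()
  if (!length(peptides)) return(character(0))
  aa <- strsplit(peptides, "", fixed = TRUE)
  flat <- unlist(aa, use.names = FALSE)
  bad <- !flat %in% names(tab)
  if (any(bad)) {
    stop(sprintf("cannot NNK-encode residue '%s'", flat[bad][1]))
  }
  flat_codons <- unlist(tab, use.names = FALSE)
  offset <- cumsum(lengths(tab)) - lengths(tab)
  j <- match(flat, names(tab))
  pick <- floor(stats::runif(length(flat)) * lengths(tab)[j]) + 1L
  codons <- flat_codons[offset[j] + pick]
  idx <- factor(rep(seq_along(peptides), nchar(peptides)),
                levels = seq_along(peptides))
  unname(vapply(split(codons, idx), paste, character(1), collapse = ""))
}

# residue -> NNK codon choices (amber TAG excluded: encoding emits only
# sense codons).
nnk_by_residue <- function() {
  codons <- nnk_codons()
  aa <- Biostrings::GENETIC_CODE[codons]
  keep <- aa != "*"
  split(codons[keep], aa[keep])
}

#' Simulation settings for a 454-style amplicon run
#'
#' @param layout a [construct_layout()].
#' @param sheet a [sample_sheet()].
#' @param spectra integer matrix of true read counts, peptides in rows,
#'   sample barcodes in columns (all columns must exist in `sheet`).
#' @param wt_rate fraction of each sample's reads that are insert-less
#'   wild-type contaminants (added on top of the spectra counts so the
#'   per-peptide truth is exact).
#' @param sub_rate per-base substitution probability.
#' @param hp_indel_rate per-homopolymer-run (length >= 2) probability of a
#'   +/-1 length error.
#' @param qual_mean,qual_slope base quality model: quality at position `i`
#'   (1-based) is `round(qual_mean + qual_slope * (i - 1))`, clipped to
#'   `[2, 40]`; substituted bases are flagged at quality 10 and inserted
#'   bases at quality 5 (the strict minimum).
#' @param seed integer seed; identical configs give byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(layout, sheet, spectra, wt_rate = 0.05,
                       sub_rate = 0.005, hp_indel_rate = 0.005,
                       qual_mean = 34, qual_slope = -0.02, seed = 1L) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "integer"
  if (anyNA(spectra) || any(spectra < 0L)) stop("spectra counts must be nonnegative")
  if (is.null(colnames(spectra)) || !all(colnames(spectra) %in% sheet$barcode)) {
    stop("every spectra column must be a barcode present in the sample sheet")
  }
  for (r in c(wt_rate, sub_rate, hp_indel_rate)) {
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  }
  if (wt_rate >= 1) stop("wt_rate must be < 1 (WT reads are added on top of the spectra)")
  structure(list(layout = layout, sheet = sheet, spectra = spectra,
                 wt_rate = wt_rate, sub_rate = sub_rate,
                 hp_indel_rate = hp_indel_rate, qual_mean = qual_mean,
                 qual_slope = qual_slope, seed = as.integer(seed)),
            class = "sim_config")
}

# Fixed downstream stuffer (post-spacer gIII-side filler) and the WT-read
# stuffer. Constants chosen free of the fixture anchors/borders and their
# reverse complements.
sim_stuffers <- function() {
  list(
    downstream = "CACTACGCTAAGCTACAAGTCTACGATGTA",
    wt = paste0("CAGTACTAACGTTACAGCATCAAGTGACTA",
                "GCTTACGAATCTCAGTTAGCATACGTGCAA")
  )
}

build_amplicons <- function(peptides, barcode, layout, wt = FALSE) {
  st <- sim_stuffers()
  tail3 <- paste0(reverse_complement(barcode), reverse_complement(layout$rev_anchor))
  if (wt) {
    paste0(layout$fwd_anchor, barcode, st$wt, tail3)
  } else {
    inserts <- encode_peptides_nnk(peptides)
    paste0(layout$fwd_anchor, barcode, layout$left_border, inserts,
           layout$right_border, st$downstream, tail3)
  }
}

# Apply the error model to a read set. Homopolymer +/-1 indels first (they
# change coordinates), then substitutions on the final coordinates. Event
# counts are drawn binomially and placed uniformly, which is equivalent to
# independent per-site draws; only reads with events pay per-read work.
apply_errors <- function(bases, quals, sub_rate, hp_rate) {
  n <- length(bases)
  n_sub <- integer(n); n_ins <- integer(n); n_del <- integer(n)
  if (hp_rate > 0) {
    runs <- gregexpr("([ACGTN])\\1+", bases, perl = TRUE)
    nrun <- vapply(runs, function(m) if (m[1] == -1L) 0L else length(m),
                   integer(1))
    nhit <- stats::rbinom(n, nrun, hp_rate)
    for (i in which(nhit > 0L)) {
      m <- runs[[i]]
      ends <- as.integer(m) + attr(m, "match.length") - 1L
      sel <- ends[sample.int(length(ends), nhit[i])]
      plus <- stats::runif(nhit[i]) < 0.5
      ord <- order(sel, decreasing = TRUE)  # right-to-left keeps positions valid
      b <- bases[i]; q <- quals[[i]]
      for (j in ord) {
        pos <- sel[j]
        if (plus[j]) {
          b <- paste0(substr(b, 1L, pos), substr(b, pos, pos),
                      substr(b, pos + 1L, nchar(b)))
          q <- append(q, 5L, after = pos)
        } else {
          b <- paste0(substr(b, 1L, pos - 1L), substr(b, pos + 1L, nchar(b)))
          q <- q[-pos]
        }
      }
      bases[i] <- b; quals[[i]] <- q
      n_ins[i] <- sum(plus); n_del[i] <- sum(!plus)
    }
  }
  if (sub_rate > 0) {
    len <- nchar(bases)
    nsub <- stats::rbinom(n, len, sub_rate)
    alt <- c("A", "C", "G", "T")
    for (i in which(nsub > 0L)) {
      pos <- sample.int(len[i], nsub[i])
      for (p in pos) {
        cur <- substr(bases[i], p, p)
        substr(bases[i], p, p) <- sample(setdiff(alt, cur), 1L)
      }
      quals[[i]][pos] <- 10L
      n_sub[i] <- nsub[i]
    }
  }
  list(bases = bases, quals = quals, n_sub = n_sub, n_ins = n_ins,
       n_del = n_del)
}

#' Simulate a 454-style amplicon sequencing run
#'
#' Emits exactly `spectra[p, s]` reads of peptide `p` under sample `s`, plus
#' `round(depth * wt_rate / (1 - wt_rate))` wild-type reads per sample, each
#' on the forward or reverse strand with equal probability, with the error
#' model of [sim_config()] applied. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param fasta_file,qual_file,fastq_file,truth_file optional output paths.
#' @return A list of class `ground_truth`: `reads` (a [seq_reads()] table),
#'   `truth` (`data.frame` of true per-sample peptide counts, `"WT"` rows for
#'   wild-type reads), and `provenance` (per-read sample, peptide or WT,
#'   strand and injected error counts).
#' @export
simulate_reads <- function(config, fasta_file = NULL, qual_file = NULL,
                           fastq_file = NULL, truth_file = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  layout <- config$layout
  spectra <- config$spectra
  sample_bc <- colnames(spectra)
  pep <- character(0); bc <- character(0)
  for (s in sample_bc) {
    cnt <- spectra[, s]
    pep_s <- rep(rownames(spectra), cnt)
    depth <- sum(cnt)
    n_wt <- if (config$wt_rate > 0) {
      as.integer(round(depth * config$wt_rate / (1 - config$wt_rate)))
    } else 0L
    pep <- c(pep, pep_s, rep("WT", n_wt))
    bc <- c(bc, rep(s, length(pep_s) + n_wt))
  }
  n <- length(pep)
  ord <- sample.int(n)
  pep <- pep[ord]; bc <- bc[ord]

  is_wt <- pep == "WT"
  bases <- character(n)
  if (any(!is_wt)) {
    bases[!is_wt] <- build_amplicons(pep[!is_wt], bc[!is_wt], layout)
  }
  if (any(is_wt)) {
    bases[is_wt] <- build_amplicons(NULL, bc[is_wt], layout, wt = TRUE)
  }
  strand <- ifelse(stats::runif(n) < 0.5, "forward", "reverse")

  rev_idx <- strand == "reverse"
  if (any(rev_idx)) bases[rev_idx] <- reverse_complement(bases[rev_idx])
  len <- nchar(bases)
  qmodel <- as.integer(pmin(40, pmax(2, round(
    config$qual_mean + config$qual_slope * (seq_len(max(len, 0L)) - 1L)
  ))))
  quals <- lapply(len, function(L) qmodel[seq_len(L)])
  n_sub <- integer(n); n_ins <- integer(n); n_del <- integer(n)
  if (config$sub_rate > 0 || config$hp_indel_rate > 0) {
    e <- apply_errors(bases, quals, config$sub_rate, config$hp_indel_rate)
    bases <- e$bases; quals <- e$quals
    n_sub <- e$n_sub; n_ins <- e$n_ins; n_del <- e$n_del
  }
  read_id <- sprintf("sim_%06d", seq_len(n))
  reads <- seq_reads(read_id, bases, quals)

  prov <- data.frame(read_id = read_id, barcode = bc, peptide = pep,
                     strand = strand, n_sub = n_sub, n_ins = n_ins,
                     n_del = n_del, stringsAsFactors = FALSE)
  truth <- as.data.frame(table(peptide = pep, barcode = bc),
                         stringsAsFactors = FALSE)
  names(truth)[3] <- "count"
  truth <- truth[truth$count > 0, ]
  truth <- truth[order(truth$barcode, -truth$count, truth$peptide), ]
  rownames(truth) <- NULL

  write_reads(reads, fasta_file, qual_file, fastq_file)
  if (!is.null(truth_file)) {
    con <- file(truth_file, "wb")
    writeLines(c("peptide\tbarcode\tcount",
                 paste(truth$peptide, truth$barcode, truth$count, sep = "\t")),
               con, sep = "\n")
    close(con)
  }
  structure(list(reads = reads, truth = truth, provenance = prov),
            class = "ground_truth")
}

#' True per-sample peptide counts as a count table
#'
#' Converts a simulator ground truth into the same [count_table()] shape that
#' [tabulate_peptides()] produces (wild-type reads, which carry no peptide,
#' are excluded), so recovered and true tables compare directly.
#'
#' @param gt a `ground_truth` from [simulate_reads()].
#' @param sheet the [sample_sheet()] used in the simulation.
#' @return A [count_table()].
#' @export
truth_count_table <- function(gt, sheet) {
  tr <- gt$truth[gt$truth$peptide != "WT", , drop = FALSE]
  peptides <- sort(unique(tr$peptide))
  samples <- as.data.frame(sheet, stringsAsFactors = FALSE)
  class(samples) <- "data.frame"
  counts <- matrix(0L, length(peptides), nrow(samples),
                   dimnames = list(peptides, samples$barcode))
  idx <- cbind(match(tr$peptide, peptides), match(tr$barcode, samples$barcode))
  counts[idx] <- tr$count
  count_table(counts, samples)
}
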