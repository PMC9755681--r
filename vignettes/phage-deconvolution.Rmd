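---
title: "Deconvoluting pooled phage-display amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting pooled phage-display amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagedeconv)
```

## The experiment this package models

Biopanning screens a combinatorial phage-display library (here the Ph.D.-12
format: random 12-mer peptides fused to the M13 pIII coat protein through a
Gly-Gly-Gly-Ser spacer) against an immobilized target over successive rounds
of binding, washing and elution. Deep sequencing replaces colony picking:
every eluted pool is PCR-amplified with primers that carry an inline
trinucleotide barcode, all pools are sequenced together on a 454-style
platform, and the reads are deconvoluted in software back to
(peptide, sample) counts.

The construct arithmetic anchors the whole analysis. A library clone's
amplicon is the wild-type amplicon plus the insert and spacer:

$$L_{\text{lib}} = L_{\text{wt}} + 3(k_{\text{insert}} + k_{\text{spacer}})$$

so for the 12-mer library with its 4-codon spacer and a 381-nt wild-type
amplicon, `amplicon_length()` gives 429 nt for a clone carrying an insert
and 381 nt for contaminating insert-less wild-type phage, and the variable
region itself is $3 \times 12 = 36$ nt.

```{r arithmetic}
layout <- example_layout()
amplicon_length(layout, with_insert = TRUE)
amplicon_length(layout, with_insert = FALSE)
insert_nt_length(layout)
```

## The per-read extraction procedure

`deconvolve_read()` (and its vectorized batch form `deconvolve_reads()`)
applies six steps in a fixed order; the first failure fixes the read's fate,
so fates and discard reasons always partition the input:

1. **Length prefilter.** Reads shorter than (shorter anchor) + barcode +
   left border + 36 nt + right border cannot contain the variable region and
   are discarded (`too_short`).
2. **Orientation and barcode.** A bounded 5' window (anchor length +
   barcode length + 8 nt) is scanned for an exact occurrence of the forward
   or reverse primer anchor. The barcode is the `barcode_length` bases
   immediately 3' of the anchor. No anchor, a truncated or `N`-containing
   barcode, or both anchors at once discard the read.
3. **Insert extraction.** The insert is the substring strictly between the
   first occurrence of the left border after the barcode and the next
   occurrence of the right border. Reverse reads run the same search with
   reverse-complemented borders and the extracted insert is flipped back to
   message sense, its quality slice reversed, so downstream steps never see
   strand.
4. **Quality repair and codon check.** An insert longer than 36 nt is
   repaired by iteratively deleting the base with the current minimum Phred
   quality until 36 remain; a shorter insert is discarded. The repaired
   insert must parse into 12 NNK codons (third base G or T) with no stop
   codon.
5. **Translation** under the standard genetic code.
6. **Tabulation** of accepted (peptide, barcode) pairs into a count table.

### Numerical and policy choices

* **Exact matching everywhere.** Anchors, barcodes and borders are matched
  without mismatches. Fuzzy primer matching would rescue a few percent of
  reads at the cost of cross-sample bleed-through, which is the one error
  that corrupts enrichment ratios rather than just shrinking depth.
* **Anchor length** defaults to 12 nt (`anchor_min_length`); when a longer
  primer fragment is configured, the 3'-terminal 12 nt — those adjacent to
  the barcode — are used, fixing the barcode position by adjacency.
* **Repair tie rule.** When several bases share the minimum quality the
  3'-most one is removed first (`repair_tie = "right"`), because 454 base
  quality degrades toward the 3' end; `"left"` is available. The iterative
  procedure is order-equivalent to removing the lowest-quality multiset in
  one shot, which is how the tests cross-check it.
* **Amber policy.** The NNK scheme's only stop is amber (TAG). The default
  `amber = "reject"` discards TAG-containing inserts as stop codons,
  honouring the no-stop validation rule; `amber = "suppress"` translates
  TAG as glutamine, the behaviour of supE hosts used to propagate these
  libraries. Suppression changes only the fate of TAG-containing reads.
* **`N` handling.** Input is normalized tolerantly (case, `U`→`T`, other
  characters to `N`), but any `N` in the barcode or final insert discards
  the read: exact-match semantics apply where the science does.
* **Border recurrences.** If a border sequence happens to recur inside an
  insert it is taken at face value (first left, then next right); the scan
  is single-pass and deterministic.
* Coordinates are 1-based inclusive in the R API, as is idiomatic.

Two points the procedure leaves open were decided as follows: borders are
located once, before repair, and are not re-searched after bases are removed
(repair edits only the extracted insert, so border positions cannot
shift); and reads in which both primer anchors occur inside the search
window are discarded as `ambiguous_orientation` rather than resolved by
precedence, since their origin cannot be determined.

## Background filters

Two classes of false positives dominate these screens and are removed from
the count table, not per read, so the filter report can show what was
removed and why:

* **Poly-His plate binders** (`his_filter`). His-tagged targets are captured
  on nickel plates; histidine-rich peptides bind the plate. The default rule
  removes peptides containing a contiguous `HHH` run. A stricter variant
  (`total3`) removes peptides with three or more histidines anywhere; it is
  not the default because known genuine binders with three dispersed
  histidines (e.g. HMGRHMHEGASS, HYTHTHQYTYSM) survive the run rule but not
  the total rule. Both are exposed.
* **Parental propagation bias** (`parental_filter`). A peptide abundant in
  the unpanned parental library owes its abundance to faster phage
  propagation in bacteria, not to binding; any peptide seen more than
  `parental_max` times in the parental (round 0) sample is removed from
  *every* sample. The default threshold is 2 (keep at most twice-seen); the
  stricter more-than-once variant is `parental_max = 1`. Both thresholds
  appear in practice and the choice is left to the analyst.

Both filters are idempotent, commute with each other, and partition the
peptide set into kept and removed — properties the test suite asserts on
randomized tables.

## Enrichment summaries

Enrichment of a peptide in a sample is defined as its share of that sample's
accepted reads (`sample_fraction`), the only definition consistent with
statements like "99% of a round's reads carry the top binder".
`round_trajectory` strings those fractions across panning rounds for a fixed
(target, wash, amplified) selector; `target_overlap` compares two targets'
peptide sets with both a Jaccard and a min-denominator metric (the
denominator convention is reported, not guessed); and
`position_frequency_matrix` gives a lightweight consensus summary: per-column
residue frequencies and a consensus string with the strict-majority residue
per position, `x` where no residue exceeds half the sequences. (A strict
majority, not a plurality, is required: on two aligned sequences a
disagreeing position is a 50/50 tie and must read `x`.) This is a
descriptive stand-in for motif discovery, not a replacement for MEME-class
tools.

## The read simulator and what the tests prove

`simulate_reads()` generates 454-style reads with full ground truth so every
stage is verifiable offline. Reads have the form

```
anchor + barcode + left_border + insert(36) + right_border(spacer) +
downstream + revcomp(barcode + rev_anchor)
```

with wild-type contaminant reads lacking insert, spacer and borders, each
read emitted on either strand with equal probability. The error model
captures the two dominant 454 modes: uniform substitutions (default 0.5%
per base, flagged at quality 10) and ±1 homopolymer-run length errors
(default 0.5% per run of length ≥ 2), with inserted bases written at
quality 5 — strictly below every model quality (the baseline declines from
34 by 0.02/base, floor 2), so the quality-repair step is exercised exactly
as designed: an insertion inside the variable region yields a 37-nt extract
whose minimum-quality base is the inserted one. Event counts are drawn
binomially and placed uniformly, which is distributionally identical to
independent per-site draws. Per-peptide read counts are emitted exactly as
configured (wild-type reads are added on top at
`depth * wt_rate / (1 - wt_rate)`), so an error-free run must round-trip to
the configured spectra without tolerance, and does.

The reference fixture replays the study design at desk scale: five barcodes
(AAA tagging the unpanned parental library; ACT, ATC, AGG tagging target
rounds 3, 1, 2 under stringent slow washes; ACG a round-1 amplified pool),
twenty 12-mer peptides, 2,000 reads per sample. Its spectra emulate the
canonical enrichment pattern — the top binder absent from round 1 and
dominant by round 3, a propagation-biased peptide at 3.6% of the parental
pool and absent from the most stringent round — with consecutive per-sample
counts separated widely enough (≥ roughly four standard deviations of
binomial read loss at the default error rates) that top-5 rank recovery is
a property of the pipeline, not luck. The anchors and borders of the fixture
are invented sequences (the right border doubles as a plausible
Gly-Gly-Gly-Ser spacer codon run); real runs supply their own layout
config.

What passing tests do **not** show about real data: the simulator draws
substitutions uniformly (no flow-order or position-specific bias), models
homopolymer errors only as ±1 at run ends, and omits PCR chimeras,
cross-sample index hopping and quality miscalibration. Results on real 454
data therefore inherit the guarantees of the exact-match design (no
bleed-through by construction) but not the simulator's acceptance rates.

Problem sizes in the shipped tests — 10,000-read fixture runs, 50 seeded
replicates for the noisy-recovery property, 1,000-case oracle comparisons —
were chosen so the full suite completes in a couple of minutes while keeping
every binomial margin analysed above comfortably wide.

## Scope and limitations

* Readers return whole-run tables; the interface is contract-compatible
  with streaming but sized for desk-scale amplicon runs (≲ 10⁵ reads).
* SFF/flowgram decoding, paired-end merging, fuzzy primer matching,
  chimera detection and motif discovery are out of scope.
* Enrichment significance testing is deliberately absent: with single
  sequencing replicates per pool there is no within-condition variance to
  estimate, and the headline statistic of such screens is the trajectory
  and cross-target overlap, both of which are reported descriptively.
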