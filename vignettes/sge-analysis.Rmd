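---
title: "Scoring and classifying variants from SGE depletion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying variants from SGE depletion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgescreen)
```

## The assay and its readout

Saturation genome editing (SGE) installs every possible single-nucleotide
variant (SNV) and 3-bp deletion of a ~120-nt target region into the
endogenous locus of a cell line in which the gene is essential, via
Cas9 cutting and homology-directed repair (HDR) from a pooled repair
template library. Because unrepaired or re-cut alleles are common, every
repair template carries *fixed edits* — synonymous substitutions that
block re-cutting and mark HDR-derived alleles. Cells are sampled at the
plasmid-library stage (day 0) and at days 5 and 13; the edited region is
amplified and sequenced, and the relative abundance of each variant over
time is the fitness readout. A day-5 mRNA amplicon additionally reads
out each variant's effect on transcript abundance.

`sgescreen` implements the analysis from merged reads onward, together
with a generative simulator so that every stage can be verified against
known ground truth. Read merging, alignment, and consequence annotation
(e.g. VEP) are upstream of this package; their outputs (merged reads,
or count tables, plus an annotation table) are its inputs. For
simulated targets, consequences come from the target's own coding frame.

## Read validity

`classify_read()` encodes the screen's validity rules. A read must have
the expected length, contain **all** fixed edits, and carry exactly one
additional mismatch inside the edited region (the programmed SNV), or
match the edited reference with one programmed 3-bp deletion applied and
no further edited-region mismatch. Mismatches outside the edited region
are tolerated (they usually reflect the PCR handle or sequencing error
far from the programmed positions). Reads equal to the unedited
reference are wild-type (uncut or repaired without the marker);
reads with the fixed edits but no programmed variant are HDR wild-type;
everything else — including reads combining a substitution with a
deletion — is invalid.

Two practical refinements matter:

* **Homopolymer tolerance.** Amplicon sequencing slips at homopolymer
  runs. For targets containing runs of at least four identical bases, a
  sequenced run-length change of up to two bases is permitted: the read
  is re-anchored by restoring one run to its expected length before the
  length test, and the usual rules are applied to the run-normalised
  read. The allowance affects only the length test; the single-mismatch
  rule is evaluated afterwards.
* **Deletion ambiguity.** In repeat contexts, deleting three bases at
  two different start positions can produce the same sequence. The
  matcher scans candidate deletion templates in ascending start order
  and reports the leftmost match, consistent with standard indel
  left-alignment. `enumerate_variants()` marks the non-leftmost members
  of such equivalence sets (`canonical = FALSE`); they are
  indistinguishable at the read level and are not simulated. SNVs
  programmed on top of a fixed edit destroy the HDR marker and can
  never produce a valid read; these are flagged `callable = FALSE`.

Coordinates are 1-based and inclusive throughout, the native R and
Biostrings convention; output identifiers use HGVS-style `c.` notation
on target-local coordinates.

## Quality control

`run_library_qc()` applies one gate per printed threshold, all
inclusive on the passing side and all overridable in one place
(`qc_thresholds()`): plasmid library ≥ 500,000 merged reads with ≥ 30%
valid and ≤ 10% wild-type; negative control ≤ 1% valid; every
day-5/day-13 replicate ≥ 150,000 valid reads; at least two valid
replicates per timepoint; and minimum pairwise replicate Pearson
correlation ≥ 0.5. Correlations are computed on raw frequencies of
shared variants by default; frequencies are heavy-tailed, so a
`log10(f + 1e-7)` option is provided, but the raw-frequency default
matches the plain reading of "correlation between replicates". The
verdict is a pure function of the count table.

## Position-effect correction and scoring

Variant recovery depends on the distance between the programmed edit
and the cut site (conversion tracks shorten away from the break, and
coverage dips near it). This appears as a smooth positional trend in
the day-5 log2 frequency ratios. `fit_position_smoother()` fits a
one-dimensional LOESS (local linear, tricube weights, span 0.20, no
robustness iterations — only the span is a scientific choice here, and
all knobs are exposed) per replicate, using only variants whose day-5
frequency is at least half their starting frequency, so that genuinely
depleting variants do not drag the trend down. The fit is evaluated at
every variant position (`surface = "direct"`, so positions outside the
fit subset extrapolate rather than return `NA`) and subtracted from
that replicate's day-5 **and** day-13 ratios — the day-13 ratio shares
its replicate's day-5 positional distortion.

`score_variants()` then regresses adjusted log2 ratio on day over
`(0, 0)` ∪ `(5, adj5_r)` ∪ `(13, adj13_r)` per replicate `r`, with a
free intercept (the anchor keeps it near zero regardless). The slope is
the functional score in log2/day; its OLS standard error is reported;
variants with fewer than four finite points are left unscored. The
`(0, 0)` anchor is included once per replicate, so replicate count
weights the fit. Variants covered by two adjacent targets pool both
point sets into one regression (`score_overlapping()`).

A pseudocount of 0.5 is added to every raw count before a frequency
enters a log ratio, keeping fully depleted variants finite; raw counts
remain the basis of the min-count filter (default 10, applied to the
plasmid library and every DNA timepoint library — applying it to day-13
libraries where lethal variants legitimately deplete is debatable, so
the library set is an argument) and of QC. A consequence of the
pseudocount is that scores are exactly scale invariant only in the
large-count limit; at the simulated depths the effect is below 0.01
log2/day.

**What the score means.** Because frequencies are relative (counts over
total valid reads), the score measures depletion relative to the
library-average trajectory, recentred by the LOESS on the
fit-subset (≈ neutral) variants. In the intended regime — a
neutral-dominated library — this equals the absolute fitness effect to
within sampling noise, and the simulator's null model (all slopes zero)
is recovered without bias. If essentially *every* variant depletes, the
common collapse of the library inflates all ratios and the fit subset
no longer isolates neutral variants; slope rankings survive almost
perfectly (Spearman > 0.95 in our recovery tests) but a systematic
offset of order +0.1 log2/day appears. This is a property of any
relative-abundance assay, not of the implementation; interpretation of
absolute score values should always lean on the synonymous/nonsense
anchor distributions, as the classifier does.

RNA scores are `log2(f_RNA / f_DNA)` at day 5, where DNA frequencies
are first renormalised over the variants inside the RNA amplicon window
(only those positions are sequenced in the mRNA), per replicate, then
collapsed by the median; two-target variants report the mean of their
per-target scores.

## Functional classification

A two-component Gaussian mixture is fitted to the SNV scores by EM with
free means, variances and weights. Initialisation is anchored, not
random, which makes the fit deterministic: the normal component starts
at the mean of the middle 95% (2.5–97.5 percentile trim) of
synonymous + intronic SNV scores, the abnormal component at the mean
nonsense SNV score outside exons where truncation can escape selection
(for the simulated single-exon targets no exon is excluded; the
excluded-exon list is an argument). Initial weights are 0.5/0.5 and
initial variances default to the overall sample variance — the anchors
pin only the means, which is what determines which basin EM lands in.
Convergence is declared when the log-likelihood improves by < 1e-6
(500-iteration cap, warning and best model on non-convergence); a
component that empties or collapses flags the fit degenerate.

SNVs with posterior probability > 0.95 for a component take its label;
the band between is indeterminate. For the 3-bp deletions the mixture
is *not* refitted: the scores of the observed SNVs whose posteriors are
closest to the 0.95 cutoffs become reusable thresholds, and deletions
are classified by threshold (≤ LoF threshold abnormal, ≥ normal
threshold normal, boundary values classified, not indeterminate). In
principle posterior-based SNV labels and threshold-based labels can
disagree deep in the tails when variances are unequal; SNVs keep their
posterior labels, thresholds serve deletions and reporting.

The RNA threshold is one standard deviation above the mean nonsense RNA
score, with mean and SD computed from the bottom 97.5% (top 2.5%
discarded) of eligible nonsense RNA scores; a variant's RNA abundance
is "normal" iff its score is at least the threshold (boundary
inclusive).

## Clinical calibration

`compute_oddspath()` implements the Bayesian odds of pathogenicity:
with prior `P1` (fraction pathogenic in the truth set, after excluding
variants with indeterminate or missing functional class) and posterior
`P2` (fraction pathogenic among truth variants called abnormal, or
normal), `OddsPath = P2(1 − P1) / ((1 − P2) P1)`. A cell with no
counter-examples is continuity-adjusted by adding one and flagged —
a perfect classifier otherwise yields infinite odds. Evidence strength
follows the standard thresholds (> 350 very strong, > 18.7 strong,
> 4.3 moderate, > 2.08 supporting; reciprocals for benign), mapped to
±8/±4/±2/±1 points. `combine_points()` sums per-criterion points
(PS3/BS3 from calibration; PP3/BP4, PM2, PVS1 etc. are consumed as
precomputed inputs, as a clinical laboratory supplies them) with
thresholds ≥ 10 P, 6–9 LP, −1–5 VUS, −6 – −2 LB (the −2-point LB
variant of the scheme), ≤ −7 B. Variants with indeterminate functional
class receive no PS3/BS3 points.

ROC/AUC is the rank-based (Mann–Whitney) statistic with ties averaged,
oriented so that lower scores are more pathogenic. Case-control
enrichment uses the cross-product odds ratio `ad/bc` with the two-sided
exact hypergeometric p-value (`stats::fisher.test`) and a Woolf log-OR
95% CI (0.5 added to every cell when one is empty, flagged); an exact
conditional CI was considered and rejected because the Z-test comparing
two odds ratios recovers standard errors from the *printed* CIs,
`SE = (log U − log L)/(2·1.96)`, and mixing CI types would bias that
comparison.

## The simulator

`simulate_sge_study()` draws a random target (default 160 nt: 20-nt PCR
flanks, a 120-nt edited region containing a central coding block and
12-nt intronic margins so canonical-splice, splice-region and intronic
variants all arise), enumerates variants, assigns ground truth and
generates counts. Defaults are chosen once to emulate the screen's
conditions:

* **Design**: 3 replicates, days 0/5/13, 2×10⁵ reads per replicate
  library (plasmid-library depth separately configurable, since real
  designs sequence it deeper to clear the 500,000-read QC gate).
* **Truth**: truncating and canonical-splice variants deplete at −0.2 ±
  0.03 log2/day; 13% of missense and splice-region variants are
  loss-of-function; synonymous/intronic variants are neutral (SD
  0.015) with a small (0.5–1%) cryptic-splice LoF rate; transcript-
  depleting variants carry an RNA effect of −2.24 ± 0.8 log2.
* **Library composition**: symmetric Dirichlet (concentration 50) over
  variants, emulating uneven synthesis; the real library composition
  model is unpublished, so this is a stand-in, not an inference.
  Wild-type (unedited) reads are 5% of each library so the QC gates are
  exercised.
* **Position effect**: a Gaussian dip in apparent slope centred at the
  cut site (amplitude −0.04 log2/day, SD 15 nt), motivated by the
  cut-site coverage dips seen in real screens; shape and size are
  otherwise unspecified in the literature, so both are arguments.
* **Counts**: multinomial per library (Dirichlet-multinomial when
  overdispersion is requested), so each library's counts sum exactly to
  its depth. Expected frequencies follow
  `f_v(t) ∝ f_v(0) · 2^{(s_v + g(pos_v)) t}`, renormalised.
* **Reads**: one read per count, of the variant-modified edited
  reference; i.i.d. substitution errors and per-run homopolymer
  slippage (±1–2 nt) are injected on request. The negative control is
  wild-type-dominated with ~0.2% valid contamination.
* **Seeding**: one top-level seed; every library and stage draws from a
  derived sub-seed, so studies are bit-reproducible.

What the simulator does **not** emulate — and therefore what passing
tests cannot certify about real data — includes PCR jackpotting and
duplicate structure, quality-score-dependent error profiles, NHEJ indel
spectra beyond the programmed deletions, guide off-target effects, and
real library synthesis biases. Its valid-read fractions (~95%) are far
above the 10–40% usable-edit rates of real screens, because unedited
and NHEJ-repaired alleles dominate real libraries; the QC and
editing-rate machinery is exercised by the simulated wild-type and
negative-control fractions instead.

## Numerical choices and edge cases

* LOESS with fewer than 10 fit points is skipped (fits 0) with a
  warning rather than extrapolating from nothing.
* EM posteriors guard against zero densities; variances are floored at
  1e-10.
* The min-count filter uses raw counts; the pseudocount applies only
  inside log ratios.
* Thresholds derived from observed scores agree with a dense-grid
  posterior inversion to within the local inter-variant spacing (this
  is tested).
* Percentile trims use R's default (type 7) quantiles.
* All boundary semantics ("at least", "no more than", "no less than")
  are inclusive on the passing side, and boundary scores at the derived
  thresholds are classified, not indeterminate.

## Problem sizes used in the checks

The shipped tests and the acceptance script run on single synthetic
regions of 120–340 nt (300–1,200 variants) at depths of 10⁴–6×10⁵ reads
per library — sizes chosen so the whole suite exercises every stage,
including read-level round trips, in well under a minute while leaving
sampling noise small relative to the tested tolerances. The read-calling
oracle check compares 1,000 random reads against a brute-force
enumeration oracle; slope recovery uses 300 variants at 2×10⁵ reads as
its reference condition.
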