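---
title: "Quantifying base-editing outcomes in arrayed protoplast screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying base-editing outcomes in arrayed protoplast screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Arrayed protoplast transfection turns base-editor development into a
plate-scale assay: each well of a 96-well plate receives one editor/guide
configuration, a constitutive nuclear mCherry marks delivery, and a nuclear
GFP reporter switches on only when the editor makes its programmed base
change. The quantity of interest is the **editing efficiency**

\[
E = 100 \times \frac{n_{\mathrm{GFP^+}}}{n_{\mathrm{mCherry^+}}}
\]

— the percentage of transfected cells in which editing restored (or
created) the GFP signal. Because the denominator is the transfected
population, the statistic is self-normalizing with respect to well-to-well
transfection variability, which in practice spans roughly 40–65% and can
vary ~2-fold between constructs.

The same activity is measured at endogenous loci by amplicon sequencing:
the per-position fraction of reads carrying the programmed substitution
inside a quantification window around the protospacer.

protoquant implements both read-outs, together with a synthetic-data
generator that produces plate images and read sets with known ground
truth, so that every stage — projection, segmentation, gating, counting,
aggregation, testing; demultiplexing, alignment, window arithmetic — can
be verified without any instrument data.

## The synthetic plate generator

`simulation_config()` encodes the acquisition geometry being emulated: an
8×12 plate, 9 fields of view per well, 7 Z planes, and four channels
(brightfield, chlorophyll, GFP, mCherry). Each well's biology is three
numbers: cells plated, transfection rate, editing rate. Ground truth is
drawn first (positions, radii, per-cell transfected/edited flags) and the
pixels are rendered afterwards, so `render = FALSE` produces an identical
truth table at a fraction of the cost.

What the generator emulates, and how:

* **Cells** are discs with chlorophyll-channel fluorescence (wheat mode).
  Centers are rejection-sampled with a minimum spacing of 2.2× the mean
  radius and radii are capped at half the nearest-neighbour distance, so
  rendered cells never merge: the generator's contract is *unambiguous
  truth matching*, because a detection-F1 benchmark is meaningless if the
  truth itself is ambiguous. Overlap and clumping in real fields are
  exactly what the roundness filter is there to reject; the generator
  exercises that filter with debris instead.
* **Nuclei** are smaller concentric discs: mCherry in transfected cells,
  GFP additionally in edited cells, so `edited ⊆ transfected` holds by
  construction.
* **Debris** are elongated streaks (axis ratio 3–4) with chlorophyll-like
  intensity and no nuclear signal, placed clear of cells. They exist to
  exercise the roundness filter.
* **Z structure**: each object's intensity follows a Gaussian profile
  across planes with a random focal plane (σ = z/4 planes). This makes a
  maximum-intensity projection meaningful without modelling optics.
* **Vignetting**: a radially symmetric multiplicative falloff (default
  strength 0.25) gives `flatfield_correct()` something real to remove.
* **Noise**: additive Gaussian read noise per channel, plus per-object
  intensity variation. Default foreground means put nuclear reporters
  ~50 background SDs above background — strong constitutive promoters are
  genuinely that bright. Chlorophyll foreground CV is ~13%, the spread of
  a healthy, uniform protoplast prep.

What it deliberately does **not** emulate: point-spread functions and
confocal optics, chromatic aberration, cell clumping and partial lysis,
autofluorescence spectra, and focus failures. Passing tests therefore
demonstrate that the *quantification logic* is correct on data matching
its assumptions — not that segmentation is robust to every microscopy
pathology.

Seeding: one master seed expands into named substreams per well, field
and module (`substream_seed()`), so a single field can be regenerated
without replaying the plate, and rendering does not perturb truth
determinism.

Reads are simulated as single full-length amplicon sequences from an
allele mixture (`allele_spec()`): substitutions and/or one indel per
haplotype, deterministic (`round(fraction × n)`) or multinomial
allocation, per-base error rate, constant or Gaussian Phred qualities,
optional reverse-complementation (probability 0.5 where strand handling
is under test) and an optional 6-nt inline index. Paired-end simulation
and merging are out of scope; real 2×150 data are assumed pre-merged.

## The imaging pipeline

`analyze_field()` runs, per field:

1. **Maximum-intensity projection** per channel. The acquisition takes
   7 Z planes but the source workflow does not state a projection; the
   maximum is robust for sparse bright nuclei and is the documented
   choice.
2. **Pseudo-flatfield correction** of the chlorophyll channel: divide by
   a heavily smoothed copy (σ = 50 px by default, far above the ~11 px
   cell radius), rescale to preserve the mean. The smoother uses
   replicated-edge padding — an FFT/circular convolution would bleed
   opposite borders into each other, which is precisely what a background
   estimate must not do.
3. **Protoplast segmentation** (wheat mode): Gaussian smoothing (σ = 2),
   Otsu threshold, hole filling, distance-transform watershed
   (tolerance 2) to split touching cells. Every region is kept and
   *flagged*: `is_protoplast` requires roundness ≥ 0.8, area within
   bounds (100–4000 px²) and no border contact (standard HCS practice;
   partial cells bias both counts and intensities).
4. **Nucleus segmentation**: Otsu threshold of the pixelwise maximum of
   the mCherry and GFP projections (union semantics — a GFP-only nucleus
   is still a nucleus), filtered by nucleus area bounds. In maize mode
   (etiolated tissue, no chlorophyll) these nuclei *are* the analysis
   units.
5. **Measurement**: each cell is assigned at most one nucleus by centroid
   containment, ties broken by the brighter mean nuclear mCherry
   (deterministic and order-independent); cells without a nucleus get
   background-level reporter means measured over the cell body.

**Roundness.** The metric is the isoperimetric quotient
\(4\pi A / P^2\) with cutoff 0.8 (the source names "roundness" but gives
no formula or value; both are configurable). The perimeter matters more
than it looks: pixel-edge perimeter estimates run so low that a 6:1
ellipse scores ≈0.8. protoquant computes \(P\) as the chain-code length
of the traced boundary (diagonal steps count √2), which puts digital
discs at ≈0.9–1.0 and 3–4:1 streaks at ≈0.55–0.66 — a clean margin on
both sides of the cutoff.

**Thresholding guard.** Otsu on an essentially flat image splits noise;
`resolve_threshold()` returns "no foreground" when the Otsu value fails
to clear the median by 3 MADs. Empty fields thus yield zero regions, not
artifacts.

## Gating

Two thresholds turn measurements into flags:

* **mCherry (transfection) gate**: Otsu over all per-cell mean nuclear
  mCherry values of the plate. Every well contains untransfected cells
  (transfection is 40–65%), so the background mode is always present;
  a plate never has mCherry-negative control wells, which is why the
  quantile method does not apply here. A fixed threshold can be supplied
  instead.
* **GFP (editing) gate**: the 99.9th percentile of nuclear GFP among
  transfected cells in the plate's no-guide control wells. This is the
  operational meaning of "normalizing against the negative control": the
  gate is placed where the null distribution ends, accepting a designed
  0.1% false-positive rate. Otsu and fixed fallbacks exist for plates
  without controls.

Gating is nested by default: `is_gfp_positive` requires
`is_transfected`, so counts always satisfy
\(n_{GFP^+} \le n_{mCherry^+} \le n_{cells}\). An independent
(non-nested) GFP gate is kept alongside for co-transfection
measurements, whose ratio may legitimately exceed 100% and is reported
unclipped.

Because the GFP gate is a null-distribution quantile, every condition
carries a ~0.1-point additive false-positive floor. `aggregate_condition()`
therefore reports the negative-control mean and a control-corrected mean
next to the raw mean; at editing rates near the floor (≤1%) the corrected
value is the meaningful one.

**Replicate aggregation** is the mean of per-well efficiencies, not the
pooled count ratio: published per-condition numbers of the form
"57.3% (n = 1908/3316)" do not equal their pooled ratio (57.5%), which
identifies wells — the biological replicates — as the unit of analysis.
Both values are emitted; the mean is primary.

## Plate statistics

`compare_groups()` provides the four tests used in reporter-screen
figures: one-way ANOVA with Tukey's HSD, Kruskal–Wallis with Dunn's post
hoc (Holm-adjusted; Holm is the conservative default where no adjustment
is prescribed), exact Mann–Whitney, and the pooled two-proportion
z test (pairwise, Holm-adjusted beyond two groups). Significance letters
are assigned at α = 0.05 by insert-and-absorb.

`detection_threshold()` asks: given \(k\) replicate wells of \(n\)
transfected cells and a control background, what is the smallest true
editing rate that a one-sided two-proportion z test detects with power
≥ 0.8 at α = 0.05? The answer is estimated by Monte-Carlo (2000
replicates per point) over a logarithmic grid from 0.05% to 10%. It is a
*property of the replicate structure*, reported with its simulation SE —
with 8 wells × 1000 transfected cells and zero background it sits well
under 1%, and it is non-increasing in the replicate count. The published
"average threshold efficiency of 0.6%" characterization of real plates
(with real backgrounds and real well-to-well variance) is mirrored as
this property, never reproduced as a number.

## Amplicon quantification

`amplicon_target()` binds an amplicon to its protospacer (validated to
occur exactly once on the stated strand) and the scoring parameters:
window size \(w = 10\), window center \(c = -12\) relative to the
protospacer 3′ end, substitution cleavage offset −1, indel cleavage
offset −4 (the staggered Cas12a cut), and minimum mean read quality
Q30 — the parameterization standard amplicon quantifiers expose for
Cas12a base-editing experiments.

The window arithmetic, with protospacer length \(L\):

\[
p_c = L + c,\qquad
\mathrm{window} = [\,p_c - \lceil w/2\rceil + 1,\; p_c + \lfloor w/2\rfloor\,]
\cap [1, L].
\]

For the canonical \(L = 20, w = 10, c = -12\) this yields positions 4–13,
the classic base-editing window; for a 23-nt Cas12a spacer the same
formula applies and is the documented convention here. Positions are numbered 5′→3′ along the
protospacer (position 1 is the 5′ base), which coincides with
"PAM-distal base is position 1" for Cas9 (3′ PAM) and "PAM-adjacent base
is position 1" for Cas12a (5′ PAM); the table carries the figure-style
tag.

Processing per sample: 6-nt inline-index demultiplexing (exact match by
default; a mismatch tolerance is available and index pairs closer than
2× the tolerance are a configuration error), inclusive mean-Phred
filtering, then semi-global alignment of each read against the amplicon
(free end gaps on the amplicon; match +2, mismatch −1, gap of length
\(k\) costs \(5 + k\)); both orientations are scored and reads below
0.4 × the perfect score are counted as unalignable. A read is
**indel-class** iff its alignment has an insertion or deletion
overlapping the indel window; indel-class reads are excluded from
substitution denominators. The classification — indel, substituted,
unmodified, incomplete (window not covered) — partitions the aligned
reads exactly, and assigned + unassigned = input at every stage.

`allele_table()` groups reads by their window haplotype (deletions as
`-`, insertions spliced in), sorted by count with ties broken by
sequence, and annotates each deviation from reference.
`call_zygosity()` applies the 25/70 rule: below 25% wild type, 25–70%
inclusive heterozygous, above 70% homozygous — "between 25 and 70%" is
read as inclusive on both ends, making the HM boundary exclusive at 70.
`annotate_spacer_mismatches()` labels mismatched protospacer positions
seed (positions 1–8 for Cas12a; the 3′ eight for Cas9) or distal,
supporting homeolog off-target bookkeeping in polyploid genomes.

## Numerical and design choices

* Pixel coordinates are 1-based matrix indices (row, column), top-left
  origin; areas in px². Percentages are reported to one decimal
  (`report_pct()`) with raw values retained.
* The quality filter is inclusive (mean Phred ≥ Q passes at exactly Q).
* Deterministic read allocation settles rounding remainders on the most
  abundant haplotype, so `round(fraction × n)` holds wherever the rounded
  counts already sum to n.
* Negative radius or intensity draws are resampled, never clamped to
  zero.
* Watershed tolerance 2 px: ellipse ridges (debris) stay whole while
  touching-disc saddles (gap ≥ ~6 px in distance-map height) still split.
* Degenerate inputs: empty wells produce zero-count rows with a warning;
  zero denominators yield `NA`-flagged efficiencies excluded from
  aggregation; an all-reference read set yields an all-zero table, not an
  error.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run: one noise-free 380×380 px
field with 50 cells and 10 debris for segmentation recovery; record-level
plates of 8 replicate wells × 1800 cells (~1000 transfected) at editing
rates 0.5 / 5 / 30% for parameter recovery; 2000 Monte-Carlo replicates
per grid point for the detection limit; 1000-read deterministic mixtures
and 100 randomized ~50-read mixtures for the amplicon invariants; and 500
null simulations for the z test's size. These sizes were chosen so each
property is measured with comfortable statistical margin (3-SE binomial
bounds throughout) while a full run stays in the tens of seconds.

## Known limitations

* The imaging model is geometric, not optical; segmentation performance
  on real confocal data will be worse than on synthetic fields, and the
  shipped F1 figures should be read as a correctness check of the logic,
  not an accuracy claim for instruments.
* The aligner assumes reads from a single amplicon; multiplex panels are
  handled by iterating targets and assigning each read to its
  best-scoring amplicon with a 10-point margin, which will misassign
  reads from near-identical homeologs that differ by less.
* Dunn's test uses the large-sample normal approximation; for very small
  replicate counts the exact Mann–Whitney path is preferable.
* The detection-limit estimate conditions on a known, homogeneous
  cells-per-well count; real plates add well-to-well variance that
  inflates the threshold.
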