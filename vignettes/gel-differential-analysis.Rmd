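---
title: "Differential 2-DE spot analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential 2-DE spot analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelprot)
```

gelprot implements the quantitative core of a classical two-dimensional gel
electrophoresis (2-DE) comparison, of the kind used to profile proteins in
low-volume clinical samples such as muscle microdialysate collected through
a 100 kDa cut-off catheter membrane. This vignette explains the model
behind each stage, the tunable parameters and why their defaults are what
they are, what the synthetic data generator does and does not emulate, and
the design decisions taken where the methodology left genuine choices.

## The measurement model

A 2-DE gel separates proteins by isoelectric point (pI) along a linear
immobilized pH gradient (first dimension) and by molecular weight along an
approximately log-linear migration axis (second dimension). After
staining, each protein appears as a roughly Gaussian spot on a digitized
12-bit image. The quantity attached to a spot is its **integrated optical
density (IOD)**: the background-corrected optical density summed over all
pixels of the spot.

Staining intensity varies globally from gel to gel, so raw IODs of
different gels are not comparable. The standard correction is **ppm
normalization**: a spot's IOD is divided by the summed IOD of all spots on
the same gel and scaled to parts per million,

$$\mathrm{ppm}_i = \frac{\mathrm{IOD}_i}{\sum_j \mathrm{IOD}_j} \times 10^6 .$$

This makes the spot vector of a gel invariant under any global
multiplicative rescaling of its intensities (`normalize_ppm()` is tested
for exact invariance to 1e-9 relative tolerance), at the cost of coupling
all spots through the denominator: a large abundance change in a dominant
spot shifts every other spot's ppm slightly. With the differential
fractions and effect sizes typical of this design the coupling is a
few percent and does not move spots across a two-fold boundary; it is,
however, the reason the simulator draws differential effects comfortably
above the threshold (below).

### The fold-change rule

Comparisons are made per matched spot between one case gel and one control
gel, as a ratio of ppm values. A spot is called differential when its
concentration is *at least two-fold* higher or lower than in the control:
`ratio >= 2` or `ratio <= 0.5`, with the boundary **inclusive** — "at
least two-fold" reads as inclusive, so a ratio of exactly 2.0 passes.
Direction is `up` for ratio above 1, `down` below 1, `unchanged` at
exactly 1 (forced by trichotomy). There is no significance testing: the
design this package serves compares single pooled gels per group, so a
fold-change filter is the only defensible rule, and `classify_twofold()`
implements exactly that.

Edge policy: gels differ in how many spots they show, so presence/absence
events happen. A spot absent from the control side (control ppm 0, case
ppm positive) is assigned ratio `Inf`, direction up, and passes; the
converse is assigned ratio 0, direction down, and passes. Both carry a
`presence_absence` flag so downstream consumers can treat them separately
from quantified ratios. Pairs absent on both sides are flagged
`absent_absent` and never pass.

### Matching and overlap

When two tables share spot identifiers (the packaged fixture tables are
already matched upstream), `match_spots()` pairs by identifier. Otherwise
it pairs by **mutual nearest neighbor** in (pI, log10 MW) space, within
tolerances (default 0.15 pH units and 0.05 log10 kDa — roughly the
positional scatter of a well-run gel pair after warping); a pair is kept
only when each spot is the other's nearest neighbor inside the tolerance
ellipse. Unmatched spots are reported with ppm 0 on the missing side
rather than dropped, feeding the presence/absence policy above.

Overlap between two case-control comparisons (`overlap_analysis()`) is
keyed on **spot identifier, not protein accession**: the same protein
routinely appears as several isoform spots (glycosylation and truncation
shift pI), and isoforms of one protein can move in opposite directions.
Collapsing to accessions would silently merge those.

## The synthetic data generator

Real gel images of this design are not redistributable, so validation
rests on a simulator with exact ground truth. `simulation_config()`
defaults define one fixed set of study conditions:

* **300 spots** per gel, the typical detectable count for a silver-stained
  microdialysate gel; positions uniform over the usable frame with a
  12 px minimum center separation (spot trains that co-migrate closer
  than the detector's resolution limit are a stress case, not the
  benchmark).
* **pI uniform on pH 3–10** (linear gradient) and **MW log-uniform on
  10–100 kDa**, truncated at the **100 kDa membrane cutoff**: nothing
  larger crosses the catheter membrane, so nothing larger may appear in
  the truth table (tested exactly).
* **Baseline volumes log-normal** (meanlog `log(2000)`, sdlog 1.2,
  truncated below at 300 intensity units). Real spot tables span roughly
  three orders of magnitude; the truncation keeps the faintest simulated
  spot detectable in principle (peak about 1.5 noise SD before
  smoothing), because a benchmark containing spots that are invisible by
  construction measures nothing.
* **15% differential spots** (`round(0.15 * 300) = 45`), matching the
  15–18% differential fractions characteristic of this comparison type.
  True ratios are drawn log-uniformly in magnitude from **[2.5, 8]** and
  inverted with probability 1/2. The support deliberately excludes the
  interval (0.5, 2) — a designated differential spot must truly violate
  the two-fold rule — and starts at 2.5 rather than 2.0 because an effect
  sitting exactly on the decision boundary is undetectable by
  construction; observed passing ratios in real tables of this design
  run from 2 to above 10 with a median near 3, which this range mirrors.
  Case and control volumes split the fold symmetrically
  (`case = base * sqrt(r)`, `control = base / sqrt(r)`), keeping the
  group-mean abundance at baseline so the two gel totals stay comparable.
  Non-differential spots have ratio exactly 1; all observed scatter in
  their measured ratios comes from the measurement chain, which is the
  thing under test.
* **Rendering**: each spot is an isotropic Gaussian (sd 2.5 px on a
  1000 × 1000 px frame) whose integrated volume equals the true volume
  times a per-gel **global scale factor** (defaults 1.0 and 1.3),
  emulating staining differences that ppm normalization must remove; a
  constant background of 40 and Gaussian pixel noise of sd 5 are added
  (peak SNR ≈ 10 for the median spot), and values clip at the 12-bit
  ceiling with the clipped fraction reported. No per-spot noise model is
  prescribed by the underlying methodology, so these defaults are
  repository conventions and are echoed into every exported scene.

What the simulator does **not** emulate: electrophoretic migration
physics, staining kinetics and saturation curves (clipping is a hard
ceiling, not a dye response), spatial background gradients, streaks,
co-migrating isoform trains at sub-resolution spacing, and cross-gel
geometric distortion (both simulated gels share true spot positions, so
coordinate matching faces positional noise only from centroid estimation).
Passing the synthetic benchmark therefore demonstrates that the
quantification and classification chain is correct and well-calibrated
under its own assumptions — not that it would match a commercial imaging
system's output on real, warped, saturated gels.

## Spot quantification numerics

`correct_background()` estimates background as the grayscale morphological
opening of the image with a disc of radius 25 px (ten times the spot sd:
spots are erased, smooth background survives). The opening is computed on
a lightly smoothed copy (Gaussian sd 1.5 px) because the morphological
minimum chases negative noise excursions; the residual median offset is
then subtracted and the result floored at zero. On a noiseless constant
background the output is exactly zero, and a single spot's corrected sum
recovers its volume within 2% (tested).

`detect_spots()` seeds spots at local maxima of a Gaussian-smoothed copy
(sd 2 px, matched to the spot scale) above a threshold expressed in
**median absolute deviations** of the smoothed image — a robust noise unit
that makes the threshold invariant under global gel scaling. Defaults
(seed threshold 5 MADs, mask threshold 2 MADs) were tuned once on the
packaged benchmark scene. Two numerical guards matter:

* an absolute threshold floor at 1e-6 of the dynamic range, because on a
  noiseless image the MAD is numerically zero and the smoothing
  convolution leaves float residue (~1e-14) that must not seed spots;
* maxima closer than `min_separation` (8 px) merge, keeping the higher
  peak — a deterministic, documented merge policy; tied plateau maxima
  collapse to one seed per connected component.

Pixels above the mask threshold are assigned to their nearest seed by
marker-based propagation, which guarantees **disjoint masks**. Centroids
are intensity-weighted within a 9 × 9 px window around each seed and
restricted to the seed's own region: a whole-region centroid would be
dragged off-center by residual noise pixels in large masks (this failure
mode was observed and is why the window exists). `integrate_iod()` then
sums corrected intensities over each mask and maps centroids to (pI, MW)
through the axis calibration.

## Sequence physicochemistry

Masses use standard monoisotopic and average residue masses shipped as a
CSV (`aa_mass_table()`), so tests and oracles read the same constants as
the implementation. `protein_mw()` reports the **average mass of the full
unprocessed chain, initiator methionine retained** — the convention behind
database-reported protein masses, and the one that reproduces 17.2 kDa for
canonical human myoglobin (the packaged `P02144.fasta`). Whether a mature
or canonical chain is intended varies by database entry, so only the
myoglobin value is asserted numerically.

`isoelectric_point()` solves net-charge(pH) = 0 under the
Henderson–Hasselbalch occupancy model by bisection on [0, 14] to 0.01 pH.
The charge curve is continuous and strictly decreasing, positive at pH 0
and negative at pH 14, so the root exists and is unique; bisection is
preferred over derivative methods because the curve is nearly flat between
pKa clusters. Two pKa conventions ship: EMBOSS (default) and Bjellqvist.
Neither reproduces every database-printed pI exactly — printed values stem
from heterogeneous tooling — so the pKa set is explicit configuration
rather than a hidden constant.

`tryptic_digest()` cleaves after K or R except before P; a C-terminal K/R
is not a site (nothing to cleave), and the initiator methionine is not
removed. Peptides carry 0..`max_missed` internal missed cleavages. Two
identities pin the implementation against a brute-force oracle: the
0-missed peptides concatenate to the input, and a sequence with *s*
internal sites yields exactly `s + 1 - m` peptides with *m* missed
cleavages. `digest_peptides()` expands modification variants: fixed
carbamidomethyl-C (+57.02146 Da, the standard alkylation in in-gel
digests) and up to one variable oxidation-M (+15.9949 Da) per peptide by
default — matching common search settings while bounding combinatorics.

## Fingerprint matching and identification criteria

`pmf_search()` digests every candidate, then assigns each observed peak to
at most one theoretical peptide within the mass tolerance (default 50 ppm,
the reflectron-MALDI convention, on monoisotopic masses). Assignment is
greedy by absolute error with ties broken toward the lower peptide mass,
and each theoretical peptide is consumed at most once — one-to-one
matching prevents a single peak from inflating the score through several
near-isobaric peptides. Candidates are ranked by a **MOWSE-style rarity
score**: each matched peptide contributes `log10(1/f)`, where `f` is the
relative frequency of theoretical peptides of the whole search collection
in that peptide's 100 Da mass bin. Matching a rare heavy peptide is worth
more than matching a ubiquitous light one. The score is repository-defined
and used **only for ranking**; it is not comparable to probabilistic
scores printed by commercial engines, whose internals (and 2012-era
databases) are out of scope. Both the matched count and the score are
provably non-decreasing in the tolerance, and the ranking is invariant
under relabeling of the candidate collection — both tested.

`apply_msms_criteria()` implements the stated tandem-MS acceptance rule:
identified if and only if at least 3 peptides have score strictly over 25
and expectation value strictly under 1. Published catalogs routinely
contain rows that fail such a rule (single-peptide identifications with
low scores accepted on other grounds); `check_identification_criteria()`
therefore **flags** non-conforming rows rather than guessing intent or
dropping them — the packaged 97-spot catalog keeps all rows, 62 of which
conform.

## Fixture conventions

The imaging-system export format behind published spot tables is never
specified, so the packaged fixtures use a deliberately plain dialect:
headered, comma-delimited, UTF-8, one row per spot per gel, with unset
numeric fields as empty cells (never 0 — a zero IOD is a real measurement
meaning an absent spot). Spot identifiers are opaque strings, because
matching software assigns arbitrary numeric labels. The fixture tables are
differential *subsets* of their gels, so their ppm values cannot sum to
1e6; the completeness invariant is therefore an opt-in check
(`validate_spot_table(x, complete = TRUE)`) enforced on `normalize_ppm()`
output, not at load. Likewise, whether published ppm totals were taken
over all detected or only matched spots is unknowable from the tables;
fixture ppm values are taken as given, and the simulator normalizes over
all detected spots.

## Problem sizes and determinism

The test suite and the acceptance script use: the full 300-spot benchmark
scene (one case and one control gel at 1000 × 1000 px) for end-to-end
recovery; a 40-spot noiseless scene for conservation; 1000 random
sequences for the digestion oracle; 100 random peptides for the pI grid
cross-check; and 50 residue-shuffled decoys per fixture protein for
self-identification. These sizes make every stochastic claim replayable in
seconds while keeping estimator variance far from the decision thresholds.
Every stochastic step takes an explicit integer seed — simulation without
a seed is deliberately impossible — and identical configuration plus seed
gives bit-identical truth tables and images.

## Known limitations

* Coordinate matching assumes gels are already in a common (pI, MW)
  frame; no image warping or registration is provided.
* The fold rule is a filter, not a test: with single pooled gels there is
  no replication, hence no error model and no multiple-testing control.
* The PMF score has no absolute calibration (no expectation values).
* Saturation, spatial background structure, and isoform trains below the
  detector's resolution are outside the simulator's defaults, so the
  benchmark does not certify behavior under those conditions.
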