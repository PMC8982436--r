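---
title: "embryoquant: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{embryoquant: models, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(embryoquant)
```

`embryoquant` quantifies single-molecule FISH data at the single-cell level
and ships a ground-truthed synthetic-embryo generator so that every
quantification stage can be validated without microscope data. This
vignette is the package's account of its science: the models, the
parameters that matter, the numerical choices, and what passing the test
suite does and does not establish about real data.

## The synthetic embryo

### Tissue geometry

The tissue is a two-dimensional strip: the analysis targets the surface
cell layer of the pre-gastrulation blastoderm, which is imaged as a single
focal plane of roughly one cell in depth, so planar geometry is the right
level of description. Cells are the Voronoi tessellation of a staggered
hexagonal lattice of centers, each displaced by a uniform-in-disk jitter of
up to `jitter * cell_pitch_px` pixels. The tessellation is computed
directly on the pixel raster (nearest center per pixel), which is exactly
the label image that segmentation and spot assignment consume downstream,
and each cell's polygon is the convex hull of its pixels (Voronoi cells are
convex, so nothing is lost). Rows index the dorsoventral (DV) axis; each
cell carries `dv = (row - 0.5) / n_rows`.

One geometric consequence worth stating: when a staggered lattice is
clipped to a rectangular strip, the boundary-column cells necessarily have
different areas from interior cells (up to about a quarter pitch of
overhang per side). Equal-area checks in the test suite therefore apply to
interior cells; boundary cells are flagged `border` and excluded from
neighbor statistics anyway.

### Expression domains

Gene activity is a function of `dv` alone: a gene is active in a cell iff
`dv` lies in the gene's half-open interval `[lo, hi)`. The configuration
requires the `rho` interval to nest inside the `mir9a` interval, mirroring
the observed nesting of the two expression domains; when the intervals
differ, a band of mir9a-only cells appears at the ventral edge. Half-open
intervals make the empty interval `[x, x)` genuinely empty and keep
boundary rows unambiguous.

### Transcription

Each allele runs an exact event-driven (Gillespie) simulation of the
telegraph model: OFF→ON at `k_on`, ON→OFF at `k_off`, transcription at
`k_tx` while ON, first-order decay at `k_deg`. The knockout genotype
divides `k_deg_wt` by `ko_deg_factor` (> 1 means slower decay). Promoters
start at the stationary ON probability and mRNA at zero; with the default
`t_end = 200` min and `k_deg = 0.05`/min the count distribution is
stationary to within `exp(-10)`. A transcription site is an allele that is
ON at `t_end`, with nascent load `1 + Poisson(nascent_mean - 1)`.

The telegraph model was chosen because the TS classes the analysis reports
(0 / 1 / 2+ active alleles) map directly onto allele ON/OFF states; no
kinetic model is fitted to data anywhere in the package. Chromosome
replication is represented as `n_alleles = 4` with independent alleles, off
by default — observed 3–4-TS cells are rare, and independence is the
simplest adequate assumption.

Cells outside the gene's domain fire leakily: constitutive Poisson
birth–death at `leak_frac * k_tx` (default 2%) per allele, with **no** TS.
Leak is modelled as instantaneous firing with no stable ON state, so
quiescent-looking cells with a handful of transcripts — the population the
low-expression filter exists for — never display a transcription site.
Because constitutive birth–death from an empty start is exactly Poisson,
these counts are drawn in closed form rather than simulated.

No kinetic rates are published for this system, so the defaults are
illustrative and documented as such: `k_on = 1`, `k_off = 0.5` (ON
probability 2/3), `k_tx = 1.875` mRNA/min, `k_deg_wt = 0.05`/min, giving a
wild-type stationary mean of 50 mRNAs/cell — the low end of the
50–150/cell order of magnitude such experiments report. The low end was
picked deliberately and jointly with the cell size (below) so that the
default rendering keeps single molecules optically countable; this joint
choice was made at design time, before the validation thresholds were
exercised, and is not revisited.

### Protein

Protein accumulates deterministically per cell by linear birth–death
sourced by the genotype's stationary mean mRNA, starting at the genotype's
onset time: `P(t) = k_translate * mbar / k_pdeg * (1 - exp(-k_pdeg (t -
t_on)))`. The knockout onset (default 60 min) precedes the wild-type onset
(default 300 min, i.e. after the simulated window) — so at times between
the onsets the knockout shows protein where the wild type shows none,
which is the premature-protein contrast the protein experiment measures.
Note the coupling: protein levels also inherit the mRNA contrast, so a
protein-pathway *null* requires both equal onsets and `ko_deg_factor = 1`.

### Rendering

Each mature mRNA becomes a Gaussian spot (sigma `psf_sigma_px`, peak
`spot_amp`) at a uniform-random position inside its cell; each active TS
becomes a spot inside the nucleus disk with peak `spot_amp * ts_amp_scale *
load`, rendered in **both** the exon and intron channels (nascent
transcripts still carry exons), while mature mRNA appears in the exon
channel only. The membrane channel is the rasterized cell boundaries; the
nuclei channel is filled disks at cell centers. All channels get a constant
camera background plus Gaussian read noise. Defaults `spot_amp = 40`,
`noise_sd = 5` give single-molecule SNR 8; `cell_pitch_px = 96` and
`psf_sigma_px = 1.1` correspond to ~10 µm cells at a ~0.1 µm pixel scale
(high-NA 100× imaging).

Two rendering options define the *well-separated* validation regime:
`margin_px` keeps mRNA spots away from cell boundaries (default 1 px) and
`min_sep_px` rejection-samples positions to a minimum pairwise distance
(default 0, i.e. fully uniform). Noiseless exact-recovery validation uses
`min_sep_px` ≈ 4–5 PSF sigma; at full uniform placement, spots can land
arbitrarily close and no detector can count them separately — the renderer
logs a warning whenever the expected spot spacing falls below 2 sigma.

### Reproducibility

One top-level seed drives everything; per-cell, per-embryo and per-stage
streams are derived deterministically (multiplicative fold of the seed and
the cell label/stage tag), so results are independent of iteration order
and of how many other cells are simulated, and identical configurations
reproduce bit-identical ground truth.

## Quantification

**Segmentation** re-implements marker-controlled watershed: nuclei are
smoothed, thresholded halfway between the background level and the nuclear
plateau (5th and 99.5th percentiles), and labelled to give one seed per
cell; seeds grow over the smoothed membrane channel with EBImage's
`propagate`, whose flooding resolves ties deterministically by label order.
A precomputed label image can bypass segmentation (ground-truth mode), which
is how detection errors are isolated from segmentation errors in the tests.

**Spot detection** is scale-normalized Laplacian-of-Gaussian filtering at
the PSF scale, local maxima (strict on half the neighborhood, non-strict on
the other half, so plateaus yield exactly one maximum), a robust threshold
of `threshold_factor` (default 5) times the median absolute deviation of
the filter response, and 3×3 response-weighted centroid refinement. An
absolute response floor (`min_response = 1e-3`) guards the noise-free case
where the MAD collapses to numerical ripple. A constant background shifts
the LoG response by exactly zero, and raising the threshold can only remove
detections — both properties are asserted in the tests. Detector
parameters are arguments, not constants, since no reference values exist
for the commercial software they replace.

**TS calling** is intron-channel-primary: an intron spot inside the nuclei
mask is a TS; it is greedily matched (nearest first) to an exon spot within
`coloc_radius_px` (default 2 PSF sigma — the same radius used to score
detection), and that exon spot is excluded from the mature-mRNA count.
Unmatched nuclear intron spots still count; extranuclear intron spots are
discarded and logged; per-cell TS counts cap at 4 with the excess logged.
Exon-channel brightness is deliberately **not** used as a TS criterion —
bright single mRNAs and dim TSs would both confound it, and the intron
channel already carries the physical information.

**Assignment** takes the label-image value at the rounded spot position
(pixel centers at integer coordinates, origin top-left, x = column); label
0 is unassigned. Count conservation — counted + TS-flagged + unassigned =
detected — holds by construction and is asserted.

## Statistics

* `filter_low_expression` drops cells with *fewer than* `min_count = 10`
  mRNAs; the boundary cell with exactly 10 survives.
* `group_by_ts` partitions into TS classes {0}, {1}, {2+}.
* `build_neighbor_graph`: two cells are neighbors iff their labels touch
  across a pixel edge (4-connectivity). When only centroids exist, the
  discrete Voronoi adjacency of the centroids is used instead (the raster
  equivalent of Delaunay adjacency), with edges longer than twice the
  median pruned.
* `local_dispersion` computes, per non-border focal cell, the cluster mean,
  sample variance, FF and CV. Three choices here were genuinely open and
  are exposed as arguments: the focal cell **is** included in its own
  cluster by default (larger, more stable clusters; `include_focal`
  switches it); the variance denominator is `n - 1` (clusters have ~7
  members, bias matters; switchable to `n`); clusters with fewer than 3
  members or zero mean are **missing**, never zero — 0/0 is not evidence
  of low variability. Border cells are excluded as focal cells but allowed
  as neighbors, which maximizes usable clusters without truncation bias.
* `compare_genotypes` is a two-sided Mann–Whitney rank-sum test — the
  defensible nonparametric default for count data when the original test
  is unnamed — with exact enumeration when both samples have ≤ 8 untied
  values and the tie-corrected, continuity-corrected normal approximation
  otherwise; it reports medians and the Hodges–Lehmann shift. The normal
  path tracks exact enumeration within a few percent for p ≥ 0.05; in the
  extreme tail (e.g. the fully separated n = 8 case, exact p = 2/12870)
  the normal tail is off by several fold, as any normal approximation is —
  the validation asserts the 10% agreement outside that tail and the exact
  value inside it.
* `adjusted_fluorescence` is the literal background formula
  `integrated_density − area × background_mean`; negative values are
  flagged, never clamped, and the Log10 reporting scale is applied only at
  presentation (non-positive values become missing there, and only there).
* `sample_measurement_areas` draws 5 non-overlapping square ROIs in each of
  the anterior/central/posterior thirds of the tissue along its long axis
  (15 per embryo), by rejection sampling with a deterministic seed.

## The end-to-end experiments

`run_experiment_counts` chains simulate → quantify → filter → TS classes →
dispersion → genotype comparison for `n_replicates` independent replicate
experiments of `n_embryos` embryos per genotype. The two "independent
experiments" of the original design are modelled as independent seed sets —
fluorophore identity has no computational analogue. By default the
replicated experiment runs at the count level (`imaging = FALSE`): the
replicated calibration experiments (power, type-I error) need hundreds of
simulated embryos, and their claims are about the statistics, not the
imaging; `imaging = TRUE` runs the full render → segment → detect path and
is validated separately.

`run_experiment_protein` renders a protein channel per embryo (per-cell
uniform intensity plus camera noise, with an off-tissue margin), samples 15
ROIs inside the *rho* expression band — measurement follows the expression
border, where the signal lives — and compares adjusted fluorescence per
time point at an early time (between the knockout and wild-type onsets) and
a late one (after both). The background mean is taken over the whole
off-tissue region: it is the limiting case of repeated manual background
measurements, and it keeps the per-embryo background error negligible
against ROI-level noise, so that pooled ROI comparisons stay calibrated
under the null. With few-box background estimation, the shared background
error would correlate ROIs within an embryo and inflate the pooled test —
a pseudo-replication effect worth remembering when applying the formula to
real images with manual background boxes.

## The seed-site scanner

Patterns derive from miRNA nt 1–8 only; DNA and RNA alphabets are both
accepted and canonicalized to RNA internally; `N` never matches. At each
UTR position at most one site is reported with precedence 8mer > 7mer-m8 >
7mer-A1, and a 7mer whose window lies inside a reported 8mer window is
suppressed as the same physical site (the strongest-site convention;
stated explicitly because no source pins it down). Positions are 0-based
site starts by default with `one_based` and `alias_7mer` flags, since the
published tables' conventions are not stated — both conventions are
available rather than guessed. Only the three canonical types are
implemented: no 6mers, no 3'-supplementary pairing, no context scoring.
The scanner is validated against an independent naive oracle that tests
every window against the pairing rules directly.

## Validation scope and problem sizes

The test suite and `scripts/acceptance.R` validate, among others: telegraph
moments against the closed forms at 600 cells (3 standard errors);
noiseless well-separated exact recovery for every cell; detection F1 ≥ 0.95
and TS-class accuracy ≥ 90% on a default-density SNR-8 embryo;
exact agreement of the dispersion map with a brute-force recomputation and
mean FF within [0.9, 1.1] on Poisson lattices; the exact FF/CV scale laws;
the exact rank-sum oracle 2/12870; ≥ 95% power at `ko_deg_factor = 1.5`
with ≥ 300 cells/arm and a ~5% type-I rate over 100 null replicates; and
seed-scanner equality with the naive oracle on one hundred random 10 kb
UTRs. Problem sizes (600-cell lattices for moment checks, 10×10 to 18×17
lattices for the replicated experiments, one full-size rendered embryo for
the imaging checks) were chosen as the smallest sizes at which the
Monte-Carlo tolerances above are meaningful.

What passing these tests does **not** show: the generator has no 3-D PSF,
no autofluorescence structure, no segmentation-relevant debris, no
cell-size gradients, no embryo-to-embryo biological variability (embryos
differ only by seed), and no spatial correlation of transcription beyond
the domain structure. Real-data performance of the detector and of the
dispersion statistics will be bounded by exactly these omissions, most of
all by optical crowding (the renderer's spacing warning is the relevant
guard) and by segmentation quality on imperfect membranes.
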