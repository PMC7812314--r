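---
title: "Identifying parent proteins of MALDI-IMS peptide masses with maldiMLP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying parent proteins of MALDI-IMS peptide masses with maldiMLP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldiMLP)
```

## The problem

MALDI imaging mass spectrometry (IMS) acquires a mass spectrum at every
pixel of a tissue section, mapping peptide signals in space — but a
MALDI-TOF peak at, say, m/z 763.5 with ±0.1 Da accuracy is anonymous: many
tryptic peptides share that mass, and MS1 alone cannot name the parent
protein. Shotgun LC-MS/MS of a serial section has the opposite problem:
deep, confident peptide and protein identifications with no spatial
information. `maldiMLP` implements a pipeline that combines the two for a
two-condition comparison (a control tissue, here labelled "WT", and a
diseased one, "AROM"): spatial segmentation of the IMS data,
co-localization-driven deisotoping, differential statistics on the shotgun
side, and a maximum-likelihood assignment of each imaged mass to its most
plausible parent protein.

## The model and its assumptions

The pipeline rests on two assumptions about MALDI-IMS of tryptic digests:

1. **Abundance bias.** Without chromatographic separation, abundant
   peptides dominate MALDI-TOF spectra, so an imaged mass more likely
   belongs to an abundant peptide than to a rare isobar.
2. **Condition restriction.** A spatial cluster that occurs
   predominantly in one condition's tissue is searched only against
   peptides classified to that condition.

Peptides are classified by the fold change of their mean intensities
across replicates,

$$\log_2\!FC \;=\; \log_2\frac{\mu^{\mathrm{disease}}}{\mu^{\mathrm{control}}},$$

computed on the linear scale after imputation: positive values classify a
peptide to the diseased condition, negative to the control, zero stays
unclassified. Differential confidence comes from an empirical-Bayes
moderated t-test: per-peptide pooled variances $s_g^2$ (on $d_g$ degrees
of freedom, log2 scale) are shrunk towards a prior $(d_0, s_0^2)$
estimated from all peptides by moment matching on log variances, giving

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  t = \frac{\bar x_{\mathrm{disease}} - \bar x_{\mathrm{control}}}
           {\tilde s_g\sqrt{1/n_1 + 1/n_2}},$$

with p-values on $d_0 + d_g$ degrees of freedom. With $d_0 = 0$ this is
exactly the ordinary pooled t-test (a tested identity); the data-driven
prior typically yields a much larger $d_0$ at $n = 3$ per group, which is
where the power gain comes from.

Each deisotoped IMS mass $m$ is matched against the protonated LC-MS
peptide masses ($MH^+ = M + 1.007276$) within a tolerance $\tau$
(default ±0.1 Da, matching the instrument accuracy), restricted to the
cluster's condition. Among the candidates, the winner maximizes the MLP
("most likely peptide") score

$$\mathrm{MLP} = \frac{\mu \cdot |\log_2\!FC|}{p},$$

the product of shotgun abundance and differential magnitude over the
moderated p-value. We use $|\log_2\!FC|$ rather than the signed value so
that control-side scores are positive and comparable within the
condition-restricted search space; a `signed = TRUE` mode exists for the
raw reading. The score is a ranking device, not a probability; its p
denominator is the unadjusted moderated p-value, floored at 1e-300 so the
ratio stays finite. Ties are broken deterministically (larger $\mu$, then
smaller mass error, then accession), and an assignment whose runner-up
scores within a factor 2 is flagged ambiguous for reporting honesty — the
flag never changes the winner.

## Spatial segmentation and discriminative masses

Per-pixel centroided spectra are TIC-normalized (each pixel scaled to the
dataset-mean total ion current, keeping intensities on the acquisition
scale), binned onto a uniform axis of half-open 0.1 Da bins
(`[lo, lo + w)`, boundary peaks joining the higher bin — the convention
must be fixed because an interval width alone does not), and clustered by
Ward linkage on Euclidean distances of square-root-transformed binned
intensities. Ward/Euclidean is the common imaging default; the square
root stabilizes the variance of intensity-like data. Above 5,000 pixels
the tree is built on a seeded random subsample and remaining pixels adopt
the label of their nearest sampled pixel — a memory bound for desk-scale
runs; smaller images are clustered exactly. The cluster count k is a user
choice: in real tissue the cut is judged against histology, which no
algorithm here automates. Likewise the cluster-to-condition declaration
is a user input mirroring that manual judgment (for synthetic runs,
`simulateAndRun()` derives it from the planted layout).

Cluster markers are found by a receiver-operating-characteristic screen:
for every bin, the AUC of in-cluster versus out-of-cluster pixel
intensities (ties counted one half — identical to the Mann-Whitney
statistic, which the tests verify by brute-force pair counting). The
orientation is one-sided: only cluster-enriched bins (AUC at or above the
0.7 default) are reported, sorted by AUC with ties broken by ascending
m/z for reproducibility.

## Deisotoping by spatial co-localization

Overlapping isotope envelopes are the classic obstacle to MS1
identification in tissue digests. The pipeline's answer is spatial: all
isotopes of one peptide share a spatial distribution, so envelopes that
overlap in m/z but belong to different structures separate cleanly in
image space. Cluster-wise, pooled peaks are aligned (sorted m/z split at
gaps > 0.05 Da; groups wider than 0.25 Da — about twice the spread a
single centroid cloud shows at ±0.1 Da accuracy — are further split at
the deepest kernel-density minimum, which resolves peak pairs whose
jitter tails would otherwise bridge the gap criterion). Envelopes are
grown greedily from each unconsumed peak ascending in m/z; a peak joins
as isotope k if

* it lies within ±0.15 Da of mono + k × 1.00235 Da (the averagine average
  spacing for singly charged peptides; MALDI ions are treated as 1+
  throughout),
* its intensity is within ±50% of the averagine-expected intensity for
  isotope k at the anchor mass (the tolerance needs a reference, which we
  take to be the averagine prediction; both the interpretation and the
  value are configurable), and
* its ion image correlates with the anchor's at Pearson r ≥ 0.7
  ("co-localized" is operationalized as image correlation; the threshold
  is exposed). Zero-variance images count as not co-localized.

Consumed peaks are never reused; singletons become their own entries, so
the peak-conservation identity |input peaks| = Σ members + |unassigned|
holds exactly. Aligned peaks supported by fewer than 5% of a cluster's
pixels are set aside as noise before envelope growth. A branch-and-bound
exhaustive mode maximizing explained peaks exists for small instances and
is used in tests to confirm the greedy solution. Isotope intensity
expectations use the averagine Poisson approximation (rate 5.359e-4 per
Da, the summed A+1 abundance of the averagine residue), validated in the
tests against a full elemental isotope convolution.

## The synthetic-data generator

No public raw IMS data accompany the study design this package targets,
so the generator is a first-class module producing ground-truthed inputs
with the structure the pipeline assumes: two conditions × 3 replicates;
per-peptide base abundance log-normal (log2 mean 25, sd 2) with replicate
sd 0.5; planted protein-level log2 fold changes as point masses at 0 and
±3 (half of the proteins differential by default);
missing-not-at-random values, logistic in log2 intensity around the 10%
detection-limit quantile (steepness 1.5 per log2 unit) — so low-abundance
peptides are missing more often, the regime the down-shifted-normal
imputation is built for; a 64×64 pixel grid partitioned into 3 Voronoi
regions (two control-like tubular analogues and one disease-like
interstitial analogue) at a nominal 25 μm pitch; tryptic-like peptides
with neutral masses in 600–3,200 Da rendered as 4-peak averagine
envelopes; centroid mass error N(0, 0.04 Da), so the ±0.1 Da tolerance
covers ≈2.5σ; per-pixel gain noise (log-sd 0.2), multiplicative peak
noise (log-sd 0.15) and two uniform baseline peaks per pixel.

Each planted peptide additionally carries a smooth spatial abundance
modulation within its region (a Gaussian bump of amplitude U(1.5, 3) log
units at a random center). This emulates the within-region structure of
real tissue — individual tubule cross-sections differ — and it is what
makes isotope images of one peptide genuinely co-localize (r ≈ 0.9 after
TIC normalization) while different peptides do not. The co-localization
criterion is sensitive to this: at pixel log-noise 0.25 and no spatial
structure, isotope-image correlations fall below 0.7 and envelopes
fragment, which is the honest behaviour of the method outside its
operating regime, not a bug. Optional near-isobaric decoys (within ±0.09
Da of a planted mass, same fold-change sign, lower abundance and smaller
effect) exercise the MLP ranking.

What the generator does **not** emulate: chimeric/overlapping envelopes
within one region with correlated images, real tryptic mass-defect
clustering (masses are uniform), charge states above 1+, in-source decay,
matrix clusters, and spatial intensity gradients from matrix deposition.
Passing tests therefore show the pipeline is correct under its stated
assumptions, not that those assumptions hold for any particular
instrument or tissue.

## Numerical and design choices

* Statistics are computed on log2 intensities; the fold-change means
  $\mu$ are linear-scale (back-transformed after imputation). The
  linear/log distinction is configurable where it matters (MLP's $\mu$ is
  linear by default).
* Imputation draws per sample column from
  N(mean − 1.8 sd, (0.3 sd)²) on the log2 scale, the conventional
  down-shift parameters; columns need ≥3 observed values, otherwise the
  error names the column.
* Benjamini-Hochberg is the only multiple-testing adjustment shipped.
* The protein presence rule (≥1 unique peptide observed in ≥2 of 3
  replicates of a condition) and the enrichment rule (>4-fold, strict, in
  ≥2 of 3 animals) are pure set functions. Because the two conditions are
  distinct individuals, the enrichment default compares each diseased
  animal against the control group mean; a replicate-index-paired variant
  is available.
* Binning conserves total intensity exactly (guard-band peaks within
  ±0.5 Da of the declared range are clamped into the edge bins).
* Degenerate inputs are defined, not fatal: zero-TIC pixels are flagged
  and left untouched; empty clusters deisotope to empty lists; candidate-
  free IMS masses are reported as unmatched rather than dropped.
* All randomness (subsampling, imputation, simulation) is seeded; a
  pipeline run writes a manifest (input MD5s, every parameter, the seed)
  sufficient to reproduce it byte-for-byte, and re-runs are tested to be
  byte-identical.

## Problem sizes used in the tests

The shipped test-suite and acceptance script run entirely on generated
data at sizes chosen to make the statistical checks sharp while staying
desk-scale: 10,000 null peptides for test calibration, 5,000 peptides ×
1,000 queries for the mass-search oracle, ~200 planted IMS peptides with
3 decoys each for MLP ranking, ~300 planted envelopes on a 64×64 grid for
deisotoping, ten seeds of the 3-region 64×64 layout for segmentation, and
full end-to-end runs at the generator defaults.

## Known limitations

* MS1-only assignment carries no false-discovery control; in the
  intended workflow, assignments are validated orthogonally (e.g.,
  immunohistochemistry), which software cannot replace.
* The method needs two conditions with differential signal: clusters
  similar in both conditions, or single-condition studies, give
  fold changes near zero and uninformative MLP scores.
* Co-localization deisotoping assumes isotope images correlate within a
  cluster; very noisy or spatially structureless data violate this.
* The imzML reader/writer covers the processed-mode centroided subset
  this pipeline produces and consumes, not the full standard.

## A minimal run

```{r eval = FALSE}
cfg <- simConfig(seed = 1)
res <- simulateAndRun(cfg, outDir = "run1")
res$metrics
```

For real data: `readIms()` + `readPeptideTable()`, then `runConfig()` and
`runAll()`, declaring `clusterConditions` after inspecting the
segmentation against histology.
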