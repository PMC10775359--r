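---
title: "Methods: synthetic domain-shift studies for six-direction FOD estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic domain-shift studies for six-direction FOD estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Learned fiber-orientation-distribution (FOD) estimators can reconstruct
white-matter FODs from as few as six diffusion directions, but they are
trained on one cohort and protocol.  When the test data come from a
different scanner, protocol, or developmental stage — newborn versus
baby brains being an extreme case — performance degrades.  Two families
of remedies exist at opposite ends of the pipeline: harmonize the
*signal* (Method of Moments, MoM) so the trained model sees data that
look like its training site, or adapt the *model* (fine-tuning, FT) with
a handful of labelled target subjects.

`fodshift` implements both remedies, together with everything needed to
study them quantitatively without access to the real cohorts: a
two-site, age-structured synthetic dMRI cohort generator with known
crossing-fiber ground truth, a spherical-harmonic (SH) substrate, a
diffusion-tensor module with the site-specific white-matter mask rules,
single-tissue constrained spherical deconvolution (CSD) for reference
FODs and split-half "gold standard" consistency, a trainable
six-direction FOD regressor, and the evaluation suite (agreement rate
AR, angular error AE, apparent-fiber-density error dAFD, stratified by
fiber count).

# Spherical-harmonic substrate

All FODs and signal fields use one fixed convention: the real,
antipodally symmetric SH basis restricted to even orders, columns
ordered by order `l` with `m` running from `-l` to `+l`
(MRtrix-compatible; negative `m` carries the sine terms).  Up to order
`lmax` there are `(lmax+1)(lmax+2)/2` coefficients: 6 at order 2 (the
six-direction input representation) and 45 at order 8 (the FOD
representation).  The basis is orthonormal over the sphere, which the
test suite verifies by quadrature on a dense grid.

Ground-truth FODs are band-limited apodized delta lobes.  A Watson-like
axial kernel `exp(kappa t^2)` (default `kappa = 12`, chosen so lobes
stay sharp at order 8 while the truncation ringing remains below ~2 % of
the peak) is expanded in Legendre polynomials and rotated to each fiber
direction by the addition theorem; fractions weight the lobes so the
sphere integral of the FOD equals the total fiber fraction.  Peaks of
these FODs recover the generating directions to well under a degree.

Peak extraction finds strict local maxima of the FOD on a 724-point
antipodally symmetric spherical grid (golden-angle spiral plus its
mirror), merges peaks closer than 15 degrees (keeping the larger, which
also removes each lobe's antipodal twin), discards peaks below 0.1 of
the largest amplitude, caps the count at 3, and refines surviving peaks
by batched tangent-plane gradient ascent (~0.1 degree accuracy).  A
constant FOD has no strict local maximum, so isotropic inputs yield
zero peaks by construction.  Ties are broken lexicographically so the
procedure is deterministic.

# The synthetic cohorts

Each subject phantom is a 24^3 voxel volume (nominal 1.5 mm isotropic)
whose central box (~18^3) is white matter.  The white-matter voxels are
split into contiguous regions holding exactly the configured shares of
1-, 2-, and 3-fiber voxels (default 30/50/20 %).

**Fiber geometry.**  The primary fiber direction is a smoothly varying
random unit-vector field (three low-frequency random-phase cosine
fields, normalized).  This matters: an earlier design that gave each
region a single random base direction per subject left the training
cohort covering only a handful of directions, and no regressor — not
even an oracle fit — could generalize to a new subject's directions.
Real anatomy shows essentially all orientations within every brain; the
smooth random field reproduces that while keeping neighbouring voxels
coherent (the property spatial models exploit).  Crossing fibers are
built in the primary fiber's orthogonal plane at an angle drawn
uniformly from [45, 90] degrees (with mild smooth spatial variation);
the third population is orthogonal to the first two.  Fractions are
equal within a voxel.

**Signal.**  A multi-tensor forward model: each population contributes
a prolate tensor (axial diffusivity fixed at 1.7e-3 mm^2/s) and
fiber-free voxels an isotropic compartment (1.2e-3 mm^2/s).  Age enters
through a single arctan maturation curve `FA(t) = a atan(b (t - t0)) + d`
(defaults a = 0.06, b = 0.35 /month, t0 = 2 months, d = 0.22, i.e. FA
rising from ~0.16 in preterm-equivalent ages to a plateau of ~0.31 by
age three), and the radial diffusivity is solved in closed form so a
single-fiber voxel's tensor FA equals the curve.  Newborn-like ages are
handled as postnatal months (post-menstrual weeks convert by
subtracting 40 weeks and dividing by 4.345), so the neonatal range is
roughly [-2.5, 1] months.

**Site effects.**  Each site applies a smooth multiplicative gain field
and a smooth additive offset field (deterministic functions of the site
name), modulated per subject by ~5 % smooth jitter (positioning and
coil-load variation), followed by Rician noise
`sqrt((S + e1)^2 + e2^2)` with `sigma = rician_sigma * S0`.  The
magnitudes are free study-design parameters — the source publication
reports no quantitative intensity model of the two scanners — and were
chosen to produce a clear but recoverable cross-site penalty.  Because
the six-direction pipeline normalizes by the voxel's mean b0, a pure
gain field cancels exactly, and the component that actually shifts the
input contrast is the additive baseline, which compresses the
normalized signal toward 1.  Two further facts shaped the defaults.
First, the target cohort is older and hence higher-FA, so on identical
scanners cross-testing would be *easier* than self-testing; the site
effect must overcome that, and a strong additive baseline (~45 % of b0,
with a 0.75–1.25 gain field) is what produces the marked single-fiber
penalty that real cross-site transfers show (real shifts also involve
sequence and distortion differences not modelled here).  Second, both
sites share the noise level (sigma 0.02): a noise-dominated shift sends
fine-tuning toward MSE-optimal *oversmoothing*, which degrades peak
metrics — a trade-off worth knowing about, but not the regime the
cross-site study design emulates, where adaptation is known to help.

**Protocols.**  Desk-scale analogues of the two acquisition schemes:
`dhcp_scheme()` with shells b = {0, 400, 1000, 2600} s/mm^2
(2/20/48/48 measurements) and `bcp_scheme()` with
b = {0, 500, ..., 3000} (2 + 6 x 16).  Both keep >= 90
diffusion-weighted directions so split-half CSD stays determined at
order 8.  Schemes read and write FSL-style `bvals`/`bvecs` text files;
volumes are NIfTI via RNifti.

# Tensor module and mask rules

The tensor is fitted by log-linear least squares on the b <= 1000
shells (Gaussian-regime convention).  FA/MD come from closed-form
eigenvalues.  The two white-matter mask rules use strict inequalities
exactly as printed for the two cohorts: the neonatal rule is
`tissue OR FA > 0.3`; the baby rule is
`tissue OR FA > 0.4 OR (FA > 0.15 AND MD > 0.0011 mm^2/s)`.
The arctan growth fit is nonlinear least squares (`minpack.lm::nlsLM`)
with multi-start initialization over growth rates and inflection ages;
a fitted curve whose total swing over the observed age range is below
1e-3 is flagged degenerate (flat data).

# Reference FODs: single-tissue CSD and split-half consistency

The phantoms are white-matter-only, so a single-compartment
deconvolution plays the role that a multi-shell multi-tissue variant
plays on real data.  The response function is estimated from known
single-fiber voxels (reorient to +z by the tensor's principal
eigenvector, fit even zonal SH per shell, average).  The deconvolution
solves a penalized least-squares problem per voxel with an iterative
active set: grid points of a 300-point symmetric constraint grid where
the current FOD falls below 0.1 x the initial mean amplitude are
penalized (weight scaled to the data term) until the active set
stabilizes.  A small relative ridge (1e-4 of the mean normal-matrix
diagonal) prevents near-null deconvolution modes — orders where the
response carries almost no energy — from amplifying sampling residuals.

Two numeric realities are worth stating plainly.  First, a sharp
band-limited lobe cannot be non-negative everywhere: the order-8
apodized delta itself rings at about -2 % of its peak, so the
soft-constrained FOD retains ringing at that scale (voxels beyond -5 %
are flagged and fall back to isotropic).  Second, a single-compartment
model cannot represent a free-water decay exactly, so a pure-water
voxel leaks a few percent of energy into higher orders; an isotropic
FOD convolved with the response is recovered with < 1 % leakage.

Gold-standard (GS) consistency splits the diffusion-weighted
measurements into two interleaved halves (sorted by shell then index;
b0s shared), reconstructs each half with CSD, and evaluates the two
reconstructions against each other with the standard metric suite —
an upper bound on achievable agreement.  Without noise the two halves
agree perfectly on peak count (AR 100 %, AE < 1 degree); agreement
decays monotonically as noise grows.

# The six-direction estimator

`select_six_directions()` picks the six measurements of the b = 1000
s/mm^2 shell (the shell both protocols share) minimizing the condition
number of the order-2 SH design matrix — exhaustively when
`choose(n, 6) <= 50000`, otherwise by greedy seeding plus
best-improvement exchange.  `prepare_input()` divides the six signals
by the voxelwise mean b0 and projects them onto order-2 SH by the exact
6 x 6 solve.

The regressor is a small fully-convolutional network: one 3x3x3 spatial
layer over the 6-coefficient input field (162 features), two hidden
layers of 96 ReLU units (1x1x1), and a 45-coefficient linear output —
trained with Adam, decoupled weight decay 1e-3, dropout 0.1, and a
masked MSE loss over white-matter voxels of sampled patches (12^3,
>= 30 % WM coverage; non-overlapping cover for training, half-stride
overlap-averaged windows for inference).  The spatial context is not an
optimization: with six noisy measurements of a low-FA neonatal voxel,
the per-voxel direction information is at the noise floor, and no
voxelwise map outperforms predicting the cohort mean (we verified this
with linear and quadratic oracle fits).  Pooling a coherent
neighbourhood is what makes six-direction estimation work, which is the
same reason the full-scale backbones use large fields of view.

Model selection keeps the epoch with the lowest validation MSE.
Fine-tuning continues from those weights at a reduced learning rate and
small batches; with n >= 2 target subjects the last subject is held out
for validation-based selection, with one subject the final epoch is
kept.  One master seed fans out deterministically (via a labelled
seed-derivation function) to cohort generation, noise, initialization,
batch order and dropout, so every run is exactly reproducible.

Desk-scale hyperparameter defaults (learning rates 2e-3 / 2e-4, 80
training and 50 fine-tuning epochs, batches of 4 training / 2
fine-tuning patches, width 96) are sized to this small network and 24^3 phantoms;
the full-scale study protocol (5e-5 / 5e-6, batches of 35 / 10, 1000 /
100 epochs, 16^3 patches) is documented in `estimator_config()` and can
be requested explicitly.  With the full-scale rates the desk model
performs a few hundred Adam steps and never leaves initialization —
learning rates do not transfer across four orders of magnitude of
model/data scale.

# Method of Moments harmonization

For each subject the per-voxel mean and population (1/n) variance of
the six selected-direction signals are computed; voxelwise medians
across subjects give the site's moment maps, smoothed with a Gaussian
filter (sigma 1 voxel; normalized convolution, so constants are
preserved).  The harmonization field is the voxelwise linear map
`alpha = sqrt(var_ref / max(var_src, floor))`,
`beta = mean_ref - alpha * mean_src`, with alpha clipped to [0.1, 10]
and floored voxels counted.  Because the mean and variance over six
well-spread directions are approximately rotation invariant, the maps
transfer across subjects whose fiber geometry differs — the property
that makes signal-moment harmonization work at all.

Two conventions are deliberate: one (alpha, beta) pair per voxel is
shared by all six directions (a monotone map, so the within-voxel
signal ranking is preserved exactly), and the map is applied to the six
selected directions *and* the b0s used for normalization.  The second
matters: the shift is multiplicative-plus-additive in the raw signal,
and harmonizing the six directions while normalizing by an
un-harmonized b0 would reintroduce the gain.  For an exactly affine
site effect the map recovers the source-site signal exactly (the
worked example in the tests: source moments (2, 4) mapped to reference
(3, 1) give alpha = 0.5, beta = 2).

Harmonization direction follows the study design: target-site data is
mapped toward the *training* site, and the originally trained model
evaluates the harmonized data; fine-tuned models evaluate the original
data.  MoM arms never touch model parameters, FT arms never touch test
signals.

# Study designs

`run_inter_site()` reproduces the cross-site design at desk scale: 20
subjects per site split 14/3/3 (train/validation/test, the 70/15/15
ratio), a baseline model trained on the source site, then per transfer
direction: self-test (upper bound), raw cross-test (lower bound),
MoM(n) and FT(n) for n in {1, 2, 5, 10} target training subjects
(nested subsets of one seeded shuffle, so the 1-subject set is
contained in the 2-subject set, reducing variance across arms), and the
from-scratch ablation trained only on 10 target subjects.  Leakage is
asserted programmatically: test-subject identifiers never appear in any
training, fine-tuning or moment-estimation set.

`run_intra_site()` mirrors the age-group design: young and old cohorts
(neonatal-equivalent [-3.1, -1.2] vs [0, 1] months for the newborn-like
site; [0.5, 11] vs [20, 36] months for the baby-like site), 12 subjects
per group split 8/2/2 (the 40/10/10 ratio), all four train-test
combinations, and cross-age fine-tuning with 5 target-group subjects.
`run_gs_consistency()` adds the split-half CSD row.  Reports serialize
to a results-table-like CSV and a JSON with full provenance (master
seed, configuration hash, subject identifiers per split); 3-fiber
strata are computed but flagged for exclusion from headline
comparisons, reflecting how unreliable 3-fiber depictions are at these
measurement counts.

Problem sizes throughout (24^3 volumes, 20-subject cohorts, 80/50
epochs, one transfer direction per acceptance run) were chosen so the
complete inter-site study runs in minutes on a single CPU while
preserving the design's split ratios and arm structure.

# What passing tests do and do not show

The phantoms share a template grid (no registration), contain
white-matter-only anatomy (no GM/CSF partial volume), use a single
diffusivity model per age, and their site effects are smooth affine
fields plus Rician noise.  Consequently the test suite demonstrates the
*mechanics* and the *qualitative behaviour* of the methods — moment
alignment is exact for affine shifts, fine-tuning recovers cross-site
loss with few subjects, gold-standard consistency bounds the
achievable agreement — but absolute metric values are not comparable
to real-cohort results, which involve registration error, multi-tissue
signal, motion, and far larger models and datasets.  The generator
does not emulate EPI distortion, subject motion, or anatomy, and the
regressor is deliberately small; claims about real data require the
real pipelines.

# Known limitations

* Multi-fiber (2/3-F) agreement rates are low for the desk-scale
  regressor, as they are for the full-scale systems this emulates; the
  package reports them but headline comparisons use single-fiber rates.
* The CSD reference is single-tissue; free-water-like signal leaks a
  few percent of energy into higher orders.
* Peak metrics depend on the extraction parameters (grid density,
  separation, relative threshold); all arms of any comparison use one
  shared parameter set, which the evaluation functions enforce by
  construction.
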