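---
title: "Models and methods behind the image3c pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the image3c pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(image3c)
```

image3c analyses imaging flow cytometry experiments without antibodies: it
quantifies each cell from its multi-channel image, discovers cell
populations de novo by density clustering, tests whether population
abundances shift between conditions, and trains a convolutional classifier
on the discovered clusters so that later experiments can be mapped onto the
same classes. This vignette explains the models, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and does
not emulate.

## The synthetic-data generator

No instrument data ships with the package; every stage is exercised on
synthetic events whose ground truth is known. A `population_spec()` fixes a
morphology (cell diameter mean and SD in pixels, nuclear/cell area ratio,
granularity) and per-channel fluorescence intensities; a `sample_spec()`
mixes populations at stated frequencies and adds the nuisance structure the
pipeline must correct: per-channel multiplicative intensity drift, doublets
(two overlapping cells), debris (sub-threshold fragments without nuclear
signal), and optional spillover mixing between channels.

Cells are elliptical, with three deliberate touches of realism:

* **Half-normal eccentricity.** Most singlets are nearly round; elongation
  is `1 + |N(0, 0.05)|`. A bounded-uniform elongation produces a plateau
  with cliff edges in the aspect-ratio distribution, and density-based
  clustering faithfully reports such artifacts as modes.
* **Membrane undulation.** The outline carries four low-order radial
  harmonics (`N(0, 0.02)` amplitudes). Perfectly crisp analytic ellipses
  alias moment-based shape features into a comb of discrete values on a
  pixel raster; real outlines do not.
* **Realistic pixel scale.** At the magnification of typical imaging flow
  cytometers the smallest nucleated cells span roughly 12 px; far smaller
  objects quantise shape features so coarsely that any density method
  splits them into raster classes rather than biology.

The nuclear channel deposits a fixed total intensity per genome copy
(doubled for 4N events), so DNA-content histograms show the 2N/4N
bimodality that landmark normalization relies on. Side scatter is zero
outside cells and, inside, proportional to the population's granularity
with multiplicative log-normal speckle whose amplitude also grows with
granularity — the feature module's granularity spectrum must respond
monotonically to it. Doublets are homotypic (two draws of the same
population), mirroring the homotypic aggregation seen in real suspensions
and giving doublets their characteristic elongation; the two cells overlap
by 30–60% of one cell's area. Images can be quantised to 16-bit integers
(`quantize = TRUE`) to mirror instrument TIFF exports; all float
computations happen before quantisation.

The default recovery fixture (`demo_populations()`) contains four
well-separated populations: small blast-like cells with high
nuclear/cytoplasmic ratio, large granular, large agranular, and an
intermediate population bright on an extra fluorescence channel. It is
deliberately non-cycling (`dna_4n = 0`): a 4N subpopulation is a genuinely
distinct density mode — at fixture scale it holds hundreds of events, more
than any neighbourhood size on the default k grid — so a "four clusters"
ground truth would be ill-posed with cycling cells. The 2N/4N machinery is
exercised where it is the point, in the DNA-normalization tests.

**What passing on this generator shows, and what it does not.** The
generator emulates the statistical structure the pipeline assumes —
population mixtures, drift, spillover, contamination — but not
photorealistic optics: there is no point-spread function, no flow-speed
artifact, no illumination gradient, and texture is independent per pixel.
Success here demonstrates the algorithms are correct and calibrated, not
that segmentation will be equally accurate on any instrument's images.

## Feature extraction

IDEAS-style feature panels are proprietary, so the package computes a
documented open analog of the named feature families. Per event:

* **Geometry** on cell and nucleus masks: area (pixel count), a
  two-direction Crofton perimeter (`pi/4` times the axis-aligned boundary
  crossings, asymptotically exact for smooth convex shapes), equivalent
  circle diameter, major/minor axes from mask moments (an ellipse's axis is
  four times the square root of the corresponding eigenvalue of the pixel
  covariance), aspect ratio (minor/major), circularity (`4*pi*A/P^2`), and
  a shape ratio (diameter/major) measuring compactness along the
  elongation; plus the nuclear/cell area ratio.
* **Intensity** per channel within the cell mask: integrated, mean,
  maximum pixel, RMS contrast (the in-mask standard deviation), and a
  brightfield gradient-RMS focus proxy (central differences).
* **Texture**: the granularity spectrum `G(s)`, `s` in {1, 2, 3} px — the
  fraction of in-mask integrated intensity removed by a grayscale
  morphological opening of size `s`, computed on brightfield and side
  scatter. The structuring elements are squares of half-width `s`: square
  families are closed under dilation, which guarantees the spectrum is
  monotone in `s` on a discrete raster; discrete "disc" families are not,
  and can violate monotonicity by a pixel's worth of intensity.

Segmentation is parameter-light: the cell mask is the largest connected
component of an Otsu threshold on the brightfield gradient magnitude,
closed with a radius-3 disc, hole-filled, and eroded by one pixel (the
gradient ridge straddles the true edge, so the filled region is one pixel
too generous — measured on the generator, the erosion lifts the median
mask IoU from 0.80 to 0.89). Masks larger than half the frame or smaller
than 5 px are flagged unsegmentable. The nucleus is an Otsu split of the
DNA signal within the cell, with a guard: when the nucleus fills the cell
there is no cytoplasm class and Otsu splits the nuclear texture instead,
so if the lower class is not clearly dimmer (mean below 0.3 of the upper),
the threshold falls back to a near-zero cytoplasm floor (0.15 of the 90th
percentile).

Background subtraction removes the per-channel median of the pixels
outside the cell mask. Brightfield needs one twist: its object is darker
than its background, and subtract-and-clamp would erase the cell entirely;
channels whose in-object median lies below the background are therefore
inverted into background-relative absorbance, which preserves morphology
and still zeroes the background.

**Gating** retains focused, nucleated singlets, in that order. The focus
and nucleated thresholds are automatic but engage only when a distinct
low-signal mode exists (a KDE valley whose lower mode sits below 0.4 of
the top mode's location): an unconditional Otsu split would cut an
all-focused or debris-free sample in half, and a 2N peak must never be
mistaken for a debris band. The singlet gate is a polygon in the area vs
aspect-ratio plane; the default box keeps aspect ratios of at least 0.8
(singlets are near-round; overlapped doublets elongate well below that)
with a generous area cap against gross aggregates. Any additional manual
gates (for example erythrocyte out-gating, whose exact shape is an
instrument- and organism-specific choice) are user-supplied polygons in
any feature pair. Finally, retained events must have a complete feature
row — the event table contract is "no NaN after gating".

## Preprocessing

* **Redundancy trimming.** Spearman correlations between all feature pairs
  on one representative sample (the largest, by default); walking pairs in
  panel order, the later-listed member of any pair at |rho| ≥ 0.85 is
  dropped. Keeping the earlier-listed feature is an arbitrary but
  deterministic rule; the surviving set provably contains no pair at or
  above the threshold, which the tests verify against an exhaustive
  re-scanning oracle.
* **Replicate QC.** Each sample is summarised by its per-feature mean
  vector and correlated (Spearman) against the element-wise median of the
  other samples — a leave-one-out reference that one bad sample cannot
  poison. Samples below 0.85 are dropped. Whether the original analysis
  used Pearson or Spearman here is not recorded; Spearman is chosen for
  consistency with trimming and robustness to feature scales.
* **Logicle transform.** Fluorescence intensity features go through the
  standard biexponential (logicle) scale, linear around zero and
  logarithmic above. The biexponential coefficients are derived from
  (T, M, W, A) exactly as in the standard parameterisation; the forward
  transform inverts the biexponential by bracketed bisection (60 halvings,
  beating the 1e-10 tolerance), which is slower than Newton but
  unconditionally monotone and robust. Parameters are auto-estimated per
  feature: T is the observed maximum, M = 4.5 decades, W from the 5th
  percentile of negative values (0.5 when there are none), A = 0. Output
  is on the 0..1 scale of M decades, so the high-intensity slope is 1/M
  per decade.
* **DNA landmark normalization.** Per sample, a Gaussian KDE (Silverman's
  bandwidth) of the transformed DNA intensity; the two highest-prominence
  modes, in ascending order, are the 2N and 4N landmarks. The per-landmark
  median across samples defines the base positions, and each sample is
  warped by a monotone piecewise-linear map through its landmarks with
  identity-slope extrapolation outside. This shift-and-stretch warp is a
  simpler analog of Gaussian-weighted landmark shifting; it is monotone by
  construction, so within-sample event order (and hence every Spearman
  correlation) is exactly preserved. Samples with fewer landmarks than
  requested are aligned on the landmarks found and flagged; samples with
  none are left unwarped.
* **Scaling.** Every surviving feature is divided by its pooled standard
  deviation (means untouched), equalising feature contributions to the
  Euclidean metric used downstream.

## De novo clustering

Density is estimated by the standard k-nearest-neighbour estimator,
`f(x) = k / (n * V_d * r_k(x)^d)`; since k, n and d are constant within a
run, the density ordering is exactly the (reversed) ordering of the k-th
neighbour distances, and all mode seeking is done on `r_k`, avoiding
overflow in high dimension. Each event points to the densest point among
its k nearest neighbours (itself included; ties broken by index, making
the pointer graph acyclic and the result deterministic), and clusters are
the basins of the resulting ascent.

Pure ascent has a known failure: the kNN density estimate fluctuates with
relative noise of order `1/sqrt(k)`, so a single large cluster fragments
into several spurious modes whenever k is much smaller than the cluster's
population. The package therefore consolidates modes after the ascent:
each mode considers its nearest strictly denser mode and merges into it
unless the density along the straight segment between them dips below
**half** of the weaker mode's density (probed at 10 interior points;
expressed on the radius scale the factor of two becomes `2^(1/d)`). Any
two empirical local maxima have some dip between them, so a threshold-free
valley test would never merge anything; halving is the package's
definition of a genuine valley. The margin between the merge criterion and
the estimator noise grows like `sqrt(k)`, so the test is stable across
dimensions. The original mode-seeking method merges modes with a
Mahalanobis-gated segment test; the half-density rule is this package's
simpler, threshold-light analog.

k is selected by clustering over a grid (default 5 to 150 in steps of 5)
and taking the elbow of the (k, number of clusters) curve: the point of
maximum distance from the chord joining the curve's endpoints in log-log
space. The curve is always returned — confirming that the chosen k does
not over- or under-cluster remains the analyst's job, as it is in
interactive use.

The force-directed layout subsamples up to a cap per cluster (default
200), builds the union-symmetrised kNN graph with weights `1/(1+d)`, and
runs seeded Fruchterman-Reingold; disconnected graphs are laid out
component by component, side by side. Coordinates and the graph (graphML)
are exportable, along with the master per-event table, per-cluster feature
means, and the clusters-by-samples count matrix.

## Differential abundance

Counts per cluster and sample are modelled as negative binomial with
variance `mu + phi * mu^2` and log-total offsets. A single common
dispersion is shared by all clusters — the simplest defensible choice when
nothing is known about per-cluster dispersions — and is estimated by
maximising the Cox-Reid adjusted profile likelihood (the adjustment,
`-0.5 * log` Fisher information per profiled mean, corrects the downward
bias of plain profile ML; without it the type-I error of the downstream
test runs visibly hot). The search is bounded on 0..10 with tolerance
1e-6.

Per cluster, the two-condition model `log mu = log(total) + b0 + b1 *
condition` is fitted by Fisher scoring (with a one-parameter-per-group
design this is exactly IRLS on the log link), and `b1 = 0` is tested by
likelihood ratio against chi-square with 1 degree of freedom — preferred
over Wald for the 4–8 replicates typical of these designs. Log fold
changes are reported in log2 units; Benjamini-Hochberg FDR is applied
across clusters; all-zero clusters are flagged with p = 1. Multi-group
comparisons of relative abundances use a classical one-way ANOVA per
cluster with the same FDR correction. A volcano table/plot (logFC vs
-log10 FDR, capped) is the standard export.

## The image classifier

Images are centre-cropped or symmetrically zero-padded to 32 x 32 (the
extra pixel goes on the trailing side when the difference is odd) and
stacked as brightfield, side scatter, DNA. The network is a compact
DenseNet-style model: three dense blocks, each with three 3 x 3
same-padding convolutions whose inputs are the concatenation of the block
input and all previous layer outputs, each followed by a leaky ReLU
(slope 0.1); each block ends in a 3 x 3 stride-2 transition convolution
halving the spatial size, 32 -> 16 -> 8 -> 4. The transition widths are
(22, 44, 87); the final 4 x 4 x 87 maps flatten to a 1392-vector fully
connected to the class logits. The final width of 87 (hence the 1392
flatten) is part of the architecture contract and asserted at build time;
the growth rate (default 8) and the first two transition widths are
implementation choices exposed in `classifier_config()`.

Training minimises softmax cross-entropy plus an L2 weight penalty
(1e-4) with Adam. The learning rate starts at 0.001 and decays by 1% per
100-iteration step; a decay of 1% per *iteration* would vanish within a
few thousand iterations, so the step is interpreted as the logging
interval, and a constant rate (for example 0.0006) is available by
setting the decay to 1. Batches of 256 are sampled with replacement for
25,000 iterations by default; loss and accuracy on the training batch and
on a held-out test split are logged every 100 iterations, and the model
warns when the test loss ends more than 20% above its minimum while the
training loss kept falling — the memorisation signature. Data are split
80/10/10 (train/test/validate), stratified by class; inputs are scaled
per channel by the 99.5th percentile of the training set, stored with the
model. Evaluation reports per-class precision/recall/f1, support-weighted
f1, the confusion matrix, and each event's true-match probability (the
softmax mass on its original cluster). Inference returns the full
probability vector per event (summing to 1 within 1e-6) and a reliability
report: the fraction of events whose maximum probability exceeds 0.5,
with a warning when that fraction is low. Clusters with overlapping
morphology can be merged into training classes beforehand
(`merge_classes()`), e.g. nine de novo clusters with two merges giving
seven classes.

The forward/backward pass is implemented in single-precision compiled
code (feature maps in a zero-halo layout so a stride-1 convolution is
nine shifted SGEMM calls). Gradients are verified in the tests against
finite differences of an independent double-precision R forward pass.
Training is seed-deterministic on one platform with single-threaded BLAS;
bit-identity across platforms is not promised.

## Problem sizes used by the tests and the acceptance script

The package's own checks run at desk scale, chosen to exercise each claim
meaningfully: cluster recovery on 4 samples x 4,000 events through the
full image pipeline (the test suite) and 4 x 1,200 in the acceptance
script; null calibration of the count test over 2,000 simulated designs
(600 in the script) of 20 clusters x 12 samples at 10,000 expected events
per sample; classifier training scaled down to 2,000 iterations at batch
64 on the four-population fixture (800 iterations in the script). The
vignette states these as the package's study sizes; all are set in one
place in the tests and script and scale linearly if changed.

## Known limitations

* Segmentation is tuned for single roundish cells on a clean background;
  it has no notion of touching-cell splitting beyond the singlet gate.
* The spillover model is linear and global; no per-event autofluorescence.
* A single common NB dispersion can under-fit datasets where a few
  clusters are far noisier than the rest; per-cluster (tagwise) shrinkage
  is out of scope.
* The elbow rule picks one k; multi-resolution structure is visible only
  by inspecting the returned curve.
* FCS export writes float LIST-mode FCS 3.1 with linear scaling only —
  enough for interoperability, not a general FCS toolkit.
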