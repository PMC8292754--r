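---
title: "Re-identifying individuals from spot constellations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-identifying individuals from spot constellations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotmatch)
```

Many fish (and other animals) carry stable natural spot markings. If the
spots on a flank can be extracted from a photograph and matched against
earlier photographs, individuals can be re-identified without handling or
tagging — and, in tagged populations, lost tags can be detected and
capture histories repaired before demographic models are fitted. spotmatch
implements that pipeline end to end: segmentation of the body and spots,
normalization of the resulting spot constellation, two triangle-based
point-pattern matchers, a chronological matching database with open-set
decisions, capture-history correction, and a Bayesian Cormack–Jolly–Seber
(CJS) survival model. A synthetic-data module generates every input the
pipeline consumes, so the whole chain is testable at desk scale.

This vignette explains the models, their assumptions, the tunable
parameters, and the design choices made where the design was genuinely
open. Nothing here states an empirical result that the package's tests or
`scripts/acceptance.R` do not themselves compute.

## 1. The synthetic data and what it emulates

The generator renders a dark, egg-shaped body (blunt head, thin caudal
tail) with dark circular spots on a light background:

```{r render, eval = FALSE}
r <- render_fish_image(fish_spec(rng_seed = 1))
str(r, max.level = 1)
```

Defaults: 1882×830 px frame; body semi-axes 0.33·width and 0.23·height;
grey levels 210 (background), 60 (body), 20 (spots), Gaussian pixel noise
sd 4; 30 spots with radii 14–22 px and a minimum centre separation of
twice the maximum radius so spots never merge. The frame width anchors
the spot-blur rule of the classical segmenter (Section 2) at its
calibration point, and the spot radii are chosen so that blur scale and
spot scale are in the same regime as full-resolution field photographs.
Optional distractors emulate what degrades classical segmentation in the
field: a dark ruler bar with bright ticks, dark debris blobs, and a
lateral shadow gradient.

Re-captures are emulated by `perturb_constellation()`: a similarity
transform (rotation, growth scale, translation) about the constellation
centroid, isotropic positional jitter, spot turnover (a deterministic
`floor(n · drop_fraction)` spots removed uniformly at random) and new
spots without correspondence. `perturb_recapture()` bundles the default
re-capture conditions: rotation uniform in ±10°, growth scale uniform in
(1.0, 1.3), jitter sd 0.005 fish lengths, and 10% turnover in both
directions. Spot turnover rates between captures are not quantified in
the literature for this system; the 10% default is a deliberately
challenging free parameter, not an estimate.

Capture histories are simulated forward from the CJS process itself
(Section 6), with first captures spread uniformly over occasions
1..T−1, and tag loss injected per re-capture event: with the stated
probability the observed id switches to a fresh, never-seen id from that
event onward, exactly the fragmentation a lost passive tag causes. True
ids are carried along as hidden ground truth.

What the generator does **not** emulate: lighting and colour variation,
fin occlusion, parr-marked juveniles, non-rigid body bending, and
photograph-to-photograph segmentation disagreement beyond what the
baseline segmenter itself produces. Tests that pass on these synthetics
therefore validate the algorithmic chain, not field performance.

## 2. Classical baseline segmentation

The body mask is extracted by greyscale conversion, a heavy Gaussian
blur, a fixed threshold (grey level 80), connected-component labelling,
selection of the component whose centroid is nearest the image centre
(ties broken by area), and a disc erosion. The spot mask is extracted
inside the body mask by a second Gaussian blur whose standard deviation
follows the resolution rule

σ₂(L) = ((L − 1882)/440)·2 + 19,

with L the larger image dimension, followed by adaptive mean
thresholding (a pixel is a candidate when it is at least 5 grey levels
darker than its local block mean; block size 4σ₂ forced odd) and a shape
filter keeping regions that are roughly circular (4πA/P² ≥ 0.5) and
medium-sized (between 10⁻⁵ and 5·10⁻³ of the body area).

Free parameters the field does not pin down, with the package defaults:
the Gaussian is interpreted as a kernel standard deviation; the erosion
element is a disc of radius 5 px at full resolution, scaled with image
width; the adaptive offset is 5 grey levels; σ₂ is clamped below at a
configurable minimum (3 px). The published body blur (σ₁ = 125 px at
5184 px width) is tuned for field photographs with debris and background
texture; on clean synthetic renders a much lighter blur (0.008·width,
`baseline_config_synthetic()`) avoids shrinking the thresholded mask and
is the calibration used in all synthetic evaluations.

## 3. Learned segmentation

The learned segmenter is a U-Net-style encoder–decoder: per encoder
level one 3×3 convolution + ReLU (+ dropout) and 2×2 max pooling; a
bottleneck convolution; a mirrored decoder with nearest-neighbour
upsampling and skip concatenation; a final 1×1 convolution with sigmoid
output. The reference configuration is 512×512 RGB input, four encoder
levels, 64 filters per layer, 50% dropout per encoder level, 150 epochs
of 50 image draws each. The network, backpropagation and the Adam
optimizer are implemented in base R, which keeps the package free of
heavyweight dependencies and is entirely adequate at the smoke scale the
tests use (64×64 inputs, depth 3, 8 filters,
`unet_smoke_config()`). Choices the architecture description leaves
open, resolved here: the decoder mirrors the encoder with skip
connections; the loss is pixelwise binary cross-entropy; the optimizer
is Adam at 10⁻³ (2·10⁻³ at smoke scale); dropout sits after each
encoder ReLU; probability maps are binarized at 0.5. The overfit smoke
test disables dropout — it measures capacity, and regularization would
only obscure that.

Images enter the network through `pad_to_input()` (longest side scaled
to the input size, aspect preserved, black padding) or, for the spot
network, `crop_and_rescale_to_mask()` (tight crop to the body mask
first, so small spots survive downsampling). Both return a placement
record that maps predictions back to original coordinates exactly.
Predictions are post-processed by hole filling, morphological closing
and selection of the large central component (`postprocess_mask()`,
idempotent).

## 4. Constellation normalization

`spots_from_mask()` turns each connected component of the spot mask into
one spot: centroid (x right, y down, 0-based pixel centres) and
pixel-count area. `pca_align()` rotates the body-mask pixel cloud so its
first principal axis is horizontal, then scales all coordinates by the
mask extent along that axis (the fish length), so x spans [0, 1]; the y
axis uses the same scale, preserving aspect. Spot sizes are divided by
the squared length scale.

The 180° ambiguity of the principal axis is resolved by a fixed
skewness convention: after alignment the third central moment of mask
pixels along the major axis is negative. For the synthetic fish — whose
mass distribution is decisively skewed by the thin caudal tail — the
convention is stable and places every render of the same fish in the
same orientation regardless of its pose in the image, which is the
property the matcher needs. The aligned mask is rasterized on a regular
grid in fish-length units (cell size 1/128 by default) for the mask
overlap gate of Section 5.2.

## 5. Constellation matching

Both matchers characterize triangles of spots by similarity-invariant
features and are built locally: triangles join each spot with pairs
among its k nearest neighbours (k = 25 for the voting matcher, 15 for
the RANSAC matcher), which bounds the triangle count and concentrates
evidence on local structure. Neither applies the classical side-ratio or
cosine caps: spot patterns on fish flanks are often nearly linear and
those caps discard too much of the signal on small constellations.

### 5.1 Voting (Groth-style) matcher

Per triangle: vertex order with v1 at the junction of the shortest and
longest side; side ratio R = longest/shortest; cosine C of the angle at
v1; log perimeter; handedness of the shortest-to-longest traversal; and
the angle between v1, the triangle centroid and the horizontal.
Candidate pairs are mutual nearest neighbours between the two triangle
sets in (R, C, angle) feature space, found with dual k-d trees, then
filtered: invariant differences within first-order tolerances propagated
from the positional tolerance ε (the classical error model), same
handedness, centroid-angle difference ≤ 10°, and log-perimeter
difference within 1.5 standard deviations of the candidate-set mean (the
magnification filter). Each surviving pair casts one vote for each of
its three vertex pairs; votes are sorted and assigned top-down until a
vote cliff (next count below half the previous), a conflict with an
already assigned point, or exhaustion. The whole pipeline is repeated
using only the matched points; if the verification round returns as many
matches as the first, the match stands, otherwise the pair of
constellations is declared impossible to match.

Parameter choices that required a decision:

* **ε = 0.0075 fish lengths.** ε is the expected positional uncertainty
  of a spot centroid between two captures; it must sit at or slightly
  above the data's jitter scale (0.005 in the synthetic re-capture
  conditions) or the tolerance test rejects genuinely corresponding
  triangles.
* **Angle weight 0.25.** The centroid angle enters the nearest-neighbour
  feature space down-weighted (radians × 0.25): the angle of *every*
  triangle shifts coherently with the residual rotation between two
  captures, so at full weight a 10° pose difference displaces every
  true pair in feature space by more than the typical spacing between
  triangles. The full-resolution angle still acts through the 10°
  filter. Both the weight and each filter are configurable, and each
  filter can only ever remove candidates (a tested invariant).
* **Vote cliff relative to the previous pair; conflicts stop the
  assignment.** Measuring the factor-2 drop against the top pair
  truncates smoothly decaying vote tables halfway through the
  well-supported block; the cliff rule instead detects the transition
  to the spurious tail. Conflicts terminate the first-round assignment
  (conservative), while the verification round skips individual
  contested pairs — it re-examines an already vetted subset, where a
  contest reflects vote-order ties rather than a bad match.
* **Score** = (number of assigned pairs) × (fraction of first-round
  votes captured by those pairs). Identical constellations of n spots
  score exactly n; genuine re-captures concentrate votes and score
  high; chance matches scatter votes and score near zero. The open-set
  threshold of 6.5 then reads as "roughly seven well-supported pairs";
  it is configuration, not physics, and is exposed as such.

### 5.2 RANSAC similarity matcher

Per triangle, with side lengths L2 ≥ L1 ≥ L0: the ratios L2/L1 and
L1/L0, the centroid angle at the L0∩L1 vertex, and the three vertex
coordinates scaled down by a factor of 5 — nine features. The coordinate
features exploit the fact that both constellations are already
normalized: triangles can only match triangles in the same body region,
which suppresses spot alignments that would not align the bodies.
Matched triangles are mutual nearest neighbours in the nine-dimensional
space. RANSAC then repeatedly draws one matched triangle, fits the
similarity transform to its three vertex pairs in closed form, and
measures consensus at reprojection error ≤ 0.02 fish lengths. A
transform reaching 85% consensus terminates the search early if its
*transformation disturbance*

|rotation°|/60 + |scale − 1|/2 + (|tx| + |ty|)/2

is within 1.0; qualifying transforms above the cap are retained and the
smallest-disturbance one used, so strongly grown fish can still be
scored. The selected transform is refitted by least squares on all
inlier vertex pairs. The score is the fraction of target spots in an
inlier pair times the source analogue, and — independently of the
score — a match is rejected when the transformed body mask overlaps the
target mask with an F-score below 0.75.

Design decisions: consensus is measured on **points** by default (the
smaller of the source and target inlier-spot fractions), with the
triangle-level variant behind `consensus_on = "triangles"`. With locally
built triangles a large share of matched triangles is spurious even for
a perfect copy (near-duplicate sliver invariants), so triangle-level
consensus at 85% is unreachable while point-level consensus measures
exactly the quantity the score is defined on. The Sampson first-order
geometric error reduces, for this transform family, to the Euclidean
reprojection distance, which is what `pair_error()` computes. Inlier
threshold 0.02, disturbance cap 1.0 and 500 iterations are free
defaults.

### 5.3 Database, decisions and ensemble

Records are stored in collections with strictly increasing dates; a
query is compared only against earlier collections, mirroring the field
protocol. Rankings are sorted by score with unscorable comparisons
("impossible to match", no consensus) ordered last. The open-set
decision accepts the top-ranked record when its score reaches the
threshold (6.5 for the voting matcher; the RANSAC matcher's threshold is
a configuration value calibrated on synthetic data, with its mask gate
always applied). The ensemble is a simple OR: a match is declared when
either matcher accepts; when both accept different records the voting
matcher wins — its false-positive behaviour is the sharper of the two —
and the conflict is flagged for audit.

`link_fragments()` applies this machinery to a stream of capture
events: the first event of every observed tag id is queried against the
most recent prior record of each consolidated individual (individuals
already handled at the same occasion are excluded). Comparing against
one record per individual keeps the comparison count linear in the
number of individuals per query; since an accepted link merges the
fragment into the individual, later queries always see the freshest
record. Accepted links are merged by union-find in
`correct_capture_histories()`, with element-wise OR of the fragment
histories; fragments of one individual captured in the same collection
raise a conflict error.

## 6. Survival model

The CJS model conditions on first capture: an individual alive at
occasion t−1 survives to t with probability φ; an individual alive at t
is captured with probability p. The likelihood marginalizes the latent
alive states by a forward recursion over (alive, dead) occupancy — exact
and fast — rather than sampling them. Priors are uniform on [0, 1] for
both parameters. The default sampler is random-walk Metropolis on the
logit scale (step 0.15, with the Jacobian correction), several chains
from dispersed starts, first half discarded; a data-augmented Gibbs
sampler (`method = "latent"`), which alternates latent death times with
conjugate Beta draws, is provided and tested to agree with the marginal
sampler within Monte-Carlo error. Summaries are posterior means with
95% highest-posterior-density intervals (shortest sorted-sample window)
and split-chain R-hat.

Known limitation: with constant φ and p the final-interval product is
only weakly identified from short studies (the classical terminal
confounding); the simulated study designs use T ≥ 10 where recovery is
stable. Duplicated histories are collapsed with multiplicities before
evaluation, which makes the likelihood cost scale with the number of
distinct histories, not individuals.

## 7. Numerical choices and degenerate inputs

Coordinates are x right, y down, 0-based pixel centres, everywhere.
De-duplication removes spots within 3ε of a kept spot, in input order.
Triangles with a shortest side below 10⁻¹² are dropped. Collinear
source triples raise a degeneracy error in transform estimation; the
RANSAC loop simply skips them. Empty masks, empty spot sets,
out-of-range probabilities and chronology violations raise classed
errors (`spotmatch_*`). All randomness flows from explicit per-call
seeds through an RNG-state-preserving wrapper; no global RNG state
leaks. The RANSAC loop and the k-d tree are compiled (Rcpp) with a
platform-independent linear-congruential draw sequence, so results are
bit-reproducible across machines.

## 8. Problem sizes used in the tests

The test-suite study conditions are: 40 individuals with 15–60 spots for
the closed-set and open-set matcher evaluations (5 replicate suites);
populations of 150 (noiseless) and 300 (noisy) individuals over 12–15
occasions at φ = 0.78, p = 0.53 with 7% tag loss for the end-to-end
correction; 20 renders for the segmentation scores; 20 replicates of
n = 300, T = 15 for posterior recovery; and the 64×64 smoke
configuration for network training. These sizes give stable Monte-Carlo
margins for every asserted bound while keeping a full run of the suite
on a single CPU in the tens of minutes.
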