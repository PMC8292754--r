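# spotmatch

Photo re-identification of individual animals from their natural spot
markings, built around dark-spotted fish photographed on a light
background, plus the capture–mark–recapture machinery that makes the
re-identifications count: capture-history correction for tag loss and a
Bayesian Cormack–Jolly–Seber (CJS) survival model.

The package is aimed at researchers running individual-based field studies
where tags can be lost or were never applied. It implements the full chain:

1. **Segmentation** — a classical feature-engineered pipeline (Gaussian
   blur, fixed/adaptive thresholds, morphology, shape filters) and a
   U-Net-style encoder–decoder network (implemented in base R) extract the
   body mask and the spot mask from a photograph.
2. **Normalization** — spot masks become `(x, y, size)` constellations;
   the body's principal axes rotate the constellation into a canonical
   pose and scale it by the fish length so coordinates span [0, 1].
3. **Matching** — two triangle-invariant point-pattern matchers compare
   constellations: a Groth-style voting matcher (triangle side ratio R,
   cosine C, centroid angle; mutual nearest neighbours via dual k-d trees;
   handedness/angle/magnification filters; vote-based assignment with a
   verification round) and a RANSAC similarity-transform matcher
   (side-ratio invariants plus coordinate features, consensus at a
   reprojection-error threshold, a transformation-disturbance penalty
   `|rot|/60 + |s-1|/2 + |t|_1/2`, and a mask-overlap F-score gate at
   0.75).
4. **Decisions** — chronological database, score ranking, open-set
   thresholding (score ≥ 6.5 for the voting matcher) and an OR ensemble.
5. **Demography** — accepted links merge fragmented capture histories
   (union-find), and the CJS model `a[i,t] ~ Bern(a[i,t-1]·phi)`,
   `y[i,t] ~ Bern(a[i,t]·p)` with uniform priors is sampled by
   random-walk Metropolis on the marginal likelihood (latent states summed
   out by a forward recursion; a latent-state Gibbs sampler is available).

A synthetic-data module renders fish images with ground-truth masks,
generates perturbed re-captures with known correspondence, and simulates
capture histories with injected tag loss, so everything is testable
without field photographs.

## Worked example

Simulate an individual, a re-capture of it and an imposter, then match:

```r
library(spotmatch)

fish  <- generate_constellation(30, frame = c(1, 0.33), seed = 1,
                                spot_radius_range = c(0.008, 0.012))
recap <- perturb_recapture(fish, seed = 7)   # rotation, growth, jitter, turnover
other <- generate_constellation(30, frame = c(1, 0.33), seed = 99,
                                spot_radius_range = c(0.008, 0.012))

groth_match(recap$spots, fish)
#> <match_result: accepted, score 10.548, 26 matched pairs>
groth_match(other, fish)
#> <match_result: rejected, score 0.000, 0 matched pairs>
```

The re-capture scores 10.5 — well above the open-set threshold 6.5, i.e.
about ten well-supported spot pairs back the identity, with 26 of the 27
surviving spots re-assigned — while the imposter fails the matcher's
verification round and is unscored. The RANSAC matcher additionally
recovers the growth/pose transform:

```r
r <- ransac_match_aa(recap$spots, fish, seed = 1)
r$transform
#> <similarity: rotation 8.514 deg, scale 0.8666, translation (0.0934, -0.0612)>
```

(The inverse of the simulated re-capture perturbation: the second capture
was rotated about -8.5 degrees and ~15% larger than the first.)

Downstream, fragmented capture histories are repaired and survival
re-estimated:

```r
y   <- simulate_capture_histories(300, 15, phi = 0.78, p = 0.53, seed = 11)
rec <- inject_tag_loss(capture_records(y), rate = 0.07, seed = 12)
fit <- fit_cjs(histories_from_records(rec, 15, id_col = "observed_id"),
               n_samples = 3000, seed = 2, chains = 2)
coef(fit)
#>       phi         p
#> 0.7852437 0.4649343
```

Tag loss fragments histories and biases the estimates (here the capture
probability drops to 0.47 against a simulated 0.53); after matching the
fragments photographically (`link_fragments()` +
`correct_capture_histories()`) the corrected fit moves back to the
simulated truth — the end-to-end test and the acceptance script run
exactly this experiment.

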