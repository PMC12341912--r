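---
title: "Methods: task-dependent category representations from epoched EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task-dependent category representations from epoched EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(catrep)
```

# The scientific question and the analysis it requires

When an observer categorizes the same images at different levels of
abstraction — "is this an animal?" (superordinate) versus "is this a bird?"
(basic) — do the neural representations of the categories themselves change
with the task, and when? `catrep` implements the full multivariate EEG
analysis needed to answer that question: per-timepoint pairwise decoding,
cross-validated representational distances, temporal generalization,
representational geometry, cluster-based inference, drift-diffusion
behavioral modeling utilities, and template-based source statistics. Because
real recordings are not required to validate the machinery, the package
ships a synthetic-data generator that emulates the experimental design with
a fully known ground truth, so every stage has a parameter-recovery test.

The expected signature, which the generator plants by default, is a
*selective* task effect: the bird vs non-bird-animal representations are
indistinguishable when the task does not require separating them and pull
apart from about 250 ms when it does, while the animal vs vehicle
separations are identical across tasks.

# Data model and epoch conditioning

`eeg_epochs` holds a trials x channels x timepoints array (microvolts) with
latencies in milliseconds relative to stimulus onset. The experimental epoch
is -150..+500 ms; all window arguments are closed intervals on sample
latencies. Channel order comes from the data source and is never reordered.

Conditioning operations follow standard practice:

* `baseline_correct()` subtracts the per-trial, per-channel mean over
  -150..0 ms. Idempotent by construction.
* `reject_eye_epochs()` drops trials whose maximum absolute instantaneous
  difference between the two vertical EOG channels exceeds 150 microvolts.
  The maximum over the whole epoch is the conservative reduction of the
  threshold rule. It is applied *after* baseline correction in the pipeline;
  the screening criterion is a difference between two channels, so the
  common-mode baseline shift cancels either way, but the order is fixed and
  recorded for reproducibility.
* `subsample_equal()` equalizes group counts to the smallest group,
  uniformly without replacement. Every randomized operation in the package
  takes an explicit integer seed and restores the caller's RNG state; the
  package never draws from unseeded global state.
* `bin_time()` averages consecutive samples (used before temporal
  generalization); trailing samples that do not fill a block are dropped,
  and binned latencies are block centers.
* Trials without a response are retained for EEG analyses (both correct and
  incorrect trials carry signal) and are excluded only by the behavioral RT
  filters.

Epoch sets round-trip through a plain-text interchange container
(`write_epochs()` / `read_epochs()`): a directory holding `meta.json`
(sampling rate, latencies, channels, dimensions, schema version),
`labels.tsv`, and `data.tsv` (one row per trial, channel-major within
timepoint). Plain text keeps the container language-neutral and
diff-friendly; the cost is size, which is irrelevant at the problem sizes
this package targets.

# The synthetic generator

## Design

`sim_design()` defaults reproduce the study design: 2,000 trials split
1,000/1,000 between the superordinate and basic tasks; category proportions
25% bird / 25% non-bird animal / 50% vehicle in superordinate blocks and
50% / 25% / 25% in basic blocks; 64 channels at 256 Hz (at that rate the
temporal-generalization bin of 4 samples is ~4 ms wide, mirroring common
practice). One synthetic participant corresponds to one seed;
multi-participant datasets are lists of seeded generations, which gives the
group-level tests their exchangeable units.

## Representational geometry

`geometry_schedule()` declares latent category positions over time. The
construction guarantees the hypothesized contrast structure *exactly*: the
vehicle position sits at the origin and the two animal categories sit on a
circle of radius `r(t)` around it, separated by an angle that opens only in
the basic task. Hence bird-vehicle and animal-vehicle distances equal `r(t)`
in both tasks at every latency, while the bird/non-bird distance ramps from
0 at 250 ms to its plateau at 350 ms in the basic task and stays 0 in the
superordinate task. Declared pairwise distances ramp linearly between
breakpoints; the common separation starts at 120 ms and plateaus at 200 ms.

The latent positions are mixed into channel space by a matrix with
orthonormal columns, so channel-space mean separations equal the latent
distances and the ground truth stored alongside the data
(`generate_epochs()$ground_truth`) can be recomputed exactly.

Noise is stationary multivariate Gaussian with exponential spatial falloff
over a ring channel layout (`exp(-d/2)` with per-channel SD 10 microvolts by
default), optionally with 1/f temporal coloring (off by default; the
permutation tests only require exchangeability across units, which holds
either way). Plateau separations default to 14 (same units as the noise
SD), equal for all pairs at plateau so the three categories end up
equidistant in the basic task. These values were fixed once, by pilot simulation at design time, to
put peak pairwise decoding in the 0.75-0.85 range and to make the planted
250-ms onset
recoverable at the package's demonstration scale — smaller separations left
the between-task contrast detectable only ~50 ms into the ramp, because the
squared-distance ramp rises quadratically and cluster onsets lag the true
onset by however long the effect stays under the pointwise threshold. That
detection lag is a property of real cluster statistics too, and is worth
remembering when interpreting onset latencies.

What the generator does *not* emulate: realistic ERP waveshapes, volume
conduction from a head model, non-stationary noise, eye/muscle artifact
morphology (the planted artifact is a simple square deflection on the EOG
pair), learning or fatigue across blocks, and between-participant
variability in topography (all participants share the hypothesis structure;
only noise and trial sampling differ). Passing recovery tests therefore
demonstrates that the estimators and tests are correct and calibrated, not
that they will be as sensitive on real recordings.

## Behavior

`simulate_ddm()` draws first passages of a drift-diffusion process between
an upper (correct) and lower (error) boundary by Euler-Maruyama at
dt = 0.5 ms, with two refinements: the crossing time is linearly
interpolated within the final step, and a Brownian-bridge term accounts for
within-step excursions (without it, choice probabilities are biased by
~0.005 at this step size). The diffusion coefficient is fixed at s = 1, the
scaling convention of common hierarchical DDM tools, so drift rates are
directly comparable. Default per-condition parameters are arbitrary but
plausible (accuracy ~0.83-0.95, mean RT ~0.55-0.65 s) and encode the
hypothesized direction of task effects (drift slows at the basic level for
animal categories, speeds up for vehicles); no fitted magnitudes are
published for the study design, so these are labeled arbitrary.

`generate_posterior_samples()` fabricates Gaussian posterior draws around
the true parameters — the package consumes posterior samples for its overlap
statistic but deliberately does not fit a hierarchical model.

# Behavioral scoring

d-prime uses the log-linear correction (add 0.5 to each cell, 1 to each
denominator) so ceiling performance stays finite. Trials are filtered by
the standard exclusions (RT < 200 ms anticipatory; no response). Hit rates
are "yes" rates on target trials; for distractor categories both the
false-alarm rate and the correct-rejection rate are exposed, since a "hit"
on distractor trials admits either reading. Paired comparisons are
two-sided paired t-tests with Cohen's d for paired data and Bonferroni
correction (family of 3 for the three category pairs).

The posterior overlap probability P(a > b) compares equal-length chains
draw-by-draw (preserving MCMC dependence) and falls back to the full
cross-product for unequal lengths; ties count one half. P = 0.5 means full
overlap, P near 0 or 1 separation.

# Cluster-based permutation inference

`cluster_permutation_test()` is the shared inferential engine. Pointwise
paired t statistics are thresholded at a two-sided pointwise p < 0.05
(cluster-forming alpha, configurable); suprathreshold points form contiguous
clusters in 1D or 4-connected (faces-only) clusters in 2D; cluster mass is
the summed t. The null is the maximum cluster mass over within-unit sign
flips of the paired differences, with positive and negative families
compared against the common max-|mass| null. With 12 or fewer units all
2^n sign patterns are enumerated exactly; otherwise `n_perm` (default
1,000) random flips are drawn and p = (1 + #{null >= observed}) /
(1 + n_perm). Participants are the exchangeable units; trials are never
permuted across participants.

Numerical edge cases: points with zero variance across units produce
infinite t values; these are capped at the largest finite |t| in the data
(with a warning) so masses stay finite. For 2D masks,
`fill_holes = TRUE` adds nonsignificant points fully enclosed by a
significant cluster (flood-fill of the complement from the border),
mirroring the usual image-fill treatment of temporal-generalization maps.

# Decoding

`fit_lda()` implements two-class LDA with the pooled within-class
covariance shrunk toward a scaled identity at the analytic (Ledoit-Wolf)
intensity by default. Shrinkage is the default because average-referenced
EEG makes the channel covariance rank-deficient; `shrinkage = 0` (with a
pseudo-inverse fallback) reproduces the behavior of common toolbox defaults.
Classification at a timepoint uses only the channel vector at that
timepoint. Decision values w.x + b are positive for the first class;
exact-zero ties go to the second class (fixed, documented).

`decode_timecourse()` equalizes counts per repetition, splits into
stratified folds (equal class counts per fold), trains/tests per timepoint,
and averages over 10 folds x 10 repetitions. `shuffled_baseline()` runs the
identical procedure with labels permuted per repetition — an empirical
chance distribution that, unlike a fixed 0.5, carries sampling variance.
`temporal_generalization()` bins time by a factor of 4 first and reuses the
same cross-validation plan, so its diagonal equals a timepoint-wise run with
the same seed exactly. Between-task comparisons are performed on accuracy
time courses across participants; decoding the same category across tasks is
deliberately not implemented, because task blocks can differ in noise alone.

# Representational similarity analysis

The distance measure is the *squared* cross-validated Euclidean distance:
the inner product between the train-fold and test-fold pattern differences.
Its defining property is zero expectation when the two conditions are
identical — individual estimates may legitimately be negative, and negative
values are retained everywhere (clipping would reintroduce bias).

Per iteration (20 by default): trials are equalized, partitioned per
condition into 5 pseudotrials (random near-equal subsets, averaged), and
each fold holds out one pseudotrial pair. Multivariate noise normalization
whitens patterns by the inverse square root of the within-condition error
covariance with analytic shrinkage; by default the covariance is estimated
from the training folds of each iteration (time-averaged before inversion),
with `whiten = "all"` and `"none"` as alternatives. One implementation
detail: the shrinkage *intensity* is estimated once per dataset from
all-trial residuals and reused across folds, while the covariance itself is
always re-estimated from training folds — the intensity is a scalar
stabilizer whose fold-to-fold variation is negligible, and fixing it makes
the fold loop dramatically cheaper via sufficient statistics.

`rdm_at_window()` averages distances over 30-ms windows (15 ms either side;
default centers 50..400 by 50 plus 480 ms) into symmetric, zero-diagonal
dissimilarity matrices. `classical_mds()` double-centers the squared
dissimilarities into a Gram matrix and eigendecomposes it. The standard
`cmdscale` is not used for the embedding itself because it squares its
input, which is undefined for the signed cross-validated distances; the
package's implementation consumes squared dissimilarities directly and
reports the full eigenvalue spectrum so callers can detect dimensionality
loss or non-embeddable (negative-spectrum) input rather than having it
silently clipped. Coordinates are defined up to rotation/reflection;
`procrustes_align()` is provided purely for plotting sequences of solutions.

# Source statistics

Classifier weights are not interpretable topographies, so
`weights_to_pattern()` applies the forward-model (Haufe) transform:
pattern = Sigma_x w / var(w.x) per timepoint. On two-class data this equals
the ERP difference up to scale, which is both a test oracle and the reason
the transform is trustworthy. `localize_templates()` then solves, per
timepoint, the simultaneous ordinary least-squares fit of the pattern as a
linear combination of all area templates (a non-negativity option exists but
is off by default, since plain least squares is the minimal reading of a
"simultaneous fit"). The template matrix is consumed as data (areas x
channels, TSV); the package ships a synthetic smooth-topography fixture
generator (`generate_templates()`), not a reproduction of any published
template set.

`signflip_bootstrap_null()` flips the sign of each participant's pattern
with probability 0.5 per draw (1,000 draws by default), recomputes the
group mean, and reapplies the projection. The sign-flip unit is the
participant — flipping per timepoint would destroy the temporal structure
the method depends on. Patterns are normalized to unit Frobenius norm per
participant before averaging so no participant dominates. A Gaussian is
fitted to the null per area and timepoint; z = (obs - mean)/sd gives
p = 2(1 - Phi(|z|)), and the significance mask requires p < 0.005 sustained
for at least 15 consecutive milliseconds. Note an inherent ceiling: the
attainable |z| against a sign-flip null of n participants is about sqrt(n),
so the p < 0.005 rule is only reachable with roughly a dozen participants or
more — a design constraint, not an implementation limit.

# Pipeline, configuration, and determinism

`validate_config()` fills defaults (folds 10, repetitions 10, pseudotrials
5, iterations 20, n_perm 1,000, n_boot 1,000, p < 0.005 / 15 ms), checks
ranges, and rejects unknown keys with their path. `run_pipeline()` executes
the enabled stages in dependency order (sources requires decode; MDS
requires RSA), writes plain TSV/JSON outputs, and records a manifest with
seeds, parameters and MD5 checksums. Child seeds are derived by hashing
(master seed, stage name, indices), so enabling or disabling one stage never
shifts another stage's random stream, and a rerun with the same master seed
reproduces every output byte-identically.

# Problem sizes used by the tests

The package's own validation runs at sizes chosen to make the statistical
properties measurable at desk scale, stated here as the package's test
design: null calibration uses 200 group datasets of 17 participants at a
reduced per-participant size (120 trials, 16 channels, 100 Hz, 5 RSA
iterations, 200 permutations); estimator-bias checks use 100 such runs;
parameter recovery uses 20 replicate group datasets of 17 participants
(the study's group size) at 600 trials / 32 channels / 100 Hz; the
demonstration pipeline (`demo_config()`) runs 4 participants end-to-end.
The full study scale (17+ participants, 2,000 trials, 64 channels, 256 Hz)
is the generator default and runs the same code paths.

# Known limitations

* The generator's participants are exchangeable replicas of one hypothesis
  structure; there is no between-participant topographic variability, so
  group statistics on synthetic data are better calibrated than they would
  be on real data.
* Whitening assumes noise stationarity within the epoch when the
  time-averaged scope is used; strongly non-stationary noise favors
  `scope = "per_timepoint"` at the cost of estimator variance.
* Cluster onsets are biased late relative to true effect onsets (detection
  lag); the recovery tests bound this at 30 ms for the default SNR, but the
  bias grows as SNR falls.
* The EEGLAB `.set` reader is not included in this build; epochs enter
  through the plain-text interchange container.
* The hierarchical DDM itself is not fitted; the package only simulates the
  generative model and scores fabricated or externally supplied posterior
  samples.
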