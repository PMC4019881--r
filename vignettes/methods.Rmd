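---
title: "Modeling statistical structure in observed action sequences: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling statistical structure in observed action sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqBOLD)
```

## The scientific problem

When people watch everyday object-directed actions, they implicitly track
two distinct statistical properties of each upcoming action step: how
*probable* the step that actually occurs is (its conditional surprisal,
$I(x_t \mid x_{t-1}) = -\log p(x_t \mid x_{t-1})$), and how *predictable*
the next step is in the first place (operationalized by its inverse, the
specific conditional entropy of the successor distribution,
$H(x_t \mid x_{t-1}) = -p(x_{t-1}) \sum_i p(x_t^i \mid x_{t-1}) \log
p(x_t^i \mid x_{t-1})$, the successor entropy weighted by the probability
of the context). Dissociating the neural correlates of the two requires a
stimulus set whose statistics decouple them from stimulus identity, an
observer model that assigns a value to every event, and a GLM analysis
able to recover both parametric effects from BOLD data. `seqBOLD`
implements that entire chain, plus a synthetic-data generator so every
stage is testable without access to scanner data.

## The action grammar and the stimulus corpus

Sequences of six construction-toy action steps (board, cube, long screw,
short screw, nut, washer) follow a first-order Markov chain with
transition probabilities restricted to $\{0.25, 0.5, 0.75, 1.0\}$, no
immediate repetitions, and in-/out-degrees of 1–3 per step, with the cube
the only step with a single possible predecessor. The original study's full
matrix is not available in machine-readable form; `defaultChain()`
therefore ships a *reconstruction* that satisfies every textual
constraint (board→cube $= 1.0$; cube→{short screw $.5$, nut $.25$,
washer $.25$}; board–cube, short screw–long screw and washer–nut as the
highest-probability pairs). Among the admissible matrices we selected the
one whose stationary distribution is exactly uniform, because the study
design requires all steps to have a comparable base rate. Any
user-supplied matrix (CSV/JSON via `readChain()`) can replace it;
`validateChain()` checks the invariants.

`generateCorpus()` reproduces the corpus-level design: 74 sequences of
3–7 steps and 362 steps in total, so the mean length is $362/74 = 4.89$
and each step occurs 58–63 times (mean $60.33$); each step opens and
closes 10–15 sequences. It additionally forces the *realized* transition
counts to implement the designed probabilities exactly
(`balanceTransitions`, total deviation `transTol`, default 0): a stimulus
set is a designed artifact, not a random sample, and without this the
realized conditional frequencies of a nominal 0.25 transition wander
roughly between 0.19 and 0.31, which distorts every downstream regressor.
The search is rejection sampling with local repair — sequence lengths are
fixed first, then single sequences are resampled with start steps biased
toward first-count deficits and transitions biased toward their designed
share, with restarts on plateaus and a $10^5$ iteration cap — and is
deterministic given a seed. A corollary of exact balancing is that
non-final occurrence totals settle on multiples of the probability
denominators (typically 44/48/52 per row).

Step durations are lognormal with mean $4.115$ s (so that the mean
sequence duration is $\approx 20.1$ s at mean length 4.89) and SD
$1.34$ s, chosen so that sequence durations have an SD of roughly 6 s;
only sequence-level duration moments are reported for the original
stimulus set, so the step-level distribution is a modeling choice. Presentation order
(`randomizeOrder()`) allows at most two consecutive sequences sharing the
scaffold, length, first or last step, and forbids adjacent pairs in which
one step list is a contiguous subsequence of the other; the checker used
in the test-suite is an independent brute-force implementation.

## The ideal observer

The observer tracks occurrence and transition counts and turns them into
probabilities with an add-one (Dirichlet) prior. The estimator denominator
as originally reported, $\sum_i x_i + 1$, does not yield a proper conditional
distribution; the package default is therefore the Dirichlet(1) posterior
mean $(n + 1)/(N + K)$ (`dirichlet_K`), with `literal_plus1`
($(n+1)/(N+1)$) and `binomial_plus2` ($(n+1)/(N+2)$) available as
alternative conventions in the literature. Logarithms are natural (the
study's reported regressor maximum of $1.38 \approx -\ln 0.25$ rules out
base 2, which would give 2.0). The marginal $p(x_{t-1})$ in the entropy weighting is
the add-one-smoothed base rate — the only reading consistent with a
standalone $p(x_{t-1})$ factor.

`annotateEvents()` replays an event stream in presentation order,
annotating each event with the state *before* its own update.
Sequence-initial steps have no predecessor; their conditional quantities
are undefined and they are flagged out of the parametric regressors
(362 − 74 = 288 candidate transitions per pass). Learning accumulates
over the two training passes; at scan time the pipeline freezes the
counts (`update = FALSE`), treating the transition probabilities as
established. This matters quantitatively: with updating continuing
through the scan, the running ratio $n/N$ of a 0.25 transition
fluctuates enough mid-session to push the surprisal maximum to ≈ 1.5,
whereas frozen-at-scan estimates give a maximum of ≈ 1.41 and a
surprisal–entropy correlation of ≈ 0.67 over the scanned session, the
calibration regime this design targets. Both behaviors are one flag
apart and both are under test.

## First-level design and precolored GLM

`buildDesign()` implements a mixed event/epoch design: a main-effect
column for action onsets (amplitude 1, 1 s boxcars), mean-centered
entropy and surprisal modulators (centering decorrelates them from the
main effect; a flag disables it), question trials (3 s), video epochs
(their own duration), and a step-duration regressor of no interest.
Events closer than 2 s to the last *kept* event are dropped to the
implicit baseline (`mergeEvents()`; the comparison is against the last
kept event and the boundary is inclusive — both conventions are pinned by
brute-force tests). Columns are built on a 0.1 s microtime grid (1 s
events on a 2 s grid need super-resolution), convolved with a
double-gamma HRF (response peak ≈ 5 s, undershoot ≈ 15 s, ratio 6,
configurable), sampled at TR midpoints, and each event column carries a
first-derivative twin to absorb latency differences.

Serial correlation is handled by *precoloring*: a temporal Gaussian
filter of FWHM 4 s ($\sigma = 1.699$ s) is imposed on both data and
design, and ordinary least squares is run on the filtered system, with a
Satterthwaite-type trace correction
($\mathrm{df} = \mathrm{tr}(RV)^2 / \mathrm{tr}(RVRV)$) for the effective
degrees of freedom. Slow drift is removed beforehand by projecting out
sine/cosine harmonics of the acquisition window below the highpass cutoff
(default $1/70$ Hz; the per-participant $1/55$ alternative is an
argument — the optimization that chose between them per participant is
not documented and not reimplemented). A harmonic basis rather than a
cosine-only one is used so that drift of either phase is removed; the
mean survives and the intercept column stays estimable.

## Synthetic BOLD and what it does (not) emulate

`simulateParticipant()`/`simulateCohort()` generate 15 participants' 4-D
series on a 20×20×20 grid of 3 mm voxels at TR 2 s: voxel series are
design × betas plus AR(1) noise (lag-1 coefficient 0.3), white noise, and
a slow cosine drift with random phase per voxel. Three disjoint compact
spherical voxel sets carry the entropy effect, the surprisal effect, and
both (compact, because cluster-level inference is only meaningful for
focal activations). Per-participant random effects are scalar shifts per
effect map (SD 0.15 in effect units), shared across a map's voxels — the
across-subject variance component that second-level inference actually
tests. `calibrateNoiseSd()` sets the noise SD by design algebra (the
precolored-OLS sampling variance of the modulator beta under the
AR-plus-white covariance) so that designated voxels carry a group-level
effect size of Cohen's $d \approx 0.8$. Everything is seeded and
bit-reproducible; a JSON sidecar stores the ground truth so recovery can
be scored without re-reading generator internals.

The generator emulates the study's temporal structure, autocorrelation,
drift and between-subject variability. It does **not** emulate anatomy,
motion, physiological noise, spatial nonstationarity, or registration
error — so passing recovery tests demonstrates the correctness of the
analysis chain, not robustness to real-scanner artifacts. Spatial
smoothing (FWHM 5.65 mm) is available behind a flag and is off in the
desk-scale default for speed.

## Second level, cluster correction, ROI and behavior

Group inference is a per-voxel one-sample t-test over participants'
contrast maps ($\mathrm{df} = n - 1$), transformed to z by one-tailed
tail-probability matching (t and z are rank-identical; zero-variance
voxels are flagged and guarded). The two-step multiple-comparison
correction thresholds the z map at 2.33 ($p < 0.01$, one-tailed) and
keeps clusters that survive both a cluster-size and a cluster-mass
threshold ("cluster value" is read as the sum of suprathreshold z, the
standard size-plus-value combination; an OR rule is available by flag).
Thresholds come from a seeded Monte Carlo simulation of smooth Gaussian
null fields, analytically restandardized to unit variance, at the
$1-\alpha$ exceedance quantiles. Connectivity (26 by default, 6/18
configurable) is enforced to match between simulation and application by
a shared labeling code path. The null-field smoothness mirrors the
smoothing actually applied to the analyzed maps — 5.65 mm when spatial
smoothing is on, 0 for the unsmoothed desk-scale default; mismatched
smoothness (smooth nulls against unsmoothed maps) inflates the size
threshold several-fold and destroys sensitivity.

The ROI reading of "a sphere of six adjacent voxels" is the center voxel
plus its six face-adjacent neighbors (7 voxels) — the only geometry that
yields exactly six adjacent voxels around a center; a radius-based sphere
is the alternative mode. On the desk-scale default grid (±28.5 mm) the
left anterior hippocampus center (−25, −16, −18) falls inside, while the
right-hemisphere center (+31) does not; the default pipeline therefore
extracts only the left ROI, and larger grids can add the right one back.
Post-test judgments are aggregated per implemented probability level
(0, 0.25, 0.5, 0.75, 1.0); one paper–pencil cross corresponds to
$p = 0.125$ (×12.5 to percent). Familiarity is
$p_{\max} - \tfrac1n \sum_n |\hat p_n - p_n|$ with $p_{\max}$ 100
(computer test) or 8 (paper–pencil), and ROI betas are correlated with it
via Pearson's $r$ with $t = r\sqrt{n-2}/\sqrt{1-r^2}$. The synthetic
responder model adds truncated Gaussian noise to the implemented
probabilities; the paper–pencil variant allocates 8 crosses per
predecessor by largest-remainder rounding. Whether the computer test
spans 30 ordered pairs (no immediate repeats) or 36 is exposed as a flag
(`includeRepeats`), as the original trial structure is ambiguous.

## Numerical choices and degenerate inputs

* Convolution uses a 0.1 s microtime grid, box integration, and sampling
  at TR midpoints.
* The Gaussian temporal smoother is row-renormalized at the series edges
  so constants are preserved.
* Cluster thresholds are the smallest values whose exceedance probability
  across the null simulations is at most $\alpha$; the size threshold is
  never below 1 voxel.
* Zero-variance voxels in the group test yield $t = 0$ (zero mean) or a
  guarded finite z (nonzero mean), and are flagged.
* Infeasible corpus constraint sets fail fast with the binding constraint
  named; absorbing states, out-of-vocabulary labels, unsorted onsets,
  events beyond the scan end, and rank-deficient designs raise specific
  errors.
* All randomness flows from a master seed through `childSeed()` (a
  31-bit stage hash), so any stage can be re-run in isolation.

## Problem sizes used in the test-suite

The packaged tests run the full 74-sequence corpus assembly, a
15-participant cohort on a $20^3$ grid (~940 volumes) for recovery and
dissociation, 1000 Monte Carlo iterations plus 1000 fresh null fields for
familywise-error calibration, and toy-scale pipelines elsewhere; these
sizes were chosen as the smallest that exercise every stage at the
study's own dimensions.

## Known limitations

* The default chain is a constrained reconstruction, not a transcription
  of the original matrix; analyses tied to the exact matrix should
  supply their own.
* The per-participant highpass-width optimization, slice-timing, motion
  correction and anatomical registration of the original processing
  chain are out of scope; synthetic volumes are generated already
  aligned.
* Printed human results (activation tables, ROI statistics, judgment
  means) derive from unavailable participant data and are not
  reproduction targets; the package targets the design-level statistics
  and property-based recovery instead.
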