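---
title: "Models and methods: simulating and analysing nap-dependent insight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analysing nap-dependent insight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(napinsight)
```

This vignette documents the models implemented by `napinsight`, the
assumptions behind its synthetic-data generator, and the numerical and
design choices a user should know before trusting (or extending) the
pipeline. The package addresses a specific study design: participants
learn a perceptual classification with a hidden, better strategy, nap
for 20 minutes with EEG, and may or may not discover the strategy — an
insight — afterwards. The analysis chain links the probability of that
insight to nap sleep stages (Wake / N1 / N2) and to the aperiodic (1/f)
structure of the nap EEG.

## The behavioural task and agent model

The task is a random-dot motion/colour discrimination: 9 blocks of 100
trials, five motion-coherence levels (5, 23, 41, 59, 76%), with 30 of
every 100 trials at the hardest 5% level and 10/20/20/20 at the others.
Block 1 is pure 100%-coherence training, block 2 uses only the easy
levels. From trial 351 (mid block 4) the stimulus colour silently
becomes fully predictive of the correct response; the nap sits between
trials 400 and 401; before block 9 the colour rule is explicitly
instructed.

Simulated agents hold two strategies. Motion-based accuracy is a
monotone psychometric function of coherence, anchored at 56% for the 5%
level and 92% for the 76% level (the pre-insight accuracies the design
assumes), with an exact ceiling at full coherence. Colour-based
accuracy is `p_colour = 0.97`, between the post-switch accuracy on
hard trials (about 91%) and the near-ceiling instructed-block accuracy
(about 98%) such a design produces. Insight agents blend the two
strategies with a logistic weight centred at the true switch trial
`t_s_true` with per-trial slope `m_true`; a 2% lapse rate mixes every
trial towards chance. Reaction times are log-normal with pre/post
switch means of 767/527 ms; they are descriptive only.

**Calibration of the switch slope and ceiling.** The defaults
`p_colour = 0.97` and `m_true ~ lognormal(log 0.08, 0.1)` are set so
that three constraints hold at once: (1) a true insight agent is
classified as insight (block-8 hard-trial accuracy above 85%, i.e. at
least 26 of 30) with probability 0.994, so classifier sensitivity
clears 95% and a 48-insight cohort is almost always labelled exactly;
(2) a non-insight agent essentially never clears the criterion
(specificity ~1); and (3) when each insight agent's 5%-coherence trial
series is aligned at its true switch centre, the mean accuracy in the
15 hard trials before and after the switch is about 63% and 89% — a
jump of about one quarter, the headline abruptness statistic of this
design. Steeper defaults saturate the jump at the full range between
floor and ceiling; flatter defaults wash it out.

## Inclusion, the change-point model, and classification

Two exclusion rules mirror the study design: (1) below 80% accuracy on
the three easiest coherence levels in block 3 (the last fully
uncorrelated block — colour becomes predictive mid-block 4, so block 3
is the conservative reading of "last block of the uncorrelated phase");
(2) a pre-nap strategy switch, operationalised as classifier-positive
accuracy (>85%) on hard trials between colour onset and the nap
*and* a fitted switch point before trial 400.

The change-point model is the four-parameter sigmoid
$$y(t) = y_{min} + \frac{y_{max} - y_{min}}{1 + e^{-m (t - t_s)}}$$
fit by Bernoulli maximum likelihood to the binary outcomes of the
5%-coherence trials of blocks 3–8 (about 180 trials), not by least
squares on smoothed accuracy: the raw-likelihood version is testable by
parameter recovery and makes no smoothing choices. Parameters are
box-constrained (`0 <= y_min <= y_max <= 1` via a nested
parameterisation, `0 <= m <= 10`, `t_s` inside the fitted range).
Optimisation is multi-start: switch-point starts every 10 trials are
scored with plug-in pre/post rate estimates, and the best five are
refined by L-BFGS-B from three slope initialisations (0.03, 0.1, 0.5).
The returned optimum is never worse than any grid start; exact ties are
broken towards the smallest `t_s`. A subject counts as insight if
block-8 accuracy on 5%-coherence trials exceeds 85% (26/30); the
reported switch point is the fitted sigmoid midpoint, which is one of
several defensible readings of "switch point" and is recorded as such.

**A caveat on switch alignment.** The Bernoulli MLE prefers step-like
fits whose boundary is placed exactly between the last pre-switch error
and the first post-switch correct run. Aligning windows at such fitted
switch points therefore *overstates* the jump (the pre-window is
enriched with errors, the post-window with correct runs): the shipped
analysis configuration reports a fitted-aligned jump of about 0.40
where alignment at the generative switch centres gives about 0.26, and
the inflation persists regardless of the true slope. The package's
jump calibration is therefore checked against the generative switch
centres; when you align real data at fitted switch points, expect this
bias.

## The nap EEG generator

Hypnograms are 40 epochs of 30 s with W/N1/N2(/N3) labels drawn from a
semi-Markov scheme (geometric latency and run lengths); group semantics
are strict — Wake-group naps never leave W, N1-group naps reach N1 but
never N2, N2-group naps contain at least `min_n2_minutes = 2` minutes
of N2 (naps below that quota are redrawn, mirroring the exclusion of
marginal N2 sleepers).

EEG is synthesised per 30-s epoch as Gaussian white noise shaped in the
frequency domain to the stage's target one-sided spectrum
$$\log_{10} P(f) = b - x \log_{10} f + \sum_k h_k
  e^{-(f - c_k)^2 / 2 w_k^2},$$
i.e. an aperiodic component with offset `b` and exponent `x` (the
reported "slope" is `-x`) plus Gaussian oscillatory bumps in log power.
Defaults: exponents 1.37 (W), 1.47 (N1), 1.79 (N2), 2.20 (N3) —
the canonical steepening with sleep depth at frontal sites — with
waking alpha (10 Hz), attenuated alpha plus theta in N1, and spindle
(13.5 Hz) plus slow activity in N2. Frequency-domain shaping makes the
target spectrum exact in expectation, which is what allows the
round-trip recovery tests (simulate at exponent x, recover x̂ within
±0.1) to be sharp. Below 0.5 Hz the target spectrum is attenuated by an
order-4 Butterworth-style magnitude response (cutoff 0.3 Hz), emulating
the high-pass preprocessing applied to real recordings; without it,
very steep spectra leak low-frequency power across epoch windows and
bias the fitted exponent upward. Epoch edges carry 25-ms cosine ramps
so concatenation is step-free. Channels share stage parameters; a
subject-level exponent shift (`subject_sd`, default 0.1) and an
optional insight coupling (`slope_coupling`) add between-subject
structure.

What the generator does *not* emulate: morphologically realistic
spindles or K-complexes (bumps are stationary within an epoch), eye or
muscle artifacts, channel-specific topographies, or non-stationarity
within a stage. Passing tests on this generator therefore validate the
estimators' statistical behaviour, not their robustness to artifactual
real-world EEG.

## Spectral estimation and parameterization

Spectra are computed from 6-s epochs with 50% overlap, Hanning-tapered,
window-power normalised, averaged, on a 1–45 Hz grid at 0.2 Hz. A 6-s
epoch natively yields a 1/6-Hz grid; each epoch is therefore
zero-padded to the next multiple of `fs/0.2` samples (10 s at 200 Hz)
so the FFT grid contains exact 0.2-Hz multiples. Whether the original
analyses achieved 0.2 Hz by padding or otherwise is not stated
anywhere we could check; padding honours both printed numbers and is
configurable.

The spectral decomposition follows the standard two-stage
parameterization with the knee fixed at 0 (the fitted range starts at
1 Hz precisely to avoid the low-frequency plateau that would need a
knee): (1) a robust aperiodic fit — ordinary log-log least squares,
then a refit on the bins at or below the 2.5th percentile of the
positive residuals, which drops oscillatory bins; (2) iterative
extraction of up to 3 Gaussian peaks from the flattened spectrum, each
accepted only if it exceeds both 0.3 log10-power units (the 3 dB
minimum height, read as 0.3 bel) and twice the flattened spectrum's
standard deviation, followed by a joint bounded least-squares
refinement; (3) a final aperiodic refit on the peak-removed spectrum.
Peak widths are bounded to 0.5–12 Hz (Gaussian sd 0.25–6 Hz). Band
power (delta 1–4, alpha 5.8–11.3, spindle 11.5–15.2 Hz) is the mean
flattened residual over in-band bins, bounds inclusive.

Slope tables can be computed from the whole nap or restricted to each
subject's deepest stage; stage-restricted epoching only uses 6-s
windows fully contained in contiguous 30-s epochs of the target stage,
so no window mixes stages.

## Cluster-based permutation inference

For channel × frequency data (flattened spectra) or channel-only data
(slope maps, treated as a single bin), element-wise statistics (Welch t
for two groups, one-way F for three) are thresholded at the parametric
critical value for `cluster_alpha` (two-sided split for t); clusters
form over spatial neighbours (montage distance ≤ radius, default 0.8 in
schematic head units — every channel of the 8-channel scoring montage
has at least one neighbour) and adjacent frequency bins within a
channel, with no diagonal hops, and t clusters are sign-separated.
Cluster mass is the sum of element statistics; the null is the maximum
absolute cluster mass over label permutations, and cluster p-values use
the (+1)/(+1) correction so 1000 permutations can never report p = 0.
The permutation p converges to the exhaustive-enumeration p on small
cohorts (checked against full enumeration at n = 8), and family-wise
error on null data is confirmed within [0.01, 0.10] at nominal 0.05.

## The inference ladder

Contingency tables are tested with the two-sided Fisher convention that
sums hypergeometric point probabilities no larger than the observed
one (the convention of R's exact test; required to reproduce two-sided
p-values computed that way). Logistic models for insight —
intercept-only, `~ stage`, `~ stage + slope`, `~ slope` — use treatment
coding with Wake as the reference (the coding under which the published
group-contrast coefficients have closed forms, e.g.
`beta = log((24/4)/(10/8)) = 1.57` for N2 vs Wake on the study counts).
Model comparison uses AIC, likelihood-ratio tests
(`X2 = 2 (LL_full - LL_null)`, chi-square with df = parameter
difference; identical models return X2 = 0, p = 1), and adjusted
McFadden R² `1 - (LL - k)/LL_0`. No multiple-testing correction is
applied across channels in the ladder: per-channel AICs are reported as
such, and family-wise control over channels is the cluster test's job.

## Problem sizes and determinism

The test-suite and acceptance runs use deliberately moderate sizes:
20-minute single-channel recordings for exponent recovery; cohorts of
40–80 agents for classifier operating characteristics; 200 insight
agents for the jump; 200 null simulations at 500 permutations for
cluster calibration; 18-subject cohorts (6 per group) with full EEG for
the generator-concordance runs. These sizes keep every Monte-Carlo
standard error well inside the asserted tolerance. All simulators take
explicit integer seeds, restore the caller's RNG state, and derive
per-subject streams by a counter scheme, so enlarging a cohort never
reshuffles earlier subjects and identical seeds give bit-identical
schedules, label sequences and sample arrays.

## Known limitations

- The EDF writer/reader covers plain 16-bit continuous EDF only (no
  EDF+ annotations); quantization error is bounded by the physical
  range over 2^16.
- Whole-nap spectra of N2-group subjects mix W, N1 and N2 epochs, so
  simulated group slope means are flatter than the stage parameters
  that generated them; group *ordering* is preserved and is what the
  concordance tests assert.
- The sigmoid MLE's boundary-snapping (above) makes fitted-switch
  aligned jumps upward-biased; use the generative centres when
  validating calibration, and interpret real-data jumps accordingly.
- Bayes-factor analyses for constrained hypotheses are deliberately out
  of scope; the package reports likelihood-based comparisons only.
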