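---
title: "Models and methods behind gonogo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gonogo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonogo)
```

`gonogo` simulates and analyzes head-fixed go/no-go odor discrimination
experiments in which odor cues predict an appetitive (sucrose) or aversive
(denatonium) solution, probe sessions add unreinforced mixtures of the two
odors, and extracellular single units — including optogenetically identified
corticothalamic projection neurons — are recorded throughout. This vignette
documents the generative models, the statistics, and the design choices the
code makes where the underlying procedures admit more than one reasonable
reading. Everything here is computed by the package's functions and checked
by its test suite; no empirical claim below goes beyond what those tests
exercise.

## The task model

A session schedule is described by `task_config()` and realized by
`generate_trial_table()`. The default timeline is 10 conditioning sessions,
a probe (extinction) test, 10 reversal sessions in which the sucrose- and
denatonium-predicting odors swap roles, and a second probe test.
Conditioning sessions present each of four odors (A, B, C, D) 50 times in
randomized order; probe sessions present each conditioning odor 53 times
plus 8 unreinforced presentations of each of three mixtures (85/15, 50/50,
15/85 sucrose-odor proportion), interleaved at random. Each trial is a 1 s
odor, a 1 s trace delay, the outcome, a vacuum 4 s after odor onset, a
fixed 3 s delay, and a variable inter-trial interval (ITI).

Trials are coded by `sucrose_prop`, the proportion of the currently
sucrose-predicting odor in the stimulus (1, 0.85, 0.5, 0.15, 0; `NA` for
the neutral odors C and D). This abstracts chemical identity away: odor
counterbalancing across animals is not modeled because no downstream
statistic uses the identity of the odorant, only its outcome role.

**ITIs.** ITIs are exponential with rate 0.3 s⁻¹, right-truncated at 30 s.
Truncation is implemented by resampling draws that exceed the bound, which
keeps the within-support distribution exactly exponential — and therefore
the hazard flat, so the animal's expectation of the next trial does not
grow with waiting time. Clipping at the bound would instead place an atom
at 30 s and a hazard spike there; it was rejected. The closed-form mean of
this law is
$1/\lambda - M e^{-\lambda M}/(1 - e^{-\lambda M}) \approx 3.33$ s at
$\lambda = 0.3$, $M = 30$. Task descriptions of this protocol sometimes
quote longer empirical mean ITIs; those are not producible from these
parameters (nor from a shifted version), so the sampler follows the stated
parameters and exposes `iti_rate` and `iti_max` for other regimes.

## The lick generator

Licking in the odor + trace window is a homogeneous Poisson process
(`simulate_licks()`, parameters in `lick_params()`). Only counts per
window enter any downstream statistic, so lick micro-structure (bouts,
inter-lick rhythmicity) is deliberately not modeled; conclusions about
bout structure cannot be drawn from these simulations. The rate model is:

* linear interpolation between `rate_denatonium` (default 0.3 licks/s)
  and `rate_sucrose` (default 8 licks/s) in `sucrose_prop`, matching the
  smooth scaling of anticipatory licking with mixture proportion;
* a multiplicative `group_multiplier` (default 0.8) on sucrose and
  mixture cues in the air-puff group — an aversive history depresses
  anticipatory licking without abolishing discrimination;
* optional exponential decay across the eight probe repeats
  (`extinction_decay`), and an optional logistic acquisition schedule
  across sessions (`learning_k`, `learning_x0`).

Defaults were chosen once to land in the range typical for water-restricted
head-fixed mice (anticipatory rates of ~6–8 licks/s on rewarded cues,
group differences under 1 lick/s at moderate rates) and are not tuned to
any analysis outcome.

## The spike-train generator

`simulate_unit()` draws an inhomogeneous Poisson train with piecewise-
constant rate: `baseline_rate` between trials and
`baseline_rate * (1 + cue_gain * sucrose_prop) * group_gain` during each
odor + trace window (clamped at zero, so negative gains give suppressed
units). A key departure from a pure Poisson process is an absolute
refractory period (default 2.5 ms): without it, a 5 spikes/s unit would
show ~1% ISI violations and *no* simulated unit could ever satisfy the
0.1% inclusion criterion. The generating intensity is dead-time corrected
(`lambda = r / (1 - r * tau)`), so after sequential refractory thinning
the observed rate equals the configured rate exactly (the thinned process
is a renewal process with mean interval `tau + 1/lambda`).

**Identification protocol.** After the session, 10 trains of 10 light
pulses at 10 Hz (10 s between train onsets; 100 pulses total) are
appended. Pulses are emitted for every unit — light is delivered to the
tissue regardless of which cell is recorded — but only units with
`tagged = TRUE` respond, with probability `tag_reliability` per pulse and
Gaussian latency `tag_latency_ms ± tag_jitter_ms`. For `antidromic`
units, a pulse falling within the collision window (default latency +
3 ms: the two spikes must meet within roughly the conduction time) after
a spontaneous spike evokes nothing. A collision-test epoch follows:
pulses triggered 1 ms after spontaneous spikes (default 100 of them),
which for antidromic units can never evoke a somatic spike, while
orthodromic-like units (`antidromic = FALSE`) keep responding.

## Behavioral statistics

`epoch_lick_rate()` counts licks in a half-open `[0, 2)` s window from
odor onset — the 1 s odor plus the 1 s trace delay, i.e. the anticipatory
period before the outcome can inform behavior. `learning_curve()`
averages by session × cue × group, with SEM across mice when a
`mouse_id` column is present and across trials otherwise (single-subject
synthetic data must remain analyzable). `extinction_curve()` returns the
8-point trajectory per mixture per group; because probe sessions can be
pooled either before or after averaging across mice, the per-trial table
is returned tidy so callers can choose either aggregation.

`fit_logistic()` fits $f(x) = L / (1 + e^{-k(x - x_0)})$ by
Levenberg–Marquardt least squares from a multi-start grid (both signs and
three scales of $k$, three quantiles of $x_0$), keeping the best residual
sum of squares; the learning rate is $k$. A constant response cannot
identify $k$ or $x_0$: by convention the fit returns $L$ equal to the
constant and $k = 0$, flagged `boundary = TRUE` rather than pretending
convergence. Noiseless data are recovered to $10^{-6}$; with Gaussian
noise of SD 0.5 over 10 sessions the median $\hat k$ over 200 replicate
fits stays within 10% of the generating value (both are asserted in the
test suite).

## Spike-sorting quality control

Inclusion requires, strictly: L-ratio `< 0.05`, ISI-violation fraction
`< 0.001` (2 ms refractory), and mean rate `> 0.5` spikes/s over the
session (denominator: last odor onset plus the fixed 7 s trial tail;
configurable). The L-ratio sums, over non-member spikes, the upper-tail
$\chi^2_K$ probability of their squared Mahalanobis distance to the
cluster (its own mean and covariance, $K$ = feature dimension), divided
by the cluster size. The feature space is deliberately agnostic — energy,
principal components, or peak amplitudes all work — since the metric is
invariant under affine maps of the features (a property the tests check
explicitly, along with exact agreement with a per-spike brute-force
loop). Near-singular covariances are ridged by $10^{-8}\,\mathrm{tr}/K$
on the diagonal so degenerate fixtures fail informatively rather than
crash. "ISI violations" counts consecutive-pair intervals only, the
standard convention; for a Poisson train the expected fraction is
$1 - e^{-0.002 r}$, which the simulated trains match.

## Discriminability analysis

`binned_auroc()` compares, per 100 ms bin, the per-trial spike counts of
sucrose trials against denatonium trials via the area under the ROC
curve, computed as the normalized Mann–Whitney statistic with ties
counted 0.5 (tie handling is not standardized elsewhere; the Mann–Whitney
convention makes auROC(A,B) + auROC(B,A) = 1 hold exactly). Values above
0.5 mean greater activity on sucrose trials. Profiles are not smoothed
before thresholding. `classify_discriminative()` labels a neuron
`excited` if any cue-period bin exceeds 0.7 and `inhibited` if any falls
below 0.3; when both occur the larger excursion from 0.5 decides (a rule
the thresholds alone leave open). "Cue period" is odor onset through
outcome delivery (0–2 s), consistent with the odor-and-delay window used
for the behavioral readout; the pre-CS baseline is the 1 s before odor
onset (its duration is a convention, exposed as an argument).

`cue_response_change()` is the companion filter: a paired two-sided
t-test of per-trial cue rate against per-trial baseline rate, with
direction labels at p < 0.05. Selecting units "with significant rate
changes during the cue" by this test is an interpretation — other tests
could serve — so it is a separate, inspectable step rather than being
baked into the auROC profile.

## Optotag identification

`optotag_unit()` measures, over the 100-pulse protocol: the median
first-spike latency (the central summary is a choice; `mean` latencies
can be obtained from the per-pulse table), its SD (jitter), and
reliability as the raw fraction of pulses with ≥ 1 spike in the 15 ms
response window — deliberately not chance-corrected, since at typical
rates (< 10 spikes/s) chance contributes < 15% per window and the 70%
criterion dwarfs it. Identification requires latency < 15 ms (strict),
reliability ≥ 70%, and a collision pass when a collision test was run;
untested units are decided on latency and reliability alone.

The collision test deserves detail. The pass rule is: at most 10% of
spike-triggered pulses may evoke a spike. Detection for this test uses a
narrow window centered on the unit's *own* median evoked latency
(half-width max(1.5 ms, 3 × jitter)), not the full 15 ms window. The
evoked latency is known from the identification protocol, so the absence
of the stimulus-locked spike at that latency is the informative event;
with the full window, baseline firing alone (rate × 15 ms, ~7% per pulse
at 5 spikes/s) would approach the 10% bound and well-behaved antidromic
units would fail by chance. With the latency-matched window the chance
contribution drops to ~1–2% per pulse and decisions at 100 triggered
pulses are deterministic in practice for clearly separated parameters.

One caveat the simulations make explicit: with 100 pulses, a unit whose
true reliability sits near the 70% criterion is tagged with binomial
probability, not certainty — at true reliability 0.72, roughly 71% of
runs cross the threshold. The test suite asserts agreement with that
binomial prediction rather than a near-certain classification, which the
protocol scale cannot deliver.

## Spike-count encoding model

`fit_poisson_glm()` regresses cue-window spike counts on the
sucrose-odor proportion (a 1-df linear coding of the five stimuli — a
single "mixture" slope; a categorical coding is available via
`encode_design(categorical = TRUE)`), an air-puff-group indicator, and
their interaction, with a log link fitted by IRLS (`stats::glm`). Odors
C and D are excluded by construction. Counts are pooled across trials
and units with no per-unit random effect — the plain Poisson regression
the analysis calls for — and no exposure offset is needed because all
cue windows share one length; per-unit fits can be obtained by calling
the function per unit. Estimates agree with an independent Newton
maximizer of the Poisson likelihood to $10^{-8}$, and 95% Wald intervals
cover generating coefficients at near-nominal rates in simulation
(≥ 93% per coefficient at n = 5000), both asserted in the tests.

`cs_response_correlation()` reports the Pearson correlation across units
between sucrose- and denatonium-evoked rates with a percentile bootstrap
95% CI (10,000 resamples by default). `count_summary()` /
`aggregate_counts()` produce the responsive-fraction arithmetic
(increases + decreases over total, reported as a rounded percentage with
the unrounded value retained).

## Orchestration and determinism

`run_pipeline()` chains simulate → behavior → QC → ephys → optotag → GLM
→ report, writing each stage's table as CSV plus `report.json` and a
`manifest.json` containing the config hash, seed, per-stage status, and
MD5 checksums of every output. The manifest is timestamp-free so that
identical configuration and seed give byte-identical outputs — an
invariant the tests check. One master seed drives everything;
each unit's private stream is derived from the master seed and its
`unit_id`, so adding or removing units never changes another unit's
spikes. Neural stages run on the first probe session (it contains the
mixture stimuli the encoding model needs); with an empty unit population
the behavioral stage still completes and neural stages report
`"no-units"`. A thin command-line wrapper over these functions ships in
`inst/cli/run-pipeline.R`.

## Problem sizes and limitations

The test suite and the acceptance script run at sizes chosen to make
Monte-Carlo error small relative to the asserted tolerances while keeping
a full run in minutes on one core: $10^5$ ITI draws for distributional
checks, 200 units × 200 trials for classification recovery, 5000
unit-trials × 100–200 replicates for GLM coverage, 100–200 seeds for
optotag decisions, 1000 random instances for the auROC oracle. These are
statements about the synthetic generative model only. The generator omits,
among other things: waveform shape and drift, electrode-level correlations
between simultaneously recorded units, non-Poisson spiking (bursting,
adaptation) beyond a fixed dead time, lick-bout structure, session-to-
session nonstationarity other than the configured learning schedule, and
any coupling between behavior and spiking within a trial. Passing tests
therefore validate the statistical machinery and its implementation — not
claims about biological recordings, which require the real data.
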