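---
title: "Task-switching control indices and sequential Bayes factor designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-switching control indices and sequential Bayes factor designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchbf)
```

## The scientific setting

`switchbf` implements the computational machinery of a cued task-switching
study design used to separate *cognitive control* from *automaticity*.
Participants classify a stimulus (a red or green circle or triangle shown
in one quadrant of a 2 x 2 grid) by one of four binary dimensions —
colour, shape, vertical position, horizontal position — with all four
tasks mapped onto the same two response keys. Because the irrelevant
dimensions also activate stimulus-response (S-R) rules, every trial
carries 0-3 *competitor* rules whose dictated response conflicts with the
correct one. Three indices are extracted per participant:

* **Linear congruency effect** — the linear trend of performance over the
  number of competitors (weights $-3, -1, 1, 3$ for 0-3 competitors; the
  weighted sum of the four condition means). It mixes interference from
  automatic rule activation with its controlled resolution.
* **Backward inhibition (BI)** — the cost of returning to a just-abandoned
  task (ABA task triplets) relative to fresh transitions (CBA); a
  set-level inhibition index, computed as ABA minus CBA.
* **Competitor rule suppression (CRS)** — the cost when a rule that
  competed on trial N-1 becomes relevant on trial N (CRS+) relative to a
  matched baseline in which it did not compete (CRS-); a rule-level
  suppression index, CRS+ minus CRS-.

The motivating study compared these indices between two groups whose
belief in free will was experimentally raised or lowered, using a
**Sequential Bayes Factor (SBF)** sampling plan: start at 60 participants
per group, recompute a default-prior Bayes factor as participants accrue,
stop at BF$_{10} > 10$ or $< 1/10$, and otherwise stop at 100 per group,
interpreting the final BF against the Jeffreys thresholds 3 and 1/3.

The package provides four connected layers: a generative simulator of
trial-level data with known ground-truth effects, the trial
classification and exclusion pipeline, the per-participant index and
participant-exclusion machinery, and the Bayes-factor engine with the
SBF design simulator.

## The Bayes factor engine

For a two-sample comparison with pooled-variance statistic $t$, group
sizes $n_1, n_2$, effective size $N = n_1 n_2/(n_1+n_2)$ and
$\nu = n_1+n_2-2$ degrees of freedom, the JZS Bayes factor places a
Cauchy prior with scale $r$ on the standardized effect $\delta$:

$$\mathrm{BF}_{10}
  = \frac{\int f_{\nu}\!\left(t \mid \delta\sqrt{N}\right)
          \pi_r(\delta)\, d\delta}{f_{\nu}(t \mid 0)},$$

where $f_\nu(\cdot \mid \mu)$ is the noncentral-$t$ density. The
two-sided factor is evaluated through the equivalent integral over the
variance scale $g$ (inverse-gamma$(1/2, r^2/2)$ prior), which needs only
central-$t$ kernels and is numerically benign. One-sided factors
truncate the prior to the predicted direction and integrate over
$\delta$ directly after the substitution $\delta = r\tan\theta$, which
turns the half-Cauchy measure into a flat measure on $(0, \pi/2)$.

Two numerical choices matter:

* Adaptive quadrature runs at a relative tolerance of $10^{-9}$ or
  tighter; the test suite pins the engine against an independent
  fixed-grid Simpson oracle to $10^{-6}$ relative error.
* R's built-in noncentral-$t$ density has an *absolute* error floor that
  dominates far-tail values, which would corrupt wrong-direction
  one-sided factors. The package therefore evaluates the noncentral-$t$
  log-density from its exact integral representation
  $f(x;\nu,\mu) \propto e^{-\nu\mu^2/(2(x^2+\nu))}\int_0^\infty
  u^\nu e^{-(u-a)^2/2}\,du$ with $a = x\mu/\sqrt{x^2+\nu}$, by
  peak-normalized quadrature on the log scale. This stays accurate for
  arbitrarily extreme statistics.

The default correlation test uses the exact sampling density of the
Pearson $r$ (including its Gaussian hypergeometric term, summed by
series) under a stretched-beta prior of width 1 (uniform on
$(-1, 1)$). Power statements use the exact noncentral-$t$ power of the
independent-samples test via `stats::power.t.test`.

Evidence categories follow the Jeffreys bands (anecdotal to decisive,
for H1 above 1 and reciprocally for H0), with boundary values assigned
to the weaker category.

## The SBF design simulator

`sbf_design_analysis()` draws the two groups from $N(d, 1)$ and
$N(0, 1)$ — the standard design-analysis data model; the trial-level
generator is exercised by the pipeline, not here — and replays the
sampling plan with one participant per group per look. Because the BF
is strictly monotone in $t$ (in $|t|$ for the two-sided variant) at
fixed $n$, the engine inverts each boundary once per look into a
$t$-threshold by root finding and then runs all simulated studies on
vectorized incremental sufficient statistics. Ten thousand simulations
take seconds; `simulate_sbf_study()` retraces single studies with their
full BF trajectory, and a test verifies both paths make identical
decisions on identical data.

**Sidedness.** The design's published operating characteristics do not
state whether the simulated t-tests were directional. Both variants are
implemented; the directional (one-sided) factor reproduces the printed
characteristics — 82.9% upper-boundary hits and 89.2% total H1 evidence
at $d = 0.5$, 58.2% lower-boundary hits and 85.9% total H0 evidence at
$d = 0$, mean stopping point near 73 per group — whereas the two-sided
factor at scale 1 cannot cross the $1/10$ boundary at all within
$n \le 100$ (its minimum at $t = 0$ stays above $1/10$). The default is
therefore `sided = "positive"`.

## Trial classification

Classification is purely a function of the task sequence, the stimuli
and the response mapping, so the simulator can attach ground-truth
effects to exactly the features the pipeline later recovers.

* **Competitor count**: irrelevant dimensions whose activated rule maps
  to the key opposite the correct response (0-3; over the 16 stimuli the
  counts are exactly {0:2, 1:6, 2:6, 3:2} for any task and mapping).
* **BI label**: ABA if task N equals task N-2 within the block, CBA
  otherwise; trials with fewer than two same-block predecessors stay
  unclassified. BI ignores response alternation (a set-level effect).
* **CRS label**: requires response alternation (correct keys of N-1 and
  N differ). CRS+ when the feature of N's relevant dimension repeats
  from N-1 (the now-relevant rule was activated and, under alternation
  with two keys, necessarily competed); CRS- when that feature changed
  (the activated rule of that dimension was necessarily compatible —
  the competitor-rule-priming control holds by construction in a
  two-key design).
* **Competitor-remains-competitor (CRC) control**: trial N is dropped
  from the CRS cells when any dimension irrelevant in N repeats a
  feature that competed in N-1. Under response alternation such a rule
  has become response-compatible, so both its lingering suppression and
  its response priming would contaminate either CRS cell. (The literal
  reading "competes in both trials" is unsatisfiable under response
  alternation with two keys and would make the control vacuous.)
* **Interference equating**: a CRS+ predecessor holds at least one
  competitor (the now-relevant rule itself) and a CRS- predecessor at
  most two, so the conditions are equated by restriction to the shared
  support — one or two competitors in trial N-1. The interference
  distribution of trial N itself is identical across conditions by
  construction and needs no restriction. Within the shared support the
  two conditions still weight the {1, 2} levels differently; this
  residual imbalance is a documented limitation (it is inert in the
  generator, where previous-trial interference has no effect on trial
  N).
* **Exclusion flags**: the first four trials of each block, the two
  trials after an error, stimuli repeating all four features of the
  previous trial (feature-binding control), and RTs outside 100-3000 ms
  (RT analyses only). Errors are excluded from RT means but retained
  for error proportions. Sequence-dependent flags never cross block
  boundaries. CRS validity additionally requires the predecessor trial
  to be correct and itself clean of first-four/post-error flags; a
  full-repetition flag on the predecessor does not invalidate trial N,
  since it confounds that trial's own RT, not the sequence information.

With these rules an error-free 7x64-trial session yields on average
about 280 classifiable CBA and 140 ABA trials (the exact 2:1 split of
the 420 post-removal trials) and about 40 retained CRS trials per
condition, consistent with the design's stated expectations (~280,
~140, ~43).

## Index computation and participant exclusions

Because tasks are drawn randomly under the 100%-switch constraint,
conditions can over-represent the faster spatial tasks; cell means are
therefore computed per task within each condition first and then
averaged across tasks with equal weights. RT cells use correct,
in-bounds, non-excluded trials; error-proportion cells use all
non-excluded trials.

Participant-level exclusions run in a fixed order: incomplete sessions;
an error cap of 40% computed on all trials (applied before the robust
step so outliers cannot distort the group median); exclusion beyond 2.5
scaled median absolute deviations (consistency constant 1.4826) from
the group median of overall RT and overall PE, within each experimental
group separately; minimum-trial rules; and an optional equipment
(offset-delay) filter with configurable thresholds (30/36 ms) and
comparator — the filter's published description reads as excluding
*small* delays, which appears inverted, so the direction is explicit
and surfaced in the report rather than hard-coded.

Two open points were resolved as follows. The minimum-trial rule
(at least 20 RT trials per condition, at least 5 per task x condition
cell) applies the per-task-cell floor to the congruency and BI cells
only: CRS spreads ~40 retained trials per condition over four tasks, so
a joint rule would exclude nearly every simulated participant, which is
incompatible with the scale of exclusions the design anticipates; CRS
stability is protected by the per-condition floor instead. Missing
cells propagate as missing indices, never as zeros.

Questionnaire composites: the free-will inventory score is the mean of
its five 1-7 items; subjective fatigue is the mean of tired, bored and
the reverse-coded (8 minus rating) alert and energetic items, so high
means more fatigue; locus of control counts internal choices over 23
binary items. Cronbach's alpha uses the standard variance-ratio
formula.

## The generative model

The simulator is a stand-in for the data-producing process, not a
fitted model of it; the real study specifies no trial-level generative
form. Expected RT is linear in the classified features,

$$\mathrm{RT} = \beta_0 - s\,[\text{spatial task}] + c\,n_{\mathrm{comp}}
  + b\,[\text{ABA}] + q\,[\text{CRS+}] + u_i + \varepsilon,$$

with participant intercepts $u_i \sim N(0, 100^2)$, normal
heterogeneity on $c, b, q$ across participants, and ex-Gaussian
residuals ($\sigma = 50$ ms, $\tau = 100$ ms) — the standard
descriptive family for RT data. Errors are Bernoulli with probability
`base_error_rate` $+$ `error_slope` $\times n_{\mathrm{comp}}$
(defaults 0.05 and 0.02). Stimuli are drawn uniformly per trial with no
repetition constraint; the full-repetition exclusion handles identical
consecutive stimuli downstream, as in the real design.

Defaults are anchored in the study's own summary statistics: effect
means $c = 34$ ms/competitor, $b = 25$ ms, $q = 35$ ms match the
reported index means (342.77/10, 24.47, 35.01 ms), and the
heterogeneity SDs (27, 50, 80 ms) were back-solved once so that the
simulated between-participant index SDs approximate the reported ones
(283, 53, 86 ms) after adding the measurement noise implied by the
trial counts. The spatial-task advantage defaults to 50 ms (direction
stated by the design, magnitude free); baseline RT is 900 ms, a typical
online four-task switching level.

Group effects are injected on the effect *parameters*: a standardized
difference `group_d` shifts the anti group's parameter mean by
`group_d` x the assumed index SD (divided by 10 for the congruency
slope, since the linear contrast scales the slope by ten). This makes
the replication scenario — a d = 0.5 shift on an index — constructible
by design. The questionnaire generator maps latent normal traits to
rounded, clamped 1-7 ratings; the free-will belief manipulation shift
(default d = 0.70, the reported manipulation-check magnitude) is
applied on the latent scale after calibrating against the item model's
composite SD, $\sqrt{1.2^2 + 0.8^2/5 + 1/12}$, so the realized
composite-score d recovers the target up to slight clamping
attenuation.

What the generator does *not* emulate: sequential adaptation
(post-error slowing, conflict adaptation), within-session fatigue or
practice drifts, response-repetition priming at the motor level,
previous-trial interference effects, or item-level questionnaire
structure beyond a single latent trait. Passing recovery tests
therefore show that the pipeline measures what the generator encodes;
they cannot certify behaviour on real data with these richer dynamics.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state; there is no hidden global state. The test suite
checks the SBF operating characteristics with 2,000 simulated studies
per scenario, parameter recovery and null calibration with 500
simulated participants each, and the trial-count expectations with 500
sessions — sizes chosen so Monte-Carlo error sits comfortably inside
the stated tolerances while the suite stays fast. The acceptance script
uses 10,000 studies per scenario, the size the original design analysis
reports.

## Known limitations

* The CRS controls (priming, CRC, equating) are operationalized from
  their verbal descriptions; the cited methodological literature may
  differ in detail, and the retained-trial count (~40 per condition) is
  correspondingly approximate (~7% below the design's printed ~43).
* The residual within-support imbalance of previous-trial interference
  between CRS conditions is not reweighted.
* The one-sided SBF default is an empirical resolution of an
  underdetermined published description, not a documented fact about
  the original code.
* The generator's linear-additive RT structure is a convenience; none
  of the acceptance checks depend on its exact distributional shape,
  only on the sequence/stimulus combinatorics and the effect means.
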