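---
title: "Methods: the Sequential Choice Model pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Sequential Choice Model pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The Sequential Choice Model (SCM) holds that a simultaneous choice between
two learned options is not resolved by a comparative deliberation but by a
race between the same latency processes each option elicits when
encountered alone. Writing $L_A, L_B$ for independent draws from the
options' no-choice latency distributions,

$$P(\text{choose } A) \;=\; P(L_A < L_B)
  \;=\; \int_0^\infty f_A(t)\, S_B(t)\, dt ,$$

and the latency of a choice is the winning draw $\min(L_A, L_B)$. Two
consequences structure the whole package. First, choice proportions are
predictable from no-choice latencies alone — implemented as a resampling
Monte Carlo (`predict_preference()`) and as adaptive quadrature over
parametric laws (`analytic_preference()`), each serving as the other's
check. Second, *cross-censorship*: an option's latency is observed in
choice only when it wins, so the winner-latency distribution is the
unconditional one reweighted by the rival's survival function,
$dF_w(t) \propto S_B(t)\,dF_A(t)$, which is stochastically smaller.
Shortening is therefore predicted for every option and is larger for the
less-preferred (more often censored) option; lengthening is never
predicted. These are theorems about the race, and the test suite checks
them as invariants rather than as tuned numbers.

## The emulated design

Two contexts, each with two options: context AB offers A (5-s delay to
food) and B (10 s); context CD offers C (10 s) and D (20 s). A session is
four 44-trial context visits in alternation (ABAB or BABA by day parity):
40 single-option trials (20 per option) and 4 unrewarded 60-s peak trials
(2 per option) in pseudo-random order with no two peak trials adjacent.
During testing, the first and last two single-option slots of every visit
become simultaneous choice trials offering a cross-context pairing
(A vs C or B vs C), giving 16 choice trials per day.

Reward rate is equalised across contexts through the inter-trial interval:
after every fifth single-option trial the ITI becomes
$30 + (100 - \sum \text{delays})$ seconds, where the sum runs over the
preceding five single-option delays and 100 s is that sum's theoretical
maximum (five 20-s delays). Over each five-trial block, delays plus ITIs
then total a constant 250 s whichever context is in force — the property
`test-design_scheduler.R` verifies on simulated logs. Two reading choices
were open: we count the trial that triggers the adjustment as part of its
own window (the five trials *preceding the ITI*), and we reset the
single-trial counter at each context visit so a window never spans the
45–60-minute break between contexts. Choice and peak trials never enter
the window.

One printed quantity is deliberately ambiguous in the source design: a
7.04-g daily food maximum equals 176 trials × 2 pellets × 20 mg, although
the 16 peak trials are unrewarded (strictly 6.4 g). `food_maximum()`
reproduces the all-trials arithmetic by default and exposes
`basis = "rewarded_only"` for the strict variant, taking no position on
the intent.

## The synthetic subject generator

The generator is a stated world, not a fit. Subjective value is

$$v_i = w_{imm}/d_i + w_{rank}\, r_i, \qquad r_i = \pm 1,$$

and latency is a shifted lognormal,
$L_i = t_0 + \mathrm{LogNormal}(a - b\,v_i,\ \sigma)$, chosen because
latencies are positive, right-skewed and floor-bounded; the additive floor
$t_0$ stands in for psychophysical reaction time. Defaults are solved in
closed form from four anchors that the analysis treats as the conditions
of the world:

* median latencies of 0.565 s for A and 0.654 s for C (the two printed
  medians);
* a race preference of 70% for C over B, which fixes
  $w_{rank} = \Phi^{-1}(0.70)\,\sigma\sqrt2 / (2b)$ because for a shared
  shift and common $\sigma$, $P(L_C < L_B) = \Phi\!\big(b(v_C -
  v_B)/(\sigma\sqrt2)\big)$;
* a B-to-D median ratio above 2 (the strong "worse option of the poorer
  context" separation), which forces the log-median slope to be steep
  ($b = 40$ with $w_{imm} = 1$, $\sigma = 0.5$) and in turn pins
  $t_0 = 0.5633$, $a = 1.7848$.

A consequence worth stating plainly: with these anchors the two
short-delay options sit just above the floor, their above-floor components
differ by a factor $e^4$, and the A-vs-C race saturates near 1. That is
the floor-effect regime the source analysis describes qualitatively — very
short latencies, strong preference — but it means the generator does *not*
reproduce the empirical A-vs-C numbers (observed 80.2% vs predicted
62.1%), which depend on the real birds' heavily overlapping A and C
distributions. Those numbers are not deposited and are not reproducible at
desk scale; nothing in the tests claims otherwise. An optional
`extra_route_p` knob mixes the race with a value softmax to *demonstrate*
the observed-exceeds-predicted dissociation in a high-overlap world
(`sigma_log = 3` in the demo test); it defaults to off and is not an
estimated model.

Between-subject heterogeneity perturbs only the intercept `scale_a`
(Normal SD 0.1). This scales a subject's above-floor latencies by a common
factor, so subjects differ in speed but share identical race
probabilities; the observed-vs-predicted scatter of the pipeline therefore
clusters by pairing rather than spreading along the diagonal as real birds
do. Latency dispersion and the B/D medians are calibration choices, not
reported values — the source gives no numbers for them.

Peak-trial pecking is a thinned Poisson process in 10-ms steps with
intensity $baseline + rate_{max} \exp\{-(t-d)^2/(2(cv\,d)^2)\}$: mode at
the programmed delay, spread proportional to it (scalar timing, Weber
fraction `cv = 0.3`), defaults `rate_max` 3 pecks/s and `baseline` 0.2
pecks/s chosen to give peak-trial peck counts of a few tens, typical for
starling peak procedures. The generator encodes *no* context-dependent
timing distortion, so the B-vs-C peak-time comparison is a true null and
`compare_peak_times()` should reject at the nominal $\alpha$ — which the
acceptance suite checks over 200 replicates.

On choice trials the simulator draws one latency per offered option and
records the minimum: the generative process *is* the race, making the SCM
exactly self-consistent on default synthetic data. The end-to-end
acceptance criterion (observed choices within 3 SE of predictions,
regression slope in [0.8, 1.2]) therefore verifies the pipeline's internal
consistency — scheduler, simulator, resampler, analytics — not the model's
empirical truth.

## The SCM Monte Carlo

`predict_preference()` follows the published recipe: 10,000 experiments of
96 trials each, every trial drawing one latency per option with
replacement from the single-option sample and choosing the smaller. Design
choices:

* **Seeding.** One root seed; experiment $e$ runs on a child stream hashed
  from `(seed, "experiment", e)`, so enlarging `n_experiments` extends the
  run without perturbing earlier experiments (a property under test).
* **Ties** are broken by a fair coin. For identical input samples this
  makes the conditional win probability exactly ½ by symmetry.
* **Error accounting.** Given the two samples, the resampling mean
  converges to the two-sample U statistic
  $\frac{1}{n_an_b}\sum_{ij} \mathbf 1[x_i < y_j]$ (ties half-weighted),
  not to the population probability; the population-level comparison in
  the oracle tests therefore uses the U statistic's sampling SE,
  $\sqrt{p(1-p)(1/n_a + 1/n_b)}$ to first order, *plus* the Monte Carlo SE
  of the mean across experiments. Tests never compare against the closed
  form with the Monte Carlo SE alone, which would be wrongly tight.
* **Per-subject predictions** pool each subject's single-option latencies
  from the last three testing sessions of the relevant pairing — the
  sessions that satisfied the stability criterion and supplied the
  observed choice proportions — then average across subjects, mirroring
  the per-bird simulation design. Session structure within that window is
  not preserved (the source is silent; we pool and say so).

`analytic_preference()` integrates $f_A S_B$ on $(0, \infty)$ with
`stats::integrate` at relative tolerance $10^{-8}$ and handles point
masses exactly, splitting ties ½ to match the race.

## Latency analytics

The cumulative-frequency score of a sample is the mean empirical-CDF
height over a fixed grid, in $[0,1]$; larger means shorter latencies
(greater area under the cumulative curve). The historical score's exact
recipe is not fully specified in the accessible material, so the package
defines the grid explicitly: the pooled empirical deciles of all samples
entering a comparison, shared across conditions — scale-free, reproducible
and antitone under stochastic dominance (a property under test).
Shortening is the score difference (choice − single) on such a shared
grid, paired across subjects when lists are supplied.

Tests follow the source's conventions: proportions are
arcsine-square-root transformed and latency medians log-transformed before t
tests, all tests two-tailed at $\alpha = 0.05$, df $= n - 1$.
Zero-variance inputs yield flagged degenerate results instead of errors.
The stability criterion takes the last three sessions: SD below 10
percentage points and "no visible trend", operationalised — since no
numeric rule exists — as an absolute OLS slope below 5 points/session,
configurable. The slope uses the closed-form least-squares expression so
that a series trending at exactly the threshold is classified unstable
rather than falling to floating-point rounding.

## Peak-curve fitting

Peck timestamps are binned at 1 s over the 60-s window (the bin count
implied by the 60-level time factor of the source ANOVA); binning
conserves counts exactly. The fitted family is the peak-procedure
standard, constant baseline plus Gaussian. The optimiser is L-BFGS-B with
box constraints (peak inside the window, spread positive), initialised at
the 3-bin moving-average argmax with a spread guess from the full width at
half maximum, and restarted from two further spread values to avoid the
collapse-to-spike local minimum observed with single starts on sparse
curves. Because the historical peak-location estimator is unknown, both
the Gaussian `peak_time` and the smoothed argmax are reported;
`compare_peak_times()` consumes the former by default.

## Scaling and budgets

Simulations in the shipped tests are sized to run in well under a minute
per file on one CPU: the acceptance end-to-end run uses 2,000 Monte Carlo
experiments instead of 10,000 (raising the MC SE by $\sqrt 5$, still an
order of magnitude below the binomial SE of the observed proportions it is
compared against), and the type-I-error replication for peak comparisons
uses 200 replicates, giving a $\pm 4.6$-point acceptance band around
$\alpha = 0.05$. Generator defaults themselves are never scaled.

## Known limitations

* The generator has no learning dynamics; subjects are simulated at
  stability, so stability gating in the pipeline always succeeds quickly
  and exercises the criterion's plumbing, not acquisition.
* Race probabilities are homogeneous across synthetic subjects (see
  above); between-subject spread in the preference scatter is sampling
  noise only.
* The A-vs-C floor-effect regime is qualitative: empirical medians are
  matched, full distributional overlap is not.
* No drift-diffusion or accumulator machinery, no repeated-measures ANOVA
  with sphericity corrections; those analyses are routine and outside the
  model's claims.
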