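---
title: "Dataset bias and structured decision noise in risky-choice models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dataset bias and structured decision noise in risky-choice models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choicebias)
```

## The problem

Large collections of human binary risky choices — a participant repeatedly
picks one of two monetary gambles — exist in two flavours: controlled
laboratory studies (the CPC15/CPC18 choice-prediction-competition datasets)
and large-scale online studies (choices13k, collected on a crowdsourcing
platform). Machine-learning models fit on one flavour transfer poorly to the
other: each model's error is consistently smaller on splits of its own
dataset family than on the other family. That asymmetry is the classic
signature of *dataset bias* — the two datasets sample different behaviour,
not just different gambles.

`choicebias` implements the full analysis pipeline for studying this bias:

1. readers for the three gamble-table dialects and a canonical schema;
2. the BEAST agent simulator, used both as a baseline choice model and to
   label a large synthetic problem space (a "cognitive model prior" for
   pre-training neural networks);
3. four reference choice models (sparse SReLU perceptron with sparse
   evolutionary training, a context network, random forest, SVM);
4. a transfer-testing harness (`transfer_matrix()`, `nn_difference()`);
5. handcrafted features of gamble pairs (naive, psychological, and
   higher-order stochastic dominance), group and single-feature regressions,
   and Shapley attributions of the model-disagreement field;
6. the package's centrepiece: a **hybrid generative decision-noise model**
   with MCMC posterior inference and a synthetic-data path that validates
   the inference by parameter recovery.

## The decision-noise model

Online participants' aggregate choice rates are systematically *less
extreme* than laboratory ones, most visibly for gambles where one option
stochastically dominates the other. The hybrid model explains an online
choice rate for a problem with lab-calibrated rate $p$ as a mixture of
guessing and noisy responding:

$$
p_{\text{final}} \;=\; (1 - p_{\text{guess}})\,
  \sigma\!\big(f \cdot \operatorname{logit}(p)\big)
  \;+\; \tfrac12\, p_{\text{guess}},
\qquad
k \sim \operatorname{Binomial}(n,\ p_{\text{final}}),
$$

where $\sigma$ is the logistic function, $f > 0$ multiplies the log odds
(for $0 < f < 1$ every rate shrinks strictly toward equipreference 0.5 — a
standard model of decision noise or, equivalently, limited computational
precision), $p_{\text{guess}}$ is the proportion of participants who choose
at random, $n$ is the number of participants on that problem and $k$ the
observed B-choice count. `logodds_rescale()` and `mixture_predict()` expose
the deterministic parts; `fit_noise_model()` infers $(f, p_{\text{guess}})$.

### Inference choices

* **Likelihood.** One binomial per problem at the mixture mean. An
  alternative — drawing the guesser count $n_{\text{guess}} = p_{\text{guess}} n$
  explicitly and summing two binomials — has the same mean and nearly the
  same variance for the $n$ used here; we prefer the single-binomial form
  because it is the direct likelihood of the published mixture equation and
  keeps the posterior two-dimensional.
* **Priors.** Uniform(0, 2) on $f$ (covering both shrinkage $f<1$ and
  expansion) and Uniform(0, 1) on $p_{\text{guess}}$. Both are flat over
  the scientifically plausible region, so posterior means are dominated by
  the likelihood at the problem counts used anywhere in this package.
* **Degenerate rates.** Lab rates of exactly 0 or 1 are clipped to
  $[10^{-6}, 1 - 10^{-6}]$ before the logit; the same clipping is applied
  in the generative (corruption) direction, so simulation and inference use
  the identical map.
* **Sampler.** JAGS, 10,000 retained draws after 1,000 adaptation and 1,000
  burn-in iterations, single chain by default; `n_chains = 4` gives a
  split-chain R-hat diagnostic. Non-convergence (R-hat > 1.05) raises a
  warning and is recorded in `glance()`, never silently dropped. The two
  parameters are negatively correlated along a ridge (a sharper $f$ can be
  traded against a larger guessing share), so effective sample sizes are
  well below the raw draw count, especially under ~500 problems; at 1,000
  problems the Monte Carlo error of the posterior means is still an order
  of magnitude below the recovery tolerance of 0.05. `tidy()` reports
  central credible intervals; a kernel-density unimodality check per
  parameter is part of `glance()`.

### Parameter recovery

`run_recovery_experiment()` is the package's headline validation: sample a
problem space, label it with BEAST, corrupt with known
$(f, p_{\text{guess}})$, fit, and compare. With the reference conditions
(1,000 problems, 100 participants, $f = 0.6$, $p_{\text{guess}} = 0.25$)
posterior means land within a few hundredths of the truth and the central
95% intervals cover it. `model = "oracle"` feeds the generating lab rates to
the fit, isolating the inference; `model = "rf"` interposes a trained random
forest so that model error propagates into the posterior, as it would with
real data.

## The synthetic problem space

`synth_config()` / `sample_problem_space()` emulate a CPC15-style problem
space: option A is a binary gamble (high payoff log-uniform over the payoff
range, probability from the canonical grid
$\{0.01, 0.05, \dots, 0.95, 0.99, 1\}$), option B is parameterized by
$(H_b, p_{H_b}, L_b)$ plus a lottery shape, and context flags (ambiguity at
rate 0.2, feedback at rate 0.5, payoff correlation mostly 0) are drawn per
problem. B's expected value is coupled to A's (a factor uniform in
[0.6, 1.4]) so that problems are informative rather than one-sided. Shaped
lotteries spread $p_{H_b}$ over `lot_num_b` outcomes: binomial weights
centred on $H_b$ (symmetric) or geometric weights $0.5^i$ (last doubled)
over $H_b + C \pm 2^i$ with $C = \mp(1 + k)$ (skews). All three expansions
leave the conditional mean at exactly $H_b$, which the tests exploit as an
invariant.

The generator's defaults are the package's reference study conditions —
1,000 problems, 100 participants, noise truth $(0.6, 0.25)$ — and were fixed
once, as the conditions under which the recovery property is claimed.

**What the generator does not emulate:** real participant heterogeneity
beyond the guess/noise mixture, sequential (within-block) effects, and the
exact marginal distributions of the historical problem sets. Passing
recovery and transfer-signature tests on synthetic data therefore shows
that the *inference machinery* is correct and that the *bias signature
follows from the noise mechanism*; it does not by itself certify the
historical parameter estimates, which require the original CSVs (see the
README's reproduction section).

## BEAST

Each of `n_agents` (default 4,000) simulated agents chooses gamble A iff

$$[\mathrm{BEV}_A - \mathrm{BEV}_B] + [\mathrm{ST}_A - \mathrm{ST}_B] + e > 0,$$

with best-estimate expected values (BEV), the mean of $\kappa$ draws from
four outcome-sampling tools (ST), and Gaussian noise
$e \sim \mathcal N(0, \sigma^2)$. Agent properties are uniform between 0
and per-property upper bounds (`beast_config()`), and the noise s.d. is
halved when one lottery first-order dominates the other — dominated
problems are easier, so agents err less on them.

Where the original model family leaves freedom, we concretized as follows
and flag each as a fidelity decision rather than a published formula:

* *uniform tool*: draw equiprobably among each lottery's distinct outcomes;
* *sign tool*: draw from the true distribution with payoffs replaced by
  $\operatorname{sign}(x) \cdot \max |x|$ over the problem;
* *pessimism tool*: the minimum outcome;
* *regret tool*: a single shared uniform quantile pushed through both
  lotteries' inverse CDFs;
* ambiguity: an ambiguous option's BEV blends a uniform outcome estimate
  with the minimum outcome, weighted by a per-agent pessimism parameter;
  with feedback, from block 2 onward the agent's BEV moves toward the true
  expected value by a per-agent reliance weight;
* default upper bounds (σ ≤ 7, κ ≤ 3, tool weights ≤ 1) are round values on
  the scale of the published model; `fit_upper_bounds()` re-fits them by
  grid search on any training set, which is how they should be set when
  laboratory data are available.

With all payoffs positive (as in the default generator) the sign tool
returns the same value for both lotteries and cancels, which is what makes
the add-a-constant monotonicity invariant (raising all of B's payoffs never
lowers predicted P(B)) hold exactly under common random numbers. With
mixed-sign payoffs the sign tool can break that cancellation; this is a
known property of the tool definition, not of the implementation.

## Stochastic dominance

`dominance(a, b, order)` evaluates the discrete definitions exactly:
order 1 compares survival functions on the union support; order 2 requires
the running integral of $F_B - F_A$ (piecewise linear between support
points, integrated in closed form) to be nonnegative everywhere with strict
inequality somewhere; order 3 additionally integrates that function once
more (exact trapezoid, since the integrand is piecewise linear) and
requires $EV(A) \ge EV(B)$. Identical lotteries return 0 at every order;
ties are resolved at a $10^{-9}$ tolerance. Lower order implies higher
order by construction of these conditions, and the test suite checks the
nesting on 10,000 random problems.

## Choice models and training

* **Sparse perceptron** (`"bourgin"`): inputs are the 14 problem
  descriptors (six payoffs/probabilities, lottery shape/size, four context
  flags), standardized with statistics from the first dataset the network
  sees; hidden layers of 200/275/100 SReLU units; dropout 0.15; sigmoid
  output; RMSProp. Sparse layers start at density `set_epsilon` (0.2) and
  are rewired each pre-training epoch by `set_step()`: the fraction
  `set_zeta` of smallest-magnitude positive and negative active weights is
  removed and the same number of random connections regrown, conserving the
  connection count exactly. Pre-training (300 epochs at $10^{-3}$,
  validation-checkpointed) is followed by fine-tuning at $10^{-6}$ with the
  masks frozen; from-scratch training uses the higher rate, since $10^{-6}$
  cannot move freshly initialized weights appreciably. SReLU carries four
  learnable parameters per unit (left/right thresholds and slopes),
  initialized to a near-identity leaky shape ($t_\ell = 0$, $a_\ell = 0.2$,
  $t_r = 1$, $a_r = 1$).
* **Context network** (`"peterson"`): $P(A) = g(x_A, p_A, x_B, p_B)$ on
  zero-padded outcome/probability vectors (10 slots per lottery), two
  32-unit sigmoid layers, Adam at $10^{-3}$, no regularization. On very
  small datasets it drives training error toward zero — the overfitting is
  a property of the model class and is asserted, not hidden, in the tests.
* **Random forest / SVM**: the standard implementations
  (500 trees, node size 5, `mtry` 4; RBF kernel, $C = 1$, standardized
  inputs, predictions clipped to $[0, 1]$), both consuming base + naive +
  psychological features.

Tests train these architectures at reduced epoch counts and problem sizes
(tens of epochs, hundreds of problems) — a deliberate scaling choice that
leaves every architectural element (sparsity, rewiring, checkpointing,
SReLU parameters) exercised.

## Features, regressions, attributions

`feature_table()` orients every feature so that positive favours gamble B.
`diff_bev0` uses a half-pessimistic estimate for ambiguous probabilities
(the prior mean of the agents' blend weight); `diff_bev_fb` uses the true
distribution, as revealed by feedback; `p_bet_unbiased1` assumes
independent draws (first, description-only block) while the `_fb` variant
uses the problem's experienced payoff correlation. For unambiguous problems
`diff_bev_fb` coincides with `diff_ev` — the multicollinearity among
"how much better is B" features is a property of the domain and is left in
place.

`regression_table()` reports the nested group regressions (baseline, base,
+naive, +psych, +HOSD); in-sample $R^2$ is nondecreasing by construction.
Single-feature intervals use the Fisher z-transform at the dataset's size.
`shap_attributions()` enumerates all coalitions exactly whenever
$2^m - 2$ fits the 2,048-coalition budget (true for the 10 base features),
with missing features integrated out against a marginal background sample
(default ~100 rows); the constrained weighted least-squares solve makes
local accuracy ($\phi_0 + \sum_j \phi_j = f(x)$) an identity rather than an
approximation, and reduces to the closed form
$\phi_j = \beta_j (x_j - \bar b_j)$ for linear $f$.

## Reading real data

`read_choice_data()` maps the `cpc15`, `cpc18` and `choices13k` column
dictionaries onto the canonical snake_case schema (one row per
problem × block). The CPC18 format additionally allows option A to carry a
lottery shape; such rows cannot be expressed in the earlier format, so the
compatibility filter keeps rows with `LotShapeA == "-"` and
`LotNumA <= 1`. The exact predicate is not spelled out in the literature we
re-implement; the retained fractions reported there (~90% of training, ~72%
of test rows) are the external check, and they require the original files.
Splits (`split_train_test()`) are at the problem level — all blocks of a
problem stay on one side — and stratified by the problem's feedback
condition, which the published analyses leave unspecified.

## Known limitations

* The BEAST sampling-tool formulas and the six agent-property ranges are
  concretizations (flagged above); only aggregate behaviour is calibrated.
  Our agent parameterization carries the four tool weights explicitly
  (scale-invariant, so one is redundant) plus the ambiguity and feedback
  blends.
* The historical acceptance quantities (posterior means 0.2757/0.6236,
  transfer MSEs, Table-style regression numbers) need the original CSVs,
  which are not redistributable with the package; the corresponding tests
  fail cleanly with instructions when the files are absent.
* Aggregate-only data: nothing at the level of individual participants or
  trial order is modelled, mirroring the structure of the source datasets.
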