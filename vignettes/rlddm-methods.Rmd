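---
title: "Modelling stereotype-based associative learning with the RL-DDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stereotype-based associative learning with the RL-DDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlddm)
```

## The task and the scientific question

The probabilistic selection task (PST) presents pairs of faces in which one
member — the *target* — is probabilistically reinforced: choosing it yields
"Correct" feedback with probability 0.80, 0.70 or 0.60 depending on the
pair, and choosing the other face is reinforced with the complementary
probability.  Learners complete 120-trial blocks in which each pair appears
equally often, until every pair's block accuracy reaches its criterion
(0.60 / 0.55 / 0.50, inclusive) or four blocks (480 trials) have elapsed.

The design crosses a between-subject *learning context* (stereotypic vs.
counter-stereotypic occupational or trait associations) with a
within-subject *goodness-of-stereotype-fit* of the reinforced face (high
vs. low facial typicality).  The question the modelling answers is whether
learning is faster for *surprising* targets — high-fit faces in a
counter-stereotypic context, low-fit faces in a stereotypic context — and
which cognitive parameters carry the effect.

## The RL-DDM

Each pair holds two expected values, initialised at 0.5, updated after
every choice by the delta rule for the chosen face only:

$$q' = q + \eta\,(\text{feedback} - q), \qquad \eta \in (0,1).$$

The trial's drift rate is the scaled value difference,
$v = v_\text{scaling}\,(q_\text{target} - q_\text{other})$, and the choice
and response time follow a two-boundary Wiener diffusion with boundary
separation $a$, non-decision time $t_0$, unbiased start ($z_\text{rel} =
0.5$) and unit diffusion coefficient ($s = 1$, the scaling convention that
identifies the other parameters).  Responses are coded so that the *upper*
boundary is the positively reinforced face, not the correct/error
distinction.  Inter-trial variability parameters are deliberately absent.

The first-passage density is evaluated with both the small-time
(Gaussian-term) and large-time (sinusoidal-term) series expansions of the
normalised zero-drift density; at each time point the number of terms each
expansion would need to reach an absolute tolerance of $10^{-7}$ is
computed from the standard truncation bounds and the cheaper expansion is
used.  The two expansions agree to better than $10^{-6}$ relative error
throughout the switching region, so the density is continuous across the
switch (this is tested).  First-passage sampling draws the boundary from
the exact absorption probability
$P(\text{upper}) = \frac{1 - e^{-2 v z a}}{1 - e^{-2 v a}}$ and the
conditional time by inverse-CDF lookup on a quadratically spaced grid of
the integrated density; the grid extends to where the slowest decay mode
$\exp\{-(\pi^2/2a^2 + v^2/2)\,\tau\}$ leaves negligible mass.  A naive
Euler–Maruyama path simulator with its own RNG is kept in the package as an
independent reference for all three quantities.

## Candidate models and hierarchy

Three specifications differ in which factors free $\eta$, $v_\text{scaling}$
and $a$: learning context only (2 cells), goodness-of-fit only (2 cells),
or their crossing (4 cells); $t_0$ is always subject-level and factor-free.
Parameters are sampled on transformed scales — log-odds for $\eta$, log for
$a$ and $t_0$, natural for $v_\text{scaling}$ — with subject-level values
partially pooled under cell-specific group means and SDs.  Priors are
weakly informative and declared (they are this package's choice, not an
attribution): normal(0, 2) on the sampling scales for group means
(normal(1, 2) for $v_\text{scaling}$), half-normal(1) for group SDs.

Estimation is adaptive Metropolis-within-Gibbs: scalar random walks on
subject-level nodes (step sizes tuned toward 44% acceptance during burn-in
and frozen afterwards, keeping the retained chain Markovian), conjugate
Gibbs draws for group means, and random-walk moves on log group SDs.  The
kernel choice is an implementation decision; the contract is the
diagnostics — split-free Gelman–Rubin $\hat R$ across chains (fits are
flagged when any node exceeds 1.01) — and the parameter-recovery properties
exercised in the test suite.  Subject-level $t_0$ is initialised at half
the subject's fastest response, comfortably below the $0.95 \times
\min(\text{rt})$ ceiling that keeps the starting likelihood finite;
proposals with $t_0 \ge \min(\text{rt})$ are rejected through their
$-\infty$ likelihood.

Model comparison uses DIC: $p_D = \bar D - D(\bar\theta)$ with the plug-in
deviance evaluated at the posterior means of the subject-level nodes on
their sampling scales, and $\text{DIC} = \bar D + p_D$.  Posterior
predictive checks draw one joint posterior draw per simulated dataset
(default 50), re-simulate every subject under their observed design *and
observed session length* (the accuracy-criterion stop is disabled in the
replicates), and compare per-pair choice accuracy and RT deciles; a
statistic is covered when the observed value falls in the central 95% of
its simulated distribution.  Conditioning on the observed number of blocks
is deliberate: under criterion termination the session length is highly
stochastic, early trials are slow, and pooled RT statistics would be
dominated by re-rolled lengths rather than by the parameters under check.
Deciles were chosen over full RT densities because they are stable at
desk-scale cohort sizes.

## Directional tests and the prediction-error contrast

Directional hypotheses are summarised by $p_\text{Bayes}$, the proportion
of paired posterior draws *contrary* to the stated direction, with tie
draws counted as contrary (the conservative rule), and by the
complementary posterior odds $\text{BF}_{10} = (1 - p)/p$, reported to the
nearest integer (half up) when at least 1 and as "> 1000" when
$p < 0.001$.  The package documents this formula as posterior odds; it is
not a marginal-likelihood Bayes factor.  The prediction-error contrast
works on the natural $\eta$ scale (learning rates are discussed directly on
that scale): per draw, $\Delta_\text{stereo} = \eta_\text{low} -
\eta_\text{high}$ within the stereotypic context and $\Delta_\text{counter}
= \eta_\text{high} - \eta_\text{low}$ within the counter-stereotypic
context, tested for $\Delta_\text{counter} > \Delta_\text{stereo}$.

## The synthetic cohort generator

Because no behavioural data ship with the package, every downstream stage
is exercised on synthetic cohorts with known ground truth.  Each subject
receives one normal deviation per parameter on its sampling scale, shared
across condition cells (a random intercept), around cell-specific group
means — so condition effects enter strictly through the means, and a truth
whose cell means are equal generates subjects that are genuinely free of
that factor.  Subjects are assigned alternately to learning contexts (and
counterbalance groups within context) and run through full
criterion-terminated sessions
with six pairs (three female, three male; a three-pair single-sex session
remains configurable since the task description admits both readings).

The preset truths fix the *direction* of every effect to the surprise
pattern described above and choose magnitudes once, as plausible
between-subject spreads for this class of task: learning-rate cell means
0.10 / 0.20 (stereotypic high / low fit) and 0.30 / 0.15
(counter-stereotypic high / low), giving surprise advantages of 0.10 and
0.15; drift scaling 2.5–3.5 and boundary separation 1.8–2.2 patterned per
experiment; $t_0$ mean 0.35 s; between-subject SDs 0.4 (log-odds $\eta$),
0.6 ($v_\text{scaling}$), 0.12 (log $a$), 0.15 (log $t_0$).  These
magnitudes are synthetic: the direction is the finding being emulated, the
sizes are generator choices and are documented as such.  The generator
reproduces the model's own assumptions only — it does not emulate RT
outliers, attention lapses, exclusions or any real-data idiosyncrasies, so
passing recovery tests demonstrates internal consistency of the pipeline,
not fidelity to any particular empirical dataset.

```{r cohort, eval = FALSE}
set.seed(1)
cohort <- generate_cohort(preset_expt1(n_per_context = 40))
fit <- fit_rlddm(cohort$log, "integrative",
                 n_samples = 2000, n_burn = 500, seed = 1)
prediction_error_contrast(fit)$test
```

## Problem sizes and numerical choices

The package's own validation runs at desk scale, chosen so the full suite
exercises every stage: recovery cohorts of 40 subjects per context with
full sessions, fitted with 2,000 samples (500 burn; the estimation default
of 10,000/5,000 remains available), model-recovery replicates of 12
subjects per context at 800/300, ten seeds for model recovery and three
for parameter recovery, 50 posterior predictive datasets, $10^5$-draw
sampler checks and a $10^6$-path Euler oracle at $dt = 10^{-4}$.  Series
truncation tolerance is $10^{-7}$; the RT sampler uses a 2048-point grid
for standalone draws and 256 points inside session simulation, keeping its
Kolmogorov–Smirnov distance from the integrated density well under 0.01.

Degenerate inputs are handled explicitly: densities at $t \le t_0$ are
zero rather than errors; a whole-session likelihood is $-\infty$ with a
diagnostic attribute when any RT undercuts $t_0$; zero-variance chains
define $\hat R = 1$; ties in directional tests count against the stated
direction; and the feedback schedule is i.i.d. Bernoulli per trial (an
exact-proportion shuffled schedule was considered and not adopted — the
task description states per-trial probabilities).

## Known limitations

Single learning rate per cell (no positive/negative asymmetry), no decay
of unchosen values, no starting-point bias, no inter-trial variability
parameters, no lapse process — each matches the modelled task description,
but they bound what the model can absorb from real data.  DIC is the only
comparison criterion (WAIC/LOO are out of scope), and the random-walk
kernel, while adequate at the tested sizes, mixes more slowly than
gradient-based samplers would on much larger cohorts.
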