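---
title: "Bayesian network meta-analysis of ALK inhibitors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian network meta-analysis of ALK inhibitors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
what is being modelled, which knobs matter, which design choices were open
and how they were settled, and what the bundled tests do and do not
demonstrate.

## 1. The evidence base and its data model

The package ships the trial-level summaries of 12 randomized phase-III
trials (3169 patients) comparing six ALK inhibitors and platinum-based
chemotherapy in ALK-positive NSCLC.  Everything enters as one of two
observation types:

* **Contrast observations** — a published hazard ratio with its 95% CI
  (PFS, OS, PFS in patients with baseline brain metastases).  On the log
  scale the CI is asymptotically symmetric, so
  `derive_log_hr()` recovers the standard error as
  $s_i = (\log U_i - \log L_i) / (2 z_{0.975})$ with
  $z_{0.975} = 1.959964$ (the exact normal quantile, not 1.96, so derived
  SEs reproduce to four decimals).
* **Arm-level binary observations** — arm size and event percentage (ORR,
  grade ≥ 3 AEs, discontinuation for AEs).  `reconstruct_events()` recovers
  counts as `round(percent × n / 100)` (round half to even).  Published
  safety denominators are not available separately, so the
  intention-to-treat arm sizes are used throughout; the reconstruction
  error is at most half an event per arm.

`build_network()` assembles observations into an `evidence_network`:
deduplicated treatments, per-edge trial counts, and a connectivity check
(a disconnected network admits no common ranking, so it is an error that
names the isolated component).  Two dataset quirks are preserved
deliberately: PROFILE1007 reported no discontinuation data, so that
network has 11 trials; and the CROWN discontinuation percentages are
transcribed exactly as printed in the source table (63.76 / 58.45) even
though the trial's own publication reports about 7% / 9% — the row is
flagged in the network's `notes` rather than silently "corrected".
All twelve trials are two-arm, and the package's scope is limited to
two-arm trials; multi-arm correlation handling is out of scope.

## 2. The Bayesian NMA model

For trial $i$ on edge $a(i)\!\to\!b(i)$, with trial-level effect
$\delta_i$:

* contrast likelihood: $y_i \sim N(\delta_i, s_i^2)$;
* binary likelihood: $r_{ik} \sim \mathrm{Bin}(n_{ik}, p_{ik})$ with
  $\operatorname{logit} p_{i,\mathrm{ctrl}} = \mu_i$ and
  $\operatorname{logit} p_{i,\mathrm{exp}} = \mu_i + \delta_i$.

Under consistency, $\delta_i \sim N(d_{b(i)} - d_{a(i)}, \tau^2)$
(random effects) or $\delta_i = d_{b(i)} - d_{a(i)}$ (fixed effect), where
$d_k$ is the basic parameter of treatment $k$ versus the reference
($d_\mathrm{ref}=0$).  Because every contrast is a difference of basic
parameters, the consistency relation $d_{AB} + d_{BC} = d_{AC}$ holds in
every draw by construction.  The unrelated-mean-effects (UME) model used
as the global-inconsistency benchmark replaces the basic parametrisation
with one free parameter per observed comparison — identical likelihood,
different design matrix.

**Priors.**  The source analysis does not state its priors, so the package
adopts the vague choices common in BUGS/gemtc practice:
$d_k, \mu_i \sim N(0, 10^2)$ and $\tau \sim U(0, U)$ with $U = 2$ for
contrast outcomes and $U = 5$ for binary outcomes (log-odds scales are
wider); $U$ is configurable per fit.  With 12 trials the posterior for
$\tau$ is prior-sensitive in its tail, which mostly widens credible
intervals; posterior medians of the $d_k$ are robust to $U$.

**Sampler.**  Metropolis-within-Gibbs, implemented in Rcpp.  Normal full
conditionals ($\delta_i$, and $d$ given $\delta$ and $\tau$; all of $d$ in
the fixed-effect contrast model) are drawn by exact Gibbs steps; $\mu_i$,
$\tau$, and $d$ in the fixed-effect binary model use random-walk
Metropolis whose per-parameter proposal scales adapt toward a 0.44
acceptance rate during burn-in only, so the retained chain has a fixed
kernel.  Defaults follow the source analysis: 4 chains, 10,000 burn-in
iterations, 50,000 sampling iterations, thinning 2 (100,000 retained
draws).  A thinning factor of 2 is used because the source's stated "2.5"
is not realizable for an integer thinning interval.  Chain $c$ starts all
$d_k$ at offset $(-2, -0.5, +0.5, +2)_c \times 0.1\,\mathrm{sd}_d$ and
$\tau$ spread over $(0,U)$, giving genuinely overdispersed initial values.
All randomness flows through R's RNG: the same seed and spec give
bit-identical draws.

**Convergence** is assessed by split-chain potential scale reduction
factors for every effect parameter and $\tau$ (pass iff all < 1.05), plus
a Geyer initial-positive-sequence effective sample size.  A failed check
flags the fit with a warning — it never silently passes downstream.  At
the default settings every bundled outcome converges with max PSRF < 1.01.

**Summaries.**  `league_table()` reports, for each ordered pair, the
posterior median and 2.5/97.5 percentiles of $\exp(d_\mathrm{col} -
d_\mathrm{row})$ and a two-sided Bayesian p-value
$2\min\{\Pr(\Delta>0), \Pr(\Delta<0)\}$ computed from draw counts (so it
is exactly symmetric in the pair).  The source never defines its
"Bayesian p-value"; this two-sided posterior tail probability is the
definition adopted here, with 0.05 as the significance convention.
`compute_dic()` uses the total residual deviance: $\bar D$, $p_D = \bar D
- D(\hat\theta)$ at posterior means of the trial-level parameters, and
$\mathrm{DIC} = \bar D + p_D$.

## 3. Ranking

`rank_probabilities()` ranks treatments within each draw by $d_k$
(reference included at 0), ascending when lower relative effects are
better (survival, adverse events) and descending for response.  Exact ties
are broken by treatment order; with continuous posteriors this is a
measure-zero event.  SUCRA is
$\sum_{j=1}^{K-1} \Pr(\mathrm{rank}_k \le j) / (K-1)$: 1 means certainly
best, 0 certainly worst, and the mean across treatments is exactly 0.5 —
an algebraic identity the tests exploit.  SUCRA is reported as percent to
two decimals.

## 4. Node-splitting and its power

`node_split()` refits the network giving the split edge's trials their own
direct parameter while the rest of the evidence informs the indirect
contrast; the Bayesian p-value of the direct−indirect difference measures
local inconsistency.  Only edges on a cycle are splittable — in the
bundled PFS network, the crizotinib–alectinib–chemotherapy triangle.
One practical caveat the simulations make explicit: with few trials, the
random-effects split lets the $U(0,2)$ prior on $\tau$ absorb much of a
planted direct–indirect conflict, so its power is low; the fixed-effect
split isolates the conflict and detects a 3-SE shift in most replicates.
Node-split p-values are not multiplicity-adjusted.

## 5. Frequentist companions

Pairwise pooling (fixed-effect and DerSimonian–Laird) is delegated to
`metafor::rma.uni()` behind the package's interface; $I^2$ uses the
truncated Higgins form $100\max(0,(Q-\mathrm{df})/Q)$, which coincides
with metafor's value for DL fits, and is forced to 0 with a
"heterogeneity not estimable" flag for single-study comparisons.  Odds
ratios use the Woolf SE with the Haldane–Anscombe 0.5 correction applied
to all four cells only when some cell is zero (the source is silent; this
is the standard choice); double-zero and double-full tables are excluded
with a warning.  No Knapp–Hartung adjustment is applied, matching the
plain normal-theory intervals of the source.

For publication bias the study effects are pooled across comparisons,
oriented experimental-versus-control.  The Egger test is the classic OLS
regression of $y_i/s_i$ on $1/s_i$ with a $t_{n-2}$ test of the intercept;
the Begg test is Kendall's $\tau$ between standardized deviates and
sampling variances with the tie-corrected normal approximation.  Both are
implemented directly because their textbook variants are pinned down
exactly; `metafor::regtest()` cross-checks Egger in the tests.
Trim-and-fill follows Duval–Tweedie: iterative $L_0$ (default) or $R_0$
estimation of the missing-study count with fixed-effect centering, then
mirror imputation, with the reported original and adjusted estimates
pooled by DerSimonian–Laird.  It is implemented in the package rather
than delegated because the canonical estimator returns $k_0 = 0$ on
exactly symmetric sets — an identity the module guarantees — while
metafor's small-sample side handling does not; on the bundled datasets
both implementations agree ($k_0 = 3$ for PFS and PFS-BM).

## 6. Sensitivity analyses

`leave_one_out()` refits the NMA once per excluded trial, reporting
topology consequences ("treatment dropped", "disconnects network") instead
of failing, and deriving each refit's seed from the primary seed plus the
trial index so the whole table is reproducible.  `exclude_trial()` covers
the targeted PROFILE1029 analysis.  `bland_altman_fe_re()` compares fixed-
and random-effects league tables on the log scale (mean difference and
±1.96 SD limits); simulations show the limits widen with the generating
$\tau$ once study precisions are unequal — with equal precisions FE and RE
point estimates coincide regardless of $\tau$, which is why the test
design uses a wide SE range.  The brain-metastases subgroup is treated as
its own outcome network rather than a covariate model.

## 7. The synthetic-data generator

`generate_contrast_network()` and `generate_binary_network()` simulate
exactly the data-generating process the engine assumes: known basic
effects $d$, trial effects $N(d_b-d_a, \tau^2)$, then either a
normal contrast with known SE or binomial arms on a logit baseline with
$N(0, 0.1^2)$ baseline jitter.  Topologies: `star`, `loop`, and
`paper_like` (the bundled PFS network's exact shape: 7 treatments, 7
edges, 12 trials).  A single seeded RNG stream with a documented
per-trial draw order makes every dataset a pure function of its config.
Defaults (arm sizes 100–200, contrast SEs 0.1–0.3, baseline event
probability 0.4, $\tau = 0.1$) mirror the bundled trials' scale: their
derived log-HR SEs span roughly 0.13–0.5 and arm sizes 35–189.

What the generator does *not* emulate — and what passing tests therefore
cannot show about real data: treatment crossover after progression,
non-proportional hazards compressed into a single HR, outcome-dependent
reporting, correlated outcomes within a trial, and multi-arm trials.  The
parameter-recovery suite (50 replicates of the paper-like network at
reduced draws, aggregate 95%-interval coverage ≥ 90%) validates the
machinery under its own assumptions, nothing more.

## 8. Numerical choices and degenerate inputs

* $z_{0.975} = 1.959964$ everywhere a 95% normal interval is formed.
* Zero-width CIs, non-positive HRs, percentages outside [0, 100] and
  inconsistent HR/CI orderings are rejected at parse time.
* Single-study comparisons: DL falls back to the fixed-effect result with
  $\tau^2 = 0$ and a non-estimable-heterogeneity flag, never NaN.
* League tables satisfy `entry(a,b) = 1/entry(b,a)` and a unit diagonal
  exactly; Bayesian p-values are computed from draw counts so the matrix
  is exactly symmetric.
* Trim-and-fill stops after 50 trimming iterations with an error naming
  the oscillating $k_0$ values rather than looping forever.
* The deviance of binomial arms uses the saturated-model form with
  $0\log 0 = 0$ handled explicitly.

## 9. Problem sizes used by the tests

The bundled analyses run at the full default sampler settings (4 × 60,000
iterations; a few seconds per outcome).  Simulation-based properties use
deliberately small designs chosen once: 50 replicates for interval
coverage, 20 for node-split null calibration, 10 for node-split power and
DL $\tau$ recovery, each at 2 chains × 5,000-ish iterations.  These sizes
give comfortable margins for the assertions they support (e.g. observed
coverage ≈ 0.98 against a ≥ 0.90 bound) while keeping the whole suite
under two minutes.

## 10. Known limitations

* Only two-arm trials; no arm-based survival modelling (published HRs are
  taken at face value), no meta-regression, no design-by-treatment
  interaction model (with three loop edges, node-splitting covers local
  inconsistency here).
* The binary-outcome reconstruction inherits any rounding in the printed
  percentages and assumes ITT denominators for safety endpoints.
* OS estimates inherit the crossover contamination of the underlying
  trials; the package quantifies, but cannot correct, that bias.
* The ORR network estimate for alectinib versus crizotinib computed from
  the reconstructed counts (posterior median OR ≈ 2.4, and ≈ 2.2 by a
  deterministic GLS cross-check) is substantially larger than the value
  printed in the source publication, whose own credible-interval width
  matches ours while its centre does not; the package reports what the
  printed data imply.
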