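---
title: "Segmenting genes into regulatory states with a regression hidden Markov model"
author: "reghmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting genes into regulatory states with a regression hidden Markov model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reghmm)
```

## The scientific problem

Histone modifications near a gene's transcription start site (TSS) predict
its expression level, but not equally well for all genes: constitutively
expressed genes, for instance, appear to be governed by other layers of
regulation. Rather than fitting one regression of expression on
promoter-proximal histone-mark signal for the whole genome, this package
fits a **mixture of linear regressions whose mixture component follows a
Markov chain along the genome**. Each hidden state carries its own
regression of expression on the predictors, and neighbouring genes tend to
share a state, with a persistence that decays with the physical distance
between them. Decoding the hidden states segments the gene set into groups
with distinct regulatory relationships — typically a strongly
histone-associated state and a weakly associated, higher-expressed state.

## The model

Order the $T$ genes of a chromosome by TSS coordinate and let
$O_t = (x_t, y_t)$ be gene $t$'s standardized predictor vector
($x_t \in \mathbb{R}^p$; window-averaged, rank-normalized histone signal)
and expression ($y_t$, also rank-normalized). A hidden state
$q_t \in \{1, \dots, M\}$ selects the regression in force:

$$ y_t \mid x_t, q_t = i \;\sim\; N\!\big(\beta_{i0} + x_t^\top \beta_i,\; \sigma_i^2\big). $$

The marginal density of $x_t$ given the state is taken to be 1, so the
emission probability carries only the *relationship* between predictors and
response, not the predictor distribution itself; with $M = 1$ the model is
ordinary least squares.

**Distance-dependent transitions.** With $d_t$ the distance in bp between
genes $t-1$ and $t$, the transition matrix is

$$ A(d_t) \;=\; e^{-d_t/D}\, I \;+\; \big(1 - e^{-d_t/D}\big)\, P , $$

where $P = (p_{ij})$ is a baseline stochastic matrix estimated from the
data and $D$ is a predetermined distance constant (default 4000 bp, on the
order of the spacing below which neighbouring genes share chromatin
context). At $d = 0$ the state persists with probability 1; as
$d \to \infty$ transitions mix freely according to $P$; the probability of
staying in the same state increases with $D$. Chromosomes are independent
chains, each starting from the initial distribution $\pi$ (the model is
silent about inter-chromosomal distances, so nothing else is defensible).

## Estimation

`reghmm()` maximizes the marginal likelihood by Baum–Welch EM:

* **E step** — a scaled forward–backward pass (implemented in C++ for the
  long-chain loop) yields the exact log-likelihood, posterior state
  probabilities $\gamma_t(i)$ and expected transition counts. Scaling per
  position makes chains of any length immune to underflow.
* **M step** — each state's coefficients are re-estimated by weighted
  least squares with weights $\gamma_t(i)$, and $\sigma_i^2$ as the
  $\gamma$-weighted mean squared residual. $\pi$ comes from the chain-start
  posteriors. Because $A(d)$ is a *mixture* of "stay" and "draw from $P$",
  the textbook transition update does not apply to $P$ directly; the
  package treats the stay-versus-draw indicator as an additional latent
  variable and updates $p_{ij}$ from the expected counts attributed to the
  $P$-draw. This keeps the complete EM monotone in the likelihood (checked
  to $10^{-8}$ per iteration in the test suite). $D$ is never estimated.
* **Restarts** — EM is restarted from independent random initializations
  (default 20; each assigns genes to random states and fits per-group
  least squares). The best restart by log-likelihood is kept. Convergence
  is declared when the relative log-likelihood gain falls below $10^{-6}$
  (at most 500 iterations).

**Numerical safeguards.** Residual variances are floored at $10^{-6}$ so a
state cannot collapse onto interpolating a handful of genes; a state whose
total posterior weight falls below $p + 2$ is left at its previous
parameters and flagged. Viterbi ties break toward the lower state index.
Degenerate inputs (non-finite values, negative distances, non-stochastic
$P$) are rejected at the door.

**Label convention.** The likelihood is invariant to permuting state
labels, so after fitting, states are reordered by decreasing within-state
$R^2$ of the decoded segmentation: "state 1" is always the state whose
expression the predictors explain best.

**Model size.** The number of states is chosen by maximizing
$\mathrm{BIC} = L_M - \tfrac{1}{2} N_M \log T$ with
$N_M = M(p+1) + M + M(M-1) + (M-1)$ free parameters (coefficients,
variances, baseline transitions, initial probabilities);
`reghmm(markov = FALSE)` fits the independent mixture of regressions
($N_M = M(p+2) + (M-1)$) whose BIC is directly comparable and quantifies
what the Markov structure buys.

## Preprocessing conventions

`window_average()` produces the predictor matrix from bedGraph-like
tracks: the mean signal in non-overlapping windows (default 200 bp) tiling
TSS ± 1 kb. Coordinates are 0-based half-open. Window columns are ordered
along the *transcription direction* — for a minus-strand gene the genomic
order is reversed — so that an offset such as "+500" is biologically
comparable across strands. Windows overlapping a masked interval, running
past the chromosome start, or lacking signal coverage are flagged rather
than silently truncated, and flagged genes are removed by the standard
filter chain (`filter_genes()`: unmatched annotation, strand mismatch,
masked windows, zero expression, duplicate TSSs — the duplicate-TSS
collapse keeps the highest-expression record, a choice the upstream data
description leaves open).

`quantile_normalize()` maps the value of rank $r$ among $n$ to
$\Phi^{-1}\!\big((r - 0.5)/n\big)$; the half-rank offset avoids infinite
endpoints. Ties are broken once, before ranking, by adding $N(0, 0.01)$
noise (SD 0.1; `jitter_sd` makes the scale explicit since "$N(0,0.01)$"
could be read as either variance or SD). `condition_number()` reports
$\sqrt{\lambda_{\max}/\lambda_{\min}}$ of $X^\top X$ with the conventional
multicollinearity cutoff of 30.

## The synthetic-data generator

`synthetic_spec()` + `simulate_reghmm_data()` generate complete datasets
with known truth: gene positions with log-scale inter-gene gaps, a hidden
state path from the distance-dependent chain, state-conditional
multivariate-normal predictors (AR(1) correlation within each mark,
block-diagonal across marks), expression from the state regressions, and
state-biased binary annotations. Defaults encode the study conditions:

* two states, intercepts **0.25 / 1.15** and within-state $R^2$ targets
  **0.7 / 0.4**;
* the response is rank-normalized in the real pipeline, so the generator
  calibrates slope scale to give overall $\mathrm{var}(y) \approx 1$:
  with the intercept gap of 0.9 this fixes within-state variance at
  $\approx 0.80$ and residual SDs at 0.49 / 0.69;
* slope *patterns* are opposed between states, reflecting the observed
  contrast in per-variable signed $R^2$ (strong positive marginal
  associations in state 1, weak and partly negative ones in state 2);
* $D = 4000$ bp, uniform baseline transitions, uniform $\pi$;
* one chromosome with log-uniform gaps in $[10^2, 10^6]$ bp, spanning the
  empirical inter-gene-distance range;
* one mark × 10 windows ($p = 10$) for fast tests; `n_marks = 7` gives
  the full 70-column layout;
* a CpG-island-like label with per-state rates 0.59 / 0.70.

**What the generator does and does not emulate.** It reproduces the
distance-decaying state persistence, the two-regression emission
structure, state-dependent predictor means, and state-biased annotations.
It does **not** reproduce read-level noise, realistic peak shapes, or the
real data's predictor-correlation geometry; in particular, because the
synthetic states differ in slope *pattern* while the real states appear to
differ mainly in association *strength* and intercept, the pooled
single-regression $R^2$ is much lower on synthetic data than in the real
analysis. Passing tests therefore validate the estimation machinery and
the qualitative orderings (combined $>$ single; state 1 predicted better
than a pooled model), not the real data's absolute numbers, which depend
on unreleased processed matrices.

## Validation experiment design

The test-suite experiments run at sizes chosen to exercise the method
while keeping a full run in minutes:

* **Exactness**: forward–backward and Viterbi agree with brute-force
  enumeration over all $M^T$ paths ($T \le 8$, $M \le 3$, 200 random
  instances, $|\Delta| < 10^{-9}$).
* **Recovery**: 10 replicate genomes of $T = 2000$ genes under the study
  conditions, 5 restarts. Gaps are drawn log-uniform from $[10^2, 10^4]$
  bp — the persistence decades — because a recovery experiment should
  engage the model's Markov structure: when most gaps exceed $D$ the chain
  is effectively an independent mixture and per-gene state identity is
  ambiguous at the stated $R^2$ levels (decoding with the *true*
  parameters then tops out near 87%), a regime that tests the data rather
  than the estimator. Under the persistence geometry the fitted models
  recover coefficients with RMSE well under 0.1 and decode >85% of states
  correctly.
* **Selection**: BIC over $M \in \{1,2,3\}$ picks the generating $M$ on
  both two-state and one-state data; the regHMM's BIC beats the no-Markov
  mixture on persistent data.
* **Calibration**: under a homogeneous null the resampling $R^2$-difference
  test produces uniform p-values (KS check over 200 meta-replicates).

## Downstream analyses

`per_state_ols()` reports per-state regressions, the combined $R^2$
(response regressed on concatenated per-state fitted values) and the
pooled single-regression $R^2$. `signed_r2()` gives each predictor's
univariate $R^2$ signed by its slope. Mean and coefficient contrasts
between states use Welch t-tests and independent-sample z-tests with
Bonferroni correction (denominators: the number of predictors for mean
tests, coefficients including the intercept for coefficient tests, tested
categories for the annotation scan — the upstream description says only
"Bonferroni").

`enrichment_test()` uses the Yates-corrected chi-square by default: on the
2×2 tables reconstructed from the printed state totals this dialect
reproduces the published enrichment p-values to their printed precision,
while the uncorrected statistic does not; uncorrected and Fisher-exact
variants are available by flag. Expected cell counts under 5 trigger a
warning suggesting the exact test.

The two resampling tests follow the published procedures:
`r2_difference_simtest()` re-splits the pooled gene set 1000 times into
the observed group sizes and counts splits whose absolute $R^2$ difference
reaches the observed one (two-sided by absolute value, non-strict
comparison, no pseudo-count — at 1000 replicates the resolution is
$10^{-3}$); `r2_extremity_simtest()` draws random same-size gene sets and
counts how often their $R^2$ falls on the requested side of the observed
value, reporting the null range alongside.

## Held-out prediction

New genes carry no usable chain context (their neighbours' states are
unknown), so `build_profiles()` summarizes each state's training
predictors by a multivariate normal (sample mean, sample covariance,
ridge-regularized by $10^{-6}\,\mathrm{tr}(V)/p$ when ill-conditioned) and
`assign_states()` assigns each test gene to the state maximizing
$\phi_m\, p_m(z)$ in log space, with $\phi_m$ the training state share and
ties going to the weaker-association state. Expression is then predicted
by the assigned state's regression, and evaluation regresses true on
predicted expression (with intercept, the standard simple-regression
convention). `kfold_evaluate()` wraps the cycle with gene-wise random
folds (default five); training chains recompute distances between retained
neighbours, accepting that removing a fold stretches some gaps.

## Known limitations

* The exponential-interpolation transition form is adopted from the
  model's stated limiting properties; other monotone decays would satisfy
  them too, and $D$ is fixed rather than estimated.
* BIC uses the marginal log-likelihood; a Viterbi-joint variant would
  penalize differently.
* The baseline transition matrix is weakly identified when most gaps
  exceed $D$; its maximum-likelihood estimate can drift from the truth
  without harming the likelihood, which slightly degrades Viterbi decoding
  in the mixing regime.
* The independence-across-chromosomes assumption and the gene-wise CV
  folds both ignore long-range dependence.
* Annotation labels are user-supplied tables; nothing is fetched from
  databases.

## A minimal session

```{r example, eval = FALSE}
spec <- synthetic_spec(n_genes = 1000,
                       distance_law = list(type = "log-uniform",
                                           min = 1e2, max = 1e4),
                       seed = 1)
d <- simulate_reghmm_data(spec)
fit <- reghmm(d$x, d$y, dist = d$genes$dist_prev, states = 2,
              restarts = 5, seed = 2)
summary(fit)
sel <- select_states(d$x, d$y, dist = d$genes$dist_prev, M_range = 1:3,
                     restarts = 5, seed = 3)
sel$table
```
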