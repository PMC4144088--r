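# reghmm

Regression hidden Markov models for segmenting genes by the strength of
the histone-modification / expression relationship.

## What problem this solves, and for whom

Averaged histone-mark signal around a gene's transcription start site
(TSS) predicts its expression, but a single genome-wide regression hides
real heterogeneity: some genes (e.g. housekeeping genes) are poorly
explained by chromatin marks and appear to answer to other regulatory
layers. `reghmm` is for computational biologists and statisticians who
want to *segment* a gene set into regulatory states defined by that
relationship — and who want the segmentation to respect genomic context,
because neighbouring genes tend to share chromatin environment.

## The model

Genes are ordered along each chromosome. Gene *t* carries a standardized
predictor vector *x<sub>t</sub>* (window-averaged, rank-normalized
histone signal over TSS ± 1 kb) and expression *y<sub>t</sub>*. A hidden
state *q<sub>t</sub>* ∈ {1, …, M} selects the regression in force:

> y<sub>t</sub> | x<sub>t</sub>, q<sub>t</sub> = i  ~  N(β<sub>i0</sub> + x<sub>t</sub>′β<sub>i</sub>, σ<sub>i</sub>²)

and the state sequence is a non-homogeneous Markov chain whose transition
matrix depends on the distance *d<sub>t</sub>* between adjacent genes:

> A(d) = e<sup>−d/D</sup> · I + (1 − e<sup>−d/D</sup>) · P

with baseline stochastic matrix *P* (estimated) and distance constant
*D* (fixed, default 4000 bp). Adjacent genes persist in the same state;
distant genes mix freely. Estimation is Baum–Welch EM with multi-start
(scaled forward–backward in C++), decoding is Viterbi, and the number of
states is chosen by maximizing BIC = L − ½·N·log T. A no-Markov mixture
of regressions (`markov = FALSE`) provides the baseline that quantifies
what the chain structure buys.

Around the core model the package provides the full analysis pipeline:
preprocessing from bedGraph-like tracks (`window_average`,
`quantile_normalize`, `filter_genes`, `condition_number`), state
characterization (`per_state_ols`, `signed_r2`, `compare_state_means`,
`compare_state_coefficients`, `enrichment_test`, `go_frequency_scan`,
`add_binary_covariate`, resampling R² tests), held-out prediction via
per-state multivariate-normal predictor profiles (`build_profiles`,
`assign_states`, `kfold_evaluate`), a fully specified synthetic-data
generator (`synthetic_spec`, `simulate_reghmm_data`), and a config-driven
driver (`run_pipeline`).

## Worked example

Simulate a 1000-gene chromosome under the package's study-condition
defaults (two states with intercepts 0.25 / 1.15 and within-state R² of
about 0.7 / 0.4, D = 4000 bp, gaps drawn from the persistence decades)
and refit it:

```r
library(reghmm)

spec <- synthetic_spec(n_genes = 1000,
                       distance_law = list(type = "log-uniform",
                                           min = 1e2, max = 1e4),
                       seed = 1)
d <- simulate_reghmm_data(spec)
fit <- reghmm(d$x, d$y, dist = d$genes$dist_prev, states = 2,
              restarts = 5, seed = 2)
summary(fit)
```

```
Regression hidden Markov model (distance-dependent Markov states), 2 state(s), 1000 gene(s), 10 predictor(s)
log-likelihood -1119.7378  BIC -1212.9925  (27 parameters, converged after 15 iterations)
genes per decoded state: 350 / 650 

Per-state ordinary least squares on the decoded segmentation:
               condition n_genes         r2
                 State 1     350 0.77294431
                 State 2     650 0.43399502
         Combined states    1000 0.61707981
 All (single regression)    1000 0.07384496

Intercepts: 0.2509 / 1.1846  residual SD: 0.4863 / 0.6885 
```

State 1 is (by the package's labeling convention) the state whose
expression the marks explain best: here R² = 0.77 versus 0.43, the
recovered intercepts 0.25 / 1.18 match the generating 0.25 / 1.15, and
the decoded path agrees with the true states for 88% of genes. Combining
the two state-specific fits explains far more variance (0.62) than one
pooled regression (0.07) — the signature of genuinely distinct regulatory
states. BIC picks the generating number of states:

```r
select_states(d$x, d$y, dist = d$genes$dist_prev, M_range = 1:3,
              restarts = 5, seed = 3)
```

```
State-number selection by BIC (larger is better)
 M    loglik n_params       bic
 1 -1369.803       12 -1411.250
 2 -1119.738       27 -1212.993
 3 -1093.186       44 -1245.157
chosen number of states: 2
```

See the methods vignette (`vignettes/reghmm-methods.Rmd`) for the model,
estimation details, the generator's calibration, and design decisions.

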