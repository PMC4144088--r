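test_that("gene positions follow the requested gap law", {
  # degenerate single gene
  g1 <- gen_positions(1, seed = 1)
  expect_equal(nrow(g1), 1L)
  expect_true(is.na(g1$dist_prev))

  # constant law pins every gap
  gc <- gen_positions(50, list(type = "constant", value = 4000), seed = 1)
  expect_true(all(gc$dist_prev[-1] == 4000))
  expect_true(all(diff(gc$tss) > 0))

  # log-uniform gaps: log10(d) approximately uniform over the stated range
  gl <- gen_positions(10000, list(type = "log-uniform", min = 10, max = 1e7),
                      seed = 42)
  ks <- suppressWarnings(ks.test(log10(gl$dist_prev[-1]), "punif", 1, 7))
  expect_gt(ks$p.value, 0.01)

  expect_error(gen_positions(0), "n_genes")
})

test_that("state paths have the prescribed transition law", {
  # single state: constant path
  expect_true(all(gen_state_path(c(NA, 1:9), matrix(1, 1, 1), 4000, 1,
                                 seed = 1) == 1L))

  # zero gaps: self-transition probability 1, path constant
  st0 <- gen_state_path(c(NA, rep(0, 99)), matrix(.5, 2, 2), 4000,
                        c(.5, .5), seed = 2)
  expect_equal(length(unique(st0)), 1L)

  # D -> 0 limit: transitions reduce to the baseline matrix
  P <- rbind(c(.7, .3), c(.2, .8))
  n <- 1e5
  st <- gen_state_path(c(NA, rep(1, n - 1)), P, D = 1e-9, pi = c(.5, .5),
                       seed = 3)
  emp <- prop.table(table(head(st, -1), st[-1]), 1)
  for (i in 1:2) for (j in 1:2) {
    se <- sqrt(P[i, j] * (1 - P[i, j]) / sum(head(st, -1) == i))
    expect_lt(abs(emp[i, j] - P[i, j]), 3 * se)
  }

  expect_error(gen_state_path(c(NA, 1), matrix(.5, 2, 2), 4000, c(.5, .5, 0)),
               "disagree")
})

test_that("predictors are state-conditional multivariate normal", {
  spec <- synthetic_spec(n_genes = 10, seed = 1)
  states <- rep(1:2, each = 5000)

  X <- gen_predictors(states, spec, seed = 4)
  for (m in 1:2) {
    mns <- colMeans(X[states == m, ])
    se <- sqrt(diag(spec$predictor_cov)) / sqrt(5000)
    expect_true(all(abs(mns - spec$state_means[m, ]) < 4 * se))
  }
  expect_equal(colnames(X), feature_colnames(1, 10))

  # degenerate zero covariance: rows equal the state means exactly
  spec0 <- spec
  spec0$predictor_cov <- matrix(0, spec$p, spec$p)
  X0 <- gen_predictors(states[1:4], spec0, seed = 5)
  expect_equal(unname(X0), unname(spec$state_means[states[1:4], ]),
               tolerance = 1e-12)

  # identical means across states carry no state information
  specn <- synthetic_spec(n_genes = 10, state_means = matrix(0, 2, 10))
  Xn <- gen_predictors(states, specn, seed = 6)
  expect_lt(abs(mean(Xn[states == 1, 1]) - mean(Xn[states == 2, 1])), 0.1)
})

test_that("expression follows the state-specific regressions", {
  spec <- synthetic_spec(n_genes = 10, seed = 1)
  states <- rep(1:2, 50)
  X <- gen_predictors(states, spec, seed = 7)

  # no noise: exactly the state linear predictor
  y0 <- gen_expression(X, states, spec$betas, c(0, 0))
  mu <- cbind(1, X) %*% t(spec$betas)
  expect_equal(y0, mu[cbind(seq_along(states), states)], tolerance = 1e-12)

  # zero slopes: y ~ N(intercept, 1)
  b0 <- cbind(c(.25, 1.15), matrix(0, 2, 10))
  n <- 1e4
  yb <- gen_expression(matrix(rnorm(n * 10), n, 10), rep(1L, n), b0,
                       c(1, 1), seed = 8)
  expect_lt(abs(mean(yb) - 0.25), 4 / sqrt(n))

  # shared slopes, intercepts 0.25 / 1.15: group means differ by ~0.9
  bs <- rbind(c(.25, spec$betas[1, -1]), c(1.15, spec$betas[1, -1]))
  Xs <- matrix(rnorm(n * 10), n, 10)
  sts <- rep(1:2, length.out = n)
  ys <- gen_expression(Xs, sts, bs, c(.3, .3), seed = 9)
  expect_equal(mean(ys[sts == 2]) - mean(ys[sts == 1]), 0.9, tolerance = 0.05)

  expect_error(gen_expression(X, states, spec$betas, c(-1, 1)), "non-negative")
})

test_that("signal tracks reproduce their window-average oracle", {
  genes <- toy_genes(tss = c(10000, 20000, 30000),
                     strand = c("+", "-", "+"))
  # constant signal: every window average is the constant
  vals <- matrix(3.5, 3, 10)
  tr <- gen_signal_track(genes, values = vals)
  wa <- window_average(tr, genes)
  expect_true(all(abs(wa - 3.5) < 1e-12))

  # random oracle, mixed strands, matches stored matrix
  tr2 <- gen_signal_track(genes, seed = 10)
  wa2 <- window_average(tr2, genes)
  expect_equal(bare(wa2), bare(attr(tr2, "oracle")), tolerance = 1e-10)

  # overlapping genes with contradictory values are rejected
  close_genes <- toy_genes(tss = c(10000, 10400))
  expect_error(gen_signal_track(close_genes, seed = 11), "contradictory")
})

test_that("full dataset generation is seed-reproducible and coherent", {
  d1 <- small_sim(n = 200, seed = 99)
  d2 <- small_sim(n = 200, seed = 99)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$states, d2$states)
  expect_identical(d1$genes, d2$genes)

  expect_equal(nrow(d1$x), 200L)
  expect_true(all(d1$states %in% 1:2))
  expect_equal(nrow(d1$annotations), 200L)

  # annotation rates differ by state as specified
  big <- small_sim(n = 5000, seed = 100)
  r1 <- mean(big$annotations$cpg[big$states == 1])
  r2 <- mean(big$annotations$cpg[big$states == 2])
  expect_lt(abs(r1 - 0.59), 0.04)
  expect_lt(abs(r2 - 0.70), 0.04)
})

test_that("per-state residual structure matches the generating model", {
  d <- small_sim(n = 10000, seed = 7)
  spec <- d$spec
  mu <- cbind(1, d$x) %*% t(spec$betas)
  for (m in 1:2) {
    res <- d$y[d$states == m] - mu[cbind(which(d$states == m), m)]
    expect_lt(abs(mean(res)), 4 * spec$sigmas[m] / sqrt(length(res)))
    expect_lt(abs(sd(res) - spec$sigmas[m]), 0.03)
    ks <- suppressWarnings(ks.test(res / spec$sigmas[m], "pnorm"))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("fixtures round-trip through disk exactly", {
  d <- small_sim(n = 100, seed = 5)
  dir <- withr::local_tempdir()
  write_fixture(d, dir)
  back <- read_fixture(dir)
  expect_identical(bare(back$x), bare(d$x))
  expect_equal(back$y, d$y, tolerance = 1e-12)
  expect_identical(back$states, d$states)
  expect_identical(back$genes$accession, d$genes$accession)
  expect_equal(back$genes$dist_prev, d$genes$dist_prev)
  expect_equal(back$spec$betas, d$spec$betas, tolerance = 1e-12)
  expect_identical(unname(unlist(back$annotations)),
                   unname(unlist(d$annotations)))
})
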