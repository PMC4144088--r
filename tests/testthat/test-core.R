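test_that("emission log-densities equal the normal density of residuals", {
  x <- matrix(rnorm(20), 10, 2)
  beta <- rbind(c(0, 1, -1), c(2, 0.5, 0.5))
  sig <- c(0.7, 1.3)
  y <- rnorm(10)
  ld <- emission_logdensity(x, y, beta, sig)
  # independent evaluation straight from the density formula
  for (m in 1:2) {
    mu <- beta[m, 1] + x %*% beta[m, -1]
    ref <- -0.5 * log(2 * pi * sig[m]^2) - (y - mu)^2 / (2 * sig[m]^2)
    expect_equal(ld[, m], drop(ref), tolerance = 1e-12)
  }
  # at the fitted mean with unit variance the log density is -log(2*pi)/2
  y_at <- drop(beta[1, 1] + x %*% beta[1, -1])
  ld0 <- emission_logdensity(x, y_at, beta, c(1, 1))
  expect_equal(ld0[, 1], rep(-0.5 * log(2 * pi), 10))
  expect_error(emission_logdensity(x, c(y[-1], NA), beta, sig), "non-finite")
})

test_that("distance-dependent transitions interpolate identity and baseline", {
  P <- rbind(c(.5, .5), c(.3, .7))
  expect_equal(transition_matrix(0, P, 4000), diag(2))
  expect_equal(transition_matrix(1e12, P, 4000), P, tolerance = 1e-9)
  # hand arithmetic at d = D with p_ii = 0.5
  A <- transition_matrix(4000, matrix(.5, 2, 2), 4000)
  expect_equal(A[1, 1], exp(-1) + (1 - exp(-1)) * 0.5, tolerance = 1e-12)
  expect_equal(A[1, 1], 0.6839397, tolerance = 1e-6)
  # rows are probability vectors; self-transition monotone in d and in D
  ds <- c(0, 100, 1000, 4000, 2e4, 1e6)
  selfs <- vapply(ds, function(d) transition_matrix(d, P, 4000)[1, 1],
                  numeric(1))
  expect_true(all(diff(selfs) <= 1e-12))
  Ds <- c(500, 2000, 4000, 16000)
  selfD <- vapply(Ds, function(D) transition_matrix(1000, P, D)[1, 1],
                  numeric(1))
  expect_true(all(diff(selfD) >= -1e-12))
  expect_true(all(abs(rowSums(transition_matrix(123, P, 4000)) - 1) < 1e-12))
  expect_error(transition_matrix(-1, P, 4000), "non-negative")
})

test_that("forward-backward matches the path-enumeration oracle", {
  set.seed(11)
  for (k in 1:25) {
    M <- sample(1:3, 1)
    T_obs <- sample(2:8, 1)
    inst <- random_instance(M, T_obs)
    bf <- brute_force_hmm(inst$x, inst$y, inst$params, inst$dist)
    fb <- forward_backward(inst$x, inst$y, inst$params, dist = inst$dist)
    expect_lt(abs(bf$loglik - fb$loglik), 1e-9)
    expect_lt(max(abs(bf$gamma - fb$gamma)), 1e-9)
    expect_lt(max(abs(bf$xi_sums - fb$xi_sums)), 1e-9)
    expect_lt(max(abs(bf$pstar_sums - fb$pstar_sums)), 1e-9)
    expect_true(all(abs(rowSums(fb$gamma) - 1) < 1e-10))
  }
})

test_that("forward-backward handles degenerate chains", {
  inst <- random_instance(2, 1)
  fb <- forward_backward(inst$x, inst$y, inst$params, dist = NA)
  ld <- emission_logdensity(inst$x, inst$y, inst$params$beta,
                            inst$params$sigma)
  expect_equal(fb$loglik, log(sum(inst$params$pi * exp(ld))),
               tolerance = 1e-12)
  expect_equal(drop(fb$gamma),
               as.numeric(inst$params$pi * exp(ld)) /
                 sum(inst$params$pi * exp(ld)),
               tolerance = 1e-12)

  # identical emissions across states decouple from the chain
  params <- reghmm_params(c(.4, .6), rbind(c(.8, .2), c(.3, .7)), 4000,
                          rbind(c(1, 2), c(1, 2)), c(1, 1))
  x <- matrix(rnorm(30), 30, 1)
  y <- rnorm(30)
  fb2 <- forward_backward(x, y, params, dist = c(NA, rep(1000, 29)))
  expect_equal(fb2$loglik, sum(dnorm(y, 1 + 2 * x, 1, log = TRUE)),
               tolerance = 1e-9)
})

test_that("multiple chromosomes are independent chains", {
  set.seed(12)
  inst <- random_instance(2, 6)
  chain <- c(1, 1, 1, 2, 2, 2)
  dist <- inst$dist
  dist[4] <- NA
  fb_joint <- forward_backward(inst$x, inst$y, inst$params, dist = dist,
                               chain = chain)
  bf1 <- brute_force_hmm(inst$x[1:3, , drop = FALSE], inst$y[1:3],
                         inst$params, dist[1:3])
  bf2 <- brute_force_hmm(inst$x[4:6, , drop = FALSE], inst$y[4:6],
                         inst$params, c(NA, dist[5:6]))
  expect_equal(fb_joint$loglik, bf1$loglik + bf2$loglik, tolerance = 1e-9)
})

test_that("the M step reduces to per-group least squares at hard labels", {
  set.seed(13)
  d <- small_sim(n = 300, seed = 13)
  params <- reghmm_params(d$spec$pi, d$spec$baseline_transitions, 4000,
                          d$spec$betas, d$spec$sigmas)
  gamma <- cbind(d$states == 1, d$states == 2) * 1
  chain_start <- c(TRUE, rep(FALSE, 299))
  up <- m_step(d$x, d$y, gamma, diag(2), chain_start, params)
  for (m in 1:2) {
    idx <- d$states == m
    ref <- lm(d$y[idx] ~ d$x[idx, ])
    expect_equal(unname(up$beta[m, ]), unname(coef(ref)), tolerance = 1e-9)
  }

  # all mass on one state: that state's fit is plain OLS on everything
  gamma1 <- cbind(rep(1, 300), rep(0, 300))
  up1 <- m_step(d$x, d$y, gamma1, diag(2), chain_start, params)
  expect_equal(unname(up1$beta[1, ]), unname(coef(lm(d$y ~ d$x))),
               tolerance = 1e-9)
  expect_true(2 %in% attr(up1, "degenerate"))
})

test_that("EM from the truth is a fixed point on noiseless data", {
  set.seed(14)
  spec <- synthetic_spec(n_genes = 300,
                         distance_law = list(type = "log-uniform",
                                             min = 1e2, max = 1e4),
                         seed = 14)
  d <- simulate_reghmm_data(spec)
  y0 <- gen_expression(d$x, d$states, spec$betas, c(0, 0))  # exact responses
  # residual SD at the variance floor, so the sigma update is also fixed
  truth <- reghmm_params(spec$pi, spec$baseline_transitions, 4000,
                         spec$betas, c(1e-3, 1e-3))
  fb <- forward_backward(d$x, y0, truth, dist = d$genes$dist_prev)
  up <- m_step(d$x, y0, fb$gamma, fb$pstar_sums,
               c(TRUE, rep(FALSE, 299)), truth)
  # tolerance allows for the rare gene lying near both regression planes
  expect_equal(up$beta, truth$beta, tolerance = 1e-6)
  expect_equal(up$sigma, truth$sigma, tolerance = 1e-6)
})

test_that("Viterbi matches exhaustive path maximization", {
  set.seed(15)
  for (k in 1:15) {
    M <- sample(1:3, 1)
    T_obs <- sample(2:8, 1)
    inst <- random_instance(M, T_obs)
    bf <- brute_force_hmm(inst$x, inst$y, inst$params, inst$dist)
    vit <- viterbi_path(inst$x, inst$y, inst$params, dist = inst$dist)
    expect_identical(vit, bf$viterbi)
  }
  # single state: constant path
  inst <- random_instance(1, 5)
  expect_equal(viterbi_path(inst$x, inst$y, inst$params, dist = inst$dist),
               rep(1L, 5))
  # near-deterministic emissions dominate the transitions
  dd <- simulate_reghmm_data(synthetic_spec(
    n_genes = 100, sigmas = c(1e-4, 1e-4),
    distance_law = list(type = "log-uniform", min = 1e2, max = 1e4),
    seed = 16))
  sharp <- reghmm_params(dd$spec$pi, dd$spec$baseline_transitions, 4000,
                         dd$spec$betas, c(1e-4, 1e-4))
  vit <- viterbi_path(dd$x, dd$y, sharp, dist = dd$genes$dist_prev)
  ld <- emission_logdensity(dd$x, dd$y, sharp$beta, sharp$sigma)
  expect_equal(vit, max.col(ld))
})

test_that("BIC arithmetic and the free-parameter count are correct", {
  expect_equal(bic_score(0, 0, 1), 0)
  expect_equal(bic_score(-100, 10, exp(2)), -110)
  # count the free parameters of a 2-state model directly:
  # M regressions of p slopes + intercept, M variances, M(M-1) free
  # baseline transition entries, M-1 free initial probabilities
  M <- 2; p <- 10
  expect_equal(reghmm:::n_params_reghmm(M, p, markov = TRUE),
               M * (p + 1) + M + M * (M - 1) + (M - 1))
  expect_equal(reghmm:::n_params_reghmm(3, 4, markov = TRUE),
               3 * 5 + 3 + 6 + 2)
  expect_equal(reghmm:::n_params_reghmm(2, 10, markov = FALSE),
               2 * 11 + 2 + 1)
})

test_that("label permutation leaves the likelihood unchanged", {
  set.seed(17)
  inst <- random_instance(3, 8)
  fb <- forward_backward(inst$x, inst$y, inst$params, dist = inst$dist)
  perm <- c(3, 1, 2)
  pp <- reghmm_params(inst$params$pi[perm], inst$params$P[perm, perm],
                      inst$params$D, inst$params$beta[perm, ],
                      inst$params$sigma[perm])
  fb_p <- forward_backward(inst$x, inst$y, pp, dist = inst$dist)
  expect_equal(fb$loglik, fb_p$loglik, tolerance = 1e-10)
})
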