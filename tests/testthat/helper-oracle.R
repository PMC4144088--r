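# Brute-force oracles: enumerate all M^T hidden paths of the
# distance-dependent HMM and compute the marginal likelihood, posteriors,
# expected transition counts (with stay/move attribution) and the argmax
# path directly. Independent of the scaled forward-backward implementation.

enum_paths <- function(M, T_obs) {
  as.matrix(expand.grid(rep(list(seq_len(M)), T_obs)))
}

# full enumeration: loglik, gamma, xi_sums, pstar_sums, viterbi path
brute_force_hmm <- function(x, y, params, dist) {
  T_obs <- length(y)
  M <- length(params$pi)
  logB <- emission_logdensity(x, y, params$beta, params$sigma)
  A_list <- lapply(seq_len(T_obs), function(t)
    if (t == 1 || is.na(dist[t])) NULL
    else transition_matrix(dist[t], params$P, params$D))
  paths <- enum_paths(M, T_obs)
  lp <- log(params$pi)[paths[, 1]] + logB[cbind(1, paths[, 1])]
  if (T_obs > 1) for (t in 2:T_obs) {
    if (is.null(A_list[[t]])) lp <- lp + log(params$pi)[paths[, t]]
    else lp <- lp + log(A_list[[t]])[cbind(paths[, t - 1], paths[, t])]
    lp <- lp + logB[cbind(t, paths[, t])]
  }
  mx <- max(lp)
  loglik <- mx + log(sum(exp(lp - mx)))
  post <- exp(lp - loglik)            # posterior prob of each path
  gamma <- matrix(0, T_obs, M)
  for (t in seq_len(T_obs))
    for (m in seq_len(M))
      gamma[t, m] <- sum(post[paths[, t] == m])
  xi <- pstar <- matrix(0, M, M)
  if (T_obs > 1) for (t in 2:T_obs) {
    if (is.null(A_list[[t]])) next
    w <- exp(-dist[t] / params$D)
    A <- A_list[[t]]
    for (i in seq_len(M)) for (j in seq_len(M)) {
      pr <- sum(post[paths[, t - 1] == i & paths[, t] == j])
      xi[i, j] <- xi[i, j] + pr
      r <- if (A[i, j] > 0) (1 - w) * params$P[i, j] / A[i, j] else 0
      pstar[i, j] <- pstar[i, j] + pr * r
    }
  }
  list(loglik = loglik, gamma = gamma, xi_sums = xi, pstar_sums = pstar,
       viterbi = as.integer(paths[which.max(lp), ]))
}

# random small model instance for property tests
random_instance <- function(M, T_obs, p = 2) {
  P <- matrix(rgamma(M * M, 1) + .05, M, M)
  P <- P / rowSums(P)
  pi <- rgamma(M, 1) + .05
  pi <- pi / sum(pi)
  params <- reghmm_params(pi, P, D = runif(1, 500, 8000),
                          beta = matrix(rnorm(M * (p + 1)), M),
                          sigma = runif(M, .3, 2))
  x <- matrix(rnorm(T_obs * p), T_obs, p)
  st <- sample.int(M, T_obs, replace = TRUE)
  mu <- cbind(1, x) %*% t(params$beta)
  y <- mu[cbind(seq_len(T_obs), st)] + rnorm(T_obs, 0, params$sigma[st])
  dist <- c(NA, round(10^runif(T_obs - 1, 1, 5)))
  list(params = params, x = x, y = y, dist = dist)
}
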