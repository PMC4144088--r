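# ---- chain bookkeeping -------------------------------------------------

# Resolve chain structure from `dist` (NA at the first gene of each
# chromosome) and/or an explicit `chain` id vector. Returns list with
# logical `start` (chain begins here) and numeric `dist` (0 at starts).
resolve_chain <- function(T_obs, dist = NULL, chain = NULL) {
  if (is.null(dist)) dist <- rep(NA_real_, T_obs)
  if (length(dist) != T_obs) stop("'dist' must have one entry per gene")
  start <- is.na(dist)
  if (!is.null(chain)) {
    if (length(chain) != T_obs) stop("'chain' must have one entry per gene")
    start <- start | c(TRUE, chain[-1] != chain[-T_obs])
  }
  start[1] <- TRUE
  if (any(dist[!start] <= 0, na.rm = TRUE))
    stop("inter-gene distances must be positive within a chain")
  dist[start] <- 0
  list(start = start, dist = dist)
}

# ---- E step ------------------------------------------------------------

#' Forward-backward pass for the distance-dependent regression HMM
#'
#' Computes the exact marginal log-likelihood, per-gene posterior state
#' probabilities and expected transition statistics for a non-homogeneous
#' HMM whose step-t transition matrix is
#' `exp(-d_t/D) I + (1 - exp(-d_t/D)) P`, using per-step scaling so that
#' chains of any length are handled without underflow. Chromosomes are
#' independent chains, each re-initialized from `pi`.
#'
#' @param x T x p predictor matrix.
#' @param y length-T response vector.
#' @param params a [reghmm_params()] object.
#' @param dist length-T inter-gene distances; `NA` marks the first gene of
#'   each chromosome.
#' @param chain optional chromosome/chain id per gene.
#' @return list with `loglik`, `gamma` (T x M posteriors), `xi_sums`
#'   (M x M expected transition counts) and `pstar_sums` (expected counts
#'   attributed to the baseline matrix, used to update `P`).
#' @export
forward_backward <- function(x, y, params, dist = NULL, chain = NULL) {
  stopifnot(inherits(params, "reghmm_params"))
  T_obs <- length(y)
  ch <- resolve_chain(T_obs, dist, chain)
  logB <- emission_logdensity(x, y, params$beta, params$sigma)
  if (anyNA(logB)) stop("NaN in emission densities")
  w <- exp(-ch$dist / params$D)
  .fb_cpp(logB, w, params$P, params$pi, ch$start)
}

# ---- M step ------------------------------------------------------------

#' One M step of the Baum-Welch algorithm for the regression HMM
#'
#' Given posteriors from [forward_backward()], re-estimates each state's
#' regression by weighted least squares (weights = posterior state
#' probabilities), residual variances as posterior-weighted mean squared
#' residuals, initial probabilities from chain-start posteriors, and the
#' baseline transition matrix from the expected transition counts
#' attributed to the baseline draw. The distance constant `D` is held
#' fixed throughout.
#'
#' @param x,y data as in [forward_backward()].
#' @param gamma T x M posterior state probabilities.
#' @param pstar_sums M x M baseline-attributed expected transition counts.
#' @param chain_start logical vector marking chain starts.
#' @param params current [reghmm_params()] (carries `D` and fallbacks for
#'   degenerate states).
#' @param sigma_floor lower bound on residual variance to prevent
#'   degenerate collapse (default 1e-6).
#' @return updated [reghmm_params()] with attribute `"degenerate"` listing
#'   states whose total posterior weight was too small to refit.
#' @export
m_step <- function(x, y, gamma, pstar_sums, chain_start, params,
                   sigma_floor = 1e-6) {
  x <- as.matrix(x)
  M <- ncol(gamma)
  p <- ncol(x)
  Xd <- cbind(`(Intercept)` = 1, x)
  beta <- params$beta
  sigma2 <- params$sigma^2
  degenerate <- integer(0)
  for (m in seq_len(M)) {
    wts <- gamma[, m]
    sw <- sum(wts)
    if (sw < p + 2) {              # too little effective mass to refit
      degenerate <- c(degenerate, m)
      next
    }
    fit <- lm.wfit(Xd, y, wts)
    beta[m, ] <- fit$coefficients
    sigma2[m] <- max(sum(wts * fit$residuals^2) / sw, sigma_floor)
  }
  pi_new <- colSums(gamma[chain_start, , drop = FALSE])
  pi_new <- pi_new / sum(pi_new)
  rs <- rowSums(pstar_sums)
  P_new <- params$P
  ok <- rs > 1e-12
  P_new[ok, ] <- pstar_sums[ok, , drop = FALSE] / rs[ok]
  out <- reghmm_params(pi_new, P_new, params$D, beta, sqrt(sigma2))
  attr(out, "degenerate") <- degenerate
  out
}

# ---- initialization ----------------------------------------------------

init_params <- function(x, y, M, D, strategy = c("random", "quantile"),
                        markov = TRUE) {
  strategy <- match.arg(strategy)
  T_obs <- length(y)
  p <- ncol(x)
  grp <- switch(strategy,
    random   = sample.int(M, T_obs, replace = TRUE),
    quantile = {
      br <- quantile(y, probs = seq(0, 1, length.out = M + 1L))
      findInterval(y, unique(br[-c(1, M + 1L)])) + 1L
    })
  Xd <- cbind(1, x)
  beta <- matrix(0, M, p + 1L)
  sigma <- rep(sd(y) + 1e-8, M)
  for (m in seq_len(M)) {
    idx <- which(grp == m)
    if (length(idx) > p + 2) {
      f <- lm.wfit(Xd[idx, , drop = FALSE], y[idx], rep(1, length(idx)))
      beta[m, ] <- f$coefficients
      s2 <- mean(f$residuals^2)
      if (s2 > 1e-8) sigma[m] <- sqrt(s2)
    } else {
      beta[m, 1] <- mean(y) + rnorm(1, 0, sd(y) / 4)
    }
  }
  beta[is.na(beta)] <- 0
  P <- matrix(1 / M, M, M)
  reghmm_params(rep(1 / M, M), P, D, beta, sigma)
}

# ---- single EM run -----------------------------------------------------

em_run <- function(x, y, params, ch, tol, max_iter) {
  w <- exp(-ch$dist / params$D)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  fb <- NULL
  for (it in seq_len(max_iter)) {
    logB <- emission_logdensity(x, y, params$beta, params$sigma)
    fb <- .fb_cpp(logB, w, params$P, params$pi, ch$start)
    trace <- c(trace, fb$loglik)
    if (is.finite(prev) &&
        (fb$loglik - prev) < tol * (abs(prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    prev <- fb$loglik
    params <- m_step(x, y, fb$gamma, fb$pstar_sums, ch$start, params)
  }
  if (!converged) {   # refresh E quantities so they match the returned params
    logB <- emission_logdensity(x, y, params$beta, params$sigma)
    fb <- .fb_cpp(logB, w, params$P, params$pi, ch$start)
    trace <- c(trace, fb$loglik)
  }
  list(params = params, fb = fb, trace = trace, converged = converged,
       n_iter = length(trace))
}

# ---- the user-facing fitting function ---------------------------------

#' Fit a regression hidden Markov model
#'
#' Fits an M-state mixture of linear regressions in which the latent state
#' follows a Markov chain along each chromosome with distance-dependent
#' transition probabilities, by Baum-Welch EM with multiple random
#' restarts. With `markov = FALSE` the latent states are independent and
#' the model is an ordinary mixture of regressions (the no-Markov
#' baseline for BIC comparison).
#'
#' Estimation alternates a scaled forward-backward E step with weighted
#' least squares M steps; the distance constant `D` is a predetermined
#' constant, not estimated. The restart with the highest log-likelihood is
#' returned. States are relabeled by descending within-state R-squared so
#' state 1 is always the state whose expression is best explained by the
#' predictors.
#'
#' @param x T x p matrix of standardized predictors (genes in rows).
#' @param y length-T response vector (expression levels).
#' @param dist length-T inter-gene distances in bp; `NA` marks the first
#'   gene of each chromosome. Ignored when `markov = FALSE`.
#' @param chain optional chromosome id per gene; each chromosome is an
#'   independent chain restarted from the initial distribution.
#' @param states number of hidden states M (default 2).
#' @param D distance constant in bp (default 4000).
#' @param markov if `FALSE`, fit the independent mixture of regressions.
#' @param restarts number of independent EM initializations (default 20).
#' @param init initialization: `"random"` state assignment followed by
#'   per-group least squares, or `"quantile"` split of the response.
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param seed optional integer seed governing all restarts.
#' @param relabel relabel states by descending within-state R-squared
#'   (default `TRUE`).
#' @return an object of class `"reghmm"`: a list with components `params`
#'   ([reghmm_params()]), `loglik`, `bic` (on the `loglik - 0.5 N log T`
#'   scale, larger is better), `gamma` (posterior state probabilities),
#'   `states` (Viterbi path), `loglik_trace`, `restart_logliks`,
#'   `converged`, `n_iter`, `n_params`, and the data used.
#' @seealso [select_states()], [viterbi_path()], [per_state_ols()]
#' @examples
#' spec <- synthetic_spec(n_genes = 300, seed = 1)
#' d <- simulate_reghmm_data(spec)
#' fit <- reghmm(d$x, d$y, dist = d$genes$dist_prev, states = 2,
#'               restarts = 3, seed = 1)
#' fit
#' table(truth = d$states, decoded = fit$states)
#' @export
reghmm <- function(x, y, dist = NULL, chain = NULL, states = 2, D = 4000,
                   markov = TRUE, restarts = 20,
                   init = c("random", "quantile"), tol = 1e-6,
                   max_iter = 500, seed = NULL, relabel = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  M <- as.integer(states)
  T_obs <- length(y)
  p <- ncol(x)
  if (nrow(x) != T_obs) stop("nrow(x) must equal length(y)")
  if (M < 1) stop("'states' must be >= 1")
  if (T_obs <= p + 1) stop("need more genes than predictors to fit")
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, restarts)

  ch <- resolve_chain(T_obs, if (markov) dist else NULL, if (markov) chain else NULL)
  if (markov && M > 1 && is.null(dist))
    warning("no 'dist' supplied; treating all genes as one chain with d = 0 is ",
            "not meaningful - supply distances or use markov = FALSE")

  best <- NULL
  restart_logliks <- numeric(restarts)
  for (r in seq_len(restarts)) {
    set.seed(restart_seeds[r])
    params0 <- if (M == 1L) {
      f <- lm.wfit(cbind(1, x), y, rep(1, T_obs))
      reghmm_params(1, matrix(1, 1, 1), D, matrix(f$coefficients, 1),
                    sqrt(mean(f$residuals^2)))
    } else init_params(x, y, M, D, init, markov)
    run <- if (markov) em_run(x, y, params0, ch, tol, max_iter)
           else em_mixture_run(x, y, params0, tol, max_iter)
    restart_logliks[r] <- run$fb$loglik
    if (is.null(best) || run$fb$loglik > best$fb$loglik) best <- run
    if (M == 1L) { restart_logliks <- restart_logliks[1]; break }
  }
  if (is.null(best) || !is.finite(best$fb$loglik))
    stop("all EM restarts failed to produce a finite log-likelihood")

  params <- best$params
  gamma <- best$fb$gamma
  vit <- .viterbi_cpp(emission_logdensity(x, y, params$beta, params$sigma),
                      exp(-ch$dist / params$D), params$P, params$pi, ch$start)

  n_par <- n_params_reghmm(M, p, markov)
  obj <- structure(list(
    params = params, loglik = best$fb$loglik,
    bic = bic_score(best$fb$loglik, n_par, T_obs),
    gamma = gamma, states = as.integer(vit),
    xi_sums = best$fb$xi_sums, loglik_trace = best$trace,
    restart_logliks = restart_logliks, converged = best$converged,
    n_iter = best$n_iter, n_params = n_par, n_states = M, markov = markov,
    dist = ch$dist, chain_start = ch$start, x = x, y = y, seed = seed,
    call = match.call()), class = "reghmm")
  if (relabel && M > 1L) obj <- relabel_by_r2(obj)
  obj
}

# Reorder state labels by descending within-state R^2 (Viterbi groups) so
# that "state 1" is the strongest-association state, as reported.
relabel_by_r2 <- function(object) {
  M <- object$n_states
  r2 <- vapply(seq_len(M), function(m) {
    idx <- object$states == m
    if (sum(idx) < ncol(object$x) + 2) return(-Inf)
    yhat <- cbind(1, object$x[idx, , drop = FALSE]) %*% object$params$beta[m, ]
    1 - sum((object$y[idx] - yhat)^2) / sum((object$y[idx] - mean(object$y[idx]))^2)
  }, numeric(1))
  perm <- order(r2, decreasing = TRUE)
  if (identical(perm, seq_len(M))) return(object)
  object$params$pi <- object$params$pi[perm]
  object$params$P <- object$params$P[perm, perm, drop = FALSE]
  object$params$beta <- object$params$beta[perm, , drop = FALSE]
  object$params$sigma <- object$params$sigma[perm]
  object$gamma <- object$gamma[, perm, drop = FALSE]
  object$xi_sums <- object$xi_sums[perm, perm, drop = FALSE]
  object$states <- match(object$states, perm)
  object
}

#' Viterbi decoding of the most likely state path
#'
#' Returns the jointly most probable hidden-state sequence given the
#' observations, by dynamic programming in log space. Ties are broken
#' toward the lower state index; each chromosome chain starts from the
#' initial distribution.
#'
#' @param x,y data matrices as in [reghmm()].
#' @param params a [reghmm_params()] object.
#' @param dist,chain chain structure as in [reghmm()].
#' @return integer vector of states in `1..M`.
#' @export
viterbi_path <- function(x, y, params, dist = NULL, chain = NULL) {
  stopifnot(inherits(params, "reghmm_params"))
  ch <- resolve_chain(length(y), dist, chain)
  as.integer(.viterbi_cpp(
    emission_logdensity(as.matrix(x), y, params$beta, params$sigma),
    exp(-ch$dist / params$D), params$P, params$pi, ch$start))
}

# ---- independent mixture (no Markov property) --------------------------

em_mixture_run <- function(x, y, params, tol, max_iter) {
  phi <- params$pi
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  gamma <- NULL
  T_obs <- length(y)
  for (it in seq_len(max_iter)) {
    logB <- emission_logdensity(x, y, params$beta, params$sigma)
    lw <- sweep(logB, 2, log(phi), `+`)
    mx <- apply(lw, 1, max)
    pr <- exp(lw - mx)
    rs <- rowSums(pr)
    ll <- sum(log(rs) + mx)
    gamma <- pr / rs
    trace <- c(trace, ll)
    if (is.finite(prev) && (ll - prev) < tol * (abs(prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    prev <- ll
    params <- m_step(x, y, gamma, diag(colSums(gamma) / T_obs), rep(TRUE, T_obs),
                     params)
    phi <- colMeans(gamma)
    params$pi <- phi
  }
  list(params = params, fb = list(loglik = trace[length(trace)], gamma = gamma,
                                  xi_sums = crossprod(gamma) * 0,
                                  pstar_sums = crossprod(gamma) * 0),
       trace = trace, converged = converged, n_iter = length(trace))
}

# ---- state-number selection -------------------------------------------

#' Select the number of states by BIC
#'
#' Fits the regression HMM for each candidate number of states and returns
#' the score table and the BIC-maximizing M (BIC here is
#' `loglik - 0.5 N log T`, maximized).
#'
#' @inheritParams reghmm
#' @param M_range integer vector of candidate state counts (default 1:6).
#' @param ... passed to [reghmm()].
#' @return list of class `"reghmm_selection"` with `table` (a data frame
#'   of M, loglik, n_params, bic), `best_M`, and `fits` (the fitted models).
#' @export
select_states <- function(x, y, dist = NULL, chain = NULL, M_range = 1:6,
                          D = 4000, restarts = 20, seed = NULL, ...) {
  if (length(M_range) < 1) stop("'M_range' must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(M_range))
  fits <- vector("list", length(M_range))
  names(fits) <- paste0("M", M_range)
  rows <- list()
  for (k in seq_along(M_range)) {
    f <- tryCatch(
      reghmm(x, y, dist = dist, chain = chain, states = M_range[k], D = D,
             restarts = restarts, seed = seeds[k], ...),
      error = function(e) e)
    if (inherits(f, "error")) {
      warning(sprintf("M = %d failed: %s", M_range[k], conditionMessage(f)))
      rows[[k]] <- data.frame(M = M_range[k], loglik = NA_real_,
                              n_params = NA_integer_, bic = NA_real_)
    } else {
      fits[[k]] <- f
      rows[[k]] <- data.frame(M = M_range[k], loglik = f$loglik,
                              n_params = f$n_params, bic = f$bic)
    }
  }
  tab <- do.call(rbind, rows)
  best <- tab$M[which.max(tab$bic)]
  structure(list(table = tab, best_M = best, fits = fits),
            class = "reghmm_selection")
}

#' @export
print.reghmm_selection <- function(x, ...) {
  cat("State-number selection by BIC (larger is better)\n")
  print(x$table, row.names = FALSE)
  cat("chosen number of states:", x$best_M, "\n")
  invisible(x)
}
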