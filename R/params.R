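#' Parameter set for a regression hidden Markov model
#'
#' Bundles the parameters of an M-state regression HMM: initial state
#' probabilities, the baseline transition matrix that governs transitions
#' between distant genes, the distance constant controlling how fast state
#' persistence decays with inter-gene distance, and per-state regression
#' coefficients and residual standard deviations.
#'
#' @param pi numeric vector of M initial state probabilities (sums to 1).
#' @param P M x M baseline transition matrix (rows sum to 1). At inter-gene
#'   distance `d` the effective transition matrix is
#'   `exp(-d/D) * I + (1 - exp(-d/D)) * P`.
#' @param D distance constant in bp (> 0); larger values make adjacent genes
#'   more likely to share a state. Default 4000.
#' @param beta M x (p+1) matrix of regression coefficients, intercept first.
#' @param sigma numeric vector of M positive residual standard deviations.
#' @return an object of class `"reghmm_params"`.
#' @examples
#' p <- reghmm_params(pi = c(.5, .5), P = matrix(.5, 2, 2), D = 4000,
#'                    beta = rbind(c(0.25, 1), c(1.15, 1)), sigma = c(1, 1))
#' transition_matrix(4000, p$P, p$D)
#' @export
reghmm_params <- function(pi, P, D = 4000, beta, sigma) {
  pi <- as.numeric(pi)
  P <- as.matrix(P)
  beta <- as.matrix(beta)
  M <- length(pi)
  if (!isTRUE(all.equal(sum(pi), 1, tolerance = 1e-8)))
    stop("initial probabilities 'pi' must sum to 1")
  if (any(pi < 0)) stop("'pi' must be non-negative")
  if (nrow(P) != M || ncol(P) != M)
    stop("'P' must be an M x M matrix with M = length(pi)")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("rows of 'P' must be probability vectors summing to 1")
  if (!is.numeric(D) || length(D) != 1L || D <= 0)
    stop("'D' must be a single positive number")
  if (nrow(beta) != M) stop("'beta' must have one row per state")
  if (length(sigma) != M || any(sigma <= 0))
    stop("'sigma' must be M positive residual SDs")
  structure(list(pi = pi, P = P, D = D, beta = beta, sigma = as.numeric(sigma)),
            class = "reghmm_params")
}

#' @export
print.reghmm_params <- function(x, digits = 4, ...) {
  M <- length(x$pi)
  cat(sprintf("Regression HMM parameters: %d state(s), %d predictor(s), D = %g bp\n",
              M, ncol(x$beta) - 1L, x$D))
  cat("pi:", format(round(x$pi, digits)), "\n")
  cat("baseline transition matrix P:\n")
  print(round(x$P, digits))
  cat("regression coefficients (intercept first):\n")
  print(round(x$beta, digits))
  cat("residual SD:", format(round(x$sigma, digits)), "\n")
  invisible(x)
}

#' Distance-dependent transition matrix
#'
#' The transition matrix between two adjacent genes separated by `d` bp
#' interpolates between the identity (perfect state persistence at `d = 0`)
#' and the baseline matrix `P` (free mixing as `d` grows):
#' `A(d) = exp(-d/D) * I + (1 - exp(-d/D)) * P`.
#' The self-transition probability is non-increasing in `d` and increasing
#' in `D`.
#'
#' @param d inter-gene distance in bp (>= 0).
#' @param P baseline M x M stochastic matrix.
#' @param D distance constant in bp (> 0).
#' @return M x M stochastic matrix.
#' @export
transition_matrix <- function(d, P, D = 4000) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("'d' must be a single non-negative distance")
  if (D <= 0) stop("'D' must be positive")
  P <- as.matrix(P)
  w <- exp(-d / D)
  w * diag(nrow(P)) + (1 - w) * P
}

#' Per-state log emission densities
#'
#' For each observation (x_t, y_t) and each state i, the log density of
#' y_t under that state's regression:
#' `log N(y_t; beta_{i0} + x_t' beta_i, sigma_i^2)`. The predictors enter
#' only through the regression mean (their own marginal density is taken
#' as 1, so the emission reflects the x-y relationship alone).
#'
#' @param x T x p predictor matrix.
#' @param y length-T response vector.
#' @param beta M x (p+1) coefficient matrix, intercept first.
#' @param sigma M positive residual SDs.
#' @return T x M matrix of log densities.
#' @export
emission_logdensity <- function(x, y, beta, sigma) {
  x <- as.matrix(x)
  beta <- as.matrix(beta)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in 'x' or 'y'")
  if (ncol(beta) != ncol(x) + 1L)
    stop("'beta' must have ncol(x) + 1 columns (intercept first)")
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  mu <- cbind(1, x) %*% t(beta)               # T x M state means
  matrix(dnorm(y, mu, rep(sigma, each = length(y)), log = TRUE),
         nrow = length(y))
}

# number of free parameters for BIC: M regressions with p slopes + intercept,
# M residual variances, M(M-1) free baseline transitions (Markov) or (M-1)
# mixing weights (independent mixture), and (M-1) initial probabilities.
n_params_reghmm <- function(M, p, markov = TRUE) {
  if (markov) M * (p + 2L) + M * (M - 1L) + (M - 1L)
  else        M * (p + 2L) + (M - 1L)
}

#' BIC on the maximized-score scale
#'
#' Computes `loglik - 0.5 * n_params * log(T)`; larger is better. This is
#' the score maximized when selecting the number of states.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param T_obs number of observations.
#' @return numeric scalar.
#' @export
bic_score <- function(loglik, n_params, T_obs) {
  if (T_obs < 1) stop("'T_obs' must be >= 1")
  loglik - 0.5 * n_params * log(T_obs)
}
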