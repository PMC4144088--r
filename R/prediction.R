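# log multivariate-normal density via Cholesky; V must be positive
# definite (callers regularize beforehand).
dmvnorm_log <- function(z, mu, V) {
  R <- chol(V)
  p <- length(mu)
  zc <- sweep(as.matrix(z), 2, mu)
  q <- backsolve(R, t(zc), transpose = TRUE)
  -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(q^2))
}

#' Build per-state predictor profiles from training data
#'
#' Summarizes each state's training predictor distribution by its sample
#' mean and sample covariance, together with the state's share of the
#' training genes (the mixing proportion) and, when a fitted model is
#' supplied, the state regressions used for prediction. Ill-conditioned
#' covariances are ridge-regularized (`1e-6 * trace/p` added to the
#' diagonal) and flagged.
#'
#' @param x_train training predictor matrix.
#' @param states_train decoded state labels of the training genes.
#' @param fit optional fitted [reghmm()] model providing the state
#'   regressions.
#' @return an object of class `"state_profiles"`: list with `mean` (list
#'   of state means), `cov` (list of covariances), `phi` (state
#'   proportions), `beta`, `sigma`, `ridged` (logical per state).
#' @export
build_profiles <- function(x_train, states_train, fit = NULL) {
  x_train <- as.matrix(x_train)
  M <- max(states_train)
  p <- ncol(x_train)
  mu <- cov_l <- vector("list", M)
  ridged <- logical(M)
  n_m <- tabulate(states_train, M)
  for (m in seq_len(M)) {
    idx <- which(states_train == m)
    if (length(idx) < 2) stop("state ", m, " has fewer than 2 training genes")
    mu[[m]] <- colMeans(x_train[idx, , drop = FALSE])
    V <- cov(x_train[idx, , drop = FALSE])
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (length(idx) <= p || min(ev) <= max(ev) * 1e-10) {
      V <- V + diag(1e-6 * sum(diag(V)) / p, p)
      ridged[m] <- TRUE
    }
    cov_l[[m]] <- V
  }
  structure(list(mean = mu, cov = cov_l, phi = n_m / sum(n_m),
                 beta = if (!is.null(fit)) fit$params$beta,
                 sigma = if (!is.null(fit)) fit$params$sigma,
                 ridged = ridged, n = n_m),
            class = "state_profiles")
}

#' @export
print.state_profiles <- function(x, ...) {
  cat(sprintf("State predictor profiles: %d states, %d predictors, phi = %s\n",
              length(x$mean), length(x$mean[[1]]),
              paste(round(x$phi, 3), collapse = "/")))
  invisible(x)
}

#' Assign new genes to states from their predictor profiles
#'
#' Scores each gene under each state's multivariate-normal profile
#' weighted by the state proportion, in log space, and assigns the
#' highest-scoring state. For two states this is: assign state 1 iff
#' `phi * p1(z) > (1 - phi) * p2(z)`; exact ties go to the higher-indexed
#' state.
#'
#' @param x_test matrix of predictors for the genes to assign.
#' @param profiles a [build_profiles()] result.
#' @return integer state labels.
#' @export
assign_states <- function(x_test, profiles) {
  stopifnot(inherits(profiles, "state_profiles"))
  x_test <- as.matrix(x_test)
  M <- length(profiles$mean)
  if (ncol(x_test) != length(profiles$mean[[1]]))
    stop("test predictors do not match the profile dimension")
  score <- vapply(seq_len(M), function(m) {
    lp <- if (profiles$phi[m] > 0) log(profiles$phi[m]) else -Inf
    lp + dmvnorm_log(x_test, profiles$mean[[m]], profiles$cov[[m]])
  }, numeric(nrow(x_test)))
  score <- matrix(score, nrow = nrow(x_test))
  max.col(score, ties.method = "last")
}

#' Predict expression for assigned genes and evaluate per state
#'
#' Predicts expression with each gene's assigned-state regression and,
#' when true expression is supplied, reports the evaluation R-squared per
#' state and overall, computed by regressing the true expression on the
#' predicted expression (simple regression with intercept).
#'
#' @param x_test predictor matrix for the test genes.
#' @param labels assigned state per test gene (from [assign_states()]).
#' @param fit fitted [reghmm()] model (or anything with `params$beta`).
#' @param y_test optional true expression for evaluation.
#' @return list with `y_hat` and, if `y_test` is given, `eval_r2`
#'   (per-state, `NA` for states with too few genes) and `overall_r2`.
#' @export
predict_expression <- function(x_test, labels, fit, y_test = NULL) {
  x_test <- as.matrix(x_test)
  beta <- fit$params$beta
  mu <- cbind(1, x_test) %*% t(beta)
  y_hat <- mu[cbind(seq_len(nrow(x_test)), labels)]
  out <- list(y_hat = y_hat)
  if (!is.null(y_test)) {
    eval_one <- function(idx) {
      if (length(idx) < 3 || sd(y_hat[idx]) == 0) return(NA_real_)
      f <- lm.fit(cbind(1, y_hat[idx]), y_test[idx])
      1 - sum(f$residuals^2) / sum((y_test[idx] - mean(y_test[idx]))^2)
    }
    M <- nrow(beta)
    out$eval_r2 <- vapply(seq_len(M), function(m) eval_one(which(labels == m)),
                          numeric(1))
    out$overall_r2 <- eval_one(seq_along(y_hat))
    out$n_per_state <- tabulate(labels, M)
  }
  out
}

#' k-fold cross-validated prediction
#'
#' Splits genes at random into k folds; for each fold, fits the
#' regression HMM on the remaining genes (chain distances recomputed
#' between retained neighbors), decodes their states, builds predictor
#' profiles, assigns the held-out genes to states from their predictors
#' alone, predicts their expression, and evaluates per state.
#'
#' @param genes data frame with `chrom`, `tss` (for chain rebuilding).
#' @param x,y predictors and expression for all genes.
#' @param k number of folds (default 5).
#' @param states number of hidden states (default 2).
#' @param D distance constant (default 4000).
#' @param restarts EM restarts per fold (default 5).
#' @param seed optional integer seed (fold membership and fits).
#' @param ... passed to [reghmm()].
#' @return list of class `"reghmm_cv"` with `folds` (per-fold data frame:
#'   fold, n_train, n_test, per-state evaluation R-squared, single-model
#'   R-squared) and `assignments` (per-gene fold and assigned state).
#' @export
kfold_evaluate <- function(genes, x, y, k = 5, states = 2, D = 4000,
                           restarts = 5, seed = NULL, ...) {
  if (k < 2) stop("'k' must be >= 2")
  x <- as.matrix(x)
  T_obs <- length(y)
  if (T_obs < 2 * k) stop("too few genes for ", k, " folds")
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = T_obs))
  rows <- vector("list", k)
  assigned <- integer(T_obs)
  for (f in seq_len(k)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    g_tr <- genes[tr, , drop = FALSE]
    ord <- order(g_tr$chrom, g_tr$tss)
    tr <- tr[ord]; g_tr <- g_tr[ord, , drop = FALSE]
    d_tr <- gene_distances(g_tr)
    fit <- reghmm(x[tr, , drop = FALSE], y[tr], dist = d_tr,
                  states = states, D = D, restarts = restarts,
                  seed = sample.int(.Machine$integer.max - 1L, 1), ...)
    prof <- build_profiles(x[tr, , drop = FALSE], fit$states, fit)
    lab <- assign_states(x[te, , drop = FALSE], prof)
    pe <- predict_expression(x[te, , drop = FALSE], lab, fit, y[te])
    single_r2 <- {   # out-of-sample single regression baseline
      b <- lm.fit(cbind(1, x[tr, , drop = FALSE]), y[tr])$coefficients
      yh <- drop(cbind(1, x[te, , drop = FALSE]) %*% b)
      fev <- lm.fit(cbind(1, yh), y[te])
      1 - sum(fev$residuals^2) / sum((y[te] - mean(y[te]))^2)
    }
    assigned[te] <- lab
    rows[[f]] <- data.frame(fold = f, n_train = length(tr), n_test = length(te),
                            t(setNames(pe$eval_r2,
                                       paste0("r2_state", seq_along(pe$eval_r2)))),
                            r2_overall = pe$overall_r2, r2_single = single_r2)
  }
  structure(list(folds = do.call(rbind, rows),
                 assignments = data.frame(fold = fold, state = assigned)),
            class = "reghmm_cv")
}

#' @export
print.reghmm_cv <- function(x, digits = 4, ...) {
  cat("Cross-validated prediction (per fold):\n")
  tab <- x$folds
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

# distances between consecutive TSSs within each chromosome, NA at chain
# starts; input must already be sorted by (chrom, tss).
gene_distances <- function(genes) {
  d <- c(NA_real_, diff(genes$tss))
  new_chrom <- c(TRUE, genes$chrom[-1] != genes$chrom[-nrow(genes)])
  d[new_chrom] <- NA_real_
  d[!new_chrom & !is.na(d) & d == 0] <- 1   # duplicate TSSs kept: minimal gap
  d
}
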