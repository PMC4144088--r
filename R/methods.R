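#' @export
print.reghmm <- function(x, digits = 4, ...) {
  cat(sprintf("Regression hidden Markov model (%s), %d state(s), %d gene(s), %d predictor(s)\n",
              if (x$markov) "distance-dependent Markov states" else "independent mixture",
              x$n_states, length(x$y), ncol(x$x)))
  cat(sprintf("log-likelihood %.4f  BIC %.4f  (%d parameters, %s after %d iterations)\n",
              x$loglik, x$bic, x$n_params,
              if (x$converged) "converged" else "not converged", x$n_iter))
  cat("genes per decoded state:", paste(tabulate(x$states, x$n_states),
                                        collapse = " / "), "\n")
  invisible(x)
}

#' @export
coef.reghmm <- function(object, ...) object$params$beta

#' @export
logLik.reghmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = length(object$y),
            class = "logLik")
}

#' @export
residuals.reghmm <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
fitted.reghmm <- function(object, ...) {
  mu <- cbind(1, object$x) %*% t(object$params$beta)
  mu[cbind(seq_along(object$y), object$states)]
}

#' Summarize a fitted regression HMM
#'
#' Reports per-state gene counts, within-state R-squared from the decoded
#' (Viterbi) segmentation, the combined R-squared (response regressed on
#' the concatenated per-state fitted values), and the single-regression
#' R-squared on all genes — the headline comparison of the analysis.
#'
#' @param object a fitted [reghmm()] model.
#' @param ... unused.
#' @return an object of class `"summary.reghmm"`.
#' @export
summary.reghmm <- function(object, ...) {
  tab <- per_state_ols(object$x, object$y, object$states)
  structure(list(fit = object, state_table = tab), class = "summary.reghmm")
}

#' @export
print.summary.reghmm <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nPer-state ordinary least squares on the decoded segmentation:\n")
  print(summary_table(x$state_table), row.names = FALSE)
  cat("\nIntercepts:", paste(format(round(x$fit$params$beta[, 1], digits)),
                             collapse = " / "),
      " residual SD:", paste(format(round(x$fit$params$sigma, digits)),
                             collapse = " / "), "\n")
  invisible(x)
}

#' Simulate new data from a fitted regression HMM
#'
#' Draws new hidden-state paths along the stored chain structure (using the
#' fitted distance-dependent transitions) and new responses from the
#' state-specific regressions, holding the predictors fixed.
#'
#' @param object a fitted [reghmm()] model.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `nsim` lists, each with `y` and `states`.
#' @export
simulate.reghmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$params
  dist <- object$dist
  dist[object$chain_start] <- NA
  lapply(seq_len(nsim), function(i) {
    st <- gen_state_path(dist, p$P, p$D, p$pi)
    y <- gen_expression(object$x, st, p$beta, p$sigma)
    list(y = y, states = st)
  })
}

#' Predict expression for new genes from a fitted regression HMM
#'
#' New genes carry no chain context, so states are assigned from the
#' predictor profile alone: each state's training predictor distribution is
#' summarized by a multivariate normal (sample mean and covariance of the
#' training genes decoded into that state), and a gene is assigned to the
#' state with the highest mixing-proportion-weighted density. Expression is
#' then predicted by the assigned state's regression.
#'
#' @param object a fitted [reghmm()] model.
#' @param newdata T' x p matrix of predictors for new genes. If omitted,
#'   fitted values for the training genes are returned.
#' @param type `"response"` for predicted expression, `"state"` for the
#'   assigned state labels, `"both"` for a data frame with both.
#' @param profiles optional precomputed [build_profiles()] result.
#' @param ... unused.
#' @return numeric vector, integer vector, or data frame per `type`.
#' @export
predict.reghmm <- function(object, newdata = NULL,
                           type = c("response", "state", "both"),
                           profiles = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(fitted(object))
    if (type == "state") return(object$states)
    return(data.frame(state = object$states, y_hat = fitted(object)))
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x))
    stop("'newdata' must have the same predictors as the training data")
  if (is.null(profiles)) profiles <- build_profiles(object$x, object$states, object)
  st <- assign_states(newdata, profiles)
  mu <- cbind(1, newdata) %*% t(object$params$beta)
  yhat <- mu[cbind(seq_len(nrow(newdata)), st)]
  switch(type,
         response = yhat,
         state = st,
         both = data.frame(state = st, y_hat = yhat))
}

#' Diagnostic plots for a fitted regression HMM
#'
#' Plots the EM log-likelihood trace and the posterior probability of
#' state 1 along the gene order, colored by the decoded state.
#'
#' @param x a fitted [reghmm()] model.
#' @param which which panels to draw (1 = trace, 2 = posterior path).
#' @param ... passed to plotting functions.
#' @export
plot.reghmm <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (1 %in% which)
    plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b", pch = 16,
         cex = .6, xlab = "EM iteration", ylab = "log-likelihood",
         main = "EM trace (best restart)", ...)
  if (2 %in% which && x$n_states > 1)
    plot(seq_along(x$y), x$gamma[, 1], type = "h",
         col = c("firebrick", "steelblue")[pmin(x$states, 2)],
         xlab = "gene order", ylab = "P(state 1 | data)",
         main = "Posterior state probabilities", ylim = c(0, 1), ...)
  invisible(x)
}
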