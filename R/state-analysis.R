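# Fast OLS R^2 (and optionally coefficients/SEs) via QR; used heavily by
# the resampling tests.
ols_r2 <- function(x, y) {
  fit <- lm.fit(cbind(1, x), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

ols_full <- function(x, y) {
  Xd <- cbind(`(Intercept)` = 1, x)
  fit <- lm.fit(Xd, y)
  n <- length(y); k <- fit$rank
  rss <- sum(fit$residuals^2)
  s2 <- rss / (n - k)
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  se <- sqrt(diag(XtX_inv) * s2)
  names(se) <- colnames(Xd)
  list(coefficients = fit$coefficients, se = se, r2 = 1 - rss / sum((y - mean(y))^2),
       sigma2 = s2, n = n, fitted = drop(Xd %*% fit$coefficients),
       residuals = fit$residuals, df_residual = n - k)
}

#' Per-state ordinary least squares
#'
#' Fits one linear regression of expression on the predictors per decoded
#' state, plus the two reference quantities of the headline comparison:
#' the "combined" R-squared (expression regressed on the concatenation of
#' the per-state fitted values) and the "all" R-squared (a single
#' regression on every gene).
#'
#' @param x T x p predictor matrix.
#' @param y length-T expression vector.
#' @param states integer state labels per gene.
#' @return an object of class `"state_ols"`: list with one entry per state
#'   (each with `coefficients`, `se`, `r2`, `sigma2`, `n`), plus
#'   `combined_r2`, `all_r2` and `all` (the single-regression fit). States
#'   with too few genes to fit are reported with `r2 = NA`.
#' @export
per_state_ols <- function(x, y, states) {
  x <- as.matrix(x)
  M <- max(states)
  p <- ncol(x)
  fits <- vector("list", M)
  fitted_comb <- rep(NA_real_, length(y))
  for (m in seq_len(M)) {
    idx <- which(states == m)
    if (length(idx) <= p + 1) {
      fits[[m]] <- list(state = m, n = length(idx), r2 = NA_real_,
                        unfit = TRUE)
      next
    }
    f <- ols_full(x[idx, , drop = FALSE], y[idx])
    f$state <- m
    fits[[m]] <- f
    fitted_comb[idx] <- f$fitted
  }
  ok <- !is.na(fitted_comb)
  combined_r2 <- if (any(ok)) {
    f <- lm.fit(cbind(1, fitted_comb[ok]), y[ok])
    1 - sum(f$residuals^2) / sum((y[ok] - mean(y[ok]))^2)
  } else NA_real_
  all_fit <- ols_full(x, y)
  structure(list(states = fits, combined_r2 = combined_r2,
                 all_r2 = all_fit$r2, all = all_fit),
            class = "state_ols")
}

summary_table <- function(object) {
  stopifnot(inherits(object, "state_ols"))
  rows <- lapply(object$states, function(f)
    data.frame(condition = paste("State", f$state), n_genes = f$n,
               r2 = f$r2))
  rbind(do.call(rbind, rows),
        data.frame(condition = "Combined states",
                   n_genes = sum(vapply(object$states, `[[`, 0L, "n")),
                   r2 = object$combined_r2),
        data.frame(condition = "All (single regression)",
                   n_genes = object$all$n, r2 = object$all_r2))
}

#' @export
print.state_ols <- function(x, digits = 4, ...) {
  cat("Per-state regressions of expression on predictors:\n")
  tab <- summary_table(x)
  tab$r2 <- round(tab$r2, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Signed per-variable R-squared
#'
#' For each predictor and state, the univariate R-squared of expression on
#' that predictor multiplied by the sign of the fitted slope — i.e.
#' `cor(x_j, y)^2 * sign(cor(x_j, y))` — showing both the strength and
#' direction of each marginal association. Zero-variance predictors give 0
#' with a warning.
#'
#' @param x T x p predictor matrix.
#' @param y expression vector.
#' @param states optional state labels; if supplied, one column per state
#'   plus an `"overall"` column.
#' @return matrix (p x n_groups) of signed values in `[-1, 1]`.
#' @export
signed_r2 <- function(x, y, states = NULL) {
  x <- as.matrix(x)
  one <- function(idx) {
    vapply(seq_len(ncol(x)), function(j) {
      xj <- x[idx, j]
      if (sd(xj) == 0) {
        warning("zero-variance predictor: column ", j)
        return(0)
      }
      r <- cor(xj, y[idx])
      r * abs(r)
    }, numeric(1))
  }
  if (is.null(states)) {
    out <- matrix(one(seq_along(y)), ncol = 1,
                  dimnames = list(colnames(x), "overall"))
  } else {
    M <- max(states)
    out <- vapply(seq_len(M), function(m) one(which(states == m)),
                  numeric(ncol(x)))
    out <- cbind(out, one(seq_along(y)))
    dimnames(out) <- list(colnames(x), c(paste0("state", seq_len(M)), "overall"))
  }
  out
}

#' Compare predictor means between two states
#'
#' Welch two-sample t-test per predictor column, with Bonferroni-corrected
#' significance at `alpha / n_tests`.
#'
#' @param x T x p predictor matrix.
#' @param states state labels (exactly two states are compared).
#' @param alpha familywise significance level (default 0.05).
#' @param n_tests Bonferroni denominator (default `ncol(x)`).
#' @return data frame with per-variable means, difference, t statistic,
#'   p-value and significance flag.
#' @export
compare_state_means <- function(x, states, alpha = 0.05, n_tests = ncol(x)) {
  x <- as.matrix(x)
  us <- sort(unique(states))
  if (length(us) != 2) stop("exactly two states are required")
  i1 <- states == us[1]; i2 <- states == us[2]
  if (sum(i1) < 2 || sum(i2) < 2) stop("need >= 2 genes per state")
  rows <- lapply(seq_len(ncol(x)), function(j) {
    if (sd(x[i1, j]) == 0 && sd(x[i2, j]) == 0)
      return(data.frame(variable = colnames(x)[j] %||% j,
                        mean1 = mean(x[i1, j]), mean2 = mean(x[i2, j]),
                        diff = 0, t = NA_real_, df = NA_real_,
                        p = NA_real_, significant = FALSE))
    tt <- t.test(x[i1, j], x[i2, j])
    data.frame(variable = colnames(x)[j] %||% as.character(j),
               mean1 = mean(x[i1, j]), mean2 = mean(x[i2, j]),
               diff = mean(x[i1, j]) - mean(x[i2, j]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, significant = tt$p.value < alpha / n_tests)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare regression coefficients between two independent state fits
#'
#' Normal-theory z-test on each coefficient difference,
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)`, with Bonferroni correction over
#' the tested coefficients (intercept included).
#'
#' @param fit1,fit2 per-state fits from [per_state_ols()] (elements of
#'   `$states`) or any lists with `coefficients` and `se`.
#' @param alpha familywise significance level (default 0.05).
#' @return data frame with differences, z, p, and significance flags.
#' @export
compare_state_coefficients <- function(fit1, fit2, alpha = 0.05) {
  if (is.null(fit1$se) || is.null(fit2$se)) stop("fits must carry standard errors")
  b1 <- fit1$coefficients; b2 <- fit2$coefficients
  se <- sqrt(fit1$se^2 + fit2$se^2)
  z <- (b1 - b2) / se
  p <- 2 * pnorm(-abs(z))
  k <- length(b1)
  data.frame(coefficient = names(b1) %||% as.character(seq_len(k)),
             estimate1 = unname(b1), estimate2 = unname(b2),
             diff = unname(b1 - b2), se = unname(se), z = unname(z),
             p = unname(p), significant = unname(p < alpha / k))
}

#' Enrichment test on a 2x2 state-by-label table
#'
#' Chi-square test of independence with Yates continuity correction by
#' default (the dialect that reproduces the study's printed enrichment
#' p-values); an uncorrected chi-square and Fisher's exact test are
#' available by flag. A warning suggests the exact test when any expected
#' cell count is below 5.
#'
#' @param counts 2x2 matrix of counts, states in rows, label
#'   presence/absence in columns.
#' @param correct apply the Yates continuity correction (default `TRUE`).
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return an object of class `"enrichment_test"`: list with `counts`,
#'   `proportions` (label rate per state), `statistic`, `p.value`,
#'   `method`, `expected`.
#' @export
enrichment_test <- function(counts, correct = TRUE, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("'counts' must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all margins must be positive")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (method == "chisq" && any(expected < 5))
    warning("expected cell count below 5; consider method = \"fisher\"")
  ht <- if (method == "chisq")
    suppressWarnings(chisq.test(counts, correct = correct))
  else fisher.test(counts)
  structure(list(counts = counts,
                 proportions = counts[, 1] / rowSums(counts),
                 statistic = unname(ht$statistic %||% NA_real_),
                 p.value = ht$p.value, method = method,
                 correct = if (method == "chisq") correct else NA,
                 expected = expected),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf("2x2 enrichment test (%s%s): p = %.4g\n", x$method,
              if (identical(x$correct, TRUE)) ", Yates-corrected" else "",
              x$p.value))
  print(x$counts)
  cat("label proportion per state:", format(round(x$proportions, 4)), "\n")
  invisible(x)
}

#' Scan annotation labels for state enrichment
#'
#' For each label with more than `min_count` genes in each state, tests
#' whether the label proportions differ between the two states
#' (chi-square with continuity correction by default), with Bonferroni
#' correction over the tested labels. Genes carrying no label are counted
#' per state and reported.
#'
#' @param annotations data frame with columns `gene` (index into
#'   `states`) and `label`; genes may carry several labels.
#' @param states state labels per gene (two states).
#' @param min_count a label is tested only if each state has more than
#'   this many labeled genes (default 10).
#' @param alpha familywise significance level (default 0.05).
#' @param correct continuity correction (default `TRUE`).
#' @return data frame (one row per tested label) with counts, proportions,
#'   p, Bonferroni-adjusted p and significance; skipped labels in
#'   `attr(, "skipped")`, unannotated gene counts in
#'   `attr(, "unannotated")`.
#' @export
go_frequency_scan <- function(annotations, states, min_count = 10,
                              alpha = 0.05, correct = TRUE) {
  if (nrow(annotations) == 0) stop("empty annotation table")
  us <- sort(unique(states))
  if (length(us) != 2) stop("exactly two states are required")
  n1 <- sum(states == us[1]); n2 <- sum(states == us[2])
  labs <- split(annotations$gene, annotations$label)
  counts <- t(vapply(labs, function(g) {
    g <- unique(g)
    c(sum(states[g] == us[1]), sum(states[g] == us[2]))
  }, numeric(2)))
  testable <- counts[, 1] > min_count & counts[, 2] > min_count
  rows <- lapply(which(testable), function(i) {
    tab <- rbind(c(counts[i, 1], n1 - counts[i, 1]),
                 c(counts[i, 2], n2 - counts[i, 2]))
    p <- suppressWarnings(chisq.test(tab, correct = correct)$p.value)
    data.frame(label = rownames(counts)[i],
               n_state1 = counts[i, 1], n_state2 = counts[i, 2],
               prop_state1 = counts[i, 1] / n1, prop_state2 = counts[i, 2] / n2,
               p = p)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), n_state1 = integer(), n_state2 = integer(),
               prop_state1 = numeric(), prop_state2 = numeric(), p = numeric())
  out$p_bonf <- pmin(out$p * nrow(out), 1)
  out$significant <- out$p < alpha / max(nrow(out), 1L)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  annotated <- unique(annotations$gene)
  attr(out, "skipped") <- rownames(counts)[!testable]
  attr(out, "unannotated") <-
    c(state1 = n1 - sum(states[annotated] == us[1]),
      state2 = n2 - sum(states[annotated] == us[2]))
  out
}

#' Refit per-state regressions with an added binary covariate
#'
#' Adds a 0/1 gene label (e.g. CpG-island overlap or TATA presence) to the
#' predictor set, refits each state's regression, and reports the gain in
#' R-squared, the new intercept, the label's coefficient with a
#' nested-model F-test per state, and a z-test comparing the label's
#' coefficient across the two states.
#'
#' @param x T x p predictor matrix.
#' @param y expression vector.
#' @param states state labels (two states).
#' @param label 0/1 vector per gene.
#' @return list of class `"covariate_effect"` with `per_state` (data
#'   frame: state, r2_base, r2_added, delta_r2, intercept, label
#'   coefficient, se, F, p_F) and `cross_state` (z, p for the coefficient
#'   difference).
#' @export
add_binary_covariate <- function(x, y, states, label) {
  x <- as.matrix(x)
  if (!all(label %in% 0:1)) stop("'label' must be 0/1")
  us <- sort(unique(states))
  rows <- list()
  coefs <- ses <- rep(NA_real_, length(us))
  for (k in seq_along(us)) {
    idx <- which(states == us[k])
    if (length(unique(label[idx])) < 2) {
      rows[[k]] <- data.frame(state = us[k], n = length(idx),
                              r2_base = NA, r2_added = NA, delta_r2 = NA,
                              intercept = NA, coef_label = NA, se_label = NA,
                              F = NA, p_F = NA, note = "label constant in state")
      next
    }
    base <- ols_full(x[idx, , drop = FALSE], y[idx])
    added <- ols_full(cbind(x[idx, , drop = FALSE], label = label[idx]), y[idx])
    q <- length(added$coefficients)
    rss0 <- sum(base$residuals^2); rss1 <- sum(added$residuals^2)
    Fst <- (rss0 - rss1) / (rss1 / added$df_residual)
    pF <- stats::pf(Fst, 1, added$df_residual, lower.tail = FALSE)
    coefs[k] <- added$coefficients[q]; ses[k] <- added$se[q]
    rows[[k]] <- data.frame(state = us[k], n = length(idx),
                            r2_base = base$r2, r2_added = added$r2,
                            delta_r2 = added$r2 - base$r2,
                            intercept = added$coefficients[1],
                            coef_label = coefs[k], se_label = ses[k],
                            F = Fst, p_F = pF, note = "")
  }
  cross <- if (length(us) == 2 && !anyNA(coefs)) {
    z <- (coefs[1] - coefs[2]) / sqrt(ses[1]^2 + ses[2]^2)
    list(diff = coefs[1] - coefs[2], z = z, p = 2 * pnorm(-abs(z)))
  } else list(diff = NA_real_, z = NA_real_, p = NA_real_)
  structure(list(per_state = do.call(rbind, rows), cross_state = cross),
            class = "covariate_effect")
}

#' @export
print.covariate_effect <- function(x, digits = 4, ...) {
  cat("Effect of an added binary covariate per state:\n")
  tab <- x$per_state
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("cross-state coefficient difference: %.4g (z = %.3f, p = %.4g)\n",
              x$cross_state$diff, x$cross_state$z, x$cross_state$p))
  invisible(x)
}

# ---- simulation-based R^2 tests ---------------------------------------

#' Resampling test of an R-squared difference between two gene groups
#'
#' Pools the two groups, repeatedly splits the pool at random into groups
#' of the original sizes, computes the two R-squared values and their
#' absolute difference, and counts the replicates whose difference is at
#' least the observed one; the p-value is that count over the number of
#' replicates.
#'
#' @param idx_a,idx_b integer gene indices of the two groups (disjoint).
#' @param x predictor matrix over all genes.
#' @param y expression vector over all genes.
#' @param n_reps number of random splits (default 1000).
#' @param seed optional integer seed.
#' @return an object of class `"simtest"`: list with `observed`,
#'   `null` (the replicate differences), `count`, `p.value`, `n_reps`,
#'   `sizes`, `seed`.
#' @export
r2_difference_simtest <- function(idx_a, idx_b, x, y, n_reps = 1000,
                                  seed = NULL) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (length(idx_a) <= p + 1 || length(idx_b) <= p + 1)
    stop("each group must have more genes than predictors")
  if (!is.null(seed)) set.seed(seed)
  obs <- abs(ols_r2(x[idx_a, , drop = FALSE], y[idx_a]) -
             ols_r2(x[idx_b, , drop = FALSE], y[idx_b]))
  pool <- c(idx_a, idx_b)
  na <- length(idx_a)
  null <- vapply(seq_len(n_reps), function(i) {
    a <- sample(pool, na)
    b <- setdiff(pool, a)
    abs(ols_r2(x[a, , drop = FALSE], y[a]) - ols_r2(x[b, , drop = FALSE], y[b]))
  }, numeric(1))
  cnt <- sum(null >= obs)
  structure(list(observed = obs, null = null, count = cnt,
                 p.value = cnt / n_reps, n_reps = n_reps,
                 sizes = c(length(idx_a), length(idx_b)), seed = seed,
                 type = "difference"),
            class = "simtest")
}

#' Resampling test of whether a gene set's R-squared is extreme
#'
#' Repeatedly draws random gene sets of the same size from the universe,
#' fits the regression, and counts how often the random R-squared falls on
#' the requested side of the observed one (`side = "less"` asks whether
#' the observed value is significantly small: the count of random values
#' at or below it). The null minimum and maximum are reported.
#'
#' @param idx_subset gene indices of the set under test.
#' @param idx_universe gene indices to draw from (must be at least as
#'   large as the subset).
#' @param x,y data over all genes.
#' @param n_reps number of draws (default 1000).
#' @param side `"less"` (is the observed R-squared small?) or
#'   `"greater"`.
#' @param seed optional integer seed.
#' @return an object of class `"simtest"` with `observed`, `null`,
#'   `count`, `p.value`, `null_range`.
#' @export
r2_extremity_simtest <- function(idx_subset, idx_universe, x, y,
                                 n_reps = 1000, side = c("less", "greater"),
                                 seed = NULL) {
  side <- match.arg(side)
  x <- as.matrix(x)
  if (length(idx_subset) > length(idx_universe))
    stop("subset larger than universe")
  if (length(idx_subset) <= ncol(x) + 1)
    stop("subset too small to fit the regression")
  if (!is.null(seed)) set.seed(seed)
  obs <- ols_r2(x[idx_subset, , drop = FALSE], y[idx_subset])
  ns <- length(idx_subset)
  null <- vapply(seq_len(n_reps), function(i) {
    s <- sample(idx_universe, ns)
    ols_r2(x[s, , drop = FALSE], y[s])
  }, numeric(1))
  cnt <- if (side == "less") sum(null <= obs) else sum(null >= obs)
  structure(list(observed = obs, null = null, count = cnt,
                 p.value = cnt / n_reps, n_reps = n_reps, side = side,
                 null_range = range(null), sizes = ns, seed = seed,
                 type = "extremity"),
            class = "simtest")
}

#' @export
print.simtest <- function(x, ...) {
  cat(sprintf("Simulation-based R^2 %s test: observed = %.4f, p = %g (%d/%d replicates)\n",
              x$type, x$observed, x$p.value, x$count, x$n_reps))
  if (!is.null(x$null_range))
    cat(sprintf("null R^2 range: [%.4f, %.4f]\n", x$null_range[1], x$null_range[2]))
  invisible(x)
}
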