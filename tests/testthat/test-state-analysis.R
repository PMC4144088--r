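test_that("per-state OLS reports exact and null R-squared correctly", {
  set.seed(101)
  x <- matrix(rnorm(600), 200, 3)
  st <- rep(1:2, each = 100)
  beta <- rbind(c(0, 1, -1, 2), c(5, 0.5, 0.5, 0))
  y_exact <- gen_expression(x, st, beta, c(0, 0))
  tab <- per_state_ols(x, y_exact, st)
  expect_equal(tab$states[[1]]$r2, 1, tolerance = 1e-10)
  expect_equal(tab$states[[2]]$r2, 1, tolerance = 1e-10)
  expect_equal(tab$combined_r2, 1, tolerance = 1e-10)

  # independent response: R^2 near the p/(n-1) bias level
  n <- 4000
  xn <- matrix(rnorm(n * 3), n, 3)
  yn <- rnorm(n)
  tabn <- per_state_ols(xn, yn, rep(1L, n))
  expect_lt(tabn$states[[1]]$r2, 0.01)

  # a state too small to fit is reported unfit, not an error
  st2 <- c(rep(1L, 197), rep(2L, 3))
  tab2 <- per_state_ols(x, y_exact, st2)
  expect_true(is.na(tab2$states[[2]]$r2))
})

test_that("combining distinct state fits explains more than one pooled fit", {
  d <- small_sim(n = 600, seed = 102)
  tab <- per_state_ols(d$x, d$y, d$states)
  expect_gt(tab$combined_r2, tab$all_r2)
  expect_true(all(vapply(tab$states, `[[`, 0, "r2") <= 1))
})

test_that("signed per-variable R-squared is signed squared correlation", {
  set.seed(103)
  x <- matrix(rnorm(300), 100, 3)
  y <- x[, 1] * 2 + rnorm(100)
  s <- signed_r2(x, y)
  expect_equal(drop(s), cor(x, y)^2 * sign(cor(x, y)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # perfect positive and negative associations hit the bounds
  expect_equal(unname(signed_r2(cbind(y), y)[1, 1]), 1)
  expect_equal(unname(signed_r2(cbind(-y), y)[1, 1]), -1)
  expect_true(all(abs(s) <= 1))
  # zero-variance column: 0 with a warning
  expect_warning(s0 <- signed_r2(cbind(x[, 1], 1), y), "zero-variance")
  expect_equal(unname(s0[2, 1]), 0)
})

test_that("state mean comparison has power and respects Bonferroni", {
  set.seed(104)
  # a 1-SD mean shift at n = 500 per group is detected
  x <- rbind(matrix(rnorm(500 * 4), 500, 4),
             matrix(rnorm(500 * 4, mean = c(1, 0, 0, 0)), 500, 4, byrow = TRUE))
  st <- rep(1:2, each = 500)
  out <- compare_state_means(x, st, n_tests = 70)
  expect_true(out$significant[1])
  expect_false(any(out$significant[-1]))

  # identical populations: nothing significant at the corrected level
  xnull <- matrix(rnorm(1000 * 10), 1000, 10)
  outn <- compare_state_means(xnull, rep(1:2, 500), n_tests = 70)
  expect_false(any(outn$significant))
})

test_that("coefficient comparison flags only real differences", {
  set.seed(105)
  x <- matrix(rnorm(2000 * 2), 2000, 2)
  st <- rep(1:2, each = 1000)
  # states differ only in the intercept
  y <- gen_expression(x, st, rbind(c(0, 1, -1), c(2, 1, -1)), c(.5, .5))
  tab <- per_state_ols(x, y, st)
  cmp <- compare_state_coefficients(tab$states[[1]], tab$states[[2]])
  expect_true(cmp$significant[cmp$coefficient == "(Intercept)"])
  expect_false(any(cmp$significant[cmp$coefficient != "(Intercept)"]))

  # identical fits: zero differences, nothing significant
  self <- compare_state_coefficients(tab$states[[1]], tab$states[[1]])
  expect_true(all(self$diff == 0))
  expect_false(any(self$significant))
})

test_that("enrichment test dialect matches the printed study values", {
  # housekeeping genes by state: 192 of 10211 vs 239 of 6809
  hk <- enrichment_test(rbind(c(192, 10211 - 192), c(239, 6809 - 239)))
  expect_equal(hk$p.value, 4.693e-11, tolerance = 0.01)
  # TATA-containing genes by state: 1200 of 10211 vs 629 of 6809
  tata <- enrichment_test(rbind(c(1200, 10211 - 1200), c(629, 6809 - 629)))
  expect_equal(tata$p.value, 2.42e-7, tolerance = 0.01)
  # the uncorrected statistic gives a different (smaller) p-value
  expect_lt(enrichment_test(rbind(c(192, 10019), c(239, 6570)),
                            correct = FALSE)$p.value, hk$p.value)

  # balanced table: no association
  expect_equal(enrichment_test(matrix(50, 2, 2))$p.value, 1)
  # symmetric under swapping both rows and both columns
  tab <- rbind(c(30, 70), c(55, 45))
  expect_equal(enrichment_test(tab)$p.value,
               enrichment_test(tab[2:1, 2:1])$p.value)
  expect_warning(enrichment_test(rbind(c(2, 8), c(3, 12))), "expected")
  expect_error(enrichment_test(rbind(c(0, 0), c(1, 2))), "margins")
})

test_that("annotation frequency scan tests only well-populated labels", {
  set.seed(106)
  n <- 2000
  st <- rep(1:2, each = n / 2)
  lab_diff <- rbinom(n, 1, c(0.10, 0.30)[st])      # truly state-biased
  lab_null <- rbinom(n, 1, 0.2)                    # independent of state
  rare <- c(rep(1, 5), rep(0, n - 5))              # below min_count
  ann <- rbind(
    data.frame(gene = which(lab_diff == 1), label = "biased"),
    data.frame(gene = which(lab_null == 1), label = "independent"),
    data.frame(gene = which(rare == 1), label = "rare"))
  out <- go_frequency_scan(ann, st)
  expect_true(out$significant[out$label == "biased"])
  expect_false(out$significant[out$label == "independent"])
  expect_true("rare" %in% attr(out, "skipped"))
  expect_equal(sum(attr(out, "unannotated")),
               sum(!seq_len(n) %in% ann$gene))
  expect_error(go_frequency_scan(ann[0, ], st), "empty")
})

test_that("an added binary covariate is recovered and compared across states", {
  set.seed(107)
  n <- 3000
  x <- matrix(rnorm(n * 3), n, 3)
  st <- rep(1:2, each = n / 2)
  lab <- rbinom(n, 1, 0.5)
  # same true label effect 0.5 in both states
  y <- gen_expression(x, st, rbind(c(0, 1, -1, 0), c(2, 0.5, 0.5, 0)),
                      c(.5, .5)) + 0.5 * lab
  eff <- add_binary_covariate(x, y, st, lab)
  expect_equal(eff$per_state$coef_label,
               c(0.5, 0.5), tolerance = 0.15)
  expect_true(all(eff$per_state$p_F < 1e-6))
  expect_true(all(eff$per_state$delta_r2 > 0))
  # equal effects: cross-state comparison is null
  expect_gt(eff$cross_state$p, 0.05)

  # label constant within a state is flagged, not an error
  lab2 <- lab; lab2[st == 2] <- 1
  eff2 <- add_binary_covariate(x, y, st, lab2)
  expect_match(eff2$per_state$note[2], "constant")
  expect_true(is.na(eff2$cross_state$p))
})

test_that("the R-squared difference resampling test behaves at the extremes", {
  set.seed(108)
  n <- 60
  x <- matrix(rnorm(n * 2), n, 2)
  y <- x[, 1] + rnorm(n, 0, .5)
  # duplicated block: both groups carry identical data, difference 0
  x2 <- rbind(x, x); y2 <- c(y, y)
  st0 <- r2_difference_simtest(1:n, n + 1:n, x2, y2, n_reps = 50, seed = 1)
  expect_equal(st0$observed, 0, tolerance = 1e-12)
  expect_equal(st0$p.value, 1)

  # grossly different noise levels are detected
  ya <- x[, 1] * 2 + rnorm(n, 0, .2)
  yb <- rnorm(n)
  st1 <- r2_difference_simtest(1:n, n + 1:n, rbind(x, x), c(ya, yb),
                               n_reps = 200, seed = 2)
  expect_lt(st1$p.value, 0.05)

  # reproducible under seed
  st2 <- r2_difference_simtest(1:n, n + 1:n, rbind(x, x), c(ya, yb),
                               n_reps = 200, seed = 2)
  expect_identical(st1$null, st2$null)
  expect_error(r2_difference_simtest(1:2, 3:4, x, y), "more genes")
})

test_that("the R-squared extremity test localizes weak subsets", {
  set.seed(109)
  n <- 400
  x <- matrix(rnorm(n * 2), n, 2)
  y <- x[, 1] + rnorm(n, 0, .4)
  # subset whose response is shuffled: R^2 lands in the left tail
  y[1:40] <- sample(y[1:40])
  st <- r2_extremity_simtest(1:40, 41:n, x, y, n_reps = 200, side = "less",
                             seed = 3)
  expect_lt(st$p.value, 0.05)
  expect_true(st$observed < st$null_range[2])

  # single replicate has resolution 1
  st1 <- r2_extremity_simtest(1:40, 41:n, x, y, n_reps = 1, seed = 4)
  expect_true(st1$p.value %in% c(0, 1))
  expect_error(r2_extremity_simtest(1:50, 1:40, x, y), "larger than universe")
})
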