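# Default histone-mark names used for synthetic predictor columns.
DEFAULT_MARKS <- c("H3K4me1", "H3K4me2", "H3K4me3", "H3K9me3", "H3K20me3",
                   "H3K27me3", "H3K36me3")

# AR(1) correlation within a mark's windows, block-diagonal across marks.
ar1_block_cov <- function(n_marks, windows_per_mark, rho) {
  blk <- rho^abs(outer(seq_len(windows_per_mark), seq_len(windows_per_mark), `-`))
  out <- matrix(0, n_marks * windows_per_mark, n_marks * windows_per_mark)
  for (m in seq_len(n_marks)) {
    idx <- (m - 1L) * windows_per_mark + seq_len(windows_per_mark)
    out[idx, idx] <- blk
  }
  out
}

# Residual SD giving a target within-state R^2 when predictors have
# covariance Sigma: R^2 = b'Sb / (b'Sb + sigma^2).
sigma_for_r2 <- function(slopes, Sigma, r2) {
  v <- drop(crossprod(slopes, Sigma %*% slopes))
  sqrt(v * (1 - r2) / r2)
}

#' Specification of a synthetic regression-HMM dataset
#'
#' Collects every parameter of the synthetic-data generator: the gene
#' geometry (inter-gene distance law), the hidden-state chain (baseline
#' transitions and distance constant), the state-dependent predictor
#' distribution (multivariate normal with AR(1) correlation within each
#' mark), the state-specific expression regressions, and state-biased
#' binary annotations.
#'
#' Defaults emulate the structure of the motivating study: two states with
#' intercepts 0.25 and 1.15, residual SDs chosen so the within-state
#' R-squared is about 0.7 and 0.4, a distance constant of 4000 bp with a
#' uniform baseline transition matrix, log-uniform inter-gene gaps spanning
#' 1e2 to 1e6 bp on one chromosome, and a CpG-island-like annotation with
#' per-state rates 0.59 and 0.70. One mark with ten 200-bp windows over
#' TSS +/- 1 kb is the fast default; set `n_marks = 7` for the full
#' 70-column layout.
#'
#' @param n_genes number of genes.
#' @param n_states number of hidden states M.
#' @param n_marks number of histone marks (1..7).
#' @param windows_per_mark windows per mark (default 10).
#' @param state_means M x p matrix of per-state predictor means; default
#'   separates states by 0.8 on every coordinate.
#' @param predictor_rho AR(1) correlation within a mark (default 0.5).
#' @param predictor_cov optional full p x p covariance (overrides
#'   `predictor_rho`); must be positive definite.
#' @param betas M x (p+1) coefficient matrix, intercept first. Default:
#'   intercepts 0.25 and 1.15 with distinct slope patterns per state.
#' @param target_r2 per-state within-state R-squared used to derive
#'   residual SDs when `sigmas` is not given (default c(0.7, 0.4)).
#' @param sigmas optional M positive residual SDs (overrides `target_r2`).
#' @param baseline_transitions M x M stochastic matrix (default uniform,
#'   so the baseline staying probability is 1/M).
#' @param distance_constant D in bp (default 4000).
#' @param distance_law list describing the inter-gene gap distribution:
#'   `list(type = "log-uniform", min, max)` (default 1e2..1e6),
#'   `list(type = "log-normal", meanlog, sdlog)`, or
#'   `list(type = "constant", value)`.
#' @param pi initial state probabilities (default uniform).
#' @param annotation_rates named list of per-state Bernoulli rates for each
#'   binary label (default `list(cpg = c(0.59, 0.70))`).
#' @param seed integer seed stored with the spec and used by
#'   [simulate_reghmm_data()].
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_genes = 2000, n_states = 2, n_marks = 1,
                           windows_per_mark = 10, state_means = NULL,
                           predictor_rho = 0.5, predictor_cov = NULL,
                           betas = NULL, target_r2 = c(0.7, 0.4),
                           sigmas = NULL, baseline_transitions = NULL,
                           distance_constant = 4000,
                           distance_law = list(type = "log-uniform",
                                               min = 1e2, max = 1e6),
                           pi = NULL,
                           annotation_rates = list(cpg = c(0.59, 0.70)),
                           seed = NULL) {
  if (n_genes < 1) stop("'n_genes' must be >= 1")
  M <- as.integer(n_states)
  if (M < 1) stop("'n_states' must be >= 1")
  p <- n_marks * windows_per_mark
  if (n_marks > length(DEFAULT_MARKS)) stop("at most 7 marks are named")

  Sigma <- if (!is.null(predictor_cov)) as.matrix(predictor_cov)
           else ar1_block_cov(n_marks, windows_per_mark, predictor_rho)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("predictor covariance must be positive definite")

  if (is.null(state_means)) {
    state_means <- matrix(0, M, p)
    if (M > 1) for (m in seq_len(M)) state_means[m, ] <- 0.4 - 0.8 * (m - 1) / (M - 1)
  }
  state_means <- as.matrix(state_means)
  if (!all(dim(state_means) == c(M, p))) stop("'state_means' must be M x p")

  if (is.null(betas)) {
    # Default regressions: intercepts 0.25 / 1.15, opposed slope patterns
    # per state, scaled so the response has about unit overall variance
    # (the response is rank-normal standardized, so its total variance is
    # 1: within-state variance = 1 minus the between-intercept variance)
    # and each state attains its target R^2.
    betas <- matrix(0, M, p + 1L)
    intercepts <- if (M == 2) c(0.25, 1.15) else seq(0.25, 1.15, length.out = M)
    betas[, 1] <- intercepts
    within_var <- max(1 - mean((intercepts - mean(intercepts))^2), 0.2)
    r2 <- rep_len(target_r2, M)
    base <- rep(c(0.5, -0.2, 0.3), length.out = p)
    for (m in seq_len(M)) {
      sh <- base * (-1)^(m - 1)
      v <- drop(crossprod(sh, Sigma %*% sh))
      betas[m, -1] <- sh * sqrt(r2[m] * within_var / v)
    }
  }
  betas <- as.matrix(betas)
  if (!all(dim(betas) == c(M, p + 1L))) stop("'betas' must be M x (p+1)")

  if (is.null(sigmas)) {
    r2 <- rep_len(target_r2, M)
    sigmas <- vapply(seq_len(M),
                     function(m) sigma_for_r2(betas[m, -1], Sigma, r2[m]),
                     numeric(1))
  }
  if (any(sigmas <= 0)) stop("'sigmas' must be positive")

  if (is.null(baseline_transitions)) baseline_transitions <- matrix(1 / M, M, M)
  baseline_transitions <- as.matrix(baseline_transitions)
  if (any(abs(rowSums(baseline_transitions) - 1) > 1e-12))
    stop("rows of 'baseline_transitions' must sum to 1")
  if (distance_constant <= 0) stop("'distance_constant' must be positive")
  if (is.null(pi)) pi <- rep(1 / M, M)

  annotation_rates <- lapply(annotation_rates, function(r) {
    r <- rep_len(r, M)
    if (any(r < 0) || any(r > 1))
      stop("annotation rates must be probabilities")
    r
  })

  structure(list(n_genes = as.integer(n_genes), n_states = M,
                 n_marks = n_marks, windows_per_mark = windows_per_mark,
                 p = p, state_means = state_means, predictor_cov = Sigma,
                 betas = betas, sigmas = as.numeric(sigmas),
                 baseline_transitions = baseline_transitions,
                 distance_constant = distance_constant,
                 distance_law = distance_law, pi = as.numeric(pi),
                 annotation_rates = annotation_rates, seed = seed),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("Synthetic regression-HMM spec: %d genes, %d states, %d marks x %d windows (p = %d)\n",
              x$n_genes, x$n_states, x$n_marks, x$windows_per_mark, x$p))
  cat(sprintf("D = %g bp, gap law %s, intercepts %s, residual SD %s\n",
              x$distance_constant, x$distance_law$type,
              paste(round(x$betas[, 1], 3), collapse = "/"),
              paste(round(x$sigmas, 3), collapse = "/")))
  invisible(x)
}

#' Generate ordered gene positions with a prescribed gap distribution
#'
#' Places `n_genes` TSSs on one chromosome with strictly increasing
#' coordinates, gaps drawn from the given distance law, and random strands.
#'
#' @param n_genes number of genes (>= 1).
#' @param distance_law see [synthetic_spec()].
#' @param seed optional integer seed.
#' @param chrom chromosome name (default "chr1").
#' @param origin coordinate of the first TSS (default 10000).
#' @return data frame with columns `accession`, `chrom`, `tss`, `strand`,
#'   `dist_prev` (`NA` for the first gene).
#' @export
gen_positions <- function(n_genes, distance_law = list(type = "log-uniform",
                                                       min = 1e2, max = 1e6),
                          seed = NULL, chrom = "chr1", origin = 10000) {
  if (!is.numeric(n_genes) || n_genes < 1) stop("'n_genes' must be >= 1")
  n_genes <- as.integer(n_genes)
  if (!is.null(seed)) set.seed(seed)
  gaps <- if (n_genes == 1L) numeric(0) else switch(
    distance_law$type,
    "log-uniform" = round(10^runif(n_genes - 1L, log10(distance_law$min),
                                   log10(distance_law$max))),
    "log-normal" = round(exp(rnorm(n_genes - 1L, distance_law$meanlog,
                                   distance_law$sdlog))),
    "constant" = rep(distance_law$value, n_genes - 1L),
    stop("unknown distance law type: ", distance_law$type))
  gaps <- pmax(gaps, 1)
  tss <- origin + c(0, cumsum(gaps))
  data.frame(accession = sprintf("NM_%06d", seq_len(n_genes)),
             chrom = chrom, tss = tss,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             dist_prev = c(NA_real_, gaps),
             stringsAsFactors = FALSE)
}

#' Generate a hidden-state path with distance-dependent persistence
#'
#' The first gene of each chain draws its state from `pi`; each subsequent
#' gene draws from the row of `transition_matrix(d, P, D)` given the
#' previous state, where `d` is the gap to the previous gene.
#'
#' @param dist length-T gap vector (`NA` marks chain starts), e.g. the
#'   `dist_prev` column of [gen_positions()].
#' @param P baseline M x M transition matrix.
#' @param D distance constant in bp.
#' @param pi initial state probabilities.
#' @param seed optional integer seed.
#' @return integer state vector in `1..M`.
#' @export
gen_state_path <- function(dist, P, D, pi, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- as.matrix(P)
  M <- nrow(P)
  if (length(pi) != M) stop("'pi' and 'P' dimensions disagree")
  T_obs <- length(dist)
  st <- integer(T_obs)
  for (t in seq_len(T_obs)) {
    pr <- if (t == 1L || is.na(dist[t])) pi
          else transition_matrix(dist[t], P, D)[st[t - 1L], ]
    st[t] <- sample.int(M, 1L, prob = pr)
  }
  st
}

#' Generate state-conditional multivariate-normal predictors
#'
#' Row t is drawn from the multivariate normal of state `states[t]`, with
#' mark/offset column names attached.
#'
#' @param states integer state vector.
#' @param spec a [synthetic_spec()].
#' @param seed optional integer seed.
#' @return T x p matrix with column names `mark_offset` (e.g.
#'   `"H3K4me1_-900"`).
#' @export
gen_predictors <- function(states, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T_obs <- length(states)
  p <- spec$p
  # eigen square root tolerates positive semi-definite covariances
  # (e.g. the degenerate zero-covariance case)
  es <- eigen(spec$predictor_cov, symmetric = TRUE)
  if (min(es$values) < -1e-8 * max(abs(es$values)))
    stop("predictor covariance is not positive semi-definite")
  R <- diag(sqrt(pmax(es$values, 0)), p) %*% t(es$vectors)
  Z <- matrix(rnorm(T_obs * p), T_obs, p) %*% R
  X <- Z + spec$state_means[states, , drop = FALSE]
  colnames(X) <- feature_colnames(spec$n_marks, spec$windows_per_mark)
  X
}

#' Predictor column labels
#'
#' Builds the standard `mark_offset` column labels: offsets are window
#' centers in the transcription direction over TSS +/- `span` (e.g.
#' `"H3K4me3_-900"` for the most upstream 200-bp window).
#'
#' @param n_marks number of marks (1..7, named in ChIP order).
#' @param windows_per_mark windows per mark.
#' @param span,window geometry in bp (defaults 1000 and 200).
#' @return character vector of length `n_marks * windows_per_mark`.
#' @export
feature_colnames <- function(n_marks, windows_per_mark, span = 1000,
                             window = 200) {
  offsets <- seq(-span + window / 2, span - window / 2, by = window)
  offsets <- offsets[seq_len(windows_per_mark)]
  as.vector(t(outer(DEFAULT_MARKS[seq_len(n_marks)], offsets,
                    function(m, o) paste0(m, "_", o))))
}

#' Generate expression from state-specific regressions
#'
#' `y_t = beta[q_t, 1] + x_t' beta[q_t, -1] + eps_t`,
#' `eps_t ~ N(0, sigma[q_t]^2)`.
#'
#' @param x T x p predictor matrix.
#' @param states integer state vector.
#' @param betas M x (p+1) coefficients, intercept first.
#' @param sigmas M non-negative residual SDs (0 gives noiseless output).
#' @param seed optional integer seed.
#' @return numeric expression vector.
#' @export
gen_expression <- function(x, states, betas, sigmas, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  betas <- as.matrix(betas)
  if (nrow(x) != length(states)) stop("dimensions of 'x' and 'states' disagree")
  if (any(sigmas < 0)) stop("'sigmas' must be non-negative")
  mu <- cbind(1, x) %*% t(betas)
  mu[cbind(seq_along(states), states)] + rnorm(length(states), 0, sigmas[states])
}

#' Generate state-biased binary annotation labels
#'
#' Each label is Bernoulli with a state-specific rate, so downstream
#' enrichment tests can be validated against a known truth.
#'
#' @param states integer state vector.
#' @param annotation_rates named list of per-state rates.
#' @param seed optional integer seed.
#' @return data frame of 0/1 columns, one per label.
#' @export
gen_annotations <- function(states, annotation_rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(annotation_rates, function(r) rbinom(length(states), 1, r[states]))
  as.data.frame(out)
}

#' Generate a bedGraph-like signal track with a known window-average oracle
#'
#' Lays down piecewise-constant signal over each gene's TSS-centered
#' windows (strand-aware: values are ordered upstream to downstream along
#' the transcription direction) so that [window_average()] applied to the
#' track must reproduce a known matrix exactly. The oracle matrix is
#' attached as attribute `"oracle"`.
#'
#' @param genes data frame with `chrom`, `tss`, `strand`.
#' @param values optional T x w matrix of window values (default standard
#'   normal draws).
#' @param span,window window geometry in bp (defaults 1000 and 200).
#' @param seed optional integer seed.
#' @return data frame with `chrom`, `start`, `end`, `value` (0-based
#'   half-open intervals), oracle matrix in `attr(, "oracle")`.
#' @export
gen_signal_track <- function(genes, values = NULL, span = 1000, window = 200,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- 2L * span %/% window
  n <- nrow(genes)
  if (is.null(values)) values <- matrix(rnorm(n * w), n, w)
  if (!all(dim(values) == c(n, w))) stop("'values' must be n_genes x n_windows")

  recs <- vector("list", n)
  for (g in seq_len(n)) {
    a <- genes$tss[g] - span + (seq_len(w) - 1L) * window
    v <- if (genes$strand[g] == "+") values[g, ] else rev(values[g, ])
    recs[[g]] <- data.frame(chrom = genes$chrom[g], start = a,
                            end = a + window, value = v,
                            stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, recs)
  track <- track[order(track$chrom, track$start), ]
  for (ch in unique(track$chrom)) {
    tt <- track[track$chrom == ch, ]
    ov <- which(tt$start[-1] < tt$end[-nrow(tt)])
    if (length(ov) &&
        any(tt$value[ov] != tt$value[ov + 1L]))
      stop("overlapping intervals with contradictory values; ",
           "gene windows overlap - space genes at least 2*span apart")
  }
  rownames(track) <- NULL
  attr(track, "oracle") <- values
  track
}

#' Simulate a complete synthetic dataset
#'
#' Runs the whole generator: positions, hidden-state path, predictors,
#' expression, and annotations, all driven by the spec's seed. With a
#' fixed seed the output is bit-reproducible.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `"reghmm_sim"`: list with `genes` (including
#'   `expression`), `x` (predictor matrix), `y`, `states` (true states),
#'   `annotations`, and the `spec`.
#' @export
simulate_reghmm_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  genes <- gen_positions(spec$n_genes, spec$distance_law)
  states <- gen_state_path(genes$dist_prev, spec$baseline_transitions,
                           spec$distance_constant, spec$pi)
  x <- gen_predictors(states, spec)
  y <- gen_expression(x, states, spec$betas, spec$sigmas)
  ann <- gen_annotations(states, spec$annotation_rates)
  genes$expression <- y
  structure(list(genes = genes, x = x, y = y, states = states,
                 annotations = ann, spec = spec), class = "reghmm_sim")
}

#' @export
print.reghmm_sim <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d genes, %d predictors, states table: %s\n",
              nrow(x$x), ncol(x$x),
              paste(tabulate(x$states, x$spec$n_states), collapse = "/")))
  invisible(x)
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Writes `genes.bed` (BED6, 0-based half-open, score = expression),
#' `predictors.tsv` (gene id + named predictor columns),
#' `annotations.tsv`, `states.tsv` (true states), and `spec.yaml`.
#' [read_fixture()] round-trips the dataset.
#'
#' @param dataset a [simulate_reghmm_data()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "reghmm_sim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  g <- dataset$genes
  bed <- data.frame(chrom = g$chrom,
                    start = ifelse(g$strand == "+", g$tss, g$tss),
                    end = g$tss + 1L, name = g$accession,
                    score = sprintf("%.15g", g$expression), strand = g$strand)
  f_genes <- file.path(dir, "genes.bed")
  write.table(bed, f_genes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  f_x <- file.path(dir, "predictors.tsv")
  write_feature_matrix(dataset$x, f_x, gene_ids = g$accession)
  f_ann <- file.path(dir, "annotations.tsv")
  write.table(cbind(gene_id = g$accession, dataset$annotations), f_ann,
              sep = "\t", quote = FALSE, row.names = FALSE)
  f_st <- file.path(dir, "states.tsv")
  write.table(data.frame(gene_id = g$accession, state = dataset$states),
              f_st, sep = "\t", quote = FALSE, row.names = FALSE)
  f_spec <- file.path(dir, "spec.yaml")
  sp <- dataset$spec
  yaml::write_yaml(list(
    n_genes = sp$n_genes, n_states = sp$n_states, n_marks = sp$n_marks,
    windows_per_mark = sp$windows_per_mark,
    state_means = as.vector(t(sp$state_means)),
    predictor_cov = as.vector(sp$predictor_cov),
    betas = as.vector(t(sp$betas)), sigmas = sp$sigmas,
    baseline_transitions = as.vector(t(sp$baseline_transitions)),
    distance_constant = sp$distance_constant,
    distance_law = sp$distance_law, pi = sp$pi,
    annotation_rates = sp$annotation_rates, seed = sp$seed), f_spec,
    precision = 15)
  invisible(c(f_genes, f_x, f_ann, f_st, f_spec))
}

#' Read back a fixture written by [write_fixture()]
#'
#' @param dir directory containing the fixture files.
#' @return an object of class `"reghmm_sim"` equal to the written dataset.
#' @export
read_fixture <- function(dir) {
  f_spec <- file.path(dir, "spec.yaml")
  if (!file.exists(f_spec)) stop("no spec.yaml under: ", dir)
  s <- yaml::read_yaml(f_spec)
  M <- s$n_states; p <- s$n_marks * s$windows_per_mark
  spec <- synthetic_spec(
    n_genes = s$n_genes, n_states = M, n_marks = s$n_marks,
    windows_per_mark = s$windows_per_mark,
    state_means = matrix(unlist(s$state_means), M, p, byrow = TRUE),
    predictor_cov = matrix(unlist(s$predictor_cov), p, p),
    betas = matrix(unlist(s$betas), M, p + 1L, byrow = TRUE),
    sigmas = unlist(s$sigmas),
    baseline_transitions = matrix(unlist(s$baseline_transitions), M, M,
                                  byrow = TRUE),
    distance_constant = s$distance_constant,
    distance_law = s$distance_law, pi = unlist(s$pi),
    annotation_rates = lapply(s$annotation_rates, unlist), seed = s$seed)
  genes <- read_gene_table(file.path(dir, "genes.bed"))
  xm <- read_feature_matrix(file.path(dir, "predictors.tsv"))
  ann <- read.delim(file.path(dir, "annotations.tsv"),
                    stringsAsFactors = FALSE)
  st <- read.delim(file.path(dir, "states.tsv"), stringsAsFactors = FALSE)
  ord <- match(rownames(xm), genes$accession)
  genes <- genes[ord, ]; rownames(genes) <- NULL
  structure(list(genes = genes, x = xm, y = genes$expression,
                 states = st$state[match(genes$accession, st$gene_id)],
                 annotations = ann[match(genes$accession, ann$gene_id),
                                   -1, drop = FALSE],
                 spec = spec), class = "reghmm_sim")
}
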