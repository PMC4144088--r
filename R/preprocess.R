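# ---- window averaging of signal tracks --------------------------------

# Overlap-weighted mean of sorted non-overlapping intervals over [a, b);
# returns c(value, covered_width). Uncovered basepairs are excluded from
# the average (denominator = covered width).
interval_mean <- function(starts, ends, values, a, b) {
  if (length(starts) == 0L) return(c(NA_real_, 0))
  i1 <- findInterval(a, ends) + 1L          # first interval with end > a
  i2 <- findInterval(b - 1e-9, starts)      # last interval with start < b
  if (i1 > i2) return(c(NA_real_, 0))
  s <- pmax(starts[i1:i2], a)
  e <- pmin(ends[i1:i2], b)
  wd <- e - s
  c(sum(values[i1:i2] * wd) / sum(wd), sum(wd))
}

#' Average signal in TSS-centered windows, strand-aware
#'
#' Computes, for each gene, the mean signal in non-overlapping windows
#' tiling `[tss - span, tss + span)` (0-based half-open). Window columns
#' are ordered upstream to downstream along the transcription direction,
#' so for minus-strand genes the genomic order is reversed and window
#' `"-900"` is always 900 bp upstream of the TSS. Windows that overlap a
#' masked interval, extend past the chromosome start, or have no signal
#' coverage are flagged in the `mask_flags` attribute rather than
#' silently truncated.
#'
#' @param track a bedGraph-like data frame (`chrom`, `start`, `end`,
#'   `value`; 0-based half-open, non-overlapping per chromosome) or a
#'   named list of such data frames, one per mark.
#' @param genes data frame with `chrom`, `tss`, `strand`.
#' @param span half-width of the region around the TSS in bp (default
#'   1000).
#' @param window window size in bp (default 200); must divide `span`.
#' @param mask optional BED-like data frame (`chrom`, `start`, `end`) of
#'   masked intervals; any overlap flags the window.
#' @param mark name used in column labels when `track` is a single data
#'   frame (default "signal").
#' @return T x (n_marks * 2*span/window) matrix with `mark_offset` column
#'   names (offsets are window centers) and a logical `mask_flags`
#'   attribute of the same shape.
#' @export
window_average <- function(track, genes, span = 1000, window = 200,
                           mask = NULL, mark = "signal") {
  if (span %% window != 0) stop("'span' must be divisible by 'window'")
  if (is.data.frame(track)) {
    track <- setNames(list(track), mark)
  }
  w <- 2L * span %/% window
  n <- nrow(genes)
  offsets <- seq(-span + window / 2, span - window / 2, by = window)

  one_mark <- function(tr) {
    out <- matrix(NA_real_, n, w)
    flg <- matrix(FALSE, n, w)
    by_chrom <- split(seq_len(nrow(tr)), tr$chrom)
    mask_by_chrom <- if (!is.null(mask)) split(seq_len(nrow(mask)), mask$chrom)
    for (g in seq_len(n)) {
      ch <- genes$chrom[g]
      idx <- by_chrom[[ch]]
      starts <- tr$start[idx]; ends <- tr$end[idx]; vals <- tr$value[idx]
      o <- order(starts); starts <- starts[o]; ends <- ends[o]; vals <- vals[o]
      a0 <- genes$tss[g] - span
      for (k in seq_len(w)) {
        # genomic interval of the k-th transcription-direction window
        if (genes$strand[g] == "+") {
          a <- a0 + (k - 1L) * window
        } else {
          a <- genes$tss[g] + span - k * window
        }
        b <- a + window
        if (a < 0) { flg[g, k] <- TRUE; next }
        im <- interval_mean(starts, ends, vals, a, b)
        out[g, k] <- im[1]
        if (im[2] < window) flg[g, k] <- TRUE
        if (!is.null(mask)) {
          mi <- mask_by_chrom[[ch]]
          if (length(mi) &&
              any(mask$start[mi] < b & mask$end[mi] > a)) flg[g, k] <- TRUE
        }
      }
    }
    list(values = out, flags = flg)
  }

  res <- lapply(track, one_mark)
  values <- do.call(cbind, lapply(res, `[[`, "values"))
  flags <- do.call(cbind, lapply(res, `[[`, "flags"))
  colnames(values) <- as.vector(vapply(names(track), function(m)
    paste0(m, "_", offsets), character(w)))
  attr(values, "mask_flags") <- flags
  values
}

# ---- rank-based inverse-normal standardization ------------------------

#' Add small normal noise to break ties
#'
#' Adds i.i.d. `N(0, sd^2)` noise; with `sd = 0` the input is returned
#' unchanged. Deterministic under a fixed seed.
#'
#' @param values numeric vector.
#' @param sd noise SD; the default 0.1 corresponds to a `N(0, 0.01)`
#'   disturbance in mean/variance notation.
#' @param seed optional integer seed.
#' @return numeric vector of the same length.
#' @export
jitter_ties <- function(values, sd = 0.1, seed = NULL) {
  if (sd < 0) stop("'sd' must be non-negative")
  if (sd == 0) return(values)
  if (!is.null(seed)) set.seed(seed)
  values + rnorm(length(values), 0, sd)
}

#' Rank-based inverse-normal standardization
#'
#' Maps the quantiles of the data to standard-normal quantiles: the value
#' of rank r among n becomes `qnorm((r - 0.5) / n)`, a monotone transform
#' whose order statistics are exactly those normal quantiles. Ties are
#' broken beforehand by [jitter_ties()]; with `jitter_sd = 0` ties share
#' the average rank.
#'
#' @param values numeric vector (length >= 2) or a matrix, standardized
#'   per column.
#' @param jitter_sd SD of the tie-breaking disturbance (default 0.1).
#' @param seed optional integer seed for the jitter.
#' @return standardized vector or matrix (attributes of a matrix input,
#'   e.g. `mask_flags`, are preserved).
#' @export
quantile_normalize <- function(values, jitter_sd = 0.1, seed = NULL) {
  if (is.matrix(values)) {
    if (!is.null(seed)) set.seed(seed)
    out <- apply(values, 2, quantile_normalize, jitter_sd = jitter_sd)
    attributes(out) <- attributes(values)[c("dim", "dimnames", "mask_flags")]
    return(out)
  }
  n <- length(values)
  if (n < 2) stop("need at least 2 values to standardize")
  v <- jitter_ties(values, jitter_sd)
  r <- rank(v, ties.method = "average")
  qnorm((r - 0.5) / n)
}

# ---- gene filtering ----------------------------------------------------

#' Filter genes and report per-step removals
#'
#' Applies the data-processing filters in a fixed order and records how
#' many genes each step removes: removal of genes absent from a reference
#' annotation, removal of genes whose strand disagrees with the reference,
#' removal of genes with any masked predictor window, removal of
#' zero-expression genes, and collapse of duplicate TSSs (keeping the
#' record with the highest expression).
#'
#' @param genes data frame with `accession`, `chrom`, `tss`, `strand`,
#'   `expression`.
#' @param x predictor matrix aligned with `genes` (its `mask_flags`
#'   attribute drives the masked-window rule); may be `NULL` if that rule
#'   is not requested.
#' @param rules character vector, a subset of `c("unmatched", "strand",
#'   "masked", "zero_expression", "duplicate_tss")`, applied in that order.
#' @param reference optional data frame with `accession` and `strand`
#'   columns, required by the `"unmatched"` and `"strand"` rules.
#' @return list with `genes`, `x` (both filtered) and `report`, a data
#'   frame of class `"filter_report"` with columns `filter`, `n_removed`,
#'   `n_remaining`.
#' @export
filter_genes <- function(genes, x = NULL,
                         rules = c("masked", "zero_expression", "duplicate_tss"),
                         reference = NULL) {
  all_rules <- c("unmatched", "strand", "masked", "zero_expression",
                 "duplicate_tss")
  rules <- all_rules[all_rules %in% match.arg(rules, all_rules, several.ok = TRUE)]
  keep_order <- function(keep) {
    genes <<- genes[keep, , drop = FALSE]
    if (!is.null(x)) {
      flg <- attr(x, "mask_flags")
      x <<- x[keep, , drop = FALSE]
      if (!is.null(flg)) attr(x, "mask_flags") <<- flg[keep, , drop = FALSE]
    }
  }
  report <- data.frame(filter = "all", n_removed = 0L,
                       n_remaining = nrow(genes), stringsAsFactors = FALSE)
  for (rule in rules) {
    n0 <- nrow(genes)
    keep <- switch(rule,
      unmatched = {
        if (is.null(reference)) stop("'unmatched' rule needs a reference table")
        genes$accession %in% reference$accession
      },
      strand = {
        if (is.null(reference)) stop("'strand' rule needs a reference table")
        ref_strand <- reference$strand[match(genes$accession, reference$accession)]
        !is.na(ref_strand) & genes$strand == ref_strand
      },
      masked = {
        flg <- attr(x, "mask_flags")
        if (is.null(flg)) rep(TRUE, n0) else rowSums(flg) == 0
      },
      zero_expression = genes$expression != 0,
      duplicate_tss = {
        key <- paste(genes$chrom, genes$tss)
        ord <- order(key, -genes$expression)
        first <- !duplicated(key[ord])
        keep <- logical(n0)
        keep[ord] <- first
        keep
      })
    keep_order(keep)
    report <- rbind(report,
                    data.frame(filter = rule, n_removed = n0 - nrow(genes),
                               n_remaining = nrow(genes)))
  }
  if (nrow(genes) == 0L) stop("all genes removed by filtering")
  class(report) <- c("filter_report", "data.frame")
  list(genes = genes, x = x, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Gene filtering report:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# ---- multicollinearity diagnostic -------------------------------------

#' Condition number of a design matrix
#'
#' The square root of the ratio of the largest to the smallest eigenvalue
#' of `X'X`. Values at or above the cutoff (default 30) indicate
#' multicollinearity; a rank-deficient matrix gives `Inf`.
#'
#' @param X numeric matrix.
#' @param with_intercept prepend a column of ones (default `FALSE`).
#' @param cutoff multicollinearity cutoff (default 30).
#' @return the condition number, with logical attribute `"multicollinear"`.
#' @export
condition_number <- function(X, with_intercept = FALSE, cutoff = 30) {
  X <- as.matrix(X)
  if (with_intercept) X <- cbind(1, X)
  ev <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
  kappa <- if (min(ev) <= max(ev) * 1e-14) Inf else sqrt(max(ev) / min(ev))
  structure(kappa, multicollinear = kappa >= cutoff)
}
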