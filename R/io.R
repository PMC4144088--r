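# ---- gene tables -------------------------------------------------------

#' Read a BED-like gene table
#'
#' Reads a 6-column BED file (chrom, start, end, name, score, strand;
#' 0-based half-open; score holds the expression level), derives the TSS
#' (start for plus-strand genes, end - 1 for minus-strand genes), sorts by
#' (chrom, tss), and computes the distance to the previous gene within
#' each chromosome.
#'
#' @param path path to a tab-separated BED6 file without header.
#' @return data frame with `accession`, `chrom`, `tss`, `strand`,
#'   `expression`, `dist_prev` (`NA` at the first gene per chromosome).
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("malformed gene table line ", which(nf < 6)[1], ": expected 6 columns")
  tab <- data.frame(
    chrom = vapply(fields, `[[`, "", 1),
    start = as.numeric(vapply(fields, `[[`, "", 2)),
    end = as.numeric(vapply(fields, `[[`, "", 3)),
    accession = vapply(fields, `[[`, "", 4),
    expression = as.numeric(vapply(fields, `[[`, "", 5)),
    strand = vapply(fields, `[[`, "", 6),
    stringsAsFactors = FALSE)
  bad <- which(is.na(tab$start) | is.na(tab$end) | !tab$strand %in% c("+", "-"))
  if (length(bad)) stop("malformed gene table line ", bad[1])
  if (anyDuplicated(tab$accession))
    stop("duplicate gene ids: ", tab$accession[duplicated(tab$accession)][1])
  tab$tss <- ifelse(tab$strand == "+", tab$start, tab$end - 1)
  tab <- tab[order(tab$chrom, tab$tss), ]
  rownames(tab) <- NULL
  tab$dist_prev <- gene_distances(tab)
  tab[, c("accession", "chrom", "tss", "strand", "expression", "dist_prev")]
}

#' Read a bedGraph-like signal track
#'
#' @param path tab-separated file with columns chrom, start, end, value
#'   (no header).
#' @return data frame with those columns.
#' @export
read_signal_track <- function(path) {
  tr <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tr) < 4) stop("signal track must have 4 columns: ", path)
  setNames(tr[, 1:4], c("chrom", "start", "end", "value"))
}

# ---- feature matrices --------------------------------------------------

#' Write / read a predictor matrix as TSV
#'
#' The first column holds gene ids; the header names predictor columns as
#' `mark_offset` (e.g. `H3K4me3_-900`). Values are written with 17
#' significant digits so the round trip is exact.
#'
#' @param x T x p matrix with column names.
#' @param path output path.
#' @param gene_ids row identifiers (default `rownames(x)` or an index).
#' @return invisibly, `path`.
#' @export
write_feature_matrix <- function(x, path, gene_ids = NULL) {
  x <- as.matrix(x)
  if (is.null(gene_ids))
    gene_ids <- rownames(x) %||% sprintf("g%05d", seq_len(nrow(x)))
  df <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x)))
    df[[colnames(x)[j] %||% paste0("V", j)]] <- sprintf("%.17g", x[, j])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @return `read_feature_matrix`: the matrix with gene ids as rownames and
#'   a `columns` attribute (data frame of mark and offset parsed from the
#'   header on the last underscore).
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("feature matrix must have gene_id plus columns")
  n <- nrow(df)
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) stop("non-numeric or ragged rows in: ", path)
  rownames(m) <- df[[1]]
  cn <- colnames(m)
  parts <- regmatches(cn, regexpr("_[^_]*$", cn))
  attr(m, "columns") <- data.frame(
    mark = substr(cn, 1, nchar(cn) - nchar(parts)),
    offset = as.numeric(sub("^_", "", parts)),
    stringsAsFactors = FALSE)
  m
}

#' Read a binary annotation table
#'
#' @param path TSV with a `gene_id` column and one 0/1 column per label.
#' @return data frame.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("annotation table needs a gene_id column")
  df
}

# ---- configuration and the end-to-end driver ---------------------------

#' Assemble a pipeline configuration
#'
#' Collects the tunable constants of the analysis with their standard
#' defaults: TSS +/- 1 kb span, 200 bp windows, distance constant 4000 bp,
#' 1 to 6 candidate states, 20 EM restarts, 1000 resampling replicates,
#' significance level 0.05.
#'
#' @param ... named overrides of the defaults; unknown names are an error.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(span = 1000, window = 200, D = 4000, M_range = 1:6,
              restarts = 20, reps = 1000, alpha = 0.05, seed = 1,
              jitter_sd = 0.1, genes = NULL, signal = NULL, mask = NULL,
              features = NULL, annotations = NULL, simulate = NULL,
              outdir = NULL, kfold = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$span %% cfg$window != 0) stop("'span' must be divisible by 'window'")
  if (any(c(cfg$restarts, cfg$reps, cfg$span, cfg$window, cfg$D) <= 0))
    stop("counts and constants must be positive")
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with flat keys matching [run_config()] fields.
#' @return a [run_config()] object.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full pipeline from a configuration
#'
#' Executes the configured stages end to end: load or simulate inputs;
#' preprocess (window averaging over signal tracks if given, quantile
#' standardization, gene filtering); fit the regression HMM over the
#' candidate state numbers and pick the best by BIC; characterize the
#' decoded states (per-state regressions, signed per-variable R-squared,
#' mean comparisons, annotation enrichment); optionally cross-validate
#' prediction. Writes TSV/JSON artifacts plus a machine-readable manifest
#' (parameters, seed, per-stage status, output file hashes) to
#' `config$outdir`.
#'
#' @param config a [run_config()] object (or path to a YAML file).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir %||% stop("config$outdir is required")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  set.seed(config$seed)
  stages <- character(0)
  manifest <- list(parameters = unclass(config)[c("span", "window", "D",
                   "restarts", "reps", "alpha", "seed")],
                   M_range = config$M_range)

  # --- inputs
  if (!is.null(config$simulate)) {
    spec <- do.call(synthetic_spec, c(config$simulate,
                                      list(seed = config$seed)))
    sim <- simulate_reghmm_data(spec)
    genes <- sim$genes
    x_raw <- sim$x
    ann <- cbind(gene_id = genes$accession, sim$annotations)
    stages <- c(stages, "simulate")
  } else {
    genes <- read_gene_table(config$genes)
    ann <- if (!is.null(config$annotations))
      read_annotation_table(config$annotations)
    if (!is.null(config$features)) {
      x_raw <- read_feature_matrix(config$features)
      x_raw <- x_raw[match(genes$accession, rownames(x_raw)), , drop = FALSE]
    } else {
      tracks <- lapply(config$signal, read_signal_track)
      mask <- if (!is.null(config$mask)) read_signal_track(config$mask)[1:3]
      x_raw <- window_average(tracks, genes, span = config$span,
                              window = config$window, mask = mask)
      stages <- c(stages, "window_average")
    }
    stages <- c(stages, "load")
  }

  # --- preprocess
  x <- quantile_normalize(x_raw, jitter_sd = config$jitter_sd)
  flt <- filter_genes(genes, x, rules = c("masked", "zero_expression",
                                          "duplicate_tss"))
  genes <- flt$genes; x <- flt$x
  y <- quantile_normalize(genes$expression, jitter_sd = config$jitter_sd)
  write.table(flt$report, file.path(outdir, "filter_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "preprocess")

  # --- fit and select
  dist <- gene_distances(genes)
  sel <- select_states(x, y, dist = dist, M_range = config$M_range,
                       D = config$D, restarts = config$restarts,
                       seed = config$seed)
  fit <- sel$fits[[paste0("M", sel$best_M)]]
  write.table(sel$table, file.path(outdir, "bic_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = genes$accession, state = fit$states,
                         posterior_state1 = fit$gamma[, 1]),
              file.path(outdir, "states.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "fit")

  # --- characterize
  ols <- per_state_ols(x, y, fit$states)
  write.table(summary_table(ols), file.path(outdir, "state_r2.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sr2 <- signed_r2(x, y, fit$states)
  write.table(data.frame(variable = rownames(sr2), sr2),
              file.path(outdir, "signed_r2.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- list()
  if (!is.null(ann) && fit$n_states == 2) {
    for (lab in setdiff(names(ann), "gene_id")) {
      v <- ann[[lab]][match(genes$accession, ann$gene_id)]
      ok <- !is.na(v)
      tab <- rbind(c(sum(v[ok] == 1 & fit$states[ok] == 1),
                     sum(v[ok] == 0 & fit$states[ok] == 1)),
                   c(sum(v[ok] == 1 & fit$states[ok] == 2),
                     sum(v[ok] == 0 & fit$states[ok] == 2)))
      enr[[lab]] <- enrichment_test(tab)
    }
    enr_tab <- data.frame(label = names(enr),
                          p = vapply(enr, `[[`, 0, "p.value"),
                          prop_state1 = vapply(enr, function(e) e$proportions[1], 0),
                          prop_state2 = vapply(enr, function(e) e$proportions[2], 0))
    write.table(enr_tab, file.path(outdir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stages <- c(stages, "analyze")

  # --- prediction
  cv <- NULL
  if (config$kfold >= 2) {
    cv <- kfold_evaluate(genes, x, y, k = config$kfold,
                         states = fit$n_states, D = config$D,
                         restarts = min(config$restarts, 5),
                         seed = config$seed)
    write.table(cv$folds, file.path(outdir, "crossval.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stages <- c(stages, "predict")
  }

  outs <- list.files(outdir, full.names = TRUE)
  outs <- outs[!grepl("manifest", outs)]
  manifest$stages <- stages
  manifest$best_M <- sel$best_M
  manifest$loglik <- fit$loglik
  manifest$bic <- fit$bic
  manifest$n_genes <- nrow(genes)
  manifest$files <- as.list(tools::md5sum(outs))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
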