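# Small shared builders for unit tests.

# fast, well-separated 2-state dataset with strong persistence
small_sim <- function(n = 400, seed = 1, ...) {
  spec <- synthetic_spec(
    n_genes = n,
    distance_law = list(type = "log-uniform", min = 1e2, max = 1e4),
    seed = seed, ...)
  simulate_reghmm_data(spec)
}

# plain gene table on one chromosome
toy_genes <- function(tss, strand = NULL, chrom = "chr1", expression = NULL) {
  n <- length(tss)
  data.frame(accession = sprintf("NM_%06d", seq_len(n)), chrom = chrom,
             tss = tss, strand = strand %||% rep("+", n),
             expression = expression %||% rnorm(n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip everything but dim, for bitwise value comparisons
bare <- function(m) {
  a <- attributes(m)
  attributes(m) <- a[intersect(names(a), "dim")]
  m
}
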