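# Build a fold_matrix directly from a y matrix, bypassing the expression
# route, for tests that exercise PCA/tails in isolation.
make_fold <- function(y, ref_ids = NULL) {
  if (is.null(rownames(y))) rownames(y) <- paste0("g", seq_len(nrow(y)))
  if (is.null(colnames(y))) colnames(y) <- paste0("s", seq_len(ncol(y)))
  if (is.null(ref_ids)) ref_ids <- colnames(y)[1L]
  structure(
    list(y = y, gene_ids = rownames(y), sample_ids = colnames(y),
         pseudocount = 0.1, reference_sample_ids = ref_ids),
    class = "fold_matrix"
  )
}

# Random non-negative expression matrix with named dims.
random_expr <- function(G, N) {
  m <- matrix(rexp(G * N, rate = 0.1), G, N)
  dimnames(m) <- list(paste0("g", seq_len(G)), paste0("s", seq_len(N)))
  m
}

# Two-group sample table for an N_i + N_f column layout.
two_group_samples <- function(expr, n_initial) {
  ids <- colnames(expr)
  build_sample_table(
    sample_id = ids,
    group = rep(c("initial", "final"),
                c(n_initial, length(ids) - n_initial))
  )
}

# Anchored random fold matrix: reference over the first n_initial columns,
# so the per-gene reference mean of y is zero by construction.
random_anchored_fold <- function(G, N, n_initial = max(2L, N %/% 2L)) {
  expr <- random_expr(G, N)
  ref <- compute_reference(expr, colnames(expr)[seq_len(n_initial)], 0.1)
  compute_fold(expr, ref)
}
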