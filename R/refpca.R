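#' Reference-anchored principal component analysis
#'
#' Diagonalizes the second-moment matrix of log2 fold variations,
#' \deqn{\sigma_{ij} = \sum_s y_i(s) y_j(s) / (N_{samples} - 1),}
#' where the sum runs over all samples entering the analysis and
#' \eqn{y_i(s)} is gene i's log2 differential expression in sample s.
#' No further centering is applied: deviations are measured about the
#' initial-state origin (per-gene mean of y over the reference samples is
#' zero by construction), *not* about the grand sample mean. A stock PCA
#' routine would silently re-center and change every downstream number.
#'
#' With tens of thousands of genes the genes x genes matrix is never
#' materialized: eigenpairs are obtained from the thin singular value
#' decomposition of the genes x samples matrix Y, with
#' \eqn{\lambda_k = s_k^2 / (N-1)} and components the left singular
#' vectors. Equivalence with explicit diagonalization is enforced by the
#' test suite.
#'
#' Sign convention: each component is oriented so that the mean projection
#' of the final-group samples is non-negative (progression towards the
#' final state reads as increasing x); if the final group is absent or its
#' mean projection is zero, the first nonzero loading is made positive.
#'
#' @param fold a `fold_matrix` from [compute_fold()].
#' @param K number of components to retain (default 2: analyses are read
#'   on the PC2-vs-PC1 map).
#' @param final_ids sample ids of the final/disease group, used only for
#'   the sign convention. `NULL` falls back to the first-nonzero-loading
#'   rule.
#' @param sample_ids samples entering the second-moment sum; default all
#'   columns of the fold matrix (initial plus final).
#' @return Object of class `refpca_model`: list with `components` (genes
#'   x K orthonormal matrix), `eigenvalues` (all min(G, N) values,
#'   descending), `variance_fractions` (eigenvalues / total variance),
#'   `n_samples`, `sample_ids`, `gene_ids`, `sign_rule`.
#' @export
fit_refpca <- function(fold, K = 2L, final_ids = NULL, sample_ids = NULL) {
  stopifnot(inherits(fold, "fold_matrix"))
  if (is.null(sample_ids)) sample_ids <- fold$sample_ids
  missing_ids <- setdiff(sample_ids, fold$sample_ids)
  if (length(missing_ids) > 0L) {
    stop("unknown sample ids: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  Y <- fold$y[, sample_ids, drop = FALSE]
  G <- nrow(Y)
  N <- ncol(Y)
  if (N < 2L) stop("at least 2 samples required", call. = FALSE)
  K <- as.integer(K)
  if (K < 1L || K > min(G, N)) {
    stop("K must lie in [1, min(genes, samples)]", call. = FALSE)
  }

  # thin SVD of Y: sigma = Y Y^T / (N-1) = U diag(s^2/(N-1)) U^T
  sv <- svd(Y, nu = min(G, N), nv = 0L)
  eigenvalues <- sv$d^2 / (N - 1L)
  total_var <- sum(Y^2) / (N - 1L)  # trace of sigma
  components <- sv$u[, seq_len(K), drop = FALSE]

  sign_rule <- if (is.null(final_ids)) "first-nonzero-loading-positive"
               else "final-group-mean-projection-nonnegative"
  for (k in seq_len(K)) {
    flip <- FALSE
    if (!is.null(final_ids)) {
      fin <- intersect(final_ids, sample_ids)
      m <- if (length(fin) > 0L)
        mean(crossprod(Y[, fin, drop = FALSE], components[, k])) else 0
      if (m < 0) flip <- TRUE
      if (m == 0) {
        nz <- which(components[, k] != 0)[1L]
        if (!is.na(nz) && components[nz, k] < 0) flip <- TRUE
      }
    } else {
      nz <- which(components[, k] != 0)[1L]
      if (!is.na(nz) && components[nz, k] < 0) flip <- TRUE
    }
    if (flip) components[, k] <- -components[, k]
  }
  rownames(components) <- fold$gene_ids
  colnames(components) <- paste0("u", seq_len(K))

  structure(
    list(
      components = components,
      eigenvalues = eigenvalues,
      variance_fractions = eigenvalues / total_var,
      n_samples = N,
      sample_ids = sample_ids,
      gene_ids = fold$gene_ids,
      sign_rule = sign_rule
    ),
    class = "refpca_model"
  )
}

#' Project samples onto principal components
#'
#' Computes the coordinates \eqn{x_k(s) = \sum_g y(g,s)\, u_k(g)}. Samples
#' not used in fitting may be projected with the same formula. Because the
#' per-gene mean of y over the reference samples is zero, the initial
#' group's mean projection is zero on every axis.
#'
#' @param fold a `fold_matrix` whose gene space matches the model.
#' @param model a `refpca_model`.
#' @param K number of axes to report (default: all retained in the model).
#' @param samples optional sample table; when given, the group label is
#'   carried into the output.
#' @return data.frame with `sample_id`, optional `group`, and coordinate
#'   columns `x1`, ..., `xK`.
#' @export
project_samples <- function(fold, model, K = NULL, samples = NULL) {
  stopifnot(inherits(fold, "fold_matrix"), inherits(model, "refpca_model"))
  if (!identical(fold$gene_ids, model$gene_ids)) {
    stop("gene spaces of fold matrix and model differ", call. = FALSE)
  }
  if (is.null(K)) K <- ncol(model$components)
  K <- as.integer(K)
  if (K < 1L || K > ncol(model$components)) {
    stop("K exceeds the number of fitted components", call. = FALSE)
  }
  X <- crossprod(fold$y, model$components[, seq_len(K), drop = FALSE])
  colnames(X) <- paste0("x", seq_len(K))
  out <- data.frame(sample_id = fold$sample_ids, stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    out$group <- samples$group[match(out$sample_id, samples$sample_id)]
  }
  cbind(out, as.data.frame(X, row.names = NULL))
}

#' @export
print.refpca_model <- function(x, ...) {
  K <- ncol(x$components)
  cat("Reference-anchored PCA model\n")
  cat("  genes:   ", nrow(x$components), "\n")
  cat("  samples: ", x$n_samples, "\n")
  cat("  retained:", K, "components\n")
  vf <- x$variance_fractions[seq_len(min(K, length(x$variance_fractions)))]
  cat("  variance fractions:",
      paste(sprintf("%.1f%%", 100 * vf), collapse = ", "), "\n")
  invisible(x)
}
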