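#' Geometric-mean reference profile over initial-state samples
#'
#' Builds the per-gene reference expression `e_ref` as the geometric mean of
#' the pseudocounted expression values over the initial-state (normal)
#' samples:
#' \deqn{e_{ref}(g) = \exp\left(\frac{1}{n}\sum_{s \in \mathrm{initial}} \ln(e(g,s) + c)\right)}
#' The pseudocount `c > 0` regularizes zeroes: a gene absent from every
#' sample ends up with differential expression exactly 1 downstream.
#'
#' @param expr numeric matrix, genes x samples, non-negative linear-scale
#'   expression with gene ids as rownames and sample ids as colnames (see
#'   [read_expression_matrix()]).
#' @param initial_ids character vector of initial-group sample ids; must be
#'   a non-empty subset of `colnames(expr)`.
#' @param pseudocount positive constant added to every expression value
#'   before taking logs. Typical values: `1e-4` for microarray intensities
#'   already on a small scale, `0.1` for RNA-seq quantifications.
#' @return An object of class `ref_profile`: a list with `gene_ids`,
#'   `e_ref` (named numeric, one value per gene, each `>= pseudocount`),
#'   `pseudocount`, and `reference_sample_ids`.
#' @examples
#' m <- matrix(c(0.9, 9.9, 0, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ref <- compute_reference(m, c("s1", "s2"), pseudocount = 0.1)
#' ref$e_ref  # g1: sqrt(1 * 10), g2: 0.1
#' @seealso [compute_fold()]
#' @export
compute_reference <- function(expr, initial_ids, pseudocount = 0.1) {
  expr <- validate_expression_matrix(expr)
  if (length(initial_ids) == 0L) {
    stop("initial sample set is empty", call. = FALSE)
  }
  missing_ids <- setdiff(initial_ids, colnames(expr))
  if (length(missing_ids) > 0L) {
    stop("initial sample ids not in matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be a single positive number", call. = FALSE)
  }
  # geometric mean in log space for numerical stability
  log_e <- log(expr[, initial_ids, drop = FALSE] + pseudocount)
  e_ref <- exp(rowMeans(log_e))
  structure(
    list(
      gene_ids = rownames(expr),
      e_ref = stats::setNames(e_ref, rownames(expr)),
      pseudocount = pseudocount,
      reference_sample_ids = as.character(initial_ids)
    ),
    class = "ref_profile"
  )
}

#' Log2 fold-variation matrix relative to a reference profile
#'
#' Computes, for every gene g and sample s, the log2 differential
#' expression
#' \deqn{y(g,s) = \log_2\frac{e(g,s) + c}{e_{ref}(g)}}
#' with the same pseudocount `c` used when building the reference, so that
#' a gene at its reference level has differential expression d = 2^y = 1
#' exactly. Because `e_ref` is the geometric mean of the same pseudocounted
#' values, the mean of `y` over the reference samples is 0 for every gene:
#' all downstream deviations are anchored at the initial-state origin.
#'
#' @param expr numeric genes x samples matrix, same genes (and order) as
#'   the reference.
#' @param ref a `ref_profile` from [compute_reference()].
#' @return An object of class `fold_matrix`: a list with `y` (genes x
#'   samples matrix of log2 differential expressions), `gene_ids`,
#'   `sample_ids`, `pseudocount` and `reference_sample_ids`.
#' @export
compute_fold <- function(expr, ref) {
  expr <- validate_expression_matrix(expr)
  stopifnot(inherits(ref, "ref_profile"))
  if (!identical(rownames(expr), ref$gene_ids)) {
    stop("gene ids of expression matrix and reference profile differ",
         call. = FALSE)
  }
  y <- log2((expr + ref$pseudocount) / ref$e_ref)
  structure(
    list(
      y = y,
      gene_ids = rownames(expr),
      sample_ids = colnames(expr),
      pseudocount = ref$pseudocount,
      reference_sample_ids = ref$reference_sample_ids
    ),
    class = "fold_matrix"
  )
}

#' Differential expressions d = 2^y from a fold matrix
#'
#' @param fold a `fold_matrix`.
#' @return genes x samples matrix of dimensionless differential
#'   expressions, 1 meaning unchanged relative to the reference.
#' @export
fold_d <- function(fold) {
  stopifnot(inherits(fold, "fold_matrix"))
  2^fold$y
}

#' @export
print.ref_profile <- function(x, ...) {
  cat("Reference expression profile\n")
  cat("  genes:            ", length(x$gene_ids), "\n")
  cat("  reference samples:", length(x$reference_sample_ids), "\n")
  cat("  pseudocount:      ", format(x$pseudocount), "\n")
  invisible(x)
}

#' @export
print.fold_matrix <- function(x, ...) {
  cat("Log2 fold-variation matrix\n")
  cat("  genes:  ", nrow(x$y), "\n")
  cat("  samples:", ncol(x$y),
      sprintf("(%d reference)\n", length(x$reference_sample_ids)))
  invisible(x)
}
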