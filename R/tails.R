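#' Group-level differential expressions
#'
#' Collapses a fold matrix to one differential expression per gene for a
#' group of samples. The default is the geometric mean of d across the
#' group's samples, i.e. `2^mean(y)` — consistent with the log-space
#' treatment in which over- and under-expression are symmetric. With
#' `per_sample = TRUE` the per-sample d vectors are returned instead (one
#' column per sample), for per-sample curves that are later averaged.
#'
#' When the group is the reference samples themselves, every gene's
#' group-level d is exactly 1: the anchoring identity.
#'
#' @param fold a `fold_matrix`.
#' @param ids sample ids of the group; must be non-empty.
#' @param per_sample return the per-sample matrix instead of collapsing.
#' @return named numeric vector of per-gene d (or genes x samples matrix).
#' @export
group_differential <- function(fold, ids, per_sample = FALSE) {
  stopifnot(inherits(fold, "fold_matrix"))
  if (length(ids) == 0L) stop("empty group", call. = FALSE)
  missing_ids <- setdiff(ids, fold$sample_ids)
  if (length(missing_ids) > 0L) {
    stop("unknown sample ids: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  y <- fold$y[, ids, drop = FALSE]
  if (per_sample) return(2^y)
  stats::setNames(2^rowMeans(y), fold$gene_ids)
}

#' Cumulative over-/under-expression distribution curves
#'
#' Builds the pair of integral distribution functions of differential
#' expression: the over-expression branch counts genes with d greater than
#' or equal to each grid value, the under-expression branch counts genes
#' with d lower than or equal to it (both inclusive, so genes exactly at a
#' grid value belong to both branches there). Given a genes x samples
#' matrix, counts are computed per sample and then arithmetically
#' averaged (average group curves).
#'
#' @param d positive per-gene differential expressions (vector), or a
#'   genes x samples matrix of them.
#' @param grid evaluation points; default `n_grid` log-spaced values
#'   between the observed minimum and maximum.
#' @param n_grid grid size when `grid` is `NULL`.
#' @return list with elements `over` and `under`, each a `tail_curve`:
#'   list with `branch`, `grid`, `counts` (mean over samples of integer
#'   per-sample counts) and `n_genes`.
#' @export
cumulative_curves <- function(d, grid = NULL, n_grid = 200L) {
  D <- if (is.matrix(d)) d else matrix(d, ncol = 1L)
  if (anyNA(D) || any(D <= 0)) {
    stop("differential expressions must be positive", call. = FALSE)
  }
  if (is.null(grid)) {
    lo <- min(D)
    hi <- max(D)
    if (lo == hi) {
      grid <- lo
    } else {
      grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
      grid[1L] <- lo          # pin endpoints: exp(log(x)) is not exact
      grid[n_grid] <- hi
    }
  } else {
    grid <- sort(as.numeric(grid))
    if (any(grid <= 0)) stop("grid values must be positive", call. = FALSE)
  }
  n_genes <- nrow(D)
  over <- under <- matrix(0, nrow = length(grid), ncol = ncol(D))
  for (j in seq_len(ncol(D))) {
    ds <- sort(D[, j])
    under[, j] <- findInterval(grid, ds)                       # d <= g
    over[, j] <- n_genes - findInterval(grid, ds, left.open = TRUE)  # d >= g
  }
  mk <- function(branch, counts) {
    structure(list(branch = branch, grid = grid,
                   counts = rowMeans(counts), n_genes = n_genes),
              class = "tail_curve")
  }
  list(over = mk("over", over), under = mk("under", under))
}

#' Pareto exponent of a cumulative tail curve
#'
#' Least-squares slope of log10(counts) against log10(d) over the grid
#' points inside `[d_lo, d_hi]`; grid points with zero counts are dropped
#' rather than offset. The reported `exponent` is the raw log-log slope —
#' negative in the over-expression branch, positive in the under branch —
#' and `pareto_index` is its magnitude, the exponent of the 1/d^v decay
#' law.
#'
#' @param curve a `tail_curve`.
#' @param d_lo,d_hi fit window bounds, `d_lo < d_hi`; `Inf` allowed for
#'   `d_hi`.
#' @return Object of class `pareto_fit`: list with `branch`, `fit_range`,
#'   `exponent`, `pareto_index`, `intercept` (log10 scale), `r_squared`,
#'   `n_points`.
#' @export
fit_pareto <- function(curve, d_lo, d_hi) {
  stopifnot(inherits(curve, "tail_curve"))
  if (!(d_lo < d_hi)) stop("d_lo must be below d_hi", call. = FALSE)
  keep <- curve$grid >= d_lo & curve$grid <= d_hi & curve$counts > 0
  if (sum(keep) < 3L) {
    stop("fewer than 3 usable grid points in fit window", call. = FALSE)
  }
  lx <- log10(curve$grid[keep])
  ly <- log10(curve$counts[keep])
  fit <- loglog_ls(lx, ly)
  structure(
    list(
      branch = curve$branch,
      fit_range = c(d_lo, d_hi),
      exponent = fit$slope,
      pareto_index = abs(fit$slope),
      intercept = fit$intercept,
      r_squared = fit$r_squared,
      n_points = sum(keep)
    ),
    class = "pareto_fit"
  )
}

# closed-form simple least squares; exact power laws are a common input,
# where summary.lm would warn about a perfect fit
loglog_ls <- function(lx, ly) {
  mx <- mean(lx)
  my <- mean(ly)
  sxx <- sum((lx - mx)^2)
  if (sxx == 0) stop("degenerate fit window: single abscissa", call. = FALSE)
  slope <- sum((lx - mx) * (ly - my)) / sxx
  intercept <- my - slope * mx
  ss_res <- sum((ly - intercept - slope * lx)^2)
  ss_tot <- sum((ly - my)^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
       ss_res = ss_res)
}

#' Two-segment power-law fit with a breakpoint
#'
#' Detects a change of Pareto exponent along a cumulative curve: for each
#' candidate breakpoint, fits separate log-log slopes to the grid points
#' at or below and at or above the candidate, and keeps the candidate
#' minimizing the total squared residual. Candidates leaving fewer than 3
#' usable points in either segment are discarded; if none survive, an
#' error is raised.
#'
#' @param curve a `tail_curve`.
#' @param breakpoints numeric vector of candidate breakpoints in d.
#' @return list with `breakpoint`, `left` and `right` (`pareto_fit`s for
#'   the two segments) and `total_ss` (summed squared log10 residuals).
#' @export
detect_slope_change <- function(curve, breakpoints) {
  stopifnot(inherits(curve, "tail_curve"))
  if (length(breakpoints) == 0L) {
    stop("no candidate breakpoints supplied", call. = FALSE)
  }
  lo <- min(curve$grid)
  hi <- max(curve$grid)
  best <- NULL
  for (b in sort(breakpoints)) {
    fits <- tryCatch(
      list(left = fit_pareto(curve, lo, b), right = fit_pareto(curve, b, hi)),
      error = function(e) NULL
    )
    if (is.null(fits)) next
    ss <- segment_ss(curve, lo, b) + segment_ss(curve, b, hi)
    if (is.null(best) || ss < best$total_ss) {
      best <- list(breakpoint = b, left = fits$left, right = fits$right,
                   total_ss = ss)
    }
  }
  if (is.null(best)) {
    stop("no candidate breakpoint leaves 3 usable points in both segments",
         call. = FALSE)
  }
  best
}

segment_ss <- function(curve, d_lo, d_hi) {
  keep <- curve$grid >= d_lo & curve$grid <= d_hi & curve$counts > 0
  loglog_ls(log10(curve$grid[keep]), log10(curve$counts[keep]))$ss_res
}

#' Extremes and strict-threshold differential gene counts
#'
#' Minimal and maximal differential expressions of a group, and the
#' numbers of genes in the extreme regions beyond the thresholds. The
#' extreme-region counts are strict (`d > t_over`, `d < t_under`),
#' matching the usual reading of "genes with d > 2"; the cumulative
#' curves, by contrast, are inclusive. The two conventions coexist
#' deliberately.
#'
#' @param d positive per-gene differential expressions.
#' @param t_over over-expression threshold, > 1 (default 2).
#' @param t_under under-expression threshold, < 1 (default 1/2).
#' @return list with `d_min`, `d_max`, `n_over`, `n_under`.
#' @export
extremes_and_counts <- function(d, t_over = 2, t_under = 0.5) {
  if (anyNA(d) || any(d <= 0)) {
    stop("differential expressions must be positive", call. = FALSE)
  }
  if (!(t_over > 1)) stop("t_over must exceed 1", call. = FALSE)
  if (!(t_under < 1) || t_under <= 0) {
    stop("t_under must lie in (0, 1)", call. = FALSE)
  }
  list(d_min = min(d), d_max = max(d),
       n_over = sum(d > t_over), n_under = sum(d < t_under))
}

#' Classify a state transition as continuous or discontinuous
#'
#' Decision rule: the transition is continuous when the fraction of
#' differentially expressed genes is below `f_c`, discontinuous otherwise
#' (the boundary is assigned to the heavier class). The default
#' `f_c = 0.02` sits between the ~1/200-1/500 fractions seen in
#' continuous transitions (experimental evolution, neurodegeneration) and
#' the ~1/10 fractions of the normal-to-tumor transition. When cloud
#' geometry is supplied, the overlap ratio
#' intercenter distance / (R_initial + R_final) is recorded as supporting
#' evidence but does not influence the decision.
#'
#' @param differential_fraction fraction of genes beyond the differential
#'   thresholds, in `[0, 1]`.
#' @param geometry optional `cloud_geometry` for the evidence record.
#' @param f_c critical fraction separating the two classes.
#' @return list with `class` (`"continuous"` or `"discontinuous"`) and
#'   `criteria` (the fraction, `f_c`, and the overlap ratio or `NA`).
#' @export
classify_transition <- function(differential_fraction, geometry = NULL,
                                f_c = 0.02) {
  if (is.na(differential_fraction) || differential_fraction < 0 ||
      differential_fraction > 1) {
    stop("differential_fraction must lie in [0, 1]", call. = FALSE)
  }
  overlap_ratio <- NA_real_
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "cloud_geometry"))
    overlap_ratio <- geometry$intercenter_distance /
      (geometry$initial$radius + geometry$final$radius)
  }
  list(
    class = if (differential_fraction < f_c) "continuous"
            else "discontinuous",
    criteria = list(differential_fraction = differential_fraction,
                    f_c = f_c, overlap_ratio = overlap_ratio)
  )
}

#' @export
print.tail_curve <- function(x, ...) {
  cat(sprintf("Cumulative %s-expression curve: %d grid points, %d genes\n",
              x$branch, length(x$grid), x$n_genes))
  invisible(x)
}

#' @export
print.pareto_fit <- function(x, ...) {
  cat(sprintf(
    "Pareto fit (%s branch, d in [%.3g, %.3g]): exponent %.3f, R^2 %.3f, %d points\n",
    x$branch, x$fit_range[1L], x$fit_range[2L], x$exponent, x$r_squared,
    x$n_points))
  invisible(x)
}
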