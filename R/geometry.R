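#' Cloud geometry of the two sample groups in PC space
#'
#' Summarizes the initial and final sample clouds along one principal
#' axis: centers (mean coordinate), radii (standard deviation of the
#' coordinate within each group) and the intercenter distance. By
#' construction the initial-group center is zero when the projections come
#' from the fitting samples of a reference-anchored model.
#'
#' @param proj projection table from [project_samples()] with a `group`
#'   column.
#' @param axis component index used for centers and the intercenter
#'   distance (default 1). Supplying several indices (e.g. `c(1, 2)`)
#'   computes radii in the corresponding plane,
#'   \eqn{R = \sqrt{\sum_k \mathrm{sd}(x_k)^2}}, useful only for drawing
#'   ellipses; centers and intercenter distance still use the first index.
#' @param ddof degrees-of-freedom correction for the radius: 1 (default,
#'   sample standard deviation) or 0 (population).
#' @return Object of class `cloud_geometry`: list with per-group `center`,
#'   `radius`, `n`, plus `intercenter_distance`, `axis` and `ddof`.
#' @export
cloud_stats <- function(proj, axis = 1L, ddof = 1L) {
  check_projection(proj)
  if (!ddof %in% c(0L, 1L)) stop("ddof must be 0 or 1", call. = FALSE)
  cols <- paste0("x", axis)
  if (!all(cols %in% colnames(proj))) {
    stop("projection table lacks columns: ",
         paste(setdiff(cols, colnames(proj)), collapse = ", "),
         call. = FALSE)
  }
  main <- cols[1L]
  per_group <- lapply(c(initial = "initial", final = "final"), function(g) {
    sub <- proj[proj$group == g, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) {
      stop("group '", g, "' has fewer than 2 samples", call. = FALSE)
    }
    vars <- vapply(cols, function(cl) {
      v <- sub[[cl]]
      sum((v - mean(v))^2) / (n - ddof)
    }, numeric(1L))
    list(center = mean(sub[[main]]), radius = sqrt(sum(vars)), n = n)
  })
  structure(
    list(
      initial = per_group$initial,
      final = per_group$final,
      intercenter_distance = abs(per_group$final$center -
                                   per_group$initial$center),
      axis = as.integer(axis),
      ddof = as.integer(ddof)
    ),
    class = "cloud_geometry"
  )
}

#' Coexistence interval of the two groups along PC1
#'
#' The PC1 interval where both groups are observed: the intersection of
#' the two groups' observed coordinate ranges. Returns `NULL` when the
#' ranges are disjoint (no coexistence). Symmetric in the two groups.
#'
#' @param proj projection table with `group` and `x1` columns.
#' @return numeric `c(lo, hi)` or `NULL` when the ranges are disjoint.
#' @export
coexistence_interval <- function(proj) {
  check_projection(proj)
  r_i <- range(proj$x1[proj$group == "initial"])
  r_f <- range(proj$x1[proj$group == "final"])
  lo <- max(r_i[1L], r_f[1L])
  hi <- min(r_i[2L], r_f[2L])
  if (lo > hi) NULL else c(lo, hi)
}

#' Drift of a sample cloud along PC1 as a function of age
#'
#' Ordinary least-squares regression of the PC1 coordinate on age within
#' one group, used to follow a slow drift of the normal cloud towards the
#' disease region over the lifespan. Fits per-sample coordinates, not
#' age-binned means.
#'
#' @param proj projection table with `group` and `x1` columns.
#' @param ages numeric vector of ages in years, aligned with `proj` rows
#'   (or named by sample id). Missing ages are dropped.
#' @param group which group to fit (default `"initial"`).
#' @return Object of class `age_drift_fit`: list with `group`, `slope`
#'   (PC1 units per year), `intercept`, `p_value` (two-sided t test of the
#'   slope) and `n`.
#' @export
age_drift_regression <- function(proj, ages, group = c("initial", "final")) {
  check_projection(proj)
  group <- match.arg(group)
  if (!is.null(names(ages))) {
    ages <- ages[match(proj$sample_id, names(ages))]
  }
  if (length(ages) != nrow(proj)) {
    stop("ages must align with the projection table rows", call. = FALSE)
  }
  keep <- proj$group == group & !is.na(ages)
  x1 <- proj$x1[keep]
  age <- ages[keep]
  if (length(age) < 3L) {
    stop("need at least 3 samples with non-missing age", call. = FALSE)
  }
  if (length(unique(age)) == 1L) {
    stop("all ages identical: degenerate regression design", call. = FALSE)
  }
  fit <- stats::lm(x1 ~ age)
  coefs <- summary(fit)$coefficients
  structure(
    list(
      group = group,
      slope = unname(coefs["age", "Estimate"]),
      intercept = unname(coefs["(Intercept)", "Estimate"]),
      p_value = unname(coefs["age", "Pr(>|t|)"]),
      n = length(age)
    ),
    class = "age_drift_fit"
  )
}

check_projection <- function(proj) {
  if (!is.data.frame(proj) || !all(c("group", "x1") %in% colnames(proj))) {
    stop("expected a projection table with 'group' and 'x1' columns",
         call. = FALSE)
  }
  if (!all(c("initial", "final") %in% proj$group)) {
    stop("both groups required", call. = FALSE)
  }
  invisible(proj)
}

#' @export
print.cloud_geometry <- function(x, ...) {
  cat("Cloud geometry along PC", paste(x$axis, collapse = "-"), "\n",
      sep = "")
  cat(sprintf("  initial: center %.4g, radius %.4g (n = %d)\n",
              x$initial$center, x$initial$radius, x$initial$n))
  cat(sprintf("  final:   center %.4g, radius %.4g (n = %d)\n",
              x$final$center, x$final$radius, x$final$n))
  cat(sprintf("  intercenter distance: %.4g\n", x$intercenter_distance))
  invisible(x)
}

#' @export
print.age_drift_fit <- function(x, ...) {
  cat(sprintf("Age drift (%s group, n = %d): x1 = %.2f %+.2f age, p = %.3g\n",
              x$group, x$n, x$intercept, x$slope, x$p_value))
  invisible(x)
}
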