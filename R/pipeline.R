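#' End-to-end state-transition analysis
#'
#' Chains the full procedure: geometric-mean reference over the
#' initial-group samples, log2 fold matrix, reference-anchored PCA,
#' sample projections, cloud geometry along PC1, group-level cumulative
#' differential-expression curves for the final group, Pareto tail fits,
#' extremes/counts, and the continuous-vs-discontinuous classification.
#'
#' Two presets bundle the analysis constants for the two data families:
#' `"rnaseq"` (pseudocount 0.1; tail fit windows beyond the 2-fold bulk,
#' over `[2.5, 50]`, under `[0.02, 0.4]`) and `"ltee"` (microarray-scale
#' pseudocount 1e-4; near-bulk fit windows over `[1, 2]`, under
#' `[1/3, 1]`). Any constant can be overridden individually.
#'
#' @param expr genes x samples matrix (see [read_expression_matrix()]).
#' @param samples sample table (see [read_sample_table()]); must contain
#'   every matrix column and both groups.
#' @param preset `"rnaseq"` (default) or `"ltee"`.
#' @param pseudocount,K,fit_over,fit_under,t_over,t_under,f_c,ddof,n_grid
#'   analysis constants; `NULL` takes the preset value. See
#'   [compute_reference()], [fit_refpca()], [fit_pareto()],
#'   [extremes_and_counts()], [classify_transition()], [cloud_stats()]
#'   and [cumulative_curves()].
#' @return Object of class `transition_report`: a list with `params`,
#'   `pca` (variance fractions, eigenvalues), `geometry` (`mean_x1`,
#'   `R_initial`, `R_final`, intercenter distance, coexistence interval),
#'   `tails` (`d_min`, `d_max`, `upsilon_over`, `upsilon_under`, extreme
#'   counts, `differential_fraction`), `class`, `criteria`, plus the
#'   per-sample `projections` and per-gene `genes` tables and the fitted
#'   `model`.
#' @export
analyze_transition <- function(expr, samples,
                               preset = c("rnaseq", "ltee"),
                               pseudocount = NULL, K = NULL,
                               fit_over = NULL, fit_under = NULL,
                               t_over = NULL, t_under = NULL,
                               f_c = NULL, ddof = NULL, n_grid = NULL) {
  preset <- match.arg(preset)
  p <- list(
    pseudocount = if (preset == "ltee") 1e-4 else 0.1,
    K = 2L,
    fit_over = if (preset == "ltee") c(1, 2) else c(2.5, 50),
    fit_under = if (preset == "ltee") c(1 / 3, 1) else c(0.02, 0.4),
    t_over = 2, t_under = 0.5, f_c = 0.02, ddof = 1L, n_grid = 200L
  )
  override <- list(pseudocount = pseudocount, K = K, fit_over = fit_over,
                   fit_under = fit_under, t_over = t_over,
                   t_under = t_under, f_c = f_c, ddof = ddof,
                   n_grid = n_grid)
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) p[[nm]] <- override[[nm]]
  }

  expr <- validate_expression_matrix(expr)
  samples <- check_samples_cover(expr, samples)
  init_ids <- group_ids(samples, "initial")
  fin_ids <- group_ids(samples, "final")
  if (length(init_ids) == 0L || length(fin_ids) == 0L) {
    stop("both groups required", call. = FALSE)
  }

  ref <- compute_reference(expr, init_ids, p$pseudocount)
  fold <- compute_fold(expr, ref)
  model <- fit_refpca(fold, K = p$K, final_ids = fin_ids)
  proj <- project_samples(fold, model, samples = samples)
  geom <- cloud_stats(proj, axis = 1L, ddof = p$ddof)
  coex <- coexistence_interval(proj)

  d_final <- group_differential(fold, fin_ids)
  curves <- cumulative_curves(d_final, n_grid = p$n_grid)
  safe_fit <- function(curve, win) {
    tryCatch(fit_pareto(curve, win[1L], win[2L]), error = function(e) NULL)
  }
  fit_o <- safe_fit(curves$over, p$fit_over)
  fit_u <- safe_fit(curves$under, p$fit_under)
  ext <- extremes_and_counts(d_final, p$t_over, p$t_under)
  frac <- (ext$n_over + ext$n_under) / length(d_final)
  cls <- classify_transition(frac, geom, p$f_c)

  branch <- rep("none", length(d_final))
  branch[d_final > p$t_over] <- "over"
  branch[d_final < p$t_under] <- "under"
  genes <- data.frame(
    gene_id = fold$gene_ids,
    e_ref = unname(ref$e_ref),
    d_final = unname(d_final),
    y_final = unname(log2(d_final)),
    branch = branch,
    stringsAsFactors = FALSE
  )

  structure(
    list(
      params = p,
      n_genes = nrow(expr),
      n_initial = length(init_ids),
      n_final = length(fin_ids),
      pca = list(
        variance_fractions = model$variance_fractions[seq_len(p$K)],
        eigenvalues = model$eigenvalues[seq_len(p$K)]
      ),
      geometry = list(
        mean_x1 = geom$final$center,
        R_initial = geom$initial$radius,
        R_final = geom$final$radius,
        intercenter_distance = geom$intercenter_distance,
        coexistence_interval = coex
      ),
      tails = list(
        d_min = ext$d_min, d_max = ext$d_max,
        upsilon_over = if (is.null(fit_o)) NA_real_ else fit_o$exponent,
        upsilon_under = if (is.null(fit_u)) NA_real_ else fit_u$exponent,
        fit_over = p$fit_over, fit_under = p$fit_under,
        n_over = ext$n_over, n_under = ext$n_under,
        t_over = p$t_over, t_under = p$t_under,
        differential_fraction = frac
      ),
      class = cls$class,
      criteria = cls$criteria,
      projections = proj,
      genes = genes,
      model = model,
      curves = curves
    ),
    class = "transition_report"
  )
}

.pipeline_keys <- c("expr", "samples", "preset", "pseudocount", "K",
                    "fit_over", "fit_under", "t_over", "t_under", "f_c",
                    "ddof", "n_grid", "out_dir", "orientation",
                    "group_aliases")

#' Run the pipeline from a configuration list
#'
#' Thin orchestration wrapper around [analyze_transition()]: resolves
#' file paths, validates the configuration against the known key set
#' (unknown keys raise), logs each stage, and optionally writes the
#' report to disk. Deterministic: identical inputs and configuration give
#' byte-identical output files.
#'
#' @param config named list. Required: `expr` (matrix or path),
#'   `samples` (table or path). Optional: `preset`, the analysis
#'   constants of [analyze_transition()], `orientation` and
#'   `group_aliases` for the readers, and `out_dir` to write the report.
#' @param quiet suppress stage log messages.
#' @return a `transition_report`, invisibly when `out_dir` is written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!is.list(config) || is.null(names(config)) ||
      any(names(config) == "")) {
    stop("config must be a fully named list", call. = FALSE)
  }
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$expr) || is.null(config$samples)) {
    stop("config must name 'expr' and 'samples'", call. = FALSE)
  }
  note <- function(...) if (!quiet) message("[statescape] ", ...)

  expr <- config$expr
  if (is.character(expr)) {
    note("reading expression matrix: ", expr)
    expr <- read_expression_matrix(
      expr, orientation = config$orientation %||% "genes-rows")
  }
  samples <- config$samples
  if (is.character(samples)) {
    note("reading sample table: ", samples)
    samples <- read_sample_table(samples,
                                 group_aliases = config$group_aliases)
  }
  args <- config[intersect(names(config),
                           c("preset", "pseudocount", "K", "fit_over",
                             "fit_under", "t_over", "t_under", "f_c",
                             "ddof", "n_grid"))]
  note("analyzing ", nrow(expr), " genes x ", ncol(expr), " samples")
  report <- do.call(analyze_transition,
                    c(list(expr = expr, samples = samples), args))
  note("class: ", report$class,
       " (differential fraction ",
       format(report$tails$differential_fraction, digits = 4), ")")
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    note("report written to ", config$out_dir)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

report_scalars <- function(report) {
  list(
    params = report$params,
    n_genes = report$n_genes,
    n_initial = report$n_initial,
    n_final = report$n_final,
    pca = report$pca,
    geometry = report$geometry,
    tails = report$tails,
    class = report$class,
    criteria = report$criteria
  )
}

#' Write a transition report to a directory
#'
#' Writes `report.json` (all scalar results and parameters),
#' `projections.tsv` (per sample: id, group, x1..xK) and `genes.tsv`
#' (per gene: reference expression, final-group differential expression,
#' log2 fold, branch membership). Full numeric precision is kept so that
#' a round trip through [read_report()] recovers every scalar exactly.
#'
#' @param report a `transition_report`.
#' @param dir output directory, created if needed.
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "transition_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_scalars(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       pretty = TRUE)
  utils::write.table(report$projections, file.path(dir, "projections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read back the scalar part of a written report
#' @param path path to a `report.json` written by [write_report()].
#' @return named list of scalar results.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.transition_report <- function(x, ...) {
  cat("State-transition report\n")
  cat(sprintf("  genes: %d   samples: %d initial + %d final\n",
              x$n_genes, x$n_initial, x$n_final))
  cat(sprintf("  PC1 variance fraction: %.1f%%\n",
              100 * x$pca$variance_fractions[1L]))
  cat(sprintf("  <x1> final: %.4g   radii: %.4g / %.4g\n",
              x$geometry$mean_x1, x$geometry$R_initial,
              x$geometry$R_final))
  cat(sprintf("  d range: [%.4g, %.4g]   exponents: over %.3g, under %.3g\n",
              x$tails$d_min, x$tails$d_max, x$tails$upsilon_over,
              x$tails$upsilon_under))
  cat(sprintf("  differential genes: %d over + %d under (fraction %.4g)\n",
              x$tails$n_over, x$tails$n_under,
              x$tails$differential_fraction))
  cat("  transition class:", x$class, "\n")
  invisible(x)
}
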