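#' Draw Pareto-tailed fold factors by inverse-CDF sampling
#'
#' Over-expression branch: `d = d0 * U^(-1/alpha)` with U uniform(0,1),
#' so the survival count `#{d >= t}` decays as `t^(-alpha)` for
#' `t >= d0`. Under-expression branch: `d = d0 * U^(+1/alpha)`, so
#' `#{d <= t}` grows as `t^(+alpha)` for `t <= d0`. Inverse-CDF sampling
#' makes the planted tail law exact, not asymptotic.
#'
#' @param n number of draws.
#' @param alpha positive Pareto tail index; large alpha concentrates the
#'   folds at the onset `d0`.
#' @param d0 tail onset: `>= 1` for the over branch, in `(0, 1]` for the
#'   under branch.
#' @param branch `"over"` or `"under"`.
#' @return numeric vector of n fold factors.
#' @export
sample_pareto_folds <- function(n, alpha, d0, branch = c("over", "under")) {
  branch <- match.arg(branch)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("alpha must be a single positive number", call. = FALSE)
  }
  if (branch == "over" && d0 < 1) {
    stop("over-branch onset d0 must be >= 1", call. = FALSE)
  }
  if (branch == "under" && (d0 <= 0 || d0 > 1)) {
    stop("under-branch onset d0 must lie in (0, 1]", call. = FALSE)
  }
  u <- stats::runif(n)
  if (branch == "over") d0 * u^(-1 / alpha) else d0 * u^(1 / alpha)
}

#' Configuration for the synthetic two-state generator
#'
#' @param G gene count (at least 10).
#' @param n_initial,n_final sample counts per group.
#' @param mu_b,sigma_b natural-log mean and sd of the lognormal baseline
#'   expression profile (heavy-tailed positive baseline).
#' @param sigma_n sd (log2 units) of the multiplicative lognormal
#'   within-group noise applied to every value.
#' @param f_over,f_under fractions of genes receiving planted over-/
#'   under-expression fold changes in the final state; `f_over + f_under`
#'   must not exceed 1.
#' @param alpha_over,alpha_under Pareto tail indices of the planted folds.
#' @param d0_over,d0_under tail onsets (defaults 2 and 1/2, aligned with
#'   the 2-fold differential thresholds).
#' @param seed integer RNG seed; the generator is fully reproducible.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(G = 10000L, n_initial = 20L, n_final = 20L,
                         mu_b = 3, sigma_b = 1.5, sigma_n = 0.3,
                         f_over = 0.02, f_under = 0.02,
                         alpha_over = 2, alpha_under = 2,
                         d0_over = 2, d0_under = 0.5, seed = 1L) {
  cfg <- list(G = as.integer(G), n_initial = as.integer(n_initial),
              n_final = as.integer(n_final), mu_b = mu_b, sigma_b = sigma_b,
              sigma_n = sigma_n, f_over = f_over, f_under = f_under,
              alpha_over = alpha_over, alpha_under = alpha_under,
              d0_over = d0_over, d0_under = d0_under, seed = as.integer(seed))
  if (cfg$G < 10L) stop("G must be at least 10", call. = FALSE)
  if (cfg$n_initial < 1L || cfg$n_final < 1L) {
    stop("each group needs at least one sample", call. = FALSE)
  }
  if (cfg$f_over < 0 || cfg$f_under < 0 || cfg$f_over + cfg$f_under > 1) {
    stop("fractions must be non-negative with f_over + f_under <= 1",
         call. = FALSE)
  }
  if (cfg$sigma_b <= 0 || cfg$sigma_n < 0) {
    stop("scale parameters must be positive (sigma_n may be 0)",
         call. = FALSE)
  }
  if (cfg$alpha_over <= 0 || cfg$alpha_under <= 0) {
    stop("Pareto indices must be positive", call. = FALSE)
  }
  if (cfg$d0_over < 1) stop("d0_over must be >= 1", call. = FALSE)
  if (cfg$d0_under <= 0 || cfg$d0_under > 1) {
    stop("d0_under must lie in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Preset configurations emulating the three studied data regimes
#'
#' Three scales of state transition are emulated:
#' \describe{
#'   \item{`ltee-like`}{experimental-evolution scale: 4290 genes,
#'     8 + 8 samples, ~25 perturbed genes (fraction ~1/170, mostly
#'     silenced), steep tails (indices 10 over, 4 under) — a continuous
#'     transition.}
#'   \item{`ad-like`}{neurodegeneration scale: 50281 genes, 47 + 28
#'     samples, ~110 perturbed genes (fraction ~1/460, mostly
#'     over-expressed), steep tails (8 over, 9 under) — continuous.}
#'   \item{`tumor-like`}{carcinogenesis scale: 60483 genes, 72 + 739
#'     samples, ~1/10 of genes perturbed (silencing dominant), heavy
#'     tails (1.4 over, 0.7 under) — discontinuous.}
#' }
#' `G` rescales the gene count for demo runs while keeping the perturbed
#' fractions; sample counts are kept.
#'
#' @param name preset name.
#' @param G optional reduced gene count.
#' @param seed RNG seed.
#' @return a `synth_config`.
#' @export
synth_preset <- function(name = c("ltee-like", "ad-like", "tumor-like"),
                         G = NULL, seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    "ltee-like" = synth_config(
      G = 4290L, n_initial = 8L, n_final = 8L,
      f_over = 5 / 4290, f_under = 20 / 4290,
      alpha_over = 10, alpha_under = 4, seed = seed),
    "ad-like" = synth_config(
      G = 50281L, n_initial = 47L, n_final = 28L,
      f_over = 100 / 50281, f_under = 10 / 50281,
      alpha_over = 8, alpha_under = 9, seed = seed),
    "tumor-like" = synth_config(
      G = 60483L, n_initial = 72L, n_final = 739L,
      f_over = 0.04, f_under = 0.06,
      alpha_over = 1.4, alpha_under = 0.7, seed = seed)
  )
  if (!is.null(G)) cfg$G <- as.integer(G)
  if (cfg$G < 10L) stop("G must be at least 10", call. = FALSE)
  cfg
}

#' Generate a synthetic two-state expression dataset with known truth
#'
#' Baseline expression `b_g` is lognormal (natural-log parameters `mu_b`,
#' `sigma_b`). Initial-group values are `b_g * 2^eps` with
#' `eps ~ N(0, sigma_n^2)` i.i.d. per cell; final-group values are
#' `b_g * fold_g * 2^eps`, where `fold_g = 1` except for disjoint gene
#' sets drawn without replacement that receive Pareto-tailed fold factors
#' from [sample_pareto_folds()]. Sets RNG state from `cfg$seed`, so two
#' runs with the same config are identical.
#'
#' @param cfg a `synth_config` (see also [synth_preset()]).
#' @return list with `expr` (genes x samples matrix, initial samples
#'   first), `samples` (sample table as in [read_sample_table()]) and
#'   `truth` (list: `fold` per-gene true factors, `over_genes`,
#'   `under_genes`, `config`).
#' @export
generate_two_state_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n_over <- round(cfg$f_over * cfg$G)
  n_under <- round(cfg$f_under * cfg$G)
  if (cfg$f_over > 0 && n_over < 1L) {
    warning("f_over * G below 1: no over-expressed gene planted")
  }
  if (cfg$f_under > 0 && n_under < 1L) {
    warning("f_under * G below 1: no under-expressed gene planted")
  }
  set.seed(cfg$seed)
  gene_ids <- sprintf("gene_%05d", seq_len(cfg$G))
  baseline <- exp(stats::rnorm(cfg$G, cfg$mu_b, cfg$sigma_b))

  perturbed <- sample.int(cfg$G, n_over + n_under)
  over_idx <- perturbed[seq_len(n_over)]
  under_idx <- perturbed[seq_len(n_under) + n_over]
  fold <- rep(1, cfg$G)
  if (n_over > 0L) {
    fold[over_idx] <- sample_pareto_folds(n_over, cfg$alpha_over,
                                          cfg$d0_over, "over")
  }
  if (n_under > 0L) {
    fold[under_idx] <- sample_pareto_folds(n_under, cfg$alpha_under,
                                           cfg$d0_under, "under")
  }

  noise <- function(n_samples) {
    if (cfg$sigma_n == 0) {
      matrix(1, cfg$G, n_samples)
    } else {
      2^matrix(stats::rnorm(cfg$G * n_samples, 0, cfg$sigma_n),
               cfg$G, n_samples)
    }
  }
  expr_i <- baseline * noise(cfg$n_initial)
  expr_f <- (baseline * fold) * noise(cfg$n_final)
  expr <- cbind(expr_i, expr_f)
  sample_ids <- c(sprintf("init_%03d", seq_len(cfg$n_initial)),
                  sprintf("final_%03d", seq_len(cfg$n_final)))
  dimnames(expr) <- list(gene_ids, sample_ids)

  samples <- build_sample_table(
    sample_id = sample_ids,
    group = rep(c("initial", "final"), c(cfg$n_initial, cfg$n_final))
  )
  list(
    expr = expr,
    samples = samples,
    truth = list(fold = stats::setNames(fold, gene_ids),
                 over_genes = gene_ids[over_idx],
                 under_genes = gene_ids[under_idx],
                 config = cfg)
  )
}
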