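test_that("group differential expression is the geometric mean of d", {
  y <- rbind(g1 = c(1, 3), g2 = c(0, 0), g3 = c(-2, 0))
  colnames(y) <- c("a", "b")
  fold <- make_fold(y, ref_ids = c("a", "b"))
  d <- group_differential(fold, c("a", "b"))
  expect_equal(unname(d["g1"]), 4)       # geometric mean of 2 and 8
  expect_equal(unname(d["g2"]), 1)
  expect_equal(unname(d["g3"]), 1 / 2)   # gm of 1/4 and 1

  # single-sample group: that sample's d unchanged
  expect_equal(group_differential(fold, "a"), c(g1 = 2, g2 = 1, g3 = 0.25))
  # per-sample mode keeps the matrix
  expect_equal(dim(group_differential(fold, c("a", "b"),
                                      per_sample = TRUE)), c(3L, 2L))
  expect_error(group_differential(fold, character(0)), "empty")
})

test_that("anchoring identity: reference samples have group d = 1 exactly", {
  withr::with_seed(9, {
    fold <- random_anchored_fold(30, 8, 4)
    d_ref <- group_differential(fold, fold$reference_sample_ids)
    expect_equal(max(abs(d_ref - 1)), 0, tolerance = 1e-12)
  })
})

test_that("cumulative branches count inclusively and hit the boundaries", {
  cc <- cumulative_curves(c(0.5, 1, 2), grid = c(0.5, 1, 2))
  expect_equal(cc$over$counts, c(3, 2, 1))
  expect_equal(cc$under$counts, c(1, 2, 3))

  # default grid: all genes at the extremes
  d <- c(0.2, 0.7, 1, 1.3, 8)
  cc2 <- cumulative_curves(d, n_grid = 50)
  expect_equal(cc2$over$counts[1], length(d))
  expect_equal(cc2$under$counts[50], length(d))
  # monotone branches
  expect_true(all(diff(cc2$over$counts) <= 0))
  expect_true(all(diff(cc2$under$counts) >= 0))

  expect_error(cumulative_curves(c(1, -2)), "positive")
})

test_that("per-sample curves average the per-sample counts", {
  # sample 1 has 4 genes in the over tail at d0 = 3, sample 2 has none
  D <- cbind(c(4, 5, 6, 7, 1, 1), c(1, 1, 1, 1, 1, 1))
  cc <- cumulative_curves(D, grid = c(1, 3))
  expect_equal(cc$over$counts[cc$over$grid == 3], 2)  # (4 + 0) / 2
  expect_equal(cc$over$counts[cc$over$grid == 1], 6)
})

test_that("branch counts conserve the gene total with exact tie bookkeeping", {
  withr::with_seed(27, {
    d <- round(2^rnorm(500), 1)   # rounding forces plenty of ties
    grid <- sort(unique(c(d, 0.3, 1, 2.7)))
    cc <- cumulative_curves(d, grid = grid)
    ties <- vapply(grid, function(g) sum(d == g), numeric(1))
    expect_equal(cc$over$counts + cc$under$counts,
                 rep(length(d), length(grid)) + ties)
  })
})

test_that("pareto fit recovers exact power laws on both branches", {
  grid <- exp(seq(log(1), log(10), length.out = 40))
  over <- structure(list(branch = "over", grid = grid,
                         counts = 5000 * grid^(-2), n_genes = 5000),
                    class = "tail_curve")
  fit <- fit_pareto(over, 1, 10)
  expect_equal(fit$exponent, -2, tolerance = 1e-10)
  expect_equal(fit$pareto_index, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  ugrid <- exp(seq(log(1 / 3), log(1), length.out = 20))
  under <- structure(list(branch = "under", grid = ugrid,
                          counts = 300 * ugrid^4, n_genes = 1000),
                     class = "tail_curve")
  fit_u <- fit_pareto(under, 1 / 3, 1)
  expect_equal(fit_u$exponent, 4, tolerance = 1e-10)

  expect_error(fit_pareto(over, 11, 20), "fewer than 3")
  expect_error(fit_pareto(over, 5, 2), "d_lo")
})

test_that("pareto fit recovers a sampled tail index within Monte-Carlo error", {
  withr::with_seed(55, {
    n <- 1e4
    d_tail <- sample_pareto_folds(n, alpha = 1.5, d0 = 2, branch = "over")
    d <- c(d_tail, rep(1, 9 * n))   # regularized bulk at d = 1
    cc <- cumulative_curves(d, n_grid = 300)
    fit <- fit_pareto(cc$over, 2.5, 20)
    expect_equal(fit$exponent, -1.5, tolerance = 0.1)
  })
})

test_that("slope-change detection finds a constructed breakpoint", {
  grid <- exp(seq(log(1), log(10), length.out = 60))
  # d^-10 below 2 glued continuously to d^-2 above 2
  counts <- ifelse(grid < 2, 1e6 * grid^(-10), 1e6 * 2^(-8) * grid^(-2))
  curve <- structure(list(branch = "over", grid = grid, counts = counts,
                          n_genes = 1e6), class = "tail_curve")
  res <- detect_slope_change(curve, c(1.5, 2, 3))
  expect_equal(res$breakpoint, 2)
  expect_equal(res$left$exponent, -10, tolerance = 0.05)
  expect_equal(res$right$exponent, -2, tolerance = 0.05)

  # degenerate: a pure power law gives the same exponent in both segments
  pure <- structure(list(branch = "over", grid = grid,
                         counts = 1e4 * grid^(-3), n_genes = 1e4),
                    class = "tail_curve")
  res_p <- detect_slope_change(pure, c(2, 3))
  expect_equal(res_p$left$exponent, res_p$right$exponent,
               tolerance = 0.05)

  # breakpoint beyond the data leaves an empty segment
  expect_error(detect_slope_change(curve, 1000), "3 usable points")
})

test_that("extremes use strict thresholds on the proper side of one", {
  res <- extremes_and_counts(c(0.25, 1, 5), t_over = 2, t_under = 1 / 3)
  expect_equal(res, list(d_min = 0.25, d_max = 5, n_over = 1, n_under = 1))

  flat <- extremes_and_counts(rep(1, 4))
  expect_equal(flat$n_over + flat$n_under, 0)
  expect_equal(c(flat$d_min, flat$d_max), c(1, 1))

  # strictness: a gene exactly at the threshold is not counted
  expect_equal(extremes_and_counts(2, t_over = 2)$n_over, 0)
  expect_error(extremes_and_counts(c(1, 2), t_over = 0.5), "exceed 1")
})

test_that("transition classification is monotone with a documented tie rule", {
  expect_equal(classify_transition(1 / 500)$class, "continuous")
  expect_equal(classify_transition(1 / 10)$class, "discontinuous")
  expect_equal(classify_transition(0.02)$class, "discontinuous") # boundary

  # monotone: increasing the fraction never flips back to continuous
  fr <- seq(0, 1, by = 0.05)
  classes <- vapply(fr, function(f) classify_transition(f)$class, "")
  flips <- which(classes == "discontinuous")
  expect_true(all(diff(flips) == 1) && max(flips) == length(fr))

  geom <- cloud_stats(data.frame(
    sample_id = paste0("s", 1:4),
    group = factor(rep(c("initial", "final"), each = 2),
                   levels = c("initial", "final")),
    x1 = c(-1, 1, 9, 11)))
  cls <- classify_transition(0.2, geom)
  expect_equal(cls$criteria$overlap_ratio, 10 / (sqrt(2) + sqrt(2)))
  expect_error(classify_transition(1.2), "0, 1")
})
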