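proj_df <- function(x1_init, x1_final, x2_init = NULL, x2_final = NULL) {
  n_i <- length(x1_init)
  n_f <- length(x1_final)
  df <- data.frame(
    sample_id = paste0("s", seq_len(n_i + n_f)),
    group = factor(rep(c("initial", "final"), c(n_i, n_f)),
                   levels = c("initial", "final")),
    x1 = c(x1_init, x1_final),
    stringsAsFactors = FALSE
  )
  if (!is.null(x2_init)) df$x2 <- c(x2_init, x2_final)
  df
}

test_that("cloud centers and radii follow the n-1 standard deviation", {
  proj <- proj_df(c(-1, 1), c(1, 3))
  geom <- cloud_stats(proj)
  expect_equal(geom$final$center, 2)
  expect_equal(geom$final$radius, sqrt(2))   # sd of {1, 3}
  expect_equal(geom$initial$center, 0)
  expect_equal(geom$intercenter_distance, 2)

  # ddof = 0 population variant
  geom0 <- cloud_stats(proj, ddof = 0)
  expect_equal(geom0$final$radius, 1)

  # identical final samples: zero radius, center at the common value
  geom_c <- cloud_stats(proj_df(c(-1, 1), c(5, 5, 5)))
  expect_equal(geom_c$final$center, 5)
  expect_equal(geom_c$final$radius, 0)

  expect_error(cloud_stats(proj_df(c(-1, 1), 7)), "fewer than 2")
})

test_that("initial cloud of fitting samples is centered at the origin", {
  withr::with_seed(23, {
    fold <- random_anchored_fold(60, 12, 6)
    model <- fit_refpca(fold, K = 2)
    tab <- build_sample_table(fold$sample_ids,
                              rep(c("initial", "final"), each = 6))
    proj <- project_samples(fold, model, samples = tab)
    geom <- cloud_stats(proj)
    expect_lt(abs(geom$initial$center), 1e-8)
  })
})

test_that("radius over all fitting samples equals sqrt(lambda_1)", {
  withr::with_seed(14, {
    fold <- random_anchored_fold(50, 10, 5)
    model <- fit_refpca(fold, K = 1)
    proj <- project_samples(fold, model)
    # population-style second moment about the origin (the reference),
    # not about the pooled mean: sum x1^2 / (N-1) = lambda_1
    expect_equal(sqrt(sum(proj$x1^2) / (nrow(proj) - 1)),
                 sqrt(model$eigenvalues[1]), tolerance = 1e-8)
  })
})

test_that("translating the final cloud shifts centers, not radii", {
  base <- proj_df(c(-2, 0, 2), c(3, 5, 10))
  geom <- cloud_stats(base)
  shifted <- base
  shifted$x1[shifted$group == "final"] <-
    shifted$x1[shifted$group == "final"] + 7
  geom_s <- cloud_stats(shifted)
  expect_equal(geom_s$final$center, geom$final$center + 7)
  expect_equal(geom_s$intercenter_distance,
               geom$intercenter_distance + 7)
  expect_equal(geom_s$final$radius, geom$final$radius)
  expect_equal(geom_s$initial$radius, geom$initial$radius)
})

test_that("coexistence interval is the range intersection, symmetric", {
  overlap <- proj_df(c(-3, 40), c(30, 200))
  expect_equal(coexistence_interval(overlap), c(30, 40))

  disjoint <- proj_df(c(-3, 10), c(50, 200))
  expect_null(coexistence_interval(disjoint))

  nested <- proj_df(c(5, 10), c(0, 50))
  expect_equal(coexistence_interval(nested), c(5, 10))

  # symmetry in the two groups
  swapped <- overlap
  swapped$group <- factor(ifelse(swapped$group == "initial",
                                 "final", "initial"),
                          levels = c("initial", "final"))
  expect_equal(coexistence_interval(swapped),
               coexistence_interval(overlap))
})

test_that("age regression recovers a noiseless line and rejects degeneracy", {
  ages <- c(70, 80, 90, 100, 75, 85)
  proj <- proj_df(2 * ages[1:4] - 10, c(1, 2))
  fit <- suppressWarnings(   # summary.lm flags the perfect fit
    age_drift_regression(proj, c(ages[1:4], NA, NA), "initial"))
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, -10, tolerance = 1e-8)
  expect_equal(fit$n, 4)

  # duplicating points leaves the OLS line unchanged
  proj2 <- proj_df(rep(2 * ages[1:4] - 10, 2), c(1, 2))
  fit2 <- suppressWarnings(
    age_drift_regression(proj2, c(rep(ages[1:4], 2), NA, NA), "initial"))
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-10)

  expect_error(
    age_drift_regression(proj, c(80, 80, 80, 80, NA, NA), "initial"),
    "identical")
  expect_error(
    age_drift_regression(proj, c(70, 80, NA, NA, NA, NA), "initial"),
    "at least 3")
})

test_that("age unrelated to position yields a flat, non-significant slope", {
  withr::with_seed(42, {
    n <- 200
    ages <- runif(n, 70, 100)
    x1 <- rep(c(-1, 1), n / 2) * rexp(n)   # symmetric about 0, age-free
    proj <- proj_df(x1, c(0, 0))
    fit <- age_drift_regression(proj, c(ages, NA, NA), "initial")
    expect_lt(abs(fit$slope), 0.05)
    expect_gt(fit$p_value, 0.05)
  })
})
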