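test_that("null generation is reproducible and well-formed", {
  params <- simulation_params(subjects_per_group = 6)
  nd1 <- build_null_distribution(params, "ratio", m = 10, L = 20,
                                 seed = 11)
  nd2 <- build_null_distribution(params, "ratio", m = 10, L = 20,
                                 seed = 11)
  expect_identical(nd1$deviates, nd2$deviates)
  expect_length(nd1$deviates, 20)
  expect_true(all(is.finite(nd1$deviates)))
  expect_true(all(nd1$deviates >= 0))

  nd3 <- build_null_distribution(params, "ratio", m = 10, L = 20,
                                 seed = 12)
  expect_false(identical(nd1$deviates, nd3$deviates))
})

test_that("the generator refuses a non-null scenario", {
  params <- simulation_params(group_effects = c(0, 1))
  expect_error(build_null_distribution(params, "ratio", L = 20),
               "H0 must hold")
  expect_error(
    build_null_distribution(simulation_params(), "ratio", L = 5),
    "L >= 20")
})

test_that("statistic variants produce finite df_eff-paired deviates", {
  params <- simulation_params(n_measures = 2, subjects_per_group = 6)
  for (statname in c("teststat0", "teststat1R", "teststat1M")) {
    nd <- build_null_distribution(params, statname, m = 10, L = 20,
                                  seed = 13)
    expect_true(all(is.finite(nd$deviates)))
    expect_true(all(is.finite(nd$df_eff)))
    expect_true(all(nd$df_eff >= 1 - 1e-9))
  }
})

test_that("empirical quantiles follow the rank-order rule", {
  nd <- structure(list(deviates = as.numeric(1:100), L = 100L),
                  class = "null_distribution")
  expect_equal(empirical_quantile(nd, 0.05), 5)
  expect_equal(empirical_quantile(nd, 0.501), 51)
  expect_error(empirical_quantile(nd, 0), "P must lie")
  expect_error(empirical_quantile(nd, 1), "P must lie")

  # monotone in P
  set.seed(14)
  nd$deviates <- rexp(100)
  qs <- vapply(seq(0.05, 0.95, by = 0.1),
               function(P) empirical_quantile(nd, P), numeric(1))
  expect_true(all(diff(qs) >= 0))

  nd$deviates <- rep(3.3, 100)
  expect_equal(empirical_quantile(nd, 0.05), 3.3)
  expect_equal(empirical_quantile(nd, 0.95), 3.3)
})

test_that("Monte Carlo p-values follow the add-one counting rule", {
  nd <- structure(list(deviates = as.numeric(1:99), L = 99L, fit = NULL),
                  class = "null_distribution")
  expect_equal(p_value(nd, 0.5), 1 / 100)          # below every deviate
  expect_equal(p_value(nd, 50), (50 + 1) / 100)    # direct count
  expect_equal(p_value(nd, 1e9), 1)
  # median lands near 0.5
  expect_equal(p_value(nd, median(nd$deviates)), 0.51)
})

test_that("quantile-vs-df_eff fits recover exact linear structure", {
  # deviates exactly linear in df_eff, one df level per bin: the binned
  # quantiles lie on the line, so the fit must recover it exactly
  df_eff <- rep(seq(1, 3, length.out = 5), each = 20)
  nd <- structure(list(deviates = 0.2 + 0.45 * df_eff, df_eff = df_eff,
                       L = 100L), class = "null_distribution")
  fit <- quantile_vs_dfeff(nd, P = 0.5, bins = 5)
  expect_equal(fit$a, 0.2, tolerance = 1e-6)
  expect_equal(fit$b, 0.45, tolerance = 1e-6)
  expect_equal(fit$predict(2), 0.2 + 0.9, tolerance = 1e-6)

  # constant df_eff: degenerate fit with zero slope
  nd2 <- structure(list(deviates = rnorm(50, 1), df_eff = rep(2, 50),
                        L = 50L), class = "null_distribution")
  expect_warning(fit2 <- quantile_vs_dfeff(nd2, P = 0.5), "degenerate")
  expect_equal(fit2$b, 0)

  # the df_eff adjustment maps every deviate onto the line at the
  # observed df, so the p-value flips across the predicted level
  lvl <- fit$predict(2)
  expect_equal(p_value(nd, lvl - 1e-9, df_eff = 2, fit = fit),
               1 / 101)
  expect_equal(p_value(nd, lvl + 1e-9, df_eff = 2, fit = fit), 1)
})

test_that("the 5% Monte Carlo test is type-I calibrated", {
  params <- simulation_params(subjects_per_group = 8, k = 2)
  nd <- build_null_distribution(params, "ratio", m = 12, L = 200,
                                seed = 15)
  q5 <- empirical_quantile(nd, 0.05)
  set.seed(16)
  hits <- vapply(1:150, function(i)
    resample_f(simulate_dataset(params), m = 12,
               per_measure = FALSE)$ratio <= q5, logical(1))
  # binomial 99% band around 0.05 at n = 150
  band <- qbinom(c(0.005, 0.995), 150, 0.05) / 150
  expect_gte(mean(hits), band[1])
  expect_lte(mean(hits), band[2])
})

test_that("null distributions are invariant to the condition offsets", {
  p_a <- simulation_params(subjects_per_group = 6, k = 2,
                           condition_offsets = c(0, 0))
  p_b <- simulation_params(subjects_per_group = 6, k = 2,
                           condition_offsets = c(-5, 40))
  nd_a <- build_null_distribution(p_a, "ratio", m = 10, L = 100,
                                  seed = 17)
  nd_b <- build_null_distribution(p_b, "ratio", m = 10, L = 100,
                                  seed = 18)
  ks <- suppressWarnings(ks.test(nd_a$deviates, nd_b$deviates))
  expect_gt(ks$p.value, 0.01)
})

test_that("comparison study is calibrated when the null is true", {
  params <- simulation_params(subjects_per_group = 8, k = 2)
  cr <- compare_with_classical(params, n_datasets = 100, m = 12, L = 100,
                               seed = 19)
  expect_length(cr$delta_p, 100)
  expect_true(all(abs(cr$delta_p) <= 1))
  # sign counts compatible with 50/50 at alpha = 0.01
  expect_lt(cr$summary$chisq, qchisq(0.99, df = 1))
})

test_that("the F-ratio p-value gains power with the effect size", {
  ps <- lapply(c(0, 2), function(da)
    simulation_params(subjects_per_group = 8, k = 2,
                      group_effects = c(0, da)))
  nd <- build_null_distribution(ps[[1]], "ratio", m = 12, L = 100,
                                seed = 20)
  pv <- lapply(seq_along(ps), function(i) {
    set.seed(30 + i)
    vapply(1:40, function(j) {
      rs <- resample_f(simulate_dataset(ps[[i]]), m = 12,
                       per_measure = FALSE)
      p_value(nd, rs$ratio)
    }, numeric(1))
  })
  expect_lt(median(pv[[2]]), median(pv[[1]]))
})
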