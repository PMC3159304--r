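test_that("univariate decomposition matches hand-computed sums of squares", {
  df <- data.frame(subject = paste0("s", 1:6),
                   group = rep(c("g1", "g2"), each = 3),
                   condition = "c1", x = c(1, 2, 3, 4, 5, 6))
  dec <- manova_decompose(feature_dataset(df))
  # grand mean 3.5, group means 2 and 5: H = 3*1.5^2*2 = 13.5; E = 2+2 = 4
  expect_equal(unname(dec$H[1, 1]), 13.5)
  expect_equal(unname(dec$E[1, 1]), 4)
  expect_equal(dec$eigenvalues[1], 3.375)
  expect_equal(dec$df_h, 1L)
  expect_equal(dec$df_e, 4L)
})

test_that("identical groups give a rank-zero effect", {
  df <- make_long_df(n_per = 3, k = 2, seed = 8)
  df$x <- rep(c(1, 2), each = 6)  # depends on condition only
  dec <- manova_decompose(feature_dataset(df))
  expect_equal(max(abs(dec$H)), 0)
  expect_equal(dec$s, 0L)
  expect_error(manova_f(dec), "degenerate")
})

test_that("decompose agrees with the brute-force SSCP oracle", {
  for (seed in 1:5) {
    n_meas <- 1 + seed %% 3
    fd <- simulate_dataset(
      simulation_params(n_measures = n_meas, subjects_per_group = 4,
                        k = 3, between_measure_corr = 0.3 * (n_meas > 1)),
      seed = 100 + seed)
    dec <- manova_decompose(fd)
    oracle <- brute_sscp(fd)
    expect_equal(unname(dec$H), unname(oracle$H), tolerance = 1e-10)
    expect_equal(unname(dec$E), unname(oracle$E), tolerance = 1e-10)
    expect_equal(dec$df_h, oracle$df_h)
    expect_equal(dec$df_e, oracle$df_e)
    # trace identity against an independent solve()
    expect_equal(sum(dec$eigenvalues),
                 sum(diag(oracle$H %*% solve(oracle$E))),
                 tolerance = 1e-10)
  }
})

test_that("adding a constant to one measure changes nothing", {
  fd <- simulate_dataset(simulation_params(n_measures = 2,
                                           subjects_per_group = 5),
                         seed = 21)
  fd2 <- fd
  fd2$values[, , 1] <- fd2$values[, , 1] + 17.3
  d1 <- manova_decompose(fd)
  d2 <- manova_decompose(fd2)
  expect_equal(d1$H, d2$H, tolerance = 1e-9)
  expect_equal(d1$E, d2$E, tolerance = 1e-9)
  expect_equal(manova_f(d1, "pillai")$value, manova_f(d2, "pillai")$value,
               tolerance = 1e-9)
})

test_that("the three multivariate F constructions obey their formulas", {
  # s = 1, c = 0.5, df_e/df_h = 28: all three equal 14
  dec1 <- forge_dec(H = matrix(0.5), E = matrix(1), df_h = 1, df_e = 28)
  for (st in c("hotelling", "pillai", "roy")) {
    expect_equal(manova_f(dec1, st)$value, 14.0, tolerance = 1e-12)
  }

  # s = 2, c = {1, 1}, df_e/df_h = 28: pillai = (1)/(2-1)*28 = 28
  dec2 <- forge_dec(H = diag(c(1, 1)), E = diag(c(1, 1)),
                    df_h = 2, df_e = 56)
  expect_equal(manova_f(dec2, "pillai")$value, 28)
  expect_equal(manova_f(dec2, "hotelling")$value, 28)
  expect_equal(manova_f(dec2, "roy")$value, 28)

  # univariate reduction: every stattype returns (h2/e2) * df_e/df_h
  fd <- make_fd(n_per = 4, k = 2, seed = 3)
  dec <- manova_decompose(fd)
  for (st in c("hotelling", "pillai", "roy")) {
    expect_equal(manova_f(dec, st)$value, unname(dec$F_univ[1]),
                 tolerance = 1e-12)
  }
})

test_that("s = 1 statistics coincide exactly on real decompositions", {
  fd <- simulate_dataset(simulation_params(n_measures = 3,
                                           subjects_per_group = 6),
                         seed = 31)
  dec <- manova_decompose(fd)
  expect_equal(dec$s, 1L)  # two groups: rank(H E^-1) = df_h = 1
  vals <- vapply(c("hotelling", "pillai", "roy"),
                 function(st) manova_f(dec, st)$value, numeric(1))
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12 * max(vals))
})

test_that("eigen contributions reconstruct the df-adjusted eigenvalues", {
  # diagonal H, E: selection matrix
  decd <- forge_dec(H = diag(c(3, 1)), E = diag(c(1, 1)),
                    df_h = 2, df_e = 20)
  K <- eigen_contributions(decd)
  expect_equal(sort(as.vector(K)), c(0, 0, 1, 1))
  expect_equal(rowSums(K > 0.5), c(1, 1))

  # reconstruction and trace identities on random decompositions
  for (seed in 1:4) {
    fd <- simulate_dataset(
      simulation_params(n_measures = 2, n_groups = 3,
                        subjects_per_group = 5,
                        between_measure_corr = 0.4),
      seed = 200 + seed)
    dec <- manova_decompose(fd)
    K <- eigen_contributions(dec)
    F_diag <- attr(K, "F_diag")
    r <- dec$df_e / dec$df_h
    for (i in seq_len(dec$s)) {
      expect_equal(sum(K[i, ] * F_diag), dec$eigenvalues[i] * r,
                   tolerance = 1e-10)
    }
    expect_equal(sum(K %*% F_diag),
                 sum(diag(dec$H %*% solve(dec$E))) * r,
                 tolerance = 1e-8)
    expect_true(all(K >= 0))
  }

  # rank-one case: every measure contributes its diagonal share (k = 1)
  fd1 <- simulate_dataset(simulation_params(n_measures = 3,
                                            subjects_per_group = 8),
                          seed = 77)
  K1 <- eigen_contributions(manova_decompose(fd1))
  expect_equal(unname(K1[1, ]), rep(1, 3), tolerance = 1e-8)
})

test_that("variance components recover the generative parameters", {
  params <- simulation_params(subjects_per_group = 100, sigma_e = 1,
                              sigma_p = 2)
  fd <- simulate_dataset(params, seed = 41)
  vc <- estimate_variance_components(fd)
  expect_lt(abs(vc$sigma_e2 - 1) / 1, 0.15)
  expect_lt(abs(vc$sigma_p2 - 4) / 4, 0.15)

  # cross-check the mean squares against aov() on the same table
  df <- as.data.frame(fd)
  av <- summary(aov(v1 ~ condition + subject, data = df))[[1]]
  rn <- trimws(rownames(av))
  expect_equal(vc$ms_subject, av[rn == "subject", "Mean Sq"],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(vc$ms_residual, av[rn == "Residuals", "Mean Sq"],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("variance components handle degenerate inputs", {
  # zero noise: offsets only
  fd <- simulate_dataset(simulation_params(sigma_e = 0, sigma_p = 0,
                                           subjects_per_group = 4),
                         seed = 1)
  vc <- estimate_variance_components(fd)
  expect_equal(vc$sigma_e2, 0)
  expect_equal(vc$sigma_p2, 0)

  # clamping: no person effect, small sample -> MS_subject can undershoot
  set.seed(12)
  clamped <- FALSE
  for (i in 1:20) {
    fd <- simulate_dataset(simulation_params(sigma_p = 0,
                                             subjects_per_group = 3))
    vc <- estimate_variance_components(fd)
    expect_gte(vc$sigma_p2, 0)
    if (vc$ms_subject < vc$ms_residual) clamped <- TRUE
  }
  expect_true(clamped)

  fd1 <- make_fd(n_per = 3, k = 1)
  expect_error(estimate_variance_components(fd1), "not separable")
})

test_that("classical mixed-model F matches hand and aov computations", {
  # balanced toy: subject means {1,2,3 | 4,5,6}, k = 1
  df <- data.frame(subject = paste0("s", 1:6),
                   group = rep(c("g1", "g2"), each = 3),
                   condition = "c1", x = c(1, 2, 3, 4, 5, 6))
  cf <- classical_mixed_f(feature_dataset(df))
  expect_equal(cf$statistic, 13.5)  # MS_group = 13.5, MS_subj = 1
  expect_equal(cf$df1, 1L)
  expect_equal(cf$df2, 4L)

  # aov oracle on subject means for a k = 4 design
  fd <- simulate_dataset(simulation_params(subjects_per_group = 6),
                         seed = 51)
  cf <- classical_mixed_f(fd)
  sm <- rowMeans(fd$values[, , 1])
  av <- summary(aov(sm ~ factor(fd$group)))[[1]]
  expect_equal(cf$statistic, av[1, "F value"], tolerance = 1e-10,
               ignore_attr = TRUE)
  # k cancels from the F ratio so the subject-mean one-way F is identical
})

test_that("classical mixed-model p-values are calibrated and powered", {
  params <- simulation_params(subjects_per_group = 8)
  set.seed(61)
  pv <- vapply(1:500, function(i)
    classical_mixed_f(simulate_dataset(params))$p.value, numeric(1))
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)

  strong <- simulation_params(subjects_per_group = 15,
                              group_effects = c(0, 10))
  fd <- simulate_dataset(strong, seed = 62)
  expect_lt(classical_mixed_f(fd)$p.value, 0.001)
})
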