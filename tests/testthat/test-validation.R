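test_that("calibration statistics follow their definitions", {
  set.seed(11)
  z <- rnorm(10)
  m <- fit_pls(matrix(z, ncol = 1), 1 + 2 * z, 1)
  cs <- calibration_stats(m, matrix(z, ncol = 1), 1 + 2 * z)
  expect_equal(cs$r2, 1, tolerance = 1e-10)
  expect_equal(cs$RMSEC, 0, tolerance = 1e-10)

  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- rnorm(12)
  m2 <- fit_pls(X, y, 3)
  cs2 <- calibration_stats(m2, X, y)
  yhat <- predict(m2, X)
  expect_equal(cs2$r2, 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  expect_equal(cs2$RMSEC, sqrt(mean((y - yhat)^2)), tolerance = 1e-10)
  expect_error(calibration_stats(m2, X, rep(1, 12)), "constant")
})

test_that("leave-one-out q2 equals the explicit refit oracle and is below r2", {
  set.seed(12)
  X <- matrix(rnorm(8 * 5), 8, 5)
  y <- X[, 1] + rnorm(8, 0, 0.3)
  l <- loo_q2(X, y, 2)
  press <- sum(sapply(1:8, function(i) {
    m <- fit_pls(X[-i, ], y[-i], 2)
    (y[i] - predict(m, X[i, , drop = FALSE]))^2
  }))
  expect_equal(l$q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(l$RMSECV, sqrt(press / 8), tolerance = 1e-10)

  # noiseless linear data: q2 = 1
  z <- rnorm(10)
  expect_equal(loo_q2(matrix(z, ncol = 1), 2 * z, 1)$q2, 1, tolerance = 1e-6)

  # q2 <= r2 and invariance to sample reordering
  for (s in 1:5) {
    set.seed(400 + s)
    X <- matrix(rnorm(14 * 10), 14, 10)
    y <- X[, 1] + rnorm(14, 0, 0.5)
    m <- fit_pls(X, y, 3)
    r2 <- calibration_stats(m, X, y)$r2
    q <- loo_q2(X, y, 3)
    expect_lte(q$q2, r2)
    perm <- sample(14)
    expect_equal(loo_q2(X[perm, ], y[perm], 3)$q2, q$q2, tolerance = 1e-8)
  }
  expect_error(loo_q2(X[1:2, ], y[1:2], 1), "n >= 3")
})

test_that("Y-randomization collapses the correlation and is reproducible", {
  ds <- generate_dataset(generator_config(n_samples = 30, seed = 13))
  desc <- build_descriptor_matrix(ds$sketches, "r_vdw")
  X <- desc$X
  y <- ds$activities$pki
  # degenerate hook: identity permutation reproduces the true model
  m <- fit_pls(X, y, 3)
  r2 <- calibration_stats(m, X, y)$r2
  yr0 <- y_randomization(X, y, 3, perms = list(seq_along(y)))
  expect_equal(yr0$r2_y_rand, r2, tolerance = 1e-8)
  expect_equal(yr0$c_r2_p, 0, tolerance = 1e-6)

  yr1 <- y_randomization(X, y, 3, n_perm = 20, seed = 77)
  yr2 <- y_randomization(X, y, 3, n_perm = 20, seed = 77)
  expect_identical(yr1$r2_perm, yr2$r2_perm)
  expect_lt(yr1$r2_y_rand, r2 - 0.2)
  expect_gt(yr1$c_r2_p, 0)
})

test_that("bootstrap external validation sizes holdouts and scores cycles", {
  # 57 calibration samples at 25% give 14-sample holdouts
  set.seed(14)
  X <- matrix(rnorm(57 * 12), 57, 12)
  y <- X[, 1] + rnorm(57, 0, 0.3)
  bt <- bootstrap_external(X, y, A_max = 4, frac = 0.25, n_iter = 5, seed = 5)
  expect_true(all(lengths(bt$holdouts) == 14))

  # reproducible draws
  bt2 <- bootstrap_external(X, y, A_max = 4, frac = 0.25, n_iter = 5, seed = 5)
  expect_identical(bt$holdouts, bt2$holdouts)
  expect_equal(bt$iterations, bt2$iterations)

  # noiseless rank-3 data: perfect external prediction in every cycle
  Tm <- matrix(rnorm(57 * 3), 57, 3)
  Xr <- Tm %*% matrix(rnorm(3 * 12), 3, 12)
  yy <- as.numeric(Tm %*% c(1, -2, 0.5))
  bt3 <- bootstrap_external(Xr, yy, A_max = 3, frac = 0.25, n_iter = 4, seed = 6)
  expect_true(all(abs(bt3$iterations$r2_pred - 1) < 1e-6))
  expect_true(all(abs(bt3$iterations$ccc - 1) < 1e-6))

  expect_error(bootstrap_external(X[1:8, ], y[1:8], 2, frac = 0.25),
               "too small")
})

test_that("Roy's metrics match a direct-formula oracle", {
  y <- c(7.1, 6.4, 8.0, 7.7, 6.9)
  expect_equal(roy_metrics(y, y)$r2_m, 1, tolerance = 1e-12)
  expect_equal(roy_metrics(y, y)$delta_r2_m, 0, tolerance = 1e-12)

  set.seed(15)
  obs <- rnorm(12, 7, 0.5)
  pred <- obs + rnorm(12, 0.1, 0.3)
  rm <- roy_metrics(obs, pred)
  r2 <- cor(obs, pred)^2
  k <- sum(obs * pred) / sum(pred^2)
  r02 <- 1 - sum((obs - k * pred)^2) / sum((obs - mean(obs))^2)
  expect_equal(rm$r2_m, r2 * (1 - sqrt(abs(r2 - r02))), tolerance = 1e-12)
  kp <- sum(obs * pred) / sum(obs^2)
  r02p <- 1 - sum((pred - kp * obs)^2) / sum((pred - mean(pred))^2)
  expect_equal(rm$r2_m_reverse, r2 * (1 - sqrt(abs(r2 - r02p))), tolerance = 1e-12)
  expect_equal(rm$avg_r2_m, (rm$r2_m + rm$r2_m_reverse) / 2)
  expect_equal(rm$delta_r2_m, abs(rm$r2_m - rm$r2_m_reverse))
  expect_error(roy_metrics(rep(1, 5), 1:5), "zero-variance")
})

test_that("Lin's CCC penalises location shift and never exceeds |r|", {
  y <- rnorm(10, 7)
  expect_equal(ccc(y, y), 1)
  expect_lt(ccc(y, y + 0.5), 1)
  expect_equal(cor(y, y + 0.5), 1)
  for (s in 1:5) {
    set.seed(500 + s)
    a <- rnorm(15); b <- 0.6 * a + rnorm(15, 0.2, 0.4)
    expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
    expect_gte(ccc(a, b), -1)
    expect_lte(ccc(a, b), 1)
  }
  expect_error(ccc(rep(1, 4), rep(2, 4)), "constant")
})

test_that("Williams leverages obey the trace identity and symmetry", {
  set.seed(16)
  X <- matrix(rnorm(12 * 8), 12, 8)
  X[2, ] <- X[1, ]                      # duplicated sample
  y <- X[, 1] + rnorm(12, 0, 0.2)
  y[2] <- y[1]
  m <- fit_pls(X, y, 3)
  w <- williams(m, X, y)
  expect_equal(sum(w$leverage), m$n_components + 1, tolerance = 1e-6)
  expect_equal(w$leverage[1], w$leverage[2], tolerance = 1e-10)
  expect_true(all(w$leverage > 0 & w$leverage <= 1))
})

test_that("a planted 5-sigma response outlier is the only flagged sample", {
  fx <- williams_outlier_fixture(base_seed = 1L)
  flagged <- which(fx$williams$residual_outlier)
  expect_identical(flagged, fx$index)
  expect_gt(abs(fx$williams$stud_residual[fx$index]), 2.5)
})

test_that("the cross-channel summary computes averages, spreads and verdicts", {
  stats <- list(
    r_vdw  = c(r2 = 0.91, q2 = 0.62, ccc = 0.84, delta_r2_m = 0.13),
    epsilon = c(r2 = 0.89, q2 = 0.60, ccc = 0.86, delta_r2_m = 0.12),
    ratio  = c(r2 = 0.90, q2 = 0.61, ccc = 0.82, delta_r2_m = 0.14))
  rep_tab <- channel_summary(stats)
  M <- do.call(cbind, stats)
  expect_equal(rep_tab$Average, unname(rowMeans(M)))
  expect_equal(rep_tab$Std.Dev, unname(apply(M, 1, sd)))
  expect_true(all(rep_tab$verdict[rep_tab$statistic %in%
                                    c("r2", "q2", "ccc", "delta_r2_m")]))
  low <- channel_summary(list(a = c(q2 = 0.4), b = c(q2 = 0.45)))
  expect_false(low$verdict[1])
})
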