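test_that("a one-factor linear response is fit exactly with one component", {
  set.seed(1)
  z <- rnorm(12)
  m <- fit_pls(matrix(z, ncol = 1), 3 + 2 * z, 1)
  expect_lt(max(abs(m$residuals)), 1e-10)
})

test_that("full-rank PLS reproduces the minimum-norm least-squares solution", {
  for (s in 1:4) {
    set.seed(100 + s)
    X <- matrix(rnorm(6 * 4), 6, 4)
    y <- rnorm(6)
    m <- fit_pls(X, y, 4)
    Xc <- scale(X, scale = FALSE)
    b_ls <- MASS::ginv(Xc) %*% (y - mean(y))
    expect_lt(max(abs(m$coefficients - b_ls)), 1e-8)
  }
})

test_that("score vectors are mutually orthogonal and both prediction routes agree", {
  for (s in 1:5) {
    set.seed(200 + s)
    X <- matrix(rnorm(15 * 40), 15, 40)
    y <- rnorm(15)
    m <- fit_pls(X, y, 5)
    G <- crossprod(m$scores)
    off <- G - diag(diag(G))
    expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
    # latent-route prediction equals the coefficient route on training data
    y_lat <- m$y_mean + m$scores %*% m$y_loadings
    expect_lt(max(abs(y_lat - m$fitted.values)), 1e-8)
  }
})

test_that("component selection minimises the brute-force LOO RMSECV curve", {
  # noiseless one-factor data
  set.seed(2)
  z <- rnorm(10)
  expect_equal(select_components(matrix(z, ncol = 1), 1 + z, 1)$A, 1)

  # three planted orthogonal effects, low noise
  set.seed(3)
  n <- 24
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  X <- cbind(Q, matrix(rnorm(n * 5, 0, 0.05), n, 5))
  y <- as.numeric(Q %*% c(1, 2, 3)) + rnorm(n, 0, 0.02)
  sel <- select_components(X, y, 6)
  expect_gte(sel$A, 3)

  # the reported curve matches an explicit refit-per-fold oracle
  oracle <- sapply(1:6, function(A) {
    press <- sum(sapply(seq_len(n), function(i) {
      m <- fit_pls(X[-i, ], y[-i], A)
      (y[i] - predict(m, X[i, , drop = FALSE]))^2
    }))
    sqrt(press / n)
  })
  expect_equal(sel$rmsecv, oracle, tolerance = 1e-10)
  expect_equal(sel$A, which.min(oracle))
})

test_that("prediction obeys the centering identity and checks dimensions", {
  set.seed(5)
  X <- matrix(rnorm(10 * 6), 10, 6)
  y <- rnorm(10)
  m <- fit_pls(X, y, 3)
  expect_equal(predict(m, X), m$fitted.values)
  expect_equal(predict(m, matrix(m$x_mean, nrow = 1)), m$y_mean)
  expect_error(predict(m, X[, 1:4]), "columns")
})

test_that("a constant column never changes the fit", {
  set.seed(6)
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- rnorm(10)
  m1 <- fit_pls(X, y, 3)
  m2 <- fit_pls(cbind(X, 5), y, 3)
  expect_equal(m2$fitted.values, m1$fitted.values, tolerance = 1e-10)
  expect_equal(m2$coefficients[6], 0)
})

test_that("RMSEC is non-increasing in the number of components", {
  set.seed(7)
  X <- matrix(rnorm(14 * 20), 14, 20)
  y <- rnorm(14)
  rmsec <- sapply(1:6, function(A) sqrt(mean(fit_pls(X, y, A)$residuals^2)))
  expect_true(all(diff(rmsec) <= 1e-12))
})

test_that("requesting more components than the data supports is an error", {
  set.seed(8)
  X <- matrix(rnorm(10), 10, 1) %*% t(rnorm(6))   # rank 1
  y <- rnorm(10)
  expect_error(fit_pls(X, y, 3), "attainable maximum")
  expect_error(fit_pls(matrix(rnorm(20), 5, 4), rnorm(5), 5), "exceeds")
})

test_that("VIP satisfies its normalisation and collapses to |w| for one component", {
  set.seed(9)
  X <- matrix(rnorm(16 * 30), 16, 30)
  y <- rnorm(16)
  m <- fit_pls(X, y, 4)
  v <- vip(m)
  expect_equal(sum(v^2), ncol(X), tolerance = 1e-6)
  m1 <- fit_pls(X, y, 1)
  v1 <- vip(m1)
  w <- abs(m1$weights[, 1])
  expect_equal(v1 / sqrt(mean(v1^2)), w / sqrt(mean(w^2)), tolerance = 1e-10)
})

test_that("interpretation maps localise the planted substituent effects", {
  # R3 dominates the planted variation; the maps should say so
  pos <- list(R1 = list(pool = c("H", "CH3"), effects = c(H = 0, CH3 = -0.15)),
              R2 = list(pool = c("H", "Cl"), effects = c(H = 0, Cl = 0.1)),
              R3 = list(pool = c("H", "CH3", "Cl", "OCH3"),
                        effects = c(H = 0, CH3 = 0.5, Cl = 0.9, OCH3 = 1.3)),
              R4 = list(pool = c("H", "F"), effects = c(H = 0, F = 0.1)))
  ds <- generate_dataset(generator_config(seed = 21, positions = pos))
  desc <- build_descriptor_matrix(ds$sketches, "r_vdw")
  m <- fit_pls(desc, ds$activities$pki, select_components(desc, ds$activities$pki, 10)$A)

  regions <- substituent_pixel_regions(ds$truth$config)
  all_region <- sort(unique(unlist(regions)))
  # top-5% VIP pixels sit in substituent territory
  v <- vip(m)
  top <- desc$kept_columns[v >= quantile(v, 0.95)]
  expect_gte(mean(top %in% all_region), 0.8)

  # coefficient map: R3 (largest planted spread) has the strongest mean signal
  b_by_pos <- sapply(names(regions), function(tag)
    mean(abs(m$coefficients[desc$kept_columns %in% regions[[tag]]])))
  expect_identical(names(which.max(b_by_pos)), "R3")

  # refold is the exact inverse of unfolding on kept pixels
  mp <- refold(m$coefficients, m, kind = "coefficient")
  flat <- as.vector(t(unclass(mp)))
  expect_equal(flat[desc$kept_columns], m$coefficients)
  expect_true(all(is.na(flat[-desc$kept_columns])))
  ones <- refold(rep(1, length(desc$kept_columns)), desc, kind = "vip")
  expect_equal(unique(ones[!is.na(ones)]), 1)
  expect_error(refold(1:3, desc), "length")
})

test_that("kernel-space refits are exactly equivalent to explicit NIPALS refits", {
  for (s in 1:3) {
    set.seed(300 + s)
    X <- matrix(rnorm(15 * 25), 15, 25)
    y <- X[, 1] * 2 + rnorm(15, 0, 0.5)
    K <- tcrossprod(X)
    test <- c(2, 9)
    train <- setdiff(1:15, test)
    cv <- miaqsar:::.pls_kernel_cv(K, y, train, test, 4)
    for (A in 1:4) {
      m <- fit_pls(X[train, ], y[train], A)
      expect_equal(cv$pred[, A], predict(m, X[test, , drop = FALSE]),
                   tolerance = 1e-8)
    }
  }
})

test_that("models survive a JSON save / load round-trip", {
  ds <- generate_dataset(generator_config(n_samples = 15, seed = 31))
  desc <- build_descriptor_matrix(ds$sketches, "epsilon")
  m <- fit_pls(desc, ds$activities$pki, 3)
  tf <- withr::local_tempfile(fileext = ".json")
  save_model(m, tf)
  m2 <- load_model(tf)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(predict_sketches(m2, ds$sketches[1:3]),
               predict_sketches(m, ds$sketches[1:3]))
})
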