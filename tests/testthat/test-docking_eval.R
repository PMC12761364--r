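test_that("pose RMSD matches the per-atom loop oracle", {
  a <- matrix(rnorm(15), 5, 3)
  expect_equal(pose_rmsd(a, a), 0)
  expect_equal(pose_rmsd(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1)), 5)
  set.seed(51)
  b <- a + matrix(rnorm(15, 0, 0.8), 5, 3)
  acc <- 0
  for (i in 1:5) acc <- acc + sum((a[i, ] - b[i, ])^2)
  expect_equal(pose_rmsd(a, b), sqrt(acc / 5), tolerance = 1e-12)
  expect_error(pose_rmsd(a, b[1:4, ]), "shape")
})

test_that("Docking Accuracy reproduces the closed-interval scoring rule", {
  # 83 poses within 2 A, 17 between 2 and 3 A
  rmsd <- c(runif(83, 0.4, 2), runif(17, 2.1, 3))
  expect_equal(docking_accuracy(rmsd, 2, 3), 0.915)
  # boundary poses count inside their closed limits
  expect_equal(docking_accuracy(c(2, 2, 3, 3), 2, 3), 0.75)
  expect_equal(docking_accuracy(rep(1, 10), 2, 3), 1)
  expect_equal(docking_accuracy(rep(5, 10), 2, 3), 0)
  expect_error(docking_accuracy(numeric(0)), "empty")
  expect_error(docking_accuracy(c(-1, 1)), ">= 0")
  expect_error(docking_accuracy(1, 3, 2), "l < h")
})

test_that("DA is order-invariant and monotone when poses improve", {
  set.seed(52)
  for (rep in 1:10) {
    rmsd <- runif(40, 0, 5)
    da <- docking_accuracy(rmsd)
    expect_equal(docking_accuracy(sample(rmsd)), da)
    j <- sample(40, 1)
    better <- rmsd
    better[j] <- better[j] * runif(1)
    expect_gte(docking_accuracy(better), da)
  }
})

test_that("binding-energy totals exclude the internal term and flag misprints", {
  rows <- table4_rows()
  tot <- total_binding_energy(rows)
  expect_equal(tot$total[rows$id == "P1"], -9.57)
  expect_equal(tot$total[rows$id == "A7"], -9.12)
  expect_equal(tot$total[rows$id == "B1"], -8.56)
  # the crystal-pose row is the one inconsistent entry at 0.015 kcal/mol
  expect_false(tot$consistent[rows$id == "Mesotrione_Cryst"])
  expect_equal(tot$total[rows$id == "Mesotrione_Cryst"], -5.29)
  expect_identical(sum(tot$consistent), 5L)

  zero <- data.frame(electrostatic = 0, vdw = 0, internal = 0, torsional = 0)
  expect_equal(total_binding_energy(zero)$total, 0)
  expect_error(total_binding_energy(zero[, -2]), "missing energy term")

  # linearity in each term
  r <- data.frame(electrostatic = -2, vdw = -7, internal = -1, torsional = 1.5)
  t0 <- total_binding_energy(r)$total
  r2 <- r; r2$vdw <- r2$vdw - 1
  expect_equal(total_binding_energy(r2)$total, t0 - 1)
})

test_that("activity-energy regression matches closed-form OLS and lack-of-fit oracles", {
  # replicate means exactly on a line, replicates with spread: no lack of fit
  en <- rep(seq(-9, -6, length.out = 5), each = 3)
  sprd <- rep(c(-0.1, 0, 0.1), 5)
  d1 <- data.frame(id = rep(letters[1:5], each = 3), energy = en,
                   pki = 5.6 - 0.25 * en + sprd)
  f1 <- activity_energy_fit(d1)
  expect_equal(f1$lof_F, 0, tolerance = 1e-10)

  # perfectly collinear, zero spread
  d2 <- d1; d2$pki <- 5.6 - 0.25 * d2$energy
  f2 <- suppressWarnings(activity_energy_fit(d2))  # summary.lm perfect-fit note
  expect_equal(f2$r2, 1, tolerance = 1e-12)

  # seeded data against independent formula oracles
  set.seed(53)
  d3 <- data.frame(id = rep(sprintf("P%d", 1:8), each = 3),
                   energy = rep(runif(8, -10, -6), each = 3))
  d3$pki <- 5.6 - 0.25 * d3$energy + rnorm(24, 0, 0.15)
  f3 <- activity_energy_fit(d3)
  x <- d3$energy; yy <- d3$pki
  slope <- sum((x - mean(x)) * (yy - mean(yy))) / sum((x - mean(x))^2)
  intercept <- mean(yy) - slope * mean(x)
  expect_equal(f3$slope, slope, tolerance = 1e-10)
  expect_equal(f3$intercept, intercept, tolerance = 1e-10)
  res <- yy - intercept - slope * x
  expect_equal(f3$r2, 1 - sum(res^2) / sum((yy - mean(yy))^2), tolerance = 1e-10)
  # lack-of-fit decomposition via the nested-model ANOVA oracle
  an <- anova(lm(pki ~ energy, d3), lm(pki ~ factor(energy), d3))
  expect_equal(f3$lof_F, an$F[2], tolerance = 1e-8)
  expect_equal(f3$lof_p, an$`Pr(>F)`[2], tolerance = 1e-8)

  expect_error(activity_energy_fit(d3[1:6, ]), "distinct")
  expect_error(activity_energy_fit(d3[-1, ]), "exactly 3")
})
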