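test_that("exact DVH is a step function of the dose and matches direct counting", {
  spec <- dvh_spec()
  # constant dose: all volume above thresholds up to the dose, none after
  D <- array(50, c(4, 4, 4)); M <- array(1, c(4, 4, 4))
  v <- exact_dvh(D, M, spec)
  expect_identical(v, as.numeric(spec$thresholds <= 50))

  D2 <- array(0, c(2, 2, 1)); D2[] <- c(10, 20, 30, 40)
  M2 <- array(1, c(2, 2, 1))
  expect_equal(exact_dvh(D2, M2, dvh_spec(thresholds = 25)), 0.5)

  expect_error(exact_dvh(D, array(0, c(4, 4, 4))), "empty structure")
})

test_that("sigmoid DVH matches its closed form and converges to the exact curve", {
  one <- array(70, c(1, 1, 1)); M <- array(1, c(1, 1, 1))
  # a voxel exactly on the threshold contributes sigmoid(0) = 1/2
  expect_identical(approx_dvh(one, M, dvh_spec(thresholds = 70)), 0.5)
  # m = 1, beta = 1, 71 Gy vs threshold 70 -> sigmoid(1)
  one71 <- array(71, c(1, 1, 1))
  expect_equal(approx_dvh(one71, M, dvh_spec(thresholds = 70)), plogis(1))

  # steep sigmoid: with all doses at least 0.5 Gy away from every threshold,
  # the smoothed curve collapses onto the exact one
  spec_steep <- dvh_spec(steepness = 1000)
  set.seed(11)
  for (i in 1:5) {
    D <- array(sample(0:79, 512, replace = TRUE) + 0.5, c(8, 8, 8))
    Mk <- array(rbinom(512, 1, 0.4), c(8, 8, 8))
    if (!any(Mk != 0)) Mk[1] <- 1
    expect_lt(max(abs(approx_dvh(D, Mk, spec_steep) - exact_dvh(D, Mk, spec_steep))),
              1e-3)
  }
})

test_that("both DVH forms are non-increasing and the smoothed one stays in (0,1)", {
  set.seed(3)
  spec <- dvh_spec()
  for (i in 1:10) {
    D <- array(runif(216, 0, 80), c(6, 6, 6))
    M <- array(rbinom(216, 1, 0.5), c(6, 6, 6))
    if (!any(M != 0)) M[1] <- 1
    ve <- exact_dvh(D, M, spec); va <- approx_dvh(D, M, spec)
    expect_true(all(diff(ve) <= 0))
    expect_true(all(diff(va) <= 1e-12))
    expect_true(all(va > 0 & va < 1))
    expect_true(all(ve >= 0 & ve <= 1))
  }
})

test_that("the DVH loss is zero at identity, symmetric, and matches a hand-expanded sum", {
  case <- toy_case(seed = 5)
  D <- case$reference_dose$values
  spec <- dvh_spec()
  expect_identical(dvh_loss(D, D, case$structures, spec), 0)

  set.seed(6)
  D2 <- D + array(rnorm(length(D), 0, 3), dim(D))
  expect_equal(dvh_loss(D, D2, case$structures, spec),
               dvh_loss(D2, D, case$structures, spec))

  # independent summation oracle over both structures and all thresholds
  manual <- 0
  for (nm in names(case$structures$masks)) {
    Mk <- case$structures$masks[[nm]]
    idx <- which(Mk == 1)
    for (t in spec$thresholds) {
      va <- mean(1 / (1 + exp(-(D[idx] - t))))
      vb <- mean(1 / (1 + exp(-(D2[idx] - t))))
      manual <- manual + (va - vb)^2
    }
  }
  manual <- manual / (2 * length(spec$thresholds))
  expect_equal(dvh_loss(D, D2, case$structures, spec), manual, tolerance = 1e-10)

  empty <- structure_set(list(a = array(0, dim(D))))
  expect_error(dvh_loss(D, D2, empty, spec), "no nonempty")
})

test_that("relabeling structures leaves the DVH loss unchanged", {
  case <- toy_case(seed = 8)
  D <- case$reference_dose$values
  set.seed(9)
  D2 <- D + array(rnorm(length(D)), dim(D))
  sw <- structure_set(rev(case$structures$masks), rev(case$structures$roles))
  expect_equal(dvh_loss(D, D2, case$structures), dvh_loss(D, D2, sw))
})

test_that("the combined objective weights its terms as w1*MSE + w2*DVH", {
  w <- loss_weights(1, 0.1)
  expect_equal(hdadose:::combine_loss_terms(w, 0.5, 0.3), 0.53)

  case <- toy_case(seed = 7)
  D <- case$reference_dose$values
  set.seed(10)
  D2 <- pmax(D + array(rnorm(length(D), 0, 2), dim(D)), 0)
  l <- combined_loss(D, D2, case$structures, dvh_spec(), w)
  expect_equal(l$total, 1 * l$mse + 0.1 * l$dvh)
  expect_equal(l$mse, mean((D - D2)^2))

  # w2 = 0 reduces exactly to the plain MSE
  l0 <- combined_loss(D, D2, case$structures, dvh_spec(), loss_weights(1, 0))
  expect_identical(l0$total, l0$mse)
})

test_that("the analytic loss gradient matches central finite differences", {
  set.seed(12)
  shape <- c(4, 4, 4)
  Dt <- array(runif(64, 0, 70), shape)
  Dp <- array(runif(64, 0, 70), shape)
  M <- array(rbinom(64, 1, 0.5), shape); M[1] <- 1
  ss <- structure_set(list(PTV = M))
  spec <- dvh_spec(thresholds = seq(0, 80, by = 4))
  w <- loss_weights(1, 0.1)
  g <- combined_loss_grad(Dt, Dp, ss, spec, w)
  eps <- 1e-5
  for (i in c(1, 9, 23, 40, 64)) {
    Dp1 <- Dp; Dp1[i] <- Dp[i] + eps
    Dp2 <- Dp; Dp2[i] <- Dp[i] - eps
    num <- (combined_loss(Dt, Dp1, ss, spec, w)$total -
            combined_loss(Dt, Dp2, ss, spec, w)$total) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
  # masked voxels with differing curves feel a DVH pull beyond plain MSE
  gd <- combined_loss_grad(Dt, Dp, ss, spec, loss_weights(0, 1))
  expect_true(all(abs(gd[M == 1]) > 0))
  expect_true(all(gd[M == 0] == 0))
})

test_that("dvh_table returns tidy per-structure curves", {
  case <- toy_case()
  tab <- dvh_table(case$reference_dose, case$structures)
  expect_s3_class(tab, "dvh_table")
  expect_identical(sort(unique(tab$structure)), c("PTV", "spinal_cord"))
  expect_equal(nrow(tab), 2 * 81)
  expect_true(all(tab$volume_fraction >= 0 & tab$volume_fraction <= 1))
  p <- ggplot2::autoplot(tab)
  expect_s3_class(p, "ggplot")
})
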