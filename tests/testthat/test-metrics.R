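test_that("dose percentiles follow the descending ceil-rank convention", {
  M <- array(1, c(2, 5, 1))
  u <- array(70, c(2, 5, 1))
  for (p in c(99, 98, 95, 50, 2)) expect_equal(dose_percentile(u, M, p), 70)

  D <- array(seq(10, 100, by = 10), c(2, 5, 1))
  expect_equal(dose_percentile(D, M, 95), 10)  # rank ceil(9.5) = 10 of 10
  expect_equal(dose_percentile(D, M, 50), 60)  # rank 5 descending
  expect_equal(dose_percentile(D, M, 2), 100)  # rank 1

  set.seed(1)
  for (i in 1:10) {
    Dv <- array(runif(125, 0, 80), c(5, 5, 5))
    ps <- vapply(c(99, 98, 95, 50, 2), function(p) dose_percentile(Dv, array(1, dim(Dv)), p),
                 numeric(1))
    expect_true(all(diff(ps) >= 0))  # D99 <= D98 <= D95 <= D50 <= D2
    # brute-force rank enumeration oracle
    srt <- sort(as.vector(Dv), decreasing = TRUE)
    expect_identical(ps[1], srt[ceiling(0.99 * 125)])
    expect_identical(ps[4], srt[ceiling(0.50 * 125)])
  }
  expect_error(dose_percentile(D, M, 0), "in \\(0, 100\\)")
})

test_that("coverage and Dmax are fractions of prescription with exhaustive oracles", {
  case <- toy_case(seed = 3)
  ctx <- prescription_context(70)
  D <- array(70, dim(case$ct))
  one <- which(case$structures$masks$PTV == 0)[1]
  D[one] <- 1.06 * 70
  cov <- coverage_and_max(D, case$structures, ctx)
  expect_equal(cov$d95, 1)
  expect_equal(cov$dmax, 1.06)

  set.seed(4)
  Dr <- array(runif(length(D), 0, 90), dim(D))
  cv <- coverage_and_max(Dr, case$structures, ctx)
  expect_identical(cv$dmax, max(Dr) / 70)
  srt <- sort(Dr[case$structures$masks$PTV == 1], decreasing = TRUE)
  expect_identical(cv$d99, srt[ceiling(0.99 * length(srt))] / 70)
})

test_that("homogeneity indices match an explicit percentile oracle", {
  case <- toy_case()
  ctx <- prescription_context(70)
  u <- array(64, dim(case$ct))
  h <- homogeneity(u, case$structures, ctx)
  expect_equal(h$h1, 0)
  expect_equal(h$h2, 1)

  # linear dose 60..70 across the target voxels
  D <- array(0, dim(case$ct))
  idx <- which(case$structures$masks$PTV == 1)
  vals <- seq(60, 70, length.out = length(idx))
  D[idx] <- vals
  h2 <- homogeneity(D, case$structures, ctx)
  srt <- sort(vals, decreasing = TRUE)
  n <- length(vals)
  d2 <- srt[ceiling(0.02 * n)]; d98 <- srt[ceiling(0.98 * n)]; d50 <- srt[ceiling(0.5 * n)]
  expect_equal(h2$h1, (d2 - d98) / d50)
  expect_equal(h2$h2, srt[ceiling(0.95 * n)] / d50)
  expect_gte(h2$h1, 0)
})

test_that("conformity measures match set-count oracles and their inequality", {
  case <- toy_case()
  ctx <- prescription_context(70)
  ptv <- case$structures$masks$PTV
  # the prescription isodose exactly covers the PTV
  D <- array(0, dim(ptv)); D[ptv == 1] <- 70
  cf <- conformity(D, case$structures, ctx)
  expect_equal(cf$ci, 1); expect_equal(cf$vant_riet, 1)

  # V100 twice the PTV size: full coverage, halved selectivity
  D2 <- D
  outside <- which(ptv == 0)[seq_len(sum(ptv))]
  D2[outside] <- 70
  cf2 <- conformity(D2, case$structures, ctx)
  expect_equal(cf2$ci, 1); expect_equal(cf2$vant_riet, 0.5)

  # no voxel reaches prescription
  cf0 <- conformity(array(1, dim(ptv)), case$structures, ctx)
  expect_equal(cf0$vant_riet, 0)

  set.seed(5)
  for (i in 1:10) {
    Dr <- array(runif(length(ptv), 0, 90), dim(ptv))
    cfr <- conformity(Dr, case$structures, ctx)
    v100 <- Dr >= 70
    expect_identical(cfr$ci, sum(v100 & ptv == 1) / sum(ptv))
    expect_lte(cfr$vant_riet, cfr$ci + 1e-12)
  }
})

test_that("mean dose error is a per-structure percent of prescription", {
  case <- toy_case()
  ctx <- prescription_context(70)
  D <- case$reference_dose$values
  z <- mean_dose_error(D, D, case$structures, ctx)
  expect_true(all(z$mean_dose_error_pct == 0))

  off <- mean_dose_error(D, D + 0.7, case$structures, ctx)
  expect_equal(off$mean_dose_error_pct, rep(1, nrow(off)))

  set.seed(6)
  D2 <- D + array(rnorm(length(D), 0, 2), dim(D))
  e <- mean_dose_error(D, D2, case$structures, ctx)
  for (k in seq_len(nrow(e))) {
    idx <- which(case$structures$masks[[e$structure[k]]] == 1)
    manual <- 0
    for (i in idx) manual <- manual + abs(D[i] - D2[i])
    expect_equal(e$mean_dose_error_pct[k], manual / length(idx) / 70 * 100,
                 tolerance = 1e-10)
  }
})

test_that("Vx agrees with the exact DVH at the same threshold", {
  M <- array(1, c(3, 3, 3))
  expect_equal(vxx(array(40, dim(M)), M, 30), 100)
  expect_equal(vxx(array(20, dim(M)), M, 30), 0)
  set.seed(7)
  D <- array(runif(27, 0, 60), dim(M))
  for (x in c(10, 30, 35)) {
    expect_identical(vxx(D, M, x), 100 * exact_dvh(D, M, dvh_spec(thresholds = x)))
  }
})

test_that("the method comparison is a two-tailed equal-variance Student t-test", {
  same <- compare_methods(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  r <- compare_methods(c(1, 2, 3), c(2, 3, 4))
  # hand computation: pooled variance 1, t = -1/sqrt(2/3), 4 df
  t_hand <- -1 / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(r$statistic, t_hand)
  expect_equal(r$p_value, 2 * pt(t_hand, df = 4))

  expect_equal(compare_methods(c(2, 3, 4), c(1, 2, 3))$p_value, r$p_value)
  expect_equal(compare_methods(c(5, 5), c(5, 5))$p_value, 1)
  expect_error(compare_methods(1, c(1, 2)), "at least 2")
})

test_that("plan and cohort reports assemble the full metric set", {
  cohort <- generate_cohort(tiny_phantom_spec(seed = 41), 3)
  gt <- cohort_metrics(cohort)
  expect_equal(nrow(gt), 3)
  expect_true(all(c("d99", "d98", "d95", "dmax", "h1", "h2", "ci", "vant_riet")
                  %in% names(gt)))
  # H1 and H2 are recomputable from stored percentiles by construction
  cs <- cohort[[1]]
  pm <- plan_metrics(cs$reference_dose, cs$structures,
                     prescription_context(cs$prescription),
                     reference = cs$reference_dose, case_id = cs$case_id)
  expect_equal(pm$mean_error_target_pct, 0)
  errs <- attr(pm, "structure_errors")
  expect_true(all(errs$mean_dose_error_pct == 0))
  sm <- summarize_metrics(gt)
  expect_true(all(c("metric", "mean", "sd", "n") %in% names(sm)))
  p <- plot_dose_error(errs)
  expect_s3_class(p, "ggplot")
})
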