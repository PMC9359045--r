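# Dosimetric plan-quality measurements: coverage percentiles, maximum dose,
# homogeneity, conformity, per-structure mean dose error, Vx, and the
# between-method t-test. All voxels are treated as equal-volume.

#' Prescription context
#'
#' The prescription level and the name of the target structure against which
#' coverage, homogeneity and conformity are measured. The 100% isodose set
#' `V100` is the set of voxels receiving at least the prescription.
#'
#' @param prescription prescription dose in Gy, `> 0`.
#' @param target_name structure treated as the PTV (default `"PTV"`).
#' @return An object of class `prescription_context`.
#' @export
prescription_context <- function(prescription, target_name = "PTV") {
  if (prescription <= 0) stop("prescription must be > 0")
  structure(list(prescription = prescription, target_name = target_name),
            class = "prescription_context")
}

as_ctx <- function(ctx) {
  if (inherits(ctx, "prescription_context")) return(ctx)
  if (is.numeric(ctx)) return(prescription_context(ctx))
  stop("ctx must be a prescription_context or a prescription in Gy")
}

target_mask <- function(structures, ctx) {
  m <- structures$masks[[ctx$target_name]]
  if (is.null(m)) stop("empty structure: target '", ctx$target_name, "' not present")
  if (!any(m != 0)) stop("empty structure: target '", ctx$target_name, "' has no voxels")
  m
}

#' Dose percentile Dp
#'
#' The dose received by at least `p`% of the structure's volume: masked doses
#' are sorted in descending order and Dp is the value at rank
#' `ceiling(p/100 * n)` (the lower empirical quantile, so D99 <= D98 <= D95
#' <= D50 <= D2 always holds).
#'
#' @param D dose ([dose_volume()] or 3D array).
#' @param M binary mask with at least one voxel.
#' @param p percent in (0, 100).
#' @return Dose in the units of `D`.
#' @export
dose_percentile <- function(D, M, p) {
  if (p <= 0 || p >= 100) stop("p must be in (0, 100)")
  d <- sort(masked_doses(D, M), decreasing = TRUE)
  d[ceiling(p / 100 * length(d))]
}

#' Target coverage and maximum dose
#'
#' D99, D98 and D95 of the target structure and the global maximum voxel
#' dose, all as fractions of the prescription.
#'
#' @param D dose in Gy.
#' @param structures a [structure_set()] containing the target.
#' @param ctx a [prescription_context()] (or a prescription in Gy).
#' @return Named list `d99`, `d98`, `d95`, `dmax`.
#' @export
coverage_and_max <- function(D, structures, ctx) {
  ctx <- as_ctx(ctx)
  M <- target_mask(structures, ctx)
  Dv <- as_volume_array(D)
  list(d99 = dose_percentile(Dv, M, 99) / ctx$prescription,
       d98 = dose_percentile(Dv, M, 98) / ctx$prescription,
       d95 = dose_percentile(Dv, M, 95) / ctx$prescription,
       dmax = max(Dv) / ctx$prescription)
}

#' Homogeneity indices
#'
#' `H1 = (D2 - D98) / D50` (0 for a perfectly uniform target) and
#' `H2 = D95 / D50` (1 for a perfectly uniform target), both within the
#' target structure.
#'
#' @inheritParams coverage_and_max
#' @return Named list `h1`, `h2`.
#' @export
homogeneity <- function(D, structures, ctx) {
  ctx <- as_ctx(ctx)
  M <- target_mask(structures, ctx)
  Dv <- as_volume_array(D)
  d50 <- dose_percentile(Dv, M, 50)
  if (d50 <= 0) stop("degenerate plan: D50 of the target is zero")
  list(h1 = (dose_percentile(Dv, M, 2) - dose_percentile(Dv, M, 98)) / d50,
       h2 = dose_percentile(Dv, M, 95) / d50)
}

#' Conformity measures
#'
#' With `V100` the set of voxels at or above the prescription: the conformity
#' index here is the target coverage fraction `|PTV n V100| / |PTV|`, and the
#' van't Riet conformation number is `|PTV n V100|^2 / (|PTV| * |V100|)`
#' (defined as 0 when `V100` is empty). The van't Riet number factorizes as
#' coverage times selectivity, so it never exceeds the conformity index.
#'
#' @inheritParams coverage_and_max
#' @return Named list `ci`, `vant_riet`.
#' @export
conformity <- function(D, structures, ctx) {
  ctx <- as_ctx(ctx)
  M <- target_mask(structures, ctx)
  Dv <- as_volume_array(D)
  v100 <- Dv >= ctx$prescription
  n_t <- sum(M != 0)
  n_iso <- sum(v100)
  n_int <- sum(v100[M != 0])
  list(ci = n_int / n_t,
       vant_riet = if (n_iso == 0) 0 else n_int^2 / (n_t * n_iso))
}

#' Per-structure mean dose error
#'
#' Mean absolute voxel difference inside each structure, as a percentage of
#' the prescription. Empty structures are skipped.
#'
#' @param Dtrue,Dpred doses in Gy on a shared grid.
#' @param structures a [structure_set()].
#' @param ctx a [prescription_context()] (or a prescription in Gy).
#' @return A tibble with `structure`, `role`, `mean_dose_error_pct`.
#' @export
mean_dose_error <- function(Dtrue, Dpred, structures, ctx) {
  ctx <- as_ctx(ctx)
  dt <- as_volume_array(Dtrue); dp <- as_volume_array(Dpred)
  ok <- nonempty_structures(structures)
  tibble::tibble(
    structure = ok,
    role = unname(structures$roles[ok]),
    mean_dose_error_pct = unname(vapply(ok, function(nm) {
      idx <- which(structures$masks[[nm]] != 0)
      mean(abs(dt[idx] - dp[idx])) / ctx$prescription * 100
    }, numeric(1))))
}

#' Vx: percent volume at or above a dose level
#'
#' @param D dose in Gy.
#' @param M binary mask with at least one voxel.
#' @param x dose level in Gy.
#' @return Percent of the structure's voxels with `D >= x`; agrees exactly
#'   with `100 * exact_dvh()` at threshold `x`.
#' @export
vxx <- function(D, M, x) 100 * mean(masked_doses(D, M) >= x)

#' Compare per-case scores of two methods
#'
#' Two-tailed two-sample Student's t-test (equal variance by default,
#' matching the named test; Welch via `var_equal = FALSE`). Two samples with
#' zero variance and equal means return p = 1 by convention.
#'
#' @param scores_a,scores_b numeric vectors of per-case values, each `n >= 2`.
#' @param var_equal assume equal variances (classic Student's t).
#' @param alpha significance level for the `significant` flag.
#' @return A one-row tibble: `estimate_a`, `estimate_b`, `statistic`,
#'   `p_value`, `significant`.
#' @export
compare_methods <- function(scores_a, scores_b, var_equal = TRUE, alpha = 0.05) {
  if (length(scores_a) < 2 || length(scores_b) < 2)
    stop("each sample needs at least 2 values")
  if (sd(scores_a) == 0 && sd(scores_b) == 0 && mean(scores_a) == mean(scores_b)) {
    stat <- 0; p <- 1
  } else {
    ht <- t.test(scores_a, scores_b, var.equal = var_equal)
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  tibble::tibble(estimate_a = mean(scores_a), estimate_b = mean(scores_b),
                 statistic = stat, p_value = p, significant = p < alpha)
}

#' Full per-case plan-quality report
#'
#' All target metrics (coverage, Dmax, homogeneity, conformity) for one dose
#' volume, plus the per-structure mean dose error against a reference if one
#' is given.
#'
#' @param D dose in Gy.
#' @param structures a [structure_set()] containing the target.
#' @param ctx a [prescription_context()] (or a prescription in Gy).
#' @param reference optional reference dose in Gy for the error columns.
#' @param case_id identifier carried into the output.
#' @return A one-row tibble of target metrics, of class `plan_metrics`; the
#'   per-structure error table (if computed) is attached as
#'   `attr(, "structure_errors")`.
#' @export
plan_metrics <- function(D, structures, ctx, reference = NULL, case_id = "case") {
  ctx <- as_ctx(ctx)
  cov <- coverage_and_max(D, structures, ctx)
  hom <- homogeneity(D, structures, ctx)
  con <- conformity(D, structures, ctx)
  out <- tibble::tibble(case_id = case_id,
                        d99 = cov$d99, d98 = cov$d98, d95 = cov$d95, dmax = cov$dmax,
                        h1 = hom$h1, h2 = hom$h2,
                        ci = con$ci, vant_riet = con$vant_riet)
  if (!is.null(reference)) {
    err <- mean_dose_error(reference, D, structures, ctx)
    err$case_id <- case_id
    out$mean_error_target_pct <-
      mean(err$mean_dose_error_pct[err$role == "target"])
    out$mean_error_oar_pct <-
      if (any(err$role == "oar")) mean(err$mean_dose_error_pct[err$role == "oar"]) else NA_real_
    attr(out, "structure_errors") <- err
  }
  class(out) <- c("plan_metrics", class(out))
  out
}

#' Cohort plan-quality report
#'
#' [plan_metrics()] applied case by case over matched lists of predictions
#' and reference cases.
#'
#' @param cases list of [plan_case()] objects (references).
#' @param predictions optional list of predicted doses ([dose_volume()] or
#'   arrays) matched by position; if `NULL`, the reference doses themselves
#'   are scored (the ground-truth row of a report).
#' @param target_name target structure name.
#' @return A tibble with one row per case, of class `plan_metrics`.
#' @export
cohort_metrics <- function(cases, predictions = NULL, target_name = "PTV") {
  rows <- lapply(seq_along(cases), function(i) {
    case <- cases[[i]]
    ctx <- prescription_context(case$prescription, target_name)
    D <- if (is.null(predictions)) case$reference_dose else predictions[[i]]
    ref <- if (is.null(predictions)) NULL else case$reference_dose
    plan_metrics(D, case$structures, ctx, reference = ref, case_id = case$case_id)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("plan_metrics", class(out))
  out
}

#' Cohort mean and SD per metric
#'
#' @param metrics a [cohort_metrics()] tibble.
#' @return A tibble with `metric`, `mean`, `sd`, `n`.
#' @export
summarize_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(dplyr::select(tibble::as_tibble(metrics),
                                            -dplyr::any_of("case_id")),
                              dplyr::everything(),
                              names_to = "metric", values_to = "value")
  dplyr::summarise(dplyr::group_by(long, .data$metric),
                   mean = mean(.data$value, na.rm = TRUE),
                   sd = sd(.data$value, na.rm = TRUE),
                   n = sum(!is.na(.data$value)), .groups = "drop")
}

#' Plot per-structure mean dose error
#'
#' Bar chart of the mean dose error (as % of prescription) per structure,
#' optionally grouped by a `method` column.
#'
#' @param errors a tibble from [mean_dose_error()] (rows from several cases
#'   and/or methods may be concatenated).
#' @return A ggplot object.
#' @export
plot_dose_error <- function(errors) {
  agg_vars <- intersect(c("structure", "method"), names(errors))
  agg <- dplyr::summarise(dplyr::group_by(errors, dplyr::across(dplyr::all_of(agg_vars))),
                          mean_dose_error_pct = mean(.data$mean_dose_error_pct),
                          .groups = "drop")
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$structure,
                                         y = .data$mean_dose_error_pct))
  p <- if ("method" %in% names(agg)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$method), position = "dodge")
  } else p + ggplot2::geom_col()
  p + ggplot2::labs(x = NULL, y = "Mean dose error (% of prescription)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
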