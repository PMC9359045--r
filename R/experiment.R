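# End-to-end orchestration: phantom generation or case loading, training of
# each requested variant x loss combination, prediction on the held-out test
# split, metric reports, and a cross-method comparison table.

#' Run a full dose-prediction experiment
#'
#' Resolves a run configuration (a named list, or the path of a YAML file
#' with the same layout), obtains a cohort (generated phantoms or NIfTI cases
#' on disk), trains every requested architecture-variant / loss combination
#' with a shared split, predicts on the test cases, and writes per-run
#' histories and metric reports plus a cross-method comparison table with
#' two-tailed t-test p-values against the last (proposed) method. The
#' resolved configuration is stored in the run directory, so every artifact
#' is reproducible from it.
#'
#' Configuration fields (all optional unless noted): `out_dir` (required),
#' `cases_dir` (directory of NIfTI cases; otherwise `phantom` settings are
#' used to generate a cohort), `phantom` (arguments of [phantom_spec()] plus
#' `n_cases`), `variants` (default `"hda"`), `losses` (default
#' `c("mse", "mse_dvh")`), `arch` (arguments of [arch_config()]), `train`
#' (arguments of [train_config()]), `split` (arguments of [split_spec()]),
#' `target_name` (default `"PTV"`).
#'
#' @param config named list or path to a YAML file.
#' @return Invisibly, a list with `runs`, `metrics`, `comparison`, `out_dir`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) {
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    for (f in c("out_dir", "cases_dir")) {
      if (!is.null(config[[f]]) && !startsWith(config[[f]], "/"))
        config[[f]] <- file.path(base, config[[f]])
    }
  }
  if (is.null(config$out_dir)) stop("config error: out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  variants <- config$variants %||% "hda"
  losses <- config$losses %||% c("mse", "mse_dvh")
  target_name <- config$target_name %||% "PTV"

  cohort <- if (!is.null(config$cases_dir)) {
    stage("load", {
      dirs <- list.dirs(config$cases_dir, recursive = FALSE)
      dirs <- dirs[file.exists(file.path(dirs, "manifest.yaml"))]
      if (length(dirs) == 0) stop("no NIfTI cases under ", config$cases_dir)
      lapply(dirs, read_nifti_case)
    })
  } else {
    stage("phantom", {
      ph <- config$phantom %||% list()
      n_cases <- ph$n_cases %||% 20L
      ph$n_cases <- NULL
      generate_cohort(do.call(phantom_spec, ph), n_cases)
    })
  }

  split <- do.call(split_spec, config$split %||% list())
  parts <- split_cohort(vapply(cohort, function(c) c$case_id, character(1)), split)
  n_struct <- length(cohort_layout(cohort))

  runs <- list(); metrics <- list()
  for (variant in variants) for (loss in losses) {
    key <- paste(variant, loss, sep = "_")
    run_dir <- file.path(out_dir, key)
    dir.create(run_dir, showWarnings = FALSE)
    run <- stage(paste0("train[", key, "]"), {
      arch_args <- config$arch %||% list()
      arch_args$variant <- variant
      arch_args$in_channels <- 1L + n_struct
      train_args <- config$train %||% list()
      train_args$arch <- do.call(arch_config, arch_args)
      train_args$loss <- loss
      train(cohort, do.call(train_config, train_args),
            split_spec(train = parts$train, val = parts$val, test = parts$test))
    })
    mt <- stage(paste0("evaluate[", key, "]"), {
      test_cases <- cohort[match(parts$test, vapply(cohort, `[[`, "", "case_id"))]
      preds <- lapply(test_cases, function(cs) predict(run, cs))
      cohort_metrics(test_cases, preds, target_name = target_name)
    })
    mt$method <- key
    write.csv(run$history, file.path(run_dir, "history.csv"), row.names = FALSE)
    write.csv(mt, file.path(run_dir, "metrics.csv"), row.names = FALSE)
    saveRDS(run, file.path(run_dir, "run.rds"))
    runs[[key]] <- run
    metrics[[key]] <- mt
  }

  all_metrics <- dplyr::bind_rows(metrics)
  write.csv(all_metrics, file.path(out_dir, "metrics_all.csv"), row.names = FALSE)

  comparison <- NULL
  if (length(metrics) >= 2 && length(parts$test) >= 2) {
    ref_key <- names(metrics)[length(metrics)]
    cols <- c("d99", "d98", "d95", "dmax", "h1", "h2", "ci", "vant_riet")
    comparison <- dplyr::bind_rows(lapply(setdiff(names(metrics), ref_key), function(k) {
      dplyr::bind_rows(lapply(cols, function(cl) {
        cmp <- compare_methods(metrics[[k]][[cl]], metrics[[ref_key]][[cl]])
        tibble::tibble(method = k, reference = ref_key, metric = cl,
                       mean_method = cmp$estimate_a, mean_reference = cmp$estimate_b,
                       p_value = cmp$p_value, significant = cmp$significant)
      }))
    }))
    write.csv(comparison, file.path(out_dir, "comparison.csv"), row.names = FALSE)
  }

  config$variants <- variants; config$losses <- losses
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  invisible(list(runs = runs, metrics = all_metrics, comparison = comparison,
                 out_dir = out_dir))
}

# Run a pipeline stage, rethrowing errors with the stage name attached.
stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}
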