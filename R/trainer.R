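# Cohort splitting, CPU training with Adam, best-validation-epoch model
# selection, and prediction back to Gy.

#' Training configuration
#'
#' The optimization protocol: Adam with learning rate 1e-3, batch size 1,
#' beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7, 200 epochs, and either a plain
#' MSE objective or the weighted MSE + DVH objective.
#'
#' @param arch an [arch_config()]; its `in_channels` is overridden to match
#'   the cohort's channel layout at [train()] time.
#' @param loss `"mse"` or `"mse_dvh"`.
#' @param weights a [loss_weights()]; the DVH weight is zeroed for `"mse"`.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param batch_size fixed at 1 (one volumetric case per step).
#' @param epochs training epochs, `>= 1`.
#' @param seed integer; weight init and per-epoch data order derive from it.
#' @param dvh a [dvh_spec()] for the training objective (in Gy; it is
#'   rescaled onto each case's normalized dose scale internally).
#' @return An object of class `train_config`.
#' @export
train_config <- function(arch, loss = c("mse_dvh", "mse"), weights = loss_weights(),
                         learning_rate = 1e-3, batch_size = 1L, beta1 = 0.9,
                         beta2 = 0.999, epsilon = 1e-7, epochs = 200L, seed = 1L,
                         dvh = dvh_spec()) {
  loss <- match.arg(loss)
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size != 1L) stop("only batch size 1 is supported")
  if (loss == "mse") weights <- loss_weights(weights$w1, 0)
  structure(list(arch = arch, loss = loss, weights = weights,
                 learning_rate = learning_rate, batch_size = 1L, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon, epochs = as.integer(epochs),
                 seed = as.integer(seed), dvh = dvh),
            class = "train_config")
}

#' Split specification
#'
#' Either fractional (train, validation, test) proportions resolved with a
#' seeded shuffle, or explicit case-id lists passed through untouched.
#'
#' @param fractions numeric length-3 summing to 1 (train, val, test).
#' @param seed integer driving the shuffle for fractional splits.
#' @param train,val,test optional explicit character vectors of case ids;
#'   when given they must be disjoint.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.70, val = 0.15, test = 0.15),
                       seed = 1L, train = NULL, val = NULL, test = NULL) {
  explicit <- !is.null(train) || !is.null(val) || !is.null(test)
  if (!explicit && abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 train = train, val = val, test = test, explicit = explicit),
            class = "split_spec")
}

#' Split a cohort into train/validation/test
#'
#' Fractional splits draw a seeded permutation and size the validation and
#' test sets as `round(n * fraction)`, with the remainder going to training.
#' Explicit id lists pass through untouched (after a disjointness check).
#'
#' @param case_ids character vector of case ids.
#' @param spec a [split_spec()].
#' @return A list with `train`, `val`, `test` id vectors.
#' @export
split_cohort <- function(case_ids, spec = split_spec()) {
  if (spec$explicit) {
    ids <- c(spec$train, spec$val, spec$test)
    if (anyDuplicated(ids) > 0)
      stop("invalid argument: explicit split lists overlap")
    return(list(train = spec$train %||% character(),
                val = spec$val %||% character(),
                test = spec$test %||% character()))
  }
  n <- length(case_ids)
  if (n < 3) stop("fractional splits need at least 3 cases")
  n_val <- round(n * spec$fractions[2])
  n_test <- round(n * spec$fractions[3])
  n_train <- n - n_val - n_test
  perm <- with_seed(spec$seed, sample(case_ids))
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[n_train + n_val + seq_len(n_test)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cohort-wide channel layout: structure names in order of first appearance.
cohort_layout <- function(cohort) {
  layout <- character()
  for (case in cohort) layout <- union(layout, names(case$structures$masks))
  layout
}

# Network-ready encoding of one case: input channels, normalized dose target
# (divided by the per-case max, so the target lives in [0, 1]), and the DVH
# spec rescaled onto that normalized scale.
prep_case <- function(case, layout, dvh) {
  x <- assemble_channels(case, layout)
  dmax <- max(case$reference_dose$values)
  if (dmax <= 0) stop("degenerate case '", case$case_id, "': reference dose is all zero")
  list(x = x, y = case$reference_dose$values / dmax, scale = dmax,
       structures = case$structures, dvh = scale_dvh_spec(dvh, dmax))
}

snapshot_params <- function(model) lapply(model$params, function(p) p$value)
restore_params <- function(model, snap) {
  for (nm in names(snap)) model$params[[nm]]$value <- snap[[nm]]
  invisible(model)
}
snapshot_bn <- function(model) lapply(model$bn, function(s) list(mean = s$mean, var = s$var))
restore_bn <- function(model, snap) {
  for (nm in names(snap)) {
    model$bn[[nm]]$mean <- snap[[nm]]$mean
    model$bn[[nm]]$var <- snap[[nm]]$var
  }
  invisible(model)
}

case_loss <- function(model, prep, weights, training = FALSE) {
  out <- net_forward(model, prep$x, training = training)
  pred <- out$value
  dim(pred) <- dim(pred)[1:3]
  loss <- combined_loss(prep$y, pred, prep$structures, prep$dvh, weights)
  list(out = out, pred = pred, loss = loss)
}

#' Train a dose-prediction model
#'
#' Runs the full optimization protocol on a cohort: per-epoch seeded shuffle
#' of the training cases, one Adam step per case (batch size 1), per-epoch
#' training and validation loss tracking, and selection of the weights from
#' the epoch with the lowest validation loss. Losses are computed on the
#' normalized dose scale; the DVH term sees the threshold grid rescaled by
#' each case's normalization so it matches its Gy-space value. Fully
#' reproducible given `cfg$seed`.
#'
#' @param cohort list of [plan_case()] objects.
#' @param cfg a [train_config()].
#' @param split a [split_spec()]; the test ids are carried along untouched.
#'   With an empty validation set, model selection falls back to the training
#'   loss.
#' @return An object of class `dose_train_run` with the best weights loaded,
#'   a per-epoch `history` tibble, and the resolved split and channel layout.
#' @export
train <- function(cohort, cfg, split = split_spec()) {
  ids <- vapply(cohort, function(c) c$case_id, character(1))
  names(cohort) <- ids
  parts <- split_cohort(ids, split)
  if (length(parts$train) == 0) stop("invalid argument: empty training set")
  if (!all(c(parts$train, parts$val, parts$test) %in% ids))
    stop("invalid argument: split references unknown case ids")

  layout <- cohort_layout(cohort)
  arch <- cfg$arch
  arch$in_channels <- 1L + length(layout)
  preps <- lapply(cohort[c(parts$train, parts$val)], prep_case, layout = layout,
                  dvh = cfg$dvh)

  with_seed(cfg$seed, {
    model <- build_model(arch)
    adam <- lapply(model$params, function(p)
      list(m = p$value * 0, v = p$value * 0))
    step <- 0L
    hist <- vector("list", cfg$epochs)
    best <- list(val = Inf, epoch = NA_integer_, params = NULL, bn = NULL)

    for (epoch in seq_len(cfg$epochs)) {
      order_ids <- if (length(parts$train) > 1) sample(parts$train) else parts$train
      tr <- c(total = 0, mse = 0, dvh = 0)
      for (id in order_ids) {
        prep <- preps[[id]]
        ag_start_tape()
        res <- case_loss(model, prep, cfg$weights, training = TRUE)
        if (!is.finite(res$loss$total))
          stop("divergence error: non-finite loss at epoch ", epoch)
        g <- combined_loss_grad(prep$y, res$pred, prep$structures, prep$dvh,
                                cfg$weights)
        dim(g) <- c(dim(g), 1L)
        ag_backward(res$out, g)
        ag_end_tape()
        step <- step + 1L
        adam <- adam_step(model, adam, cfg, step)
        tr <- tr + c(res$loss$total, res$loss$mse, res$loss$dvh)
      }
      tr <- tr / length(order_ids)

      if (length(parts$val) > 0) {
        vl <- vapply(parts$val, function(id) {
          l <- case_loss(model, preps[[id]], cfg$weights)$loss
          c(l$total, l$mse, l$dvh)
        }, numeric(3))
        va <- rowMeans(vl)
      } else va <- unname(tr)

      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, train_total = tr[["total"]], train_mse = tr[["mse"]],
        train_dvh = tr[["dvh"]], val_total = va[1], val_mse = va[2], val_dvh = va[3])
      if (va[1] < best$val) {
        best <- list(val = va[1], epoch = epoch,
                     params = snapshot_params(model), bn = snapshot_bn(model))
      }
    }
    restore_params(model, best$params)
    restore_bn(model, best$bn)
    structure(list(model = model, history = dplyr::bind_rows(hist),
                   best_epoch = best$epoch, best_val_loss = best$val,
                   cfg = cfg, split = parts, layout = layout),
              class = "dose_train_run")
  })
}

# One Adam update over every trainable parameter; zeroes gradients.
adam_step <- function(model, adam, cfg, step) {
  b1 <- cfg$beta1; b2 <- cfg$beta2
  c1 <- 1 - b1^step; c2 <- 1 - b2^step
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st <- adam[[nm]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g * g
    p$value <- p$value - cfg$learning_rate * (st$m / c1) /
      (sqrt(st$v / c2) + cfg$epsilon)
    p$grad <- NULL
    adam[[nm]] <- st
  }
  adam
}

#' @export
print.dose_train_run <- function(x, ...) {
  cat(sprintf("<dose_train_run> %s/%s, %d epochs (best %d, val loss %.4g), %d train / %d val / %d test\n",
              x$cfg$arch$variant, x$cfg$loss, nrow(x$history), x$best_epoch,
              x$best_val_loss, length(x$split$train), length(x$split$val),
              length(x$split$test)))
  invisible(x)
}

#' Per-epoch training history
#'
#' @param x a [train()] result.
#' @param ... ignored.
#' @return The per-epoch loss history as a tibble.
#' @method tidy dose_train_run
#' @export
tidy.dose_train_run <- function(x, ...) x$history

#' One-row training summary
#'
#' @param x a [train()] result.
#' @param ... ignored.
#' @return A one-row tibble: variant, loss, epochs, best epoch and losses,
#'   parameter count, split sizes.
#' @method glance dose_train_run
#' @export
glance.dose_train_run <- function(x, ...) {
  tibble::tibble(variant = x$cfg$arch$variant, loss = x$cfg$loss,
                 epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 final_train_loss = x$history$train_total[nrow(x$history)],
                 n_parameters = count_parameters(x$model),
                 n_train = length(x$split$train), n_val = length(x$split$val),
                 n_test = length(x$split$test))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Predict a dose distribution
#'
#' Single deterministic forward pass in evaluation mode; the normalized
#' network output is clipped at zero and mapped back to Gy with the case's
#' recorded dose normalization (the maximum of its reference dose).
#'
#' @param object a [train()] result.
#' @param case a [plan_case()] with the same grid-and-structure conventions
#'   as the training cohort (missing structures become zero channels).
#' @param ... ignored.
#' @return A [dose_volume()] in Gy on the case grid.
#' @export
predict.dose_train_run <- function(object, case, ...) {
  x <- assemble_channels(case, object$layout)
  v <- net_predict(object$model, x)
  scale <- max(case$reference_dose$values)
  dose_volume(pmax(v, 0) * scale, spacing = case$spacing)
}

#' Plot a training history
#'
#' @param object a [train()] result.
#' @param ... ignored.
#' @return A ggplot object of train/validation loss per epoch.
#' @method autoplot dose_train_run
#' @export
autoplot.dose_train_run <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history[, c("epoch", "train_total", "val_total")],
                           -"epoch", names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss", colour = NULL) +
    ggplot2::theme_minimal()
}
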