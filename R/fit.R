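#' Fit the PERMA multi-topology graph attention predictor
#'
#' Trains the full pipeline — PERMA token embedding, per-topology GCN + GAT
#' encoding with graph-level attention fusion, cross-modal enhancement,
#' five-head transformer encoding and dual sigmoid heads — by minimizing the
#' consistency-regularized multi-task loss with AdamW. Training is
#' transductive: the four relationship graphs are built once over the whole
#' cohort and message passing always runs over the full graph, while losses
#' and metrics only ever read the relevant split's rows (labels of
#' validation/test students never enter a gradient). Early stopping watches
#' the validation total loss with the configured patience and the returned
#' parameters come from the best validation epoch. The run is fully
#' reproducible from `config$seed`.
#'
#' @param cohort a labelled [perma_cohort()] (wellbeing and PERMA labels),
#'   features scaled to `[0, 1]`.
#' @param config a [permanet_config()].
#' @param prior a [perma_prior()]; defaults to the block-aligned prior.
#' @param topologies optional pre-built [build_topology_set()]; built from
#'   the cohort at `config$graph_threshold` when missing.
#' @return An object of class `"permanet"` with components `params`,
#'   `history` (per-epoch data frame), `best_epoch`, `stop_reason`, `split`,
#'   `config`, `prior`, `cohort`, `topologies`, plus fitted-cohort
#'   predictions and fusion weights. Supports `print()`, `summary()`,
#'   `predict()`, `coef()`, `residuals()` and `plot()`.
#' @export
#' @examples
#' \donttest{
#' co <- generate_cohort(synthetic_spec(n = 64, seed = 1))
#' fit <- permanet_fit(co, permanet_config("reduced", epochs = 3, seed = 1))
#' fit
#' }
permanet_fit <- function(cohort, config = permanet_config("reduced"),
                         prior = default_perma_prior(cohort$schema),
                         topologies = NULL) {
  stopifnot(inherits(cohort, "perma_cohort"))
  if (!cohort$has_wellbeing || !cohort$has_perma) {
    stopf("training requires both wellbeing and PERMA labels")
  }
  validate_config(config)
  split <- stratified_split(cohort, config)
  if (is.null(topologies)) {
    topologies <- build_topology_set(cohort, prior, config$graph_threshold)
  }
  data <- pnet_prep_data(cohort, topologies)
  labels <- list(wellbeing = cohort$wellbeing, perma = cohort$perma)

  params <- pnet_init_params(cohort$schema$d, nlevels(cohort$learning_style),
                             nlevels(cohort$culture), config, prior,
                             seed = config$seed)
  flat <- pnet_flatten(params)
  opt <- adamw_state(flat)
  n_train <- length(split$train)
  batch <- min(config$batch_size, n_train)
  steps_per_epoch <- ceiling(n_train / batch)
  total_steps <- config$epochs * steps_per_epoch

  history <- vector("list", config$epochs)
  best <- list(total = Inf, epoch = 0L, flat = flat)
  since_best <- 0L
  stop_reason <- "max_epochs"
  step <- 0L
  lr_last <- NA_real_

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      order_idx <- split$train[sample.int(n_train)]
      for (b in seq_len(steps_per_epoch)) {
        rows <- order_idx[((b - 1) * batch + 1):min(b * batch, n_train)]
        step <- step + 1L
        lr_last <- lr_schedule(step, total_steps, config)
        tape <- ad_begin_tape()
        P <- pnet_wrap(pnet_unflatten(flat, params), ad_param)
        fw <- pnet_forward_nodes(P, data, config, train = TRUE)
        loss <- pnet_loss_nodes(fw, labels$wellbeing, labels$perma,
                                config$lambdas, idx = rows)
        if (!is.finite(loss$total$value)) {
          ad_end_tape()
          stopf(paste0("training diverged at epoch %d, step %d ",
                       "(non-finite loss %g); lower the learning rate"),
                epoch, step, loss$total$value)
        }
        ad_backward(loss$total, tape)
        ad_end_tape()
        grads <- flat_grads(P, flat)
        grads <- clip_global_norm(grads, config$grad_clip)
        flat <- adamw_step(flat, grads, opt, lr_last, config)
      }
      # eval-mode pass for the epoch record
      P_eval <- pnet_wrap(pnet_unflatten(flat, params), ad_const)
      fw <- pnet_forward_nodes(P_eval, data, config, train = FALSE)
      bundle <- list(wellbeing = as.vector(fw$wellbeing$value),
                     perma = fw$perma$value)
      tr <- split_loss(bundle, labels, config$lambdas, split$train)
      va <- split_loss(bundle, labels, config$lambdas, split$valid)
      va_mae <- mean(abs(bundle$wellbeing[split$valid] -
                           labels$wellbeing[split$valid]))
      history[[epoch]] <- data.frame(
        epoch = epoch, step = step, lr = lr_last,
        train_total = tr$total, train_wellbeing = tr$wellbeing,
        train_perma = tr$perma, train_consistency = tr$consistency,
        valid_total = va$total, valid_mae = va_mae)
      if (va$total < best$total - 1e-12) {
        best <- list(total = va$total, epoch = epoch, flat = flat)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) {
          stop_reason <- "early_stop"
          break
        }
      }
    }
  })
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  params_best <- pnet_unflatten(best$flat, params)

  P_best <- pnet_wrap(params_best, ad_const)
  fw <- pnet_forward_nodes(P_best, data, config, train = FALSE)
  perma_pred <- fw$perma$value
  colnames(perma_pred) <- perma_dims()
  fitted_bundle <- structure(
    list(wellbeing = as.vector(fw$wellbeing$value), perma = perma_pred),
    class = "perma_predictions")

  structure(
    list(params = params_best, history = history,
         best_epoch = best$epoch, stop_reason = stop_reason,
         split = split, config = config, prior = prior,
         cohort = cohort, topologies = topologies,
         fitted = fitted_bundle, fusion_weights = fw$beta,
         profile = fw$profile),
    class = "permanet")
}

# ---- optimizer internals --------------------------------------------------

lr_schedule <- function(step, total_steps, config) {
  w <- config$warmup_steps
  lr_max <- config$learning_rate
  if (w > 0 && step <= w) return(lr_max * step / w)
  span <- max(total_steps - w, 1L)
  frac <- min((step - w) / span, 1)
  config$lr_min + 0.5 * (lr_max - config$lr_min) * (1 + cos(pi * frac))
}

adamw_state <- function(flat) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(flat, function(x) x * 0)
  st$v <- lapply(flat, function(x) x * 0)
  st$t <- 0L
  st
}

adamw_step <- function(flat, grads, st, lr, config) {
  st$t <- st$t + 1L
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    m_hat <- st$m[[nm]] / bc1
    v_hat <- st$v[[nm]] / bc2
    flat[[nm]] <- flat[[nm]] - lr * (m_hat / (sqrt(v_hat) + config$adam_eps) +
                                       config$weight_decay * flat[[nm]])
  }
  flat
}

flat_grads <- function(P, flat) {
  flatP <- pnet_flatten(P)
  out <- vector("list", length(flat))
  names(out) <- names(flat)
  for (nm in names(flat)) {
    node <- flatP[[nm]]
    out[[nm]] <- if (!is.null(node) && !is.null(node$grad)) node$grad
                 else flat[[nm]] * 0
  }
  out
}

clip_global_norm <- function(grads, clip) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > clip) {
    grads <- lapply(grads, function(g) g * (clip / total))
  }
  grads
}

split_loss <- function(bundle, labels, lambdas, idx) {
  loss_total(list(wellbeing = bundle$wellbeing[idx],
                  perma = bundle$perma[idx, , drop = FALSE]),
             list(wellbeing = labels$wellbeing[idx],
                  perma = labels$perma[idx, , drop = FALSE]),
             lambdas)
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.permanet <- function(x, ...) {
  a <- x$config$arch
  cat(sprintf(
    "PERMA multi-topology graph attention predictor\n  %d students, %d features; %d-layer encoder (width %d)\n",
    x$cohort$n, x$cohort$schema$d, a$n_layers, a$d_model))
  cat(sprintf("  trained %d epoch(s), best validation epoch %d (%s)\n",
              nrow(x$history), x$best_epoch, x$stop_reason))
  cat(sprintf("  validation MAE at best epoch: %.4f\n",
              x$history$valid_mae[x$best_epoch]))
  invisible(x)
}

#' @describeIn permanet_fit Evaluate the fitted model on its held-out test
#'   students (metric report plus mean fusion weights).
#' @param object,x a fitted `"permanet"` object.
#' @param ... unused.
#' @export
summary.permanet <- function(object, ...) {
  idx <- object$split$test
  bundle <- list(wellbeing = object$fitted$wellbeing[idx],
                 perma = object$fitted$perma[idx, , drop = FALSE])
  labels <- list(wellbeing = object$cohort$wellbeing[idx],
                 perma = object$cohort$perma[idx, , drop = FALSE])
  report <- evaluate_predictions(bundle, labels,
                                 epsilon = object$config$epsilon,
                                 pce_weights = object$config$pce_weights,
                                 strata = droplevels(object$cohort$culture[idx]))
  out <- list(report = report,
              mean_fusion = if (!is.null(object$fusion_weights))
                colMeans(object$fusion_weights),
              best_epoch = object$best_epoch,
              history = object$history)
  class(out) <- "summary.permanet"
  out
}

#' @export
print.summary.permanet <- function(x, ...) {
  cat("Held-out test performance:\n")
  print(x$report)
  if (!is.null(x$mean_fusion)) {
    cat("Mean topology fusion weights:\n")
    print(round(x$mean_fusion, 4))
  }
  invisible(x)
}

#' @describeIn permanet_fit Predict well-being and PERMA scores. With
#'   `newdata` (a cohort) the relationship graphs are rebuilt for it;
#'   without, the fitted cohort's predictions are returned.
#' @param newdata optional [perma_cohort()].
#' @export
predict.permanet <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  stopifnot(inherits(newdata, "perma_cohort"))
  topo <- build_topology_set(newdata, object$prior,
                             object$config$graph_threshold)
  forward_full(newdata, topo, object$params, object$config)$bundle
}

#' @describeIn permanet_fit The interpretable `d x 5` feature-to-PERMA score
#'   map.
#' @export
coef.permanet <- function(object, ...) {
  object$params$embed$score_map
}

#' @describeIn permanet_fit Well-being residuals (label minus prediction) on
#'   the fitted cohort.
#' @export
residuals.permanet <- function(object, ...) {
  object$cohort$wellbeing - object$fitted$wellbeing
}

#' @describeIn permanet_fit Plot training curves (`type = "history"`), the
#'   per-student fusion-weight distribution (`type = "fusion"`) or the
#'   attention alignment matrix (`type = "alignment"`).
#' @param type one of `"history"`, `"fusion"`, `"alignment"`.
#' @export
plot.permanet <- function(x, type = c("history", "fusion", "alignment"),
                          ...) {
  type <- match.arg(type)
  if (type == "history") {
    h <- x$history
    graphics::plot(h$epoch, h$train_total, type = "l", col = "steelblue",
                   xlab = "epoch", ylab = "total loss",
                   ylim = range(c(h$train_total, h$valid_total)),
                   main = "Training history")
    graphics::lines(h$epoch, h$valid_total, col = "firebrick")
    graphics::abline(v = x$best_epoch, lty = 3)
    graphics::legend("topright", c("train", "validation"),
                     col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  } else if (type == "fusion") {
    if (is.null(x$fusion_weights)) stopf("model was fitted without the GNN")
    graphics::boxplot(as.data.frame(x$fusion_weights),
                      ylab = "fusion weight",
                      main = "Per-student topology fusion weights")
    graphics::abline(h = 0.25, lty = 3)
  } else {
    if (is.null(x$profile)) stopf("model was fitted without the encoder")
    M <- alignment_matrix(x$profile)
    graphics::image(1:5, 1:5, t(M[5:1, ]), axes = FALSE,
                    xlab = "token", ylab = "head",
                    main = "Attention-PERMA alignment")
    graphics::axis(1, 1:5, perma_dims())
    graphics::axis(2, 1:5, rev(perma_dims()))
  }
  invisible(x)
}

#' Export per-student fusion weights
#'
#' @param object a fitted `"permanet"`.
#' @param path optional CSV destination.
#' @return Data frame `(student_id, beta_cosine, beta_euclidean,
#'   beta_learning, beta_perma)`.
#' @export
fusion_weight_table <- function(object, path = NULL) {
  stopifnot(inherits(object, "permanet"))
  if (is.null(object$fusion_weights)) stopf("model was fitted without the GNN")
  df <- data.frame(student_id = seq_len(nrow(object$fusion_weights)))
  for (k in topology_order()) {
    df[[paste0("beta_", k)]] <- object$fusion_weights[, k]
  }
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
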