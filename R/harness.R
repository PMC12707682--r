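# Baselines and reduced-scale experiment harnesses: stepwise ablation over
# the model's components and hyperparameter sweeps.

#' Mean-predictor baseline
#'
#' Predicts the training-set mean well-being and per-dimension PERMA means
#' for every student — the no-information reference any trained model must
#' beat.
#'
#' @param cohort a labelled [perma_cohort()].
#' @param train_idx training row indices.
#' @return A `"perma_predictions"` bundle over the whole cohort.
#' @export
baseline_mean <- function(cohort, train_idx) {
  stopifnot(cohort$has_wellbeing, cohort$has_perma)
  n <- cohort$n
  perma <- matrix(colMeans(cohort$perma[train_idx, , drop = FALSE]),
                  n, 5, byrow = TRUE, dimnames = list(NULL, perma_dims()))
  structure(list(
    wellbeing = rep(mean(cohort$wellbeing[train_idx]), n),
    perma = perma), class = "perma_predictions")
}

#' Ridge-regression baseline
#'
#' A linear baseline: one ridge regression (via [MASS::lm.ridge()]) per
#' target (overall well-being and each PERMA dimension) on the raw scaled
#' features, predictions clipped to `[0, 1]`.
#'
#' @inheritParams baseline_mean
#' @param lambda ridge penalty (default 1).
#' @return A `"perma_predictions"` bundle over the whole cohort.
#' @export
baseline_ridge <- function(cohort, train_idx, lambda = 1) {
  stopifnot(cohort$has_wellbeing, cohort$has_perma)
  X <- cohort$features
  Xtr <- X[train_idx, , drop = FALSE]
  fit_one <- function(y) {
    fit <- MASS::lm.ridge(y ~ ., data = as.data.frame(Xtr), lambda = lambda)
    clip01(as.vector(cbind(1, X) %*% stats::coef(fit)))
  }
  perma <- vapply(1:5, function(p) fit_one(cohort$perma[train_idx, p]),
                  numeric(cohort$n))
  colnames(perma) <- perma_dims()
  structure(list(wellbeing = fit_one(cohort$wellbeing[train_idx]),
                 perma = perma), class = "perma_predictions")
}

eval_on_test <- function(fit) {
  idx <- fit$split$test
  evaluate_predictions(
    list(wellbeing = fit$fitted$wellbeing[idx],
         perma = fit$fitted$perma[idx, , drop = FALSE]),
    list(wellbeing = fit$cohort$wellbeing[idx],
         perma = fit$cohort$perma[idx, , drop = FALSE]),
    epsilon = fit$config$epsilon, pce_weights = fit$config$pce_weights)
}

#' Stepwise component ablation
#'
#' Trains a ladder of model variants at reduced scale, each adding one
#' component: (a) the token embedding with dual heads only, with an
#' uninformed (Xavier) score map; (b) plus the psychological prior in the
#' embedding initialization; (c) plus the multi-topology GNN with
#' cross-modal enhancement; (d) plus the PERMA-aligned transformer encoder;
#' (e) the full model with the consistency loss switched on. Each variant is
#' trained over `k` seeds and test MAE/PDA/PCI/PCE are reported as
#' mean and standard deviation.
#'
#' @param cohort a labelled [perma_cohort()].
#' @param config base [permanet_config()] (the reduced preset by default).
#' @param k number of seeds per variant (default 3).
#' @param variants optional named list of config-override lists; labels must
#'   be unique. Defaults to the five-step ladder above.
#' @return Data frame with one row per variant: mean and sd of test MAE,
#'   PDA, PCI, PCE over seeds.
#' @export
run_ablation <- function(cohort, config = permanet_config("reduced"), k = 3L,
                         variants = NULL) {
  if (is.null(variants)) {
    variants <- list(
      tokens_heads = list(prior_strength = 0, use_gnn = "none",
                          use_encoder = FALSE,
                          lambdas = c(config$lambdas[1:2], 0)),
      plus_prior = list(use_gnn = "none", use_encoder = FALSE,
                        lambdas = c(config$lambdas[1:2], 0)),
      plus_multi_gnn = list(use_encoder = FALSE,
                            lambdas = c(config$lambdas[1:2], 0)),
      plus_attention = list(lambdas = c(config$lambdas[1:2], 0)),
      full_consistency = list())
  }
  if (is.null(names(variants)) || anyDuplicated(names(variants))) {
    stopf("variant labels must be unique and non-empty")
  }
  rows <- lapply(names(variants), function(lab) {
    per_seed <- vapply(seq_len(k), function(s) {
      cfg <- config
      ov <- variants[[lab]]
      cfg[names(ov)] <- ov
      cfg$seed <- config$seed + s - 1L
      fit <- permanet_fit(cohort, cfg)
      r <- eval_on_test(fit)
      c(mae = r$mae, pda = r$pda, pci = r$pci, pce = r$pce)
    }, numeric(4))
    per_seed <- matrix(per_seed, nrow = 4,
                       dimnames = list(c("mae", "pda", "pci", "pce"), NULL))
    data.frame(variant = lab, k = k,
               mae_mean = mean(per_seed["mae", ]), mae_sd = stats::sd(per_seed["mae", ]),
               pda_mean = mean(per_seed["pda", ]), pda_sd = stats::sd(per_seed["pda", ]),
               pci_mean = mean(per_seed["pci", ]), pci_sd = stats::sd(per_seed["pci", ]),
               pce_mean = mean(per_seed["pce", ]), pce_sd = stats::sd(per_seed["pce", ]))
  })
  do.call(rbind, rows)
}

#' Hyperparameter sweep
#'
#' Trains and evaluates one reduced-scale model per grid point. Grid names
#' address top-level scalar config fields (`learning_rate`, `batch_size`,
#' ...) or architecture fields as `"arch.<field>"` (e.g. `"arch.n_heads"`).
#' Sweeping `arch.d_model` re-derives the GAT head width to keep the
#' concatenated GAT output equal to the model width. A diverging
#' configuration is flagged in the `diverged` column rather than failing the
#' sweep.
#'
#' @param cohort a labelled [perma_cohort()].
#' @param grid named list of value vectors; the sweep runs over
#'   `expand.grid` of them.
#' @param config base [permanet_config()].
#' @return Data frame: one row per grid point with the swept values, test
#'   metrics and a `diverged` flag.
#' @export
run_sweep <- function(cohort, grid, config = permanet_config("reduced")) {
  if (!length(grid) || is.null(names(grid))) {
    stopf("`grid` must be a named list of value vectors")
  }
  pts <- expand.grid(grid, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    cfg <- config
    for (nm in names(pts)) {
      val <- pts[[nm]][i]
      if (startsWith(nm, "arch.")) {
        f <- sub("^arch\\.", "", nm)
        cfg$arch[[f]] <- val
        if (f == "d_model") {
          if (val %% cfg$arch$gat_heads != 0) {
            stopf("d_model %d not divisible by %d GAT heads", val,
                  cfg$arch$gat_heads)
          }
          cfg$arch$gat_head_dim <- val %/% cfg$arch$gat_heads
        }
      } else if (nm %in% names(cfg)) {
        cfg[[nm]] <- val
      } else {
        stopf("unknown config field '%s'", nm)
      }
    }
    validate_config(cfg)
    res <- tryCatch({
      fit <- permanet_fit(cohort, cfg)
      r <- eval_on_test(fit)
      data.frame(mae = r$mae, rmse = r$rmse, pda = r$pda, pci = r$pci,
                 pce = r$pce, diverged = FALSE, note = "")
    }, error = function(e) {
      if (grepl("diverged", conditionMessage(e))) {
        data.frame(mae = NA_real_, rmse = NA_real_, pda = NA_real_,
                   pci = NA_real_, pce = NA_real_, diverged = TRUE,
                   note = conditionMessage(e))
      } else stop(e)
    })
    cbind(pts[i, , drop = FALSE], res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Train the model and baselines and compare them
#'
#' Fits the full predictor plus the mean and ridge baselines on the same
#' split, then runs pairwise paired t-tests on the per-student absolute
#' test errors.
#'
#' @param cohort a labelled [perma_cohort()].
#' @param config a [permanet_config()].
#' @return List with the fitted model (`fit`), the test metric reports per
#'   model (`reports`) and the [compare_models()] table (`comparison`).
#' @export
run_comparison <- function(cohort, config = permanet_config("reduced")) {
  fit <- permanet_fit(cohort, config)
  idx <- fit$split$test
  y <- cohort$wellbeing[idx]
  bundles <- list(
    permanet = list(wellbeing = fit$fitted$wellbeing[idx],
                    perma = fit$fitted$perma[idx, , drop = FALSE]),
    mean_baseline = local({
      b <- baseline_mean(cohort, fit$split$train)
      list(wellbeing = b$wellbeing[idx], perma = b$perma[idx, , drop = FALSE])
    }),
    ridge_baseline = local({
      b <- baseline_ridge(cohort, fit$split$train)
      list(wellbeing = b$wellbeing[idx], perma = b$perma[idx, , drop = FALSE])
    }))
  labels <- list(wellbeing = y,
                 perma = cohort$perma[idx, , drop = FALSE])
  reports <- lapply(bundles, evaluate_predictions, labels = labels,
                    epsilon = config$epsilon,
                    pce_weights = config$pce_weights)
  errors <- lapply(bundles, function(b) abs(b$wellbeing - y))
  list(fit = fit, reports = reports, comparison = compare_models(errors))
}
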