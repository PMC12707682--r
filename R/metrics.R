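# PERMA evaluation framework: MAE/RMSE, dimension accuracy (PDA),
# consistency index (PCI), composite score (PCE), consistency-violation
# rate, and paired-comparison testing.

#' Mean absolute and root-mean-square error
#'
#' @param y,y_hat equal-length numeric vectors, `n >= 1`.
#' @return Named vector `c(mae = , rmse = )`; `rmse >= mae` always.
#' @export
error_metrics <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (!length(y)) stopf("empty input")
  if (length(y) != length(y_hat)) stopf("length mismatch")
  e <- y - y_hat
  c(mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' PERMA Dimension Accuracy
#'
#' One minus the mean absolute error, averaged over the five PERMA
#' dimensions: `PDA = (1/5) sum_p (1 - (1/n) sum_i |y_ip - yhat_ip|)`.
#' With labels and predictions in `[0, 1]`, PDA lies in `[0, 1]`.
#'
#' @param Y,Y_hat `n x 5` matrices of labels and predictions in `[0, 1]`.
#' @return Scalar PDA.
#' @export
pda <- function(Y, Y_hat) {
  Y <- as.matrix(Y); Y_hat <- as.matrix(Y_hat)
  if (!all(dim(Y) == dim(Y_hat)) || ncol(Y) != 5L) {
    stopf("PDA needs two n x 5 matrices of equal shape")
  }
  if (any(Y < 0 | Y > 1) || any(Y_hat < 0 | Y_hat > 1)) {
    stopf("PDA assumes values in [0, 1]; rescale labels first")
  }
  mean(1 - colMeans(abs(Y - Y_hat)))
}

#' PERMA Consistency Index
#'
#' One minus the mean absolute gap between the overall well-being prediction
#' and the mean of the five dimension predictions:
#' `PCI = 1 - (1/n) sum_i |yhat_i - mean_p(yhat_ip)|`. Depends on
#' predictions only, never on labels.
#'
#' @param y_hat length-`n` overall predictions in `[0, 1]`.
#' @param Y_perma `n x 5` dimension predictions in `[0, 1]`.
#' @return Scalar PCI in `[0, 1]`.
#' @export
pci <- function(y_hat, Y_perma) {
  y_hat <- as.numeric(y_hat); Y_perma <- as.matrix(Y_perma)
  if (length(y_hat) != nrow(Y_perma) || ncol(Y_perma) != 5L) {
    stopf("shape mismatch between overall and PERMA predictions")
  }
  1 - mean(abs(y_hat - rowMeans(Y_perma)))
}

#' PERMA Comprehensive Evaluation
#'
#' Weighted composite `PCE = alpha PDA + beta PCI + gamma (1 - RMSE_norm)`
#' with default weights (0.4, 0.3, 0.3). The normalized RMSE divides by the
#' label range (1 for unit-interval labels) and is capped at 1, keeping PCE
#' in `[0, 1]` for unit-interval inputs.
#'
#' @param pda_value,pci_value scalar PDA and PCI.
#' @param rmse scalar RMSE of the overall prediction.
#' @param label_range positive width of the label scale (default 1).
#' @param weights nonnegative `(alpha, beta, gamma)` summing to 1.
#' @return Named vector `c(pce = , rmse_norm = )`.
#' @export
pce <- function(pda_value, pci_value, rmse, label_range = 1,
                weights = c(0.4, 0.3, 0.3)) {
  if (label_range <= 0) stopf("`label_range` must be positive")
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stopf("weights must be nonnegative and sum to 1")
  }
  rmse_norm <- min(1, rmse / label_range)
  c(pce = weights[1] * pda_value + weights[2] * pci_value +
      weights[3] * (1 - rmse_norm),
    rmse_norm = rmse_norm)
}

#' Consistency-violation rate
#'
#' Fraction of students whose overall prediction deviates from the mean of
#' their five PERMA predictions by more than the tolerance `epsilon`.
#'
#' @param bundle a [predict_heads()] result (or list with `wellbeing`,
#'   `perma`).
#' @param epsilon nonnegative tolerance (default 0.1).
#' @return Scalar rate in `[0, 1]`.
#' @export
consistency_violation_rate <- function(bundle, epsilon = 0.1) {
  if (epsilon < 0) stopf("`epsilon` must be nonnegative")
  dev <- abs(as.numeric(bundle$wellbeing) - rowMeans(as.matrix(bundle$perma)))
  mean(dev > epsilon)
}

#' Paired t-test on per-sample prediction errors
#'
#' Two-sided paired t-test on aligned per-sample absolute errors of two
#' models: `t = dbar / (s_d / sqrt(n))` with `n - 1` degrees of freedom and
#' the sample standard deviation using the `n - 1` denominator. Degenerate
#' zero-variance differences are flagged: identical errors give `t = 0,
#' p = 1`; a constant nonzero difference gives `p = 0`.
#'
#' @param errors_a,errors_b aligned per-sample error vectors, `n >= 2`.
#' @return An object of class `"paired_test"`: `t_stat`, `df`, `p_value`,
#'   `mean_diff`, `sd_diff`, `degenerate`.
#' @export
paired_ttest <- function(errors_a, errors_b) {
  a <- as.numeric(errors_a); b <- as.numeric(errors_b)
  if (length(a) != length(b)) stopf("error vectors must be aligned")
  n <- length(a)
  if (n < 2L) stopf("need at least 2 paired samples")
  d <- a - b
  dbar <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    res <- list(t_stat = if (dbar == 0) 0 else sign(dbar) * Inf,
                df = n - 1L,
                p_value = if (dbar == 0) 1 else 0,
                mean_diff = dbar, sd_diff = sd_d, degenerate = TRUE)
    return(structure(res, class = "paired_test"))
  }
  t_stat <- dbar / (sd_d / sqrt(n))
  structure(list(t_stat = t_stat, df = n - 1L,
                 p_value = 2 * stats::pt(-abs(t_stat), n - 1),
                 mean_diff = dbar, sd_diff = sd_d, degenerate = FALSE),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4f, df = %d, p = %.4g (mean diff %.4g)%s\n",
              x$t_stat, x$df, x$p_value, x$mean_diff,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Evaluate predictions against labels
#'
#' Computes the full metric report — MAE, RMSE, PDA, PCI, PCE, normalized
#' RMSE and the consistency-violation rate — on the whole sample and,
#' optionally, per stratum (e.g. per culture).
#'
#' @param bundle a [predict_heads()] result.
#' @param labels list with `wellbeing` and `perma` labels.
#' @param epsilon consistency tolerance (default 0.1).
#' @param pce_weights PCE weights (default `c(0.4, 0.3, 0.3)`).
#' @param strata optional factor of length `n`; when given, the report
#'   carries a per-stratum breakdown.
#' @return An object of class `"perma_metric_report"`.
#' @export
evaluate_predictions <- function(bundle, labels, epsilon = 0.1,
                                 pce_weights = c(0.4, 0.3, 0.3),
                                 strata = NULL) {
  if (is.null(labels$wellbeing) || is.null(labels$perma)) {
    stopf("evaluation requires both wellbeing and PERMA labels")
  }
  one <- function(idx) {
    yw <- as.numeric(labels$wellbeing)[idx]
    Yp <- as.matrix(labels$perma)[idx, , drop = FALSE]
    pw <- as.numeric(bundle$wellbeing)[idx]
    Pp <- as.matrix(bundle$perma)[idx, , drop = FALSE]
    em <- error_metrics(yw, pw)
    pda_v <- pda(Yp, Pp)
    pci_v <- pci(pw, Pp)
    pc <- pce(pda_v, pci_v, em["rmse"], 1, pce_weights)
    list(n = length(idx),
         mae = unname(em["mae"]), rmse = unname(em["rmse"]),
         pda = pda_v, pci = pci_v,
         pce = unname(pc["pce"]), rmse_norm = unname(pc["rmse_norm"]),
         consistency_violation_rate = consistency_violation_rate(
           list(wellbeing = pw, perma = Pp), epsilon))
  }
  n <- length(bundle$wellbeing)
  rep_all <- one(seq_len(n))
  by_stratum <- NULL
  if (!is.null(strata)) {
    strata <- factor(strata)
    if (length(strata) != n) stopf("`strata` must have length n")
    by_stratum <- lapply(split(seq_len(n), strata, drop = TRUE), one)
  }
  structure(c(rep_all,
              list(epsilon = epsilon, pce_weights = pce_weights,
                   strata = by_stratum)),
            class = "perma_metric_report")
}

#' @export
print.perma_metric_report <- function(x, ...) {
  cat(sprintf(
    "<perma_metric_report> n=%d\n  MAE %.4f | RMSE %.4f | PDA %.4f | PCI %.4f | PCE %.4f\n",
    x$n, x$mae, x$rmse, x$pda, x$pci, x$pce))
  cat(sprintf("  consistency violations (eps=%.2f): %.1f%%\n",
              x$epsilon, 100 * x$consistency_violation_rate))
  if (!is.null(x$strata)) {
    for (nm in names(x$strata)) {
      s <- x$strata[[nm]]
      cat(sprintf("  [%s] n=%d MAE %.4f PCE %.4f\n", nm, s$n, s$mae, s$pce))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.perma_metric_report <- function(x, ...) {
  data.frame(n = x$n, mae = x$mae, rmse = x$rmse, pda = x$pda, pci = x$pci,
             pce = x$pce, rmse_norm = x$rmse_norm,
             consistency_violation_rate = x$consistency_violation_rate)
}

#' Pairwise paired-comparison table across models
#'
#' Runs [paired_ttest()] on every unordered model pair and reports per-model
#' MAE, sorted best first. P-values are reported raw by default; Holm
#' adjustment is available via `adjust`.
#'
#' @param model_errors named list (>= 2 entries) of aligned per-sample
#'   absolute-error vectors, one per model.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return List with `models` (data frame of per-model MAE, sorted) and
#'   `pairs` (data frame of pairwise tests).
#' @export
compare_models <- function(model_errors, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (length(model_errors) < 2L) stopf("need at least 2 models")
  if (is.null(names(model_errors)) || anyDuplicated(names(model_errors))) {
    stopf("model errors must be uniquely named")
  }
  lens <- vapply(model_errors, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stopf("all models must be evaluated on the same aligned samples")
  }
  maes <- vapply(model_errors, function(e) mean(abs(e)), numeric(1))
  models <- data.frame(model = names(maes), mae = unname(maes))
  models <- models[order(models$mae), , drop = FALSE]
  rownames(models) <- NULL
  combs <- utils::combn(names(model_errors), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    tt <- paired_ttest(abs(model_errors[[a]]), abs(model_errors[[b]]))
    data.frame(model_a = a, model_b = b, t_stat = tt$t_stat, df = tt$df,
               p_value = tt$p_value, mean_diff = tt$mean_diff,
               degenerate = tt$degenerate)
  }))
  if (adjust == "holm") {
    pairs$p_adjusted <- stats::p.adjust(pairs$p_value, "holm")
  }
  list(models = models, pairs = pairs)
}
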