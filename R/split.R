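#' Stratified train/validation/test split
#'
#' Partitions a cohort into train/validation/test index sets at the
#' configured ratios (default 7:2:1) within every stratum, so each stratum's
#' proportions are preserved to within one sample. Strata default to the
#' crossing of learning style and stress level, with culture added
#' automatically when the cohort is multi-cultural. Strata smaller than 3
#' students are merged into the largest stratum (with a warning). The split
#' is deterministic given `config$seed`.
#'
#' @param cohort a [perma_cohort()].
#' @param config a [permanet_config()] (fields `split_ratios`, `strata`,
#'   `seed`).
#' @return List of disjoint, exhaustive integer index vectors `train`,
#'   `valid`, `test`.
#' @export
stratified_split <- function(cohort, config = permanet_config("reduced")) {
  stopifnot(inherits(cohort, "perma_cohort"))
  ratios <- config$split_ratios
  keys <- config$strata
  if (nlevels(droplevels(cohort$culture)) > 1L && !"culture" %in% keys) {
    keys <- c(keys, "culture")
  }
  parts <- lapply(keys, function(k) cohort[[k]])
  strata <- droplevels(interaction(parts, drop = TRUE, sep = ":"))
  tab <- table(strata)
  small <- names(tab)[tab < 3L]
  if (length(small) && length(tab) > 1L) {
    host <- names(tab)[which.max(tab)]
    warning(sprintf("merging %d stratum(s) with < 3 students into '%s'",
                    length(small), host), call. = FALSE)
    levels(strata)[levels(strata) %in% small] <- host
    strata <- droplevels(strata)
  }
  with_seed(config$seed, {
    out <- list(train = integer(0), valid = integer(0), test = integer(0))
    for (s in levels(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      sizes <- largest_remainder(length(idx), ratios)
      out$train <- c(out$train, idx[seq_len(sizes[1])])
      out$valid <- c(out$valid, idx[sizes[1] + seq_len(sizes[2])])
      out$test <- c(out$test, idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
    }
    lapply(out, sort)
  })
}

# Apportion n into integer counts proportional to `ratios` (sum 1) by the
# largest-remainder rule; each count is within 1 of n * ratio.
largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac_order <- order(exact - base, decreasing = TRUE)
    base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
  }
  as.integer(base)
}
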