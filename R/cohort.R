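#' Construct a student cohort table
#'
#' A cohort bundles an `n x d` feature matrix with its [perma_schema()] and
#' optional labels: an overall well-being score in `[0, 1]`, five PERMA
#' dimension scores in `[0, 1]`, and per-student culture, learning-style and
#' ordinal stress-level metadata. Label presence is all-or-none per label
#' type.
#'
#' @param schema a [perma_schema()].
#' @param features numeric `n x d` matrix, columns ordered as in the schema.
#' @param wellbeing optional length-`n` numeric in `[0, 1]`.
#' @param perma optional `n x 5` numeric matrix in `[0, 1]`, columns P,E,R,M,A.
#' @param culture,learning_style factors (or coercible) of length `n`.
#' @param stress_level ordered factor with levels `low < medium < high`.
#' @return An object of class `"perma_cohort"`.
#' @export
perma_cohort <- function(schema, features, wellbeing = NULL, perma = NULL,
                         culture = NULL, learning_style = NULL,
                         stress_level = NULL) {
  stopifnot(inherits(schema, "perma_schema"))
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 1L) stopf("a cohort must contain at least one student")
  check_matrix(features, ncol = schema$d, name = "features")
  colnames(features) <- schema$feature_names
  if (!all(is.finite(features))) stopf("features must be finite")
  if (!is.null(wellbeing)) {
    wellbeing <- as.numeric(wellbeing)
    if (length(wellbeing) != n) stopf("`wellbeing` must have length n")
    bad <- which(wellbeing < 0 | wellbeing > 1 | !is.finite(wellbeing))
    if (length(bad)) {
      stopf("wellbeing outside [0, 1] at row(s) %s",
            paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (!is.null(perma)) {
    perma <- as.matrix(perma)
    check_matrix(perma, nrow = n, ncol = 5L, name = "perma")
    colnames(perma) <- perma_dims()
    bad <- which(perma < 0 | perma > 1 | !is.finite(perma), arr.ind = TRUE)
    if (nrow(bad)) {
      stopf("PERMA label outside [0, 1] at row %d, column %s",
            bad[1, 1], perma_dims()[bad[1, 2]])
    }
  }
  culture <- factor(culture %||% rep("default", n))
  learning_style <- factor(learning_style %||% rep("style_1", n))
  stress_level <- stress_level %||% rep("medium", n)
  stress_level <- factor(as.character(stress_level),
                         levels = c("low", "medium", "high"), ordered = TRUE)
  if (anyNA(stress_level)) stopf("`stress_level` must be low/medium/high")
  if (length(culture) != n || length(learning_style) != n ||
      length(stress_level) != n) {
    stopf("metadata vectors must all have length n = %d", n)
  }
  structure(
    list(schema = schema, features = features, wellbeing = wellbeing,
         perma = perma, culture = culture, learning_style = learning_style,
         stress_level = stress_level, n = n,
         has_wellbeing = !is.null(wellbeing), has_perma = !is.null(perma)),
    class = "perma_cohort")
}

#' @export
print.perma_cohort <- function(x, ...) {
  cat(sprintf("<perma_cohort> %d students x %d features\n", x$n, x$schema$d))
  cat(sprintf("  labels: wellbeing=%s, PERMA=%s\n",
              x$has_wellbeing, x$has_perma))
  cat(sprintf("  cultures: %s | styles: %d | stress: %s\n",
              paste(levels(x$culture), collapse = "/"),
              nlevels(x$learning_style),
              paste(table(x$stress_level), collapse = "/")))
  invisible(x)
}

#' Specification for the synthetic cohort generator
#'
#' Describes the generative model the synthetic cohort follows: latent PERMA
#' factor vectors drawn per culture from a truncated normal on `[0, 1]`,
#' features produced as noisy nonnegative mixtures of the latents through a
#' block-aligned loading matrix, and a well-being label equal to the latent
#' PERMA mean plus noise.
#'
#' @param n number of students (positive).
#' @param schema a [perma_schema()].
#' @param cultures data frame with columns `name`, `prop` (proportions summing
#'   to 1), `mean_P`..`mean_A` (latent means) and `sd` (latent standard
#'   deviation). Defaults to two cultures with shifted well-being profiles.
#' @param loading `d x 5` nonnegative matrix of ground-truth feature loadings;
#'   each feature's dominant column must agree with its block (learn to E/A,
#'   social to R, physical to P, mental to P/M). Default built from the schema.
#' @param feature_noise_sd,label_noise_sd nonnegative noise levels.
#' @param n_styles number of learning styles (>= 1), drawn uniformly.
#' @param seed integer seed; the generated cohort is a pure function of the
#'   spec including this seed.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n, schema = default_schema(),
                           cultures = default_cultures(),
                           loading = default_loading(schema),
                           feature_noise_sd = 0.05, label_noise_sd = 0.05,
                           n_styles = 4L, seed = 1L) {
  stopifnot(inherits(schema, "perma_schema"))
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stopf("`n` must be a positive count")
  cultures <- as.data.frame(cultures)
  need <- c("name", "prop", paste0("mean_", perma_dims()), "sd")
  if (!all(need %in% names(cultures))) {
    stopf("`cultures` needs columns: %s", paste(need, collapse = ", "))
  }
  if (abs(sum(cultures$prop) - 1) > 1e-9) {
    stopf("culture proportions must sum to 1 (got %.12f)", sum(cultures$prop))
  }
  loading <- as.matrix(loading)
  check_matrix(loading, nrow = schema$d, ncol = 5L, name = "loading")
  if (any(loading < 0)) stopf("loading rows must be nonnegative")
  colnames(loading) <- perma_dims()
  rownames(loading) <- schema$feature_names
  dom <- block_dominant_dims()
  for (j in seq_len(schema$d)) {
    allowed <- dom[[schema$block_of[j]]]
    top <- perma_dims()[which.max(loading[j, ])]
    if (!top %in% allowed) {
      stopf("feature '%s' (block %s) has dominant loading on %s; expected %s",
            schema$feature_names[j], schema$block_of[j], top,
            paste(allowed, collapse = "/"))
    }
  }
  if (feature_noise_sd < 0 || label_noise_sd < 0) {
    stopf("noise sds must be nonnegative")
  }
  n_styles <- as.integer(n_styles)
  if (n_styles < 1L) stopf("`n_styles` must be >= 1")
  structure(
    list(n = n, schema = schema, cultures = cultures, loading = loading,
         feature_noise_sd = feature_noise_sd, label_noise_sd = label_noise_sd,
         n_styles = n_styles, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_cultures <- function() {
  data.frame(
    name = c("western", "east_asian"),
    prop = c(0.6, 0.4),
    mean_P = c(0.62, 0.52), mean_E = c(0.58, 0.60), mean_R = c(0.60, 0.50),
    mean_M = c(0.55, 0.57), mean_A = c(0.57, 0.63),
    sd = c(0.15, 0.15))
}

#' @rdname synthetic_spec
#' @export
default_loading <- function(schema) {
  dom <- block_dominant_dims()
  L <- matrix(0.15, schema$d, 5,
              dimnames = list(schema$feature_names, perma_dims()))
  for (j in seq_len(schema$d)) {
    allowed <- dom[[schema$block_of[j]]]
    # alternate among the block's dominant dimensions so both get coverage
    pick <- allowed[1L + (j %% length(allowed))]
    L[j, pick] <- 1
  }
  L
}

#' Named synthetic cohort presets
#'
#' `"large"` mirrors the scale of a big lifestyle survey (n = 12757, d = 23);
#' `"small"` mirrors a single-campus mental-health survey (n = 268, d = 23);
#' `"default"` is the desk-scale preset (n = 512, d = 23) used by the training
#' harnesses and examples.
#'
#' @param name one of `"default"`, `"large"`, `"small"`.
#' @param seed integer seed forwarded to [synthetic_spec()].
#' @return A [synthetic_spec()].
#' @export
cohort_preset <- function(name = c("default", "large", "small"), seed = 1L) {
  name <- match.arg(name)
  n <- switch(name, default = 512L, large = 12757L, small = 268L)
  synthetic_spec(n = n, schema = default_schema(23L), seed = seed)
}

#' Generate a synthetic student cohort
#'
#' Draws per-student latent PERMA factor vectors from culture-specific
#' truncated normals on `[0, 1]`, produces features as
#' `clip01(L %*% latent + noise)` rescaled per column to fill `[0, 1]`, sets
#' the PERMA labels to the latents, the well-being label to
#' `clip01(mean(latent) + noise)`, draws learning styles uniformly and derives
#' stress level as the tertile of `1 - latent_P`. Identical specs (including
#' the seed) give bit-identical cohorts.
#'
#' @param spec a [synthetic_spec()].
#' @return A [perma_cohort()] with full labels.
#' @export
#' @examples
#' co <- generate_cohort(synthetic_spec(n = 50, seed = 7))
#' co
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    d <- spec$schema$d
    k <- nrow(spec$cultures)
    culture_idx <- sample.int(k, n, replace = TRUE, prob = spec$cultures$prop)
    latent <- matrix(0, n, 5, dimnames = list(NULL, perma_dims()))
    for (p in 1:5) {
      mu <- spec$cultures[[paste0("mean_", perma_dims()[p])]][culture_idx]
      sd <- spec$cultures$sd[culture_idx]
      latent[, p] <- rtruncnorm01(n, mu, sd)
    }
    raw <- latent %*% t(spec$loading)
    if (spec$feature_noise_sd > 0) {
      raw <- raw + matrix(stats::rnorm(n * d, 0, spec$feature_noise_sd), n, d)
    }
    raw <- clip01(raw)
    # per-column min-max rescale so every feature fills [0, 1]
    X <- apply(raw, 2, function(col) {
      rng <- range(col)
      if (rng[2] - rng[1] < 1e-12) rep(0.5, length(col))
      else (col - rng[1]) / (rng[2] - rng[1])
    })
    X <- matrix(X, n, d, dimnames = list(NULL, spec$schema$feature_names))
    wb <- rowMeans(latent)
    if (spec$label_noise_sd > 0) {
      wb <- wb + stats::rnorm(n, 0, spec$label_noise_sd)
    }
    wb <- clip01(wb)
    styles <- paste0("style_", sample.int(spec$n_styles, n, replace = TRUE))
    stress <- stress_tertiles(1 - latent[, "P"])
    perma_cohort(
      schema = spec$schema, features = X, wellbeing = wb, perma = latent,
      culture = spec$cultures$name[culture_idx],
      learning_style = factor(styles,
                              levels = paste0("style_", seq_len(spec$n_styles))),
      stress_level = stress)
  })
}

# Tertile assignment: sorted thirds of `x` (low stress = smallest x).
# Group sizes differ by at most one (hence <= 2 between any two groups is
# guaranteed with slack) for tie-free inputs.
stress_tertiles <- function(x) {
  n <- length(x)
  ord <- order(x, seq_len(n)) # stable tie-break on index
  sizes <- rep(n %/% 3L, 3L)
  rem <- n %% 3L
  if (rem >= 1L) sizes[1L] <- sizes[1L] + 1L
  if (rem == 2L) sizes[2L] <- sizes[2L] + 1L
  lab <- rep(c("low", "medium", "high"), times = sizes)
  out <- character(n)
  out[ord] <- lab
  factor(out, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Min-max scale cohort features into the unit interval
#'
#' Rescales every feature column into `[0, 1]` using the schema's declared
#' `value_range` (not the empirical range), so scaling is stable across
#' cohorts sharing a schema. Constant declared ranges are impossible by
#' schema invariant; a feature value outside its declared range is an error.
#' Features already on `[0, 1]` ranges pass through unchanged, so the
#' operation is idempotent.
#'
#' @param cohort a [perma_cohort()].
#' @return A [perma_cohort()] with features in `[0, 1]` and a unit-interval
#'   schema range.
#' @export
scale_features <- function(cohort) {
  stopifnot(inherits(cohort, "perma_cohort"))
  rng <- cohort$schema$value_range
  X <- cohort$features
  offenders <- character(0)
  for (j in seq_len(ncol(X))) {
    out <- X[, j] < rng[j, 1] - 1e-12 | X[, j] > rng[j, 2] + 1e-12
    if (any(out)) {
      offenders <- c(offenders,
                     sprintf("%s (rows %s)", colnames(X)[j],
                             paste(utils::head(which(out), 3), collapse = ",")))
    }
  }
  if (length(offenders)) {
    stopf("features outside declared range: %s",
          paste(offenders, collapse = "; "))
  }
  Xs <- sweep(sweep(X, 2, rng[, 1], "-"), 2, rng[, 2] - rng[, 1], "/")
  schema2 <- cohort$schema
  schema2$value_range[, 1] <- 0
  schema2$value_range[, 2] <- 1
  perma_cohort(schema2, Xs, cohort$wellbeing, cohort$perma, cohort$culture,
               cohort$learning_style, cohort$stress_level)
}

reserved_cols <- function() {
  c("wellbeing", paste0("perma_", perma_dims()), "culture", "learning_style",
    "stress_level")
}

#' Write a cohort to CSV plus a JSON schema sidecar
#'
#' The CSV holds one row per student: the schema's feature columns, the
#' reserved metadata columns (`culture`, `learning_style`, `stress_level`)
#' and, when present, the label columns (`wellbeing`, `perma_P` ..
#' `perma_A`). Values are serialized with 15 significant digits so
#' [read_cohort()] round-trips losslessly.
#'
#' @param cohort a [perma_cohort()].
#' @param table_path CSV destination.
#' @param schema_path JSON destination for the schema.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, table_path, schema_path) {
  stopifnot(inherits(cohort, "perma_cohort"))
  df <- as.data.frame(cohort$features)
  if (cohort$has_wellbeing) df$wellbeing <- cohort$wellbeing
  if (cohort$has_perma) {
    for (p in 1:5) df[[paste0("perma_", perma_dims()[p])]] <- cohort$perma[, p]
  }
  df$culture <- as.character(cohort$culture)
  df$learning_style <- as.character(cohort$learning_style)
  df$stress_level <- as.character(cohort$stress_level)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.csv(df, table_path, row.names = FALSE, quote = FALSE)
  sch <- cohort$schema
  jsonlite::write_json(
    list(feature_names = sch$feature_names,
         block_of = as.list(sch$block_of),
         value_range = list(min = unname(sch$value_range[, 1]),
                            max = unname(sch$value_range[, 2])),
         style_levels = levels(cohort$learning_style),
         culture_levels = levels(cohort$culture)),
    schema_path, auto_unbox = TRUE, digits = NA)
  invisible(c(table = table_path, schema = schema_path))
}

#' Read a cohort from CSV plus a JSON schema sidecar
#'
#' Labels are flagged present only when their columns exist and are fully
#' populated; label values outside `[0, 1]` raise an error naming the row and
#' column.
#'
#' @param table_path CSV path as written by [write_cohort()] (or any CSV whose
#'   columns cover the schema's features plus the reserved metadata columns).
#' @param schema_path JSON schema path.
#' @return A [perma_cohort()].
#' @export
read_cohort <- function(table_path, schema_path) {
  sj <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  schema <- perma_schema(sj$feature_names, unlist(sj$block_of),
                         cbind(min = sj$value_range$min,
                               max = sj$value_range$max))
  df <- utils::read.csv(table_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  missing <- setdiff(schema$feature_names, names(df))
  if (length(missing)) {
    stopf("CSV is missing feature column(s): %s",
          paste(missing, collapse = ", "))
  }
  X <- as.matrix(df[schema$feature_names])
  if (!is.numeric(X) || anyNA(X)) {
    bad <- which(is.na(suppressWarnings(
      apply(df[schema$feature_names], 2, as.numeric))), arr.ind = TRUE)
    stopf("non-numeric feature cell at row %d, column '%s'",
          bad[1, 1], schema$feature_names[bad[1, 2]])
  }
  grab_label <- function(col) {
    if (!col %in% names(df)) return(NULL)
    v <- df[[col]]
    if (anyNA(v)) return(NULL)
    bad <- which(v < 0 | v > 1)
    if (length(bad)) {
      stopf("label '%s' outside [0, 1] at row %d (value %g)",
            col, bad[1], v[bad[1]])
    }
    v
  }
  wb <- grab_label("wellbeing")
  perma_cols <- paste0("perma_", perma_dims())
  perma <- NULL
  if (all(perma_cols %in% names(df))) {
    cols <- lapply(perma_cols, grab_label)
    if (!any(vapply(cols, is.null, logical(1)))) {
      perma <- do.call(cbind, cols)
    }
  }
  style <- df$learning_style %||% rep("style_1", nrow(df))
  if (!is.null(sj$style_levels)) {
    style <- factor(style, levels = sj$style_levels)
  }
  culture <- df$culture %||% rep("default", nrow(df))
  if (!is.null(sj$culture_levels)) {
    culture <- factor(culture, levels = sj$culture_levels)
  }
  perma_cohort(schema, X, wb, perma, culture, style,
               df$stress_level %||% rep("medium", nrow(df)))
}
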