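#' Feature-to-PERMA relevance prior
#'
#' A `d x 5` row-stochastic matrix stating how relevant each feature is to
#' each PERMA dimension, plus a 5-vector of dimension weights summing to 1.
#' The prior drives the PERMA-weighted relationship graph
#' ([build_perma_graph()]), the prior-informed initialization of the score
#' map ([init_from_prior()]) and the per-dimension feature masking used for
#' tokenization.
#'
#' @param weights `d x 5` nonnegative matrix; each row must sum to 1
#'   (tolerance 1e-9). Row names should be feature names.
#' @param dim_weights nonnegative 5-vector summing to 1; defaults to uniform
#'   0.2 per dimension.
#' @return An object of class `"perma_prior"`.
#' @export
perma_prior <- function(weights, dim_weights = rep(0.2, 5)) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 5L) stopf("`weights` must have 5 columns (P,E,R,M,A)")
  if (any(weights < 0)) stopf("prior weights must be nonnegative")
  rs <- rowSums(weights)
  if (any(abs(rs - 1) > 1e-9)) {
    stopf("each prior row must sum to 1 (row %d sums to %.12f)",
          which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))])
  }
  dim_weights <- as.numeric(dim_weights)
  if (length(dim_weights) != 5L || any(dim_weights < 0) ||
      abs(sum(dim_weights) - 1) > 1e-9) {
    stopf("`dim_weights` must be a nonnegative 5-vector summing to 1")
  }
  colnames(weights) <- perma_dims()
  structure(list(weights = weights, dim_weights = dim_weights,
                 d = nrow(weights)),
            class = "perma_prior")
}

#' @export
print.perma_prior <- function(x, ...) {
  cat(sprintf("<perma_prior> %d features x 5 dimensions; dim weights: %s\n",
              x$d, paste(format(x$dim_weights), collapse = " ")))
  invisible(x)
}

#' Default block-aligned prior
#'
#' Puts `dominant` total mass on a feature's block-dominant PERMA
#' dimension(s) (learn to E/A, social to R, physical to P, mental to P/M) and
#' spreads the remainder evenly over the others. The mapping from survey
#' features to PERMA dimensions has no canonical published form, so this
#' prior is a configurable convention, not ground truth.
#'
#' @param schema a [perma_schema()].
#' @param dominant total mass on the dominant dimension(s), in `(0, 1)`.
#' @return A [perma_prior()].
#' @export
default_perma_prior <- function(schema, dominant = 0.6) {
  stopifnot(inherits(schema, "perma_schema"))
  if (dominant <= 0 || dominant >= 1) stopf("`dominant` must be in (0, 1)")
  dom <- block_dominant_dims()
  W <- matrix(0, schema$d, 5,
              dimnames = list(schema$feature_names, perma_dims()))
  for (j in seq_len(schema$d)) {
    dims <- dom[[schema$block_of[j]]]
    W[j, dims] <- dominant / length(dims)
    W[j, setdiff(perma_dims(), dims)] <- (1 - dominant) / (5 - length(dims))
  }
  perma_prior(W)
}

#' Read / write a prior map as JSON
#'
#' The JSON carries the five named dimension columns per feature plus the
#' dimension weights; row normalization is re-validated on load.
#'
#' @param prior a [perma_prior()].
#' @param path JSON file path.
#' @return `write_perma_prior()` returns the path invisibly;
#'   `read_perma_prior()` returns a [perma_prior()].
#' @export
write_perma_prior <- function(prior, path) {
  stopifnot(inherits(prior, "perma_prior"))
  jsonlite::write_json(
    list(features = rownames(prior$weights),
         weights = stats::setNames(
           lapply(1:5, function(p) unname(prior$weights[, p])), perma_dims()),
         dim_weights = prior$dim_weights),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_perma_prior
#' @export
read_perma_prior <- function(path) {
  pj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- do.call(cbind, pj$weights[perma_dims()])
  rownames(W) <- pj$features
  perma_prior(W, pj$dim_weights)
}
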