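#' Student-relationship topology
#'
#' One of the four student-relationship graphs: a symmetric `n x n` weighted
#' adjacency matrix with zero diagonal whose nonzero entries lie in
#' `[threshold, 1]`. Entries below the threshold are pruned as weak
#' connections (closed semantics: weights exactly at the threshold are kept).
#'
#' @param kind one of `"cosine"`, `"euclidean"`, `"learning"`, `"perma"`.
#' @param adjacency numeric symmetric matrix, zero diagonal.
#' @param threshold edge-weight threshold used to build it (default 0.3).
#' @return An object of class `"perma_topology"`.
#' @export
perma_topology <- function(kind, adjacency, threshold = 0.3) {
  kind <- match.arg(kind, c("cosine", "euclidean", "learning", "perma"))
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stopf("adjacency must be square")
  if (max(abs(adjacency - t(adjacency))) > 1e-12) {
    stopf("adjacency must be symmetric")
  }
  if (any(diag(adjacency) != 0)) stopf("adjacency must have zero diagonal")
  nz <- adjacency[adjacency != 0]
  if (length(nz) && (min(nz) < threshold - 1e-12 || max(nz) > 1 + 1e-12)) {
    stopf("nonzero edge weights must lie in [threshold, 1]")
  }
  structure(list(kind = kind, adjacency = adjacency, threshold = threshold,
                 n = n),
            class = "perma_topology")
}

#' @export
print.perma_topology <- function(x, ...) {
  m <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat(sprintf("<perma_topology:%s> %d nodes, %d edges (threshold %.2f)\n",
              x$kind, x$n, m, x$threshold))
  invisible(x)
}

apply_threshold <- function(A, threshold) {
  A[A < threshold] <- 0
  diag(A) <- 0
  # enforce exact symmetry against floating-point asymmetry
  (A + t(A)) / 2
}

#' Cosine-similarity relationship graph
#'
#' Edge weight between two students is the cosine of their feature vectors,
#' clipped below at 0 so all graphs share a comparable `[0, 1]` weight scale,
#' then thresholded. A zero-norm feature row yields zero similarity to every
#' other student (with a warning).
#'
#' @param X numeric `n x d` feature matrix (rows are students), `n >= 2`.
#' @param threshold edge-weight threshold (default 0.3, closed: `>=` kept).
#' @return A [perma_topology()] of kind `"cosine"`.
#' @export
build_cosine_graph <- function(X, threshold = 0.3) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stopf("need at least 2 students")
  if (!all(is.finite(X))) stopf("features must be finite")
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm < 1e-300
  if (any(zero)) {
    warning(sprintf("%d zero-norm row(s); their similarities are set to 0",
                    sum(zero)), call. = FALSE)
    nrm[zero] <- 1
  }
  S <- tcrossprod(X / nrm)
  S[zero, ] <- 0
  S[, zero] <- 0
  S <- pmin(pmax(S, 0), 1)
  perma_topology("cosine", apply_threshold(S, threshold), threshold)
}

#' Euclidean-kernel relationship graph
#'
#' Pairwise Euclidean distances are mapped to similarities through a Gaussian
#' kernel `exp(-dist^2 / (2 sigma^2))` with bandwidth `sigma` equal to the
#' median of the nonzero pairwise distances, then thresholded. If every
#' pairwise distance is zero the graph is complete with unit weights.
#'
#' @inheritParams build_cosine_graph
#' @return A [perma_topology()] of kind `"euclidean"`.
#' @export
build_euclidean_graph <- function(X, threshold = 0.3) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stopf("need at least 2 students")
  if (!all(is.finite(X))) stopf("features must be finite")
  D <- as.matrix(stats::dist(X))
  nz <- D[upper.tri(D)][D[upper.tri(D)] > 0]
  if (!length(nz)) {
    message("all pairwise distances are zero; returning the complete graph")
    A <- matrix(1, nrow(X), nrow(X))
    diag(A) <- 0
    return(perma_topology("euclidean", A, threshold))
  }
  sigma <- stats::median(nz)
  A <- exp(-D^2 / (2 * sigma^2))
  perma_topology("euclidean", apply_threshold(A, threshold), threshold)
}

#' Learning-style relationship graph
#'
#' Binary graph connecting students who share a learning style.
#'
#' @param styles length-`n` categorical vector (factor or character).
#' @param threshold kept for interface symmetry; style edges have weight 1 and
#'   always survive any threshold `<= 1`.
#' @return A [perma_topology()] of kind `"learning"`.
#' @export
build_style_graph <- function(styles, threshold = 0.3) {
  styles <- as.character(styles)
  n <- length(styles)
  if (n < 2L) stopf("need at least 2 students")
  A <- outer(styles, styles, "==") * 1
  diag(A) <- 0
  perma_topology("learning", apply_threshold(A, threshold), threshold)
}

#' PERMA-weighted relationship graph
#'
#' Theory-driven graph: for each PERMA dimension `p` the features are masked
#' by the prior's relevance column, a clipped cosine similarity is computed on
#' the masked features, and the five per-dimension similarities are combined
#' with the prior's dimension weights (which sum to 1, so raw weights stay in
#' `[0, 1]`), then thresholded.
#'
#' @inheritParams build_cosine_graph
#' @param prior a [perma_prior()] with `d` matching `ncol(X)`.
#' @return A [perma_topology()] of kind `"perma"`.
#' @export
build_perma_graph <- function(X, prior, threshold = 0.3) {
  X <- as.matrix(X)
  stopifnot(inherits(prior, "perma_prior"))
  if (nrow(X) < 2L) stopf("need at least 2 students")
  if (ncol(X) != prior$d) {
    stopf("prior has %d features but X has %d columns", prior$d, ncol(X))
  }
  n <- nrow(X)
  S <- matrix(0, n, n)
  for (p in 1:5) {
    Xp <- sweep(X, 2, prior$weights[, p], "*")
    nrm <- sqrt(rowSums(Xp^2))
    zero <- nrm < 1e-300
    nrm[zero] <- 1
    Sp <- tcrossprod(Xp / nrm)
    Sp[zero, ] <- 0
    Sp[, zero] <- 0
    S <- S + prior$dim_weights[p] * pmin(pmax(Sp, 0), 1)
  }
  S <- pmin(S, 1)
  perma_topology("perma", apply_threshold(S, threshold), threshold)
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Returns `D^{-1/2} (A + I) D^{-1/2}` where `D` is the degree matrix of
#' `A + I` — the propagation operator of graph convolution. Isolated nodes
#' reduce to the identity entry. All eigenvalues lie in `[-1, 1]`.
#'
#' @param topology a [perma_topology()] (or a plain symmetric adjacency
#'   matrix with zero diagonal).
#' @return A symmetric `n x n` matrix.
#' @export
normalize_adjacency <- function(topology) {
  A <- if (inherits(topology, "perma_topology")) topology$adjacency
       else as.matrix(topology)
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * tcrossprod(dinv)
}

#' Build the full four-topology set for a cohort
#'
#' Applies the four graph builders — cosine, Euclidean-kernel, learning-style
#' and PERMA-weighted — with a shared threshold, in that fixed order.
#'
#' @param cohort a [perma_cohort()] with features scaled to `[0, 1]`.
#' @param prior a [perma_prior()] over the cohort's schema.
#' @param threshold shared edge-weight threshold (default 0.3).
#' @return An object of class `"perma_topology_set"`: a list with elements
#'   `cosine`, `euclidean`, `learning`, `perma`.
#' @export
build_topology_set <- function(cohort, prior = default_perma_prior(cohort$schema),
                               threshold = 0.3) {
  stopifnot(inherits(cohort, "perma_cohort"))
  X <- cohort$features
  if (any(X < -1e-9) || any(X > 1 + 1e-9)) {
    stopf("cohort features must be scaled to [0, 1]; run scale_features()")
  }
  out <- list(
    cosine = build_cosine_graph(X, threshold),
    euclidean = build_euclidean_graph(X, threshold),
    learning = build_style_graph(cohort$learning_style, threshold),
    perma = build_perma_graph(X, prior, threshold))
  structure(out, class = "perma_topology_set", n = cohort$n,
            threshold = threshold)
}

#' @export
print.perma_topology_set <- function(x, ...) {
  cat(sprintf("<perma_topology_set> %d nodes, threshold %.2f\n",
              attr(x, "n"), attr(x, "threshold")))
  for (t in x) print(t)
  invisible(x)
}

#' Export a normalized adjacency in MatrixMarket format
#'
#' Writes the symmetrically normalized self-looped adjacency of a topology
#' as a sparse MatrixMarket (.mtx) file. Requires the Matrix package.
#'
#' @param topology a [perma_topology()].
#' @param path destination `.mtx` path.
#' @return The path, invisibly.
#' @export
write_normalized_mtx <- function(topology, path) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stopf("MTX export requires the Matrix package")
  }
  N <- normalize_adjacency(topology)
  Matrix::writeMM(methods::as(Matrix::Matrix(N, sparse = TRUE),
                              "generalMatrix"), path)
  invisible(path)
}

#' Export a topology as an edge list
#'
#' @param topology a [perma_topology()].
#' @param path optional TSV destination; when `NULL` the data frame is
#'   returned only.
#' @return Data frame with 0-based columns `i`, `j` (`i < j`) and `weight`.
#' @export
topology_edge_list <- function(topology, path = NULL) {
  stopifnot(inherits(topology, "perma_topology"))
  A <- topology$adjacency
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   weight = A[idx])
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  df
}
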