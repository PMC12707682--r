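# Reverse-mode automatic differentiation on dense matrices.
#
# A tape records nodes in creation order; ad_backward() sweeps it in reverse,
# calling each node's vector-Jacobian product. All node values are numeric
# matrices (scalars are 1x1, vectors n x 1). The engine is deliberately
# minimal: just the operations the model's forward pass needs, each with an
# analytic vjp. Gradient correctness is established by finite-difference
# tests rather than by construction.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_begin_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$k <- 0L
  .ad$tape <- tape
  invisible(tape)
}

ad_end_tape <- function() {
  tape <- .ad$tape
  .ad$tape <- NULL
  invisible(tape)
}

ad_node <- function(value, parents = list(), vjp = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$vjp <- vjp
  node$grad <- NULL
  tape <- .ad$tape
  if (!is.null(tape) && length(parents)) {
    tape$k <- tape$k + 1L
    if (tape$k > length(tape$nodes)) {
      length(tape$nodes) <- 2L * length(tape$nodes)
    }
    tape$nodes[[tape$k]] <- node
  }
  node
}

ad_const <- function(x) {
  ad_node(as.matrix(x))
}

ad_param <- function(x) {
  n <- ad_node(as.matrix(x))
  n$is_param <- TRUE
  n
}

ad_value <- function(node) node$value

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# Backpropagate from a scalar node through the active tape.
ad_backward <- function(loss, tape) {
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_len(tape$k))) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$vjp)) next
    gs <- node$vjp(node$grad)
    for (j in seq_along(node$parents)) {
      if (!is.null(gs[[j]])) ad_accum(node$parents[[j]], gs[[j]])
    }
  }
  invisible(loss)
}

# ---- primitive operations -------------------------------------------------

ad_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_div <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av / bv, list(a, b),
          function(g) list(g / bv, -g * av / bv^2))
}

# add a 1 x k bias row to every row of an n x k matrix
ad_add_bias <- function(a, b) {
  bv <- as.vector(b$value)
  ad_node(sweep(a$value, 2, bv, "+"), list(a, b),
          function(g) list(g, matrix(colSums(g), 1)))
}

ad_scale <- function(a, s) {
  ad_node(a$value * s, list(a), function(g) list(g * s))
}

# multiply row i of a (n x k) by scalar s_i (s is n x 1)
ad_scale_rows <- function(a, s) {
  av <- a$value; sv <- as.vector(s$value)
  ad_node(av * sv, list(a, s),
          function(g) list(g * sv, matrix(rowSums(g * av), ncol = 1)))
}

ad_relu <- function(a) {
  av <- a$value
  ad_node(pmax(av, 0), list(a), function(g) list(g * (av > 0)))
}

ad_leaky_relu <- function(a, slope = 0.2) {
  av <- a$value
  fac <- slope + (1 - slope) * (av > 0)
  ad_node(av * fac, list(a), function(g) list(g * fac))
}

ad_elu <- function(a, alpha = 1) {
  av <- a$value
  neg <- av <= 0
  out <- av
  deriv <- array(1, dim(av))
  ex <- alpha * exp(av[neg])
  out[neg] <- ex - alpha
  deriv[neg] <- ex
  ad_node(out, list(a), function(g) list(g * deriv))
}

# exact GELU: x * Phi(x)
ad_gelu <- function(a) {
  av <- a$value
  pn <- stats::pnorm(av)
  ad_node(av * pn, list(a),
          function(g) list(g * (pn + av * stats::dnorm(av))))
}

ad_tanh <- function(a) {
  tv <- tanh(a$value)
  ad_node(tv, list(a), function(g) list(g * (1 - tv^2)))
}

ad_sigmoid <- function(a) {
  sv <- stats::plogis(a$value)
  ad_node(sv, list(a), function(g) list(g * sv * (1 - sv)))
}

ad_sum <- function(a) {
  dims <- dim(a$value)
  ad_node(matrix(sum(a$value), 1, 1), list(a),
          function(g) list(matrix(as.vector(g), dims[1], dims[2])))
}

ad_mean <- function(a) {
  dims <- dim(a$value)
  ad_node(matrix(mean(a$value), 1, 1), list(a),
          function(g) list(matrix(as.vector(g) / prod(dims),
                                  dims[1], dims[2])))
}

ad_rowsums <- function(a) {
  k <- ncol(a$value)
  ad_node(matrix(rowSums(a$value), ncol = 1), list(a),
          function(g) list(matrix(g, nrow(g), k)))
}

ad_rowmeans <- function(a) {
  k <- ncol(a$value)
  ad_node(matrix(rowMeans(a$value), ncol = 1), list(a),
          function(g) list(matrix(g / k, nrow(g), k)))
}

ad_cbind <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_node(do.call(cbind, lapply(nodes, ad_value)), nodes,
          function(g) lapply(seq_along(nodes), function(i) {
            g[, starts[i]:ends[i], drop = FALSE]
          }))
}

ad_cols <- function(a, idx) {
  dims <- dim(a$value)
  ad_node(a$value[, idx, drop = FALSE], list(a),
          function(g) {
            z <- matrix(0, dims[1], dims[2])
            z[, idx] <- g
            list(z)
          })
}

# row gather, with accumulation on repeated indices (embedding lookup)
ad_rows <- function(a, idx) {
  dims <- dim(a$value)
  ad_node(a$value[idx, , drop = FALSE], list(a),
          function(g) {
            acc <- rowsum(g, group = idx)
            z <- matrix(0, dims[1], dims[2])
            z[as.integer(rownames(acc)), ] <- acc
            list(z)
          })
}

# E_ij = f_i + g_j from column vectors f, g (both n x 1 / m x 1)
ad_outer_sum <- function(f, g) {
  fv <- as.vector(f$value); gv <- as.vector(g$value)
  n <- length(fv); m <- length(gv)
  ad_node(matrix(fv, n, m) + matrix(gv, n, m, byrow = TRUE), list(f, g),
          function(gr) list(matrix(rowSums(gr), ncol = 1),
                            matrix(colSums(gr), ncol = 1)))
}

# row-wise softmax restricted to `mask` (logical matrix); masked entries are 0.
# Rows must have at least one unmasked entry.
ad_masked_softmax <- function(a, mask = NULL) {
  lv <- a$value
  if (!is.null(mask)) lv[!mask] <- -Inf
  mx <- lv[cbind(seq_len(nrow(lv)), max.col(lv, ties.method = "first"))]
  e <- exp(lv - mx) # masked entries: exp(-Inf) = 0
  S <- e / rowSums(e)
  ad_node(S, list(a),
          function(g) list(S * (g - rowSums(g * S))))
}

# row-wise layer normalization with learned gain/bias (1 x k each)
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- a$value
  k <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$value)
  out <- sweep(sweep(xhat, 2, gv, "*"), 2, as.vector(beta$value), "+")
  ad_node(out, list(a, gamma, beta),
          function(g) {
            dxhat <- sweep(g, 2, gv, "*")
            term1 <- dxhat
            term2 <- rowMeans(dxhat)
            term3 <- xhat * rowMeans(dxhat * xhat)
            dx <- (term1 - term2 - term3) * inv
            list(dx,
                 matrix(colSums(g * xhat), 1),
                 matrix(colSums(g), 1))
          })
}

# inverted dropout; draws from the active RNG stream
ad_dropout <- function(a, rate, train = FALSE) {
  if (!train || rate <= 0) return(a)
  keep <- matrix(stats::runif(length(a$value)) >= rate,
                 nrow(a$value), ncol(a$value))
  scale <- 1 / (1 - rate)
  ad_node(a$value * keep * scale, list(a),
          function(g) list(g * keep * scale))
}

ad_mse <- function(pred, target) {
  ad_mean(ad_mul(ad_sub(pred, target), ad_sub(pred, target)))
}
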