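# Forward pass of the PERMA multi-topology graph attention network.
#
# Every operation is written once, as a builder over autodiff nodes
# (R/autodiff.R); the exported functions wrap plain matrices in constant
# nodes, run the builder and return plain values, while training wraps the
# parameters in gradient-carrying nodes and reuses the same builders.

topology_order <- function() c("cosine", "euclidean", "learning", "perma")

# ---- PERMA embedding stage ------------------------------------------------

nodes_score_perma <- function(X, Pe) {
  ad_add_bias(ad_matmul(X, Pe$score_map), Pe$score_bias)
}

nodes_tokenize <- function(X, Pe) {
  toks <- lapply(1:5, function(p) {
    ad_matmul(ad_gelu(ad_add_bias(ad_matmul(X, Pe$U[[p]]),
                                  Pe$dim_embed[[p]])),
              Pe$lift)
  })
  names(toks) <- perma_dims()
  toks
}

nodes_cross_modal <- function(tokens, h_graph, Pcm) {
  V <- ad_matmul(h_graph, Pcm$W_v)
  # a single key/value per student makes the softmax a singleton (weight
  # exactly 1), so query/key projections cancel and the update is the
  # projected graph vector itself, added residually to every token
  lapply(tokens, function(t) ad_add(t, V))
}

# ---- relational GNN stage -------------------------------------------------

nodes_gcn_branch <- function(X, A_norm, Wlist) {
  H <- X
  for (W in Wlist) H <- ad_relu(ad_matmul(ad_matmul(A_norm, H), W))
  H
}

nodes_gat <- function(H, mask, gat, slope = 0.2) {
  outs <- vector("list", length(gat))
  attn <- vector("list", length(gat))
  for (h in seq_along(gat)) {
    Z <- ad_matmul(H, gat[[h]]$W)
    f <- ad_matmul(Z, gat[[h]]$a_src)
    g <- ad_matmul(Z, gat[[h]]$a_dst)
    E <- ad_leaky_relu(ad_outer_sum(f, g), slope)
    A <- ad_masked_softmax(E, mask)
    outs[[h]] <- ad_elu(ad_matmul(A, Z))
    attn[[h]] <- A$value
  }
  list(H = ad_cbind(outs), attn = attn)
}

nodes_fusion <- function(H_list, style_idx, stress_idx, Pf) {
  hs <- ad_rows(Pf$style_embed, style_idx)
  ht <- ad_rows(Pf$stress_embed, stress_idx)
  tfeat <- ad_tanh(ad_add_bias(ad_matmul(ad_cbind(list(hs, ht)), Pf$W_g),
                               Pf$b_g))
  scores <- ad_matmul(tfeat, Pf$v)
  B <- ad_masked_softmax(scores)
  H_final <- NULL
  for (k in seq_along(H_list)) {
    term <- ad_scale_rows(H_list[[k]], ad_cols(B, k))
    H_final <- if (is.null(H_final)) term else ad_add(H_final, term)
  }
  list(H = H_final, beta = B)
}

nodes_encode_relations <- function(X, A_norm, A_mask, style_idx, stress_idx,
                                   Pg, Pf, use = "multi") {
  kinds <- topology_order()
  branches <- list()
  attn <- list()
  run <- if (use == "single") "cosine" else kinds
  for (k in run) {
    H <- nodes_gcn_branch(X, A_norm[[k]], Pg[[k]]$W)
    gat <- nodes_gat(H, A_mask[[k]], Pg[[k]]$gat)
    branches[[k]] <- gat$H
    attn[[k]] <- gat$attn
  }
  if (use == "single") {
    beta <- matrix(c(1, 0, 0, 0), nrow(X$value), 4, byrow = TRUE,
                   dimnames = list(NULL, kinds))
    return(list(H = branches$cosine, beta = beta, attn = attn))
  }
  fu <- nodes_fusion(branches, style_idx, stress_idx, Pf)
  beta <- fu$beta$value
  colnames(beta) <- kinds
  list(H = fu$H, beta = beta, attn = attn)
}

# ---- transformer encoder stage --------------------------------------------

nodes_encoder <- function(tokens, Penc, dropout = 0.1, train = FALSE) {
  n_layers <- length(Penc)
  n_tok <- length(tokens)
  n_heads <- length(Penc[[1]]$heads)
  profile <- array(NA_real_, c(n_layers, n_heads, n_tok, n_tok))
  for (l in seq_len(n_layers)) {
    L <- Penc[[l]]
    head_dim <- ncol(L$heads[[1]]$Wq$value)
    ln <- lapply(tokens, function(t) ad_layernorm(t, L$ln1_g, L$ln1_b))
    head_out <- vector("list", n_heads) # per head: list over positions
    for (p in seq_len(n_heads)) {
      hp <- L$heads[[p]]
      Q <- lapply(ln, function(x) ad_matmul(x, hp$Wq))
      K <- lapply(ln, function(x) ad_matmul(x, hp$Wk))
      V <- lapply(ln, function(x) ad_matmul(x, hp$Wv))
      outs <- vector("list", n_tok)
      for (a in seq_len(n_tok)) {
        s <- lapply(seq_len(n_tok), function(b) {
          ad_scale(ad_rowsums(ad_mul(Q[[a]], K[[b]])), 1 / sqrt(head_dim))
        })
        W <- ad_masked_softmax(ad_cbind(s))
        profile[l, p, a, ] <- colMeans(W$value)
        o <- NULL
        for (b in seq_len(n_tok)) {
          term <- ad_scale_rows(V[[b]], ad_cols(W, b))
          o <- if (is.null(o)) term else ad_add(o, term)
        }
        outs[[a]] <- o
      }
      head_out[[p]] <- outs
    }
    tokens <- lapply(seq_len(n_tok), function(a) {
      cat5 <- ad_cbind(lapply(head_out, `[[`, a))
      upd <- ad_dropout(ad_matmul(cat5, L$W_O), dropout, train)
      ad_add(tokens[[a]], upd)
    })
    tokens <- lapply(tokens, function(t) {
      h <- ad_layernorm(t, L$ln2_g, L$ln2_b)
      h <- ad_gelu(ad_add_bias(ad_matmul(h, L$ffn_W1), L$ffn_b1))
      h <- ad_add_bias(ad_matmul(h, L$ffn_W2), L$ffn_b2)
      ad_add(t, ad_dropout(h, dropout, train))
    })
    names(tokens) <- perma_dims()[seq_len(n_tok)]
  }
  list(tokens = tokens, profile = profile)
}

nodes_heads <- function(tokens, Ph) {
  pooled <- NULL
  for (t in tokens) pooled <- if (is.null(pooled)) t else ad_add(pooled, t)
  pooled <- ad_scale(pooled, 1 / length(tokens))
  list(
    wellbeing = ad_sigmoid(ad_add_bias(ad_matmul(pooled, Ph$W_wb), Ph$b_wb)),
    perma = ad_sigmoid(ad_add_bias(ad_matmul(pooled, Ph$W_perma),
                                   Ph$b_perma)))
}

# ---- full pipeline --------------------------------------------------------

# Precompute the constant per-cohort inputs of the forward pass.
pnet_prep_data <- function(cohort, topologies) {
  kinds <- topology_order()
  A_norm <- lapply(kinds, function(k) normalize_adjacency(topologies[[k]]))
  A_mask <- lapply(kinds, function(k) {
    m <- topologies[[k]]$adjacency > 0
    diag(m) <- TRUE
    m
  })
  names(A_norm) <- names(A_mask) <- kinds
  list(X = cohort$features,
       A_norm = A_norm, A_mask = A_mask,
       style_idx = as.integer(cohort$learning_style),
       stress_idx = as.integer(cohort$stress_level),
       culture_idx = as.integer(cohort$culture))
}

# The complete forward pass over ad nodes. `P` is the nested parameter list
# wrapped as nodes; `data` comes from pnet_prep_data().
pnet_forward_nodes <- function(P, data, cfg, train = FALSE) {
  X <- ad_const(data$X)
  tokens <- nodes_tokenize(X, P$embed)
  if (!is.null(P$culture)) {
    ce <- ad_rows(P$culture$embed, data$culture_idx)
    tokens <- lapply(tokens, function(t) ad_add(t, ce))
  }
  beta <- NULL
  gnn_attn <- NULL
  if (cfg$use_gnn != "none") {
    A_norm <- lapply(data$A_norm, ad_const)
    rel <- nodes_encode_relations(X, A_norm, data$A_mask, data$style_idx,
                                  data$stress_idx, P$gnn, P$fusion,
                                  use = cfg$use_gnn)
    tokens <- nodes_cross_modal(tokens, rel$H, P$cm)
    beta <- rel$beta
    gnn_attn <- rel$attn
  }
  profile <- NULL
  if (isTRUE(cfg$use_encoder)) {
    enc <- nodes_encoder(tokens, P$enc, cfg$dropout, train)
    tokens <- enc$tokens
    profile <- enc$profile
  }
  preds <- nodes_heads(tokens, P$heads)
  list(wellbeing = preds$wellbeing, perma = preds$perma, beta = beta,
       profile = profile, gnn_attn = gnn_attn, tokens = tokens)
}

# Multi-task loss over ad nodes, restricted to the rows in `idx`.
pnet_loss_nodes <- function(fw, wb_label, perma_label, lambdas, idx = NULL) {
  wb <- fw$wellbeing
  pm <- fw$perma
  if (!is.null(idx)) {
    wb <- ad_rows(wb, idx)
    pm <- ad_rows(pm, idx)
    wb_label <- wb_label[idx]
    perma_label <- perma_label[idx, , drop = FALSE]
  }
  L_wb <- ad_mse(wb, ad_const(matrix(wb_label, ncol = 1)))
  L_pm <- ad_mse(pm, ad_const(perma_label))
  L_cons <- ad_mse(wb, ad_rowmeans(pm))
  total <- ad_add(ad_add(ad_scale(L_wb, lambdas[1]),
                         ad_scale(L_pm, lambdas[2])),
                  ad_scale(L_cons, lambdas[3]))
  list(total = total, wellbeing = L_wb, perma = L_pm, consistency = L_cons)
}

# ---- exported operation wrappers ------------------------------------------

#' Map features to the five PERMA scores
#'
#' The interpretable linear stage of the PERMA embedding: `X W + b` with the
#' `d x 5` score map.
#'
#' @param X numeric `n x d` matrix.
#' @param params embedding parameters from [init_from_prior()].
#' @return `n x 5` matrix of PERMA scores (columns P, E, R, M, A).
#' @export
score_perma <- function(X, params) {
  X <- as.matrix(X)
  check_matrix(X, ncol = nrow(params$score_map), name = "X")
  out <- ad_value(nodes_score_perma(ad_const(X),
                                    pnet_wrap(params, ad_const)))
  colnames(out) <- perma_dims()
  out
}

#' Embed features as five PERMA dimension tokens
#'
#' Each PERMA dimension gets one token:
#' `lift(GELU(X U_p + offset_p))`, giving a sequence of 5 tokens of model
#' width per student, in the fixed order P, E, R, M, A.
#'
#' @inheritParams score_perma
#' @return Named list of 5 matrices (`n x d_model`), one per dimension.
#' @export
tokenize <- function(X, params) {
  X <- as.matrix(X)
  check_matrix(X, ncol = nrow(params$U[[1]]), name = "X")
  lapply(nodes_tokenize(ad_const(X), pnet_wrap(params, ad_const)), ad_value)
}

#' Enhance PERMA tokens with the graph representation
#'
#' Single-head cross-modal attention from each token to the student's fused
#' graph vector, with a residual connection. Because each student contributes
#' exactly one key/value, the attention weight is identically 1 and the
#' update reduces to the value-projected graph vector; a zero value
#' projection therefore leaves the tokens untouched.
#'
#' @param tokens token sequence from [tokenize()].
#' @param h_graph `n x d_model` matrix of fused graph representations.
#' @param params list with value projection `W_v` (`d_model x d_model`).
#' @return Token sequence of the same shape.
#' @export
cross_modal_enhance <- function(tokens, h_graph, params) {
  h_graph <- as.matrix(h_graph)
  if (ncol(h_graph) != ncol(tokens[[1]])) {
    stopf("graph representation width %d does not match token width %d",
          ncol(h_graph), ncol(tokens[[1]]))
  }
  toks <- lapply(tokens, ad_const)
  lapply(nodes_cross_modal(toks, ad_const(h_graph),
                           pnet_wrap(params, ad_const)),
         ad_value)
}

#' One graph convolution layer
#'
#' `ReLU(A_norm H W)` with the symmetrically normalized self-looped
#' adjacency from [normalize_adjacency()].
#'
#' @param H `n x w` input representation.
#' @param A_norm normalized adjacency.
#' @param W `w x w'` weight matrix.
#' @return `n x w'` matrix.
#' @export
gcn_layer <- function(H, A_norm, W) {
  H <- as.matrix(H); A_norm <- as.matrix(A_norm); W <- as.matrix(W)
  if (ncol(H) != nrow(W)) stopf("H and W dimensions do not agree")
  if (ncol(A_norm) != nrow(H)) stopf("A_norm and H dimensions do not agree")
  ad_value(ad_relu(ad_matmul(ad_matmul(ad_const(A_norm), ad_const(H)),
                             ad_const(W))))
}

#' One multi-head graph attention layer
#'
#' Per head, attention logits `LeakyReLU(a_src' W h_i + a_dst' W h_j)` (slope
#' 0.2) are soft-maxed over each node's neighbourhood — the nodes it shares
#' an edge with, plus itself — and the aggregated messages pass through an
#' ELU. Head outputs are concatenated.
#'
#' @param H `n x w` input representation.
#' @param topology a [perma_topology()] (or adjacency matrix) defining
#'   neighbourhoods; edge weights act as a mask only.
#' @param gat_params list of per-head lists with `W` (`w x head_dim`),
#'   `a_src`, `a_dst` (`head_dim x 1`).
#' @param slope LeakyReLU negative slope (default 0.2).
#' @return List with `H` (`n x heads*head_dim`) and `attention` (per-head
#'   `n x n` matrices; each row sums to 1 over the node's neighbourhood).
#' @export
gat_layer <- function(H, topology, gat_params, slope = 0.2) {
  H <- as.matrix(H)
  A <- if (inherits(topology, "perma_topology")) topology$adjacency
       else as.matrix(topology)
  mask <- A > 0
  diag(mask) <- TRUE
  res <- nodes_gat(ad_const(H), mask, pnet_wrap(gat_params, ad_const), slope)
  list(H = ad_value(res$H), attention = res$attn)
}

#' Fuse per-topology representations by graph-level attention
#'
#' Per student, a score for each topology is computed from embeddings of the
#' student's learning style and stress level,
#' `v_k' tanh(W_g [h_style | h_stress] + b_g)`, soft-maxed into fusion
#' weights `beta` (a convex combination), and the four branch outputs are
#' mixed accordingly. With the default zero scoring vectors every student
#' starts at exactly uniform weights (0.25, 0.25, 0.25, 0.25).
#'
#' @param H_set list of four `n x w` matrices, ordered cosine, euclidean,
#'   learning, perma.
#' @param styles,stresses factors (or positive integer codes) of length `n`.
#' @param params fusion parameter list (`style_embed`, `stress_embed`, `W_g`,
#'   `b_g`, `v`).
#' @return List with `H` (`n x w`) and `beta` (`n x 4`, rows sum to 1).
#' @export
fuse_topologies <- function(H_set, styles, stresses, params) {
  stopifnot(length(H_set) == 4L)
  style_idx <- as.integer(if (is.factor(styles)) styles else factor(styles))
  stress_idx <- if (is.factor(stresses)) as.integer(stresses)
                else as.integer(factor(as.character(stresses),
                                       levels = c("low", "medium", "high")))
  if (anyNA(style_idx) || max(style_idx) > nrow(params$style_embed)) {
    stopf("unknown learning-style category")
  }
  if (anyNA(stress_idx) || max(stress_idx) > nrow(params$stress_embed)) {
    stopf("unknown stress-level category")
  }
  fu <- nodes_fusion(lapply(H_set, ad_const), style_idx, stress_idx,
                     pnet_wrap(params, ad_const))
  beta <- fu$beta$value
  colnames(beta) <- topology_order()
  list(H = ad_value(fu$H), beta = beta)
}

#' Encode a cohort over its four relationship graphs
#'
#' Per topology: three GCN layers on the normalized self-looped adjacency,
#' then one GAT layer on the raw thresholded adjacency; branch outputs are
#' combined by [fuse_topologies()] conditioned on learning style and stress
#' level.
#'
#' @param cohort a [perma_cohort()] (features scaled to `[0, 1]`).
#' @param topologies a [build_topology_set()] over the cohort.
#' @param params `gnn` + `fusion` parameter lists (from the full parameter
#'   set, e.g. `fitted$params`).
#' @return List with `H_graph` (`n x d_model`), `fusion_weights` (`n x 4`),
#'   and `attention` (per-topology, per-head GAT maps).
#' @export
encode_relations <- function(cohort, topologies, params) {
  stopifnot(inherits(cohort, "perma_cohort"))
  data <- pnet_prep_data(cohort, topologies)
  rel <- nodes_encode_relations(
    ad_const(data$X), lapply(data$A_norm, ad_const), data$A_mask,
    data$style_idx, data$stress_idx,
    pnet_wrap(params$gnn, ad_const), pnet_wrap(params$fusion, ad_const))
  list(H_graph = ad_value(rel$H), fusion_weights = rel$beta,
       attention = rel$attn)
}

#' PERMA-aligned transformer encoder forward pass
#'
#' Pre-norm residual blocks: `x + MultiHead(LN(x))` then `x + FFN(LN(x))`,
#' with five attention heads (one per PERMA dimension) of `head_dim` columns
#' concatenated through a shared output projection, a GELU feed-forward, and
#' dropout active only in training mode.
#'
#' @param tokens token sequence (named list of 5 `n x d_model` matrices).
#' @param params encoder parameter list (one element per layer).
#' @param dropout dropout rate (default 0.1).
#' @param train_mode logical; dropout is applied only when `TRUE`.
#' @return List with `tokens` (encoded sequence) and `profile` (array
#'   `layers x heads x 5 x 5` of attention maps averaged over students).
#' @export
encoder_forward <- function(tokens, params, dropout = 0.1,
                            train_mode = FALSE) {
  if (length(tokens) != 5L) stopf("the encoder expects exactly 5 tokens")
  res <- nodes_encoder(lapply(tokens, ad_const),
                       pnet_wrap(params, ad_const), dropout, train_mode)
  list(tokens = lapply(res$tokens, ad_value), profile = res$profile)
}

#' Dual prediction heads
#'
#' Global average pooling over the five encoded tokens followed by two
#' sigmoid affine heads: overall well-being (`n x 1`) and the five PERMA
#' dimensions (`n x 5`), all strictly inside `(0, 1)`.
#'
#' @param tokens encoded token sequence.
#' @param params head parameters (`W_wb`, `b_wb`, `W_perma`, `b_perma`).
#' @return An object of class `"perma_predictions"`: list with `wellbeing`
#'   (length-`n` vector) and `perma` (`n x 5` matrix).
#' @export
predict_heads <- function(tokens, params) {
  res <- nodes_heads(lapply(tokens, ad_const), pnet_wrap(params, ad_const))
  perma <- ad_value(res$perma)
  colnames(perma) <- perma_dims()
  structure(list(wellbeing = as.vector(ad_value(res$wellbeing)),
                 perma = perma),
            class = "perma_predictions")
}

#' @export
print.perma_predictions <- function(x, ...) {
  cat(sprintf("<perma_predictions> %d students; wellbeing in [%.3f, %.3f]\n",
              length(x$wellbeing), min(x$wellbeing), max(x$wellbeing)))
  invisible(x)
}

#' Multi-task loss with consistency regularization
#'
#' `L_total = lambda1 MSE(wellbeing) + lambda2 mean-MSE(PERMA) +
#' lambda3 MSE(wellbeing_pred, rowmean(PERMA_pred))`. The consistency term
#' ties the overall prediction to the mean of the five dimension
#' predictions and involves predictions only.
#'
#' @param bundle a [predict_heads()] result (or compatible list).
#' @param labels list with `wellbeing` (length `n`) and `perma` (`n x 5`).
#' @param lambdas nonnegative weights, default `c(1.0, 0.8, 0.5)`.
#' @return An object of class `"perma_loss"` with fields `wellbeing`,
#'   `perma`, `consistency`, `total`, `lambdas`.
#' @export
loss_total <- function(bundle, labels, lambdas = c(1.0, 0.8, 0.5)) {
  if (is.null(labels$wellbeing) || is.null(labels$perma)) {
    stopf("loss_total() requires both wellbeing and PERMA labels")
  }
  yw <- as.numeric(labels$wellbeing)
  Yp <- as.matrix(labels$perma)
  pw <- as.numeric(bundle$wellbeing)
  Pp <- as.matrix(bundle$perma)
  stopifnot(length(pw) == length(yw), all(dim(Pp) == dim(Yp)))
  L_wb <- mean((pw - yw)^2)
  L_pm <- mean(colMeans((Pp - Yp)^2))
  L_cons <- mean((pw - rowMeans(Pp))^2)
  structure(list(wellbeing = L_wb, perma = L_pm, consistency = L_cons,
                 total = sum(lambdas * c(L_wb, L_pm, L_cons)),
                 lambdas = lambdas),
            class = "perma_loss")
}

#' @export
print.perma_loss <- function(x, ...) {
  cat(sprintf(
    "<perma_loss> total %.6f = %.1f x %.6f + %.1f x %.6f + %.1f x %.6f\n",
    x$total, x$lambdas[1], x$wellbeing, x$lambdas[2], x$perma,
    x$lambdas[3], x$consistency))
  invisible(x)
}

#' Full forward pass over a cohort
#'
#' Composes the pipeline: tokenize, encode relations over the four graphs,
#' cross-modal enhancement, transformer encoding, dual heads. Deterministic
#' when `train_mode = FALSE` (no dropout).
#'
#' @param cohort a [perma_cohort()].
#' @param topologies a [build_topology_set()] over the cohort.
#' @param params full parameter set (e.g. `fitted$params` or
#'   `pnet_init_params()` internals via [permanet_fit()]).
#' @param config a [permanet_config()].
#' @param train_mode logical; enables dropout.
#' @return List with `bundle` (a `"perma_predictions"`), `fusion_weights`
#'   (`n x 4`) and `profile` (encoder attention array).
#' @export
forward_full <- function(cohort, topologies, params, config,
                         train_mode = FALSE) {
  stopifnot(inherits(cohort, "perma_cohort"))
  data <- pnet_prep_data(cohort, topologies)
  P <- pnet_wrap(params, ad_const)
  fw <- pnet_forward_nodes(P, data, config, train = train_mode)
  perma <- ad_value(fw$perma)
  colnames(perma) <- perma_dims()
  bundle <- structure(list(wellbeing = as.vector(ad_value(fw$wellbeing)),
                           perma = perma),
                      class = "perma_predictions")
  list(bundle = bundle, fusion_weights = fw$beta, profile = fw$profile)
}

#' Attention-to-PERMA alignment matrix
#'
#' Summarizes an encoder attention profile into a `5 x 5` matrix whose entry
#' (head, dimension) is the mean attention mass that head assigns to that
#' dimension's token, averaged over layers, query positions and students.
#' Rows sum to 1. A diagonal-dominant matrix indicates each head attends
#' chiefly to its own PERMA dimension.
#'
#' @param profile attention array from [encoder_forward()] /
#'   [forward_full()] (`layers x heads x 5 x 5`).
#' @return `5 x 5` matrix with head rows and token columns named P,E,R,M,A.
#' @export
alignment_matrix <- function(profile) {
  stopifnot(length(dim(profile)) == 4L)
  M <- apply(profile, c(2, 4), mean)
  dimnames(M) <- list(head = perma_dims(), token = perma_dims())
  M
}
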