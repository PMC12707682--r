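#' Model and training configuration
#'
#' Collects every tunable of the predictor in one list. The `"full"` preset
#' carries the reference configuration: 6 transformer layers of width 256
#' with 5 attention heads of dimension 64 and a 1024-wide feed-forward, a
#' 128-dimensional PERMA token embedding, 3 GCN layers of width 128 and an
#' 8-head x 32 GAT per topology, AdamW (beta 0.9/0.999, eps 1e-8, weight
#' decay 1e-5) with linear warmup over 500 steps then cosine annealing to
#' 1e-6, 100 epochs, batch size 32, gradient clipping at 1.0, early-stopping
#' patience 15, dropout 0.1, edge threshold 0.3, multi-task loss weights
#' (1.0, 0.8, 0.5), PCE weights (0.4, 0.3, 0.3) and consistency tolerance
#' 0.1. The `"reduced"` preset keeps the same architecture family at desk
#' scale (2 layers of width 64, 32-wide tokens, 3 GCN layers of width 32,
#' 4 x 16 GAT, 30 epochs, batch 64, learning rate 1e-3 with 30 warmup steps)
#' and is what the ablation/sweep harnesses and examples use.
#'
#' @param preset `"full"` or `"reduced"`.
#' @param ... named overrides of any configuration field.
#' @return An object of class `"permanet_config"`.
#' @export
#' @examples
#' cfg <- permanet_config("reduced", epochs = 10)
#' cfg$lambdas
permanet_config <- function(preset = c("full", "reduced"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = 1L,
    split_ratios = c(train = 0.7, valid = 0.2, test = 0.1),
    strata = c("learning_style", "stress_level"),
    learning_rate = 1e-4,
    adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8,
    weight_decay = 1e-5,
    lr_min = 1e-6, warmup_steps = 500L,
    epochs = 100L, batch_size = 32L,
    grad_clip = 1.0, patience = 15L,
    lambdas = c(1.0, 0.8, 0.5),
    dropout = 0.1,
    graph_threshold = 0.3,
    pce_weights = c(0.4, 0.3, 0.3),
    epsilon = 0.1,
    prior_strength = 0.7,
    use_gnn = "multi",       # "multi", "single" (cosine only) or "none"
    use_encoder = TRUE,
    use_culture_embed = FALSE,
    arch = list(d_model = 256L, n_layers = 6L, n_heads = 5L, head_dim = 64L,
                ffn_dim = 1024L, token_dim = 128L, gcn_dim = 128L,
                gcn_layers = 3L, gat_heads = 8L, gat_head_dim = 32L,
                embed_dim = 32L, fusion_dim = 32L))
  if (preset == "reduced") {
    cfg$arch <- list(d_model = 64L, n_layers = 2L, n_heads = 5L,
                     head_dim = 16L, ffn_dim = 128L, token_dim = 32L,
                     gcn_dim = 32L, gcn_layers = 3L, gat_heads = 2L,
                     gat_head_dim = 32L, embed_dim = 16L, fusion_dim = 16L)
    cfg$learning_rate <- 1e-3
    cfg$warmup_steps <- 30L
    cfg$epochs <- 30L
    cfg$batch_size <- 128L
  }
  dots <- list(...)
  if ("arch" %in% names(dots)) {
    cfg$arch[names(dots$arch)] <- dots$arch
    dots$arch <- NULL
  }
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "permanet_config")
}

validate_config <- function(cfg) {
  if (abs(sum(cfg$split_ratios) - 1) > 1e-9) {
    stopf("split ratios must sum to 1")
  }
  if (any(cfg$lambdas < 0)) stopf("loss weights must be nonnegative")
  if (abs(sum(cfg$pce_weights) - 1) > 1e-9 || any(cfg$pce_weights < 0)) {
    stopf("PCE weights must be nonnegative and sum to 1")
  }
  a <- cfg$arch
  if (a$n_heads < 1L) stopf("the encoder needs at least one attention head")
  if (a$gat_heads * a$gat_head_dim != a$d_model) {
    stopf("GAT heads x head dim must equal the model width (%d x %d != %d)",
          a$gat_heads, a$gat_head_dim, a$d_model)
  }
  with(cfg, stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
                      dropout >= 0, dropout < 1, epsilon >= 0,
                      graph_threshold >= 0, patience >= 1))
  invisible(cfg)
}

#' @export
print.permanet_config <- function(x, ...) {
  a <- x$arch
  cat(sprintf(
    "<permanet_config> %d-layer encoder (width %d, 5 heads x %d), token %d\n",
    a$n_layers, a$d_model, a$head_dim, a$token_dim))
  cat(sprintf("  GCN %d x %d, GAT %d x %d; lr %g, epochs %d, batch %d\n",
              a$gcn_layers, a$gcn_dim, a$gat_heads, a$gat_head_dim,
              x$learning_rate, x$epochs, x$batch_size))
  cat(sprintf("  lambdas (%.1f, %.1f, %.1f), threshold %.2f, dropout %.2f\n",
              x$lambdas[1], x$lambdas[2], x$lambdas[3], x$graph_threshold,
              x$dropout))
  invisible(x)
}

# ---- weight initializers --------------------------------------------------

xavier_uniform <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

kaiming_normal <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

#' Prior-informed PERMA embedding parameters
#'
#' Builds the parameters of the PERMA embedding stage: the interpretable
#' `d x 5` score map (a convex combination of the psychological prior and a
#' Xavier-uniform draw, controlled by `strength`), the five per-dimension
#' token projections `U_p` (Xavier draws whose feature rows are rescaled by
#' `(1 - strength) + 5 * strength * prior[, p]` so dimension-relevant
#' features dominate the corresponding token), five learned token offsets,
#' and the shared lift from token width to model width.
#'
#' @param prior a [perma_prior()].
#' @param strength mixing weight in `[0, 1]`: 1 returns the prior exactly,
#'   0 ignores it.
#' @param seed integer seed; the draw is deterministic given it.
#' @param token_dim,d_model token and model widths (defaults 128 and 256).
#' @return A list with elements `score_map`, `score_bias`, `U`, `dim_embed`,
#'   `lift`.
#' @export
init_from_prior <- function(prior, strength = 0.7, seed = 1L,
                            token_dim = 128L, d_model = 256L) {
  stopifnot(inherits(prior, "perma_prior"))
  if (strength < 0 || strength > 1) stopf("`strength` must be in [0, 1]")
  d <- prior$d
  with_seed(seed, {
    score_map <- strength * prior$weights + (1 - strength) * xavier_uniform(d, 5)
    dimnames(score_map) <- dimnames(prior$weights)
    U <- lapply(1:5, function(p) {
      scale_rows <- (1 - strength) + 5 * strength * prior$weights[, p]
      xavier_uniform(d, token_dim) * scale_rows
    })
    names(U) <- perma_dims()
    dim_embed <- lapply(1:5, function(p) {
      matrix(stats::runif(token_dim, -0.1, 0.1), 1)
    })
    names(dim_embed) <- perma_dims()
    list(score_map = score_map,
         score_bias = matrix(0, 1, 5),
         U = U, dim_embed = dim_embed,
         lift = xavier_uniform(token_dim, d_model))
  })
}

# Full parameter set for the predictor. Transformer and embedding weights use
# Xavier Uniform (the embedding additionally blended with the prior); GNN
# weights use Kaiming Normal; fusion scorers start at zero so the topology
# weights begin exactly uniform at 0.25.
pnet_init_params <- function(d, n_styles, n_cultures, cfg, prior, seed = 1L) {
  a <- cfg$arch
  with_seed(seed, {
    embed <- init_from_prior(prior, cfg$prior_strength,
                             seed = stats::runif(1, 1, 2^30),
                             token_dim = a$token_dim, d_model = a$d_model)
    gnn <- lapply(1:4, function(k) {
      W <- vector("list", a$gcn_layers)
      for (l in seq_len(a$gcn_layers)) {
        W[[l]] <- kaiming_normal(if (l == 1) d else a$gcn_dim, a$gcn_dim)
      }
      gat <- lapply(seq_len(a$gat_heads), function(h) {
        list(W = kaiming_normal(a$gcn_dim, a$gat_head_dim),
             a_src = xavier_uniform(a$gat_head_dim, 1),
             a_dst = xavier_uniform(a$gat_head_dim, 1))
      })
      list(W = W, gat = gat)
    })
    names(gnn) <- c("cosine", "euclidean", "learning", "perma")
    e <- a$embed_dim
    f <- a$fusion_dim
    fusion <- list(
      style_embed = xavier_uniform(n_styles, e),
      stress_embed = xavier_uniform(3, e),
      W_g = xavier_uniform(2 * e, f),
      b_g = matrix(0, 1, f),
      v = matrix(0, f, 4)) # zero scorers -> uniform 0.25 fusion at start
    cm <- list(W_v = xavier_uniform(a$d_model, a$d_model))
    enc <- lapply(seq_len(a$n_layers), function(l) {
      heads <- lapply(seq_len(a$n_heads), function(p) {
        list(Wq = xavier_uniform(a$d_model, a$head_dim),
             Wk = xavier_uniform(a$d_model, a$head_dim),
             Wv = xavier_uniform(a$d_model, a$head_dim))
      })
      list(heads = heads,
           W_O = xavier_uniform(a$n_heads * a$head_dim, a$d_model),
           ln1_g = matrix(1, 1, a$d_model), ln1_b = matrix(0, 1, a$d_model),
           ln2_g = matrix(1, 1, a$d_model), ln2_b = matrix(0, 1, a$d_model),
           ffn_W1 = xavier_uniform(a$d_model, a$ffn_dim),
           ffn_b1 = matrix(0, 1, a$ffn_dim),
           ffn_W2 = xavier_uniform(a$ffn_dim, a$d_model),
           ffn_b2 = matrix(0, 1, a$d_model))
    })
    heads <- list(W_wb = xavier_uniform(a$d_model, 1), b_wb = matrix(0, 1, 1),
                  W_perma = xavier_uniform(a$d_model, 5),
                  b_perma = matrix(0, 1, 5))
    culture <- if (isTRUE(cfg$use_culture_embed)) {
      list(embed = xavier_uniform(n_cultures, a$d_model))
    }
    list(embed = embed, gnn = gnn, fusion = fusion, cm = cm, enc = enc,
         heads = heads, culture = culture)
  })
}

# Flatten a nested parameter list into a named flat list of matrices.
# Unnamed list elements are keyed by their 1-based position.
pnet_flatten <- function(params, prefix = "") {
  out <- list()
  keys <- names(params) %||% as.character(seq_along(params))
  keys[!nzchar(keys)] <- as.character(which(!nzchar(keys)))
  for (i in seq_along(params)) {
    x <- params[[i]]
    if (is.null(x)) next
    key <- if (nzchar(prefix)) paste0(prefix, "/", keys[i]) else keys[i]
    if (is.list(x)) out <- c(out, pnet_flatten(x, key))
    else out[[key]] <- x
  }
  out
}

# Inverse of pnet_flatten given the structural template.
pnet_unflatten <- function(flat, template) {
  assign_in <- function(tpl, path, value) {
    p <- path[1]
    if (grepl("^[0-9]+$", p) && is.null(names(tpl))) p <- as.integer(p)
    if (length(path) == 1L) tpl[[p]] <- value
    else tpl[[p]] <- assign_in(tpl[[p]], path[-1], value)
    tpl
  }
  for (nm in names(flat)) {
    template <- assign_in(template, strsplit(nm, "/", fixed = TRUE)[[1]],
                          flat[[nm]])
  }
  template
}

# Map every parameter leaf to an ad node (param or const).
pnet_wrap <- function(params, wrap = ad_param) {
  lapply(params, function(x) {
    if (is.null(x)) NULL
    else if (is.list(x)) pnet_wrap(x, wrap)
    else wrap(x)
  })
}
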