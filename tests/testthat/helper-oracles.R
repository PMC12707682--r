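# Independent brute-force oracles, written as plain double loops so they
# share no code path with the implementation they audit.

oracle_cosine_graph <- function(X, threshold = 0.3) {
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ni <- sqrt(sum(X[i, ]^2)); nj <- sqrt(sum(X[j, ]^2))
      s <- if (ni == 0 || nj == 0) 0 else sum(X[i, ] * X[j, ]) / (ni * nj)
      s <- min(max(s, 0), 1)
      A[i, j] <- if (s >= threshold) s else 0
    }
  }
  A
}

oracle_euclidean_graph <- function(X, threshold = 0.3) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  nz <- D[upper.tri(D)][D[upper.tri(D)] > 0]
  sigma <- stats::median(nz)
  A <- exp(-D^2 / (2 * sigma^2))
  diag(A) <- 0
  A[A < threshold] <- 0
  A
}

oracle_perma_graph <- function(X, weights, dim_weights, threshold = 0.3) {
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (p in 1:5) {
      xi <- X[i, ] * weights[, p]; xj <- X[j, ] * weights[, p]
      ni <- sqrt(sum(xi^2)); nj <- sqrt(sum(xj^2))
      sp <- if (ni == 0 || nj == 0) 0 else sum(xi * xj) / (ni * nj)
      s <- s + dim_weights[p] * min(max(sp, 0), 1)
    }
    s <- min(s, 1)
    A[i, j] <- if (s >= threshold) s else 0
  }
  A
}

oracle_normalize <- function(A) {
  At <- A + diag(nrow(A))
  Dt <- diag(rowSums(At))
  Dm <- diag(1 / sqrt(diag(Dt)))
  Dm %*% At %*% Dm
}

oracle_gcn <- function(H, A_norm, W) {
  out <- A_norm %*% H %*% W
  pmax(out, 0)
}

oracle_gat <- function(H, A, gat, slope = 0.2) {
  n <- nrow(H)
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  lrelu <- function(x) ifelse(x > 0, x, slope * x)
  outs <- list(); attns <- list()
  for (h in seq_along(gat)) {
    Z <- H %*% gat[[h]]$W
    alpha <- matrix(0, n, n)
    for (i in seq_len(n)) {
      Ni <- sort(unique(c(i, which(A[i, ] > 0))))
      e <- vapply(Ni, function(j) {
        lrelu(sum(gat[[h]]$a_src * Z[i, ]) + sum(gat[[h]]$a_dst * Z[j, ]))
      }, numeric(1))
      w <- exp(e - max(e)); w <- w / sum(w)
      alpha[i, Ni] <- w
    }
    out <- matrix(0, n, ncol(Z))
    for (i in seq_len(n)) {
      acc <- rep(0, ncol(Z))
      for (j in seq_len(n)) acc <- acc + alpha[i, j] * Z[j, ]
      out[i, ] <- elu(acc)
    }
    outs[[h]] <- out; attns[[h]] <- alpha
  }
  list(H = do.call(cbind, outs), attention = attns)
}

oracle_fusion <- function(H_set, style_idx, stress_idx, pf) {
  n <- nrow(H_set[[1]])
  beta <- matrix(0, n, 4)
  H <- matrix(0, n, ncol(H_set[[1]]))
  for (i in seq_len(n)) {
    hcat <- c(pf$style_embed[style_idx[i], ], pf$stress_embed[stress_idx[i], ])
    tf <- tanh(as.vector(hcat %*% pf$W_g) + as.vector(pf$b_g))
    s <- vapply(1:4, function(k) sum(pf$v[, k] * tf), numeric(1))
    w <- exp(s - max(s)); w <- w / sum(w)
    beta[i, ] <- w
    for (k in 1:4) H[i, ] <- H[i, ] + w[k] * H_set[[k]][i, ]
  }
  list(H = H, beta = beta)
}

oracle_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  (x - mu) / sqrt(v + eps) * gamma + beta
}

# one pre-norm encoder layer for a single student's 5 tokens (5 x m matrix)
oracle_encoder_layer <- function(tok, L) {
  gelu <- function(x) x * pnorm(x)
  m <- ncol(tok)
  n_heads <- length(L$heads)
  dk <- ncol(L$heads[[1]]$Wq)
  ln <- t(apply(tok, 1, oracle_layernorm,
                gamma = as.vector(L$ln1_g), beta = as.vector(L$ln1_b)))
  head_outs <- list()
  attn <- array(0, c(n_heads, 5, 5))
  for (p in seq_len(n_heads)) {
    Q <- ln %*% L$heads[[p]]$Wq
    K <- ln %*% L$heads[[p]]$Wk
    V <- ln %*% L$heads[[p]]$Wv
    out <- matrix(0, 5, dk)
    for (a in 1:5) {
      s <- vapply(1:5, function(b) sum(Q[a, ] * K[b, ]) / sqrt(dk),
                  numeric(1))
      w <- exp(s - max(s)); w <- w / sum(w)
      attn[p, a, ] <- w
      for (b in 1:5) out[a, ] <- out[a, ] + w[b] * V[b, ]
    }
    head_outs[[p]] <- out
  }
  tok1 <- tok + do.call(cbind, head_outs) %*% L$W_O
  ln2 <- t(apply(tok1, 1, oracle_layernorm,
                 gamma = as.vector(L$ln2_g), beta = as.vector(L$ln2_b)))
  ffn <- gelu(sweep(ln2 %*% L$ffn_W1, 2, as.vector(L$ffn_b1), "+")) %*%
    L$ffn_W2
  ffn <- sweep(ffn, 2, as.vector(L$ffn_b2), "+")
  list(tokens = tok1 + ffn, attn = attn)
}

# random single-layer encoder parameters and token fixtures
make_enc_params <- function(n_layers = 1, m = 16, dk = 4, ffn = 16,
                            seed = 1) {
  permanet:::with_seed(seed, {
    lapply(seq_len(n_layers), function(l) {
      list(heads = lapply(1:5, function(p) {
             list(Wq = matrix(rnorm(m * dk, 0, 0.2), m),
                  Wk = matrix(rnorm(m * dk, 0, 0.2), m),
                  Wv = matrix(rnorm(m * dk, 0, 0.2), m))
           }),
           W_O = matrix(rnorm(5 * dk * m, 0, 0.2), 5 * dk),
           ln1_g = matrix(1, 1, m), ln1_b = matrix(0, 1, m),
           ln2_g = matrix(1, 1, m), ln2_b = matrix(0, 1, m),
           ffn_W1 = matrix(rnorm(m * ffn, 0, 0.2), m),
           ffn_b1 = matrix(0, 1, ffn),
           ffn_W2 = matrix(rnorm(ffn * m, 0, 0.2), ffn),
           ffn_b2 = matrix(0, 1, m))
    })
  })
}

rand_tokens <- function(n = 3, m = 16, seed = 2) {
  permanet:::with_seed(seed, {
    toks <- lapply(1:5, function(p) matrix(rnorm(n * m), n))
    names(toks) <- perma_dims()
    toks
  })
}

# small labelled cohort for fast training tests
tiny_cohort <- function(n = 32, seed = 1, label_noise_sd = 0.05) {
  generate_cohort(synthetic_spec(
    n = n, schema = default_schema(8L), label_noise_sd = label_noise_sd,
    feature_noise_sd = 0.05, n_styles = 2L, seed = seed))
}

# very small architecture for fast gradient / training checks
tiny_config <- function(...) {
  permanet_config(
    "reduced",
    arch = list(d_model = 16L, n_layers = 1L, head_dim = 4L, ffn_dim = 16L,
                token_dim = 8L, gcn_dim = 8L, gcn_layers = 2L,
                gat_heads = 2L, gat_head_dim = 8L, embed_dim = 4L,
                fusion_dim = 4L),
    warmup_steps = 5L, ...)
}

tiny_params <- function(cohort, cfg, seed = 1) {
  permanet:::pnet_init_params(cohort$schema$d,
                              nlevels(cohort$learning_style),
                              nlevels(cohort$culture),
                              cfg, default_perma_prior(cohort$schema), seed)
}

# permanet_fit silencing the expected small-stratum merge warnings of tiny
# test cohorts
quiet_fit <- function(...) suppressWarnings(permanet_fit(...))
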