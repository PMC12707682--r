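test_that("identical tokens produce uniform attention", {
  m <- 16
  one <- matrix(rnorm(2 * m), 2)
  toks <- lapply(1:5, function(p) one)
  names(toks) <- perma_dims()
  enc <- encoder_forward(toks, make_enc_params(), train_mode = FALSE)
  expect_equal(as.vector(enc$profile), rep(0.2, length(enc$profile)),
               tolerance = 1e-12)
})

test_that("attention rows always sum to one", {
  enc <- encoder_forward(rand_tokens(), make_enc_params(n_layers = 2))
  sums <- apply(enc$profile, c(1, 2, 3), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-6)
})

test_that("one encoder layer matches a step-by-step manual computation", {
  P <- make_enc_params(seed = 3)
  toks <- rand_tokens(n = 1, seed = 4)
  enc <- encoder_forward(toks, P, train_mode = FALSE)
  tok_mat <- do.call(rbind, lapply(toks, function(t) t[1, ]))
  want <- oracle_encoder_layer(tok_mat, P[[1]])
  for (p in 1:5) {
    expect_lt(max(abs(enc$tokens[[p]][1, ] - want$tokens[p, ])), 1e-8)
  }
  for (h in 1:5) {
    expect_lt(max(abs(enc$profile[1, h, , ] - want$attn[h, , ])), 1e-8)
  }
})

test_that("encoder rejects malformed token sequences", {
  toks <- rand_tokens()
  expect_error(encoder_forward(toks[1:4], make_enc_params()), "5 tokens")
})

test_that("prediction heads pool, project and squash", {
  m <- 16
  zero_toks <- lapply(1:5, function(p) matrix(0, 3, m))
  hp <- list(W_wb = matrix(0, m, 1), b_wb = matrix(0, 1, 1),
             W_perma = matrix(0, m, 5), b_perma = matrix(0, 1, 5))
  b <- predict_heads(zero_toks, hp)
  expect_equal(b$wellbeing, rep(0.5, 3))
  expect_equal(unname(b$perma), matrix(0.5, 3, 5))
  # saturation
  hp$b_wb <- matrix(30, 1, 1)
  b_sat <- predict_heads(zero_toks, hp)
  expect_true(all(b_sat$wellbeing > 1 - 1e-9 & b_sat$wellbeing < 1))
  # random instance vs manual pool + affine + sigmoid
  set.seed(5)
  toks <- rand_tokens(n = 4, seed = 6)
  hp <- list(W_wb = matrix(rnorm(m), m), b_wb = matrix(0.3, 1, 1),
             W_perma = matrix(rnorm(m * 5), m), b_perma = matrix(rnorm(5), 1))
  b <- predict_heads(toks, hp)
  pooled <- Reduce(`+`, toks) / 5
  expect_lt(max(abs(b$wellbeing -
                      plogis(as.vector(pooled %*% hp$W_wb) + 0.3))), 1e-12)
  want_p <- plogis(sweep(pooled %*% hp$W_perma, 2, as.vector(hp$b_perma),
                         "+"))
  expect_lt(max(abs(b$perma - want_p)), 1e-12)
})

test_that("the multi-task loss satisfies its arithmetic identities", {
  # perfect self-consistent predictions: every component zero
  y <- c(0.2, 0.6)
  Yp <- rbind(rep(0.2, 5), rep(0.6, 5))
  perfect <- loss_total(list(wellbeing = y, perma = Yp),
                        list(wellbeing = y, perma = Yp))
  expect_equal(perfect$total, 0)
  # maximal inconsistency: overall 1, dimensions 0 -> consistency exactly 1
  bundle <- list(wellbeing = rep(1, 3), perma = matrix(0, 3, 5))
  l <- loss_total(bundle, list(wellbeing = rep(1, 3),
                               perma = matrix(0, 3, 5)))
  expect_equal(l$consistency, 1)
  # unit component losses combine as 1.0 + 0.8 + 0.5 = 2.3
  unit <- loss_total(list(wellbeing = rep(1, 4), perma = matrix(0, 4, 5)),
                     list(wellbeing = rep(0, 4), perma = matrix(1, 4, 5)))
  expect_equal(unit$wellbeing, 1)
  expect_equal(unit$perma, 1)
  expect_equal(unit$consistency, 1)
  expect_equal(unit$total, 2.3)
  # linear-combination identity on random inputs
  set.seed(7)
  b2 <- list(wellbeing = runif(6), perma = matrix(runif(30), 6))
  l2 <- loss_total(b2, list(wellbeing = runif(6),
                            perma = matrix(runif(30), 6)),
                   lambdas = c(0.7, 0.2, 1.3))
  expect_equal(l2$total,
               0.7 * l2$wellbeing + 0.2 * l2$perma + 1.3 * l2$consistency,
               tolerance = 1e-9)
})

test_that("full forward is deterministic in eval mode and equivariant", {
  co <- tiny_cohort(n = 12, seed = 8)
  ts <- build_topology_set(co)
  cfg <- tiny_config()
  params <- tiny_params(co, cfg)
  a <- forward_full(co, ts, params, cfg)
  b <- forward_full(co, ts, params, cfg)
  expect_identical(a$bundle$wellbeing, b$bundle$wellbeing)
  expect_identical(a$bundle$perma, b$bundle$perma)
  expect_true(all(a$bundle$wellbeing > 0 & a$bundle$wellbeing < 1))
  expect_true(all(a$bundle$perma > 0 & a$bundle$perma < 1))
})

test_that("full forward equals the audited composition of its stages", {
  co <- tiny_cohort(n = 12, seed = 9)
  ts <- build_topology_set(co)
  cfg <- tiny_config()
  params <- tiny_params(co, cfg)
  got <- forward_full(co, ts, params, cfg)
  # manual composition through the exported stage functions
  toks <- tokenize(co$features, params$embed)
  rel <- encode_relations(co, ts, params)
  toks <- cross_modal_enhance(toks, rel$H_graph, params$cm)
  enc <- encoder_forward(toks, params$enc, dropout = cfg$dropout,
                         train_mode = FALSE)
  bundle <- predict_heads(enc$tokens, params$heads)
  expect_lt(max(abs(got$bundle$wellbeing - bundle$wellbeing)), 1e-10)
  expect_lt(max(abs(got$bundle$perma - bundle$perma)), 1e-10)
  expect_lt(max(abs(got$fusion_weights - rel$fusion_weights)), 1e-12)
  expect_lt(max(abs(got$profile - enc$profile)), 1e-12)
})

test_that("alignment matrix summarizes attention mass per head", {
  # identical tokens: every entry 0.2
  m <- 16
  one <- matrix(rnorm(2 * m), 2)
  toks <- lapply(1:5, function(p) one)
  names(toks) <- perma_dims()
  enc <- encoder_forward(toks, make_enc_params())
  A <- alignment_matrix(enc$profile)
  expect_equal(unname(A), matrix(0.2, 5, 5), tolerance = 1e-12)
  # hand-built concentrated profile: identity alignment
  prof <- array(0, c(2, 5, 5, 5))
  for (h in 1:5) prof[, h, , h] <- 1
  expect_equal(unname(alignment_matrix(prof)), diag(5))
  # random profile vs direct averaging
  set.seed(10)
  prof_r <- array(runif(2 * 5 * 5 * 5), c(2, 5, 5, 5))
  A_r <- alignment_matrix(prof_r)
  for (h in 1:5) for (p in 1:5) {
    expect_equal(A_r[h, p], mean(prof_r[, h, , p]), tolerance = 1e-12)
  }
})

test_that("dropout perturbs training mode but never eval mode", {
  toks <- rand_tokens()
  P <- make_enc_params()
  set.seed(11)
  a <- encoder_forward(toks, P, dropout = 0.5, train_mode = TRUE)
  b <- encoder_forward(toks, P, dropout = 0.5, train_mode = TRUE)
  expect_false(identical(a$tokens[[1]], b$tokens[[1]]))
  c1 <- encoder_forward(toks, P, dropout = 0.5, train_mode = FALSE)
  c2 <- encoder_forward(toks, P, dropout = 0.5, train_mode = FALSE)
  expect_identical(c1$tokens[[1]], c2$tokens[[1]])
})
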