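test_that("noiseless generation makes wellbeing exactly the PERMA mean", {
  co <- generate_cohort(synthetic_spec(n = 40, label_noise_sd = 0, seed = 2))
  expect_identical(co$wellbeing, unname(rowMeans(co$perma)))
})

test_that("generation is a pure function of the spec and seed", {
  s <- synthetic_spec(n = 25, seed = 11)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$features, b$features)
  expect_identical(a$wellbeing, b$wellbeing)
  expect_identical(a$perma, b$perma)
  expect_identical(a$learning_style, b$learning_style)
  c2 <- generate_cohort(synthetic_spec(n = 25, seed = 12))
  expect_false(identical(a$features, c2$features))
})

test_that("block features correlate most with their dominant latent factor", {
  spec <- synthetic_spec(n = 2000, feature_noise_sd = 0.05, seed = 5)
  co <- generate_cohort(spec)
  dom_dim <- apply(spec$loading, 1, which.max)
  for (blk in c("learn", "social", "physical", "mental")) {
    feats <- which(co$schema$block_of == blk)
    own <- vapply(feats, function(j) {
      abs(cor(co$features[, j], co$perma[, dom_dim[j]]))
    }, numeric(1))
    other <- vapply(feats, function(j) {
      mean(abs(cor(co$features[, j], co$perma[, -dom_dim[j]])))
    }, numeric(1))
    expect_gt(mean(own), mean(other))
  }
})

test_that("stress tertiles partition the cohort nearly evenly", {
  for (n in c(30, 100, 101)) {
    co <- generate_cohort(synthetic_spec(n = n, seed = 3))
    sizes <- table(co$stress_level)
    expect_lte(max(sizes) - min(sizes), 2)
    expect_equal(sum(sizes), n)
  }
  # low stress corresponds to high positive-emotion latent
  co <- generate_cohort(synthetic_spec(n = 90, seed = 4))
  expect_gt(mean(co$perma[co$stress_level == "low", "P"]),
            mean(co$perma[co$stress_level == "high", "P"]))
})

test_that("write_cohort / read_cohort round-trips the table", {
  co <- generate_cohort(synthetic_spec(n = 20, seed = 6))
  tp <- tempfile(fileext = ".csv")
  sp <- tempfile(fileext = ".json")
  write_cohort(co, tp, sp)
  back <- read_cohort(tp, sp)
  expect_lt(max(abs(back$features - co$features)), 1e-9)
  expect_lt(max(abs(back$wellbeing - co$wellbeing)), 1e-9)
  expect_lt(max(abs(back$perma - co$perma)), 1e-9)
  expect_identical(as.character(back$culture), as.character(co$culture))
  expect_identical(as.character(back$stress_level),
                   as.character(co$stress_level))
  expect_identical(levels(back$learning_style), levels(co$learning_style))
})

test_that("label columns are optional and flagged on read", {
  co <- generate_cohort(synthetic_spec(n = 10, seed = 7))
  unlabelled <- perma_cohort(co$schema, co$features, wellbeing = co$wellbeing,
                             culture = co$culture,
                             learning_style = co$learning_style,
                             stress_level = co$stress_level)
  tp <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".json")
  write_cohort(unlabelled, tp, sp)
  back <- read_cohort(tp, sp)
  expect_true(back$has_wellbeing)
  expect_false(back$has_perma)
})

test_that("out-of-range labels raise errors naming the offending cell", {
  co <- generate_cohort(synthetic_spec(n = 5, seed = 8))
  tp <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".json")
  write_cohort(co, tp, sp)
  df <- read.csv(tp, check.names = FALSE)
  df$wellbeing[3] <- 1.2
  write.csv(df, tp, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(tp, sp), "wellbeing.*row 3|row 3.*wellbeing")
})

test_that("degenerate generator specs are rejected", {
  expect_error(synthetic_spec(n = 0), "positive")
  bad_cult <- default_cultures()
  bad_cult$prop <- c(0.6, 0.5)
  expect_error(synthetic_spec(n = 10, cultures = bad_cult), "sum to 1")
  sch <- default_schema(8L)
  L <- default_loading(sch)
  L[1, ] <- c(1, 0, 0, 0, 0) # learn-block feature loaded on P
  expect_error(synthetic_spec(n = 10, schema = sch, loading = L), "dominant")
  expect_error(perma_schema(paste0("f", 1:4),
                            setNames(rep("learn", 4), paste0("f", 1:4))),
               "non-empty")
})

test_that("scale_features maps declared ranges onto [0, 1] and is idempotent", {
  sch <- perma_schema(
    paste0("f", 1:4),
    setNames(c("learn", "social", "physical", "mental"), paste0("f", 1:4)),
    cbind(min = c(0, 0, -5, 1), max = c(10, 1, 5, 3)))
  X <- rbind(c(5, 0.2, 0, 2), c(0, 1, -5, 1), c(10, 0.5, 5, 3))
  co <- perma_cohort(sch, X)
  sc <- scale_features(co)
  expect_equal(unname(sc$features[1, 1]), 0.5)
  # direct per-column recomputation
  rng <- sch$value_range
  expected <- sweep(sweep(X, 2, rng[, 1], "-"), 2, rng[, 2] - rng[, 1], "/")
  expect_lt(max(abs(sc$features - expected)), 1e-12)
  twice <- scale_features(sc)
  expect_lt(max(abs(twice$features - sc$features)), 1e-12)
  # out-of-range features are refused with the offender named
  X2 <- X; X2[2, 1] <- 11
  expect_error(scale_features(perma_cohort(sch, X2)), "f1")
})

test_that("cohort presets mirror the survey scales", {
  lg <- cohort_preset("large")
  sm <- cohort_preset("small")
  expect_equal(lg$n, 12757L)
  expect_equal(sm$n, 268L)
  expect_equal(lg$schema$d, 23L)
  expect_equal(cohort_preset("default")$n, 512L)
})

test_that("prior map JSON round-trips and validates row sums", {
  prior <- default_perma_prior(default_schema(10L))
  path <- tempfile(fileext = ".json")
  write_perma_prior(prior, path)
  back <- read_perma_prior(path)
  expect_lt(max(abs(back$weights - prior$weights)), 1e-12)
  expect_error(perma_prior(matrix(0.3, 4, 5)), "sum to 1")
})
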