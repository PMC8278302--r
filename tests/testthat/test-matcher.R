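tiny_mat_config <- function(seed = 1L, K = 2L) {
  matcher_config(query_max_length = 4L, doc_max_length = 8L,
                 embedding_dim = 3L, num_kernels = K, kernel_size = 3L,
                 pool_grid = c(2L, 2L), mlp_hidden = 5L, batch_size = 4L,
                 seed = seed,
                 vocabulary = build_vocabulary(list(c("D000001", "alpha", "beta",
                                                      "gamma", "delta"))))
}

test_that("matching matrix is the dot-product grid with zero PAD bands", {
  E <- rbind(UNK = c(0, 0), PAD = c(0, 0), a = c(1, 0), b = c(0, 1),
             c = sqrt(c(0.5, 0.5)))
  # identical single-token query and doc with unit-norm embedding
  S <- build_matching_matrix(token_sequence("c", stage = "matcher"),
                             token_sequence("c", stage = "matcher"), E)
  expect_equal(S[1, 1], 1, tolerance = 1e-12)
  # orthogonal embeddings
  S2 <- build_matching_matrix(token_sequence("a", stage = "matcher"),
                              token_sequence("b", stage = "matcher"), E)
  expect_equal(S2[1, 1], 0, tolerance = 1e-12)
  # PAD rows/cols are zero
  S3 <- build_matching_matrix(token_sequence(c("a", "b"), stage = "matcher"),
                              token_sequence("a", stage = "matcher"), E,
                              query_len = 4L, doc_len = 3L)
  expect_identical(dim(S3), c(4L, 3L))
  expect_true(all(S3[3:4, ] == 0))
  expect_true(all(S3[, 2:3] == 0))
})

test_that("matching matrix equals an entrywise loop oracle", {
  set.seed(3)
  toks <- c("a", "b", "c", "d", "e")
  E <- matrix(rnorm(7 * 4), 7, 4,
              dimnames = list(c("UNK", "PAD", toks), NULL))
  q <- sample(toks, 3, replace = TRUE)
  d <- sample(toks, 4, replace = TRUE)
  S <- build_matching_matrix(token_sequence(q, stage = "matcher"),
                             token_sequence(d, stage = "matcher"), E)
  for (i in 1:3) for (j in 1:4) {
    want <- sum(E[q[i], ] * E[d[j], ])
    expect_equal(S[i, j], want, tolerance = 1e-8)
  }
})

test_that("all-zero matching matrix with zero biases scores exactly zero", {
  model <- init_matcher(tiny_mat_config())
  v2 <- matcher_forward(model, matrix(0, 4, 8))
  expect_identical(v2, 0)
})

test_that("forward pass equals the nested-loop oracle on tiny configurations", {
  set.seed(13)
  for (rep in 1:5) {
    model <- init_matcher(tiny_mat_config(seed = rep, K = 2L))
    # non-zero biases too, so the oracle exercises every term
    model$params$b1 <- rnorm(2, sd = 0.1)
    model$params$b2 <- rnorm(2, sd = 0.1)
    model$params$b3 <- rnorm(5, sd = 0.1)
    model$params$b4 <- rnorm(1, sd = 0.1)
    S <- matrix(rnorm(4 * 8), 4, 8)
    got <- matcher_forward(model, S)
    want <- oracle_matcher_forward(S, model$params, c(2L, 2L))
    expect_equal(got, as.numeric(want), tolerance = 1e-8)
    expect_true(is.finite(got))
    expect_length(got, 1L)
  }
})

test_that("appending PAD tokens to either sequence leaves v2 unchanged", {
  model <- init_matcher(tiny_mat_config(seed = 4L))
  q <- token_sequence(c("alpha", "beta"), stage = "matcher")
  d <- token_sequence(c("gamma", "alpha", "delta"), stage = "matcher")
  qp <- token_sequence(c(q$tokens, "PAD", "PAD"), stage = "matcher")
  dp <- token_sequence(c(d$tokens, rep("PAD", 4L)), stage = "matcher")
  expect_equal(matcher_score(model, q, d), matcher_score(model, qp, dp),
               tolerance = 1e-12)
})

test_that("matcher backprop agrees with finite differences", {
  cfg <- tiny_mat_config(seed = 9L)
  model <- init_matcher(cfg)
  params <- model$params
  S <- matrix(rnorm(4 * 8), 4, 8)
  target <- 1
  loss_at <- function(p) {
    0.5 * (pmrank:::mp_forward_cache(p, S, cfg)$v2 - target)^2
  }
  cache <- pmrank:::mp_forward_cache(params, S, cfg)
  g <- pmrank:::mp_backward(params, cache, cache$v2 - target, cfg)
  eps <- 1e-6
  set.seed(10)
  for (leaf in c("W1", "b1", "W2", "b2", "W3", "b3", "w4", "b4")) {
    x <- params[[leaf]]
    i <- sample(length(x), 1)
    pp <- params; pp[[leaf]][i] <- pp[[leaf]][i] + eps
    pm <- params; pm[[leaf]][i] <- pm[[leaf]][i] - eps
    fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    an <- g[[leaf]][i]
    denom <- max(abs(fd), abs(an), 1e-6)
    expect_lt(abs(fd - an) / denom, 1e-3)
  }
})

test_that("disease annotations map to the three grades", {
  expect_identical(label_disease_grade("exact"), 2L)
  expect_identical(label_disease_grade("more specific"), 1L)
  expect_identical(label_disease_grade("more general"), 1L)
  expect_identical(label_disease_grade("not disease"), 0L)
  expect_error(label_disease_grade("other"))
})

make_tiny_pairs <- function(n = 40L) {
  # grade-2 pairs share the planted entity token with the query
  lapply(seq_len(n), function(i) {
    grade <- c(0L, 1L, 2L)[i %% 3L + 1L]
    doc <- c(sample(c("alpha", "beta", "gamma", "delta"), 5L, TRUE),
             if (grade == 2L) "D000001")
    list(query = token_sequence("D000001", stage = "matcher"),
         doc = token_sequence(sample(doc), stage = "matcher"),
         grade = grade)
  })
}

test_that("matcher training splits 8:1:1, needs two grades, and descends", {
  pairs <- make_tiny_pairs(40L)
  single <- lapply(pairs, function(p) { p$grade <- 2L; p })
  expect_error(train_matcher(single, tiny_mat_config()), "two grades")
  cfg <- tiny_mat_config(seed = 2L)
  cfg$max_epochs <- 5L
  cfg$patience <- 5L
  cfg$learning_rate <- 0.05
  model <- train_matcher(pairs, cfg)
  expect_identical(lengths(model$split)[c("train", "dev", "test")],
                   c(train = 32L, dev = 4L, test = 4L))
  expect_lt(tail(model$history$train_loss, 1), model$history$train_loss[1])
})

test_that("seeded matcher training is reproducible", {
  pairs <- make_tiny_pairs(24L)
  cfg <- tiny_mat_config(seed = 6L)
  cfg$max_epochs <- 2L
  m1 <- train_matcher(pairs, cfg)
  m2 <- train_matcher(pairs, cfg)
  expect_identical(m1$params, m2$params)
  s1 <- vapply(pairs, function(p) matcher_score(m1, p$query, p$doc), numeric(1))
  s2 <- vapply(pairs, function(p) matcher_score(m2, p$query, p$doc), numeric(1))
  expect_identical(s1, s2)
})
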