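tiny_config <- function(vocab, h = 6L, dims = 4L, seed = 1L) {
  classifier_config(h = h, embedding_dim = dims, hidden_dim = dims,
                    batch_size = 4L, seed = seed, vocabulary = vocab)
}

tiny_vocab <- build_vocabulary(list(c("melanoma", "therapy", "tumor", "gene",
                                      "cell", "trial")))

test_that("gru_cell with all-zero parameters halves the previous state", {
  De <- 3L; Dh <- 4L
  p <- list(Wz = matrix(0, De, Dh), Uz = matrix(0, Dh, Dh), bz = numeric(Dh),
            Wr = matrix(0, De, Dh), Ur = matrix(0, Dh, Dh), br = numeric(Dh),
            Wh = matrix(0, De, Dh), Uh = matrix(0, Dh, Dh), bh = numeric(Dh))
  h_prev <- c(1, -2, 0.5, 4)
  h <- gru_cell(c(1, 1, 1), h_prev, p)
  expect_equal(as.numeric(h), 0.5 * h_prev, tolerance = 1e-12)
})

test_that("gru_cell matches the scalar-loop oracle and respects gate bounds", {
  set.seed(31)
  for (rep in 1:25) {
    De <- sample(1:5, 1); Dh <- sample(1:5, 1)
    p <- random_gru_params(De, Dh)
    v <- rnorm(De); h_prev <- rnorm(Dh)
    h <- gru_cell(v, h_prev, p)
    expect_equal(as.numeric(h), oracle_gru(v, h_prev, p), tolerance = 1e-10)
    g <- attr(h, "gates")
    expect_true(all(g$z > 0 & g$z < 1))
    expect_true(all(g$r > 0 & g$r < 1))
    expect_true(all(abs(h) <= pmax(abs(h_prev), 1) + 1e-12))
  }
  expect_error(gru_cell(rnorm(3), rnorm(4), random_gru_params(2, 4)),
               "dimension mismatch")
})

test_that("encode has the right shape and direction-dependence structure", {
  cfg <- tiny_config(tiny_vocab)
  model <- init_classifier(cfg)
  seq1 <- preprocess_for_classifier(
    document("x", "melanoma", "therapy tumor gene"), cfg$h)
  H <- encode(seq1, model)
  expect_identical(dim(H), c(6L, 8L))
  # forward half at position t ignores later tokens
  seq2 <- preprocess_for_classifier(
    document("x", "melanoma", "therapy cell trial"), cfg$h)
  H2 <- encode(seq2, model)
  expect_equal(H[1:2, 1:4], H2[1:2, 1:4], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(H[1:2, 5:8], H2[1:2, 5:8])))
})

test_that("with tied direction parameters, reversing the input swaps the halves", {
  cfg <- tiny_config(tiny_vocab, h = 3L)
  model <- init_classifier(cfg)
  model$params$bwd <- model$params$fwd
  s <- token_sequence(c("melanoma", "therapy", "tumor"), "a", "classifier")
  r <- token_sequence(rev(s$tokens), "a", "classifier")
  Hs <- encode(s, model)
  Hr <- encode(r, model)
  Dh <- cfg$hidden_dim
  expect_equal(Hs[, 1:Dh], Hr[3:1, Dh + 1:Dh], tolerance = 1e-12)
  expect_equal(Hs[, Dh + 1:Dh], Hr[3:1, 1:Dh], tolerance = 1e-12)
})

test_that("an all-PAD input leaves the context matrix constant across positions", {
  cfg <- tiny_config(tiny_vocab)
  model <- init_classifier(cfg)
  H <- encode(token_sequence(rep("PAD", cfg$h), "p", "classifier"), model)
  expect_true(all(abs(sweep(H, 2L, H[1, ])) < 1e-15))
})

test_that("attention weights are a proper convex combination", {
  # identical rows: exactly uniform
  H <- matrix(rep(c(1, -1, 2), each = 5), nrow = 5)
  at <- attention_pool(H, q = c(0.3, 0.1, -0.2))
  expect_equal(at$weights, rep(1 / 5, 5), tolerance = 1e-12)
  # two positions with score gap ln(3): weights (0.25, 0.75)
  d <- 4L
  q <- c(1, 0, 0, 0)
  H2 <- rbind(rep(0, d), c(log(3) * sqrt(d), 0, 0, 0))
  at2 <- attention_pool(H2, q)
  expect_equal(at2$weights, c(0.25, 0.75), tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(2:8, 1); dd <- sample(2:6, 1)
    Hr <- matrix(rnorm(n * dd), n, dd)
    qr <- rnorm(dd)
    a <- attention_pool(Hr, qr)
    expect_true(all(a$weights >= 0))
    expect_lt(abs(sum(a$weights) - 1), 1e-6)
    # pooled vector lies in the convex hull: inside coordinate-wise bounds
    expect_true(all(a$pooled <= apply(Hr, 2, max) + 1e-12))
    expect_true(all(a$pooled >= apply(Hr, 2, min) - 1e-12))
  }
})

test_that("masked attention ignores PAD positions", {
  H <- rbind(c(1, 1), c(50, 50), c(2, 2))
  a <- attention_pool(H, c(1, 1), mask = c(1, 0, 1))
  expect_equal(a$weights[2], 0, tolerance = 1e-15)
  expect_lt(abs(sum(a$weights) - 1), 1e-12)
})

test_that("prediction is a deterministic two-class probability", {
  cfg <- tiny_config(tiny_vocab)
  model <- init_classifier(cfg)
  doc <- document("d", "melanoma therapy", "tumor gene cell")
  v1 <- predict_treatment(model, doc)
  expect_true(v1 >= 0 && v1 <= 1)
  expect_identical(predict_treatment(model, doc), v1)
  # zero output projection: exactly uniform softmax
  model$params$Wo[] <- 0
  model$params$bo[] <- 0
  expect_equal(predict_treatment(model, doc), 0.5, tolerance = 1e-12)
})

test_that("backprop agrees with finite differences on a tiny model", {
  cfg <- tiny_config(tiny_vocab, h = 6L, dims = 4L, seed = 5L)
  model <- init_classifier(cfg)
  seqs <- list(
    preprocess_for_classifier(document("a", "melanoma therapy", "tumor"), cfg$h),
    preprocess_for_classifier(document("b", "cell", "gene trial cell"), cfg$h)
  )
  b <- pmrank:::seqs_to_batch(seqs, cfg$vocabulary, cfg$h)
  y <- c(1L, 0L)
  params <- model$params
  fw <- pmrank:::clf_forward(params, b$ids, b$mask, cfg)
  grads <- pmrank:::clf_backward(params, b$ids, b$mask, y, cfg, fw)
  loss_at <- function(p) pmrank:::clf_loss(p, b$ids, b$mask, y, cfg)
  eps <- 1e-5
  set.seed(99)
  leaves <- list(c("fwd", "Wz"), c("fwd", "Uh"), c("fwd", "br"), c("bwd", "Wh"),
                 c("bwd", "Uz"), "q", "Wo", "bo", "E", c("fwd", "bh"))
  for (leaf in leaves) {
    get_leaf <- function(p) if (length(leaf) == 2) p[[leaf[1]]][[leaf[2]]] else p[[leaf]]
    set_leaf <- function(p, val) {
      if (length(leaf) == 2) p[[leaf[1]]][[leaf[2]]] <- val else p[[leaf]] <- val
      p
    }
    x <- get_leaf(params)
    i <- sample(length(x), 1)
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (loss_at(set_leaf(params, xp)) - loss_at(set_leaf(params, xm))) / (2 * eps)
    an <- get_leaf(grads)[i]
    denom <- max(abs(fd), abs(an), 1e-8)
    expect_lt(abs(fd - an) / denom, 1e-4)
  }
})

test_that("training splits 8:1:1, rejects one-class data, and descends", {
  set.seed(61)
  docs <- lapply(1:100, function(i) {
    lab <- i %% 2L
    body <- if (lab == 1L) "therapy treatment surgery outcome"
            else "cell gene protein assay"
    document(sprintf("d%03d", i), "title words", body)
  })
  labels <- (1:100) %% 2L
  expect_error(train_classifier(docs, rep(1L, 100),
                                tiny_config(NULL, h = 8L)), "both classes")
  cfg <- classifier_config(h = 8L, embedding_dim = 6L, hidden_dim = 6L,
                           batch_size = 16L, seed = 2L, max_epochs = 5L,
                           patience = 5L, learning_rate = 0.01)
  model <- train_classifier(docs, labels, cfg)
  expect_identical(lengths(model$split)[c("train", "dev", "test")],
                   c(train = 80L, dev = 10L, test = 10L))
  hist <- model$history
  expect_lt(tail(hist$train_loss, 1), hist$train_loss[1])
})

test_that("seeded training is bit-reproducible", {
  docs <- lapply(1:30, function(i) {
    document(sprintf("d%02d", i), "t",
             if (i %% 2) "therapy outcome" else "cell gene")
  })
  cfg <- classifier_config(h = 6L, embedding_dim = 4L, hidden_dim = 4L,
                           batch_size = 8L, seed = 17L, max_epochs = 2L,
                           patience = 2L)
  m1 <- train_classifier(docs, (1:30) %% 2L, cfg)
  m2 <- train_classifier(docs, (1:30) %% 2L, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(classifier_scores(m1, docs), classifier_scores(m2, docs))
})
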