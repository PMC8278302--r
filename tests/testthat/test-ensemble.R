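test_that("featurize builds [v1, v2, v1^2, v2^2] and validates v1", {
  expect_identical(featurize(0, 0), c(0, 0, 0, 0))
  expect_identical(featurize(1, -1), c(1, -1, 1, 1))
  expect_identical(featurize(0.5, 2), c(0.5, 2, 0.25, 4))
  expect_error(featurize(1.2, 0), "v1")
  expect_error(featurize(-0.1, 0), "v1")
})

test_that("lr_probability is the sigmoid of the affine score", {
  m0 <- binary_lr(rep(0, 4), 0, "definitely")
  expect_identical(lr_probability(m0, featurize(0.3, 1)), 0.5)
  m1 <- binary_lr(c(1, 0, 0, 0), 0, "partially")
  expect_equal(lr_probability(m1, featurize(0.5, 9)), 1 / (1 + exp(-0.5)),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    m <- binary_lr(rnorm(4), rnorm(1), "not")
    p <- lr_probability(m, featurize(runif(1), rnorm(1)))
    expect_true(p > 0 && p < 1)
  }
})

random_ensemble <- function() {
  lr_ensemble(binary_lr(rnorm(4), rnorm(1), "definitely"),
              binary_lr(rnorm(4), rnorm(1), "partially"),
              binary_lr(rnorm(4), rnorm(1), "not"))
}

test_that("ensemble_label is the argmax of the three probabilities", {
  set.seed(4)
  for (i in 1:100) {
    ens <- random_ensemble()
    v1 <- runif(1); v2 <- runif(1, -3, 3)
    x <- featurize(v1, v2)
    p <- c(lr_probability(ens$lr1, x), lr_probability(ens$lr2, x),
           lr_probability(ens$lr3, x))
    expect_identical(ensemble_label(ens, v1, v2),
                     c("definitely", "partially", "not")[which.max(p)])
  }
  # exact three-way tie resolves to the highest relevance level
  tied <- lr_ensemble(binary_lr(rep(0, 4), 0, "definitely"),
                      binary_lr(rep(0, 4), 0, "partially"),
                      binary_lr(rep(0, 4), 0, "not"))
  expect_identical(ensemble_label(tied, 0.5, 0), "definitely")
})

test_that("voting implements the three-region rule including v2 == 0", {
  expect_identical(voting_label(0.9, 1.2), "definitely")
  expect_identical(voting_label(0.1, -0.4), "not")
  expect_identical(voting_label(0.9, -0.4), "partially")
  expect_identical(voting_label(0.1, 0.4), "partially")
  expect_identical(voting_label(0.5, 0.4), "definitely")  # threshold inclusive
  expect_identical(voting_label(0.9, 0), "partially")     # exact zero
  expect_identical(voting_label(0.1, 0), "partially")
})

test_that("voting-mimicking LR parameters agree with voting off the margins", {
  # logits f1 = 10 v1 + v2 - 8.5, f2 = 0, f3 = -10 v1 - v2 + 1.5 carve the
  # voting quadrants for points away from v1 = 0.5 and v2 = 0
  ens <- lr_ensemble(binary_lr(c(10, 1, 0, 0), -8.5, "definitely"),
                     binary_lr(rep(0, 4), 0, "partially"),
                     binary_lr(c(-10, -1, 0, 0), 1.5, "not"))
  for (v1 in c(0.1, 0.2, 0.8, 0.9)) {
    for (v2 in c(-3, -2, -1, 1, 2, 3)) {
      expect_identical(ensemble_label(ens, v1, v2), voting_label(v1, v2),
                       info = sprintf("v1=%.1f v2=%.1f", v1, v2))
    }
  }
})

test_that("one-vs-rest relabeling matches the labeling strategy on a 6-example table", {
  levels <- c("definitely", "partially", "not", "definitely", "not", "partially")
  tgt <- one_vs_rest_targets(levels)
  expect_identical(tgt[, "lr1"], c(1L, 0L, 0L, 1L, 0L, 0L))
  expect_identical(tgt[, "lr2"], c(0L, 1L, 0L, 0L, 0L, 1L))
  expect_identical(tgt[, "lr3"], c(0L, 0L, 1L, 0L, 1L, 0L))
  expect_identical(rowSums(tgt), rep(1, 6))
})

test_that("training requires all three levels and recovers a separated toy set", {
  # labels produced by an ensemble inside the representable family, on
  # points clear of its decision margins: training must recover them all
  gen <- lr_ensemble(binary_lr(c(10, 1, 0, 0), -8.5, "definitely"),
                     binary_lr(rep(0, 4), 0, "partially"),
                     binary_lr(c(-10, -1, 0, 0), 1.5, "not"))
  grid <- expand.grid(v1 = c(0.1, 0.2, 0.8, 0.9), v2 = c(-3, -2, -1, 1, 2, 3))
  v1 <- rep(grid$v1, 8L)
  v2 <- rep(grid$v2, 8L)
  levels <- mapply(function(a, b) ensemble_label(gen, a, b), v1, v2)
  feats <- t(mapply(featurize, v1, v2))
  expect_error(train_ensemble(feats[levels != "not", ], levels[levels != "not"]),
               "missing")
  ens <- train_ensemble(feats, levels, seed = 3L)
  got <- mapply(function(a, b) ensemble_label(ens, a, b), v1, v2)
  expect_identical(unname(got), unname(levels))
})

test_that("rerank keeps same-tier order, obeys tier precedence, and validates labels", {
  rl <- ranked_list("t1", c("A", "B", "C"), c(3, 2, 1))
  same <- rerank(rl, c(A = "partially", B = "partially", C = "partially"))
  expect_identical(same$entries, rl$entries)
  flip <- rerank(ranked_list("t1", c("A", "B"), c(3, 2)),
                 c(A = "not", B = "definitely"))
  expect_identical(flip$entries$doc_id, c("B", "A"))
  expect_error(rerank(rl, c(A = "not", B = "definitely")), "missing relevance label")
  expect_error(rerank(rl, c(A = "x", B = "y", C = "z")), "relevance levels")
})

test_that("rerank matches a sort oracle, permutes, and is idempotent", {
  set.seed(12)
  lv <- c("definitely", "partially", "not")
  for (rep in 1:200) {
    n <- sample(1:30, 1)
    ids <- sprintf("d%02d", sample(99, n))
    scores <- round(runif(n, 0, 5), sample(0:3, 1)) # encourage score ties
    labels <- setNames(sample(lv, n, replace = TRUE), ids)
    rl <- ranked_list("t", ids, scores)
    out <- rerank(rl, labels)
    # independent comparison-sort oracle over (tier, -score, doc_id)
    df <- data.frame(doc_id = rl$entries$doc_id, score = rl$entries$score,
                     tier = match(labels[rl$entries$doc_id], lv),
                     stringsAsFactors = FALSE)
    df <- df[order(df$tier, -df$score, df$doc_id), ]
    expect_identical(out$entries$doc_id, df$doc_id)
    expect_identical(sort(out$entries$doc_id), sort(rl$entries$doc_id))
    expect_equal(sort(out$entries$score), sort(rl$entries$score))
    expect_identical(rerank(out, labels), out)
  }
})
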