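# Three-level relevance labels, ordered from most to least relevant.
RELEVANCE_LEVELS <- c("definitely", "partially", "not")

#' Feature vector for the logistic-regression ensemble
#'
#' `[v1, v2, v1^2, v2^2]`: the treatment probability, the disease
#' relevance score, and their squares.
#'
#' @param v1 treatment probability in `[0, 1]`.
#' @param v2 disease relevance score (any finite real).
#' @return numeric vector of length 4.
#' @export
featurize <- function(v1, v2) {
  if (!is.finite(v1) || v1 < 0 || v1 > 1) stop("v1 must lie in [0, 1]")
  stopifnot(is.finite(v2))
  c(v1, v2, v1^2, v2^2)
}

#' Construct a binary logistic-regression model
#'
#' @param weights numeric vector of length 4.
#' @param bias numeric scalar.
#' @param positive_class the relevance level treated as the positive class.
#' @return object of class `binary_lr`.
#' @export
binary_lr <- function(weights, bias, positive_class) {
  stopifnot(length(weights) == 4L, all(is.finite(weights)), is.finite(bias),
            positive_class %in% RELEVANCE_LEVELS)
  structure(list(weights = as.numeric(weights), bias = as.numeric(bias),
                 positive_class = positive_class),
            class = "binary_lr")
}

#' Positive-class probability of a binary LR
#'
#' `sigmoid(weights . x + bias)`.
#'
#' @param model a [binary_lr()].
#' @param x feature vector from [featurize()].
#' @return probability in `(0, 1)`.
#' @export
lr_probability <- function(model, x) {
  stopifnot(inherits(model, "binary_lr"), length(x) == 4L)
  sigmoid(sum(model$weights * x) + model$bias)
}

#' Assemble the three-model ensemble
#'
#' @param lr1,lr2,lr3 [binary_lr()] models whose positive classes are
#'   `definitely`, `partially` and `not`, respectively.
#' @return object of class `lr_ensemble`.
#' @export
lr_ensemble <- function(lr1, lr2, lr3) {
  stopifnot(identical(lr1$positive_class, "definitely"),
            identical(lr2$positive_class, "partially"),
            identical(lr3$positive_class, "not"))
  structure(list(lr1 = lr1, lr2 = lr2, lr3 = lr3), class = "lr_ensemble")
}

#' Relevance level from the LR ensemble
#'
#' Evaluates the three one-vs-rest probabilities on `featurize(v1, v2)`
#' and returns the positive class of the largest; exact ties resolve
#' toward the higher relevance level.
#'
#' @param ensemble an [lr_ensemble()].
#' @param v1,v2 model scores.
#' @return one of `"definitely"`, `"partially"`, `"not"`.
#' @export
ensemble_label <- function(ensemble, v1, v2) {
  stopifnot(inherits(ensemble, "lr_ensemble"))
  x <- featurize(v1, v2)
  p <- c(lr_probability(ensemble$lr1, x),
         lr_probability(ensemble$lr2, x),
         lr_probability(ensemble$lr3, x))
  RELEVANCE_LEVELS[which.max(p)] # which.max takes the first maximum
}

#' Relevance level from the voting rule
#'
#' The baseline fusion: treatment-focused (`v1 >= threshold`) and
#' `v2 > 0` is definitely relevant; not treatment-focused and `v2 < 0` is
#' not relevant; everything else (including `v2 == 0` exactly) is
#' partially relevant.
#'
#' @param v1,v2 model scores.
#' @param threshold treatment decision threshold on `v1`.
#' @return one of `"definitely"`, `"partially"`, `"not"`.
#' @export
voting_label <- function(v1, v2, threshold = 0.5) {
  flag <- v1 >= threshold
  if (flag && v2 > 0) return("definitely")
  if (!flag && v2 < 0) return("not")
  "partially"
}

# full-batch Adam fit of one binary LR (cross-entropy + ridge) with early
# stopping on the dev part of a seeded 8:1:1 split
fit_binary_lr <- function(X, y, positive_class, seed, l2 = 1.0,
                          lr = 0.1, max_epochs = 2000L, patience = 50L) {
  n <- nrow(X)
  split <- split_811(n, seed)
  params <- list(w = numeric(4L), b = 0)
  opt <- adam_init(params)
  ce <- function(p, idx) {
    pr <- sigmoid(drop(X[idx, , drop = FALSE] %*% p$w) + p$b)
    -mean(y[idx] * log(pr + 1e-12) + (1 - y[idx]) * log(1 - pr + 1e-12))
  }
  best <- list(loss = Inf, params = params)
  wait <- 0L
  tr <- split$train
  for (epoch in seq_len(max_epochs)) {
    pr <- sigmoid(drop(X[tr, , drop = FALSE] %*% params$w) + params$b)
    err <- pr - y[tr]
    grads <- list(
      w = drop(crossprod(X[tr, , drop = FALSE], err)) / length(tr) +
        l2 * params$w / length(tr),
      b = mean(err)
    )
    upd <- adam_step(params, grads, opt, lr)
    params <- upd$params
    opt <- upd$state
    dev <- ce(params, split$dev)
    if (dev < best$loss - 1e-9) {
      best <- list(loss = dev, params = params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  binary_lr(best$params$w, best$params$b, positive_class)
}

#' Train the LR ensemble
#'
#' Builds the three one-vs-rest datasets (definitely / partially / not as
#' the positive class of LR1 / LR2 / LR3 respectively) and fits each by
#' cross-entropy gradient descent with L2 shrinkage and early stopping on
#' a seeded 8:1:1 split.
#'
#' @param features matrix (n x 4) of [featurize()] rows, or a list of
#'   feature vectors.
#' @param levels character vector of relevance levels; all three must be
#'   present.
#' @param seed integer seed for the splits.
#' @return an [lr_ensemble()].
#' @export
train_ensemble <- function(features, levels, seed = 1L) {
  if (is.list(features)) features <- do.call(rbind, features)
  stopifnot(is.matrix(features), ncol(features) == 4L,
            nrow(features) == length(levels))
  if (!all(levels %in% RELEVANCE_LEVELS)) {
    stop("levels must be in {", paste(RELEVANCE_LEVELS, collapse = ", "), "}")
  }
  missing <- setdiff(RELEVANCE_LEVELS, unique(levels))
  if (length(missing)) {
    stop("all three relevance levels must be present; missing: ",
         paste(missing, collapse = ", "))
  }
  fits <- lapply(seq_along(RELEVANCE_LEVELS), function(k) {
    fit_binary_lr(features, as.numeric(levels == RELEVANCE_LEVELS[k]),
                  RELEVANCE_LEVELS[k], seed = seed + k)
  })
  lr_ensemble(fits[[1L]], fits[[2L]], fits[[3L]])
}

#' One-vs-rest target construction
#'
#' The relabeling used to build the three binary datasets: a level's
#' target vector is `(1, 0, 0)` for definitely, `(0, 1, 0)` for partially
#' and `(0, 0, 1)` for not relevant, across LR1/LR2/LR3.
#'
#' @param levels character vector of relevance levels.
#' @return integer matrix (n x 3) with columns `lr1`, `lr2`, `lr3`.
#' @export
one_vs_rest_targets <- function(levels) {
  stopifnot(all(levels %in% RELEVANCE_LEVELS))
  out <- sapply(RELEVANCE_LEVELS, function(l) as.integer(levels == l))
  out <- matrix(out, ncol = 3L, dimnames = list(NULL, c("lr1", "lr2", "lr3")))
  out
}

#' Tiered re-ranking of an initial list
#'
#' Reorders an initial BM25 ranking so that all definitely relevant
#' documents precede all partially relevant ones, with non-relevant
#' documents last; within a tier documents keep descending BM25 order
#' (ties by ascending doc_id). Scores are preserved, so the operation is
#' a permutation of its input and is idempotent.
#'
#' @param initial a [ranked_list()] from [search()].
#' @param labels named character vector doc_id -> relevance level; every
#'   document in `initial` must be labeled.
#' @return a [ranked_list()] in tier order.
#' @export
rerank <- function(initial, labels) {
  stopifnot(inherits(initial, "ranked_list"))
  ids <- initial$entries$doc_id
  lv <- labels[ids]
  if (anyNA(lv)) {
    stop("missing relevance label for: ",
         paste(head(ids[is.na(lv)], 5L), collapse = ", "))
  }
  if (!all(lv %in% RELEVANCE_LEVELS)) stop("labels must be relevance levels")
  tier <- match(lv, RELEVANCE_LEVELS)
  ord <- order(tier, -initial$entries$score, ids)
  ranked_list(initial$topic_id, ids[ord], initial$entries$score[ord], sorted = FALSE)
}
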