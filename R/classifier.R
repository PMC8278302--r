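#' Configuration for the treatment-focus classifier
#'
#' Hyperparameters of the bidirectional-GRU attention classifier. Defaults
#' follow the reference configuration: document window of 256 tokens,
#' 200-dimensional embeddings and hidden states, Adam at learning rate
#' 0.001 with batches of 128, early stopping with patience 3 over at most
#' 30 epochs. Smaller `embedding_dim`/`hidden_dim` are appropriate for
#' small synthetic corpora.
#'
#' @param h maximum document length (tokens).
#' @param embedding_dim,hidden_dim positive integer dimensions.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization, splits and batch
#'   order.
#' @param max_epochs,patience early-stopping controls (dev cross-entropy).
#' @param vocabulary optional named integer vector token -> index; built
#'   from the training corpus when `NULL`.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(h = 256L, embedding_dim = 200L, hidden_dim = 200L,
                              learning_rate = 0.001, batch_size = 128L,
                              seed = 1L, max_epochs = 30L, patience = 3L,
                              vocabulary = NULL) {
  stopifnot(h >= 1L, embedding_dim >= 1L, hidden_dim >= 1L,
            learning_rate > 0, batch_size >= 1L, max_epochs >= 1L, patience >= 1L)
  structure(
    list(h = as.integer(h), embedding_dim = as.integer(embedding_dim),
         hidden_dim = as.integer(hidden_dim), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         vocabulary = vocabulary),
    class = "classifier_config"
  )
}

#' Build a token vocabulary
#'
#' Reserved tokens `UNK`, `PAD`, `SEP`, `NUM` always occupy the first four
#' indices; remaining tokens are added in decreasing frequency (ties by
#' token) with a minimum-frequency cutoff.
#'
#' @param token_lists list of character vectors.
#' @param min_freq minimum corpus frequency for inclusion.
#' @return named integer vector token -> index.
#' @export
build_vocabulary <- function(token_lists, min_freq = 1L) {
  reserved <- c(TOKEN_UNK, TOKEN_PAD, TOKEN_SEP, TOKEN_NUM)
  counts <- table(unlist(token_lists))
  counts <- counts[!(names(counts) %in% reserved)]
  counts <- counts[counts >= min_freq]
  ord <- order(-as.integer(counts), names(counts))
  toks <- c(reserved, names(counts)[ord])
  setNames(seq_along(toks), toks)
}

tokens_to_ids <- function(tokens, vocab) {
  ids <- unname(vocab[tokens])
  ids[is.na(ids)] <- vocab[[TOKEN_UNK]]
  ids
}

# list of token_sequences -> (ids, mask) matrices of shape batch x h
seqs_to_batch <- function(seqs, vocab, h) {
  ids <- matrix(0L, length(seqs), h)
  mask <- matrix(1, length(seqs), h)
  for (i in seq_along(seqs)) {
    toks <- seqs[[i]]$tokens
    stopifnot(length(toks) == h)
    ids[i, ] <- tokens_to_ids(toks, vocab)
    mask[i, toks == TOKEN_PAD] <- 0
  }
  list(ids = ids, mask = mask)
}

#' Initialize a classifier model
#'
#' Embeddings start uniform(-0.05, 0.05); GRU and projection weights use
#' uniform Glorot ranges. All randomness is governed by `config$seed`.
#'
#' @param config a [classifier_config()] whose `vocabulary` is set.
#' @return object of class `classifier_model`.
#' @export
init_classifier <- function(config) {
  stopifnot(inherits(config, "classifier_config"), !is.null(config$vocabulary))
  V <- length(config$vocabulary)
  De <- config$embedding_dim
  Dh <- config$hidden_dim
  params <- with_seed(config$seed, {
    gru_dir <- function() {
      rw <- glorot_r(De, Dh)
      ru <- glorot_r(Dh, Dh)
      list(
        Wz = runif_mat(De, Dh, rw), Uz = runif_mat(Dh, Dh, ru), bz = numeric(Dh),
        Wr = runif_mat(De, Dh, rw), Ur = runif_mat(Dh, Dh, ru), br = numeric(Dh),
        Wh = runif_mat(De, Dh, rw), Uh = runif_mat(Dh, Dh, ru), bh = numeric(Dh)
      )
    }
    list(
      E = runif_mat(V, De, 0.05),
      fwd = gru_dir(),
      bwd = gru_dir(),
      q = runif(2 * Dh, -glorot_r(2 * Dh, 1), glorot_r(2 * Dh, 1)),
      Wo = runif_mat(2 * Dh, 2L, glorot_r(2 * Dh, 2)),
      bo = numeric(2L)
    )
  })
  structure(list(config = config, params = params), class = "classifier_model")
}

#' One GRU cell step
#'
#' Computes the gated-recurrent-unit update
#' `z = sigmoid(v W_z + h_prev U_z + b_z)`,
#' `r = sigmoid(v W_r + h_prev U_r + b_r)`,
#' `h~ = tanh(v W_h + (r * h_prev) U_h + b_h)`,
#' `h = (1 - z) * h_prev + z * h~`.
#'
#' @param v input vector (length `embedding_dim`) or batch matrix.
#' @param h_prev previous state vector (length `hidden_dim`) or batch
#'   matrix.
#' @param params one-direction parameter list with `Wz, Uz, bz, Wr, Ur,
#'   br, Wh, Uh, bh`.
#' @return new state, same shape as `h_prev`. Attribute `"gates"` carries
#'   `z`, `r` and the candidate state.
#' @export
gru_cell <- function(v, h_prev, params) {
  vec_in <- is.null(dim(v))
  if (vec_in) v <- matrix(v, 1L)
  if (is.null(dim(h_prev))) h_prev <- matrix(h_prev, 1L)
  if (ncol(v) != nrow(params$Wz) || ncol(h_prev) != nrow(params$Uz)) {
    stop("gru_cell: dimension mismatch between inputs and parameters")
  }
  z <- sigmoid(add_bias(v %*% params$Wz + h_prev %*% params$Uz, params$bz))
  r <- sigmoid(add_bias(v %*% params$Wr + h_prev %*% params$Ur, params$br))
  cand <- tanh(add_bias(v %*% params$Wh + (r * h_prev) %*% params$Uh, params$bh))
  h <- (1 - z) * h_prev + z * cand
  if (vec_in) {
    out <- drop(h)
    attr(out, "gates") <- list(z = drop(z), r = drop(r), candidate = drop(cand))
    return(out)
  }
  attr(h, "gates") <- list(z = z, r = r, candidate = cand)
  h
}

# one-direction GRU pass over a batch; PAD steps (mask 0) keep the previous
# state so padding never alters the encoding
gru_direction_forward <- function(params, E, ids, mask, Dh, reverse = FALSE) {
  batch <- nrow(ids)
  h <- ncol(ids)
  order_t <- if (reverse) rev(seq_len(h)) else seq_len(h)
  Hs <- vector("list", h)
  cache <- vector("list", h)
  state <- matrix(0, batch, Dh)
  for (t in order_t) {
    X <- E[ids[, t], , drop = FALSE]
    hprev <- state
    hnew <- gru_cell(X, hprev, params)
    g <- attr(hnew, "gates")
    attr(hnew, "gates") <- NULL
    m <- mask[, t]
    state <- hnew * m + hprev * (1 - m)
    Hs[[t]] <- state
    cache[[t]] <- list(z = g$z, r = g$r, cand = g$candidate, hprev = hprev, m = m)
  }
  list(Hs = Hs, cache = cache)
}

gru_direction_backward <- function(params, E, ids, mask, dHs, cache, reverse = FALSE) {
  batch <- nrow(ids)
  h <- ncol(ids)
  Dh <- ncol(params$Uz)
  g <- nn_zeros_like(params)
  dE_rows <- vector("list", h)
  dE_ids <- vector("list", h)
  dcarry <- matrix(0, batch, Dh)
  order_t <- if (reverse) seq_len(h) else rev(seq_len(h)) # reverse of forward order
  for (t in order_t) {
    cc <- cache[[t]]
    dh_total <- dHs[[t]] + dcarry
    m <- cc$m
    dhnew <- dh_total * m
    dhprev <- dh_total * (1 - m)
    z <- cc$z; r <- cc$r; cand <- cc$cand; hprev <- cc$hprev
    dz <- dhnew * (cand - hprev)
    dcand <- dhnew * z
    dhprev <- dhprev + dhnew * (1 - z)
    X <- E[ids[, t], , drop = FALSE]
    da_c <- dcand * (1 - cand^2)
    g$Wh <- g$Wh + crossprod(X, da_c)
    g$Uh <- g$Uh + crossprod(r * hprev, da_c)
    g$bh <- g$bh + colSums(da_c)
    dtemp <- tcrossprod(da_c, params$Uh)
    dr <- dtemp * hprev
    dhprev <- dhprev + dtemp * r
    da_z <- dz * z * (1 - z)
    g$Wz <- g$Wz + crossprod(X, da_z)
    g$Uz <- g$Uz + crossprod(hprev, da_z)
    g$bz <- g$bz + colSums(da_z)
    dhprev <- dhprev + tcrossprod(da_z, params$Uz)
    da_r <- dr * r * (1 - r)
    g$Wr <- g$Wr + crossprod(X, da_r)
    g$Ur <- g$Ur + crossprod(hprev, da_r)
    g$br <- g$br + colSums(da_r)
    dhprev <- dhprev + tcrossprod(da_r, params$Ur)
    dX <- tcrossprod(da_c, params$Wh) + tcrossprod(da_z, params$Wz) +
      tcrossprod(da_r, params$Wr)
    dE_rows[[t]] <- dX
    dE_ids[[t]] <- ids[, t]
    dcarry <- dhprev
  }
  dX_all <- do.call(rbind, dE_rows)
  id_all <- unlist(dE_ids)
  agg <- rowsum(dX_all, id_all)
  dE <- matrix(0, nrow(E), ncol(E))
  dE[as.integer(rownames(agg)), ] <- agg
  list(grads = g, dE = dE)
}

#' Scaled dot-product attention pooling
#'
#' `score_t = (q . x_t) / sqrt(d)`, `alpha = softmax(score)` over
#' positions, output `sum_t alpha_t x_t`. Masked (PAD) positions receive
#' weight 0; if every position is masked the weights fall back to uniform.
#'
#' @param H context matrix (positions x d).
#' @param q query vector of length `d`.
#' @param mask optional 0/1 vector over positions (1 = attend).
#' @return list with `pooled` (length-d vector) and `weights`
#'   (non-negative, summing to 1).
#' @export
attention_pool <- function(H, q, mask = NULL) {
  stopifnot(is.matrix(H), length(q) == ncol(H))
  d <- ncol(H)
  scores <- drop(H %*% q) / sqrt(d)
  if (!is.null(mask) && any(mask > 0)) {
    scores[mask == 0] <- -Inf
  }
  scores <- scores - max(scores)
  e <- exp(scores)
  alpha <- e / sum(e)
  list(pooled = drop(crossprod(H, alpha)), weights = alpha)
}

# full forward pass over a batch, keeping everything backward needs
clf_forward <- function(params, ids, mask, config) {
  Dh <- config$hidden_dim
  h <- ncol(ids)
  batch <- nrow(ids)
  fwd <- gru_direction_forward(params$fwd, params$E, ids, mask, Dh, reverse = FALSE)
  bwd <- gru_direction_forward(params$bwd, params$E, ids, mask, Dh, reverse = TRUE)
  d <- 2L * Dh
  scores <- matrix(0, batch, h)
  for (t in seq_len(h)) {
    Ht <- cbind(fwd$Hs[[t]], bwd$Hs[[t]])
    scores[, t] <- drop(Ht %*% params$q) / sqrt(d)
  }
  masked <- scores
  masked[mask == 0] <- -Inf
  none <- rowSums(mask) == 0
  masked[none, ] <- 0 # all-PAD row: uniform attention
  alpha <- softmax_rows(masked)
  pooled <- matrix(0, batch, d)
  for (t in seq_len(h)) {
    Ht <- cbind(fwd$Hs[[t]], bwd$Hs[[t]])
    pooled <- pooled + alpha[, t] * Ht
  }
  logits <- add_bias(pooled %*% params$Wo, params$bo)
  probs <- softmax_rows(logits)
  list(fwd = fwd, bwd = bwd, alpha = alpha, pooled = pooled, probs = probs)
}

# mean cross-entropy of labels y (0/1) under the forward pass
clf_loss <- function(params, ids, mask, y, config) {
  fw <- clf_forward(params, ids, mask, config)
  -mean(log(fw$probs[cbind(seq_along(y), y + 1L)] + 1e-12))
}

clf_backward <- function(params, ids, mask, y, config, fw) {
  batch <- nrow(ids)
  Dh <- config$hidden_dim
  d <- 2L * Dh
  h <- ncol(ids)
  Y <- matrix(0, batch, 2L)
  Y[cbind(seq_len(batch), y + 1L)] <- 1
  dlogits <- (fw$probs - Y) / batch
  gWo <- crossprod(fw$pooled, dlogits)
  gbo <- colSums(dlogits)
  dpooled <- tcrossprod(dlogits, params$Wo)
  alpha <- fw$alpha
  dalpha <- matrix(0, batch, h)
  Hts <- vector("list", h)
  for (t in seq_len(h)) {
    Hts[[t]] <- cbind(fw$fwd$Hs[[t]], fw$bwd$Hs[[t]])
    dalpha[, t] <- rowSums(dpooled * Hts[[t]])
  }
  ds <- alpha * (dalpha - rowSums(alpha * dalpha))
  gq <- numeric(d)
  dHf <- vector("list", h)
  dHb <- vector("list", h)
  for (t in seq_len(h)) {
    dHt <- alpha[, t] * dpooled + (ds[, t] / sqrt(d)) %o% params$q
    gq <- gq + colSums(Hts[[t]] * ds[, t]) / sqrt(d)
    dHf[[t]] <- dHt[, seq_len(Dh), drop = FALSE]
    dHb[[t]] <- dHt[, Dh + seq_len(Dh), drop = FALSE]
  }
  bf <- gru_direction_backward(params$fwd, params$E, ids, mask, dHf, fw$fwd$cache,
                               reverse = FALSE)
  bb <- gru_direction_backward(params$bwd, params$E, ids, mask, dHb, fw$bwd$cache,
                               reverse = TRUE)
  list(E = bf$dE + bb$dE, fwd = bf$grads, bwd = bb$grads,
       q = gq, Wo = gWo, bo = gbo)
}

#' Encode a token sequence into a context matrix
#'
#' Runs the forward and backward GRU passes and concatenates their hidden
#' states per position: row `t` is `[h_forward_t, h_backward_t]`. The
#' forward half of position `t` depends only on tokens at or before `t`,
#' the backward half only on tokens at or after `t`.
#'
#' @param seq a [token_sequence()] of exactly `config$h` tokens.
#' @param model a [init_classifier()] / [train_classifier()] model.
#' @return matrix of shape `h x 2*hidden_dim`.
#' @export
encode <- function(seq, model) {
  stopifnot(inherits(model, "classifier_model"))
  config <- model$config
  b <- seqs_to_batch(list(seq), config$vocabulary, config$h)
  fwd <- gru_direction_forward(model$params$fwd, model$params$E, b$ids, b$mask,
                               config$hidden_dim, reverse = FALSE)
  bwd <- gru_direction_forward(model$params$bwd, model$params$E, b$ids, b$mask,
                               config$hidden_dim, reverse = TRUE)
  t(vapply(seq_len(config$h), function(t) c(fwd$Hs[[t]][1L, ], bwd$Hs[[t]][1L, ]),
           numeric(2L * config$hidden_dim)))
}

#' Treatment-focus probability of a document
#'
#' Deterministic evaluation-mode forward pass; returns `v1`, the softmax
#' probability of the treatment class.
#'
#' @param model a `classifier_model`.
#' @param doc a [document()] (or an already preprocessed
#'   [token_sequence()]).
#' @return numeric `v1` in `[0, 1]`.
#' @export
predict_treatment <- function(model, doc) {
  classifier_scores(model, list(doc))[[1L]]
}

#' Treatment probabilities for many documents
#'
#' @param model a `classifier_model`.
#' @param docs list of [document()]s or classifier [token_sequence()]s.
#' @return numeric vector of `v1` values, named by document ID where
#'   available.
#' @export
classifier_scores <- function(model, docs) {
  stopifnot(inherits(model, "classifier_model"))
  config <- model$config
  seqs <- lapply(docs, function(d) {
    if (inherits(d, "token_sequence")) d else preprocess_for_classifier(d, config$h)
  })
  out <- numeric(length(seqs))
  bs <- max(1L, config$batch_size)
  for (start in seq(1L, length(seqs), by = bs)) {
    sel <- start:min(start + bs - 1L, length(seqs))
    b <- seqs_to_batch(seqs[sel], config$vocabulary, config$h)
    fw <- clf_forward(model$params, b$ids, b$mask, config)
    out[sel] <- fw$probs[, 2L]
  }
  names(out) <- vapply(seqs, `[[`, character(1), "origin_doc_id")
  out
}

#' Train the treatment-focus classifier
#'
#' Splits the labeled corpus 8:1:1 (train/dev/test) by a seeded shuffle,
#' optimizes cross-entropy with Adam, and stops early when dev loss fails
#' to improve for `patience` epochs, returning the best-dev parameters.
#'
#' @param docs list of [document()]s.
#' @param labels integer vector of 0/1 treatment-focus labels (both classes
#'   must be present).
#' @param config a [classifier_config()].
#' @param quiet suppress per-epoch messages.
#' @return a `classifier_model` with the fitted parameters; the split and
#'   per-epoch history are attached as `$split` and `$history`.
#' @export
train_classifier <- function(docs, labels, config = classifier_config(), quiet = TRUE) {
  labels <- as.integer(labels)
  stopifnot(length(docs) == length(labels), all(labels %in% 0:1))
  if (length(unique(labels)) < 2L) stop("training data must contain both classes")
  seqs <- lapply(docs, preprocess_for_classifier, h = config$h)
  split <- split_811(length(docs), config$seed)
  if (is.null(config$vocabulary)) {
    config$vocabulary <- build_vocabulary(lapply(seqs[split$train], `[[`, "tokens"))
  }
  model <- init_classifier(config)
  params <- model$params
  opt <- adam_init(params)
  dev_b <- seqs_to_batch(seqs[split$dev], config$vocabulary, config$h)
  dev_y <- labels[split$dev]
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(), dev_loss = numeric())
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    order_i <- with_seed(config$seed + epoch, sample(split$train))
    ep_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, length(order_i), by = config$batch_size)) {
      sel <- order_i[start:min(start + config$batch_size - 1L, length(order_i))]
      b <- seqs_to_batch(seqs[sel], config$vocabulary, config$h)
      y <- labels[sel]
      fw <- clf_forward(params, b$ids, b$mask, config)
      loss <- -mean(log(fw$probs[cbind(seq_along(y), y + 1L)] + 1e-12))
      grads <- clf_backward(params, b$ids, b$mask, y, config, fw)
      upd <- adam_step(params, grads, opt, config$learning_rate)
      params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + loss
      n_batches <- n_batches + 1L
    }
    dev_loss <- clf_loss(params, dev_b$ids, dev_b$mask, dev_y, config)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n_batches,
                                         dev_loss = dev_loss))
    if (!quiet) {
      message(sprintf("epoch %d: train %.4f dev %.4f", epoch,
                      ep_loss / n_batches, dev_loss))
    }
    if (dev_loss < best$loss - 1e-6) {
      best <- list(loss = dev_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(
    list(config = config, params = best$params, split = split,
         history = history, best_epoch = best$epoch),
    class = "classifier_model"
  )
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf(
    "<classifier_model> h=%d, emb=%d, hidden=%d, vocab=%d%s\n",
    x$config$h, x$config$embedding_dim, x$config$hidden_dim,
    length(x$config$vocabulary),
    if (!is.null(x$best_epoch)) sprintf(", best epoch %d", x$best_epoch) else ""
  ))
  invisible(x)
}
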