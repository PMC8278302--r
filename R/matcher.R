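#' Configuration for the disease relevance matcher
#'
#' Hyperparameters of the MatchPyramid matcher. Defaults follow the
#' reference configuration: query window 30, document window 200,
#' 200-dimensional embeddings, 400 convolution kernels of size 5, Adagrad
#' at learning rate 0.001 with batches of 64. `pool_grid` is the dynamic
#' pooling target (rows x cols) applied after each of the two convolution
#' stages. Much smaller widths are appropriate for synthetic corpora.
#'
#' @param query_max_length,doc_max_length sequence windows.
#' @param embedding_dim embedding width.
#' @param num_kernels kernels per convolution stage.
#' @param kernel_size odd kernel side length.
#' @param learning_rate Adagrad learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed.
#' @param pool_grid integer `c(rows, cols)`; must divide into positive
#'   cells of the input (`rows <= query_max_length`,
#'   `cols <= doc_max_length`).
#' @param mlp_hidden width of the tanh hidden layer of the output
#'   perceptron.
#' @param train_embeddings update the embedding table during training
#'   (default `FALSE`: the matching matrix stays stationary, which keeps
#'   the interaction signal stable while the convolution stages learn).
#' @param max_epochs,patience early-stopping controls (dev squared error).
#' @param vocabulary optional named integer vector token -> index.
#' @return object of class `matcher_config`.
#' @export
matcher_config <- function(query_max_length = 30L, doc_max_length = 200L,
                           embedding_dim = 200L, num_kernels = 400L,
                           kernel_size = 5L, learning_rate = 0.001,
                           batch_size = 64L, seed = 1L,
                           pool_grid = c(5L, 10L), mlp_hidden = 64L,
                           train_embeddings = FALSE,
                           max_epochs = 30L, patience = 3L, vocabulary = NULL) {
  stopifnot(query_max_length >= 1L, doc_max_length >= 1L, embedding_dim >= 1L,
            num_kernels >= 1L, kernel_size >= 1L, kernel_size %% 2L == 1L,
            length(pool_grid) == 2L, all(pool_grid >= 1L),
            pool_grid[1L] <= query_max_length, pool_grid[2L] <= doc_max_length)
  structure(
    list(query_max_length = as.integer(query_max_length),
         doc_max_length = as.integer(doc_max_length),
         embedding_dim = as.integer(embedding_dim),
         num_kernels = as.integer(num_kernels),
         kernel_size = as.integer(kernel_size),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         seed = as.integer(seed), pool_grid = as.integer(pool_grid),
         mlp_hidden = as.integer(mlp_hidden),
         train_embeddings = isTRUE(train_embeddings),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         vocabulary = vocabulary),
    class = "matcher_config"
  )
}

# pad/truncate a matcher token vector to exactly len tokens
pad_tokens <- function(tokens, len) {
  if (length(tokens) >= len) return(tokens[seq_len(len)])
  c(tokens, rep(TOKEN_PAD, len - length(tokens)))
}

#' Build a query-document matching matrix
#'
#' `S[i, j]` is the dot product of the i-th query and j-th document token
#' embedding; rows/columns at PAD positions are zero.
#'
#' @param query_seq,doc_seq [token_sequence()]s, already matcher
#'   preprocessed; they are padded/truncated here to the embedding
#'   windows.
#' @param embeddings numeric matrix with one row per token (rownames are
#'   tokens); must contain rows `PAD` and `UNK`.
#' @param query_len,doc_len target windows (default: the sequence lengths).
#' @return matrix of shape `query_len x doc_len`.
#' @export
build_matching_matrix <- function(query_seq, doc_seq, embeddings,
                                  query_len = NULL, doc_len = NULL) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  qt <- if (inherits(query_seq, "token_sequence")) query_seq$tokens else query_seq
  dt <- if (inherits(doc_seq, "token_sequence")) doc_seq$tokens else doc_seq
  qt <- pad_tokens(qt, query_len %||% length(qt))
  dt <- pad_tokens(dt, doc_len %||% length(dt))
  lookup <- function(tok) {
    i <- match(tok, rownames(embeddings))
    i[is.na(i)] <- match(TOKEN_UNK, rownames(embeddings))
    if (anyNA(i)) stop("embeddings lack an UNK row")
    embeddings[i, , drop = FALSE]
  }
  Q <- lookup(qt)
  D <- lookup(dt)
  S <- tcrossprod(Q, D)
  S[qt == TOKEN_PAD, ] <- 0
  S[, dt == TOKEN_PAD] <- 0
  S
}

# zero-padded shift: out[i, j] = X[i + dr, j + dc] (0 outside)
shift_mat <- function(X, dr, dc) {
  r <- nrow(X); c <- ncol(X)
  out <- matrix(0, r, c)
  ri <- max(1L, 1L - dr):min(r, r - dr)
  ci <- max(1L, 1L - dc):min(c, c - dc)
  if (length(ri) > 0L && length(ci) > 0L && ri[1L] <= ri[length(ri)] &&
      ci[1L] <= ci[length(ci)]) {
    out[ri, ci] <- X[ri + dr, ci + dc, drop = FALSE]
  }
  out
}

# same-size 2D convolution; X: (r, c, Cin) array or matrix, W: (k, k, Cin, Cout)
conv2d_same <- function(X, W, b) {
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L))
  k <- dim(W)[1L]
  pad <- (k - 1L) %/% 2L
  r <- dim(X)[1L]; cc <- dim(X)[2L]
  Cin <- dim(X)[3L]; Cout <- dim(W)[4L]
  out <- array(rep(b, each = r * cc), c(r, cc, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(0, r, cc)
    for (ci in seq_len(Cin)) {
      Xi <- X[, , ci]
      for (a in seq_len(k)) {
        for (bb in seq_len(k)) {
          w <- W[a, bb, ci, co]
          if (w != 0) acc <- acc + w * shift_mat(Xi, a - pad - 1L, bb - pad - 1L)
        }
      }
    }
    out[, , co] <- out[, , co] + acc
  }
  out
}

conv2d_same_backward <- function(X, W, dOut) {
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L))
  k <- dim(W)[1L]
  pad <- (k - 1L) %/% 2L
  Cin <- dim(X)[3L]; Cout <- dim(W)[4L]
  dW <- array(0, dim(W))
  db <- numeric(Cout)
  dX <- array(0, dim(X))
  for (co in seq_len(Cout)) {
    dO <- dOut[, , co]
    db[co] <- sum(dO)
    for (ci in seq_len(Cin)) {
      Xi <- X[, , ci]
      for (a in seq_len(k)) {
        for (bb in seq_len(k)) {
          sh <- shift_mat(Xi, a - pad - 1L, bb - pad - 1L)
          dW[a, bb, ci, co] <- sum(sh * dO)
          w <- W[a, bb, ci, co]
          if (w != 0) {
            dX[, , ci] <- dX[, , ci] + w * shift_mat(dO, -(a - pad - 1L), -(bb - pad - 1L))
          }
        }
      }
    }
  }
  list(dW = dW, db = db, dX = dX)
}

pool_bounds <- function(n, p) floor(seq(0, n, length.out = p + 1L))

# dynamic max pooling of (r, c, C) to (pr, pc, C); remembers argmax cells
dynpool <- function(X, pr, pc) {
  r <- dim(X)[1L]; cc <- dim(X)[2L]; C <- dim(X)[3L]
  rb <- pool_bounds(r, pr)
  cb <- pool_bounds(cc, pc)
  out <- array(0, c(pr, pc, C))
  arg <- array(0L, c(pr, pc, C, 2L))
  for (ch in seq_len(C)) {
    Xi <- X[, , ch]
    for (i in seq_len(pr)) {
      rows <- (rb[i] + 1L):rb[i + 1L]
      for (j in seq_len(pc)) {
        cols <- (cb[j] + 1L):cb[j + 1L]
        block <- Xi[rows, cols, drop = FALSE]
        m <- which.max(block) # first max: deterministic tie-break
        out[i, j, ch] <- block[m]
        arg[i, j, ch, ] <- c(rows[(m - 1L) %% length(rows) + 1L],
                             cols[(m - 1L) %/% length(rows) + 1L])
      }
    }
  }
  list(out = out, arg = arg)
}

dynpool_backward <- function(dOut, arg, dim_in) {
  dX <- array(0, dim_in)
  pr <- dim(dOut)[1L]; pc <- dim(dOut)[2L]; C <- dim(dOut)[3L]
  for (ch in seq_len(C)) {
    for (i in seq_len(pr)) {
      for (j in seq_len(pc)) {
        a <- arg[i, j, ch, ]
        dX[a[1L], a[2L], ch] <- dX[a[1L], a[2L], ch] + dOut[i, j, ch]
      }
    }
  }
  dX
}

#' Initialize a matcher model
#'
#' @param config a [matcher_config()] whose `vocabulary` is set.
#' @return object of class `matcher_model` holding the embedding table,
#'   two convolution stages and the output perceptron.
#' @export
init_matcher <- function(config) {
  stopifnot(inherits(config, "matcher_config"), !is.null(config$vocabulary))
  V <- length(config$vocabulary)
  K <- config$num_kernels
  k <- config$kernel_size
  nf <- K * prod(config$pool_grid)
  # embedding rows are unit-normalized so a token self-match is exactly 1
  # while cross-token products stay near zero (sd ~ 1/sqrt(dim)): the
  # matching matrix then carries clean contrast from the first epoch
  params <- with_seed(config$seed, {
    E0 <- runif_mat(V, config$embedding_dim, 0.5)
    E0 <- E0 / sqrt(rowSums(E0^2))
    list(
      E = E0,
      W1 = array(runif(k * k * K, -0.3, 0.3), c(k, k, 1L, K)),
      b1 = numeric(K),
      W2 = array(runif(k * k * K * K, -glorot_r(k * k * K, K), glorot_r(k * k * K, K)),
                 c(k, k, K, K)),
      b2 = numeric(K),
      W3 = runif_mat(nf, config$mlp_hidden, glorot_r(nf, config$mlp_hidden)),
      b3 = numeric(config$mlp_hidden),
      w4 = runif(config$mlp_hidden, -glorot_r(config$mlp_hidden, 1), glorot_r(config$mlp_hidden, 1)),
      b4 = 0
    )
  })
  structure(list(config = config, params = params), class = "matcher_model")
}

#' @export
print.matcher_model <- function(x, ...) {
  cat(sprintf(
    "<matcher_model> %dx%d window, %d kernels (%dx%d), pool %dx%d, vocab %d\n",
    x$config$query_max_length, x$config$doc_max_length, x$config$num_kernels,
    x$config$kernel_size, x$config$kernel_size, x$config$pool_grid[1L],
    x$config$pool_grid[2L], length(x$config$vocabulary)
  ))
  invisible(x)
}

mp_forward_cache <- function(params, S, config) {
  pr <- config$pool_grid[1L]; pc <- config$pool_grid[2L]
  c1 <- conv2d_same(S, params$W1, params$b1)
  r1 <- pmax(c1, 0)
  p1 <- dynpool(r1, pr, pc)
  c2 <- conv2d_same(p1$out, params$W2, params$b2)
  r2 <- pmax(c2, 0)
  p2 <- dynpool(r2, pr, pc)
  flat <- as.numeric(p2$out)
  z <- tanh(drop(flat %*% params$W3) + params$b3)
  v2 <- sum(z * params$w4) + params$b4
  list(S = S, c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
       flat = flat, z = z, v2 = v2)
}

mp_backward <- function(params, cache, dv2, config) {
  dz <- params$w4 * dv2
  da <- dz * (1 - cache$z^2)
  g <- list(
    w4 = cache$z * dv2, b4 = dv2,
    W3 = cache$flat %o% da, b3 = da
  )
  dflat <- drop(params$W3 %*% da)
  dP2 <- array(dflat, dim(cache$p2$out))
  dR2 <- dynpool_backward(dP2, cache$p2$arg, dim(cache$r2))
  dC2 <- dR2 * (cache$c2 > 0)
  bk2 <- conv2d_same_backward(cache$p1$out, params$W2, dC2)
  g$W2 <- bk2$dW; g$b2 <- bk2$db
  dR1 <- dynpool_backward(bk2$dX, cache$p1$arg, dim(cache$r1))
  dC1 <- dR1 * (cache$c1 > 0)
  bk1 <- conv2d_same_backward(array(cache$S, c(dim(cache$S), 1L)), params$W1, dC1)
  g$W1 <- bk1$dW; g$b1 <- bk1$db
  g$dS <- bk1$dX[, , 1L]
  g
}

#' Matcher forward pass on a matching matrix
#'
#' Two stacked same-padding convolution stages (ReLU), each followed by
#' dynamic max pooling to the configured grid, then a two-layer perceptron
#' with tanh hidden layer and a linear scalar output: `v2`, the disease
#' relevance score (positive means disease-relevant). Deterministic in
#' evaluation mode.
#'
#' @param model a `matcher_model` (or a bare parameter list plus `config`).
#' @param S matching matrix (query window x document window).
#' @return finite numeric scalar `v2`.
#' @export
matcher_forward <- function(model, S) {
  stopifnot(inherits(model, "matcher_model"))
  mp_forward_cache(model$params, S, model$config)$v2
}

#' Map a disease annotation to a training grade
#'
#' Exact disease matches are grade 2, broader or narrower disease matches
#' grade 1, non-disease matches grade 0.
#'
#' @param annotation one of `"exact"`, `"more specific"`, `"more general"`,
#'   `"not disease"`.
#' @return integer grade in `{0, 1, 2}`.
#' @export
label_disease_grade <- function(annotation) {
  switch(match.arg(annotation, c("exact", "more specific", "more general", "not disease")),
         "exact" = 2L,
         "more specific" = 1L,
         "more general" = 1L,
         "not disease" = 0L)
}

matcher_pair_ids <- function(pair, vocab, config) {
  qt <- pad_tokens(pair$query$tokens, config$query_max_length)
  dt <- pad_tokens(pair$doc$tokens, config$doc_max_length)
  list(
    qid = tokens_to_ids(qt, vocab), qpad = qt == TOKEN_PAD,
    did = tokens_to_ids(dt, vocab), dpad = dt == TOKEN_PAD
  )
}

mp_matrix_from_ids <- function(E, p) {
  S <- tcrossprod(E[p$qid, , drop = FALSE], E[p$did, , drop = FALSE])
  S[p$qpad, ] <- 0
  S[, p$dpad] <- 0
  S
}

#' Score a query-document pair
#'
#' @param model a trained `matcher_model`.
#' @param query_seq,doc_seq matcher-preprocessed [token_sequence()]s.
#' @return numeric `v2`.
#' @export
matcher_score <- function(model, query_seq, doc_seq) {
  stopifnot(inherits(model, "matcher_model"))
  p <- matcher_pair_ids(list(query = query_seq, doc = doc_seq),
                        model$config$vocabulary, model$config)
  matcher_forward(model, mp_matrix_from_ids(model$params$E, p))
}

#' Train the relevance matcher
#'
#' Regression on targets `grade - 1` (so `v2` crosses zero between
#' non-relevant and relevant) with squared-error loss, Adagrad updates, a
#' seeded 8:1:1 split and early stopping on dev loss; the best-dev
#' parameters are returned.
#'
#' @param pairs list of `list(query =, doc =, grade =)` with
#'   matcher-preprocessed [token_sequence()]s and grades in `{0, 1, 2}`.
#' @param config a [matcher_config()].
#' @param quiet suppress per-epoch messages.
#' @return a `matcher_model` with `$split` and `$history` attached.
#' @export
train_matcher <- function(pairs, config = matcher_config(), quiet = TRUE) {
  grades <- vapply(pairs, function(p) as.integer(p$grade), integer(1))
  stopifnot(all(grades %in% 0:2))
  if (length(unique(grades)) < 2L) stop("training pairs must span at least two grades")
  split <- split_811(length(pairs), config$seed)
  if (is.null(config$vocabulary)) {
    config$vocabulary <- build_vocabulary(
      lapply(pairs[split$train], function(p) c(p$query$tokens, p$doc$tokens))
    )
  }
  model <- init_matcher(config)
  params <- model$params
  ids <- lapply(pairs, matcher_pair_ids, vocab = config$vocabulary, config = config)
  targets <- grades - 1L
  opt <- adagrad_init(params)
  dev_loss_of <- function(params) {
    mean(vapply(split$dev, function(i) {
      S <- mp_matrix_from_ids(params$E, ids[[i]])
      0.5 * (mp_forward_cache(params, S, config)$v2 - targets[i])^2
    }, numeric(1)))
  }
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(), dev_loss = numeric())
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    order_i <- with_seed(config$seed + epoch, sample(split$train))
    ep_loss <- 0
    for (start in seq(1L, length(order_i), by = config$batch_size)) {
      sel <- order_i[start:min(start + config$batch_size - 1L, length(order_i))]
      grads <- NULL
      batch_loss <- 0
      dE <- if (config$train_embeddings) params$E * 0 else NULL
      for (i in sel) {
        p <- ids[[i]]
        S <- mp_matrix_from_ids(params$E, p)
        cache <- mp_forward_cache(params, S, config)
        err <- cache$v2 - targets[i]
        batch_loss <- batch_loss + 0.5 * err^2
        g <- mp_backward(params, cache, err / length(sel), config)
        if (config$train_embeddings) {
          dS <- g$dS
          dS[p$qpad, ] <- 0
          dS[, p$dpad] <- 0
          Qe <- params$E[p$qid, , drop = FALSE]
          De <- params$E[p$did, , drop = FALSE]
          dQ <- dS %*% De
          dD <- crossprod(dS, Qe)
          aggq <- rowsum(dQ, p$qid)
          dE[as.integer(rownames(aggq)), ] <- dE[as.integer(rownames(aggq)), ] + aggq
          aggd <- rowsum(dD, p$did)
          dE[as.integer(rownames(aggd)), ] <- dE[as.integer(rownames(aggd)), ] + aggd
        }
        g$dS <- NULL
        g$E <- NULL
        grads <- if (is.null(grads)) g else nn_map2(grads, g, `+`)
      }
      if (config$train_embeddings) grads$E <- dE else grads$E <- params$E * 0
      grads <- grads[names(params)]
      upd <- adagrad_step(params, grads, opt, config$learning_rate)
      params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + batch_loss / length(sel)
    }
    dloss <- dev_loss_of(params)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         dev_loss = dloss))
    if (!quiet) message(sprintf("epoch %d: dev %.4f", epoch, dloss))
    if (dloss < best$loss - 1e-6) {
      best <- list(loss = dloss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(
    list(config = config, params = best$params, split = split,
         history = history, best_epoch = best$epoch),
    class = "matcher_model"
  )
}
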