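# Shared numeric helpers for the hand-rolled neural models.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# add a bias vector to every row
add_bias <- function(m, b) t(t(m) + b)

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

runif_mat <- function(nr, nc, r) matrix(runif(nr * nc, -r, r), nr, nc)

glorot_r <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

# recursive map over two identically shaped nested parameter lists
nn_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(nn_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

nn_map <- function(a, f) {
  if (is.list(a)) return(lapply(a, nn_map, f = f))
  f(a)
}

nn_zeros_like <- function(p) nn_map(p, function(x) x * 0)

# Adam step; state holds first/second moments and the step counter
adam_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nn_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nn_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- nn_map2(
    params,
    nn_map2(state$m, state$v, function(m, v) (m / bc1) / (sqrt(v / bc2) + eps)),
    function(p, upd) p - lr * upd
  )
  list(params = params, state = state)
}

# Adagrad step; state accumulates squared gradients
adagrad_init <- function(params) list(g2 = nn_zeros_like(params))

adagrad_step <- function(params, grads, state, lr, eps = 1e-8) {
  state$g2 <- nn_map2(state$g2, grads, function(a, g) a + g^2)
  params <- nn_map2(
    params,
    nn_map2(grads, state$g2, function(g, a) g / (sqrt(a) + eps)),
    function(p, upd) p - lr * upd
  )
  list(params = params, state = state)
}

# seeded 8:1:1 shuffle split of n items into train/dev/test index vectors
split_811 <- function(n, seed) {
  idx <- with_seed(seed, sample.int(n))
  n_train <- floor(0.8 * n)
  n_dev <- floor(0.1 * n)
  list(
    train = idx[seq_len(n_train)],
    dev = idx[n_train + seq_len(n_dev)],
    test = idx[(n_train + n_dev + 1L):n]
  )
}
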