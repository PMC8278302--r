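# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately written as plain scalar loops / direct formula
# evaluations, sharing no code with the package internals they check.

# --- BM25 -------------------------------------------------------------------

# brute-force BM25 over a list of token vectors
oracle_bm25 <- function(token_lists, query_tokens, doc_i, k1 = 1.2, b = 0.75) {
  N <- length(token_lists)
  lens <- vapply(token_lists, length, numeric(1))
  avg <- mean(lens)
  score <- 0
  for (t in unique(query_tokens)) {
    df <- sum(vapply(token_lists, function(x) t %in% x, logical(1)))
    tf <- sum(token_lists[[doc_i]] == t)
    if (tf == 0) next
    idf <- log(1 + (N - df + 0.5) / (df + 0.5))
    score <- score + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * lens[doc_i] / avg))
  }
  score
}

# exhaustive boosted search over every document; returns ordered data frame
oracle_search <- function(token_lists, doc_ids, query_fields, boosts,
                          limit = 1000L, k1 = 1.2, b = 0.75) {
  scores <- vapply(seq_along(token_lists), function(i) {
    boosts[["disease"]] * oracle_bm25(token_lists, query_fields$disease, i, k1, b) +
      boosts[["gene"]] * oracle_bm25(token_lists, query_fields$gene, i, k1, b) +
      boosts[["treatment"]] * oracle_bm25(token_lists, query_fields$treatment, i, k1, b) +
      boosts[["demographic"]] * oracle_bm25(token_lists, query_fields$demographic, i, k1, b)
  }, numeric(1))
  keep <- which(scores > 0)
  df <- data.frame(doc_id = doc_ids[keep], score = scores[keep],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$doc_id), , drop = FALSE]
  head(df, limit)
}

# random tiny corpus of pm_documents over a small shared vocabulary
random_corpus <- function(n_docs, vocab, min_len = 3L, max_len = 12L) {
  lapply(seq_len(n_docs), function(i) {
    toks <- sample(vocab, sample(min_len:max_len, 1L), replace = TRUE)
    document(sprintf("d%03d", i),
             title = paste(toks[1:2], collapse = " "),
             abstract = paste(toks[-(1:2)], collapse = " "))
  })
}

doc_tokens <- function(doc) {
  tokenize_text(c(doc$title, doc$abstract, doc$chemical_terms,
                  doc$mesh_terms, doc$other_abstract))
}

# --- GRU --------------------------------------------------------------------

# scalar-loop evaluation of the GRU update equations
oracle_gru <- function(v, h_prev, p) {
  Dh <- length(h_prev)
  sig <- function(x) 1 / (1 + exp(-x))
  z <- r <- cand <- h <- numeric(Dh)
  for (j in seq_len(Dh)) {
    az <- p$bz[j]; ar <- p$br[j]
    for (i in seq_along(v)) { az <- az + v[i] * p$Wz[i, j]; ar <- ar + v[i] * p$Wr[i, j] }
    for (i in seq_len(Dh)) { az <- az + h_prev[i] * p$Uz[i, j]; ar <- ar + h_prev[i] * p$Ur[i, j] }
    z[j] <- sig(az); r[j] <- sig(ar)
  }
  for (j in seq_len(Dh)) {
    ah <- p$bh[j]
    for (i in seq_along(v)) ah <- ah + v[i] * p$Wh[i, j]
    for (i in seq_len(Dh)) ah <- ah + (r[i] * h_prev[i]) * p$Uh[i, j]
    cand[j] <- tanh(ah)
  }
  for (j in seq_len(Dh)) h[j] <- (1 - z[j]) * h_prev[j] + z[j] * cand[j]
  h
}

random_gru_params <- function(De, Dh) {
  m <- function(a, b) matrix(rnorm(a * b, sd = 0.5), a, b)
  list(Wz = m(De, Dh), Uz = m(Dh, Dh), bz = rnorm(Dh, sd = 0.5),
       Wr = m(De, Dh), Ur = m(Dh, Dh), br = rnorm(Dh, sd = 0.5),
       Wh = m(De, Dh), Uh = m(Dh, Dh), bh = rnorm(Dh, sd = 0.5))
}

# --- MatchPyramid -----------------------------------------------------------

# nested-loop convolution (same zero padding) + max pooling + MLP forward
oracle_matcher_forward <- function(S, params, pool_grid) {
  conv <- function(X, W, b) { # X: r x c x Cin, W: k x k x Cin x Cout
    k <- dim(W)[1L]; pad <- (k - 1L) %/% 2L
    r <- dim(X)[1L]; cc <- dim(X)[2L]
    out <- array(0, c(r, cc, dim(W)[4L]))
    for (co in seq_len(dim(W)[4L])) {
      for (i in seq_len(r)) for (j in seq_len(cc)) {
        acc <- b[co]
        for (ci in seq_len(dim(X)[3L])) {
          for (a in seq_len(k)) for (bb in seq_len(k)) {
            ii <- i + a - pad - 1L; jj <- j + bb - pad - 1L
            if (ii >= 1L && ii <= r && jj >= 1L && jj <= cc) {
              acc <- acc + W[a, bb, ci, co] * X[ii, jj, ci]
            }
          }
        }
        out[i, j, co] <- acc
      }
    }
    out
  }
  pool <- function(X, pr, pc) {
    rb <- floor(seq(0, dim(X)[1L], length.out = pr + 1L))
    cb <- floor(seq(0, dim(X)[2L], length.out = pc + 1L))
    out <- array(0, c(pr, pc, dim(X)[3L]))
    for (ch in seq_len(dim(X)[3L])) {
      for (i in seq_len(pr)) for (j in seq_len(pc)) {
        out[i, j, ch] <- max(X[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L], ch])
      }
    }
    out
  }
  x <- conv(array(S, c(dim(S), 1L)), params$W1, params$b1)
  x <- pool(pmax(x, 0), pool_grid[1L], pool_grid[2L])
  x <- conv(x, params$W2, params$b2)
  x <- pool(pmax(x, 0), pool_grid[1L], pool_grid[2L])
  z <- tanh(as.numeric(x) %*% params$W3 + params$b3)
  sum(z * params$w4) + params$b4
}

# --- fixtures ---------------------------------------------------------------

toy_kb <- function() {
  knowledge_base(list(
    entity_record("D008545", "melanoma", "disease",
                  synonyms = c("malignant melanoma"),
                  hypernyms = c("skin neoplasm")),
    entity_record("D001943", "breast carcinoma", "disease",
                  synonyms = c("breast cancer", "mammary carcinoma"),
                  hypernyms = c("neoplasm")),
    entity_record("G000673", "BRAF", "gene",
                  synonyms = c("b-raf proto-oncogene"),
                  acronyms = c("braf1"))
  ))
}

worked_run_path <- function() {
  system.file("extdata", "worked_example_run.txt", package = "pmrank")
}

worked_qrels_path <- function() {
  system.file("extdata", "worked_example_qrels.txt", package = "pmrank")
}

small_bundle <- function(seed = 7L, n_docs = 400L, n_topics = 4L) {
  generate_bundle(generator_config(
    seed = seed, n_docs = n_docs, n_topics = n_topics, vocab_size = 500L,
    n_diseases = 12L, relevant_docs_per_topic = 15L,
    distractors_per_topic = 8L, hypernym_docs_per_topic = 8L
  ))
}
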