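make_query <- function(disease = character(), gene = character(),
                       treatment = character(), demographic = character(),
                       topic_id = "t1") {
  structure(
    list(topic_id = topic_id,
         disease_terms = data.frame(term = disease,
                                    source = rep("original", length(disease)),
                                    stringsAsFactors = FALSE),
         gene_terms = data.frame(term = gene,
                                 source = rep("original", length(gene)),
                                 stringsAsFactors = FALSE),
         treatment_terms = treatment, demographic_terms = demographic),
    class = "expanded_query"
  )
}

test_that("index construction satisfies its invariants on tiny corpora", {
  docs <- list(document("a", "cancer"), document("b", "therapy"),
               document("c", "gene"))
  idx <- build_index(docs)
  expect_identical(idx$N, 3L)
  expect_identical(idx$fields$text$avg_len, 1)
  two <- build_index(list(document("a", "cancer cancer")))
  p <- two$fields$text$postings[["cancer"]]
  expect_identical(p$tf, 2)
  expect_error(build_index(list()), "empty")
})

test_that("postings match a brute-force term count on a random corpus", {
  set.seed(5)
  vocab <- c("cancer", "therapy", "braf", "tumor", "cell")
  docs <- random_corpus(12L, vocab)
  idx <- build_index(docs)
  for (term in vocab) {
    counts <- vapply(docs, function(d) sum(doc_tokens(d) == term), numeric(1))
    p <- idx$fields$text$postings[[term]]
    got <- numeric(12L)
    if (!is.null(p)) got[p$pos] <- p$tf
    expect_identical(got, counts)
  }
})

test_that("bm25_score matches the formula oracle and handles absent terms", {
  docs <- list(document("a", "melanoma treatment", "melanoma study"),
               document("b", "lung cancer", "survival analysis"),
               document("c", "kidney disease", "prognosis factor"))
  idx <- build_index(docs)
  expect_identical(bm25_score(idx, "text", "absentterm", "a"), 0)
  toks <- lapply(docs, doc_tokens)
  for (d in c("a", "b", "c")) {
    i <- match(d, c("a", "b", "c"))
    expect_equal(bm25_score(idx, "text", c("melanoma", "survival"), d),
                 oracle_bm25(toks, c("melanoma", "survival"), i),
                 tolerance = 1e-12)
  }
  # one hand-evaluated instance: term in 1 of 3 docs, tf 2, len 4, avg 4
  idf <- log(1 + (3 - 1 + 0.5) / (1 + 0.5))
  expect_equal(bm25_score(idx, "text", "melanoma", "a"),
               idf * 2 * 2.2 / (2 + 1.2 * (1 - 0.75 + 0.75 * 4 / 4)),
               tolerance = 1e-12)
  expect_error(bm25_score(idx, "text", "melanoma", "zzz"), "unknown doc_id")
  expect_error(bm25_score(idx, "nofield", "melanoma", "a"), "unknown index field")
})

test_that("search ranks the only disease-matching document first", {
  docs <- list(document("a", "treatment of fever"),
               document("b", "melanoma cases"),
               document("c", "unrelated text"))
  idx <- build_index(docs)
  rl <- search(idx, make_query(disease = "melanoma", treatment = "treatment"))
  expect_identical(rl$entries$doc_id[1], "b")
  expect_false("c" %in% rl$entries$doc_id) # zero scores dropped
})

test_that("boosting flips the ranking on a crafted corpus", {
  # d1 mentions the disease once in a long document, d2 a treatment keyword
  # in a short one: with equal idf the length normalization puts their
  # score ratio inside (1, 1.5), so only the 1.5 disease boost flips them
  docs <- list(
    document("d1", "melanoma report", "filler filler filler filler"),
    document("d2", "therapy notes", "filler"),
    document("d3", "filler piece", "filler filler"),
    document("d4", "other things", "unrelated")
  )
  idx <- build_index(docs)
  q <- make_query(disease = "melanoma", treatment = "therapy")
  toks <- lapply(docs, doc_tokens)
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  fields <- list(disease = "melanoma", gene = character(),
                 treatment = "therapy", demographic = character())
  for (w in list(boost_weights(), boost_weights(1, 1, 1, 1))) {
    got <- search(idx, q, boosts = w)
    want <- oracle_search(toks, ids, fields,
                          c(disease = w$disease, gene = w$gene,
                            treatment = w$treatment, demographic = w$demographic))
    expect_identical(got$entries$doc_id, want$doc_id)
    expect_equal(got$entries$score, want$score, tolerance = 1e-12)
  }
  flat <- search(idx, q, boosts = boost_weights(1, 1, 1, 1))$entries$doc_id
  boosted <- search(idx, q, boosts = boost_weights())$entries$doc_id
  expect_identical(flat, c("d2", "d1"))
  expect_identical(boosted, c("d1", "d2"))
})

test_that("limit truncates and empty queries error", {
  docs <- lapply(1:5, function(i) document(sprintf("d%d", i), "melanoma"))
  idx <- build_index(docs)
  rl <- search(idx, make_query(disease = "melanoma"), limit = 2L)
  expect_identical(nrow(rl$entries), 2L)
  expect_error(search(idx, make_query()), "empty expanded query")
})

test_that("search equals the exhaustive oracle on random corpora", {
  set.seed(11)
  vocab <- c("melanoma", "braf", "therapy", "surgery", "cell", "tumor",
             "gene", "study", "male")
  for (rep in 1:30) {
    n <- sample(3:20, 1)
    docs <- random_corpus(n, vocab)
    idx <- build_index(docs)
    fields <- list(disease = sample(vocab, 2), gene = sample(vocab, 1),
                   treatment = sample(vocab, 2), demographic = character())
    q <- make_query(fields$disease, fields$gene, fields$treatment)
    w <- boost_weights(runif(1, 0.5, 2), runif(1, 0.5, 2), 1, 1)
    limit <- sample(c(3L, 1000L), 1)
    got <- search(idx, q, boosts = w, limit = limit)
    want <- oracle_search(lapply(docs, doc_tokens),
                          vapply(docs, `[[`, character(1), "doc_id"),
                          fields,
                          c(disease = w$disease, gene = w$gene,
                            treatment = w$treatment, demographic = w$demographic),
                          limit = limit)
    expect_identical(got$entries$doc_id, want$doc_id)
    expect_equal(got$entries$score, want$score, tolerance = 1e-10)
  }
})

test_that("adding a document without query terms preserves the ranking", {
  set.seed(3)
  docs <- random_corpus(8L, c("melanoma", "therapy", "tumor"))
  q <- make_query(disease = "melanoma", treatment = "therapy")
  before <- search(build_index(docs), q)
  docs2 <- c(docs, list(document("zzz", "unrelated filler words")))
  after <- search(build_index(docs2), q)
  expect_identical(after$entries$doc_id, before$entries$doc_id)
})

test_that("scaling all boosts by a constant preserves the ranking", {
  set.seed(9)
  docs <- random_corpus(10L, c("melanoma", "braf", "therapy", "cell"))
  idx <- build_index(docs)
  q <- make_query(disease = "melanoma", gene = "braf", treatment = "therapy")
  a <- search(idx, q, boosts = boost_weights(1.5, 1.5, 1, 1))
  b <- search(idx, q, boosts = boost_weights(4.5, 4.5, 3, 3))
  expect_identical(a$entries$doc_id, b$entries$doc_id)
  expect_equal(b$entries$score, 3 * a$entries$score, tolerance = 1e-12)
})

test_that("search output always satisfies the ranked-list invariants", {
  set.seed(13)
  vocab <- c("melanoma", "therapy", "tumor", "gene", "cell")
  for (rep in 1:20) {
    docs <- random_corpus(sample(2:15, 1), vocab)
    rl <- search(build_index(docs), make_query(disease = sample(vocab, 1),
                                               treatment = sample(vocab, 1)),
                 limit = 7L)
    expect_lte(nrow(rl$entries), 7L)
    expect_false(anyDuplicated(rl$entries$doc_id) > 0)
    if (nrow(rl$entries) > 1) {
      s <- rl$entries$score
      expect_true(all(diff(s) <= 1e-12))
      ties <- which(abs(diff(s)) < 1e-12)
      for (i in ties) {
        expect_true(rl$entries$doc_id[i] < rl$entries$doc_id[i + 1])
      }
    }
  }
})
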