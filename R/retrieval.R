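#' Per-field query boost weights
#'
#' Multiplicative weights for the four query fields. The defaults (disease
#' 1.5, gene 1.5, treatment 1.0, demographic 1.0) boost the two fields that
#' identify the patient case most specifically.
#'
#' @param disease,gene,treatment,demographic positive reals.
#' @return object of class `boost_weights`.
#' @export
boost_weights <- function(disease = 1.5, gene = 1.5, treatment = 1.0, demographic = 1.0) {
  w <- c(disease = disease, gene = gene, treatment = treatment, demographic = demographic)
  stopifnot(all(is.finite(w)), all(w > 0))
  structure(as.list(w), class = "boost_weights")
}

#' Construct a ranked retrieval list
#'
#' Entries ordered by non-increasing score, ties broken by ascending
#' `doc_id`; at most `limit` entries; no duplicate documents.
#'
#' @param topic_id topic identifier.
#' @param doc_ids character vector of document IDs.
#' @param scores numeric scores aligned with `doc_ids`.
#' @param sorted if `TRUE` (the default) the entries are validated/sorted in
#'   score order. Re-ranked lists keep their BM25 scores while encoding tier
#'   order in entry order, and are built with `sorted = FALSE`.
#' @return object of class `ranked_list` with fields `topic_id` and
#'   `entries` (data frame `doc_id`, `score`).
#' @export
ranked_list <- function(topic_id, doc_ids, scores, sorted = TRUE) {
  stopifnot(length(doc_ids) == length(scores), !anyDuplicated(doc_ids))
  entries <- data.frame(doc_id = as.character(doc_ids), score = as.numeric(scores),
                        stringsAsFactors = FALSE)
  if (sorted && nrow(entries) > 1L) {
    ord <- order(-entries$score, entries$doc_id)
    entries <- entries[ord, , drop = FALSE]
  }
  rownames(entries) <- NULL
  structure(list(topic_id = topic_id, entries = entries), class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list %s> %d entries\n", x$topic_id, nrow(x$entries)))
  print(head(x$entries, 5L))
  invisible(x)
}

#' Build a fielded inverted index
#'
#' Indexes a document collection into per-field postings (term -> document
#' term frequencies) with per-field document lengths. By default the five
#' text fields are merged into one `"text"` field and MeSH terms are also
#' indexed separately as `"mesh"`.
#'
#' @param documents non-empty list of [document()] objects.
#' @param field_map named list mapping index-field names to functions
#'   `document -> character tokens`; `NULL` for the default two fields.
#' @return object of class `inverted_index`.
#' @export
build_index <- function(documents, field_map = NULL) {
  if (length(documents) == 0L) stop("cannot index an empty collection")
  stopifnot(all(vapply(documents, inherits, logical(1), "pm_document")))
  doc_ids <- vapply(documents, `[[`, character(1), "doc_id")
  if (anyDuplicated(doc_ids)) stop("duplicate doc_id in collection")
  if (is.null(field_map)) {
    field_map <- list(
      text = function(d) tokenize_text(c(d$title, d$abstract, d$chemical_terms,
                                         d$mesh_terms, d$other_abstract)),
      mesh = function(d) tokenize_text(d$mesh_terms)
    )
  }
  N <- length(documents)
  fields <- lapply(field_map, function(fn) {
    postings <- new.env(parent = emptyenv(), hash = TRUE)
    doc_len <- numeric(N)
    for (i in seq_len(N)) {
      toks <- fn(documents[[i]])
      doc_len[i] <- length(toks)
      if (length(toks) == 0L) next
      tf <- table(toks)
      for (j in seq_along(tf)) {
        term <- names(tf)[j]
        p <- postings[[term]]
        if (is.null(p)) p <- list(pos = integer(), tf = numeric())
        p$pos <- c(p$pos, i)
        p$tf <- c(p$tf, as.numeric(tf[[j]]))
        assign(term, p, envir = postings)
      }
    }
    list(postings = postings, doc_len = doc_len,
         avg_len = mean(doc_len))
  })
  structure(
    list(doc_ids = doc_ids, N = N, fields = fields),
    class = "inverted_index"
  )
}

#' @export
print.inverted_index <- function(x, ...) {
  cat(sprintf("<inverted_index> %d documents, fields: %s\n",
              x$N, paste(names(x$fields), collapse = ", ")))
  invisible(x)
}

bm25_idf <- function(N, df) log(1 + (N - df + 0.5) / (df + 0.5))

# query phrases -> flat lowercase tokens
query_terms_tokens <- function(terms) {
  unique(unlist(lapply(terms, tokenize_text)))
}

#' Okapi BM25 score of one document for a term list
#'
#' Sum over query terms of
#' `idf(t) * tf * (k1 + 1) / (tf + k1 * (1 - b + b * len/avglen))` with
#' `idf(t) = ln(1 + (N - df + 0.5)/(df + 0.5))`. Multi-word terms are
#' tokenized; duplicated query tokens count once.
#'
#' @param index an [build_index()] result.
#' @param field index field name.
#' @param terms character vector of query terms (phrases allowed).
#' @param doc_id document to score.
#' @param k1,b BM25 parameters.
#' @return non-negative score; 0 when no query term occurs in the document.
#' @export
bm25_score <- function(index, field, terms, doc_id, k1 = 1.2, b = 0.75) {
  stopifnot(inherits(index, "inverted_index"))
  fld <- index$fields[[field]]
  if (is.null(fld)) stop("unknown index field: ", field)
  pos <- match(doc_id, index$doc_ids)
  if (is.na(pos)) stop("unknown doc_id: ", doc_id)
  toks <- query_terms_tokens(terms)
  score <- 0
  len <- fld$doc_len[pos]
  for (t in toks) {
    p <- fld$postings[[t]]
    if (is.null(p)) next
    hit <- match(pos, p$pos)
    if (is.na(hit)) next
    tf <- p$tf[hit]
    idf <- bm25_idf(index$N, length(p$pos))
    score <- score + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * len / fld$avg_len))
  }
  score
}

# vectorized over all docs containing any of the terms: named score vector by position
bm25_scores_all <- function(index, field, terms, k1, b) {
  fld <- index$fields[[field]]
  toks <- query_terms_tokens(terms)
  scores <- numeric(index$N)
  len <- fld$doc_len
  norm <- k1 * (1 - b + b * len / fld$avg_len)
  for (t in toks) {
    p <- fld$postings[[t]]
    if (is.null(p)) next
    idf <- bm25_idf(index$N, length(p$pos))
    scores[p$pos] <- scores[p$pos] +
      idf * p$tf * (k1 + 1) / (p$tf + norm[p$pos])
  }
  scores
}

#' Boosted multi-field BM25 search
#'
#' Scores every document as the boost-weighted sum of the BM25 scores of
#' the four query fields against the merged `"text"` field, drops documents
#' scoring 0, and returns the top `limit` in ranked order (score
#' descending, doc_id ascending on ties).
#'
#' @param index an [build_index()] result.
#' @param query an [expand_query()] result.
#' @param boosts a [boost_weights()].
#' @param limit maximum entries returned (the track convention is 1000).
#' @param k1,b BM25 parameters.
#' @param field index field scored (default `"text"`).
#' @return a [ranked_list()].
#' @export
search <- function(index, query, boosts = boost_weights(), limit = 1000L,
                   k1 = 1.2, b = 0.75, field = "text") {
  stopifnot(inherits(index, "inverted_index"), inherits(query, "expanded_query"))
  n_terms <- nrow(query$disease_terms) + nrow(query$gene_terms) +
    length(query$treatment_terms) + length(query$demographic_terms)
  if (n_terms == 0L) stop("empty expanded query")
  scores <- boosts$disease * bm25_scores_all(index, field, query$disease_terms$term, k1, b) +
    boosts$gene * bm25_scores_all(index, field, query$gene_terms$term, k1, b) +
    boosts$treatment * bm25_scores_all(index, field, query$treatment_terms, k1, b) +
    boosts$demographic * bm25_scores_all(index, field, query$demographic_terms, k1, b)
  hit <- which(scores > 0)
  if (length(hit) == 0L) {
    return(ranked_list(query$topic_id, character(), numeric()))
  }
  ids <- index$doc_ids[hit]
  sc <- scores[hit]
  ord <- order(-sc, ids)
  keep <- head(ord, limit)
  ranked_list(query$topic_id, ids[keep], sc[keep], sorted = FALSE)
}
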