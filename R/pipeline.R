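#' Matcher query sequence from an expanded query
#'
#' The matcher evaluates the disease dimension only: the query sequence is
#' built from the disease field of the expanded query, matcher-preprocessed
#' (entity-ID normalized, stopword-filtered, stemmed) and de-duplicated
#' preserving first occurrence.
#'
#' @param query an [expand_query()] result.
#' @param stopwords stopword list.
#' @param entity_index disease surface index from [build_entity_index()].
#' @return a [token_sequence()] with stage `"matcher"`.
#' @export
matcher_query_sequence <- function(query, stopwords = default_stopwords(),
                                   entity_index = character()) {
  stopifnot(inherits(query, "expanded_query"))
  seq <- preprocess_for_matcher(paste(query$disease_terms$term, collapse = " "),
                                stopwords, entity_index)
  token_sequence(unique(seq$tokens), origin_doc_id = query$topic_id, stage = "matcher")
}

#' Matcher training pairs from a synthetic bundle
#'
#' Builds one (query sequence, document sequence, grade) triple per row of
#' the bundle's matcher grades, using the default expansion strategy for
#' the query side.
#'
#' @param bundle a [generate_bundle()] result.
#' @param stopwords stopword list.
#' @return list of pairs suitable for [train_matcher()].
#' @export
matcher_training_pairs <- function(bundle, stopwords = default_stopwords()) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  eidx <- build_entity_index(bundle$kb, "disease", include_hypernyms = TRUE)
  doc_by_id <- setNames(bundle$documents,
                        vapply(bundle$documents, `[[`, character(1), "doc_id"))
  doc_seqs <- new.env(parent = emptyenv())
  topic_by_id <- setNames(bundle$topics,
                          vapply(bundle$topics, `[[`, character(1), "topic_id"))
  qseq <- lapply(topic_by_id, function(tp) {
    matcher_query_sequence(expand_query(tp, expansion_strategy(), bundle$kb),
                           stopwords, eidx)
  })
  lapply(seq_len(nrow(bundle$matcher_grades)), function(i) {
    row <- bundle$matcher_grades[i, ]
    ds <- doc_seqs[[row$doc_id]]
    if (is.null(ds)) {
      ds <- preprocess_for_matcher(doc_by_id[[row$doc_id]], stopwords, eidx)
      assign(row$doc_id, ds, envir = doc_seqs)
    }
    list(query = qseq[[row$topic_id]], doc = ds, grade = row$grade)
  })
}

#' Held-out classifier accuracy
#'
#' Accuracy of the 0.5-thresholded treatment probability on the model's
#' own test split (or any index set).
#'
#' @param model a trained `classifier_model`.
#' @param docs,labels the full corpus the model was trained from.
#' @param indices document indices to evaluate (default: the test split).
#' @return accuracy in `[0, 1]`.
#' @export
classifier_accuracy <- function(model, docs, labels, indices = model$split$test) {
  v1 <- classifier_scores(model, docs[indices])
  mean(as.integer(v1 >= 0.5) == as.integer(labels[indices]))
}

#' Held-out pairwise ordering accuracy of the matcher
#'
#' Fraction of (grade-2, grade-0) pair combinations in the index set where
#' the grade-2 pair scores strictly higher.
#'
#' @param model a trained `matcher_model`.
#' @param pairs the full pair list the model was trained from.
#' @param indices pair indices to evaluate (default: the test split).
#' @return accuracy in `[0, 1]`, or `NA` if either grade is absent.
#' @export
matcher_pairwise_accuracy <- function(model, pairs, indices = model$split$test) {
  grades <- vapply(pairs[indices], function(p) as.integer(p$grade), integer(1))
  v2 <- vapply(pairs[indices], function(p) matcher_score(model, p$query, p$doc),
               numeric(1))
  hi <- v2[grades == 2L]
  lo <- v2[grades == 0L]
  if (length(hi) == 0L || length(lo) == 0L) return(NA_real_)
  mean(outer(hi, lo, `>`))
}

#' Run the full two-phase retrieval experiment on a bundle
#'
#' Executes the complete pipeline: index the corpus, expand and search
#' every topic (baseline run), train the treatment classifier and the
#' relevance matcher, score every retrieved document (`v1`, `v2`), train
#' the LR ensemble on the judged documents of the training topics, and
#' produce voting and LR re-ranked runs; all three runs are evaluated on
#' the evaluation topics.
#'
#' @param bundle a [generate_bundle()] result.
#' @param clf_config,mat_config model configurations.
#' @param strategy query-expansion strategy.
#' @param boosts field boost weights.
#' @param limit ranked-list size cap.
#' @param eval_topic_ids topics to evaluate on (default: all). The LR
#'   ensemble trains on the judged documents of the remaining topics, or
#'   of all topics when none remain.
#' @param seed seed for the ensemble fit.
#' @return list with `runs` (baseline/voting/lr per topic), `metrics`
#'   (a `metrics_report` per run type), `classifier_accuracy`,
#'   `matcher_pairwise_accuracy`, the trained models and the score tables.
#' @export
run_retrieval_experiment <- function(bundle,
                                     clf_config = classifier_config(),
                                     mat_config = matcher_config(),
                                     strategy = expansion_strategy(),
                                     boosts = boost_weights(),
                                     limit = 1000L,
                                     eval_topic_ids = NULL,
                                     seed = 1L) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  topic_ids <- vapply(bundle$topics, `[[`, character(1), "topic_id")
  if (is.null(eval_topic_ids)) eval_topic_ids <- topic_ids
  train_topic_ids <- setdiff(topic_ids, eval_topic_ids)
  if (length(train_topic_ids) == 0L) train_topic_ids <- topic_ids

  index <- build_index(bundle$documents)
  queries <- setNames(lapply(bundle$topics, expand_query, strategy = strategy,
                             kb = bundle$kb), topic_ids)
  baseline <- lapply(queries, search, index = index, boosts = boosts, limit = limit)

  doc_ids <- vapply(bundle$documents, `[[`, character(1), "doc_id")
  clf <- train_classifier(bundle$documents, bundle$classifier_labels[doc_ids],
                          clf_config)
  clf_acc <- classifier_accuracy(clf, bundle$documents,
                                 bundle$classifier_labels[doc_ids])
  v1 <- classifier_scores(clf, bundle$documents)

  pairs <- matcher_training_pairs(bundle)
  mat <- train_matcher(pairs, mat_config)
  mat_acc <- matcher_pairwise_accuracy(mat, pairs)

  eidx <- build_entity_index(bundle$kb, "disease", include_hypernyms = TRUE)
  doc_seqs <- setNames(
    lapply(bundle$documents, preprocess_for_matcher, entity_index = eidx),
    doc_ids
  )
  qseqs <- lapply(queries, matcher_query_sequence, entity_index = eidx)

  v2 <- list() # per topic: named score vector over retrieved docs
  for (tid in topic_ids) {
    ids <- baseline[[tid]]$entries$doc_id
    v2[[tid]] <- setNames(
      vapply(ids, function(d) matcher_score(mat, qseqs[[tid]], doc_seqs[[d]]),
             numeric(1)),
      ids
    )
  }

  grade_to_level <- c("not", "partially", "definitely")
  feats <- list()
  levels <- character()
  for (tid in train_topic_ids) {
    g <- bundle$qrels[[tid]]
    ids <- intersect(names(g), names(v2[[tid]]))
    for (d in ids) {
      feats[[length(feats) + 1L]] <- featurize(v1[[d]], v2[[tid]][[d]])
      levels <- c(levels, grade_to_level[g[[d]] + 1L])
    }
  }
  ens <- train_ensemble(feats, levels, seed = seed)

  label_runs <- function(labeler) {
    out <- list()
    for (tid in topic_ids) {
      ids <- baseline[[tid]]$entries$doc_id
      labs <- setNames(
        vapply(ids, function(d) labeler(v1[[d]], v2[[tid]][[d]]), character(1)),
        ids
      )
      out[[tid]] <- rerank(baseline[[tid]], labs)
    }
    out
  }
  voting <- label_runs(function(a, b) voting_label(a, b))
  lr <- label_runs(function(a, b) ensemble_label(ens, a, b))

  eval_sel <- function(runs) runs[eval_topic_ids]
  list(
    runs = list(baseline = baseline, voting = voting, lr = lr),
    metrics = list(
      baseline = evaluate_runs(eval_sel(baseline), bundle$qrels),
      voting = evaluate_runs(eval_sel(voting), bundle$qrels),
      lr = evaluate_runs(eval_sel(lr), bundle$qrels)
    ),
    classifier_accuracy = clf_acc,
    matcher_pairwise_accuracy = mat_acc,
    classifier = clf, matcher = mat, ensemble = ens,
    v1 = v1, v2 = v2,
    eval_topic_ids = eval_topic_ids, train_topic_ids = train_topic_ids
  )
}

#' Save / load a model checkpoint
#'
#' Single-file serialized parameter set with its configuration header.
#'
#' @param model a `classifier_model`, `matcher_model` or `lr_ensemble`.
#' @param path checkpoint file path.
#' @return `path` invisibly / the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("classifier_model", "matcher_model", "lr_ensemble")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  stopifnot(file.exists(path))
  model <- readRDS(path)
  stopifnot(inherits(model, c("classifier_model", "matcher_model", "lr_ensemble")))
  model
}
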