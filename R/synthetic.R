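#' Configuration for the synthetic-corpus generator
#'
#' Controls the seeded generator that emulates the statistical structure
#' the pipeline assumes: a background vocabulary with Zipf-distributed
#' frequencies, a treatment-focused subpopulation of abstracts marked by
#' treatment keywords, disease mentions that vary over knowledge-base
#' synonym surface forms, topics with disease + gene + demographic fields,
#' and 3-grade judgments consistent with the generation process.
#'
#' @param seed integer seed; the same seed yields a byte-identical bundle.
#' @param n_docs corpus size.
#' @param n_topics number of topics.
#' @param vocab_size background vocabulary size.
#' @param n_diseases,synonyms_per_disease knowledge-base shape.
#' @param p_treatment_focus probability a document is treatment-focused.
#' @param p_synonym_swap probability a disease mention uses a non-canonical
#'   surface form.
#' @param noise_token_rate per-position probability of replacing a token
#'   with out-of-vocabulary noise.
#' @param relevant_docs_per_topic disease-mentioning (grade >= 1) documents
#'   per topic.
#' @param distractors_per_topic judged grade-0 documents per topic that
#'   mention a different disease.
#' @param hypernym_docs_per_topic documents per topic mentioning the
#'   topic disease's broader (hypernym) term; they feed the matcher's
#'   grade-1 training cells.
#' @param zipf_exponent background frequency decay.
#' @param doc_length_range inclusive token-count range of document bodies.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_docs = 2000L, n_topics = 5L,
                             vocab_size = 2000L, n_diseases = 30L,
                             synonyms_per_disease = 2L,
                             p_treatment_focus = 0.4, p_synonym_swap = 0.3,
                             noise_token_rate = 0.05,
                             relevant_docs_per_topic = 20L,
                             distractors_per_topic = 10L,
                             hypernym_docs_per_topic = 10L,
                             zipf_exponent = 1.1,
                             doc_length_range = c(40L, 240L)) {
  probs <- c(p_treatment_focus, p_synonym_swap, noise_token_rate)
  stopifnot(all(probs >= 0), all(probs <= 1),
            n_docs >= 1L, n_topics >= 1L, vocab_size >= 1L, n_diseases >= 1L,
            relevant_docs_per_topic >= 1L,
            length(doc_length_range) == 2L,
            doc_length_range[1L] >= 1L,
            doc_length_range[1L] <= doc_length_range[2L])
  if (relevant_docs_per_topic > n_docs) {
    stop("relevant_docs_per_topic cannot exceed n_docs")
  }
  per_topic <- relevant_docs_per_topic + distractors_per_topic + hypernym_docs_per_topic
  if (n_topics * per_topic > n_docs) {
    stop("n_docs too small for ", n_topics, " topics using ", per_topic,
         " assigned documents each")
  }
  if (n_topics > n_diseases) stop("need at least one disease per topic")
  structure(
    list(seed = as.integer(seed), n_docs = as.integer(n_docs),
         n_topics = as.integer(n_topics), vocab_size = as.integer(vocab_size),
         n_diseases = as.integer(n_diseases),
         synonyms_per_disease = as.integer(synonyms_per_disease),
         p_treatment_focus = p_treatment_focus, p_synonym_swap = p_synonym_swap,
         noise_token_rate = noise_token_rate,
         relevant_docs_per_topic = as.integer(relevant_docs_per_topic),
         distractors_per_topic = as.integer(distractors_per_topic),
         hypernym_docs_per_topic = as.integer(hypernym_docs_per_topic),
         zipf_exponent = zipf_exponent,
         doc_length_range = as.integer(doc_length_range)),
    class = "generator_config"
  )
}

#' Generate a synthetic retrieval bundle
#'
#' Produces a knowledge base, corpus, topics, graded qrels, classifier
#' labels and matcher grades that are mutually consistent: grade-2
#' documents mention the topic disease (under any synonym surface) and
#' are treatment-focused, grade-1 documents mention it without treatment
#' focus, judged grade-0 distractors mention a different disease, and
#' hypernym-mention documents supply the matcher's broader-term grade-1
#' cells.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_bundle` with elements `config`,
#'   `kb`, `documents`, `topics`, `qrels`, `classifier_labels` (named 0/1
#'   vector by doc_id) and `matcher_grades` (data frame `topic_id`,
#'   `doc_id`, `grade`).
#' @export
generate_bundle <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_bundle_impl(config))
}

generate_bundle_impl <- function(cf) {
  # knowledge base: diseases with synonyms and a shared hypernym per block,
  # genes with one synonym and an acronym
  disease_ids <- sprintf("D%06d", seq_len(cf$n_diseases))
  canon <- sprintf("malady%03da", seq_len(cf$n_diseases))
  syns <- lapply(seq_len(cf$n_diseases), function(i) {
    if (cf$synonyms_per_disease == 0L) return(character())
    sprintf("malady%03ds%d", i, seq_len(cf$synonyms_per_disease))
  })
  hyper <- sprintf("maladygroup%02d", (seq_len(cf$n_diseases) - 1L) %/% 5L + 1L)
  n_genes <- max(10L, cf$n_topics)
  kb <- knowledge_base(c(
    lapply(seq_len(cf$n_diseases), function(i) {
      entity_record(disease_ids[i], canon[i], "disease",
                    synonyms = syns[[i]], hypernyms = hyper[i])
    }),
    lapply(seq_len(n_genes), function(i) {
      entity_record(sprintf("G%06d", i), sprintf("gene%03dx", i), "gene",
                    synonyms = sprintf("gene%03ds", i),
                    acronyms = sprintf("g%03dz", i))
    })
  ))

  # background corpus with Zipf token frequencies
  vocab <- sprintf("w%05d", seq_len(cf$vocab_size))
  zipf <- (seq_len(cf$vocab_size))^(-cf$zipf_exponent)
  zipf <- zipf / sum(zipf)
  doc_ids <- sprintf("doc%05d", seq_len(cf$n_docs))
  lens <- sample(cf$doc_length_range[1L]:cf$doc_length_range[2L], cf$n_docs,
                 replace = TRUE)
  labels <- as.integer(runif(cf$n_docs) < cf$p_treatment_focus)
  bodies <- vector("list", cf$n_docs)
  for (i in seq_len(cf$n_docs)) {
    toks <- sample(vocab, lens[i], replace = TRUE, prob = zipf)
    if (labels[i] == 1L) {
      kws <- sample(treatment_keywords(), sample(3:6, 1L))
      toks <- insert_tokens(toks, kws)
    }
    n_noise <- rbinom(1L, length(toks), cf$noise_token_rate)
    if (n_noise > 0L) {
      pos <- sample(length(toks), n_noise)
      toks[pos] <- sprintf("nz%06d", sample.int(999999L, n_noise, replace = TRUE))
    }
    bodies[[i]] <- toks
  }

  # topics over distinct diseases and genes
  topic_disease <- sample(cf$n_diseases, cf$n_topics)
  topic_gene <- sample(n_genes, cf$n_topics)
  topics <- lapply(seq_len(cf$n_topics), function(t) {
    topic(
      topic_id = sprintf("t%03d", t),
      disease = canon[topic_disease[t]],
      gene = sprintf("gene%03dx", topic_gene[t]),
      demographic = paste(sample(25:80, 1L), "year old",
                          sample(c("male", "female"), 1L))
    )
  })

  # disjoint per-topic document assignments
  per_topic <- cf$relevant_docs_per_topic + cf$distractors_per_topic +
    cf$hypernym_docs_per_topic
  pool <- sample(cf$n_docs, cf$n_topics * per_topic)
  qrels <- list()
  mg_topic <- character()
  mg_doc <- character()
  mg_grade <- integer()
  mention_surface <- function(di) {
    if (length(syns[[di]]) > 0L && runif(1L) < cf$p_synonym_swap) {
      sample(syns[[di]], 1L)
    } else {
      canon[di]
    }
  }
  for (t in seq_len(cf$n_topics)) {
    base <- (t - 1L) * per_topic
    rel <- pool[base + seq_len(cf$relevant_docs_per_topic)]
    dis <- pool[base + cf$relevant_docs_per_topic + seq_len(cf$distractors_per_topic)]
    hyp <- pool[base + cf$relevant_docs_per_topic + cf$distractors_per_topic +
                  seq_len(cf$hypernym_docs_per_topic)]
    di <- topic_disease[t]
    for (i in rel) {
      surfaces <- replicate(sample(1:3, 1L), mention_surface(di))
      bodies[[i]] <- insert_tokens(bodies[[i]], surfaces)
    }
    other <- setdiff(seq_len(cf$n_diseases), topic_disease)
    if (length(other) == 0L) other <- setdiff(seq_len(cf$n_diseases), di)
    for (i in dis) {
      oi <- if (length(other) == 1L) other else sample(other, 1L)
      surfaces <- replicate(sample(1:3, 1L), mention_surface(oi))
      bodies[[i]] <- insert_tokens(bodies[[i]], surfaces)
    }
    for (i in hyp) {
      bodies[[i]] <- insert_tokens(bodies[[i]], rep(hyper[di], sample(1:2, 1L)))
    }
    grades <- c(setNames(ifelse(labels[rel] == 1L, 2L, 1L), doc_ids[rel]),
                setNames(rep(0L, length(dis)), doc_ids[dis]))
    qrels[[topics[[t]]$topic_id]] <- grades
    mg_topic <- c(mg_topic, rep(topics[[t]]$topic_id, length(rel) + length(dis) + length(hyp)))
    mg_doc <- c(mg_doc, doc_ids[c(rel, dis, hyp)])
    mg_grade <- c(mg_grade, rep(2L, length(rel)), rep(0L, length(dis)),
                  rep(1L, length(hyp)))
  }

  documents <- lapply(seq_len(cf$n_docs), function(i) {
    toks <- bodies[[i]]
    n_title <- min(6L, length(toks))
    document(
      doc_id = doc_ids[i],
      title = paste(toks[seq_len(n_title)], collapse = " "),
      abstract = paste(toks[-seq_len(n_title)], collapse = " ")
    )
  })

  structure(
    list(
      config = cf, kb = kb, documents = documents, topics = topics,
      qrels = structure(qrels, class = "qrels"),
      classifier_labels = setNames(labels, doc_ids),
      matcher_grades = data.frame(topic_id = mg_topic, doc_id = mg_doc,
                                  grade = mg_grade, stringsAsFactors = FALSE)
    ),
    class = "synthetic_bundle"
  )
}

# insert extra tokens at random interior positions, preserving body order
insert_tokens <- function(toks, extra) {
  pos <- sort(sample(length(toks) + 1L, length(extra), replace = TRUE))
  out <- toks
  for (k in seq_along(extra)) {
    p <- pos[k] + (k - 1L)
    out <- append(out, extra[k], after = p - 1L)
  }
  out
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle> %d docs, %d topics, %d KB entities, %d judged pairs\n",
    length(x$documents), length(x$topics), length(x$kb$records),
    sum(lengths(unclass(x$qrels)))
  ))
  invisible(x)
}

#' Write a bundle to a directory
#'
#' Writes `kb.tsv`, `docs.jsonl`, `topics.jsonl`, `qrels.txt` and
#' `labels.tsv` (doc_id, treatment label).
#'
#' @param bundle a [generate_bundle()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_knowledge_base(bundle$kb, file.path(dir, "kb.tsv"))
  write_documents(bundle$documents, file.path(dir, "docs.jsonl"))
  write_topics(bundle$topics, file.path(dir, "topics.jsonl"))
  write_qrels(bundle$qrels, file.path(dir, "qrels.txt"))
  writeLines(
    c("doc_id\tlabel",
      sprintf("%s\t%d", names(bundle$classifier_labels), bundle$classifier_labels)),
    file.path(dir, "labels.tsv")
  )
  invisible(dir)
}
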