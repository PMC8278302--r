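#' Construct an entity record
#'
#' One disease or gene entity with its identifier and surface-form variants
#' (synonyms, hypernyms, acronyms), as stored in the local entity database
#' that drives query expansion and matcher entity normalization.
#'
#' @param entity_id unique identifier (kept uppercase; entity-ID tokens live
#'   in the reserved token namespace).
#' @param canonical_name non-empty preferred name.
#' @param entity_class `"disease"` or `"gene"`.
#' @param synonyms,hypernyms,acronyms character vectors (may be empty).
#' @return object of class `entity_record`.
#' @export
entity_record <- function(entity_id, canonical_name, entity_class = c("disease", "gene"),
                          synonyms = character(), hypernyms = character(),
                          acronyms = character()) {
  entity_class <- match.arg(entity_class)
  stopifnot(nzchar(entity_id), nzchar(canonical_name))
  structure(
    list(
      entity_id = toupper(entity_id), canonical_name = canonical_name,
      entity_class = entity_class,
      synonyms = as.character(synonyms), hypernyms = as.character(hypernyms),
      acronyms = as.character(acronyms)
    ),
    class = "entity_record"
  )
}

#' Build a knowledge base from entity records
#'
#' @param records list of [entity_record()] objects.
#' @return object of class `knowledge_base` with case-insensitive lookup by
#'   surface form and class.
#' @export
knowledge_base <- function(records) {
  stopifnot(is.list(records), all(vapply(records, inherits, logical(1), "entity_record")))
  ids <- vapply(records, `[[`, character(1), "entity_id")
  if (anyDuplicated(ids)) {
    stop("duplicate entity_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(records = setNames(records, ids)), class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cls <- vapply(x$records, `[[`, character(1), "entity_class")
  cat(sprintf(
    "<knowledge_base> %d entities (%d disease, %d gene)\n",
    length(x$records), sum(cls == "disease"), sum(cls == "gene")
  ))
  invisible(x)
}

#' Load a knowledge base from TSV
#'
#' Expected columns: `entity_id`, `class`, `canonical_name`, `synonyms`,
#' `hypernyms`, `acronyms`; the three variant columns are `|`-delimited
#' lists (empty string for none).
#'
#' @param path TSV file path (with header).
#' @return a [knowledge_base()].
#' @export
load_knowledge_base <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  needed <- c("entity_id", "class", "canonical_name", "synonyms", "hypernyms", "acronyms")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) stop("knowledge base missing columns: ", paste(missing, collapse = ", "))
  split_pipe <- function(x) if (!nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1L]]
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    entity_record(
      entity_id = tab$entity_id[i], canonical_name = tab$canonical_name[i],
      entity_class = tab$class[i],
      synonyms = split_pipe(tab$synonyms[i]),
      hypernyms = split_pipe(tab$hypernyms[i]),
      acronyms = split_pipe(tab$acronyms[i])
    )
  })
  knowledge_base(recs)
}

#' Write a knowledge base as TSV
#'
#' @param kb a [knowledge_base()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  stopifnot(inherits(kb, "knowledge_base"))
  rows <- vapply(kb$records, function(r) {
    paste(
      r$entity_id, r$entity_class, r$canonical_name,
      paste(r$synonyms, collapse = "|"),
      paste(r$hypernyms, collapse = "|"),
      paste(r$acronyms, collapse = "|"),
      sep = "\t"
    )
  }, character(1))
  writeLines(
    c("entity_id\tclass\tcanonical_name\tsynonyms\thypernyms\tacronyms", rows),
    path
  )
  invisible(path)
}

#' Look up an entity by surface form
#'
#' Case-insensitive lookup over canonical names, synonyms, hypernyms and
#' acronyms. When one surface form is listed under several entities, the
#' lexicographically smallest `entity_id` wins and a warning is emitted.
#'
#' @param kb a [knowledge_base()].
#' @param surface surface form to resolve.
#' @param entity_class `"disease"` or `"gene"`.
#' @return the matching [entity_record()], or `NULL` when unknown.
#' @export
kb_lookup <- function(kb, surface, entity_class = c("disease", "gene")) {
  entity_class <- match.arg(entity_class)
  surface <- tolower(trimws(surface))
  hits <- character()
  for (r in kb$records) {
    if (r$entity_class != entity_class) next
    forms <- tolower(c(r$canonical_name, r$synonyms, r$hypernyms, r$acronyms))
    if (surface %in% forms) hits <- c(hits, r$entity_id)
  }
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) {
    warning("surface form '", surface, "' is ambiguous (",
            paste(sort(hits), collapse = ", "), "); using smallest entity_id")
  }
  kb$records[[sort(hits)[1L]]]
}

#' Build a surface-form to entity-ID index
#'
#' Maps every lowercase surface form (canonical name, synonyms and, when
#' `include_hypernyms`, hypernyms) of entities of one class to its entity
#' ID, resolving collisions to the smallest entity ID. The result feeds
#' [preprocess_for_matcher()].
#'
#' @param kb a [knowledge_base()].
#' @param entity_class `"disease"` or `"gene"`.
#' @param include_hypernyms include hypernym surfaces (default `FALSE`; the
#'   matcher treats hypernym mentions as distinct, broader surfaces).
#' @return named character vector: lowercase surface -> entity ID.
#' @export
build_entity_index <- function(kb, entity_class = c("disease", "gene"),
                               include_hypernyms = FALSE) {
  entity_class <- match.arg(entity_class)
  surfaces <- character()
  ids <- character()
  for (r in kb$records) {
    if (r$entity_class != entity_class) next
    forms <- c(r$canonical_name, r$synonyms, r$acronyms)
    if (include_hypernyms) forms <- c(forms, r$hypernyms)
    forms <- tolower(unique(forms[nzchar(forms)]))
    # normalize whitespace to the tokenizer's view of the surface
    forms <- vapply(forms, function(f) paste(tokenize_text(f), collapse = " "), character(1))
    surfaces <- c(surfaces, forms)
    ids <- c(ids, rep(r$entity_id, length(forms)))
  }
  ord <- order(surfaces, ids)
  surfaces <- surfaces[ord]
  ids <- ids[ord]
  keep <- !duplicated(surfaces) # smallest id wins within a surface
  setNames(ids[keep], surfaces[keep])
}

#' The treatment keyword list
#'
#' The fixed set of 14 treatment-related keywords appended to queries so
#' that treatment-focused articles score higher in initial retrieval.
#'
#' @return character vector of 14 terms.
#' @export
treatment_keywords <- function() {
  c(
    "surgery", "therapy", "patient", "resistance", "recurrence",
    "therapeutic", "prevent", "prophylaxis", "prophylactic", "prognosis",
    "outcome", "survival", "treatment", "efficacy"
  )
}

#' Define a query-expansion strategy
#'
#' Flags controlling which knowledge-base variants are added to each query
#' field. The default — disease synonyms on, disease hypernyms off, gene
#' synonyms/acronyms off, treatment keywords on — is the configuration that
#' performed best in the underlying retrieval experiments: hypernyms dilute
#' a specific disease query, and gene synonym expansion floods the query
#' with gene terms that treatment-focused articles rarely mention.
#'
#' @param disease_synonyms,disease_hypernyms,gene_synonyms,gene_acronyms,treatment_keywords
#'   logical flags.
#' @return object of class `expansion_strategy`.
#' @export
expansion_strategy <- function(disease_synonyms = TRUE, disease_hypernyms = FALSE,
                               gene_synonyms = FALSE, gene_acronyms = FALSE,
                               treatment_keywords = TRUE) {
  structure(
    list(
      disease_synonyms = isTRUE(disease_synonyms),
      disease_hypernyms = isTRUE(disease_hypernyms),
      gene_synonyms = isTRUE(gene_synonyms),
      gene_acronyms = isTRUE(gene_acronyms),
      treatment_keywords = isTRUE(treatment_keywords)
    ),
    class = "expansion_strategy"
  )
}

#' Expand a topic into a weighted four-field query
#'
#' Produces the four query fields (disease / gene / treatment /
#' demographic). Original topic terms always come first; expansion terms
#' carry a source tag (`synonym`, `hypernym`, `acronym`); duplicates within
#' a field keep their first occurrence. Multi-variant gene fields
#' (`";"`-separated) are expanded per variant.
#'
#' @param tp a [topic()].
#' @param strategy an [expansion_strategy()].
#' @param kb a [knowledge_base()].
#' @return object of class `expanded_query` with data-frame fields
#'   `disease_terms`, `gene_terms` (columns `term`, `source`) and character
#'   vectors `treatment_terms`, `demographic_terms`.
#' @export
expand_query <- function(tp, strategy = expansion_strategy(), kb = knowledge_base(list())) {
  stopifnot(inherits(tp, "pm_topic"), inherits(strategy, "expansion_strategy"))
  if (!nzchar(tp$disease)) stop("topic disease must be non-empty")

  dedup <- function(df) df[!duplicated(tolower(df$term)), , drop = FALSE]

  disease <- data.frame(term = tp$disease, source = "original", stringsAsFactors = FALSE)
  rec <- kb_lookup(kb, tp$disease, "disease")
  if (!is.null(rec)) {
    if (strategy$disease_synonyms && length(rec$synonyms)) {
      disease <- rbind(disease, data.frame(term = rec$synonyms, source = "synonym"))
    }
    if (strategy$disease_hypernyms && length(rec$hypernyms)) {
      disease <- rbind(disease, data.frame(term = rec$hypernyms, source = "hypernym"))
    }
  }
  disease <- dedup(disease)

  genes <- trimws(strsplit(tp$gene, ";", fixed = TRUE)[[1L]])
  genes <- genes[nzchar(genes)]
  gene <- data.frame(term = character(), source = character(), stringsAsFactors = FALSE)
  for (g in genes) {
    gene <- rbind(gene, data.frame(term = g, source = "original"))
    grec <- kb_lookup(kb, g, "gene")
    if (!is.null(grec)) {
      if (strategy$gene_synonyms && length(grec$synonyms)) {
        gene <- rbind(gene, data.frame(term = grec$synonyms, source = "synonym"))
      }
      if (strategy$gene_acronyms && length(grec$acronyms)) {
        gene <- rbind(gene, data.frame(term = grec$acronyms, source = "acronym"))
      }
    }
  }
  gene <- dedup(gene)

  structure(
    list(
      topic_id = tp$topic_id,
      disease_terms = disease,
      gene_terms = gene,
      treatment_terms = if (strategy$treatment_keywords) treatment_keywords() else character(),
      demographic_terms = unique(tokenize_text(tp$demographic))
    ),
    class = "expanded_query"
  )
}

#' @export
print.expanded_query <- function(x, ...) {
  cat(sprintf(
    "<expanded_query %s> disease: %s | gene: %s | %d treatment | %d demographic\n",
    x$topic_id, paste(x$disease_terms$term, collapse = ", "),
    paste(x$gene_terms$term, collapse = ", "),
    length(x$treatment_terms), length(x$demographic_terms)
  ))
  invisible(x)
}
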