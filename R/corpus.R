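#' @importFrom stats runif rbinom setNames predict quantile
#' @importFrom utils head tail
NULL

# Reserved vocabulary lives in an uppercase namespace: raw-text tokenization
# lowercases everything, so no token produced from text can collide with
# SEP/NUM/PAD/UNK or with a knowledge-base entity ID.
TOKEN_SEP <- "SEP"
TOKEN_NUM <- "NUM"
TOKEN_PAD <- "PAD"
TOKEN_UNK <- "UNK"

is_reserved_token <- function(tokens) grepl("[A-Z]", tokens)

#' Construct a document record
#'
#' A `pm_document` is one fielded abstract record: the unit being indexed,
#' classified and ranked. Optional fields default to empty.
#'
#' @param doc_id non-empty document identifier, unique within a collection.
#' @param title,abstract,other_abstract text fields (empty string allowed).
#' @param chemical_terms,mesh_terms character vectors of controlled terms.
#' @return object of class `pm_document`.
#' @export
document <- function(doc_id, title = "", abstract = "", chemical_terms = character(),
                     mesh_terms = character(), other_abstract = "") {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  as_chr1 <- function(x) {
    if (length(x) == 0L || is.null(x) || (length(x) == 1L && is.na(x))) "" else as.character(x)[1L]
  }
  structure(
    list(
      doc_id = doc_id,
      title = as_chr1(title),
      abstract = as_chr1(abstract),
      chemical_terms = as.character(chemical_terms %||% character()),
      mesh_terms = as.character(mesh_terms %||% character()),
      other_abstract = as_chr1(other_abstract)
    ),
    class = "pm_document"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.pm_document <- function(x, ...) {
  cat(sprintf(
    "<pm_document %s> %s [%d abstract chars, %d chemical, %d MeSH]\n",
    x$doc_id, substr(x$title, 1L, 60L), nchar(x$abstract),
    length(x$chemical_terms), length(x$mesh_terms)
  ))
  invisible(x)
}

#' Construct a retrieval topic
#'
#' A topic is a structured search need standing in for a patient case:
#' a disease, one or more genetic variants (separated by `";"`), and free-text
#' demographic information (age and sex).
#'
#' @param topic_id non-empty identifier.
#' @param disease non-empty disease name.
#' @param gene genetic variant(s), `";"`-separated; may be empty.
#' @param demographic demographic text; may be empty.
#' @return object of class `pm_topic`.
#' @export
topic <- function(topic_id, disease, gene = "", demographic = "") {
  stopifnot(is.character(topic_id), length(topic_id) == 1L, nzchar(topic_id))
  stopifnot(is.character(disease), length(disease) == 1L, nzchar(disease))
  structure(
    list(
      topic_id = topic_id, disease = disease,
      gene = as.character(gene)[1L] %||% "",
      demographic = as.character(demographic)[1L] %||% ""
    ),
    class = "pm_topic"
  )
}

#' Construct a token sequence
#'
#' Ordered tokens plus provenance, as produced by the preprocessing
#' pipelines. `stage` records which pipeline produced it: matcher
#' preprocessing recognizes its own output and leaves it unchanged.
#'
#' @param tokens character vector of tokens.
#' @param origin_doc_id identifier of the source document/query.
#' @param stage one of `"raw"`, `"classifier"`, `"matcher"`.
#' @return object of class `token_sequence`.
#' @export
token_sequence <- function(tokens, origin_doc_id = "", stage = "raw") {
  stopifnot(is.character(tokens))
  structure(
    list(tokens = tokens, origin_doc_id = origin_doc_id, stage = stage),
    class = "token_sequence"
  )
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf(
    "<token_sequence %s:%s> %s%s\n", x$origin_doc_id, x$stage,
    paste(head(x$tokens, 12L), collapse = " "),
    if (length(x$tokens) > 12L) " ..." else ""
  ))
  invisible(x)
}

#' Tokenize raw text
#'
#' Lowercases and splits on anything that is not alphanumeric, keeping
#' maximal `[a-z0-9]` runs. This is the single tokenizer used for indexing,
#' classification and matching.
#'
#' @param text character vector; elements are concatenated in order.
#' @return character vector of lowercase tokens (possibly empty).
#' @export
tokenize_text <- function(text) {
  text <- paste(text[!is.na(text)], collapse = " ")
  if (!nzchar(text)) return(character())
  unlist(regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text))))
}

# digit-only tokens become NUM; mixed tokens like "v600e" are kept intact
replace_numbers <- function(tokens) {
  tokens[grepl("^[0-9]+$", tokens)] <- TOKEN_NUM
  tokens
}

#' Preprocess a document for the treatment classifier
#'
#' Title and abstract are tokenized, joined with a single `SEP` token,
#' lowercased, digit-only tokens replaced by `NUM`, then padded with `PAD`
#' or truncated to exactly `h` tokens. `PAD` appears only as a suffix.
#'
#' @param doc a [document()].
#' @param h positive integer maximum document length.
#' @return a [token_sequence()] of exactly `h` tokens, stage `"classifier"`.
#' @export
preprocess_for_classifier <- function(doc, h) {
  stopifnot(inherits(doc, "pm_document"), h >= 1L)
  tokens <- c(
    replace_numbers(tokenize_text(doc$title)),
    TOKEN_SEP,
    replace_numbers(tokenize_text(doc$abstract))
  )
  if (length(tokens) >= h) {
    tokens <- tokens[seq_len(h)]
  } else {
    tokens <- c(tokens, rep(TOKEN_PAD, h - length(tokens)))
  }
  token_sequence(tokens, origin_doc_id = doc$doc_id, stage = "classifier")
}

#' Preprocess text for the relevance matcher
#'
#' Applies the classifier normalization (without padding), replaces disease
#' surface forms with their knowledge-base entity IDs (longest match first,
#' before stemming), removes stopwords, and Porter-stems the remaining
#' tokens. Entity-ID and reserved tokens are never stemmed. Applying the
#' function to its own output is the identity.
#'
#' @param x a [document()], a [token_sequence()], or a character string.
#' @param stopwords character vector of stopwords ([default_stopwords()]).
#' @param entity_index named character vector mapping lowercase surface forms
#'   (possibly multi-word) to entity IDs; see [build_entity_index()].
#' @return a [token_sequence()] with stage `"matcher"`.
#' @export
preprocess_for_matcher <- function(x, stopwords = default_stopwords(),
                                   entity_index = character()) {
  if (inherits(x, "token_sequence") && identical(x$stage, "matcher")) {
    return(x) # already final vocabulary; see methods vignette
  }
  origin <- ""
  if (inherits(x, "pm_document")) {
    origin <- x$doc_id
    tokens <- c(
      replace_numbers(tokenize_text(x$title)),
      TOKEN_SEP,
      replace_numbers(tokenize_text(x$abstract))
    )
  } else if (inherits(x, "token_sequence")) {
    origin <- x$origin_doc_id
    tokens <- x$tokens
  } else {
    stopifnot(is.character(x))
    tokens <- replace_numbers(tokenize_text(x))
  }
  tokens <- replace_entities(tokens, entity_index)
  keep <- is_reserved_token(tokens) | !(tokens %in% c(stopwords, TOKEN_SEP, TOKEN_PAD))
  # SEP and PAD are structural, not content, for the matcher
  tokens <- tokens[keep & !(tokens %in% c(TOKEN_SEP, TOKEN_PAD))]
  plain <- !is_reserved_token(tokens)
  tokens[plain] <- porter_stem(tokens[plain])
  token_sequence(tokens, origin_doc_id = origin, stage = "matcher")
}

# Longest-match-first replacement of surface-form token n-grams by entity IDs.
# entity_index names are lowercase surfaces (space-separated when multi-word).
replace_entities <- function(tokens, entity_index) {
  if (length(entity_index) == 0L || length(tokens) == 0L) return(tokens)
  surf_tokens <- strsplit(names(entity_index), " ", fixed = TRUE)
  ord <- order(lengths(surf_tokens), decreasing = TRUE)
  surf_tokens <- surf_tokens[ord]
  ids <- unname(entity_index)[ord]
  # index candidate surfaces by first token for the scan
  first <- vapply(surf_tokens, `[`, character(1), 1L)
  by_first <- split(seq_along(surf_tokens), first)
  out <- character(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    cand <- by_first[[tokens[i]]]
    matched <- FALSE
    if (!is.null(cand)) {
      for (j in cand) { # candidates already longest-first
        st <- surf_tokens[[j]]
        k <- length(st)
        if (i + k - 1L <= n && all(tokens[i:(i + k - 1L)] == st)) {
          out <- c(out, ids[[j]])
          i <- i + k
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  out
}

#' Read a document collection
#'
#' Two dialects are supported: JSON-lines (one object per line with keys
#' `doc_id`, `title`, `abstract`, `chemical_terms`, `mesh_terms`,
#' `other_abstract`) and a minimal XML schema whose records carry
#' `ArticleTitle`, `Abstract`, `ChemicalList`, `MeshHeadingList` and
#' `OtherAbstract` elements. Missing optional fields become empty; file
#' order is preserved.
#'
#' @param path file path.
#' @param format `"json"` or `"xml"`.
#' @return list of [document()] objects.
#' @export
read_documents <- function(path, format = c("json", "xml")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  docs <- if (format == "json") read_documents_json(path) else read_documents_xml(path)
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  docs
}

read_documents_json <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) stop("malformed document record at line ", i, ": ", conditionMessage(e))
    )
    if (is.null(rec$doc_id)) stop("malformed document record at line ", i, ": missing doc_id")
    document(
      doc_id = as.character(rec$doc_id),
      title = rec$title %||% "",
      abstract = rec$abstract %||% "",
      chemical_terms = rec$chemical_terms %||% character(),
      mesh_terms = rec$mesh_terms %||% character(),
      other_abstract = rec$other_abstract %||% ""
    )
  })
}

read_documents_xml <- function(path) {
  xml <- xml2::read_xml(path)
  recs <- xml2::xml_find_all(xml, ".//Record")
  if (length(recs) == 0L) recs <- xml2::xml_children(xml)
  lapply(seq_along(recs), function(i) {
    rec <- recs[[i]]
    txt <- function(xp) {
      node <- xml2::xml_find_first(rec, xp)
      if (inherits(node, "xml_missing")) "" else xml2::xml_text(node)
    }
    all_txt <- function(xp) xml2::xml_text(xml2::xml_find_all(rec, xp))
    id <- txt("./DocID")
    if (!nzchar(id)) stop("malformed document record at index ", i, ": missing DocID")
    document(
      doc_id = id,
      title = txt("./ArticleTitle"),
      abstract = txt("./Abstract"),
      chemical_terms = all_txt("./ChemicalList/Chemical"),
      mesh_terms = all_txt("./MeshHeadingList/MeshHeading"),
      other_abstract = txt("./OtherAbstract")
    )
  })
}

#' Write a document collection as JSON-lines
#'
#' @param docs list of [document()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_documents <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(
      list(
        doc_id = jsonlite::unbox(d$doc_id),
        title = jsonlite::unbox(d$title),
        abstract = jsonlite::unbox(d$abstract),
        chemical_terms = d$chemical_terms,
        mesh_terms = d$mesh_terms,
        other_abstract = jsonlite::unbox(d$other_abstract)
      )
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read topics from JSON-lines
#'
#' One object per line with keys `topic_id`, `disease`, `gene`,
#' `demographic`.
#'
#' @param path file path.
#' @return list of [topic()] objects.
#' @export
read_topics <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]]),
      error = function(e) stop("malformed topic record at line ", i, ": ", conditionMessage(e))
    )
    topic(
      topic_id = as.character(rec$topic_id),
      disease = rec$disease %||% "",
      gene = rec$gene %||% "",
      demographic = rec$demographic %||% ""
    )
  })
}

#' Write topics as JSON-lines
#'
#' @param topics list of [topic()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topics <- function(topics, path) {
  lines <- vapply(topics, function(tp) {
    jsonlite::toJSON(lapply(
      list(topic_id = tp$topic_id, disease = tp$disease, gene = tp$gene,
           demographic = tp$demographic),
      jsonlite::unbox
    ))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
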