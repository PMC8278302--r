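#' Read TREC-style qrels
#'
#' Lines `topic_id 0 doc_id grade` with grades in `{0, 1, 2}` (not
#' relevant / partially relevant / definitely relevant). Unjudged documents
#' are simply absent and are scored as grade 0.
#'
#' @param path qrels file path.
#' @return object of class `qrels`: named list `topic_id -> named integer
#'   vector of grades by doc_id`.
#' @export
read_qrels <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]]
    if (length(parts) != 4L) stop("malformed qrels line ", i, ": expected 4 fields")
    grade <- suppressWarnings(as.integer(parts[4L]))
    if (is.na(grade) || !(grade %in% 0:2)) {
      stop("malformed qrels line ", i, ": grade must be 0, 1 or 2")
    }
    out[[parts[1L]]] <- c(out[[parts[1L]]], setNames(grade, parts[3L]))
  }
  structure(out, class = "qrels")
}

#' Write qrels
#'
#' @param qrels a [read_qrels()]-style object or plain named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qrels <- function(qrels, path) {
  lines <- unlist(lapply(names(qrels), function(tid) {
    g <- qrels[[tid]]
    sprintf("%s 0 %s %d", tid, names(g), as.integer(g))
  }))
  writeLines(lines %||% character(), path)
  invisible(path)
}

#' Write ranked lists in TREC run format
#'
#' One line per entry: `topic_id Q0 doc_id rank score tag`, ranks starting
#' at 1 per topic.
#'
#' @param runs a [ranked_list()] or list of them.
#' @param tag run tag string.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run <- function(runs, tag, path) {
  if (inherits(runs, "ranked_list")) runs <- list(runs)
  lines <- unlist(lapply(runs, function(rl) {
    n <- nrow(rl$entries)
    if (n == 0L) return(character())
    sprintf("%s Q0 %s %d %.6f %s", rl$topic_id, rl$entries$doc_id, seq_len(n),
            rl$entries$score, tag)
  }))
  writeLines(lines %||% character(), path)
  invisible(path)
}

#' Read a TREC run file
#'
#' @param path run file path.
#' @return list of [ranked_list()] objects in file order of topics;
#'   entry order follows the rank column.
#' @export
read_run <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) != 6L)
  if (length(bad)) stop("malformed run line ", bad[1L], ": expected 6 fields")
  topic_ids <- vapply(parts, `[`, character(1), 1L)
  out <- list()
  for (tid in unique(topic_ids)) {
    rows <- parts[topic_ids == tid]
    rank <- as.integer(vapply(rows, `[`, character(1), 4L))
    ord <- order(rank)
    out[[tid]] <- ranked_list(
      tid,
      vapply(rows, `[`, character(1), 3L)[ord],
      as.numeric(vapply(rows, `[`, character(1), 5L))[ord],
      sorted = FALSE
    )
  }
  out
}

topic_grades <- function(ranking, qrels) {
  g <- qrels[[ranking$topic_id]]
  if (is.null(g)) stop("topic absent from qrels: ", ranking$topic_id)
  got <- g[ranking$entries$doc_id]
  got[is.na(got)] <- 0L # unjudged counts as not relevant
  as.integer(got)
}

#' Precision at rank k
#'
#' Fraction of the top `k` ranked documents with grade >= 1. Rankings
#' shorter than `k` count the missing slots as non-relevant.
#'
#' @param ranking a [ranked_list()].
#' @param qrels a [read_qrels()] object.
#' @param k cutoff rank (>= 1).
#' @return value in `[0, 1]`.
#' @export
precision_at_k <- function(ranking, qrels, k = 10L) {
  stopifnot(k >= 1L)
  grades <- topic_grades(ranking, qrels)
  sum(head(grades, k) >= 1L) / k
}

#' R-precision
#'
#' Precision at rank R, where R is the topic's number of relevant
#' (grade >= 1) documents in the qrels. Topics with no relevant document
#' return `NA` with a warning (excluded from averages).
#'
#' @inheritParams precision_at_k
#' @return value in `[0, 1]`, or `NA` when R = 0.
#' @export
r_precision <- function(ranking, qrels) {
  g <- qrels[[ranking$topic_id]]
  if (is.null(g)) stop("topic absent from qrels: ", ranking$topic_id)
  R <- sum(g >= 1L)
  if (R == 0L) {
    warning("topic ", ranking$topic_id, " has no relevant documents; skipped")
    return(NA_real_)
  }
  grades <- topic_grades(ranking, qrels)
  sum(head(grades, R) >= 1L) / R
}

#' Normalized discounted cumulative gain
#'
#' `DCG = sum_{i<=depth} (2^g_i - 1)/log2(i + 1)`, normalized by the ideal
#' DCG obtained from the topic's qrels grades sorted descending. Returns 0
#' when the ideal DCG is 0.
#'
#' @inheritParams precision_at_k
#' @param depth evaluation depth (default 1000, the track's list size).
#' @return value in `[0, 1]`.
#' @export
ndcg <- function(ranking, qrels, depth = 1000L) {
  stopifnot(depth >= 1L)
  grades <- head(topic_grades(ranking, qrels), depth)
  dcg <- sum((2^grades - 1) / log2(seq_along(grades) + 1))
  ideal <- head(sort(qrels[[ranking$topic_id]], decreasing = TRUE), depth)
  idcg <- sum((2^ideal - 1) / log2(seq_along(ideal) + 1))
  if (idcg == 0) return(0)
  dcg / idcg
}

#' Evaluate runs over all topics
#'
#' @param runs list of [ranked_list()] objects.
#' @param qrels a [read_qrels()] object.
#' @param k P@k cutoff.
#' @param depth NDCG depth.
#' @return object of class `metrics_report`: data frame of per-topic
#'   `p10`, `rprec`, `ndcg` plus a `means` attribute of unweighted means
#'   (R-precision `NA`s excluded).
#' @export
evaluate_runs <- function(runs, qrels, k = 10L, depth = 1000L) {
  per <- do.call(rbind, lapply(runs, function(rl) {
    data.frame(
      topic_id = rl$topic_id,
      p10 = precision_at_k(rl, qrels, k),
      rprec = suppressWarnings(r_precision(rl, qrels)),
      ndcg = ndcg(rl, qrels, depth),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per) <- NULL
  means <- c(
    p10 = mean(per$p10),
    rprec = mean(per$rprec, na.rm = TRUE),
    ndcg = mean(per$ndcg)
  )
  structure(per, means = means, class = c("metrics_report", "data.frame"))
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- attr(x, "means")
  cat(sprintf("<metrics_report> %d topics | mean P@10 %.4f, R-prec %.4f, NDCG %.4f\n",
              nrow(x), m[["p10"]], m[["rprec"]], m[["ndcg"]]))
  print(as.data.frame(x))
  invisible(x)
}
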