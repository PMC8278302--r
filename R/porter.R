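#' Porter stemmer
#'
#' Reduces English words to stems with the classic Porter (1980) suffix
#' stripping algorithm: five ordered rule steps gated by the "measure" of the
#' remaining stem (its number of vowel-consonant sequences). Words of one or
#' two letters are returned unchanged, as are tokens containing characters
#' outside `a-z` (reserved tokens such as entity IDs are kept in an uppercase
#' namespace precisely so they pass through untouched).
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of stems, same length as `tokens`.
#' @examples
#' porter_stem(c("caresses", "relational", "sky"))
#' @export
porter_stem <- function(tokens) {
  stopifnot(is.character(tokens))
  vapply(tokens, porter_stem_one, character(1), USE.NAMES = FALSE)
}

porter_stem_one <- function(word) {
  if (nchar(word) <= 2L || grepl("[^a-z]", word)) {
    return(word)
  }
  w <- strsplit(word, "", fixed = TRUE)[[1L]]
  w <- pt_step1a(w)
  w <- pt_step1b(w)
  w <- pt_step1c(w)
  w <- pt_step2(w)
  w <- pt_step3(w)
  w <- pt_step4(w)
  w <- pt_step5(w)
  paste(w, collapse = "")
}

pt_vowels <- c("a", "e", "i", "o", "u")

# y is a consonant at word start or after a vowel-position consonant
pt_is_cons <- function(w, i) {
  l <- w[i]
  if (l %in% pt_vowels) return(FALSE)
  if (l == "y") {
    if (i == 1L) return(TRUE)
    return(!pt_is_cons(w, i - 1L))
  }
  TRUE
}

# m in the [C](VC)^m[V] decomposition
pt_measure <- function(w) {
  n <- length(w)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) pt_is_cons(w, i), logical(1))
  m <- 0L
  prev <- TRUE # leading consonants ignored
  for (i in seq_len(n)) {
    if (prev && !types[i]) {
      prev <- FALSE # entered a vowel run
    } else if (!prev && types[i]) {
      m <- m + 1L # completed a VC
      prev <- TRUE
    }
  }
  m
}

pt_has_vowel <- function(w) {
  n <- length(w)
  if (n == 0L) return(FALSE)
  any(!vapply(seq_len(n), function(i) pt_is_cons(w, i), logical(1)))
}

pt_double_cons <- function(w) {
  n <- length(w)
  n >= 2L && w[n] == w[n - 1L] && pt_is_cons(w, n)
}

# consonant-vowel-consonant ending where the final consonant is not w, x or y
pt_cvc <- function(w) {
  n <- length(w)
  n >= 3L &&
    pt_is_cons(w, n) && !pt_is_cons(w, n - 1L) && pt_is_cons(w, n - 2L) &&
    !(w[n] %in% c("w", "x", "y"))
}

pt_ends <- function(w, suffix) {
  s <- strsplit(suffix, "", fixed = TRUE)[[1L]]
  n <- length(w)
  k <- length(s)
  n >= k && all(w[(n - k + 1L):n] == s)
}

pt_drop <- function(w, k) w[seq_len(length(w) - k)]

pt_set_suffix <- function(w, old, new) {
  stem <- pt_drop(w, nchar(old))
  c(stem, strsplit(new, "", fixed = TRUE)[[1L]])
}

pt_step1a <- function(w) {
  if (pt_ends(w, "sses")) return(pt_set_suffix(w, "sses", "ss"))
  if (pt_ends(w, "ies")) return(pt_set_suffix(w, "ies", "i"))
  if (pt_ends(w, "ss")) return(w)
  if (pt_ends(w, "s")) return(pt_drop(w, 1L))
  w
}

pt_step1b <- function(w) {
  if (pt_ends(w, "eed")) {
    if (pt_measure(pt_drop(w, 3L)) > 0L) w <- pt_drop(w, 1L)
    return(w)
  }
  stripped <- FALSE
  if (pt_ends(w, "ed") && pt_has_vowel(pt_drop(w, 2L))) {
    w <- pt_drop(w, 2L)
    stripped <- TRUE
  } else if (pt_ends(w, "ing") && pt_has_vowel(pt_drop(w, 3L))) {
    w <- pt_drop(w, 3L)
    stripped <- TRUE
  }
  if (stripped) {
    if (pt_ends(w, "at") || pt_ends(w, "bl") || pt_ends(w, "iz")) {
      w <- c(w, "e")
    } else if (pt_double_cons(w) && !(w[length(w)] %in% c("l", "s", "z"))) {
      w <- pt_drop(w, 1L)
    } else if (pt_measure(w) == 1L && pt_cvc(w)) {
      w <- c(w, "e")
    }
  }
  w
}

pt_step1c <- function(w) {
  if (pt_ends(w, "y") && pt_has_vowel(pt_drop(w, 1L))) {
    w[length(w)] <- "i"
  }
  w
}

pt_step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
  c("iviti", "ive"), c("biliti", "ble")
)

pt_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

# longest matching suffix wins; its condition is then final for the step
pt_apply_rules <- function(w, rules, min_measure) {
  lens <- vapply(rules, function(r) nchar(r[[1L]]), numeric(1))
  for (r in rules[order(lens, decreasing = TRUE)]) {
    if (pt_ends(w, r[[1L]])) {
      if (pt_measure(pt_drop(w, nchar(r[[1L]]))) > min_measure) {
        w <- pt_set_suffix(w, r[[1L]], r[[2L]])
      }
      return(w)
    }
  }
  w
}

pt_step2 <- function(w) pt_apply_rules(w, pt_step2_rules, 0L)
pt_step3 <- function(w) pt_apply_rules(w, pt_step3_rules, 0L)

pt_step4_suffixes <- c(
  "ement", "ance", "ence", "able", "ible", "ment", "ion", "ant", "ent",
  "ism", "ate", "iti", "ous", "ive", "ize", "al", "er", "ic", "ou"
)

pt_step4 <- function(w) {
  for (s in pt_step4_suffixes[order(nchar(pt_step4_suffixes), decreasing = TRUE)]) {
    if (pt_ends(w, s)) {
      stem <- pt_drop(w, nchar(s))
      ok <- pt_measure(stem) > 1L
      if (s == "ion") {
        ok <- ok && length(stem) > 0L && stem[length(stem)] %in% c("s", "t")
      }
      if (ok) w <- stem
      return(w)
    }
  }
  w
}

pt_step5 <- function(w) {
  if (pt_ends(w, "e")) {
    stem <- pt_drop(w, 1L)
    m <- pt_measure(stem)
    if (m > 1L || (m == 1L && !pt_cvc(stem))) w <- stem
  }
  if (pt_measure(w) > 1L && pt_double_cons(w) && w[length(w)] == "l") {
    w <- pt_drop(w, 1L)
  }
  w
}
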