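# Classic Porter (1980) suffix-stripping stemmer.
#
# Operates on a single lowercase token. Words of length <= 2 are returned
# unchanged, as in the reference implementation. Within each step the
# longest matching suffix is selected, its condition tested once, and the
# step ends whether or not the rule fired (no fall-through to shorter
# suffixes) — this reproduces the reference behaviour, e.g.
# "rational" is untouched by step 2 (m = 0 stem) and only step 4 strips
# "-al".

porter_is_cons <- function(w, i) {
  ch <- w[[i]]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_is_cons(w, i - 1L))
  }
  TRUE
}

# m = number of VC sequences in [C](VC)^m[V]
porter_measure <- function(w) {
  n <- length(w)
  if (n == 0L) return(0L)
  cv <- vapply(seq_len(n), function(i) porter_is_cons(w, i), TRUE)
  runs <- rle(cv)$values
  # count vowel-run followed by consonant-run transitions
  if (length(runs) < 2L) return(0L)
  sum(!runs[-length(runs)] & runs[-1])
}

porter_has_vowel <- function(w) {
  n <- length(w)
  n > 0L && any(!vapply(seq_len(n), function(i) porter_is_cons(w, i), TRUE))
}

porter_double_cons <- function(w) {
  n <- length(w)
  n >= 2L && w[[n]] == w[[n - 1L]] && porter_is_cons(w, n)
}

# *o: stem ends cvc where the final c is not w, x or y
porter_cvc <- function(w) {
  n <- length(w)
  n >= 3L &&
    porter_is_cons(w, n - 2L) && !porter_is_cons(w, n - 1L) &&
    porter_is_cons(w, n) && !(w[[n]] %in% c("w", "x", "y"))
}

porter_ends <- function(w, suffix) {
  s <- strsplit(suffix, "", fixed = TRUE)[[1L]]
  n <- length(w)
  k <- length(s)
  n > k && identical(w[(n - k + 1L):n], s)
}

porter_trim <- function(w, k) w[seq_len(length(w) - k)]

# Apply the longest matching rule of a (suffix -> replacement) table,
# guarded by m(stem) > min_m. Returns the (possibly unchanged) word.
porter_rule_table <- function(w, rules, min_m) {
  ord <- order(-nchar(names(rules)))
  for (suffix in names(rules)[ord]) {
    if (porter_ends(w, suffix)) {
      stem <- porter_trim(w, nchar(suffix))
      if (porter_measure(stem) > min_m) {
        repl <- rules[[suffix]]
        w <- if (nzchar(repl)) c(stem, strsplit(repl, "", fixed = TRUE)[[1L]]) else stem
      }
      return(w)
    }
  }
  w
}

porter_step1 <- function(w) {
  # 1a
  if (porter_ends(w, "sses")) {
    w <- porter_trim(w, 2L)
  } else if (porter_ends(w, "ies")) {
    w <- porter_trim(w, 2L)
  } else if (!porter_ends(w, "ss") && porter_ends(w, "s")) {
    w <- porter_trim(w, 1L)
  }
  # 1b
  fired <- FALSE
  if (porter_ends(w, "eed")) {
    if (porter_measure(porter_trim(w, 3L)) > 0L) w <- porter_trim(w, 1L)
  } else if (porter_ends(w, "ed") && porter_has_vowel(porter_trim(w, 2L))) {
    w <- porter_trim(w, 2L); fired <- TRUE
  } else if (porter_ends(w, "ing") && porter_has_vowel(porter_trim(w, 3L))) {
    w <- porter_trim(w, 3L); fired <- TRUE
  }
  if (fired) {
    if (porter_ends(w, "at") || porter_ends(w, "bl") || porter_ends(w, "iz")) {
      w <- c(w, "e")
    } else if (porter_double_cons(w) && !(w[[length(w)]] %in% c("l", "s", "z"))) {
      w <- porter_trim(w, 1L)
    } else if (porter_measure(w) == 1L && porter_cvc(w)) {
      w <- c(w, "e")
    }
  }
  # 1c
  if (porter_ends(w, "y") && porter_has_vowel(porter_trim(w, 1L))) {
    w[[length(w)]] <- "i"
  }
  w
}

porter_step2_rules <- c(
  ational = "ate", tional = "tion", enci = "ence", anci = "ance",
  izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
  ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
  alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
  aliti = "al", iviti = "ive", biliti = "ble"
)

porter_step3_rules <- c(
  icate = "ic", ative = "", alize = "al", iciti = "ic",
  ical = "ic", ful = "", ness = ""
)

porter_step4_suffixes <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

porter_step4 <- function(w) {
  ord <- order(-nchar(porter_step4_suffixes))
  for (suffix in porter_step4_suffixes[ord]) {
    if (porter_ends(w, suffix)) {
      stem <- porter_trim(w, nchar(suffix))
      ok <- porter_measure(stem) > 1L
      if (suffix == "ion") {
        ok <- ok && length(stem) > 0L && stem[[length(stem)]] %in% c("s", "t")
      }
      if (ok) w <- stem
      return(w)
    }
  }
  w
}

porter_step5 <- function(w) {
  # 5a
  if (porter_ends(w, "e")) {
    stem <- porter_trim(w, 1L)
    m <- porter_measure(stem)
    if (m > 1L || (m == 1L && !porter_cvc(stem))) w <- stem
  }
  # 5b
  if (porter_measure(w) > 1L && porter_double_cons(w) && w[[length(w)]] == "l") {
    w <- porter_trim(w, 1L)
  }
  w
}

#' Porter stem of a lowercase token
#'
#' The classic Porter (1980) suffix-stripping algorithm, e.g.
#' `"caresses"` to `"caress"`, `"ponies"` to `"poni"`, `"relational"` to
#' `"relat"`. Tokens of one or two characters are returned unchanged.
#'
#' @param token A single lowercase token.
#' @return The stem, a character scalar.
#' @export
porter_stem <- function(token) {
  if (nchar(token) <= 2L) return(token)
  w <- strsplit(token, "", fixed = TRUE)[[1L]]
  w <- porter_step1(w)
  w <- porter_rule_table(w, porter_step2_rules, 0L)
  w <- porter_rule_table(w, porter_step3_rules, 0L)
  w <- porter_step4(w)
  w <- porter_step5(w)
  paste(w, collapse = "")
}

# vectorized stemming with per-call memoisation over unique tokens
stem_tokens <- function(tokens) {
  if (!length(tokens)) return(character())
  u <- unique(tokens)
  stems <- vapply(u, porter_stem, "", USE.NAMES = FALSE)
  stems[match(tokens, u)]
}
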