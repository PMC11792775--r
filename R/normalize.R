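# Token normalization shared by loaders, lexicons and the document scorer.

# Irregular English noun plurals the suffix rules below cannot reach.
.irregular_nouns <- c(
  men = "man", women = "woman", children = "child", feet = "foot",
  teeth = "tooth", mice = "mouse", geese = "goose", lice = "louse",
  oxen = "ox", people = "person"
)

#' Rule-based English noun lemmatizer
#'
#' Reduces regular English noun plurals to their singular lemma with an
#' ordered set of suffix rules (an irregular-plural table, then
#' \code{-ies -> -y}, \code{-sses/-ches/-shes/-xes/-zes -> es} stripped,
#' \code{-ves -> -f}, then a final \code{-s} stripped), leaving words ending
#' in \code{-ss}, \code{-us} or \code{-is} untouched. Purely deterministic:
#' no dictionary lookup is performed, so derived forms outside these rules
#' pass through unchanged.
#'
#' @param x character vector of lowercase tokens.
#' @return character vector of lemmas, same length as \code{x}.
#' @examples
#' lemmatize_noun(c("cigarettes", "churches", "glasses", "bad"))
#' @export
lemmatize_noun <- function(x) {
  out <- x
  irr <- match(out, names(.irregular_nouns))
  hit <- !is.na(irr)
  out[hit] <- .irregular_nouns[irr[hit]]

  todo <- !hit & nchar(out) > 3 & endsWith(out, "s") &
    !endsWith(out, "ss") & !endsWith(out, "us") & !endsWith(out, "is")

  ies <- todo & grepl("ies$", out) & nchar(out) > 4
  out[ies] <- sub("ies$", "y", out[ies])
  todo <- todo & !ies

  es <- todo & grepl("(ss|ch|sh|x|z)es$", out)
  out[es] <- sub("es$", "", out[es])
  todo <- todo & !es

  ves <- todo & grepl("ves$", out) & nchar(out) > 4
  out[ves] <- sub("ves$", "f", out[ves])
  todo <- todo & !ves

  out[todo] <- sub("s$", "", out[todo])
  out
}

#' Normalize a raw response or cue token
#'
#' Lowercases, trims surrounding whitespace and collapses internal runs of
#' whitespace to a single space. With \code{lemmatize = TRUE} (the default),
#' single-word tokens are additionally noun-lemmatized via
#' \code{\link{lemmatize_noun}}; multi-word responses are kept as a single
#' token with internal spaces and are not lemmatized, so they match lexicons
#' as whole strings. An empty result signals a droppable token.
#'
#' @param x character vector of raw tokens.
#' @param lemmatize logical; apply the noun lemmatizer (disable for
#'   non-English data).
#' @return character vector of normalized tokens.
#' @examples
#' normalize_token(c("Cigarettes", "  Smoke ", "bad"))
#' @export
normalize_token <- function(x, lemmatize = TRUE) {
  out <- tolower(trimws(as.character(x)))
  out <- gsub("[[:space:]]+", " ", out)
  if (lemmatize) {
    single <- !grepl(" ", out, fixed = TRUE) & nzchar(out)
    out[single] <- lemmatize_noun(out[single])
  }
  out
}

# Lowercase word tokens of a free-text document, in order of occurrence.
tokenize_text <- function(text, lemmatize = TRUE) {
  toks <- unlist(strsplit(tolower(text), "[^[:alpha:]']+"), use.names = FALSE)
  toks <- toks[nzchar(toks)]
  toks <- gsub("^'+|'+$", "", toks)
  toks <- toks[nzchar(toks)]
  if (lemmatize) toks <- lemmatize_noun(toks)
  toks
}
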