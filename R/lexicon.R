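# Moral / emotion lexicons with literal and prefix-wildcard entries.

#' The five moral foundations
#' @export
moral_foundations <- c("care", "fairness", "loyalty", "authority", "sanctity")

#' Construct a lexicon
#'
#' A lexicon is a set of lowercase word patterns, each either a literal token
#' or a prefix wildcard ending in \code{*} (the Moral Foundations Dictionary
#' distributes stems such as \code{kill*}). Literal entries are normalized
#' like responses (including lemmatization) so they align with normalized
#' data; wildcard stems are lowercased and trimmed but never lemmatized.
#' Entries may carry a foundation label (care, fairness, loyalty, authority,
#' sanctity, or general) and a polarity (virtue, vice, none).
#'
#' @param words character vector of patterns.
#' @param foundation optional character vector of foundation labels, recycled
#'   against \code{words}.
#' @param polarity optional character vector of polarity labels.
#' @param name lexicon name, kept for printing and sub-lexicon bookkeeping.
#' @param lemmatize logical; lemmatize literal entries (default \code{TRUE}).
#' @return an object of class \code{moral_lexicon}.
#' @export
moral_lexicon <- function(words, foundation = NULL, polarity = NULL,
                          name = "lexicon", lemmatize = TRUE) {
  words <- as.character(words)
  if (!length(words)) stop_empty("lexicon has no entries")
  if (any(grepl("\\*.", words)))
    stop_format("wildcard '*' is only allowed at the end of a pattern")
  is_wild <- endsWith(words, "*")
  pat <- character(length(words))
  pat[is_wild] <- paste0(
    gsub("[[:space:]]+", " ", tolower(trimws(sub("\\*$", "", words[is_wild])))), "*")
  pat[!is_wild] <- normalize_token(words[!is_wild], lemmatize = lemmatize)
  keep <- nzchar(sub("\\*$", "", pat))
  pat <- pat[keep]
  if (!length(pat)) stop_empty("lexicon has no non-empty entries")

  entries <- data.frame(
    pattern = pat,
    foundation = if (is.null(foundation)) NA_character_
                 else rep_len(tolower(as.character(foundation)), length(words))[keep],
    polarity = if (is.null(polarity)) NA_character_
               else rep_len(tolower(as.character(polarity)), length(words))[keep],
    stringsAsFactors = FALSE
  )
  entries <- entries[!duplicated(entries$pattern), , drop = FALSE]  # set semantics
  entries <- entries[order(entries$pattern), , drop = FALSE]
  rownames(entries) <- NULL
  structure(
    list(name = name, entries = entries,
         literals = entries$pattern[!endsWith(entries$pattern, "*")],
         stems = sub("\\*$", "", entries$pattern[endsWith(entries$pattern, "*")]),
         labeled = !all(is.na(entries$foundation))),
    class = "moral_lexicon"
  )
}

#' Read a lexicon file
#'
#' Reads a CSV with a \code{word} column and optional \code{foundation} and
#' \code{polarity} columns; lines starting with \code{#} are comments.
#' Duplicate patterns collapse to a single entry.
#'
#' @param path path to the CSV file.
#' @param name lexicon name; defaults to the file name.
#' @param lemmatize logical; lemmatize literal entries.
#' @return a \code{moral_lexicon}.
#' @export
read_lexicon <- function(path, name = basename(path), lemmatize = TRUE) {
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         comment.char = "#", fileEncoding = "UTF-8",
                         blank.lines.skip = TRUE)
  if (!"word" %in% names(raw)) stop_format("lexicon file must have a 'word' column")
  if (nrow(raw) == 0L) stop_empty(sprintf("lexicon '%s' is empty", path))
  moral_lexicon(raw$word,
                foundation = if ("foundation" %in% names(raw)) raw$foundation,
                polarity = if ("polarity" %in% names(raw)) raw$polarity,
                name = name, lemmatize = lemmatize)
}

#' Match normalized tokens against a lexicon
#'
#' A token matches if it equals a literal pattern or starts with the stem of
#' a wildcard pattern (\code{"killer"} matches \code{kill*}; \code{"skill"}
#' does not). Pure and vectorized; for wildcard-free lexicons this is set
#' membership.
#'
#' @param tokens character vector of normalized tokens.
#' @param lex a \code{moral_lexicon}.
#' @return logical vector, one element per token.
#' @export
lex_match <- function(tokens, lex) {
  stopifnot(inherits(lex, "moral_lexicon"))
  hit <- tokens %in% lex$literals
  for (s in lex$stems) hit <- hit | startsWith(tokens, s)
  hit
}

#' Restrict a lexicon to one moral foundation
#'
#' Keeps the entries labeled with foundation \code{f} (virtue and vice
#' alike). The source lexicon must carry foundation labels, and the
#' restriction must be non-empty.
#'
#' @param lex a labeled \code{moral_lexicon}.
#' @param f one of \code{\link{moral_foundations}} (or another label present
#'   in the lexicon, e.g. \code{"general"}).
#' @return a \code{moral_lexicon} named \code{"<name>:<f>"}.
#' @export
foundation_sublexicon <- function(lex, f) {
  stopifnot(inherits(lex, "moral_lexicon"))
  if (!lex$labeled)
    stop_moralassoc("lexicon carries no foundation labels",
                    "moralassoc_unlabeled_error")
  f <- tolower(f)
  sub <- lex$entries[!is.na(lex$entries$foundation) & lex$entries$foundation == f, ,
                     drop = FALSE]
  if (nrow(sub) == 0L)
    stop_empty(sprintf("foundation '%s' has no entries in lexicon '%s'", f, lex$name))
  moral_lexicon(sub$pattern, foundation = sub$foundation, polarity = sub$polarity,
                name = paste(lex$name, f, sep = ":"), lemmatize = FALSE)
}

#' @export
print.moral_lexicon <- function(x, ...) {
  cat(sprintf("Lexicon '%s': %d patterns (%d literal, %d wildcard)%s\n",
              x$name, nrow(x$entries), length(x$literals), length(x$stems),
              if (x$labeled) paste0("; foundations: ",
                paste(sort(unique(stats::na.omit(x$entries$foundation))),
                      collapse = ", "))
              else ""))
  invisible(x)
}
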