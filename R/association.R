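# Word-association data: loading, indexing, and per-cue response graphs.

#' Default missing-response sentinels
#'
#' Responses that normalize (case-insensitively) to one of these strings are
#' treated as missing and dropped by the loaders. SWOW-style exports mark
#' exhausted or unknown responses this way.
#' @export
missing_sentinels <- c("na", "", "unknown word", "no more responses")

# Construct the indexed dataset from a normalized record data frame.
new_assoc_data <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("participant", "cue", "response", "position") %in% names(records)))
  records <- records[order(records$cue, records$participant, records$position), ,
                     drop = FALSE]
  rownames(records) <- NULL
  key <- paste(records$cue, records$response, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  counts <- data.frame(
    cue      = vapply(parts, `[`, "", 1L),
    response = vapply(parts, `[`, "", 2L),
    n        = as.integer(tab),
    stringsAsFactors = FALSE
  )
  counts <- counts[order(counts$cue, counts$response), , drop = FALSE]
  rownames(counts) <- NULL
  structure(
    list(records = records, counts = counts, cues = sort(unique(records$cue))),
    class = "assoc_data"
  )
}

#' @export
print.assoc_data <- function(x, ...) {
  cat(sprintf("Word-association dataset: %d records, %d cues, %d distinct responses\n",
              nrow(x$records), length(x$cues), length(unique(x$counts$response))))
  invisible(x)
}

#' Read word-association data
#'
#' Reads participant-level cue/response records from a delimited text file in
#' either long format (one row per participant x cue x response; columns
#' \code{participant}, \code{cue}, \code{response}) or SWOW-style wide format
#' (columns \code{participant}, \code{cue}, \code{R1}, \code{R2}, \code{R3},
#' one row per participant x cue with up to three response slots). Cues and
#' responses are normalized via \code{\link{normalize_token}}; rows whose
#' response normalizes to the empty string or to a missing sentinel are
#' dropped. Lines starting with \code{#} are ignored. The two formats are
#' equivalent: a wide file and its long-format expansion yield the same
#' dataset.
#'
#' @param path path to a UTF-8 delimited text file with a header row.
#' @param format \code{"long"} or \code{"wide"}.
#' @param delimiter field delimiter (default tab).
#' @param lemmatize logical passed to \code{\link{normalize_token}}.
#' @param sentinels character vector of missing-response markers
#'   (case-insensitive), defaulting to \code{\link{missing_sentinels}}.
#' @return an object of class \code{assoc_data}: the retained records, the
#'   cue-by-response count table (the word-association matrix A in sparse
#'   triplet form) and the ordered cue set.
#' @export
read_associations <- function(path, format = c("long", "wide"), delimiter = "\t",
                              lemmatize = TRUE, sentinels = missing_sentinels) {
  format <- match.arg(format)
  raw <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           colClasses = "character", comment.char = "#",
                           fileEncoding = "UTF-8", check.names = FALSE,
                           quote = "", blank.lines.skip = TRUE)
  need <- if (format == "long") c("participant", "cue", "response")
          else c("participant", "cue", "R1", "R2", "R3")
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop_format(sprintf("missing required column(s): %s", paste(absent, collapse = ", ")))
  if (nrow(raw) == 0L)
    stop_empty(sprintf("no data rows in '%s'", path))

  if (format == "long") {
    long <- data.frame(participant = raw$participant, cue = raw$cue,
                       response = raw$response, position = 1L,
                       stringsAsFactors = FALSE)
  } else {
    long <- do.call(rbind, lapply(1:3, function(i) {
      data.frame(participant = raw$participant, cue = raw$cue,
                 response = raw[[paste0("R", i)]], position = i,
                 stringsAsFactors = FALSE)
    }))
  }

  # Sentinel test happens on the lowercased raw string, before lemmatization,
  # so "Unknown word" is caught whole.
  pre <- gsub("[[:space:]]+", " ", tolower(trimws(long$response)))
  keep <- !(pre %in% tolower(sentinels)) & !is.na(long$response)
  long <- long[keep, , drop = FALSE]
  long$cue <- normalize_token(long$cue, lemmatize = lemmatize)
  long$response <- normalize_token(long$response, lemmatize = lemmatize)
  long <- long[nzchar(long$response) & nzchar(long$cue), , drop = FALSE]
  if (nrow(long) == 0L)
    stop_empty(sprintf("no retained records in '%s' after normalization", path))
  new_assoc_data(long)
}

#' Write association records as canonical long TSV
#'
#' Emits the participant-level records of an \code{assoc_data} object as a
#' tab-delimited long-format file (columns \code{participant}, \code{cue},
#' \code{response}) that round-trips through \code{\link{read_associations}}.
#'
#' @param d an \code{assoc_data} object.
#' @param path output file path.
#' @param comment optional character vector written as leading \code{#} lines
#'   (provenance such as a generator seed).
#' @return \code{path}, invisibly.
#' @export
write_associations <- function(d, path, comment = NULL) {
  stopifnot(inherits(d, "assoc_data"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(d$records[c("participant", "cue", "response")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Named integer vector of response counts A[cue, ] for one cue.
response_counts <- function(d, cue) {
  stopifnot(inherits(d, "assoc_data"))
  if (!cue %in% d$cues) stop_missing_cue(cue)
  sub <- d$counts[d$counts$cue == cue, , drop = FALSE]
  stats::setNames(sub$n, sub$response)
}

#' Per-cue response co-occurrence graph
#'
#' Builds the undirected weighted graph over one cue's response words in
#' which the weight of edge \{a, b\} is the number of participants who gave
#' both a and b as responses to that cue. A participant contributes one unit
#' to every unordered pair of their distinct responses; repeating the same
#' response yields no self-edge, and participants with a single distinct
#' response leave their node isolated.
#'
#' @param d an \code{assoc_data} object.
#' @param cue a cue present in \code{d$cues}.
#' @return an object of class \code{response_graph}: the node set (the cue's
#'   distinct responses, sorted), the symmetric integer weight matrix
#'   \code{W} with zero diagonal, the number of contributing participants,
#'   and a logical \code{isolated} flag per node.
#' @export
response_graph <- function(d, cue) {
  stopifnot(inherits(d, "assoc_data"))
  if (!cue %in% d$cues) stop_missing_cue(cue)
  rec <- d$records[d$records$cue == cue, , drop = FALSE]
  nodes <- sort(unique(rec$response))
  n <- length(nodes)
  W <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  by_part <- split(rec$response, rec$participant)
  for (resp in by_part) {
    u <- unique(resp)
    if (length(u) < 2L) next
    idx <- match(u, nodes)
    pairs <- utils::combn(idx, 2L)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      W[a, b] <- W[a, b] + 1L
      W[b, a] <- W[b, a] + 1L
    }
  }
  structure(
    list(cue = cue, nodes = nodes, W = W,
         participant_count = length(by_part),
         isolated = rowSums(W) == 0),
    class = "response_graph"
  )
}

#' @export
print.response_graph <- function(x, ...) {
  cat(sprintf("Response co-occurrence graph for '%s': %d nodes, %d edges, %d participants\n",
              x$cue, length(x$nodes), sum(x$W[upper.tri(x$W)] > 0),
              x$participant_count))
  invisible(x)
}
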