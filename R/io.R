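#' Mention I/O
#'
#' Mentions travel as JSONL (one JSON object per line) or TSV with identical
#' columns: article_id, database, accession, source, zone, sentence_index,
#' span start/end, validated.
#'
#' @name mention-io
NULL

MENTION_COLS <- c("article_id", "database", "accession", "source", "zone",
                  "sentence_index", "start", "end", "validated")

coerce_mentions <- function(x) {
  for (col in MENTION_COLS) {
    if (!col %in% names(x)) {
      x[[col]] <- switch(col,
                         sentence_index = , start = , end = NA_integer_,
                         validated = NA,
                         NA_character_)
    }
  }
  x
}

#' Write mentions as JSONL
#'
#' @param mentions mention tibble.
#' @param path output file.
#' @export
write_mentions_jsonl <- function(mentions, path) {
  mentions <- coerce_mentions(mentions)[, MENTION_COLS]
  lines <- vapply(seq_len(nrow(mentions)), function(i) {
    as.character(jsonlite::toJSON(as.list(mentions[i, ]), auto_unbox = TRUE,
                                  na = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read mentions from JSONL
#'
#' @param path JSONL file.
#' @return mention tibble.
#' @export
read_mentions_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_mentions())
  rows <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    o[vapply(o, is.null, logical(1))] <- NA
    tibble::as_tibble(o)
  })
  out <- dplyr::bind_rows(rows)
  out$sentence_index <- as.integer(out$sentence_index)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$validated <- as.logical(out$validated)
  out
}

#' Write mentions as TSV
#'
#' @param mentions mention tibble.
#' @param path output file.
#' @export
write_mentions_tsv <- function(mentions, path) {
  mentions <- coerce_mentions(mentions)[, MENTION_COLS]
  utils::write.table(mentions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read mentions from TSV
#'
#' @param path TSV file.
#' @return mention tibble.
#' @export
read_mentions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  tibble::as_tibble(df)
}
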