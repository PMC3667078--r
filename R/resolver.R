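#' Whitelist-backed accession validation
#'
#' The final step of the annotation pipeline checks each candidate accession
#' against its database: a candidate not found there is removed, which is
#' what gives the pipeline its engineered high precision. Here the database
#' is represented by a whitelist -- an exact-membership lookup loaded from a
#' TSV file -- presenting the same pure lookup contract a live database
#' client would. (This also reproduces the documented RefSeq behaviour: a
#' RefSeq identifier shaped like a nucleotide accession is absent from an ENA
#' whitelist and is therefore discarded.)
#'
#' @name resolver
NULL

#' Construct a whitelist from in-memory data
#'
#' @param x either a named list (database -> character vector of accessions)
#'   or a data frame with columns `database` and `accession`.
#' @param path provenance label.
#' @return object of class `whitelist`.
#' @export
as_whitelist <- function(x, path = NA_character_) {
  if (is.data.frame(x)) {
    x <- split(x$accession, x$database)
  }
  if (!all(names(x) %in% database_ids())) {
    stop("unknown database label(s): ",
         paste(setdiff(names(x), database_ids()), collapse = ", "))
  }
  entries <- lapply(x, function(a) sort(unique(normalize_accession(a))))
  structure(list(entries = entries, path = path, loaded_at = Sys.time()),
            class = "whitelist")
}

#' Load a whitelist TSV
#'
#' Format: one `<database>\\t<accession>` row per line; lines starting with
#' `#` are comments; duplicate rows collapse. Unknown database labels and
#' malformed rows are load errors naming the offending line.
#'
#' @param path TSV file.
#' @return object of class `whitelist`.
#' @export
load_whitelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  entries <- list()
  for (j in seq_along(parts)) {
    p <- trimws(parts[[j]])
    p <- p[nzchar(p)]
    if (length(p) != 2) {
      stop("malformed whitelist row at line ", idx[j], " of ", path, call. = FALSE)
    }
    if (!p[1] %in% database_ids()) {
      stop("unknown database label '", p[1], "' at line ", idx[j], " of ", path,
           call. = FALSE)
    }
    entries[[p[1]]] <- c(entries[[p[1]]], normalize_accession(p[2]))
  }
  wl <- as_whitelist(entries, path = path)
  message("loaded whitelist ", path, ": ",
          paste(names(wl$entries), vapply(wl$entries, length, integer(1)),
                sep = "=", collapse = ", "))
  wl
}

#' Exact whitelist membership
#'
#' @param wl a `whitelist`.
#' @param database database name.
#' @param accession normalized accession string (vectorized).
#' @return logical vector.
#' @export
wl_contains <- function(wl, database, accession) {
  stopifnot(inherits(wl, "whitelist"))
  accession %in% (wl$entries[[database]] %||% character())
}

#' @export
print.whitelist <- function(x, ...) {
  cat("<whitelist>", if (!is.na(x$path)) x$path else "(in-memory)", "\n")
  for (db in names(x$entries)) {
    cat("  ", db, ": ", length(x$entries[[db]]), " accessions\n", sep = "")
  }
  invisible(x)
}

#' Sizes of a whitelist
#'
#' @param wl a `whitelist`.
#' @return named integer vector of per-database entry counts.
#' @export
wl_sizes <- function(wl) {
  vapply(wl$entries, length, integer(1))
}
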