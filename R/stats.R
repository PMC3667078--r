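#' Corpus-level citation analytics
#'
#' Reporting operations over mention and link sets: Venn-style overlap of
#' publisher-supplied versus text-mined citations (and of article-to-database
#' versus database-to-article links), the fraction of annotated articles,
#' per-year citation totals and averages, citations per database record, and
#' per-journal mark-up efficacy.
#'
#' @name corpus-stats
NULL

#' Set overlap under a matching key
#'
#' @param a,b data frames carrying the `key` columns (mention sets or link
#'   tables).
#' @param key matching key; `c("database", "accession")` gives
#'   accession-level semantics, the default
#'   `c("database", "accession", "article_id")` pair-level semantics.
#' @return object of class `overlap_report`: counts `only_a`, `only_b`,
#'   `both`, and the key description.
#' @export
overlap <- function(a, b, key = c("database", "accession", "article_id")) {
  ka <- unique(mention_keys(a, key))
  kb <- unique(mention_keys(b, key))
  both <- length(intersect(ka, kb))
  structure(list(
    only_a = length(ka) - both,
    only_b = length(kb) - both,
    both = both,
    key = paste(key, collapse = ",")
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report key=(", x$key, ")> only_a=", x$only_a,
      " both=", x$both, " only_b=", x$only_b,
      " union=", x$only_a + x$both + x$only_b, "\n", sep = "")
  invisible(x)
}

#' Percentage of annotated articles
#'
#' @param n_annotated,n_total counts, `n_annotated <= n_total`, `n_total > 0`.
#' @return percentage rounded half-up to two decimals (e.g. 2.26).
#' @export
annotated_fraction <- function(n_annotated, n_total) {
  if (n_total <= 0) stop("undefined: n_total must be positive")
  if (n_annotated > n_total) stop("n_annotated exceeds n_total")
  round_half_up(100 * n_annotated / n_total, 2)
}

#' Per-year citation statistics
#'
#' For each year and database: the total number of mentions and the mean
#' number per citing article (articles with at least one mention of that
#' database that year; the mean is undefined when no article cites). Years
#' span the full range observed in `articles`; articles without a year are
#' excluded. An incomplete final year can be dropped with `exclude_years`.
#'
#' @param articles metadata tibble with `article_id` and `year`
#'   (see [corpus_metadata()]).
#' @param mentions mention tibble.
#' @param exclude_years years to drop (e.g. an incomplete final year).
#' @return tibble: `year`, `database`, `total_citations`,
#'   `n_articles_with_citations`, `mean_citations_per_citing_article`.
#' @export
per_year_stats <- function(articles, mentions, exclude_years = integer()) {
  arts <- articles[!is.na(articles$year), c("article_id", "year")]
  m <- dplyr::inner_join(mentions, arts, by = "article_id")
  dbs <- sort(unique(mentions$database))
  years <- setdiff(seq(min(arts$year), max(arts$year)), exclude_years)
  grid <- expand.grid(year = years, database = dbs,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  agg <- dplyr::summarise(
    dplyr::group_by(m, .data$year, .data$database),
    total_citations = dplyr::n(),
    n_articles_with_citations = dplyr::n_distinct(.data$article_id),
    .groups = "drop")
  out <- dplyr::left_join(tibble::as_tibble(grid), agg,
                          by = c("year", "database"))
  out$total_citations[is.na(out$total_citations)] <- 0L
  out$n_articles_with_citations[is.na(out$n_articles_with_citations)] <- 0L
  out$mean_citations_per_citing_article <- ifelse(
    out$n_articles_with_citations > 0,
    out$total_citations / out$n_articles_with_citations, NA_real_)
  out[order(out$database, out$year), , drop = FALSE]
}

#' Citations per database record
#'
#' The number of accession citations relative to the size of the source
#' database, at the reported precision (2 significant figures by default,
#' which accommodates rates spanning orders of magnitude, e.g. 0.46 for a
#' structure archive and 0.0006 for a nucleotide archive; pass `digits` for
#' fixed-decimal rounding instead).
#'
#' @param total_annotations mention count (publisher + mined superset).
#' @param database_size number of records in the database; must be positive.
#' @param digits optional fixed number of decimals (half-up).
#' @return rate.
#' @export
citations_per_record <- function(total_annotations, database_size, digits = NULL) {
  if (database_size <= 0) stop("undefined: database_size must be positive")
  r <- total_annotations / database_size
  if (is.null(digits)) signif(r, 2) else round_half_up(r, digits)
}

#' Read a link table
#'
#' Format: `<database>\\t<accession>\\t<article_id>\\t<direction>` per line,
#' `#` comments allowed; direction is `article_to_db` or `db_to_article`.
#'
#' @param path TSV file.
#' @return tibble of link records.
#' @export
load_link_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("database", "accession", "article_id",
                                        "direction"))
  bad <- setdiff(unique(df$direction), c("article_to_db", "db_to_article"))
  if (length(bad)) stop("unknown link direction(s): ", paste(bad, collapse = ", "))
  df$accession <- normalize_accession(df$accession)
  tibble::as_tibble(df)
}

#' Per-journal mark-up efficacy
#'
#' For each journal: article counts, publisher-annotated article counts, and
#' the fraction of the publisher-plus-mined citation superset that carries
#' publisher mark-up. Journals split into bands: `high` (above the
#' `high_threshold`, default 98%), `zero` (no publisher tags despite mined
#' citations), `partial` in between, `none` when the journal has no
#' citations at all.
#'
#' @param articles metadata tibble with `article_id` and `journal`.
#' @param publisher,mined mention tibbles.
#' @param high_threshold fraction above which a journal counts as fully
#'   annotating.
#' @return tibble: `journal`, `n_articles`, `n_publisher_annotated_articles`,
#'   `publisher_fraction_pct`, `band`.
#' @export
per_journal_report <- function(articles, publisher, mined,
                               high_threshold = 0.98) {
  key <- c("database", "accession", "article_id")
  j <- articles[, c("article_id", "journal")]
  pub <- dplyr::inner_join(publisher, j, by = "article_id")
  min_ <- dplyr::inner_join(mined, j, by = "article_id")
  rows <- lapply(sort(unique(j$journal)), function(jn) {
    ids <- j$article_id[j$journal == jn]
    p <- pub[pub$journal == jn, , drop = FALSE]
    m <- min_[min_$journal == jn, , drop = FALSE]
    kp <- unique(mention_keys(p, key))
    sup <- unique(c(kp, mention_keys(m, key)))
    frac <- if (length(sup)) length(kp) / length(sup) else NA_real_
    band <- if (!length(sup)) {
      "none"
    } else if (frac > high_threshold) {
      "high"
    } else if (frac == 0) {
      "zero"
    } else {
      "partial"
    }
    tibble::tibble(
      journal = jn,
      n_articles = length(unique(ids)),
      n_publisher_annotated_articles = length(unique(p$article_id)),
      publisher_fraction_pct = if (is.na(frac)) NA_real_ else round_half_up(100 * frac, 2),
      band = band)
  })
  dplyr::bind_rows(rows)
}
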