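#' Evaluation against a gold standard
#'
#' Mined mentions are scored against gold mentions (publisher-supplied
#' structured citations, or synthetic ground truth) as unique
#' (article, database, accession) tuples: TP are tuples found by both, FP
#' mined-only, FN gold-only. Precision, recall and F-score follow the usual
#' definitions, with undefined values (zero denominators) reported
#' explicitly as `NA`, never silently as zero. A manual adjudication pass can
#' reassign verified false positives as true positives, reproducing the
#' automatic-to-manual assessment transition.
#'
#' @name evaluation
NULL

#' Confusion counts
#'
#' @param tp,fp,fn non-negative counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP=", x$tp, " FP=", x$fp, " FN=", x$fn, "\n", sep = "")
  invisible(x)
}

mention_keys <- function(x, key) {
  if (!nrow(x)) return(character())
  do.call(paste, c(lapply(key, function(k) x[[k]]), sep = "\r"))
}

#' Compare mined mentions to a gold standard
#'
#' @param mined,gold mention tibbles (need the `key` columns).
#' @param key matching key; default unique
#'   (article_id, database, accession) tuples.
#' @param mode `"unique"` counts distinct key tuples; `"occurrence"` counts
#'   multiset occurrences (multiplicities matched pairwise).
#' @return [confusion_counts()].
#' @export
compare_to_gold <- function(mined, gold,
                            key = c("article_id", "database", "accession"),
                            mode = c("unique", "occurrence")) {
  mode <- match.arg(mode)
  km <- mention_keys(mined, key)
  kg <- mention_keys(gold, key)
  if (mode == "unique") {
    km <- unique(km); kg <- unique(kg)
    tp <- length(intersect(km, kg))
    confusion_counts(tp, length(km) - tp, length(kg) - tp)
  } else {
    tm <- table(km); tg <- table(kg)
    shared <- intersect(names(tm), names(tg))
    tp <- sum(pmin(tm[shared], tg[shared]))
    confusion_counts(tp, sum(tm) - tp, sum(tg) - tp)
  }
}

#' Precision, recall and F-score from confusion counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F = 2PR/(P+R). A zero denominator makes
#' the metric undefined (`NA`); F is undefined unless both P and R are
#' defined, and is 0 when P + R = 0.
#'
#' @param counts a [confusion_counts()].
#' @return object of class `metrics_report` with fields `precision`,
#'   `recall`, `f_score` (fractions in \[0,1\] or `NA`).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  p <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp) else NA_real_
  r <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else NA_real_
  f <- if (is.na(p) || is.na(r)) {
    NA_real_
  } else if (p + r == 0) {
    0
  } else {
    2 * p * r / (p + r)
  }
  structure(list(precision = p, recall = r, f_score = f),
            class = "metrics_report")
}

#' Format a metrics report as two-decimal percentages
#'
#' Percentages are rounded half-up to two decimals, matching the published
#' presentation (e.g. "97.45%"); undefined metrics print as "undefined".
#'
#' @param m a `metrics_report`.
#' @return named character vector.
#' @export
format_metrics <- function(m) {
  fmt <- function(x) {
    if (is.na(x)) "undefined" else sprintf("%.2f%%", round_half_up(100 * x, 2))
  }
  c(precision = fmt(m$precision), recall = fmt(m$recall), f_score = fmt(m$f_score))
}

#' @export
print.metrics_report <- function(x, ...) {
  f <- format_metrics(x)
  cat("<metrics_report> P=", f["precision"], " R=", f["recall"],
      " F=", f["f_score"], "\n", sep = "")
  invisible(x)
}

#' Metric percentages as numbers
#'
#' @param counts a [confusion_counts()].
#' @return named numeric vector (`precision_pct`, `recall_pct`,
#'   `f_score_pct`), rounded half-up to two decimals; `NA` when undefined.
#' @export
metrics_pct <- function(counts) {
  m <- compute_metrics(counts)
  v <- c(precision_pct = m$precision, recall_pct = m$recall,
         f_score_pct = m$f_score)
  ifelse(is.na(v), NA_real_, round_half_up(100 * v, 2))
}

#' Apply manual adjudications to an automatic assessment
#'
#' Each false-positive mention re-examined and found correct moves one count
#' from FP to TP; FN is unchanged. TP + FP is conserved.
#'
#' @param counts automatic-assessment [confusion_counts()].
#' @param adjudications data frame with a `verdict` column
#'   (`"true_positive"` / `"false_positive"`), one row per re-examined FP
#'   mention; or an integer number of FPs reassigned as TP.
#' @return adjusted [confusion_counts()].
#' @export
apply_adjudications <- function(counts, adjudications) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- if (is.numeric(adjudications)) {
    as.integer(adjudications)
  } else {
    if (!all(adjudications$verdict %in% c("true_positive", "false_positive"))) {
      stop("verdict must be 'true_positive' or 'false_positive'")
    }
    sum(adjudications$verdict == "true_positive")
  }
  if (n > counts$fp) {
    stop("consistency error: ", n, " true-positive relabels exceed FP count ",
         counts$fp)
  }
  confusion_counts(counts$tp + n, counts$fp - n, counts$fn)
}

#' Evaluate mined mentions per database
#'
#' @param mined,gold mention tibbles.
#' @param databases databases to report (default: those present in either).
#' @param mode see [compare_to_gold()].
#' @return tibble with one row per database: tp, fp, fn, precision_pct,
#'   recall_pct, f_score_pct.
#' @export
evaluate_per_database <- function(mined, gold, databases = NULL,
                                  mode = c("unique", "occurrence")) {
  mode <- match.arg(mode)
  databases <- databases %||% sort(unique(c(mined$database, gold$database)))
  rows <- lapply(databases, function(db) {
    cc <- compare_to_gold(mined[mined$database == db, , drop = FALSE],
                          gold[gold$database == db, , drop = FALSE],
                          mode = mode)
    pm <- metrics_pct(cc)
    tibble::tibble(database = db, tp = cc$tp, fp = cc$fp, fn = cc$fn,
                   precision_pct = pm[["precision_pct"]],
                   recall_pct = pm[["recall_pct"]],
                   f_score_pct = pm[["f_score_pct"]])
  })
  dplyr::bind_rows(rows)
}
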