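#' Three-step accession-number annotation (ANA)
#'
#' Mining proceeds in three steps. (1) Article-level gating: candidate
#' generation only runs in articles whose selected text contains at least one
#' contextual term ("genbank", "pdb", "accession", ...). (2) Sentence-level
#' identification: each sentence's cue words decide which databases' shape
#' grammars are applied; a sentence without cues can inherit the cues of its
#' enclosing paragraph. A token that matches no cued database's shapes but
#' exactly one other enabled database's shapes is "rescued" to that database
#' (this handles stated-source errors such as a UniProt accession cited under
#' a GenBank label). (3) Validation: a candidate becomes a mention only if
#' its database whitelist contains it; everything else is removed, trading
#' recall for precision.
#'
#' @name ana-pipeline
NULL

RANGE_MARKER_RX <- "^\\s*[-–—−‐]\\s*$"

#' Pipeline configuration
#'
#' @param include_footnotes mine footnote-zone sentences as well as body
#'   (default `FALSE`: footnotes live in the back matter, which the pipeline
#'   skips to avoid annotating reference lists).
#' @param expand_ranges expand textual accession ranges
#'   ("EF151088--EF151123") to the full inclusive sequence; default `FALSE`
#'   (endpoints only).
#' @param cue_scope `"sentence-then-paragraph"` (default) falls back to the
#'   enclosing paragraph's cues when a sentence has none;
#'   `"sentence"` is strict same-sentence cueing.
#' @param validation_enabled require whitelist membership (default `TRUE`).
#' @param enabled_databases databases to mine.
#' @return object of class `ana_config`.
#' @export
ana_config <- function(include_footnotes = FALSE,
                       expand_ranges = FALSE,
                       cue_scope = c("sentence-then-paragraph", "sentence"),
                       validation_enabled = TRUE,
                       enabled_databases = database_ids(core_only = TRUE)) {
  cue_scope <- match.arg(cue_scope)
  enabled_databases <- match.arg(enabled_databases, database_ids(),
                                 several.ok = TRUE)
  if (!length(enabled_databases)) stop("enabled_databases must be non-empty")
  structure(list(
    include_footnotes = isTRUE(include_footnotes),
    expand_ranges = isTRUE(expand_ranges),
    cue_scope = cue_scope,
    validation_enabled = isTRUE(validation_enabled),
    enabled_databases = enabled_databases
  ), class = "ana_config")
}

#' Article-level context gate
#'
#' @param article a `jats_article`.
#' @param lexicon a `cue_lexicon`.
#' @param include_footnotes match the sentence selection used for mining.
#' @return `TRUE` iff any article-level term occurs as a whole,
#'   case-insensitive token in the selected sentences. When `FALSE`, the
#'   article yields zero mined mentions.
#' @export
detect_article_context <- function(article, lexicon = default_cues(),
                                   include_footnotes = FALSE) {
  sents <- select_sentences(article, include_footnotes)
  if (!nrow(sents)) return(FALSE)
  has_term(tolower(paste(sents$text, collapse = " ")), lexicon$article_terms)
}

#' Sentence-level cue detection
#'
#' @param sentence sentence text (or a one-row sentence tibble).
#' @param lexicon a `cue_lexicon`.
#' @return character vector: the databases with at least one cue term present
#'   as a whole, case-insensitive token.
#' @export
detect_sentence_context <- function(sentence, lexicon = default_cues()) {
  if (is.data.frame(sentence)) sentence <- sentence$text
  low <- tolower(sentence)
  dbs <- names(lexicon$sentence_cues)
  dbs[vapply(dbs, function(db) has_term(low, lexicon$sentence_cues[[db]]),
             logical(1))]
}

#' Cross-database rescue for shape/cue conflicts
#'
#' Invoked for a token that failed all shapes of its cued database: if the
#' token's shape identifies exactly one other enabled database, the candidate
#' is reassigned there (recorded as rescued); otherwise it is dropped.
#'
#' @param token candidate token.
#' @param cued_db the database suggested by the sentence cue.
#' @param active_dbs enabled databases.
#' @param patterns named list of [pattern_spec()].
#' @return a database name, or `NULL` when no unique alternative matches.
#' @export
rescue_cross_database <- function(token, cued_db, active_dbs,
                                  patterns = default_patterns()) {
  others <- setdiff(active_dbs, cued_db)
  hits <- others[vapply(others, function(db) {
    accession_matches(token, db, patterns[[db]])
  }, logical(1))]
  if (length(hits) == 1) hits else NULL
}

# Candidate tokens of one sentence: which enabled databases each delimited
# token's shape matches.
sentence_token_matches <- function(text, dbs, patterns) {
  per_db <- lapply(dbs, function(db) {
    m <- match_shapes(text, db, patterns[[db]])
    if (nrow(m)) m$database <- db
    m
  })
  dplyr::bind_rows(per_db)
}

#' Run the three-step annotation pipeline on one article
#'
#' @param article a `jats_article`.
#' @param config an [ana_config()].
#' @param lexicon a `cue_lexicon`.
#' @param patterns named list of [pattern_spec()].
#' @param resolver a `whitelist` (required when validation is enabled).
#' @return mention tibble (`article_id`, `database`, `accession`, `source`,
#'   `zone`, `sentence_index`, `start`, `end`, `validated`, `rescued`,
#'   `ambiguous`, `range_expanded`), ordered by sentence index then span
#'   start.
#' @export
annotate_article <- function(article, config = ana_config(),
                             lexicon = default_cues(),
                             patterns = default_patterns(),
                             resolver = NULL) {
  if (config$validation_enabled && !inherits(resolver, "whitelist")) {
    stop("configuration error: validation is enabled but no whitelist resolver was supplied",
         call. = FALSE)
  }
  empty <- empty_mined()
  sents <- select_sentences(article, config$include_footnotes)
  if (!nrow(sents)) return(empty)
  if (!detect_article_context(article, lexicon, config$include_footnotes)) {
    return(empty)
  }

  enabled <- config$enabled_databases
  cue_sets <- lapply(sents$text, function(tx) {
    intersect(detect_sentence_context(tx, lexicon), enabled)
  })
  para_cues <- tapply(cue_sets, sents$paragraph,
                      function(l) unique(unlist(l)), simplify = FALSE)

  out <- list()
  for (i in seq_len(nrow(sents))) {
    cues <- cue_sets[[i]]
    if (!length(cues) && config$cue_scope == "sentence-then-paragraph") {
      cues <- para_cues[[as.character(sents$paragraph[i])]] %||% character()
    }
    if (!length(cues)) next
    text <- sents$text[i]
    matches <- sentence_token_matches(text, enabled, patterns)
    if (!nrow(matches)) next

    cand <- list()
    for (s in unique(matches$start)) {
      tok_rows <- matches[matches$start == s, , drop = FALSE]
      dbs_here <- tok_rows$database
      assigned <- intersect(dbs_here, cues)
      rescued <- FALSE
      if (!length(assigned)) {
        alt <- rescue_cross_database(tok_rows$token[1], cues, enabled, patterns)
        if (is.null(alt) || !alt %in% dbs_here) next
        assigned <- alt
        rescued <- TRUE
      }
      for (db in assigned) {
        cand[[length(cand) + 1L]] <- tibble::tibble(
          database = db, token = tok_rows$token[1],
          start = tok_rows$start[1], end = tok_rows$end[1],
          rescued = rescued, ambiguous = length(assigned) > 1,
          range_expanded = FALSE)
      }
    }
    if (!length(cand)) next
    cand <- dplyr::bind_rows(cand)

    if (config$expand_ranges) {
      cand <- dplyr::bind_rows(cand, expand_sentence_ranges(cand, text))
    }

    cand$accession <- normalize_accession(cand$token)
    if (config$validation_enabled) {
      ok <- vapply(seq_len(nrow(cand)), function(j) {
        wl_contains(resolver, cand$database[j], cand$accession[j])
      }, logical(1))
      cand <- cand[ok, , drop = FALSE]
      cand$validated <- rep(TRUE, nrow(cand))
    } else {
      cand$validated <- rep(FALSE, nrow(cand))
    }
    if (!nrow(cand)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      article_id = article$article_id,
      database = cand$database,
      accession = cand$accession,
      source = "mined",
      zone = sents$zone[i],
      sentence_index = sents$index[i],
      start = cand$start,
      end = cand$end,
      validated = cand$validated,
      rescued = cand$rescued,
      ambiguous = cand$ambiguous,
      range_expanded = cand$range_expanded
    )
  }
  if (!length(out)) return(empty)
  res <- dplyr::bind_rows(out)
  res[order(res$sentence_index, res$start, res$database), , drop = FALSE]
}

# Interior accessions of textual ranges: two same-database shape tokens
# joined by a bare range marker (hyphen/en-dash/em-dash/minus) with no
# intervening word. Endpoints are already candidates; this adds the middles.
expand_sentence_ranges <- function(cand, text) {
  extra <- list()
  for (db in unique(cand$database)) {
    rows <- cand[cand$database == db, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) < 2) next
    for (j in seq_len(nrow(rows) - 1)) {
      gap <- substring(text, rows$end[j] + 1L, rows$start[j + 1])
      if (!grepl(RANGE_MARKER_RX, gap)) next
      seq_all <- tryCatch(
        expand_range(rows$token[j], rows$token[j + 1], db, enabled = TRUE),
        error = function(e) NULL)
      if (is.null(seq_all) || length(seq_all) <= 2) next
      mid <- seq_all[-c(1, length(seq_all))]
      extra[[length(extra) + 1L]] <- tibble::tibble(
        database = db, token = mid,
        start = rows$start[j], end = rows$end[j + 1],
        rescued = FALSE, ambiguous = FALSE, range_expanded = TRUE)
    }
  }
  if (length(extra)) dplyr::bind_rows(extra) else NULL
}

#' Mine a list of articles
#'
#' @param articles list of `jats_article` objects (or a directory / paths,
#'   loaded with [load_corpus()]).
#' @param config,lexicon,patterns,resolver see [annotate_article()].
#' @param verbose log per-article gate decisions and mention counts.
#' @return combined mention tibble.
#' @export
mine_articles <- function(articles, config = ana_config(),
                          lexicon = default_cues(),
                          patterns = default_patterns(),
                          resolver = NULL, verbose = FALSE) {
  if (is.character(articles)) articles <- load_corpus(articles)
  res <- lapply(articles, function(a) {
    m <- annotate_article(a, config, lexicon, patterns, resolver)
    if (verbose) {
      gate <- detect_article_context(a, lexicon, config$include_footnotes)
      message(a$article_id, ": gate=", gate, ", mentions=", nrow(m))
    }
    m
  })
  dplyr::bind_rows(res)
}

empty_mined <- function() {
  tibble::tibble(
    article_id = character(), database = character(), accession = character(),
    source = character(), zone = character(), sentence_index = integer(),
    start = integer(), end = integer(), validated = logical(),
    rescued = logical(), ambiguous = logical(), range_expanded = logical()
  )
}
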