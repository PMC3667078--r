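#' Reading JATS/NLM full-text XML
#'
#' Articles are loaded into a zoned, sentence-segmented in-memory form: a
#' `jats_article` holds the PMC identifier, publication year and journal
#' title from the front matter plus a tibble of sentences, each labelled with
#' its zone (`front`, `body`, `back`, `footnote`, `reference_list`) and its
#' source paragraph. Publisher-supplied structured accession citations are
#' extracted separately from `ext-link` elements.
#'
#' @name jats-corpus
NULL

ZONES <- c("front", "body", "back", "footnote", "reference_list")

#' Corpus-level configuration
#'
#' @param min_year articles published before this year are dropped by
#'   [load_corpus()] (historical articles are rare and noisy for accession
#'   mining).
#' @return list of class `corpus_config`.
#' @export
corpus_config <- function(min_year = 1990) {
  structure(list(min_year = as.integer(min_year)), class = "corpus_config")
}

read_jats_xml <- function(x) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) stop("XML parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (xml2::xml_name(doc) != "article") {
    stop("document rejected: root element is <", xml2::xml_name(doc),
         ">, expected <article>", call. = FALSE)
  }
  doc
}

node_zone <- function(node) {
  if (!is.na(xml2::xml_find_first(node, "ancestor-or-self::fn"))) return("footnote")
  if (xml2::xml_name(node) == "ref" ||
      !is.na(xml2::xml_find_first(node, "ancestor::ref-list"))) {
    return("reference_list")
  }
  if (!is.na(xml2::xml_find_first(node, "ancestor::back"))) return("back")
  if (!is.na(xml2::xml_find_first(node, "ancestor::body"))) return("body")
  "front"
}

#' Load one JATS article
#'
#' Front-matter metadata (PMC id, year, journal) is extracted; body
#' paragraphs (including figure/table captions) are sentence-segmented into
#' the `body` zone; back matter is retained with footnotes labelled
#' `footnote` and reference-list content labelled `reference_list`.
#' A missing publication year produces a warning and `NA` (such articles are
#' mined but excluded from per-year statistics); a missing article id rejects
#' the document.
#'
#' @param x path, URL, literal XML string or raw vector for one JATS article.
#' @param config a [corpus_config()] (kept on the article for provenance).
#' @return object of class `jats_article` with fields `article_id`, `year`,
#'   `journal`, `has_back_matter` and `sentences` (tibble: `article_id`,
#'   `index`, `paragraph`, `text`, `zone`).
#' @export
load_article <- function(x, config = corpus_config()) {
  doc <- read_jats_xml(x)
  id_node <- xml2::xml_find_first(
    doc, "./front/article-meta/article-id[@pub-id-type='pmc' or @pub-id-type='pmcid']")
  article_id <- squish(xml2::xml_text(id_node))
  if (is.na(id_node) || !nzchar(article_id)) {
    stop("document rejected: missing PMC article-id", call. = FALSE)
  }
  if (grepl("^[0-9]+$", article_id)) article_id <- paste0("PMC", article_id)

  year_node <- xml2::xml_find_first(doc, "./front/article-meta/pub-date/year")
  year <- suppressWarnings(as.integer(xml2::xml_text(year_node)))
  if (is.na(year)) {
    warning("article ", article_id,
            ": missing or unparseable publication year; excluded from per-year statistics",
            call. = FALSE)
    year <- NA_integer_
  }
  journal <- squish(xml2::xml_text(
    xml2::xml_find_first(doc, "./front/journal-meta//journal-title")))
  if (!nzchar(journal) || is.na(journal)) journal <- NA_character_

  nodes <- xml2::xml_find_all(doc, paste(
    "./front/article-meta/title-group/article-title",
    "./front/article-meta/abstract//p",
    "./body//p",
    "./back//p[not(ancestor::ref-list)]",
    "./back//ref-list/ref",
    sep = " | "))
  rows <- list()
  for (i in seq_along(nodes)) {
    txt <- squish(xml2::xml_text(nodes[[i]]))
    if (!nzchar(txt)) next
    sents <- segment_sentences(txt)
    if (!length(sents)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      paragraph = i, text = sents, zone = node_zone(nodes[[i]]))
  }
  sentences <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(paragraph = integer(), text = character(), zone = character())
  }
  sentences <- tibble::tibble(
    article_id = rep(article_id, nrow(sentences)),
    index = seq_len(nrow(sentences)),
    paragraph = sentences$paragraph,
    text = sentences$text,
    zone = sentences$zone
  )
  structure(list(
    article_id = article_id,
    year = year,
    journal = journal,
    has_back_matter = !is.na(xml2::xml_find_first(doc, "./back")),
    sentences = sentences,
    config = config
  ), class = "jats_article")
}

#' @export
print.jats_article <- function(x, ...) {
  cat("<jats_article> ", x$article_id,
      " (", ifelse(is.na(x$year), "year NA", x$year), ", ",
      ifelse(is.na(x$journal), "journal NA", x$journal), ")\n",
      "  sentences: ", nrow(x$sentences), " [",
      paste(names(table(x$sentences$zone)), table(x$sentences$zone),
            sep = ":", collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Load a corpus of JATS articles
#'
#' @param paths character vector of XML file paths (or a directory, expanded
#'   to its `*.xml` files, sorted).
#' @param config a [corpus_config()]; articles with a known year below
#'   `min_year` are dropped.
#' @return list of `jats_article` objects.
#' @export
load_corpus <- function(paths, config = corpus_config()) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.xml$", full.names = TRUE))
  }
  arts <- lapply(paths, load_article, config = config)
  keep <- vapply(arts, function(a) is.na(a$year) || a$year >= config$min_year,
                 logical(1))
  arts[keep]
}

#' Corpus metadata table
#'
#' @param articles list of `jats_article` objects.
#' @return tibble with `article_id`, `year`, `journal`, `has_back_matter`.
#' @export
corpus_metadata <- function(articles) {
  tibble::tibble(
    article_id = vapply(articles, `[[`, character(1), "article_id"),
    year = vapply(articles, `[[`, integer(1), "year"),
    journal = vapply(articles, `[[`, character(1), "journal"),
    has_back_matter = vapply(articles, `[[`, logical(1), "has_back_matter")
  )
}

#' Select the sentences eligible for mining
#'
#' The mining pipeline works on body text; reference lists are always
#' excluded (to avoid annotating bibliographies) and footnotes, which live in
#' the back matter, are excluded by default -- the published pipeline's
#' documented source of false negatives.
#'
#' @param article a `jats_article`.
#' @param include_footnotes also return footnote-zone sentences.
#' @return tibble of sentences.
#' @export
select_sentences <- function(article, include_footnotes = FALSE) {
  zones <- if (include_footnotes) c("body", "footnote") else "body"
  article$sentences[article$sentences$zone %in% zones, , drop = FALSE]
}

# Sentence-final abbreviations that must not end a sentence.
ABBREV_GUARD <- c("fig", "figs", "al", "no", "nos", "vs", "cf", "ca",
                  "approx", "dr", "prof", "st", "eq", "eqs", "ref", "refs")

#' Split a paragraph into sentences
#'
#' Rule-based splitter: breaks after runs of sentence-final punctuation
#' followed by a space, guarded by an abbreviation list ("Fig.", "et al.",
#' "no.", "e.g.", "i.e.", ...). Deterministic; conserves non-whitespace
#' characters and never emits an empty sentence.
#'
#' @param text plain-text paragraph (markup already stripped).
#' @return character vector of sentences.
#' @export
segment_sentences <- function(text) {
  text <- squish(text)
  if (!nzchar(text)) return(character())
  m <- gregexpr("[.!?]+(?= )", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(text)
  ends <- as.integer(m) + attr(m, "match.length") - 1L
  guard_rx <- paste0("(?i)(?:\\b(?:", paste(ABBREV_GUARD, collapse = "|"),
                     ")|\\be\\.g|\\bi\\.e)$")
  ok <- vapply(seq_along(ends), function(i) {
    prefix <- substring(text, 1, as.integer(m)[i] - 1L)
    !grepl(guard_rx, prefix, perl = TRUE)
  }, logical(1))
  ends <- ends[ok]
  starts <- c(1L, ends + 1L)
  stops <- c(ends, nchar(text))
  out <- trimws(substring(text, starts, stops))
  out[nzchar(out)]
}

#' Default mapping from `ext-link-type` codes to databases
#'
#' The three codes observed in publisher mark-up are `pdb` (PDB), `gen`
#' (ENA/GenBank) and `spr` (UniProt/Swiss-Prot). Synonym codes (`genbank`,
#' `embl`, `ddbj`, `uniprot`, `swissprot`) are available but disabled by
#' default to mirror the observed vocabulary.
#'
#' @param synonyms also map the synonym codes.
#' @return named character vector: code -> database.
#' @export
default_ext_link_types <- function(synonyms = FALSE) {
  map <- c(pdb = "PDB", gen = "ENA", spr = "UniProt")
  if (synonyms) {
    map <- c(map, genbank = "ENA", embl = "ENA", ddbj = "ENA",
             uniprot = "UniProt", swissprot = "UniProt")
  }
  map
}

#' Extract publisher-supplied structured accession citations
#'
#' One mention per `ext-link` element whose `ext-link-type` is in the type
#' map. The accession is taken from the `xlink:href` attribute, falling back
#' to the element text when the attribute is absent; href/text disagreement
#' is reported with a message (href wins). All zones are covered, including
#' footnotes -- publisher tagging, unlike mining, reaches the back matter.
#' Elements with unmapped type codes are skipped and tallied in the
#' `skipped_types` attribute of the result.
#'
#' @param x path, literal XML string, raw vector or `xml_document`.
#' @param type_map named character vector code -> database
#'   (see [default_ext_link_types()]).
#' @return mention tibble (`article_id`, `database`, `accession`, `source`,
#'   `zone`, `sentence_index`, `start`, `end`, `validated`) with attribute
#'   `skipped_types`.
#' @export
extract_publisher_mentions <- function(x, type_map = default_ext_link_types()) {
  doc <- if (inherits(x, "xml_document")) x else read_jats_xml(x)
  id_node <- xml2::xml_find_first(
    doc, "./front/article-meta/article-id[@pub-id-type='pmc' or @pub-id-type='pmcid']")
  article_id <- squish(xml2::xml_text(id_node))
  if (grepl("^[0-9]+$", article_id)) article_id <- paste0("PMC", article_id)
  links <- xml2::xml_find_all(doc, ".//ext-link[@ext-link-type]")
  skipped <- c()
  rows <- list()
  for (node in links) {
    code <- xml2::xml_attr(node, "ext-link-type")
    if (!code %in% names(type_map)) {
      skipped <- c(skipped, code)
      next
    }
    href <- xml2::xml_attr(node, "xlink:href")
    if (is.na(href)) href <- xml2::xml_attr(node, "href")
    txt <- squish(xml2::xml_text(node))
    acc <- if (!is.na(href) && nzchar(href)) href else txt
    if (!is.na(href) && nzchar(href) && nzchar(txt) &&
        normalize_accession(href) != normalize_accession(txt)) {
      message("ext-link href/text disagreement in ", article_id, ": '",
              href, "' vs '", txt, "' (href wins)")
    }
    if (!nzchar(acc)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      article_id = article_id,
      database = unname(type_map[[code]]),
      accession = normalize_accession(acc),
      source = "publisher",
      zone = node_zone(node),
      sentence_index = NA_integer_,
      start = NA_integer_,
      end = NA_integer_,
      validated = FALSE
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_mentions()
  attr(out, "skipped_types") <- table(skipped)
  out
}

#' Extract publisher mentions from a whole corpus
#'
#' @param paths XML file paths or a directory.
#' @param type_map see [extract_publisher_mentions()].
#' @return combined mention tibble.
#' @export
extract_publisher_corpus <- function(paths, type_map = default_ext_link_types()) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.xml$", full.names = TRUE))
  }
  dplyr::bind_rows(lapply(paths, extract_publisher_mentions, type_map = type_map))
}

empty_mentions <- function() {
  tibble::tibble(
    article_id = character(), database = character(), accession = character(),
    source = character(), zone = character(), sentence_index = integer(),
    start = integer(), end = integer(), validated = logical()
  )
}
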