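#' Deterministic synthetic JATS corpus
#'
#' Generates JATS XML articles with planted accession citations embedded in
#' deposition-statement sentences carrying same-sentence cue words, decoy
#' tokens drawn from the pipeline's false-positive risk surface (calendar
#' years that match the 4-character structure-archive shape, cue-less
#' valid-shaped tokens, cued tokens absent from the whitelist), publisher
#' `ext-link` mark-up for a configurable subset of citations with per-journal
#' tagging policies, and back-matter footnotes and reference lists. The
#' matching whitelist and a ground-truth ledger are emitted alongside, so
#' every pipeline stage can be scored without external data. All randomness
#' flows from the spec's seed; a fixed seed gives byte-identical output.
#'
#' @name synthetic-corpus
NULL

EXT_LINK_CODE <- c(ENA = "gen", PDB = "pdb", UniProt = "spr")

#' Specification of a synthetic corpus
#'
#' Defaults describe a small mixed corpus: nucleotide citations dominate,
#' structures next, proteins least (the ordering observed in real full-text
#' corpora); publisher mark-up covers about half of the planted citations
#' overall; a twentieth of citations sit in footnotes; four journals with
#' high / partial / zero tagging policies.
#'
#' @param n_articles number of articles.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @param per_db_citation_rate named numeric: mean planted citations per
#'   article and database (Poisson).
#' @param publisher_tag_fraction fraction of planted citations wrapped in
#'   `ext-link` mark-up in `partial`-policy journals (policy `high` tags all,
#'   `zero` tags none).
#' @param decoy_rate mean decoy tokens per article (Poisson).
#' @param footnote_fraction fraction of citations placed in footnotes.
#' @param year_range inclusive publication-year range.
#' @param journals data frame with `title` and `policy`
#'   (high / partial / zero), cycled over articles.
#' @param include_back_matter emit back matter (required when
#'   `footnote_fraction > 0`).
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_articles = 50,
                        seed = 1,
                        per_db_citation_rate = c(ENA = 2, PDB = 1.2, UniProt = 0.6),
                        publisher_tag_fraction = 0.5,
                        decoy_rate = 1.5,
                        footnote_fraction = 0.05,
                        year_range = c(1995, 2011),
                        journals = data.frame(
                          title = c("Journal of Synthetic Biology",
                                    "Synthetic Genomics Reports",
                                    "Annals of Synthetic Structures",
                                    "Molecular Data Notes"),
                          policy = c("high", "partial", "zero", "high"),
                          stringsAsFactors = FALSE),
                        include_back_matter = TRUE) {
  stopifnot(n_articles >= 1,
            all(names(per_db_citation_rate) %in% database_ids()),
            all(per_db_citation_rate >= 0),
            publisher_tag_fraction >= 0, publisher_tag_fraction <= 1,
            decoy_rate >= 0,
            footnote_fraction >= 0, footnote_fraction <= 1,
            length(year_range) == 2, year_range[1] <= year_range[2],
            all(journals$policy %in% c("high", "partial", "zero")))
  if (footnote_fraction > 0 && !include_back_matter) {
    stop("generation error: footnote_fraction > 0 requires back matter")
  }
  structure(list(
    n_articles = as.integer(n_articles), seed = as.integer(seed),
    per_db_citation_rate = per_db_citation_rate,
    publisher_tag_fraction = publisher_tag_fraction,
    decoy_rate = decoy_rate,
    footnote_fraction = footnote_fraction,
    year_range = as.integer(year_range),
    journals = journals,
    include_back_matter = isTRUE(include_back_matter)
  ), class = "corpus_spec")
}

#' Sample a shape-valid accession
#'
#' Uniform over the database's shapes, then uniform over the characters of
#' each segment (segment lengths uniform within their bounds). Every sampled
#' string matches the database's grammar by construction.
#'
#' @param database database name.
#' @param patterns named list of [pattern_spec()].
#' @return accession string.
#' @export
sample_accession <- function(database, patterns = default_patterns()) {
  spec <- patterns[[database]]
  if (is.null(spec)) stop("no pattern spec for ", database)
  shape <- spec$shapes[[sample.int(length(spec$shapes), 1)]]
  if (is.character(shape)) {
    stop("cannot sample from a plain-regex shape (database ", database, ")")
  }
  paste(vapply(shape, function(s) {
    n <- s$min + sample.int(s$max - s$min + 1L, 1) - 1L
    if (n == 0) return("")
    paste(s$chars[sample.int(length(s$chars), n, replace = TRUE)], collapse = "")
  }, character(1)), collapse = "")
}

CITE_TEMPLATES <- list(
  ENA = c(
    "The sequences obtained in this study have been deposited in GenBank [GenBank: %s].",
    "All reads were submitted to the EMBL nucleotide archive under accession %s.",
    "The assembled genome is available from DDBJ under %s."),
  PDB = c(
    "The refined coordinates (PDB ID: %s) were used for homology modelling.",
    "Atomic coordinates have been deposited in the PDB under accession %s."),
  UniProt = c(
    "The target protein corresponds to UniProt entry %s.",
    "Orthologues were retrieved from SwissProt (sprot accession %s)."),
  Ensembl = "Gene models were taken from Ensembl (%s).",
  Pfam = "The domain belongs to Pfam family %s.",
  InterPro = "The signature is described by InterPro entry %s.",
  ArrayExpress = "Raw intensities are available from ArrayExpress (%s)."
)

FILLER_SENTENCES <- c(
  "We measured expression levels in all biological replicates.",
  "Samples were incubated overnight at room temperature.",
  "Statistical analysis was carried out with standard methods.",
  "The growth curves were consistent across conditions.",
  "Cultures were maintained on selective media throughout.",
  "Protein concentrations were determined in triplicate.")

pick <- function(x) x[[sample.int(length(x), 1)]]

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# One planted citation or decoy: its visible sentence, its XML form (with
# ext-link mark-up when publisher-tagged), and its ledger row.
plant_citation <- function(db, acc, publisher_tagged, patterns) {
  sent <- sprintf(pick(CITE_TEMPLATES[[db]]), acc)
  xml <- xml_escape(sent)
  if (publisher_tagged && db %in% names(EXT_LINK_CODE)) {
    xml <- sub(acc, sprintf(
      '<ext-link ext-link-type="%s" xlink:href="%s">%s</ext-link>',
      EXT_LINK_CODE[[db]], acc, acc), xml, fixed = TRUE)
  }
  list(sentence = sent, xml = xml)
}

make_decoy <- function(planted_keys, patterns) {
  kind <- pick(c("year", "cueless", "cued_unlisted"))
  if (kind == "year") {
    acc <- as.character(sample(1990:2012, 1))
    for (k in 1:100) {
      if (!paste0("PDB\r", acc) %in% planted_keys) break
      acc <- as.character(sample(1990:2012, 1))
    }
    sent <- sprintf("In %s the PDB archive expanded considerably.", acc)
    return(list(database = "PDB", accession = acc, sentence = sent,
                xml = xml_escape(sent), kind = kind))
  }
  db <- pick(c("ENA", "PDB", "UniProt"))
  acc <- sample_accession(db, patterns)
  for (k in 1:100) {
    if (!paste0(db, "\r", acc) %in% planted_keys) break
    acc <- sample_accession(db, patterns)
  }
  sent <- if (kind == "cueless") {
    sprintf("Strain %s was isolated from the soil samples.", acc)
  } else {
    switch(db,
           ENA = sprintf("A further sequence was archived in EMBL as %s.", acc),
           PDB = sprintf("A related structure is held in the PDB as %s.", acc),
           UniProt = sprintf("A homologue is listed in UniProt as %s.", acc))
  }
  list(database = db, accession = acc, sentence = sent,
       xml = xml_escape(sent), kind = kind)
}

build_article_xml <- function(id, year, journal, body_xml_paras,
                              footnote_xml_paras, include_back_matter) {
  back <- ""
  if (include_back_matter) {
    fns <- if (length(footnote_xml_paras)) {
      paste0("<fn-group>",
             paste0("<fn><p>", footnote_xml_paras, "</p></fn>", collapse = ""),
             "</fn-group>")
    } else ""
    back <- paste0(
      "<back>", fns,
      "<ref-list><ref><mixed-citation>Smith J, Jones K (2004) Standard methods in molecular analysis. J Mol Res 12:34-45.</mixed-citation></ref>",
      "<ref><mixed-citation>Lee H (2006) Comparative genome surveys. Genome Notes 3:1-9.</mixed-citation></ref></ref-list>",
      "</back>")
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<article xmlns:xlink="http://www.w3.org/1999/xlink" article-type="research-article">',
    "<front><journal-meta><journal-title-group><journal-title>",
    xml_escape(journal),
    "</journal-title></journal-title-group></journal-meta>",
    "<article-meta>",
    '<article-id pub-id-type="pmc">', id, "</article-id>",
    "<title-group><article-title>A synthetic study of molecular records</article-title></title-group>",
    "<pub-date><year>", year, "</year></pub-date>",
    "</article-meta></front>",
    "<body><sec><title>Results</title>",
    paste0("<p>", body_xml_paras, "</p>", collapse = ""),
    "</sec></body>",
    back,
    "</article>\n")
}

#' Generate a synthetic corpus
#'
#' Writes `articles/*.xml`, `whitelist.tsv` (every planted non-decoy
#' accession; no decoy) and `truth.tsv` (the ground-truth ledger:
#' article_id, database, accession, zone, publisher_tagged, is_decoy) under
#' `out_dir`.
#'
#' @param spec a [corpus_spec()].
#' @param out_dir output directory (created).
#' @return invisible list: `articles` (paths), `whitelist_path`,
#'   `truth_path`, `truth` (ledger tibble), `spec`.
#' @export
generate_corpus <- function(spec = corpus_spec(), out_dir) {
  stopifnot(inherits(spec, "corpus_spec"))
  dir.create(file.path(out_dir, "articles"), recursive = TRUE, showWarnings = FALSE)
  patterns <- default_patterns()
  local_seed(spec$seed, {
    truth <- list()
    paths <- character(spec$n_articles)
    yrs <- seq(spec$year_range[1], spec$year_range[2])
    # corpus-wide key sets keep whitelist entries and decoys disjoint
    planted_keys <- character()
    decoy_keys <- character()
    for (i in seq_len(spec$n_articles)) {
      id <- sprintf("PMC%07d", 1000000L + i)
      jrow <- spec$journals[((i - 1L) %% nrow(spec$journals)) + 1L, ]
      year <- yrs[sample.int(length(yrs), 1)]

      plan <- list()  # rows: sentence, xml, zone
      for (db in names(spec$per_db_citation_rate)) {
        n_cit <- stats::rpois(1, spec$per_db_citation_rate[[db]])
        if (n_cit == 0) next
        for (k in seq_len(n_cit)) {
          acc <- sample_accession(db, patterns)
          for (r in 1:100) {
            if (!paste0(db, "\r", acc) %in% decoy_keys) break
            acc <- sample_accession(db, patterns)
          }
          zone <- if (stats::runif(1) < spec$footnote_fraction) "footnote" else "body"
          tagged <- switch(jrow$policy,
                           high = TRUE,
                           zero = FALSE,
                           partial = stats::runif(1) < spec$publisher_tag_fraction)
          pc <- plant_citation(db, acc, tagged, patterns)
          plan[[length(plan) + 1L]] <- list(
            sentence = pc$sentence, xml = pc$xml, zone = zone,
            database = db, accession = acc, publisher_tagged = tagged,
            is_decoy = FALSE)
          planted_keys <- c(planted_keys, paste0(db, "\r", acc))
        }
      }
      n_decoy <- stats::rpois(1, spec$decoy_rate)
      for (k in seq_len(n_decoy)) {
        d <- make_decoy(planted_keys, patterns)
        plan[[length(plan) + 1L]] <- list(
          sentence = d$sentence, xml = d$xml, zone = "body",
          database = d$database, accession = d$accession,
          publisher_tagged = FALSE, is_decoy = TRUE)
        decoy_keys <- c(decoy_keys, paste0(d$database, "\r", d$accession))
      }

      body <- Filter(function(p) p$zone == "body", plan)
      foot <- Filter(function(p) p$zone == "footnote", plan)
      filler <- sample(FILLER_SENTENCES, 2 + sample.int(2, 1))
      body_sent_xml <- c(vapply(body, `[[`, character(1), "xml"),
                         xml_escape(filler))
      # group body sentences into paragraphs of up to three
      paras <- split(body_sent_xml,
                     ceiling(seq_along(body_sent_xml) / 3))
      body_paras <- vapply(paras, paste, character(1), collapse = " ")
      foot_paras <- vapply(foot, `[[`, character(1), "xml")

      xmltxt <- build_article_xml(id, year, jrow$title, body_paras, foot_paras,
                                  spec$include_back_matter)
      paths[i] <- file.path(out_dir, "articles", paste0(id, ".xml"))
      writeLines(xmltxt, paths[i], sep = "")

      for (p in plan) {
        truth[[length(truth) + 1L]] <- tibble::tibble(
          article_id = id, database = p$database, accession = p$accession,
          zone = p$zone, publisher_tagged = p$publisher_tagged,
          is_decoy = p$is_decoy, year = year, journal = jrow$title,
          sentence = p$sentence)
      }
    }
    truth <- dplyr::bind_rows(truth)

    wl <- truth[!truth$is_decoy, c("database", "accession")]
    wl <- unique(wl[order(wl$database, wl$accession), ])
    wl_path <- file.path(out_dir, "whitelist.tsv")
    writeLines(c("# synthetic whitelist: every planted (non-decoy) accession",
                 paste(wl$database, wl$accession, sep = "\t")), wl_path)

    truth_path <- file.path(out_dir, "truth.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(list(articles = paths, whitelist_path = wl_path,
                   truth_path = truth_path, truth = truth, spec = spec))
  })
}
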