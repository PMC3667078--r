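# Fixtures are built in code: a minimal JATS article builder and canned
# sentences drawn from real error-analysis cases.

jats_article_xml <- function(id = "PMC0000001",
                             year = "2005",
                             journal = "Test Journal",
                             body_paras = character(),
                             footnote_paras = character(),
                             back = length(footnote_paras) > 0,
                             refs = character(),
                             abstract = NULL) {
  back_xml <- ""
  if (back || length(refs)) {
    fns <- if (length(footnote_paras)) {
      paste0("<fn-group>",
             paste0("<fn><p>", footnote_paras, "</p></fn>", collapse = ""),
             "</fn-group>")
    } else ""
    rl <- if (length(refs)) {
      paste0("<ref-list>",
             paste0("<ref><mixed-citation>", refs, "</mixed-citation></ref>",
                    collapse = ""),
             "</ref-list>")
    } else ""
    back_xml <- paste0("<back>", fns, rl, "</back>")
  }
  abs_xml <- if (!is.null(abstract)) paste0("<abstract><p>", abstract, "</p></abstract>") else ""
  year_xml <- if (!is.null(year)) paste0("<pub-date><year>", year, "</year></pub-date>") else ""
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<article xmlns:xlink="http://www.w3.org/1999/xlink">',
    "<front><journal-meta><journal-title-group><journal-title>", journal,
    "</journal-title></journal-title-group></journal-meta><article-meta>",
    '<article-id pub-id-type="pmc">', id, "</article-id>",
    "<title-group><article-title>A study</article-title></title-group>",
    year_xml, abs_xml,
    "</article-meta></front>",
    "<body>", paste0("<p>", body_paras, "</p>", collapse = ""), "</body>",
    back_xml, "</article>")
}

ext_link <- function(type, acc, text = acc) {
  sprintf('<ext-link ext-link-type="%s" xlink:href="%s">%s</ext-link>',
          type, acc, text)
}

# Sentences quoted from the published error analysis.
SENT_PDB_TEMPLATES <- "Hence in the present study, three templates (PDB IDs:1J4N, 1FX8 and 1RC2-B chain) were chosen for modelling."
SENT_ENA_RANGE <- "Sequences specifically obtained for this study have been deposited in GenBank [GenBank: EF151088–EF151123 and EF153103]."
SENT_SOURCE_CONFLICT <- "Two of the sequences obtained had a high degree of identity to other vertebrate sequences, such as human beta1 [Genbank Q8WUM6]."

mention_df <- function(article_id, database, accession, source = "mined") {
  tibble::tibble(article_id = article_id, database = database,
                 accession = accession, source = source)
}

# Independent oracle: position-by-position shape checker, enumerating the
# possible segment length splits by brute force (never uses the regex path).
oracle_shape_match <- function(token, shape) {
  chars <- strsplit(toupper(token), "")[[1]]
  fits <- function(seg_idx, pos) {
    if (seg_idx > length(shape)) return(pos == length(chars) + 1)
    s <- shape[[seg_idx]]
    for (n in s$min:s$max) {
      if (pos + n - 1 > length(chars)) break
      seg_chars <- if (n == 0) character() else chars[pos:(pos + n - 1)]
      if (all(seg_chars %in% s$chars) && fits(seg_idx + 1, pos + n)) return(TRUE)
    }
    if (s$min == 0 && fits(seg_idx + 1, pos)) return(TRUE)
    FALSE
  }
  fits(1, 1)
}

digest_file <- function(path) unname(tools::md5sum(path))

# integer percentage, half-up
round_trip_pct <- function(num, den) floor(100 * num / den + 0.5)

oracle_db_match <- function(token, spec) {
  any(vapply(spec$shapes, function(sh) oracle_shape_match(token, sh), logical(1)))
}
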