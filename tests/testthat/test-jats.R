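# JATS loading, zoning, sentence segmentation, publisher ext-link extraction.

test_that("a minimal article loads with zoned, ordered sentences", {
  xml <- jats_article_xml(body_paras = "A done. B done.")
  a <- load_article(xml)
  expect_s3_class(a, "jats_article")
  expect_equal(a$article_id, "PMC0000001")
  expect_equal(a$year, 2005L)
  expect_equal(a$journal, "Test Journal")
  body <- a$sentences[a$sentences$zone == "body", ]
  expect_equal(body$text, c("A done.", "B done."))
  expect_equal(a$sentences$index, seq_len(nrow(a$sentences)))
})

test_that("empty body with a back-matter footnote still loads", {
  xml <- jats_article_xml(body_paras = character(),
                          footnote_paras = "Accession CP000155 was used.")
  a <- load_article(xml)
  expect_equal(sum(a$sentences$zone == "body"), 0L)
  expect_true(a$has_back_matter)
  expect_equal(sum(a$sentences$zone == "footnote"), 1L)
})

test_that("reference-list content is zoned reference_list and back matter back", {
  xml <- jats_article_xml(body_paras = "Body text here.",
                          refs = "Author A (2001) A title. J 1:1-10.",
                          back = TRUE)
  a <- load_article(xml)
  expect_true("reference_list" %in% a$sentences$zone)
  expect_false(any(a$sentences$zone == "footnote"))
})

test_that("malformed XML, missing id, and missing year behave as contracted", {
  expect_error(load_article("<article><unclosed></article>"), "XML parse error")
  no_id <- sub('<article-id pub-id-type="pmc">PMC0000001</article-id>', "",
               jats_article_xml(body_paras = "Text here."), fixed = TRUE)
  expect_error(load_article(no_id), "missing PMC article-id")
  no_year <- jats_article_xml(body_paras = "Text here.", year = NULL)
  expect_warning(a <- load_article(no_year), "publication year")
  expect_true(is.na(a$year))
})

test_that("non-article roots are rejected", {
  expect_error(load_article("<book><front/></book>"), "expected <article>")
})

test_that("numeric PMC ids gain the PMC prefix", {
  xml <- jats_article_xml(id = "1312362", body_paras = "Some text here.")
  expect_equal(load_article(xml)$article_id, "PMC1312362")
})

test_that("select_sentences excludes footnotes by default and reference lists always", {
  xml <- jats_article_xml(
    body_paras = c("One. Two. Three."),
    footnote_paras = "A footnote sentence.",
    refs = "Ref A (2000) Title. J 2:1-5.")
  a <- load_article(xml)
  expect_equal(nrow(select_sentences(a, FALSE)), 3L)
  sel <- select_sentences(a, TRUE)
  expect_equal(nrow(sel), 4L)
  expect_false(any(sel$zone == "reference_list"))
  # monotone: footnote selection is a superset
  expect_true(all(select_sentences(a, FALSE)$index %in% sel$index))
})

test_that("sentence segmentation splits on terminal punctuation with abbreviation guards", {
  expect_equal(segment_sentences("A done. B done."), c("A done.", "B done."))
  expect_equal(segment_sentences("See Fig. 2 for details."),
               "See Fig. 2 for details.")
  expect_equal(segment_sentences("As shown by Smith et al. previously."),
               "As shown by Smith et al. previously.")
  expect_equal(segment_sentences("Used e.g. for calibration. Then stored."),
               c("Used e.g. for calibration.", "Then stored."))
  expect_equal(segment_sentences(""), character())
  expect_equal(segment_sentences("No terminal punctuation"),
               "No terminal punctuation")
})

test_that("segmentation conserves non-whitespace characters and emits no empty sentence", {
  set.seed(3)
  words <- c("alpha", "beta", "Gamma", "delta2", "PDB", "X99999", "Fig.", "sample")
  for (rep in 1:200) {
    sent <- paste(sample(words, sample(3:8, 1), replace = TRUE), collapse = " ")
    text <- paste0(sent, ". ", paste(sample(words, 4), collapse = " "), ".")
    segs <- segment_sentences(text)
    expect_true(all(nzchar(segs)))
    expect_equal(gsub("\\s", "", paste(segs, collapse = "")),
                 gsub("\\s", "", text))
  }
})

test_that("publisher ext-link mentions are extracted with the observed type codes", {
  xml <- jats_article_xml(body_paras = paste(
    "The structure", ext_link("pdb", "1EWK"), "was solved.",
    "The sequence", ext_link("gen", "AY762362"), "and protein",
    ext_link("spr", "Q08943"), "were deposited."))
  m <- extract_publisher_mentions(xml)
  expect_equal(nrow(m), 3L)
  expect_setequal(paste(m$database, m$accession),
                  c("PDB 1EWK", "ENA AY762362", "UniProt Q08943"))
  expect_true(all(m$source == "publisher"))
  expect_true(all(!m$validated))
})

test_that("href wins over element text; text is the fallback; unknown types are tallied", {
  xml <- jats_article_xml(body_paras = paste(
    ext_link("pdb", "1EWK", text = "1ABC"), "and",
    '<ext-link ext-link-type="gen">AY762362</ext-link>', "and",
    ext_link("unknowndb", "ZZZ"), "end."))
  expect_message(m <- extract_publisher_mentions(xml), "disagreement")
  expect_setequal(paste(m$database, m$accession),
                  c("PDB 1EWK", "ENA AY762362"))
  sk <- attr(m, "skipped_types")
  expect_equal(unname(sk[["unknowndb"]]), 1L)
})

test_that("publisher extraction reaches footnotes and records the zone", {
  xml <- jats_article_xml(
    body_paras = "Plain body text.",
    footnote_paras = paste("Deposited as", ext_link("gen", "CP000155"),
                           "in GenBank."))
  m <- extract_publisher_mentions(xml)
  expect_equal(m$accession, "CP000155")
  expect_equal(m$zone, "footnote")
})

test_that("synonym ext-link-type codes are available but off by default", {
  xml <- jats_article_xml(body_paras = paste(
    ext_link("genbank", "U49845"), "cited."))
  expect_equal(nrow(extract_publisher_mentions(xml)), 0L)
  m <- extract_publisher_mentions(xml, default_ext_link_types(synonyms = TRUE))
  expect_equal(paste(m$database, m$accession), "ENA U49845")
})

test_that("load_corpus filters pre-1990 articles but keeps unknown years", {
  d <- withr::local_tempdir()
  writeLines(jats_article_xml(id = "PMC1", year = "1985",
                              body_paras = "Old text."),
             file.path(d, "a.xml"))
  writeLines(jats_article_xml(id = "PMC2", year = "2001",
                              body_paras = "New text."),
             file.path(d, "b.xml"))
  arts <- load_corpus(d)
  expect_equal(vapply(arts, `[[`, character(1), "article_id"), "PMC2")
})

test_that("generated synthetic sentences round-trip through the loader", {
  d <- withr::local_tempdir()
  g <- generate_corpus(corpus_spec(n_articles = 6, seed = 5), d)
  arts <- load_corpus(file.path(d, "articles"))
  all_sent <- unlist(lapply(arts, function(a) a$sentences$text))
  for (s in g$truth$sentence) {
    expect_true(s %in% all_sent, label = paste("planted sentence found:", s))
  }
})
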