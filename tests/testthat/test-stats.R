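# Corpus-level reporting: overlaps, fractions, per-year, rates, per-journal.

test_that("overlap counts are set-theoretic under the chosen key", {
  a <- mention_df("A1", "PDB", c("X", "Y"))
  b <- mention_df("A1", "PDB", c("Y", "Z"))
  ov <- overlap(a, b)
  expect_equal(c(ov$only_a, ov$both, ov$only_b), c(1L, 1L, 1L))
  ov2 <- overlap(a, a)
  expect_equal(c(ov2$only_a, ov2$only_b), c(0L, 0L))
  # accession-level vs pair-level keys differ when articles differ
  c1 <- mention_df("A2", "PDB", "X")
  expect_equal(overlap(a, c1, key = c("database", "accession"))$both, 1L)
  expect_equal(overlap(a, c1)$both, 0L)
})

test_that("overlap equals a brute-force membership loop on random sets", {
  set.seed(15)
  for (rep in 1:5) {
    a <- tibble::tibble(database = "ENA",
                        accession = sample(sprintf("K%05d", 1:800), 500),
                        article_id = sample(sprintf("PMC%03d", 1:40), 500,
                                            replace = TRUE))
    b <- tibble::tibble(database = "ENA",
                        accession = sample(sprintf("K%05d", 1:800), 500),
                        article_id = sample(sprintf("PMC%03d", 1:40), 500,
                                            replace = TRUE))
    ov <- overlap(a, b)
    ka <- unique(paste(a$database, a$accession, a$article_id))
    kb <- unique(paste(b$database, b$accession, b$article_id))
    both <- 0L
    for (k in ka) if (k %in% kb) both <- both + 1L
    expect_equal(ov$both, both)
    expect_equal(ov$only_a, length(ka) - both)
    expect_equal(ov$only_b, length(kb) - both)
    # Venn conservation
    expect_equal(ov$only_a + ov$both + ov$only_b, length(union(ka, kb)))
  }
})

test_that("annotated_fraction reproduces printed corpus percentages", {
  expect_equal(annotated_fraction(9268, 410364), 2.26)
  expect_equal(annotated_fraction(21119, 410364), 5.15)
  expect_equal(annotated_fraction(0, 10), 0)
  expect_error(annotated_fraction(1, 0), "undefined")
  expect_error(annotated_fraction(11, 10), "exceeds")
  # monotone in the numerator
  f <- vapply(0:410364, identity, numeric(1))[c(1, 9269, 21120)]
  expect_true(annotated_fraction(9268, 410364) <= annotated_fraction(21119, 410364))
})

test_that("per-year statistics average over citing articles only", {
  arts <- tibble::tibble(article_id = c("A1", "A2", "A3"),
                         year = c(2005L, 2005L, 2006L))
  mentions <- dplyr::bind_rows(
    mention_df("A1", "ENA", c("X1", "X2", "X3")),
    mention_df("A2", "ENA", "Y1"))
  ys <- per_year_stats(arts, mentions)
  r2005 <- ys[ys$year == 2005 & ys$database == "ENA", ]
  expect_equal(r2005$total_citations, 4L)
  expect_equal(r2005$n_articles_with_citations, 2L)
  expect_equal(r2005$mean_citations_per_citing_article, 2)
  r2006 <- ys[ys$year == 2006 & ys$database == "ENA", ]
  expect_equal(r2006$total_citations, 0L)
  expect_true(is.na(r2006$mean_citations_per_citing_article))
  # incomplete final year excluded on request
  ys2 <- per_year_stats(arts, mentions, exclude_years = 2006L)
  expect_false(2006 %in% ys2$year)
})

test_that("per-year totals match the generator's ledger", {
  d <- withr::local_tempdir()
  g <- generate_corpus(corpus_spec(n_articles = 16, seed = 31,
                                   footnote_fraction = 0), d)
  arts <- load_corpus(file.path(d, "articles"))
  wl <- suppressMessages(load_whitelist(g$whitelist_path))
  mined <- mine_articles(arts, resolver = wl)
  ys <- per_year_stats(corpus_metadata(arts), mined)
  truth <- g$truth[!g$truth$is_decoy, ]
  for (db in unique(truth$database)) {
    for (y in unique(truth$year)) {
      want <- sum(truth$database == db & truth$year == y)
      got <- ys$total_citations[ys$year == y & ys$database == db]
      expect_equal(got, want, label = sprintf("%s citations in %d", db, y))
    }
  }
})

test_that("citations per record reproduce the printed rates at printed precision", {
  expect_equal(citations_per_record(39977, 86000), 0.46)
  expect_equal(citations_per_record(160112, 266e6), 0.0006)
  expect_equal(citations_per_record(9430, 540000), 0.017)
  expect_equal(citations_per_record(0, 100), 0)
  expect_equal(citations_per_record(39977, 86000, digits = 2), 0.46)
  expect_error(citations_per_record(5, 0), "undefined")
})

test_that("link tables load and article/database citation overlap is computable", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# links",
               "ENA\tAY762362\tPMC1\tarticle_to_db",
               "ENA\tAY762362\tPMC1\tdb_to_article",
               "ENA\tU49845\tPMC2\tdb_to_article"), f)
  lk <- load_link_table(f)
  a2d <- lk[lk$direction == "article_to_db", ]
  d2a <- lk[lk$direction == "db_to_article", ]
  ov <- overlap(a2d, d2a)
  expect_equal(c(ov$only_a, ov$both, ov$only_b), c(0L, 1L, 1L))
  writeLines("ENA\tX\tPMC1\tsideways", f)
  expect_error(load_link_table(f), "unknown link direction")
})

test_that("per-journal report bands journals by publisher mark-up efficacy", {
  arts <- tibble::tibble(article_id = c("A1", "A2", "A3", "A4"),
                         journal = c("Full", "Full", "None", "Quiet"))
  publisher <- mention_df(c("A1", "A2"), "PDB", c("1AAA", "1BBB"),
                          source = "publisher")
  mined <- dplyr::bind_rows(
    mention_df(c("A1", "A2"), "PDB", c("1AAA", "1BBB")),
    mention_df("A3", "ENA", "AY762362"))
  r <- per_journal_report(arts, publisher, mined)
  expect_equal(r$band[r$journal == "Full"], "high")
  expect_equal(r$publisher_fraction_pct[r$journal == "Full"], 100)
  expect_equal(r$band[r$journal == "None"], "zero")
  expect_equal(r$publisher_fraction_pct[r$journal == "None"], 0)
  expect_equal(r$band[r$journal == "Quiet"], "none")
})

test_that("per-journal rows equal a brute-force recount on a mixed synthetic corpus", {
  d <- withr::local_tempdir()
  g <- generate_corpus(corpus_spec(n_articles = 20, seed = 41), d)
  arts <- load_corpus(file.path(d, "articles"))
  wl <- suppressMessages(load_whitelist(g$whitelist_path))
  meta <- corpus_metadata(arts)
  mined <- mine_articles(arts, resolver = wl)
  publisher <- extract_publisher_corpus(file.path(d, "articles"))
  r <- per_journal_report(meta, publisher, mined)
  for (i in seq_len(nrow(r))) {
    ids <- meta$article_id[meta$journal == r$journal[i]]
    kp <- unique(paste(publisher$database, publisher$accession,
                       publisher$article_id)[publisher$article_id %in% ids])
    km <- unique(paste(mined$database, mined$accession,
                       mined$article_id)[mined$article_id %in% ids])
    sup <- union(kp, km)
    expect_equal(r$n_articles[i], length(ids))
    if (length(sup)) {
      expect_equal(r$publisher_fraction_pct[i],
                   round(100 * length(kp) / length(sup), 2), tolerance = 0.01)
    } else {
      expect_true(is.na(r$publisher_fraction_pct[i]))
    }
  }
  # the zero-policy journal must band zero when it has mined citations
  zero_j <- "Annals of Synthetic Structures"
  if (zero_j %in% r$journal && !is.na(r$publisher_fraction_pct[r$journal == zero_j]) &&
      r$publisher_fraction_pct[r$journal == zero_j] == 0) {
    expect_equal(r$band[r$journal == zero_j], "zero")
  }
})
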