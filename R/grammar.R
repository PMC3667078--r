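#' Accession shape grammars and contextual cue lexicons
#'
#' Each supported database has a small grammar of accession "shapes": a shape
#' is an ordered list of segments, each segment a character class with a
#' bounded repeat count (for example, the ENA shape "2 letters + 6 numerals").
#' Shapes serve two purposes: they compile to regular expressions for
#' matching, and they act as sampling grammars for the synthetic corpus
#' generator. Contextual cues are the lowercase trigger words (for example
#' "genbank", "pdb") whose presence licenses candidate generation for a
#' database at sentence level; the article-level gate uses the union of all
#' cues plus the word "accession".
#'
#' @name accession-grammar
NULL

CORE_DATABASES <- c("ENA", "UniProt", "PDB")
EXTENSION_DATABASES <- c("Ensembl", "Pfam", "InterPro", "ArrayExpress")

#' Supported database identifiers
#'
#' @param core_only if `TRUE`, return only the three databases that publishers
#'   tag with `ext-link` mark-up (ENA, UniProt, PDB).
#' @return character vector of database names (a closed vocabulary).
#' @export
database_ids <- function(core_only = FALSE) {
  if (core_only) CORE_DATABASES else c(CORE_DATABASES, EXTENSION_DATABASES)
}

# A shape segment: a set of allowed characters repeated between min and max
# times. Shapes built from segments are both matchable and sampleable.
seg <- function(chars, min = 1L, max = min) {
  stopifnot(length(chars) >= 1, min >= 0, max >= min)
  list(chars = chars, min = as.integer(min), max = as.integer(max))
}

lit <- function(s) lapply(strsplit(s, "")[[1]], seg)

.LET <- LETTERS
.DIG <- as.character(0:9)
.ALNUM <- c(LETTERS, .DIG)

seg_regex <- function(s) {
  chars <- s$chars
  # literal hyphen must lead the class
  chars <- c(chars[chars == "-"], chars[chars != "-"])
  cls <- if (length(chars) == 1 && grepl("^[A-Za-z0-9]$", chars)) {
    chars
  } else {
    paste0("[", paste(chars, collapse = ""), "]")
  }
  quant <- if (s$min == 1 && s$max == 1) {
    ""
  } else if (s$min == s$max) {
    paste0("{", s$min, "}")
  } else {
    paste0("{", s$min, ",", s$max, "}")
  }
  paste0(cls, quant)
}

#' Compile one shape to a regular expression fragment (no anchors)
#'
#' Shapes loaded from configuration files may already be plain regular
#' expression strings; those pass through unchanged.
#'
#' @param shape a shape (list of segments) or a regular expression string.
#' @return regular expression string.
#' @export
shape_regex <- function(shape) {
  if (is.character(shape)) return(shape)
  paste(vapply(shape, seg_regex, character(1)), collapse = "")
}

#' Construct a pattern specification for one database
#'
#' @param database database name (see [database_ids()]).
#' @param shapes ordered list of shapes; earlier shapes are tried first.
#' @param provenance `"published"` for the published grammar of the core
#'   databases, `"external-guideline"` for shapes taken from public accession
#'   format guidelines.
#' @return object of class `pattern_spec`.
#' @export
pattern_spec <- function(database, shapes, provenance = c("published", "external-guideline")) {
  database <- match.arg(database, database_ids())
  provenance <- match.arg(provenance)
  structure(list(database = database, shapes = shapes, provenance = provenance),
            class = "pattern_spec")
}

#' Default accession shape grammars
#'
#' The core grammars are, verbatim from the published rule set:
#' * ENA: 1 letter + 5 numerals; 2 letters + 6 numerals; 3 letters +
#'   5 numerals; 4 letters + 8--10 numerals; 5 letters + 7 numerals.
#' * UniProt: `[A-N,R-Z][0-9][A-Z][A-Z0-9]{2}[0-9]` and
#'   `[O,P,Q][0-9][A-Z0-9]{3}[0-9]`.
#' * PDB: `[0-9][A-Z0-9]{3}`.
#'
#' Extension-database shapes follow the public format guidelines of each
#' resource (provenance `"external-guideline"`): Pfam `PF` + 5 digits,
#' InterPro `IPR` + 6 digits, ArrayExpress `E-` + 4 letters + `-` + digits,
#' Ensembl `ENS` + up to 3 species letters + one of `G/T/P/E` + 11 digits.
#'
#' @param databases which databases to include (default: all).
#' @return named list of [pattern_spec()] objects.
#' @export
default_patterns <- function(databases = database_ids()) {
  uni_first <- setdiff(.LET, c("O", "P", "Q"))
  all <- list(
    ENA = pattern_spec("ENA", list(
      list(seg(.LET, 1), seg(.DIG, 5)),
      list(seg(.LET, 2), seg(.DIG, 6)),
      list(seg(.LET, 3), seg(.DIG, 5)),
      list(seg(.LET, 4), seg(.DIG, 8, 10)),
      list(seg(.LET, 5), seg(.DIG, 7))
    ), "published"),
    UniProt = pattern_spec("UniProt", list(
      list(seg(uni_first), seg(.DIG), seg(.LET), seg(.ALNUM), seg(.ALNUM), seg(.DIG)),
      list(seg(c("O", "P", "Q")), seg(.DIG), seg(.ALNUM, 3), seg(.DIG))
    ), "published"),
    PDB = pattern_spec("PDB", list(
      list(seg(.DIG), seg(.ALNUM, 3))
    ), "published"),
    Ensembl = pattern_spec("Ensembl", list(
      c(lit("ENS"), list(seg(.LET, 0, 3), seg(c("G", "T", "P", "E")), seg(.DIG, 11)))
    ), "external-guideline"),
    Pfam = pattern_spec("Pfam", list(
      c(lit("PF"), list(seg(.DIG, 5)))
    ), "external-guideline"),
    InterPro = pattern_spec("InterPro", list(
      c(lit("IPR"), list(seg(.DIG, 6)))
    ), "external-guideline"),
    ArrayExpress = pattern_spec("ArrayExpress", list(
      c(lit("E-"), list(seg(.LET, 4)), lit("-"), list(seg(.DIG, 1, 7)))
    ), "external-guideline")
  )
  all[match.arg(databases, names(all), several.ok = TRUE)]
}

pattern_full_rx <- function(spec) {
  paste0("^(?:", paste(vapply(spec$shapes, shape_regex, character(1)),
                       collapse = "|"), ")$")
}

#' Find accession-shaped tokens of one database in a sentence
#'
#' Returns every maximal token that matches one of the database's shapes and
#' is delimited by non-alphanumeric characters or string boundaries on both
#' sides; nothing matches inside a longer alphanumeric token. Matching is
#' performed on an uppercased copy of the text so that lowercased accessions
#' are found, while spans always refer to the original text. Note that
#' decoy-shaped tokens (a calendar year matches the PDB shape) are returned
#' by design: eliminating them is the job of the cue and validation stages,
#' not the shape matcher.
#'
#' @param text sentence string.
#' @param database database name.
#' @param spec a [pattern_spec()]; defaults to the shipped grammar.
#' @return tibble with columns `token`, `start`, `end` (0-based, half-open
#'   character offsets into `text`).
#' @export
match_shapes <- function(text, database, spec = NULL) {
  database <- match.arg(database, database_ids())
  spec <- spec %||% default_patterns(database)[[1]]
  stopifnot(inherits(spec, "pattern_spec"), spec$database == database)
  rx <- bounded_rx(paste(vapply(spec$shapes, shape_regex, character(1)),
                         collapse = "|"))
  m <- gregexpr(rx, toupper(text), perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  len <- attr(m, "match.length")
  tibble::tibble(
    token = substring(text, m, m + len - 1),
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + as.integer(len)
  )
}

#' Does a whole token match a database's shape grammar?
#'
#' @param token candidate string (case-insensitive).
#' @param database database name.
#' @param spec optional [pattern_spec()].
#' @return logical, vectorized over `token`.
#' @export
accession_matches <- function(token, database, spec = NULL) {
  spec <- spec %||% default_patterns(database)[[1]]
  grepl(pattern_full_rx(spec), toupper(token), perl = TRUE)
}

#' Normalize an accession token
#'
#' Uppercases and strips a trailing version suffix (".<digits>");
#' idempotent.
#'
#' @param token accession token.
#' @param database ignored; kept for interface symmetry (normalization is
#'   database-independent).
#' @return normalized accession string, vectorized.
#' @export
normalize_accession <- function(token, database = NULL) {
  sub("\\.[0-9]+$", "", toupper(trimws(token)))
}

#' Expand an accession range
#'
#' Given the two endpoints of a textual range such as
#' "EF151088--EF151123", either return the endpoints only (the published
#' pipeline's behaviour: it does not identify ranges) or the full inclusive
#' arithmetic sequence over the numeral part, zero-padded to the original
#' width.
#'
#' @param start,end range endpoints; must share letter prefix and numeral
#'   width and both match the database's shapes.
#' @param database database name.
#' @param enabled `FALSE` (default) returns `c(start, end)`; `TRUE` expands.
#' @param max_size guard against runaway expansions.
#' @return character vector of normalized accessions.
#' @export
expand_range <- function(start, end, database, enabled = FALSE, max_size = 1e6) {
  start <- normalize_accession(start)
  end <- normalize_accession(end)
  if (!accession_matches(start, database) || !accession_matches(end, database)) {
    stop("range rejected: endpoints do not match ", database, " shapes")
  }
  m1 <- regmatches(start, regexec("^([A-Z-]*?)([0-9]+)$", start))[[1]]
  m2 <- regmatches(end, regexec("^([A-Z-]*?)([0-9]+)$", end))[[1]]
  if (length(m1) != 3 || length(m2) != 3) {
    stop("range rejected: endpoints lack a trailing numeral part")
  }
  if (m1[2] != m2[2]) stop("range rejected: letter prefix mismatch")
  if (nchar(m1[3]) != nchar(m2[3])) stop("range rejected: numeral width mismatch")
  if (!enabled) return(c(start, end))
  s <- as.numeric(m1[3]); e <- as.numeric(m2[3])
  if (e < s) stop("range rejected: end below start")
  if (e - s + 1 > max_size) stop("range rejected: expansion exceeds max_size")
  nums <- formatC(seq(s, e, by = 1), width = nchar(m1[3]), flag = "0",
                  format = "f", digits = 0)
  paste0(m1[2], nums)
}

#' Default contextual cue lexicon
#'
#' Sentence-level cues for the core databases are exactly the published cue
#' vocabulary: ENA \{genbank, gen, ddbj, embl\}; UniProt \{swissprot, sprot,
#' uniprot\}; PDB \{pdb\}. Extension databases carry their own names as cues.
#' The article-level term set is the union of all sentence cues plus
#' "accession".
#'
#' @param include_extensions include cue entries for the extension databases.
#' @return object of class `cue_lexicon` with fields `sentence_cues`
#'   (database -> lowercase terms) and `article_terms`.
#' @export
default_cues <- function(include_extensions = TRUE) {
  sc <- list(
    ENA = c("genbank", "gen", "ddbj", "embl"),
    UniProt = c("swissprot", "sprot", "uniprot"),
    PDB = "pdb"
  )
  if (include_extensions) {
    sc <- c(sc, list(
      Ensembl = "ensembl",
      Pfam = "pfam",
      InterPro = "interpro",
      ArrayExpress = "arrayexpress"
    ))
  }
  cue_lexicon(sc)
}

#' Construct a cue lexicon
#'
#' @param sentence_cues named list: database -> character vector of lowercase
#'   cue terms.
#' @param article_terms optional extra article-level terms; the result always
#'   contains all sentence cues plus "accession".
#' @return object of class `cue_lexicon`.
#' @export
cue_lexicon <- function(sentence_cues, article_terms = character()) {
  stopifnot(all(names(sentence_cues) %in% database_ids()))
  sentence_cues <- lapply(sentence_cues, tolower)
  terms <- sort(unique(c(unlist(sentence_cues, use.names = FALSE),
                         tolower(article_terms), "accession")))
  structure(list(sentence_cues = sentence_cues, article_terms = terms),
            class = "cue_lexicon")
}

#' Load shape grammars and cues from a YAML configuration file
#'
#' The file may contain a `patterns` map (database -> list of regular
#' expression strings, each matching a whole accession) and a `cues` map
#' (database -> list of cue terms). Entries replace the shipped defaults for
#' the listed databases; unlisted databases keep their defaults.
#'
#' @param path YAML file.
#' @return list with elements `patterns` (named list of [pattern_spec()]) and
#'   `cues` (`cue_lexicon`).
#' @export
load_grammar_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  patterns <- default_patterns()
  cues <- default_cues()$sentence_cues
  for (db in names(cfg$patterns %||% list())) {
    if (!db %in% database_ids()) stop("unknown database in config: ", db)
    patterns[[db]] <- pattern_spec(db, as.list(unlist(cfg$patterns[[db]])),
                                   "external-guideline")
  }
  for (db in names(cfg$cues %||% list())) {
    if (!db %in% database_ids()) stop("unknown database in config: ", db)
    cues[[db]] <- tolower(unlist(cfg$cues[[db]]))
  }
  list(patterns = patterns, cues = cue_lexicon(cues))
}
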