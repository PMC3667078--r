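---
title: "Mining accession-number citations: method, parameters and design notes"
author: "accmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining accession-number citations: method, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accmine)
```

## The problem

Molecular-biology databases (the European Nucleotide Archive, UniProt, the
Protein Data Bank) and the journal literature cross-reference each other
through accession numbers: stable record identifiers such as `AY762362`
(a nucleotide entry), `Q08943` (a protein) or `1EWK` (a structure). Some
publishers tag these citations structurally in the article XML with the JATS
`ext-link` element; most citations, however, exist only as plain text. This
package implements a rule-based pipeline that recovers those plain-text
citations from full-text JATS articles with very high precision, plus the
machinery needed to evaluate it and to analyse citation patterns at corpus
level.

## The annotation pipeline

Mining is deliberately conservative and proceeds in three steps:

1. **Article-level gating.** An article is only processed if its selected
   text contains at least one contextual term as a whole, case-insensitive
   token: any database cue word or the word *accession*. An article that
   never mentions any of these cannot cite a record by accession in a way
   the grammar could license, and yields zero mined mentions.

2. **Sentence-level identification.** Each sentence's cue words (ENA:
   *genbank*, *gen*, *ddbj*, *embl*; UniProt: *swissprot*, *sprot*,
   *uniprot*; PDB: *pdb*) decide which databases' shape grammars are applied
   to that sentence. The grammars are per-position character-class patterns:
   for ENA, "1 letter + 5 numerals" through "5 letters + 7 numerals"; for
   UniProt, the two 6-character alphanumeric forms; for PDB, a digit
   followed by three alphanumerics. A candidate must be a whole token,
   delimited by non-alphanumeric characters or string boundaries:
   `(AY762362)` matches, `XAY762362` does not. The shape matcher is
   intentionally permissive — the calendar year `2008` matches the PDB
   shape — because eliminating such decoys is the job of the cue and
   validation stages, which is exactly how the pipeline behaves.

3. **Validation.** Every candidate is looked up in its database; a candidate
   not found is removed. Here the database is a whitelist file standing in
   for a live lookup service, keeping runs deterministic and testable
   offline. Validation is what converts a permissive grammar into a
   high-precision annotator: years, grant codes and figure labels that
   survive the cue gate die here.

Two refinements handle constructs observed in real articles:

* **Cross-database rescue.** Authors sometimes cite an accession under the
  wrong source label (a UniProt accession labelled "Genbank"). When a token
  matches no cued database's shapes but exactly one other enabled database's
  shapes, the candidate is reassigned to that database and flagged
  `rescued`; it must still validate. With more than one alternative the
  candidate is dropped — ambiguity is resolved in favour of precision.

* **Paragraph cue fallback.** Deposition statements often put the cue and
  the accession in adjacent sentences. By default a cue-less sentence
  inherits the union of cues found in its paragraph
  (`cue_scope = "sentence-then-paragraph"`); strict same-sentence cueing is
  available as `cue_scope = "sentence"`.

### Ranges and subchains

Textual ranges ("EF151088–EF151123") are detected as two same-database shape
tokens joined by a bare hyphen-like marker (ASCII hyphen, en/em dash, minus)
with no intervening word. By default only the endpoints are emitted —
matching the published pipeline, which did not identify ranges. With
`expand_ranges = TRUE` the full inclusive sequence over the numeral part is
generated (zero-padded to the original width) and each interior accession is
validated individually. Expansion requires identical letter prefixes and
numeral widths and a non-decreasing range; anything else falls back to the
endpoints. Chain suffixes on structure identifiers ("1RC2-B") are not
consumed: the matcher returns the bare accession `1RC2`, never a token
containing the chain letter.

### Zones

The loader assigns each sentence a zone: `front`, `body`, `footnote`,
`back` or `reference_list`. Mining operates on `body` only by default;
reference lists are always excluded (annotating bibliographies would
produce meaningless citation counts), and footnotes — which demonstrably
contain deposition statements — are opt-in via `include_footnotes`. This
reproduces the documented footnote false-negative class of the original
pipeline, and `include_footnotes = TRUE` is the corresponding fix. Publisher
`ext-link` extraction, by contrast, covers all zones, because publishers do
tag accessions in footnotes. Figure and table captions are treated as body
text; whether the original system did so is not documented, so this choice
is flagged as an assumption.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `include_footnotes` | `FALSE` | mine footnote-zone sentences |
| `expand_ranges` | `FALSE` | expand textual ranges to full sequences |
| `cue_scope` | `sentence-then-paragraph` | cue inheritance for cue-less sentences |
| `validation_enabled` | `TRUE` | require whitelist membership |
| `enabled_databases` | ENA, UniProt, PDB | databases to mine |

Extension databases (Ensembl, Pfam, InterPro, ArrayExpress) ship with
shapes taken from each resource's public accession-format guideline
(provenance `external-guideline`); they can be enabled through
`enabled_databases` and overridden from a YAML file with
`load_grammar_config()`. Publishers do not tag these databases, so they are
excluded from publisher/mined comparisons.

## Evaluation conventions

Mined mentions are scored against a gold standard (publisher tags, or
synthetic ground truth) as unique (article, database, accession) tuples;
an occurrence-level mode exists behind the `mode` argument of
`compare_to_gold()`. The unique-tuple default was chosen because publisher
and mined mark-up can differ in multiplicity for the same citation, which
would otherwise distort counts. Precision, recall and F-score use the
standard formulas; undefined values (zero denominators) are reported as
`NA` explicitly, never silently as zero, and percentages are formatted
half-up at two decimals. `apply_adjudications()` implements the manual
re-assessment protocol: each re-examined false positive found correct moves
one count from FP to TP, conserving TP + FP and leaving FN untouched.

Corpus analytics follow the same key conventions. Overlap reports
(publisher vs mined; article-to-database vs database-to-article links)
default to pair-level keys — (database, accession, article_id) — because
many-to-many database/literature links make accession-level keys ambiguous;
an accession-level key is available via the `key` argument. Per-year
averages are computed over citing articles only, per database, and an
incomplete final year can be excluded. Citations-per-record rates are
reported at two significant figures, which accommodates rates spanning four
orders of magnitude between a structure archive and a nucleotide archive.

## The synthetic corpus

`generate_corpus()` emits JATS articles with planted citations, the matching
whitelist and a ground-truth ledger, so that every stage is testable
without external data. What it emulates: deposition-statement sentences
with same-sentence cues; publisher `ext-link` mark-up with per-journal
policies (journals that tag everything, nothing, or a fraction); footnoted
deposition statements; reference lists; and the pipeline's false-positive
risk surface as decoys — calendar years in PDB-cued sentences, valid-shaped
tokens with no cue, and cued tokens absent from the whitelist.

Defaults, chosen once as a plausible desk-scale miniature: 50 articles;
mean citations per article ENA 2, PDB 1.2, UniProt 0.6 (preserving the
ENA ≫ PDB ≫ UniProt ordering of real corpora); publisher tagging of half
the citations in partially-tagging journals (text mining roughly doubled
publisher-supplied annotation in the motivating study); 1.5 decoys per
article; 5% of citations in footnotes; publication years 1995–2011. Counts
are Poisson; all randomness derives from the spec's seed, and a fixed seed
yields byte-identical files.

What it does *not* emulate — and therefore what passing tests do not show
about real data: linguistic variety beyond a small template bank, OCR
noise, incorrect publisher tags, RefSeq-style identifiers from outside the
whitelisted namespace, and the real corpus's scale. End-to-end tests on
synthetic corpora demonstrate the engineered properties (precision 100%
with a complete whitelist that excludes decoys; recall 100% on cue-complete
body plantings; footnote plantings missed by default and recovered with
`include_footnotes`), not the recall one would obtain on heterogeneous
real text.

## Numerical and degenerate-input choices

* Character spans are 0-based, half-open, over the normalized sentence
  text; matching runs on an uppercased copy so lowercased accessions are
  found while spans index the original text.
* Percentages round half away from zero (with a small representation-error
  fuzz); base R's half-to-even would disagree with printed tables at the
  boundary.
* Range expansion is capped (1e6 elements) as a guard against degenerate
  inputs such as `AAAA00000000–AAAA99999999`.
* Empty articles, empty bodies, cue-less articles, and empty mention sets
  all flow through and produce empty (not error) results; malformed XML,
  missing article ids, unknown whitelist database labels and inconsistent
  adjudications are hard errors.
* Sentence segmentation is a deterministic rule-based splitter with an
  abbreviation guard list ("Fig.", "et al.", "e.g.", ...). It conserves
  non-whitespace characters and never emits an empty sentence; it will
  over-split on unguarded abbreviations, which is acceptable because
  mining is token-based within sentences.
* A token matching the shapes of several cued databases in one sentence is
  emitted under every cued database that validates, flagged `ambiguous`.

## Problem sizes

The shipped tests and the acceptance script use corpora of 10–50 synthetic
articles and whitelists of a few hundred entries; the brute-force oracle
comparisons enumerate all strings of length ≤ 6 over a 4-letter alphabet.
These sizes exercise every code path while keeping a full run in well under
a minute; the pipeline itself is linear in corpus size and has been run
unchanged on the multi-hundred-article corpora the generator can produce.

## Known limitations

* RefSeq identifiers have no grammar of their own; shaped like nucleotide
  accessions they are generated as candidates and (correctly, per the
  whitelist contract) removed at validation.
* The whitelist resolver validates the version-stripped accession; whether
  a live resolver should honour versions is left to implementations of the
  same lookup contract.
* The article-level gate is global (any contextual term opens it for all
  databases), matching the published description read literally; a
  per-database gate would be slightly stricter.
* Per-journal banding uses a fixed >98% threshold for "high"; the boundary
  between "partial" and "zero" is exact zero.
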