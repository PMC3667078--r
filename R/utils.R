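# Internal helpers shared across modules.

# Round half away from zero (the convention used for the printed percentage
# tables); base round() is half-to-even. Small fuzz guards against binary
# representation error at the .xx5 boundary.
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

squish <- function(x) gsub("\\s+", " ", trimws(x))

# Wrap a pattern so it only matches tokens delimited by non-alphanumeric
# characters or string boundaries on both sides.
bounded_rx <- function(rx) {
  paste0("(?<![A-Za-z0-9])(?:", rx, ")(?![A-Za-z0-9])")
}

# Whole-token, case-insensitive alternation over a term list (terms are
# lowercase; apply to lowercased text).
term_rx <- function(terms) {
  esc <- gsub("([][{}()^$.|?*+\\\\-])", "\\\\\\1", terms)
  paste0("(?<![a-z0-9])(?:", paste(esc, collapse = "|"), ")(?![a-z0-9])")
}

has_term <- function(text_lower, terms) {
  grepl(term_rx(terms), text_lower, perl = TRUE)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
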