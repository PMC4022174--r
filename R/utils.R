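# Shared internal helpers: amino-acid alphabet, seeded evaluation, input checks.

# PAML ordering of the 20 standard residues; all JTT data files use it.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded helpers never perturb the
#' caller's random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Split a residue string into a character vector (and back).
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
chars_seq <- function(x) paste0(x, collapse = "")

# TRUE when every character of every string is one of the 20 standard letters
# (gap marker optionally allowed).
is_standard_aa <- function(x, allow_gap = FALSE) {
  alpha <- if (allow_gap) c(AA20, "-") else AA20
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) all(ch %in% alpha), logical(1))
}

assert_standard_aa <- function(x, what = "sequence", allow_gap = FALSE) {
  ok <- is_standard_aa(x, allow_gap = allow_gap)
  if (!all(ok)) {
    bad <- if (!is.null(names(x))) names(x)[!ok][1] else which(!ok)[1]
    stop(sprintf("%s contains non-standard amino-acid characters (first offender: %s)",
                 what, bad), call. = FALSE)
  }
  invisible(TRUE)
}

# Stable, locale-independent character ordering (radix = C locale).
stable_order <- function(x) order(x, method = "radix")

stable_sort <- function(x) sort(x, method = "radix")

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
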