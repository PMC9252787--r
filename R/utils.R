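#' Standard amino-acid alphabet
#'
#' The twenty canonical one-letter amino-acid codes accepted throughout the
#' package (sequence providers, variant parsing, synthetic sequence
#' generation).
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Deterministic 31-bit hash of a character string (polynomial rolling hash).
# Used to derive per-generator RNG substreams and the synthetic embedding
# provider's per-(sequence, layer) seeds. Pure integer arithmetic in doubles,
# so the result is identical across platforms; stays below 2^31.
str_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  mod <- 2147483647  # 2^31 - 1
  for (code in utf8ToInt(x)) {
    h <- (h * 131 + code) %% mod
  }
  as.integer(h)
}

#' Derive a reproducible RNG substream seed
#'
#' All stochastic operations in the package draw their seeds from one global
#' integer seed through this function, so that generators are reproducible yet
#' uncoupled: changing the draw count of one never perturbs another.
#'
#' @param seed Integer master seed.
#' @param stream Character tag naming the substream (e.g. `"couplings"`).
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) %% 65536 * 32749 + str_hash(stream)) %% 2147483647)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

check_sequence <- function(sequence, max_length = 1024L) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort("`sequence` must be a single string.")
  }
  if (nchar(sequence) >= max_length) {
    abort(sprintf(
      "Sequence of length %d exceeds the provider limit (must be shorter than %d residues).",
      nchar(sequence), max_length
    ))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf(
      "Sequence contains non-standard characters: %s. Only the 20-letter amino-acid alphabet is accepted.",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(sequence)
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}
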