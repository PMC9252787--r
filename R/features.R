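#' Per-layer mean-pooled embedding container
#'
#' Holds one transformer layer's mean-pooled receptor representations: an
#' `n x width` numeric matrix (1280 = 20 heads x 64 dims for the default
#' backbone) with receptor ids as row names.
#'
#' @param matrix Numeric matrix with finite entries.
#' @param receptor_ids Character vector matching the rows.
#' @param layer Integer layer index (0-based, matching the backbone's
#'   representation numbering).
#' @return A `layer_embeddings` object.
#' @export
layer_embeddings <- function(matrix, receptor_ids = rownames(matrix), layer) {
  matrix <- as.matrix(matrix)
  if (is.null(receptor_ids) || length(receptor_ids) != nrow(matrix)) {
    abort("`receptor_ids` must match the matrix rows.")
  }
  if (!all(is.finite(matrix))) abort("Embedding matrix must be finite.")
  rownames(matrix) <- receptor_ids
  structure(
    list(matrix = matrix, receptor_ids = receptor_ids, layer = as.integer(layer)),
    class = "layer_embeddings"
  )
}

#' @exportS3Method base::print
print.layer_embeddings <- function(x, ...) {
  cat(sprintf("<layer_embeddings> layer %d: %d receptors x %d dims\n",
              x$layer, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Synthetic embedding provider
#'
#' Returns a provider function `f(sequence, layer)` giving a deterministic
#' pseudo-random width-1280 vector per (sequence, layer) pair, derived from a
#' hash-seeded RNG. It honours the backbone's contract — the 20-letter
#' alphabet and the under-1024-residue length limit — but makes no attempt to
#' imitate real language-model statistics. Two sequences differing in a
#' single residue map to unrelated vectors.
#'
#' @param width Embedding width (default 1280).
#' @return A function `(sequence, layer) -> numeric(width)`.
#' @examples
#' prov <- synthetic_provider()
#' v <- prov("MKTAYIAK", layer = 3)
#' length(v)
#' @export
synthetic_provider <- function(width = 1280L) {
  force(width)
  function(sequence, layer) {
    check_sequence(sequence)
    stopifnot(length(layer) == 1L, layer >= 0)
    seed <- substream_seed(str_hash(sequence), paste0("provider-layer", layer))
    with_seed(seed, rnorm(width))
  }
}

#' Resolve an embedding provider by configuration key
#'
#' `"synthetic"` returns the bundled deterministic provider; an external
#' language-model backend can be plugged in by passing a function with the
#' same `(sequence, layer)` signature.
#'
#' @param provider `"synthetic"` or a provider function.
#' @return A provider function.
#' @export
resolve_provider <- function(provider = "synthetic") {
  if (is.function(provider)) return(provider)
  if (identical(provider, "synthetic")) return(synthetic_provider())
  abort(sprintf("Unknown provider '%s'. Use 'synthetic' or supply a function.", provider))
}

#' Embed a set of sequences at one layer
#'
#' @param sequences Named character vector of sequences.
#' @param layer Layer index.
#' @param provider Provider key or function (see [resolve_provider()]).
#' @return A [layer_embeddings()] object.
#' @export
embed_sequences <- function(sequences, layer, provider = "synthetic") {
  stopifnot(!is.null(names(sequences)))
  f <- resolve_provider(provider)
  mat <- t(vapply(sequences, f, numeric(length(f(sequences[[1]], layer))), layer = layer))
  layer_embeddings(mat, receptor_ids = names(sequences), layer = layer)
}

#' Reduce embeddings by PCA retaining a variance fraction
#'
#' Mean-centered principal component analysis keeping the smallest number of
#' components K whose cumulative explained-variance ratio reaches
#' `variance_target` (0.95 by default). Loadings rows are unit-norm; each
#' component's sign is fixed so its largest-magnitude loading is positive,
#' making results deterministic.
#'
#' @param emb A [layer_embeddings()] object or bare numeric matrix.
#' @param variance_target Fraction of total variance to retain.
#' @return A `reduced_features` object: `scores` (n x K), `loadings`
#'   (K x width), `explained_variance_ratio` (all components), `center`,
#'   `K`, `layer`, `receptor_ids`.
#' @export
fit_pca <- function(emb, variance_target = 0.95) {
  mat <- if (inherits(emb, "layer_embeddings")) emb$matrix else as.matrix(emb)
  layer <- if (inherits(emb, "layer_embeddings")) emb$layer else NA_integer_
  if (nrow(mat) < 2) abort("PCA needs at least 2 rows.")
  stopifnot(variance_target > 0, variance_target <= 1)

  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  total <- sum(var_all)
  if (total <= 0) abort("Zero-variance matrix: component count undefined.")
  ratio <- var_all / total
  K <- which(cumsum(ratio) >= variance_target)[1]
  if (is.na(K)) K <- length(ratio)

  loadings <- t(pc$rotation[, seq_len(K), drop = FALSE])
  scores <- pc$x[, seq_len(K), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive per component
  for (k in seq_len(K)) {
    j <- which.max(abs(loadings[k, ]))
    if (loadings[k, j] < 0) {
      loadings[k, ] <- -loadings[k, ]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(rownames(mat), paste0("PC", seq_len(K)))
  rownames(loadings) <- paste0("PC", seq_len(K))

  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_ratio = ratio, center = pc$center,
         K = as.integer(K), layer = layer, receptor_ids = rownames(mat)),
    class = "reduced_features"
  )
}

#' @exportS3Method base::print
print.reduced_features <- function(x, ...) {
  cat(sprintf("<reduced_features> K = %d components (%.1f%% variance), layer %s, n = %d\n",
              x$K, 100 * sum(x$explained_variance_ratio[seq_len(x$K)]),
              ifelse(is.na(x$layer), "?", x$layer), nrow(x$scores)))
  invisible(x)
}

#' Project new vectors onto fitted principal components
#'
#' Computes `(x - center) %*% t(loadings)` with the stored center and
#' loadings; projecting a training row reproduces its stored score.
#'
#' @param features A `reduced_features` object from [fit_pca()].
#' @param x Numeric vector (width) or matrix (n x width).
#' @return Score matrix (n x K); a vector input yields a 1 x K matrix.
#' @export
project_pca <- function(features, x) {
  stopifnot(inherits(features, "reduced_features"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(features$center)) {
    abort(sprintf("Width mismatch: got %d, expected %d.",
                  ncol(x), length(features$center)))
  }
  sweep(x, 2, features$center) %*% t(features$loadings)
}
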