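#' Normalized mutual information between two partitions
#'
#' Mutual information normalized by the arithmetic mean of the two
#' partition entropies (natural log; the base cancels). Symmetric in its
#' arguments and invariant to relabeling. If either side has a single
#' distinct value the score is defined as 0 with a warning.
#'
#' @param clusters,labels Equal-length vectors of group assignments.
#' @param normalization `"arithmetic"` (default), `"geometric"`, `"min"` or
#'   `"max"` mean of the entropies.
#' @return NMI in \[0, 1\].
#' @examples
#' nmi(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' @export
nmi <- function(clusters, labels,
                normalization = c("arithmetic", "geometric", "min", "max")) {
  normalization <- match.arg(normalization)
  if (length(clusters) != length(labels)) abort("Partition lengths differ.")
  tab <- table(clusters, labels)
  n <- sum(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warn("A partition has a single distinct value; NMI defined as 0.")
    return(0)
  }
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  denom <- switch(normalization,
    arithmetic = (hx + hy) / 2,
    geometric = sqrt(hx * hy),
    min = min(hx, hy),
    max = max(hx, hy)
  )
  if (denom == 0) return(0)
  min(1, max(0, mi / denom))
}

#' Fit the embedded receptor space for one layer
#'
#' PCA on the layer's embeddings followed by K-means (k-means++-style
#' multiple restarts: fixed seed, 10 restarts, best inertia kept) on the
#' first two principal components. The cluster count is the cardinality of
#' the functional label set, never hard-coded.
#'
#' @param embeddings A [layer_embeddings()] object.
#' @param labels Named vector of functional labels for the reference
#'   receptors (names = receptor ids); `k` defaults to its cardinality.
#' @param k Cluster count (default `length(unique(labels))`).
#' @param seed RNG seed for the K-means restarts.
#' @param variance_target Passed to [fit_pca()].
#' @return An `embedded_space`: `coordinates` tibble
#'   (`receptor_id, PC1, PC2, cluster, label`), `pca`, `k`, `layer`,
#'   `kmeans` fit.
#' @export
fit_space <- function(embeddings, labels, k = NULL, seed = 1L,
                      variance_target = 0.95) {
  stopifnot(inherits(embeddings, "layer_embeddings"))
  labels <- labels[embeddings$receptor_ids]
  if (anyNA(labels)) abort("Every reference receptor needs a functional label.")
  k <- k %||% length(unique(labels))
  n <- nrow(embeddings$matrix)
  if (k < 2) abort("Need k >= 2 clusters.")
  if (n < k) abort(sprintf("n = %d receptors cannot form k = %d clusters.", n, k))

  pca <- fit_pca(embeddings, variance_target = variance_target)
  xy <- pca$scores[, 1:2, drop = FALSE]
  if (k == n) {
    # degenerate: every receptor is its own cluster
    km <- list(cluster = seq_len(n), centers = xy, tot.withinss = 0)
  } else {
    km <- with_seed(substream_seed(seed, "kmeans"),
                    kmeans(xy, centers = k, nstart = 10))
  }

  coords <- tibble(
    receptor_id = embeddings$receptor_ids,
    PC1 = unname(xy[, 1]), PC2 = unname(xy[, 2]),
    cluster = unname(km$cluster),
    label = unname(labels)
  )
  structure(
    list(coordinates = coords, pca = pca, k = as.integer(k),
         layer = embeddings$layer, kmeans = km),
    class = "embedded_space"
  )
}

#' @exportS3Method base::print
print.embedded_space <- function(x, ...) {
  cat(sprintf("<embedded_space> layer %d: %d receptors, k = %d clusters\n",
              x$layer, nrow(x$coordinates), x$k))
  invisible(x)
}

#' Score every layer by clustering agreement and pick the best
#'
#' Fits an embedded space per layer, scores the K-means clustering against
#' the functional labels with [nmi()], and selects the layer with the
#' highest score (ties to the lowest layer index).
#'
#' @param embeddings_list List of [layer_embeddings()] objects.
#' @param labels Named vector of functional labels.
#' @param k Cluster count (default: label cardinality).
#' @param seed RNG seed.
#' @return A `layer_scan`: tibble `layer, nmi` with attributes `best_layer`
#'   and `spaces` (the fitted `embedded_space` per layer).
#' @export
best_layer <- function(embeddings_list, labels, k = NULL, seed = 1L) {
  if (length(embeddings_list) == 0) abort("Need at least one layer.")
  spaces <- lapply(embeddings_list, fit_space, labels = labels, k = k,
                   seed = seed)
  scores <- tibble(
    layer = vapply(spaces, function(s) s$layer, integer(1)),
    nmi = vapply(spaces, function(s) {
      nmi(s$coordinates$cluster, s$coordinates$label)
    }, numeric(1))
  )
  best <- scores$layer[order(-scores$nmi, scores$layer)][1]
  attr(scores, "best_layer") <- best
  attr(scores, "spaces") <- setNames(spaces, scores$layer)
  class(scores) <- c("layer_scan", class(scores))
  scores
}

#' Project a query embedding into a fitted space
#'
#' Uses the reference loadings (never refit) so queries and variants land in
#' the same coordinate system as the reference receptors.
#'
#' @param space An `embedded_space`.
#' @param query Embedding vector on the space's layer.
#' @return Named numeric `c(PC1, PC2)`.
#' @export
project_query <- function(space, query) {
  stopifnot(inherits(space, "embedded_space"))
  z <- project_pca(space$pca, query)
  setNames(as.numeric(z[1, 1:2]), c("PC1", "PC2"))
}

#' Wild-type to variant trajectory in the embedded space
#'
#' @param space An `embedded_space`.
#' @param wt,variant Embedding vectors for the wild-type and variant
#'   sequences on the space's layer.
#' @return Tibble with rows `wt` and `variant` (`point, PC1, PC2`).
#' @export
trajectory <- function(space, wt, variant) {
  w <- project_query(space, wt)
  v <- project_query(space, variant)
  tibble(point = c("wt", "variant"),
         PC1 = c(w[["PC1"]], v[["PC1"]]),
         PC2 = c(w[["PC2"]], v[["PC2"]]))
}
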