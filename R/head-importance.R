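#' Normalize classifier weights to importances
#'
#' Each component weight's importance is its absolute value over the sum of
#' absolute values, so importances are non-negative and sum to 1. The
#' intercept is excluded: importance is attributed to the K component
#' weights only.
#'
#' @param w_cl Numeric weight vector (length K).
#' @return Numeric vector summing to 1.
#' @examples
#' normalize_cl(c(3, -1))  # 0.75 0.25
#' @export
normalize_cl <- function(w_cl) {
  s <- sum(abs(w_cl))
  if (s == 0) abort("All classifier weights are zero: importance undefined.")
  abs(w_cl) / s
}

#' Normalize PCA loadings row-wise to importances
#'
#' Each loading row (one component across the original embedding
#' dimensions) is normalized by its absolute sum, giving the importance of
#' every original dimension within that component; each row sums to 1.
#'
#' @param loadings Numeric K x width matrix.
#' @return Matrix of the same shape with non-negative rows summing to 1.
#' @export
normalize_pca <- function(loadings) {
  loadings <- as.matrix(loadings)
  s <- rowSums(abs(loadings))
  if (any(s == 0)) abort("A loading row is all zero: importance undefined.")
  abs(loadings) / s
}

#' Attention-head importance by weight backprojection
#'
#' Backprojects a linear coupling classifier's weights through the PCA
#' loadings to the original embedding dimensions, then sums the reweighted
#' mass within each head's contiguous block of dimensions (head h owns
#' columns (h-1)*head_dim+1 ... h*head_dim). Both weight sets are
#' absolute-value normalized first, so the head importances are
#' non-negative and sum to exactly 1. Non-linear SVC models carry no usable
#' weight vector; the logistic regression model trained on the same layer
#' and assay must be supplied (or stored as the model's `fallback`).
#'
#' @param model A `trained_coupler` (logreg, linear-kernel svc, or any model
#'   with a logreg `fallback`).
#' @param features Optional `reduced_features`; defaults to the model's
#'   stored PCA.
#' @param n_heads Number of heads (default 20).
#' @return A `head_importance` object: `importance` (length `n_heads`,
#'   sums to 1), `best_head`, the normalized weight sets, and metadata.
#' @export
head_importance <- function(model, features = NULL, n_heads = 20L) {
  stopifnot(inherits(model, "trained_coupler"))
  if (is.null(model$weights)) {
    if (!is.null(model$fallback)) {
      return(head_importance(model$fallback, features, n_heads))
    }
    abort(paste0(
      "Model has no linear weight vector (non-linear SVC); supply the ",
      "logistic regression model trained on the same layer and assay as ",
      "`fallback`."
    ))
  }
  features <- features %||% model$pca
  if (length(model$weights) != nrow(features$loadings)) {
    abort("K mismatch between classifier weights and PCA loadings.")
  }
  width <- ncol(features$loadings)
  if (width %% n_heads != 0) {
    abort(sprintf("Width %d does not tile into %d heads.", width, n_heads))
  }
  head_dim <- width %/% n_heads

  w_cl <- normalize_cl(model$weights)              # length K, sums to 1
  w_pca <- normalize_pca(features$loadings)        # K x width, rows sum to 1
  reweighted <- w_cl * w_pca                       # row k scaled by w_cl[k]
  importance <- vapply(seq_len(n_heads), function(h) {
    sum(reweighted[, head_columns(h, head_dim), drop = FALSE])
  }, numeric(1))

  structure(
    list(
      importance = importance,
      best_head = which.max(importance),          # ties resolve to lowest index
      n_heads = as.integer(n_heads), head_dim = as.integer(head_dim),
      normalized_cl_weights = w_cl, normalized_pca_weights = w_pca,
      transducer_id = model$transducer_id, assay = model$assay,
      layer = model$layer
    ),
    class = "head_importance"
  )
}

#' @exportS3Method base::print
print.head_importance <- function(x, ...) {
  cat(sprintf("<head_importance> best head %d of %d (I = %.3f), layer %s\n",
              x$best_head, x$n_heads, x$importance[x$best_head],
              ifelse(is.na(x$layer), "?", x$layer)))
  invisible(x)
}

#' @describeIn head_importance Tidy per-head importances.
#' @param x A `head_importance` object.
#' @param ... Unused.
#' @export
tidy.head_importance <- function(x, ...) {
  tibble(
    head = seq_len(x$n_heads),
    importance = x$importance,
    is_best = seq_len(x$n_heads) == x$best_head
  )
}
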