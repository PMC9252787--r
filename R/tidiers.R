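#' Tidy a fitted coupling classifier
#'
#' One row per principal-component weight (logistic regression and
#' linear-weight models); models without a linear weight vector yield an
#' empty tibble.
#'
#' @param x A `trained_coupler`.
#' @param ... Unused.
#' @return Tibble `term, estimate`.
#' @export
tidy.trained_coupler <- function(x, ...) {
  if (is.null(x$weights)) {
    return(tibble(term = character(), estimate = numeric()))
  }
  tibble(
    term = c("(Intercept)", paste0("PC", seq_along(x$weights))),
    estimate = c(x$intercept, x$weights)
  )
}

#' Glance at a fitted coupling classifier
#'
#' One-row model summary: algorithm, layer, K, training size, and the
#' cross-validation metrics when stored.
#'
#' @param x A `trained_coupler`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.trained_coupler <- function(x, ...) {
  cv <- x$cv
  tibble(
    transducer_id = x$transducer_id, assay = x$assay,
    algorithm = x$algorithm, layer = x$layer, K = x$pca$K,
    n_train = length(x$training_ids),
    auc_mean = if (!is.null(cv)) cv$auc_mean else NA_real_,
    rec_mean = if (!is.null(cv)) cv$rec_mean else NA_real_,
    spe_mean = if (!is.null(cv)) cv$spe_mean else NA_real_,
    mcc_mean = if (!is.null(cv)) cv$mcc_mean else NA_real_
  )
}

#' Tidy an embedded receptor space
#'
#' @param x An `embedded_space`.
#' @param ... Unused.
#' @return The coordinates tibble (`receptor_id, PC1, PC2, cluster, label`).
#' @export
tidy.embedded_space <- function(x, ...) x$coordinates

#' Glance at an embedded receptor space
#'
#' @param x An `embedded_space`.
#' @param ... Unused.
#' @return One-row tibble with layer, k, n, the clustering-vs-label NMI and
#'   the variance explained by the two plotted components.
#' @export
glance.embedded_space <- function(x, ...) {
  tibble(
    layer = x$layer, k = x$k, n = nrow(x$coordinates),
    nmi = nmi(x$coordinates$cluster, x$coordinates$label),
    var_pc12 = sum(x$pca$explained_variance_ratio[1:2])
  )
}

#' Plot per-head importances
#'
#' @param object A `head_importance`.
#' @param ... Unused.
#' @return A ggplot bar chart; the most important head is highlighted.
#' @export
autoplot.head_importance <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$head), y = .data$importance,
                                   fill = .data$is_best)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#D55E00")) +
    ggplot2::labs(x = "Attention head", y = "Importance",
                  title = sprintf("Head importance (best: head %d)", object$best_head)) +
    ggplot2::theme_minimal()
}

#' Plot the embedded receptor space
#'
#' @param object An `embedded_space`.
#' @param colour `"label"` (default) or `"cluster"`.
#' @param ... Unused.
#' @return A ggplot scatter of the first two principal components.
#' @export
autoplot.embedded_space <- function(object, colour = c("label", "cluster"), ...) {
  colour <- match.arg(colour)
  df <- object$coordinates
  df$colour <- if (colour == "label") df$label else factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$colour)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = colour,
                  title = sprintf("Embedded receptor space (layer %d)", object$layer)) +
    ggplot2::theme_minimal()
}

#' Plot a differential contact enrichment map
#'
#' @param object An `enrichment_map`.
#' @param ... Unused.
#' @return A ggplot tile heatmap (green = enriched, red = depleted).
#' @export
autoplot.enrichment_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pos_i, .data$pos_j,
                                       fill = .data$normalized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#B2182B", mid = "white",
                                  high = "#1B7837", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Enrichment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
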