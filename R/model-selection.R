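#' Log-spaced regularization grid
#'
#' The studies declare only an interval for the inverse regularization
#' strength C; the grid realizes it as log-spaced points, endpoints
#' inclusive.
#'
#' @param lo,hi Interval endpoints.
#' @param n Number of points.
#' @return Numeric vector of length `n`.
#' @export
c_grid <- function(lo, hi, n = 7L) {
  stopifnot(lo > 0, hi > lo, n >= 2)
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Declared hyperparameter space for logistic regression
#'
#' Penalties l1/l2 crossed with the five named solvers, incompatible
#' (penalty, solver) pairs skipped (l1 requires liblinear or saga), C on
#' `c_grid(0.001, 100)`, max_iter 4000, class weights balanced. The solver
#' axis identifies how the optimum is found, not which model is fitted, so
#' grid search collapses it to the model-defining axes (penalty, C); the
#' full declared space remains inspectable here.
#'
#' @return Tibble with columns `penalty`, `solver`, plus attributes
#'   `C` (grid), `max_iter`, `class_weight`.
#' @export
logreg_space <- function() {
  grid <- tidyr::expand_grid(
    penalty = c("l1", "l2"),
    solver = c("newton-cg", "lbfgs", "liblinear", "sag", "saga")
  )
  grid <- dplyr::filter(
    grid,
    .data$penalty == "l2" | .data$solver %in% c("liblinear", "saga")
  )
  attr(grid, "C") <- c_grid(0.001, 100)
  attr(grid, "max_iter") <- 4000L
  attr(grid, "class_weight") <- "balanced"
  grid
}

#' Declared hyperparameter space for the support vector classifier
#'
#' Kernels linear / poly (degree 3) / rbf / sigmoid, gamma = "scale",
#' C on `c_grid(0.1, 100)`, class weights balanced.
#'
#' @return Tibble with column `kernel` plus attributes `C`, `gamma`,
#'   `degree`, `class_weight`.
#' @export
svc_space <- function() {
  grid <- tibble(kernel = c("linear", "poly", "rbf", "sigmoid"))
  attr(grid, "C") <- c_grid(0.1, 100)
  attr(grid, "gamma") <- "scale"
  attr(grid, "degree") <- 3L
  attr(grid, "class_weight") <- "balanced"
  grid
}

# Model-defining search grid for one algorithm (solver axis collapsed).
search_grid <- function(algorithm) {
  if (algorithm == "logreg") {
    tidyr::expand_grid(penalty = c("l1", "l2"), C = attr(logreg_space(), "C"))
  } else {
    tidyr::expand_grid(kernel = svc_space()$kernel, C = attr(svc_space(), "C"))
  }
}

#' Enumerate candidate model configurations
#'
#' One candidate per (layer, algorithm) pair for a transducer family; the
#' hyperparameter grid is attached per candidate, not expanded into the
#' count. The default grids — 34 layer representations and both algorithm
#' families — give 68 candidates per transducer.
#'
#' @param transducer Transducer id.
#' @param assay Assay tag.
#' @param layers Integer vector of layer indices (default 0:33).
#' @param algorithms Character vector from `c("logreg", "svc")`.
#' @return Tibble with one row per candidate: `transducer_id`, `assay`,
#'   `layer`, `algorithm`, `grid` (list column).
#' @examples
#' nrow(enumerate_candidates("GNAS", "TGF"))  # 68
#' @export
enumerate_candidates <- function(transducer, assay,
                                 layers = 0:33,
                                 algorithms = c("logreg", "svc")) {
  if (length(layers) == 0 || length(algorithms) == 0) {
    abort("`layers` and `algorithms` must be non-empty.")
  }
  if (anyDuplicated(layers)) abort("Duplicate layers.")
  algorithms <- match.arg(algorithms, c("logreg", "svc"), several.ok = TRUE)
  tidyr::expand_grid(
    transducer_id = transducer, assay = assay,
    layer = as.integer(layers), algorithm = algorithms
  ) |>
    mutate(grid = purrr::map(.data$algorithm, search_grid))
}

# ---- metrics ---------------------------------------------------------------

rank_auc <- function(labels, scores) {
  if (length(unique(labels)) < 2) return(NA_real_)
  if (length(unique(scores)) < 2) return(0.5)
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("0", "1"), direction = "<", quiet = TRUE
  )))
}

classification_metrics <- function(labels, predicted) {
  tp <- sum(labels == 1 & predicted == 1)
  tn <- sum(labels == 0 & predicted == 0)
  fp <- sum(labels == 0 & predicted == 1)
  fn <- sum(labels == 1 & predicted == 0)
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  c(rec = rec, spe = spe, mcc = mcc)
}

balanced_case_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  unname(length(y) / (2 * as.numeric(tab[as.character(y)])))
}

sklearn_scale_gamma <- function(X) {
  v <- stats::var(as.vector(X))
  if (v <= 0) v <- 1
  1 / (ncol(X) * v)
}

# Fit one grid point; returns a closure bundle with score/prob/class preds.
fit_point <- function(X, y, algorithm, params) {
  if (algorithm == "logreg") {
    lam <- 1 / (params$C * nrow(X))
    fit <- glmnet::glmnet(
      X, factor(y, levels = c(0, 1)), family = "binomial",
      alpha = if (params$penalty == "l1") 1 else 0,
      lambda = lam, standardize = FALSE,
      weights = balanced_case_weights(y),
      maxit = attr(logreg_space(), "max_iter")
    )
    list(
      weights = as.numeric(fit$beta),
      intercept = as.numeric(fit$a0),
      predict_score = function(Xn) as.numeric(predict(fit, Xn, type = "link")),
      predict_prob = function(Xn) as.numeric(predict(fit, Xn, type = "response")),
      predict_class = function(Xn) as.integer(predict(fit, Xn, type = "response") > 0.5)
    )
  } else {
    yf <- factor(y, levels = c(0, 1))
    tab <- table(yf)
    cw <- setNames(length(y) / (2 * as.numeric(tab)), names(tab))
    fit <- e1071::svm(
      x = X, y = yf, kernel = if (params$kernel == "poly") "polynomial" else
        if (params$kernel == "rbf") "radial" else params$kernel,
      degree = attr(svc_space(), "degree"),
      gamma = sklearn_scale_gamma(X), cost = params$C,
      class.weights = cw, probability = TRUE, scale = FALSE
    )
    list(
      weights = NULL, intercept = NULL, svm_fit = fit,
      predict_score = function(Xn) {
        dv <- attr(predict(fit, Xn, decision.values = TRUE), "decision.values")
        s <- as.numeric(dv[, 1])
        # decision value sign follows the first factor level seen in training
        if (colnames(dv)[1] == "0/1") -s else s
      },
      predict_prob = function(Xn) {
        pr <- attr(predict(fit, Xn, probability = TRUE), "probabilities")
        as.numeric(pr[, "1"])
      },
      predict_class = function(Xn) as.integer(as.character(predict(fit, Xn)))
    )
  }
}

# Evaluate every grid point on one train/test fold; returns a
# (grid rows) x (auc, rec, spe, mcc) matrix. Logistic regression exploits
# glmnet's regularization path: one fit per penalty covers the whole C grid.
eval_fold <- function(Xtr, ytr, Xte, yte, algorithm, grid) {
  out <- matrix(NA_real_, nrow = nrow(grid), ncol = 4,
                dimnames = list(NULL, c("auc", "rec", "spe", "mcc")))
  if (algorithm == "logreg" && all(c("penalty", "C") %in% names(grid))) {
    w <- balanced_case_weights(ytr)
    yf <- factor(ytr, levels = c(0, 1))
    for (pen in unique(grid$penalty)) {
      rows <- which(grid$penalty == pen)
      lam <- 1 / (grid$C[rows] * nrow(Xtr))
      path <- sort(unique(lam), decreasing = TRUE)
      fit <- glmnet::glmnet(Xtr, yf, family = "binomial",
                            alpha = if (pen == "l1") 1 else 0,
                            lambda = path, standardize = FALSE, weights = w,
                            maxit = attr(logreg_space(), "max_iter"))
      for (i in seq_along(rows)) {
        prob <- as.numeric(predict(fit, Xte, s = lam[i], type = "response"))
        out[rows[i], ] <- c(rank_auc(yte, prob),
                            classification_metrics(yte, as.integer(prob > 0.5)))
      }
    }
  } else {
    for (g in seq_len(nrow(grid))) {
      fit <- fit_point(Xtr, ytr, algorithm, as.list(grid[g, ]))
      out[g, ] <- c(rank_auc(yte, fit$predict_score(Xte)),
                    classification_metrics(yte, fit$predict_class(Xte)))
    }
  }
  out
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Repeated stratified cross-validation with grid search
#'
#' Runs stratified k-fold cross-validation, repeated with fresh fold draws.
#' Every grid point of the algorithm's model-defining hyperparameters is
#' evaluated on every fold of every repeat; the single search is scored
#' across repeats and the point with the best overall mean AUC is selected.
#' Reported metrics are that point's fold-averaged values per repeat,
#' summarized as means (and for AUC also the sd) over repeats. Class
#' weights are balanced throughout.
#'
#' @param scores Numeric matrix of reduced features (receptors x K), row
#'   names = receptor ids.
#' @param labels Binary vector aligned with `scores` rows.
#' @param algorithm `"logreg"` or `"svc"`.
#' @param layer,transducer,assay Metadata carried into the result.
#' @param grid Optional hyperparameter tibble (defaults to
#'   `search_grid(algorithm)`).
#' @param folds Fold count (default 5).
#' @param repeats Repetition count (default 10); fold seeds are derived as
#'   seed + repeat index.
#' @param seed Integer seed.
#' @param null_model Flag marking a label-shuffle run.
#' @return One-row tibble (class `cv_result`): metric summaries, modal
#'   `best_params` (list), per-repeat records (`repeat_records` list
#'   column), metadata.
#' @export
cross_validate <- function(scores, labels, algorithm = c("logreg", "svc"),
                           layer = NA_integer_, transducer = NA_character_,
                           assay = NA_character_, grid = NULL,
                           folds = 5L, repeats = 10L, seed = 1L,
                           null_model = FALSE) {
  algorithm <- match.arg(algorithm)
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(labels), all(labels %in% c(0L, 1L)))
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < folds)) {
    abort(sprintf(
      "Cannot stratify: class counts (%s) below the fold count %d.",
      paste(counts, collapse = "/"), folds
    ))
  }
  grid <- grid %||% search_grid(algorithm)

  # every grid point evaluated on every fold of every repeat; the search is
  # scored across repeats, so the winning point's metrics are averages over
  # fold draws it was not selected within (minimal selection optimism)
  repeat_fold_metrics <- lapply(seq_len(repeats), function(r) {
    fold <- with_seed(seed + r, stratified_folds(labels, folds))
    lapply(seq_len(folds), function(f) {
      tr <- fold != f
      eval_fold(scores[tr, , drop = FALSE], labels[tr],
                scores[!tr, , drop = FALSE], labels[!tr], algorithm, grid)
    })
  })
  grid_mean_auc <- rowMeans(vapply(
    unlist(repeat_fold_metrics, recursive = FALSE),
    function(m) m[, "auc"], numeric(nrow(grid))
  ) |> matrix(nrow = nrow(grid)), na.rm = TRUE)
  best <- which.max(grid_mean_auc)
  modal <- as.list(grid[best, ])

  per_repeat <- purrr::map_dfr(seq_len(repeats), function(r) {
    m <- rowMeans(vapply(repeat_fold_metrics[[r]], function(fm) fm[best, ],
                         numeric(4)), na.rm = TRUE)
    tibble(repeat_id = r, auc = m[["auc"]], rec = m[["rec"]],
           spe = m[["spe"]], mcc = m[["mcc"]], params = list(modal))
  })

  out <- tibble(
    transducer_id = transducer, assay = assay,
    layer = as.integer(layer), algorithm = algorithm,
    auc_mean = mean(per_repeat$auc), auc_sd = stats::sd(per_repeat$auc),
    rec_mean = mean(per_repeat$rec), spe_mean = mean(per_repeat$spe),
    mcc_mean = mean(per_repeat$mcc),
    best_params = list(modal),
    n = nrow(scores), folds = as.integer(folds),
    n_repeats = as.integer(repeats), repeat_records = list(per_repeat),
    seed = as.integer(seed),
    null_model = null_model
  )
  class(out) <- c("cv_result", class(out))
  out
}

#' Drop models with imbalanced recall/specificity
#'
#' Eliminates cross-validation results whose absolute recall-specificity
#' difference exceeds `tol`; a difference of exactly `tol` survives.
#'
#' @param results Tibble of [cross_validate()] rows.
#' @param tol Imbalance tolerance (default 0.15).
#' @return Filtered tibble.
#' @export
filter_imbalanced <- function(results, tol = 0.15) {
  # small epsilon so the exact boundary survives despite float representation
  dplyr::filter(results, abs(.data$rec_mean - .data$spe_mean) <= tol + 1e-9)
}

#' Rank filtered models by AUC and keep the top few
#'
#' Descending mean AUC; ties broken by higher mean MCC, then lower layer
#' index.
#'
#' @param results Tibble of [cross_validate()] rows (post-filter).
#' @param top Number to keep (default 5).
#' @return Tibble of at most `top` rows.
#' @export
rank_and_select <- function(results, top = 5L) {
  if (nrow(results) == 0) {
    warn("No models to rank; returning empty selection.")
    return(results)
  }
  arrange(results, desc(.data$auc_mean), desc(.data$mcc_mean), .data$layer) |>
    head(top)
}

#' Label-shuffle randomization test
#'
#' Permutes the labels (class counts preserved exactly) and reruns the full
#' cross-validation, flagging the result as a null model. Signal-free labels
#' should yield chance-level AUC; a large gap from the unshuffled run argues
#' against overfitting.
#'
#' @inheritParams cross_validate
#' @return A `cv_result` row with `null_model = TRUE`.
#' @export
randomization_test <- function(scores, labels, algorithm = c("logreg", "svc"),
                               layer = NA_integer_, transducer = NA_character_,
                               assay = NA_character_, grid = NULL,
                               folds = 5L, repeats = 10L, seed = 1L) {
  shuffled <- with_seed(substream_seed(seed, "label-shuffle"), sample(labels))
  cross_validate(scores, shuffled, algorithm, layer = layer,
                 transducer = transducer, assay = assay, grid = grid,
                 folds = folds, repeats = repeats, seed = seed,
                 null_model = TRUE)
}

#' Fit a final coupling classifier
#'
#' Fits the chosen algorithm at the chosen hyperparameters on all training
#' receptors, keeping the PCA used to reduce the features so that new
#' sequences can be projected consistently. Predictions are class
#' probabilities; 0.5 is the coupling threshold.
#'
#' @param pca A `reduced_features` object from [fit_pca()] on the training
#'   assay's embeddings.
#' @param labels Tibble from [label_vector()] (or any tibble with
#'   `receptor_id` and `label`).
#' @param algorithm `"logreg"` or `"svc"`.
#' @param params Hyperparameter list (e.g. `best_params[[1]]` from a CV row).
#' @param cv Optional `cv_result` row stored as provenance.
#' @param fallback Optional logreg `trained_coupler` on the same layer/assay,
#'   required to interpret non-linear SVC models (see [head_importance()]).
#' @return A `trained_coupler` object.
#' @export
train_coupler <- function(pca, labels, algorithm = c("logreg", "svc"),
                          params, cv = NULL, fallback = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(pca, "reduced_features"))
  idx <- match(labels$receptor_id, rownames(pca$scores))
  if (anyNA(idx)) abort("Labelled receptors missing from the reduced features.")
  X <- pca$scores[idx, , drop = FALSE]
  y <- labels$label
  fit <- fit_point(X, y, algorithm, params)
  structure(
    list(
      algorithm = algorithm, params = params,
      weights = fit$weights, intercept = fit$intercept,
      fit = fit, pca = pca,
      transducer_id = if ("transducer_id" %in% names(labels)) labels$transducer_id[1] else NA_character_,
      assay = if ("assay" %in% names(labels)) labels$assay[1] else NA_character_,
      layer = pca$layer, threshold = 0.5,
      training_ids = labels$receptor_id, cv = cv, fallback = fallback
    ),
    class = "trained_coupler"
  )
}

#' @exportS3Method base::print
print.trained_coupler <- function(x, ...) {
  cat(sprintf("<trained_coupler> %s / %s: %s on layer %s (K = %d)\n",
              x$transducer_id, x$assay, x$algorithm,
              ifelse(is.na(x$layer), "?", x$layer), x$pca$K))
  invisible(x)
}

#' Predict coupling probabilities
#'
#' @param object A `trained_coupler`.
#' @param newdata Embedding matrix (n x width) or vector on the model's
#'   layer; projected through the stored PCA before classification.
#' @param type `"prob"` (default), `"class"`, or `"score"` (decision value).
#' @param reduced Set `TRUE` if `newdata` is already in PCA score space.
#' @param ... Unused.
#' @return Numeric (prob/score) or integer (class) vector.
#' @export
predict.trained_coupler <- function(object, newdata, type = c("prob", "class", "score"),
                                    reduced = FALSE, ...) {
  type <- match.arg(type)
  Xn <- if (reduced) {
    if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  } else {
    project_pca(object$pca, newdata)
  }
  switch(type,
    prob = object$fit$predict_prob(Xn),
    class = object$fit$predict_class(Xn),
    score = object$fit$predict_score(Xn)
  )
}

#' Recall on a positive-only held-out set
#'
#' Known-coupled test receptors only (no true-negative set exists for the
#' literature-derived couplings), so recall is the fraction with predicted
#' probability above the model threshold. Receptors overlapping the
#' training set are rejected as leakage.
#'
#' @param model A `trained_coupler`.
#' @param test_embeddings [layer_embeddings()] (or matrix with receptor row
#'   names) for the known-coupled test receptors, on the model's layer.
#' @return Recall in \[0, 1\].
#' @export
evaluate_recall <- function(model, test_embeddings) {
  mat <- if (inherits(test_embeddings, "layer_embeddings")) {
    test_embeddings$matrix
  } else {
    as.matrix(test_embeddings)
  }
  if (nrow(mat) == 0) abort("Empty test set: recall undefined.")
  overlap <- intersect(rownames(mat), model$training_ids)
  if (length(overlap) > 0) {
    abort(sprintf("Test receptors overlap the training set (%s...).", overlap[1]))
  }
  probs <- predict(model, mat, type = "prob")
  mean(probs > model$threshold)
}

#' Final per-transducer model choice by held-out recall
#'
#' For each transducer picks the candidate with the highest test recall;
#' ties go to the higher cross-validation AUC. Transducers with no tested
#' candidate are reported with a warning and absent from the output.
#'
#' @param candidates Tibble with columns `transducer_id`, `model`
#'   (list of `trained_coupler`), `test_recall`, `auc_mean`.
#' @return Named list of `trained_coupler`, one per transducer.
#' @export
select_final <- function(candidates) {
  stopifnot(all(c("transducer_id", "model", "test_recall", "auc_mean") %in%
                  names(candidates)))
  picked <- candidates |>
    group_by(.data$transducer_id) |>
    arrange(desc(.data$test_recall), desc(.data$auc_mean), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  setNames(picked$model, picked$transducer_id)
}
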