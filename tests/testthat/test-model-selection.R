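test_that("candidate enumeration counts follow the layer x algorithm grid", {
  expect_identical(nrow(enumerate_candidates("GNAS", "TGF")), 68L)
  expect_identical(nrow(enumerate_candidates("GNAS", "TGF", layers = 5,
                                             algorithms = "logreg")), 1L)
  expect_identical(nrow(enumerate_candidates("GNAS", "TGF", layers = 0:2)), 6L)
  expect_error(enumerate_candidates("GNAS", "TGF", layers = c(1, 1)),
               "Duplicate layers")
  expect_error(enumerate_candidates("GNAS", "TGF", layers = integer(0)),
               "non-empty")
})

test_that("declared hyperparameter spaces match the training protocol", {
  ls <- logreg_space()
  expect_setequal(unique(ls$penalty), c("l1", "l2"))
  expect_setequal(unique(ls$solver),
                  c("newton-cg", "lbfgs", "liblinear", "sag", "saga"))
  # l1 is only solvable by liblinear/saga; incompatible pairs skipped
  expect_setequal(ls$solver[ls$penalty == "l1"], c("liblinear", "saga"))
  expect_identical(nrow(ls), 7L)
  expect_equal(range(attr(ls, "C")), c(0.001, 100))
  expect_identical(attr(ls, "max_iter"), 4000L)
  expect_identical(attr(ls, "class_weight"), "balanced")

  ss <- svc_space()
  expect_setequal(ss$kernel, c("linear", "poly", "rbf", "sigmoid"))
  expect_equal(range(attr(ss, "C")), c(0.1, 100))
  expect_identical(attr(ss, "gamma"), "scale")
  expect_identical(attr(ss, "degree"), 3L)
})

test_that("cross-validation separates a separable problem and is reproducible", {
  set.seed(10)
  y <- rep(c(0L, 1L), each = 30)
  X <- cbind(y + rnorm(60, sd = 0.05), matrix(rnorm(120), 60))
  cv <- cross_validate(X, y, "logreg", grid = small_grid, repeats = 3, seed = 4)
  expect_gte(cv$auc_mean, 0.99)
  expect_true(all(c(cv$rec_mean, cv$spe_mean) <= 1))
  expect_gte(cv$mcc_mean, -1)

  cv2 <- cross_validate(X, y, "logreg", grid = small_grid, repeats = 3, seed = 4)
  expect_identical(cv$auc_mean, cv2$auc_mean)
  expect_identical(cv$repeat_records[[1]], cv2$repeat_records[[1]])

  # svc route works on the same problem
  cvs <- cross_validate(X, y, "svc",
                        grid = tidyr::expand_grid(kernel = "linear", C = 1),
                        repeats = 2, seed = 4)
  expect_gte(cvs$auc_mean, 0.99)
})

test_that("null features give chance-level AUC", {
  set.seed(2)
  X <- matrix(rnorm(80 * 5), 80)
  y <- sample(rep(c(0L, 1L), 40))
  cv <- cross_validate(X, y, "logreg", grid = small_grid, repeats = 3, seed = 1)
  expect_lt(abs(cv$auc_mean - 0.5), 0.12)
})

test_that("classes smaller than the fold count are rejected", {
  X <- matrix(rnorm(40), 10)
  y <- c(rep(0L, 8), 1L, 1L)
  expect_error(cross_validate(X, y, "logreg", folds = 5), "Cannot stratify")
})

test_that("imbalance filter eliminates |REC - SPE| above 0.15 only", {
  results <- tibble::tibble(
    rec_mean = c(0.90, 0.80, 0.80, 0.70),
    spe_mean = c(0.70, 0.80, 0.65, 0.90),
    auc_mean = 1:4
  )
  kept <- filter_imbalanced(results)
  # 0.20 gaps eliminated; equality and the exact 0.15 boundary survive
  expect_identical(kept$auc_mean, c(2L, 3L))
})

test_that("ranking keeps the top five by AUC with MCC then layer tiebreaks", {
  results <- tibble::tibble(
    auc_mean = c(0.9, 0.95, 0.85, 0.8, 0.7, 0.99, 0.6),
    mcc_mean = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    layer = 0:6
  )
  top <- rank_and_select(results)
  expect_identical(nrow(top), 5L)
  expect_identical(top$auc_mean[1], 0.99)
  expect_false(0.6 %in% top$auc_mean)

  tie <- tibble::tibble(auc_mean = c(0.9, 0.9, 0.9), mcc_mean = c(0.2, 0.6, 0.6),
                        layer = c(3L, 5L, 1L))
  ranked <- rank_and_select(tie)
  expect_identical(ranked$layer, c(1L, 5L, 3L))  # mcc first, then lower layer

  expect_warning(out <- rank_and_select(tie[0, ]), "empty")
  expect_identical(nrow(out), 0L)
})

test_that("two results are both kept when fewer than five survive", {
  two <- tibble::tibble(auc_mean = c(0.8, 0.7), mcc_mean = c(0.1, 0.1),
                        layer = c(0L, 1L))
  expect_identical(nrow(rank_and_select(two)), 2L)
})

test_that("randomization test preserves class counts and kills the signal", {
  fx <- tiny_fixture(n = 60, seed = 21, effect = 3)
  lab <- label_vector(fx$coupling, "GNAI1")
  pca <- fit_pca(fx$embeddings[[2]])
  scores <- pca$scores[lab$receptor_id, ]

  cv <- cross_validate(scores, lab$label, "logreg", grid = small_grid,
                       repeats = 3, seed = 9)
  rt <- randomization_test(scores, lab$label, "logreg", grid = small_grid,
                           repeats = 3, seed = 9)
  expect_true(rt$null_model)
  expect_gt(cv$auc_mean, 0.95)
  expect_lt(rt$auc_mean, 0.75)
  # reproducible under the same seed
  rt2 <- randomization_test(scores, lab$label, "logreg", grid = small_grid,
                            repeats = 3, seed = 9)
  expect_identical(rt$auc_mean, rt2$auc_mean)
})

test_that("held-out recall counts probabilities above threshold, guards leakage", {
  fx <- tiny_fixture(n = 60, seed = 31, effect = 3)
  lab <- label_vector(fx$coupling, "GNAI1")
  pca <- fit_pca(fx$embeddings[[2]])
  train_lab <- lab[1:40, ]
  model <- train_coupler(pca, train_lab, "logreg", list(penalty = "l2", C = 1))

  held <- lab[41:60, ][lab$label[41:60] == 1, ]
  test_emb <- fx$embeddings[[2]]$matrix[held$receptor_id, , drop = FALSE]
  rec <- evaluate_recall(model, test_emb)
  probs <- predict(model, test_emb, type = "prob")
  expect_identical(rec, mean(probs > 0.5))  # hand count
  expect_gte(rec, 0.8)

  expect_error(evaluate_recall(model, fx$embeddings[[2]]$matrix[1:5, ]),
               "overlap")
  expect_error(evaluate_recall(model, test_emb[0, , drop = FALSE]), "Empty")
})

test_that("final selection maximizes test recall with CV-AUC tiebreak", {
  dummy <- structure(list(), class = "trained_coupler")
  cands <- tibble::tibble(
    transducer_id = c("GNAS", "GNAS", "GNAI1"),
    model = list("a", "b", "c"),
    test_recall = c(0.8, 0.6, 0.7),
    auc_mean = c(0.9, 0.99, 0.8)
  )
  picked <- select_final(cands)
  expect_identical(picked$GNAS, "a")
  expect_identical(picked$GNAI1, "c")

  tie <- tibble::tibble(
    transducer_id = c("GNAQ", "GNAQ"), model = list("x", "y"),
    test_recall = c(0.7, 0.7), auc_mean = c(0.85, 0.95)
  )
  expect_identical(select_final(tie)$GNAQ, "y")
})
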