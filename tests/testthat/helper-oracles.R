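# Independent oracles used to freeze expected values. Each is a brute-force
# or closed-form computation sharing no code path with the implementation.

# Eigendecomposition PCA oracle: scores of mean-centered X from eigen() of
# the covariance matrix, components ordered by decreasing eigenvalue.
oracle_pca_scores <- function(X) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  Xc %*% eg$vectors
}

# Brute-force head importance: explicit double loop over the reweighted
# principal-component matrix entries.
oracle_head_importance <- function(w_cl, loadings, n_heads) {
  K <- length(w_cl)
  width <- ncol(loadings)
  head_dim <- width / n_heads
  wbar <- abs(w_cl) / sum(abs(w_cl))
  lbar <- loadings
  for (k in seq_len(K)) lbar[k, ] <- abs(loadings[k, ]) / sum(abs(loadings[k, ]))
  I <- numeric(n_heads)
  for (h in seq_len(n_heads)) {
    for (k in seq_len(K)) {
      for (j in ((h - 1) * head_dim + 1):(h * head_dim)) {
        I[h] <- I[h] + wbar[k] * lbar[k, j]
      }
    }
  }
  I
}

# Entropy-arithmetic NMI oracle from the raw contingency table.
oracle_nmi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        pij <- tab[i, j] / n
        mi <- mi + pij * log(pij / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
      }
    }
  }
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi / ((ent(rowSums(tab) / n) + ent(colSums(tab) / n)) / 2)
}

# Direct-arithmetic log-odds with the same zero-cell correction rule.
oracle_log_odds <- function(aa, bb, cc, dd) {
  if (any(c(aa, bb, cc, dd) == 0)) {
    aa <- aa + 0.5; bb <- bb + 0.5; cc <- cc + 0.5; dd <- dd + 0.5
  }
  log(aa * dd) - log(bb * cc)
}

# Small planted-signal fixture shared across tests (kept light).
tiny_fixture <- function(n = 60, seed = 42, effect = 3, layers = 2) {
  make_synthetic_couplings(synthetic_spec(
    n_receptors = n, n_layers = layers, planted_layer = layers,
    planted_head = 7, effect_size = effect, seed = seed
  ))
}

# Reduced logreg grid for fast protocol tests (full grid covered elsewhere).
small_grid <- tidyr::expand_grid(penalty = "l2", C = c(0.1, 1))

# minimal linear coupler for geometry tests
fake_coupler <- function(weights, loadings) {
  pca <- structure(
    list(scores = NULL, loadings = loadings,
         explained_variance_ratio = rep(1 / nrow(loadings), nrow(loadings)),
         center = rep(0, ncol(loadings)), K = nrow(loadings),
         layer = 0L, receptor_ids = NULL),
    class = "reduced_features"
  )
  structure(list(algorithm = "logreg", weights = weights, intercept = 0,
                 pca = pca, transducer_id = "T", assay = "TGF", layer = 0L,
                 threshold = 0.5, training_ids = character()),
            class = "trained_coupler")
}
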