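test_that("variant strings parse per the ID/XnY convention", {
  v <- parse_variant("MC1R/D294H")
  expect_identical(v$receptor_id, "MC1R")
  expect_identical(v$substitutions$ref, "D")
  expect_identical(v$substitutions$position, 294L)
  expect_identical(v$substitutions$alt, "H")

  multi <- parse_variant("GENE/A12V,C30R")
  expect_identical(nrow(multi$substitutions), 2L)

  syn <- parse_variant("GENE/A1A")  # synonymous accepted
  expect_identical(syn$substitutions$ref, syn$substitutions$alt)

  expect_error(parse_variant("GENE/294H"), "Malformed")
  expect_error(parse_variant("GENE"), "Malformed")
  expect_error(parse_variant("GENE/D0H"), "1-based")
  expect_error(parse_variant("GENE/B12H"), "Non-amino-acid")
})

test_that("substitutions validate the reference residue and preserve length", {
  expect_identical(apply_substitution("ACD", parse_variant("X/C2W")), "AWD")
  expect_error(apply_substitution("ACD", parse_variant("X/A2W")),
               "found 'C', expected 'A'")
  expect_error(apply_substitution("ACD", parse_variant("X/D9H")), "out of range")

  # five substitutions -> Hamming distance exactly 5
  set.seed(3)
  wt <- paste(sample(AA_ALPHABET, 300, TRUE), collapse = "")
  pos <- sort(sample(300, 5))
  chars <- strsplit(wt, "")[[1]]
  subs <- paste0(chars[pos], pos,
                 vapply(chars[pos], function(a) setdiff(AA_ALPHABET, a)[1], ""))
  var <- apply_substitution(wt, parse_variant(paste0("X/", paste(subs, collapse = ","))))
  expect_identical(sum(strsplit(wt, "")[[1]] != strsplit(var, "")[[1]]), 5L)
  expect_identical(nchar(var), 300L)
})

test_that("switch calls follow the 0.5 threshold exhaustively", {
  expect_identical(call_switch(0.3, 0.7), "gain")
  expect_identical(call_switch(0.7, 0.3), "loss")
  expect_identical(call_switch(0.5, 0.5), "retained_uncoupled")
  expect_identical(call_switch(0.7, 0.9), "retained_coupled")

  # property sweep over a probability grid including both boundaries
  grid <- expand.grid(wt = seq(0, 1, 0.1), var = seq(0, 1, 0.1))
  calls <- call_switch(grid$wt, grid$var)
  expected <- ifelse(grid$wt > 0.5 & grid$var <= 0.5, "loss",
              ifelse(grid$wt <= 0.5 & grid$var > 0.5, "gain",
              ifelse(grid$wt > 0.5, "retained_coupled", "retained_uncoupled")))
  expect_identical(calls, expected)
  expect_error(call_switch(1.2, 0.5), "probability")
})

test_that("isoform filtering applies inclusive cutoffs and is monotone", {
  records <- tibble::tibble(
    isoform = paste0("iso", 1:6),
    tm_fraction = c(1, 0.75, 0.5, 0.25, NA, 1),
    tpm = c(1.0, 0.5, 3, 1, 2, 0)
  )
  # hand application: tm >= 0.5 AND tpm >= 1 keeps iso1, iso3
  kept <- filter_isoforms(records, min_tm_fraction = 0.5, min_tpm = 1)
  expect_identical(kept$isoform, c("iso1", "iso3"))
  # TPM boundary is inclusive
  expect_true("iso1" %in% filter_isoforms(records, 0, 1)$isoform)
  # unknown fraction passes only when the coverage cutoff is zero
  expect_true("iso5" %in% filter_isoforms(records, 0, 1)$isoform)
  expect_false("iso5" %in% filter_isoforms(records, 0.25, 1)$isoform)
  # monotone: raising either cutoff never adds survivors
  base <- filter_isoforms(records, 0.25, 0.5)$isoform
  expect_true(all(filter_isoforms(records, 0.5, 0.5)$isoform %in% base))
  expect_true(all(filter_isoforms(records, 0.25, 2)$isoform %in% base))
})

test_that("retained 7TM fraction counts annotated TM residues", {
  canonical <- "MKTAYIAKQR"
  expect_equal(tm_fraction_retained(canonical, "MKTAYIAKQR", c(2, 4, 6)), 1)
  expect_equal(tm_fraction_retained(canonical, "MKT", c(2, 4, 6)), 1 / 3)
  expect_true(is.na(tm_fraction_retained(canonical, "MKT", integer(0))))
})

test_that("variant profiling calls switches against a planted model", {
  fx <- tiny_fixture(n = 60, seed = 77, effect = 3)
  lab <- label_vector(fx$coupling, "GNAI1")
  pca <- fit_pca(fx$embeddings[[2]])
  model <- train_coupler(pca, lab, "logreg", list(penalty = "l2", C = 1))
  model$layer <- 1L

  # a provider that maps designated sequences onto planted-head embeddings:
  # "coupled-like" vectors carry the head-7 shift, null ones do not
  wt_vec <- rep(0, 1280)
  gain_vec <- wt_vec; gain_vec[(6 * 64 + 1):(7 * 64)] <- 3
  null_vec <- wt_vec; null_vec[1:64] <- 3  # perturbs a non-planted head
  stub <- function(sequence, layer) {
    switch(substr(sequence, 1, 1), "A" = wt_vec, "C" = gain_vec, "D" = null_vec)
  }

  wt_seq <- "AAAA"; gain_seq <- "CAAA"; null_seq <- "DAAA"
  prof_gain <- profile_variant(wt_seq, gain_seq, list(GNAI1 = model), provider = stub)
  expect_identical(prof_gain$call, "gain")
  prof_null <- profile_variant(wt_seq, null_seq, list(GNAI1 = model), provider = stub)
  expect_identical(substr(prof_null$call, 1, 8), "retained")
  # wt vs wt retains state
  prof_same <- profile_variant(wt_seq, wt_seq, list(GNAI1 = model), provider = stub)
  expect_true(prof_same$call %in% c("retained_coupled", "retained_uncoupled"))
  expect_identical(prof_same$wt_prob, prof_same$var_prob)
})

test_that("profiling with the synthetic provider is deterministic and spatial", {
  fx <- tiny_fixture(n = 40, seed = 5, effect = 2)
  lab <- label_vector(fx$coupling, "GNAI1")
  pca <- fit_pca(fx$embeddings[[2]])
  model <- train_coupler(pca, lab, "logreg", list(penalty = "l2", C = 1))

  gp <- make_synthetic_gpcrome(c(A = 15, B = 15), class_separation = 10,
                               n_layers = 1, planted_layer = 1, seed = 2)
  sp <- fit_space(gp$embeddings[[1]], gp$labels, seed = 1)

  wt <- paste(rep("M", 50), collapse = "")
  spec <- parse_variant("X/M10W")
  p1 <- profile_variant(wt, spec, list(GNAI1 = model), space = sp)
  p2 <- profile_variant(wt, spec, list(GNAI1 = model), space = sp)
  expect_identical(p1$wt_prob, p2$wt_prob)
  expect_identical(attr(p1, "trajectory"), attr(p2, "trajectory"))
  expect_identical(attr(p1, "trajectory")$point, c("wt", "variant"))
})
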