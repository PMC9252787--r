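toy_annotation <- function(positions, segments) {
  tibble::tibble(position = positions, segment = segments)
}

test_that("probabilistic maps binarize at a strict 0.5 and keep symmetry", {
  ann <- toy_annotation(paste0("p", 1:3), c("TM1", "TM2", "TM3"))
  pm <- tibble::tibble(
    receptor_id = "R1",
    pos_i = c("p1", "p1", "p2"), pos_j = c("p2", "p3", "p3"),
    probability = c(0.5, 0.51, 0.9)
  )
  maps <- binarize_contacts(pm, ann)
  expect_identical(nrow(maps$contacts), 2L)  # the 0.5 edge is dropped
  expect_true(all(maps$contacts$pos_i <= maps$contacts$pos_j))

  asym <- dplyr::bind_rows(pm, tibble::tibble(receptor_id = "R1", pos_i = "p2",
                                              pos_j = "p1", probability = 0.2))
  expect_error(binarize_contacts(asym, ann), "Asymmetric")
})

test_that("contingency counts tally coupled/non-coupled contact presence", {
  ann <- toy_annotation(paste0("p", 1:4), rep("TM1", 4))
  labels <- tibble::tibble(receptor_id = paste0("R", 1:8),
                           label = rep(c(1L, 0L), each = 4))
  # contact p1-p2 in receptors R1-R4 (all coupled) and none else
  maps <- contact_map_set(
    tibble::tibble(receptor_id = paste0("R", 1:4), pos_i = "p1", pos_j = "p2"),
    labels$receptor_id, ann
  )
  expect_identical(unname(contact_contingency(c("p1", "p2"), labels, maps)),
                   c(4L, 0L, 0L, 4L))
  # absent contact: (0, n+, 0, n-)
  expect_identical(unname(contact_contingency(c("p3", "p4"), labels, maps)),
                   c(0L, 4L, 0L, 4L))
  # mixed toy matches an exhaustive tally
  set.seed(4)
  edges <- tidyr::expand_grid(receptor_id = labels$receptor_id) |>
    dplyr::filter(runif(dplyr::n()) < 0.5) |>
    dplyr::mutate(pos_i = "p2", pos_j = "p3")
  maps2 <- contact_map_set(edges, labels$receptor_id, ann)
  counts <- contact_contingency(c("p2", "p3"), labels, maps2)
  have <- labels$receptor_id %in% edges$receptor_id
  expect_identical(unname(counts),
                   c(sum(have[1:4]), 4L - sum(have[1:4]),
                     sum(have[5:8]), 4L - sum(have[5:8])))
})

test_that("log-odds matches direct arithmetic including the zero correction", {
  expect_equal(contact_log_odds(7, 7, 7, 7), 0)
  expect_equal(contact_log_odds(10, 2, 3, 8), log(80 / 6), tolerance = 1e-12)
  # zero cells: 0.5 added everywhere
  expect_equal(contact_log_odds(4, 0, 0, 4), log(81), tolerance = 1e-12)
  expect_error(contact_log_odds(0, 0, 0, 0), "All-zero")
  # printed-variant flag for fidelity checks
  expect_equal(contact_log_odds(10, 2, 3, 8, formula = "printed"),
               log((10 / 8) * (3 / 2)), tolerance = 1e-12)
  # named-vector calling convention
  expect_equal(contact_log_odds(c(AA = 10, BB = 2, CC = 3, DD = 8)),
               log(80 / 6))
})

test_that("log-odds is antisymmetric under label flip, with zeros too", {
  set.seed(6)
  for (i in 1:200) {
    tabs <- rpois(4, 3)
    if (all(tabs == 0)) tabs[1] <- 1
    lhs <- contact_log_odds(tabs[1], tabs[2], tabs[3], tabs[4])
    rhs <- contact_log_odds(tabs[3], tabs[4], tabs[1], tabs[2])
    expect_equal(lhs, -rhs, tolerance = 1e-12)
  }
})

test_that("enrichment map recovers planted differential contacts", {
  n <- 200
  labels_vec <- rep(c(1L, 0L), each = n / 2)
  cm <- make_synthetic_contacts(n, 10, rbind(c(1, 5), c(2, 7)),
                                enrichment_prob = 0.9, background_prob = 0.1,
                                labels = labels_vec, seed = 13)
  labels <- tibble::tibble(receptor_id = cm$receptor_ids, label = labels_vec,
                           transducer_id = "GNAS")
  em <- enrichment_map(labels, cm, aggregate = FALSE)
  expect_equal(max(abs(em$normalized)), 1)
  planted <- dplyr::semi_join(em, cm$planted_pairs, by = c("pos_i", "pos_j"))
  expect_identical(nrow(planted), 2L)
  expect_true(all(planted$normalized >= 0.5))
})

test_that("label-shuffled enrichment is centered at zero", {
  n <- 200
  labels_vec <- rep(c(1L, 0L), each = n / 2)
  cm <- make_synthetic_contacts(n, 10, rbind(c(1, 5)), 0.9, 0.1,
                                labels = labels_vec, seed = 17)
  shuffled <- withr::with_seed(1, sample(labels_vec))
  em <- enrichment_map(tibble::tibble(receptor_id = cm$receptor_ids,
                                      label = shuffled), cm, aggregate = FALSE)
  expect_lt(abs(mean(em$log_odds)), 0.15)
})

test_that("exact null bands bracket null pairs and flag strong enrichment", {
  em <- tibble::tibble(
    pos_i = c("p1", "p1"), pos_j = c("p2", "p3"),
    AA = c(25L, 48L), BB = c(25L, 2L), CC = c(25L, 10L), DD = c(25L, 40L),
    log_odds = c(0, contact_log_odds(48, 2, 10, 40)),
    normalized = c(0, 1)
  )
  banded <- enrichment_null_band(em)
  # balanced table sits inside its own null band; the extreme one does not
  expect_true(banded$inside[1])
  expect_false(banded$inside[2])
  expect_true(all(banded$aa_lo <= banded$aa_hi))
  expect_true(all(banded$lo_lower <= banded$lo_upper))
  # each band holds at least 95% of the exact hypergeometric null mass
  for (i in 1:2) {
    n1 <- em$AA[i] + em$BB[i]; n0 <- em$CC[i] + em$DD[i]
    m <- em$AA[i] + em$CC[i]
    mass <- sum(stats::dhyper(banded$aa_lo[i]:banded$aa_hi[i], n1, n0, m))
    expect_gte(mass, 0.95)
  }
})

test_that("loop aggregation renames positions and collapses duplicates", {
  ann <- toy_annotation(c("p1", "p2", "p3", "p4"),
                        c("TM1", "ICL3", "ICL3", "Cterm"))
  maps <- contact_map_set(
    tibble::tibble(receptor_id = "R1",
                   pos_i = c("p1", "p1", "p2"), pos_j = c("p2", "p3", "p4")),
    c("R1", "R2"), ann
  )
  agg <- aggregate_loop_positions(maps)
  # p2 and p3 both become ICL3 -> the two p1 contacts collapse to one pair
  expect_identical(nrow(agg$contacts), 2L)
  expect_setequal(paste(agg$contacts$pos_i, agg$contacts$pos_j),
                  c("ICL3 p1", "Cterm ICL3"))
})

test_that("segment signatures aggregate and conserve pair sums", {
  ann <- toy_annotation(c("p1", "p2", "p3"), c("TM5", "TM6", "TM6"))
  em <- tibble::tibble(
    pos_i = c("p1", "p1"), pos_j = c("p2", "p3"),
    AA = 1, BB = 1, CC = 1, DD = 1,
    log_odds = c(0.4, -0.4), normalized = c(0.4, -0.4)
  )
  sig <- segment_signature(em, ann)
  expect_identical(nrow(sig), 1L)
  expect_equal(sig$signature, 0)
  expect_identical(c(sig$n_enriched, sig$n_depleted), c(1L, 1L))
  # conservation: total signature equals total pair value
  expect_equal(sum(sig$signature), sum(em$normalized))

  single <- segment_signature(
    tibble::tibble(pos_i = "p1", pos_j = "p2", AA = 1, BB = 1, CC = 1, DD = 1,
                   log_odds = 0.7, normalized = 0.7), ann
  )
  expect_equal(single$signature, 0.7)
  expect_error(
    segment_signature(tibble::tibble(pos_i = "qX", pos_j = "p1",
                                     normalized = 1), ann),
    "Unannotated"
  )
})

test_that("signature clustering groups planted transducer families", {
  sig <- function(v) tibble::tibble(segment_i = c("TM5", "TM1"),
                                    segment_j = c("TM6", "TM2"),
                                    signature = v,
                                    n_enriched = 1L, n_depleted = 0L)
  sigs <- list(Gs1 = sig(c(1, 0)), Gs2 = sig(c(0.9, 0.1)),
               Gi1 = sig(c(-1, 1)), Gi2 = sig(c(-0.9, 0.9)))
  hc <- cluster_signatures(sigs)
  groups <- stats::cutree(hc, k = 2)
  expect_identical(groups[["Gs1"]], groups[["Gs2"]])
  expect_identical(groups[["Gi1"]], groups[["Gi2"]])
  expect_false(groups[["Gs1"]] == groups[["Gi1"]])

  # identical signatures merge at height 0; input order does not matter
  hc0 <- cluster_signatures(list(A = sig(c(1, 1)), B = sig(c(1, 1)),
                                 C = sig(c(-1, 0))))
  expect_equal(min(hc0$height), 0)
  hc_perm <- cluster_signatures(sigs[c(3, 1, 4, 2)])
  expect_identical(stats::cutree(hc, 2), stats::cutree(hc_perm, 2)[names(cutree(hc, 2))])
})
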