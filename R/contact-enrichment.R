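SEGMENT_LEVELS <- c(
  "Nterm", paste0("TM", 1:7), "H8",
  paste0("ICL", 1:3), paste0("ECL", 1:3), "Cterm"
)

# Helical segments keep per-residue generic positions; loop/termini positions
# are aggregated to their segment label before pairing.
HELICAL_SEGMENTS <- c(paste0("TM", 1:7), "H8")

canonical_pairs <- function(df) {
  mutate(df,
    a = pmin(.data$pos_i, .data$pos_j),
    b = pmax(.data$pos_i, .data$pos_j),
    pos_i = .data$a, pos_j = .data$b
  ) |>
    select(-"a", -"b")
}

#' Construct a contact map set from a binary edge list
#'
#' @param contacts Tibble `receptor_id, pos_i, pos_j` of present contacts
#'   (one row per unordered pair per receptor).
#' @param receptor_ids All receptor ids covered (receptors with no contact
#'   still count in contingency tables).
#' @param annotation Tibble `position, segment` covering every position used.
#' @return A `contact_map_set`.
#' @export
contact_map_set <- function(contacts, receptor_ids, annotation) {
  stopifnot(all(c("receptor_id", "pos_i", "pos_j") %in% names(contacts)),
            all(c("position", "segment") %in% names(annotation)))
  if (any(contacts$pos_i == contacts$pos_j)) {
    abort("Self-contacts (zero diagonal violated) are not allowed.")
  }
  positions <- unique(c(contacts$pos_i, contacts$pos_j))
  missing <- setdiff(positions, annotation$position)
  if (length(missing) > 0) {
    abort(sprintf("Positions without a segment assignment: %s.",
                  paste(head(missing, 3), collapse = ", ")))
  }
  contacts <- canonical_pairs(contacts) |> dplyr::distinct()
  structure(
    list(contacts = contacts, receptor_ids = receptor_ids,
         positions = sort(unique(annotation$position)),
         annotation = annotation),
    class = "contact_map_set"
  )
}

#' @exportS3Method base::print
print.contact_map_set <- function(x, ...) {
  cat(sprintf("<contact_map_set> %d receptors, %d positions, %d contacts\n",
              length(x$receptor_ids), length(x$positions), nrow(x$contacts)))
  invisible(x)
}

#' Binarize probabilistic contact maps
#'
#' Retains contacts with probability strictly greater than the threshold
#' (0.5 by default). Input is a long edge list; if both orientations of a
#' pair are present their probabilities must agree (symmetry).
#'
#' @param prob_maps Tibble `receptor_id, pos_i, pos_j, probability`.
#' @param annotation Tibble `position, segment`.
#' @param receptor_ids Receptors covered (default: those appearing in
#'   `prob_maps`).
#' @param threshold Probability cutoff (strict).
#' @return A `contact_map_set`.
#' @export
binarize_contacts <- function(prob_maps, annotation,
                              receptor_ids = unique(prob_maps$receptor_id),
                              threshold = 0.5) {
  check_probability(prob_maps$probability, "probability")
  both <- canonical_pairs(prob_maps) |>
    group_by(.data$receptor_id, .data$pos_i, .data$pos_j) |>
    summarise(n_prob = dplyr::n_distinct(.data$probability), .groups = "drop")
  if (any(both$n_prob > 1)) {
    abort("Asymmetric contact probabilities: the two orientations of a pair disagree.")
  }
  kept <- dplyr::filter(prob_maps, .data$probability > threshold) |>
    select("receptor_id", "pos_i", "pos_j")
  contact_map_set(kept, receptor_ids, annotation)
}

#' Aggregate loop and termini positions to segment labels
#'
#' Positions annotated to intracellular/extracellular loops or the N-/C-
#' termini are renamed to their segment label; helical (TM1-TM7, H8)
#' positions keep their generic numbers. Duplicate pairs created by the
#' renaming are collapsed per receptor.
#'
#' @param maps A `contact_map_set`.
#' @return A `contact_map_set` over the aggregated position vocabulary.
#' @export
aggregate_loop_positions <- function(maps) {
  stopifnot(inherits(maps, "contact_map_set"))
  ann <- maps$annotation
  rename_to <- ifelse(ann$segment %in% HELICAL_SEGMENTS, ann$position, ann$segment)
  lut <- setNames(rename_to, ann$position)
  contacts <- maps$contacts |>
    mutate(pos_i = unname(lut[.data$pos_i]),
           pos_j = unname(lut[.data$pos_j])) |>
    canonical_pairs() |>
    dplyr::distinct()
  new_ann <- dplyr::bind_rows(
    dplyr::filter(ann, .data$segment %in% HELICAL_SEGMENTS),
    tibble(position = setdiff(unique(rename_to), ann$position),
           segment = setdiff(unique(rename_to), ann$position))
  ) |> dplyr::distinct()
  out <- maps
  out$contacts <- contacts
  out$annotation <- new_ann
  out$positions <- sort(unique(new_ann$position))
  out
}

#' Contingency counts for one contact pair
#'
#' AA = coupled receptors with the contact, BB = coupled without,
#' CC = non-coupled with, DD = non-coupled without.
#'
#' @param pair Character vector `c(pos_i, pos_j)`.
#' @param labels Tibble `receptor_id, label` (1 = coupled).
#' @param maps A `contact_map_set`.
#' @return Named integer vector `c(AA, BB, CC, DD)`.
#' @export
contact_contingency <- function(pair, labels, maps) {
  stopifnot(inherits(maps, "contact_map_set"), length(pair) == 2)
  if (!setequal(labels$receptor_id, maps$receptor_ids)) {
    abort("Label and contact-map receptor ids do not match.")
  }
  a <- min(pair); b <- max(pair)
  with_contact <- maps$contacts |>
    dplyr::filter(.data$pos_i == a, .data$pos_j == b) |>
    dplyr::pull("receptor_id")
  has <- labels$receptor_id %in% with_contact
  coupled <- labels$label == 1L
  c(AA = sum(coupled & has), BB = sum(coupled & !has),
    CC = sum(!coupled & has), DD = sum(!coupled & !has))
}

#' Log-odds ratio from a 2x2 contact contingency table
#'
#' Natural-log odds ratio `ln((AA * DD) / (BB * CC))`; positive values mean
#' the contact is seen more frequently in coupled receptors. When any cell
#' is zero, 0.5 is added to every cell (Haldane-Anscombe correction), which
#' preserves the label-flip antisymmetry. The literal printed variant
#' `log(AA/DD x CC/BB)` is available via `formula = "printed"` for fidelity
#' checks; it flips the sign of the standard odds ratio's log.
#'
#' @param AA,BB,CC,DD Non-negative counts (or a single named vector passed
#'   as `AA`).
#' @param formula `"standard"` (default) or `"printed"`.
#' @return Log-odds ratio (natural log).
#' @examples
#' contact_log_odds(10, 2, 3, 8)  # log(80/6)
#' @export
contact_log_odds <- function(AA, BB = NULL, CC = NULL, DD = NULL,
                             formula = c("standard", "printed")) {
  formula <- match.arg(formula)
  if (is.null(BB) && length(AA) == 4) {
    DD <- AA[[4]]; CC <- AA[[3]]; BB <- AA[[2]]; AA <- AA[[1]]
  }
  cells <- c(AA, BB, CC, DD)
  if (any(cells < 0)) abort("Counts must be non-negative.")
  if (all(cells == 0)) abort("All-zero contingency table.")
  if (any(cells == 0)) cells <- cells + 0.5
  if (formula == "standard") {
    # summed-log form: label flip swaps the two sums, so antisymmetry is
    # exact in floating point, not just mathematically
    (log(cells[1]) + log(cells[4])) - (log(cells[2]) + log(cells[3]))
  } else {
    log((cells[1] / cells[4]) * (cells[3] / cells[2]))
  }
}

#' Differential contact enrichment map for one transducer
#'
#' For every contact pair observed in at least one receptor (after loop and
#' termini aggregation), computes the coupled-vs-non-coupled log-odds ratio
#' and its MaxAbs-normalized value in \[-1, 1\].
#'
#' @param labels Tibble `receptor_id, label` (may carry `transducer_id`).
#' @param maps A `contact_map_set`.
#' @param aggregate Aggregate loops/termini first (default `TRUE`).
#' @param formula Passed to [contact_log_odds()].
#' @return An `enrichment_map`: tibble `pos_i, pos_j, AA, BB, CC, DD,
#'   log_odds, normalized` with attributes `transducer_id` and `annotation`.
#' @export
enrichment_map <- function(labels, maps, aggregate = TRUE,
                           formula = c("standard", "printed")) {
  formula <- match.arg(formula)
  stopifnot(inherits(maps, "contact_map_set"))
  if (!setequal(labels$receptor_id, maps$receptor_ids)) {
    abort("Label and contact-map receptor ids do not match.")
  }
  if (sum(labels$label == 1L) < 2 || sum(labels$label == 0L) < 2) {
    abort("Need at least 2 receptors per class for enrichment.")
  }
  if (aggregate) maps <- aggregate_loop_positions(maps)

  n_pos <- sum(labels$label == 1L)
  n_neg <- sum(labels$label == 0L)
  coupled_ids <- labels$receptor_id[labels$label == 1L]

  counts <- maps$contacts |>
    mutate(coupled = .data$receptor_id %in% coupled_ids) |>
    group_by(.data$pos_i, .data$pos_j) |>
    summarise(AA = sum(.data$coupled), CC = sum(!.data$coupled),
              .groups = "drop") |>
    mutate(BB = n_pos - .data$AA, DD = n_neg - .data$CC)

  counts$log_odds <- vapply(seq_len(nrow(counts)), function(i) {
    contact_log_odds(counts$AA[i], counts$BB[i], counts$CC[i], counts$DD[i],
                     formula = formula)
  }, numeric(1))
  max_abs <- max(abs(counts$log_odds))
  counts$normalized <- if (max_abs > 0) counts$log_odds / max_abs else counts$log_odds

  out <- select(counts, "pos_i", "pos_j", "AA", "BB", "CC", "DD",
                "log_odds", "normalized")
  attr(out, "transducer_id") <- if ("transducer_id" %in% names(labels)) {
    labels$transducer_id[1]
  } else {
    NA_character_
  }
  attr(out, "annotation") <- maps$annotation
  class(out) <- c("enrichment_map", class(out))
  out
}

#' Permutation null for contact enrichment
#'
#' Recomputes raw per-pair log-odds under label permutations (class counts
#' preserved), yielding a null distribution against which observed
#' enrichments can be banded.
#'
#' @param labels,maps,aggregate,formula As in [enrichment_map()].
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return Tibble `perm, pos_i, pos_j, log_odds`.
#' @export
enrichment_null <- function(labels, maps, n_perm = 50L, seed = 1L,
                            aggregate = TRUE, formula = "standard") {
  purrr::map_dfr(seq_len(n_perm), function(p) {
    shuffled <- labels
    shuffled$label <- with_seed(substream_seed(seed, paste0("perm", p)),
                                sample(labels$label))
    em <- enrichment_map(shuffled, maps, aggregate = aggregate,
                         formula = formula)
    tibble(perm = p, pos_i = em$pos_i, pos_j = em$pos_j,
           log_odds = em$log_odds)
  })
}

#' Exact permutation-null acceptance bands for contact enrichment
#'
#' Under label permutation with the pair's margins fixed, the number of
#' coupled receptors carrying a contact is hypergeometric; the exact
#' permutation null therefore needs no sampling. For each pair this returns
#' the central acceptance region holding at least `level` of the null mass
#' (equal-tail, inclusive endpoints — conservative on the discrete null),
#' expressed both as bounds on the coupled-carrier count and as the
#' corresponding log-odds band.
#'
#' @param enrichment An [enrichment_map()] (its `AA..DD` columns carry the
#'   margins).
#' @param level Nominal band level (default 0.95).
#' @param formula Passed to [contact_log_odds()].
#' @return The enrichment tibble with columns `aa_lo, aa_hi, lo_lower,
#'   lo_upper, inside` appended.
#' @export
enrichment_null_band <- function(enrichment, level = 0.95,
                                 formula = "standard") {
  stopifnot(level > 0, level < 1)
  tail_mass <- (1 - level) / 2
  n1 <- enrichment$AA + enrichment$BB
  n0 <- enrichment$CC + enrichment$DD
  m <- enrichment$AA + enrichment$CC
  bounds <- vapply(seq_len(nrow(enrichment)), function(i) {
    supp <- max(0, m[i] - n0[i]):min(m[i], n1[i])
    pr <- stats::dhyper(supp, n1[i], n0[i], m[i])
    lo <- supp[which(cumsum(pr) > tail_mass)[1]]
    hi <- supp[rev(which(rev(cumsum(rev(pr))) > tail_mass))[1]]
    c(lo, hi)
  }, numeric(2))
  out <- enrichment
  out$aa_lo <- bounds[1, ]
  out$aa_hi <- bounds[2, ]
  out$lo_lower <- vapply(seq_len(nrow(out)), function(i) {
    contact_log_odds(out$aa_lo[i], n1[i] - out$aa_lo[i],
                     m[i] - out$aa_lo[i], n0[i] - m[i] + out$aa_lo[i],
                     formula = formula)
  }, numeric(1))
  out$lo_upper <- vapply(seq_len(nrow(out)), function(i) {
    contact_log_odds(out$aa_hi[i], n1[i] - out$aa_hi[i],
                     m[i] - out$aa_hi[i], n0[i] - m[i] + out$aa_hi[i],
                     formula = formula)
  }, numeric(1))
  out$inside <- out$AA >= out$aa_lo & out$AA <= out$aa_hi
  out
}

position_segment <- function(positions, annotation) {
  lut <- setNames(annotation$segment, annotation$position)
  seg <- unname(lut[positions])
  # aggregated positions are already segment labels
  seg[is.na(seg) & positions %in% SEGMENT_LEVELS] <-
    positions[is.na(seg) & positions %in% SEGMENT_LEVELS]
  if (anyNA(seg)) {
    abort(sprintf("Unannotated position(s): %s.",
                  paste(head(unique(positions[is.na(seg)]), 3), collapse = ", ")))
  }
  seg
}

#' Segment-level contact enrichment signature
#'
#' Aggregates an enrichment map to unordered secondary-structure segment
#' pairs: the sum of member-pair normalized log-odds plus the counts of
#' enriched (> 0) and depleted (< 0) pairs.
#'
#' @param enrichment An `enrichment_map`.
#' @param annotation Tibble `position, segment`; defaults to the one stored
#'   on the map.
#' @return Tibble `segment_i, segment_j, signature, n_enriched, n_depleted`.
#' @export
segment_signature <- function(enrichment, annotation = NULL) {
  annotation <- annotation %||% attr(enrichment, "annotation")
  if (is.null(annotation)) abort("No segment annotation available.")
  seg_i <- position_segment(enrichment$pos_i, annotation)
  seg_j <- position_segment(enrichment$pos_j, annotation)
  tibble(
    segment_i = pmin(seg_i, seg_j),
    segment_j = pmax(seg_i, seg_j),
    value = enrichment$normalized
  ) |>
    group_by(.data$segment_i, .data$segment_j) |>
    summarise(
      signature = sum(.data$value),
      n_enriched = sum(.data$value > 0),
      n_depleted = sum(.data$value < 0),
      .groups = "drop"
    )
}

#' Cluster transducer families by their contact signatures
#'
#' Average-linkage hierarchical clustering on the Euclidean distances
#' between segment-signature vectors (missing segment pairs filled with 0).
#' Transducers are ordered alphabetically before clustering so the tree is
#' independent of input order.
#'
#' @param signatures Named list of [segment_signature()] tibbles, one per
#'   transducer.
#' @return An `hclust` object with transducer labels.
#' @export
cluster_signatures <- function(signatures) {
  if (length(signatures) < 2) abort("Need at least 2 transducers to cluster.")
  if (is.null(names(signatures))) abort("`signatures` must be named by transducer.")
  wide <- purrr::imap_dfr(signatures, function(sig, id) {
    mutate(sig, transducer_id = id,
           pair = paste(.data$segment_i, .data$segment_j, sep = ":"))
  }) |>
    select("transducer_id", "pair", "signature") |>
    tidyr::pivot_wider(names_from = "pair", values_from = "signature",
                       values_fill = 0) |>
    arrange(.data$transducer_id)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$transducer_id
  mat <- mat[, sort(colnames(mat)), drop = FALSE]
  hclust(dist(mat, method = "euclidean"), method = "average")
}
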