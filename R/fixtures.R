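#' Specification for a synthetic coupling study
#'
#' Describes a synthetic GPCRome with a plantable discriminative attention
#' head: embeddings are wide Gaussian-noise matrices structured as
#' `n_heads` contiguous blocks of `head_dim` dimensions (1280 = 20 x 64 by
#' default, mirroring the pooled transformer representation), and exactly one
#' head of one layer carries a mean shift of `effect_size` between coupled
#' and non-coupled receptors. The continuous binding activities are drawn
#' label-conditionally so that the assay binarization rule recovers the
#' planted labels exactly.
#'
#' @param n_receptors Number of receptors.
#' @param n_layers Number of embedding layers to emit.
#' @param n_heads Attention heads per layer (embedding width is
#'   `n_heads * head_dim`).
#' @param head_dim Dimensions contributed by each head.
#' @param planted_layer Layer index (1-based position in the emitted list)
#'   carrying the signal.
#' @param planted_head Head index in `1:n_heads` carrying the signal.
#' @param effect_size Mean shift, in noise standard deviations when
#'   `noise_sd = 1`, applied to the planted head's dimensions for coupled
#'   receptors.
#' @param noise_sd Standard deviation of the Gaussian embedding noise.
#' @param coupled_fraction Fraction of receptors labelled coupled, in (0, 1).
#' @param assay Assay tag driving the activity scale: `"TGF"` (logRAi,
#'   threshold -1), `"GEMTA"` or `"UCM"` (threshold 0).
#' @param transducer_id Identifier for the single synthetic transducer column.
#' @param sequence_length Length of the synthetic receptor sequences.
#' @param seed Master RNG seed.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_receptors = 200L,
                           n_layers = 4L,
                           n_heads = 20L,
                           head_dim = 64L,
                           planted_layer = 2L,
                           planted_head = 7L,
                           effect_size = 2,
                           noise_sd = 1,
                           coupled_fraction = 0.5,
                           assay = c("TGF", "GEMTA", "UCM"),
                           transducer_id = "GNAI1",
                           sequence_length = 300L,
                           seed = 1L) {
  assay <- match.arg(assay)
  stopifnot(
    n_receptors >= 1, n_layers >= 1, n_heads >= 1, head_dim >= 1,
    planted_layer >= 1, planted_layer <= n_layers,
    planted_head >= 1, planted_head <= n_heads,
    effect_size >= 0, noise_sd > 0,
    coupled_fraction > 0, coupled_fraction < 1,
    sequence_length >= 1
  )
  n_coupled <- round(n_receptors * coupled_fraction)
  if (n_coupled < 2 || n_receptors - n_coupled < 2) {
    abort("Degenerate spec: each class needs at least 2 receptors.")
  }
  structure(
    list(
      n_receptors = as.integer(n_receptors), n_layers = as.integer(n_layers),
      n_heads = as.integer(n_heads), head_dim = as.integer(head_dim),
      planted_layer = as.integer(planted_layer),
      planted_head = as.integer(planted_head),
      effect_size = effect_size, noise_sd = noise_sd,
      coupled_fraction = coupled_fraction, assay = assay,
      transducer_id = transducer_id,
      sequence_length = as.integer(sequence_length),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# Label-conditional activities that are guaranteed to binarize back to the
# planted labels: Gaussians straddling the assay threshold, resampled on the
# (rare) wrong side of the strict cutoff.
draw_activities <- function(labels, assay) {
  params <- switch(assay,
    TGF   = list(threshold = -1, mu1 = 0, mu0 = -2, sd = 0.3),
    GEMTA = list(threshold = 0, mu1 = 1, mu0 = -1, sd = 0.3),
    UCM   = list(threshold = 0, mu1 = 1, mu0 = -1, sd = 0.3)
  )
  mu <- ifelse(labels == 1L, params$mu1, params$mu0)
  x <- rnorm(length(labels), mean = mu, sd = params$sd)
  bad <- which((labels == 1L) != (x > params$threshold))
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean = mu[bad], sd = params$sd)
    bad <- bad[(labels[bad] == 1L) != (x[bad] > params$threshold)]
  }
  x
}

random_sequences <- function(n, length, ids) {
  seqs <- vapply(
    seq_len(n),
    function(i) paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = ""),
    character(1)
  )
  setNames(seqs, ids)
}

#' Generate a synthetic coupling study with a planted discriminative head
#'
#' Emits per-layer mean-pooled embedding matrices, a continuous coupling
#' table, synthetic receptor sequences, and a truth record. Embeddings are
#' i.i.d. Gaussian noise everywhere except the planted head of the planted
#' layer, whose dimensions are shifted by `effect_size` for coupled
#' receptors. Activities are drawn so the assay rule reproduces the planted
#' labels exactly (see [binarize_activity()]).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with components `embeddings` (list of [layer_embeddings()]
#'   objects, one per layer), `coupling` (a [coupling_matrix()]), `sequences`
#'   (named character vector), and `truth` (planted labels, head, layer).
#' @examples
#' fx <- make_synthetic_couplings(synthetic_spec(n_receptors = 40, seed = 7))
#' dim(fx$embeddings[[2]]$matrix)
#' @export
make_synthetic_couplings <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  width <- spec$n_heads * spec$head_dim
  ids <- sprintf("RCPT%04d", seq_len(spec$n_receptors))

  n_coupled <- round(spec$n_receptors * spec$coupled_fraction)
  labels <- with_seed(substream_seed(spec$seed, "labels"), {
    sample(c(rep(1L, n_coupled), rep(0L, spec$n_receptors - n_coupled)))
  })

  embeddings <- lapply(seq_len(spec$n_layers), function(l) {
    mat <- with_seed(substream_seed(spec$seed, paste0("layer", l)), {
      matrix(rnorm(spec$n_receptors * width, sd = spec$noise_sd),
             nrow = spec$n_receptors, ncol = width)
    })
    if (l == spec$planted_layer && spec$effect_size > 0) {
      cols <- head_columns(spec$planted_head, spec$head_dim)
      mat[labels == 1L, cols] <- mat[labels == 1L, cols] + spec$effect_size
    }
    rownames(mat) <- ids
    layer_embeddings(mat, receptor_ids = ids, layer = l - 1L)
  })

  activities <- with_seed(
    substream_seed(spec$seed, "activities"),
    draw_activities(labels, spec$assay)
  )
  values <- matrix(activities, ncol = 1,
                   dimnames = list(ids, spec$transducer_id))
  coupling <- coupling_matrix(values, assay = spec$assay)

  sequences <- with_seed(
    substream_seed(spec$seed, "sequences"),
    random_sequences(spec$n_receptors, spec$sequence_length, ids)
  )

  list(
    embeddings = embeddings,
    coupling = coupling,
    sequences = sequences,
    truth = list(
      labels = setNames(labels, ids),
      planted_layer = spec$planted_layer,
      planted_head = spec$planted_head,
      spec = spec
    )
  )
}

# Column indices of head h (1-based) in the concatenated representation.
head_columns <- function(h, head_dim) {
  ((h - 1L) * head_dim + 1L):(h * head_dim)
}

#' Generate synthetic contact maps with plantable coupling-associated pairs
#'
#' Each receptor receives a symmetric binary contact map over `n_positions`
#' generic positions. Planted pairs are present with probability
#' `enrichment_prob` in coupled receptors and `background_prob` otherwise;
#' every other pair is present with `background_prob` regardless of label.
#'
#' @param n_receptors Number of receptors (must match `length(labels)`).
#' @param n_positions Number of generic residue positions.
#' @param planted_pairs Two-column matrix or data frame of 1-based position
#'   index pairs to enrich.
#' @param enrichment_prob,background_prob Contact probabilities in \[0, 1\].
#' @param labels Binary vector (1 = coupled).
#' @param seed RNG seed.
#' @param n_segments Number of transmembrane-like segments the positions are
#'   split into for the bundled annotation table.
#' @return A `contact_map_set`: list with `contacts` (tibble
#'   `receptor_id, pos_i, pos_j`), `receptor_ids`, `positions`, and
#'   `annotation` (tibble `position, segment`).
#' @export
make_synthetic_contacts <- function(n_receptors, n_positions, planted_pairs,
                                    enrichment_prob, background_prob,
                                    labels, seed = 1L, n_segments = 7L) {
  check_probability(enrichment_prob, "enrichment_prob")
  check_probability(background_prob, "background_prob")
  stopifnot(length(labels) == n_receptors, all(labels %in% c(0L, 1L)))
  planted_pairs <- as.matrix(planted_pairs)
  if (ncol(planted_pairs) != 2) abort("`planted_pairs` needs two columns.")
  if (any(planted_pairs < 1) || any(planted_pairs > n_positions)) {
    abort("Planted pair indices out of position range.")
  }
  if (any(planted_pairs[, 1] == planted_pairs[, 2])) {
    abort("Planted pairs must be off-diagonal.")
  }
  # canonical upper-triangle orientation
  planted_pairs <- t(apply(planted_pairs, 1, sort))

  positions <- sprintf("p%03d", seq_len(n_positions))
  ids <- sprintf("RCPT%04d", seq_len(n_receptors))
  all_pairs <- t(combn(n_positions, 2))
  pair_key <- paste(all_pairs[, 1], all_pairs[, 2])
  planted_key <- paste(planted_pairs[, 1], planted_pairs[, 2])
  is_planted <- pair_key %in% planted_key

  contacts <- with_seed(substream_seed(seed, "contacts"), {
    purrr::map_dfr(seq_len(n_receptors), function(r) {
      p <- ifelse(is_planted & labels[r] == 1L, enrichment_prob, background_prob)
      keep <- runif(nrow(all_pairs)) < p
      tibble(
        receptor_id = ids[r],
        pos_i = positions[all_pairs[keep, 1]],
        pos_j = positions[all_pairs[keep, 2]]
      )
    })
  })

  segments <- paste0("TM", seq_len(n_segments))
  annotation <- tibble(
    position = positions,
    segment = segments[((seq_len(n_positions) - 1L) %% n_segments) + 1L]
  )

  structure(
    list(contacts = contacts, receptor_ids = ids, positions = positions,
         annotation = annotation,
         planted_pairs = tibble(
           pos_i = positions[planted_pairs[, 1]],
           pos_j = positions[planted_pairs[, 2]]
         )),
    class = "contact_map_set"
  )
}

#' Generate a synthetic GPCRome with class structure planted in one layer
#'
#' One designated layer carries class-wise mean-separated Gaussian blobs
#' (class means are random directions scaled to `class_separation`); every
#' other layer is unstructured noise. Used to exercise the embedded-space
#' layer scan.
#'
#' @param n_per_class Named integer vector of class sizes (names become the
#'   class labels).
#' @param class_separation Euclidean distance scale between class means.
#' @param n_layers Number of layers to emit.
#' @param planted_layer Position (1-based) of the structured layer.
#' @param width Embedding width.
#' @param noise_sd Noise standard deviation.
#' @param seed RNG seed.
#' @return List with `embeddings` (list of [layer_embeddings()]) and `labels`
#'   (named character vector of class labels).
#' @export
make_synthetic_gpcrome <- function(n_per_class, class_separation,
                                   n_layers = 3L, planted_layer = 2L,
                                   width = 1280L, noise_sd = 1,
                                   seed = 1L) {
  if (length(n_per_class) < 2) abort("Need at least 2 classes.")
  if (is.null(names(n_per_class))) {
    names(n_per_class) <- paste0("class", seq_along(n_per_class))
  }
  stopifnot(planted_layer >= 1, planted_layer <= n_layers, class_separation >= 0)
  n <- sum(n_per_class)
  ids <- sprintf("RCPT%04d", seq_len(n))
  labels <- setNames(rep(names(n_per_class), n_per_class), ids)

  class_means <- with_seed(substream_seed(seed, "class-means"), {
    m <- matrix(rnorm(length(n_per_class) * width), nrow = length(n_per_class))
    m <- m / sqrt(rowSums(m^2)) * class_separation
    rownames(m) <- names(n_per_class)
    m
  })

  embeddings <- lapply(seq_len(n_layers), function(l) {
    mat <- with_seed(substream_seed(seed, paste0("gpcrome-layer", l)), {
      matrix(rnorm(n * width, sd = noise_sd), nrow = n, ncol = width)
    })
    if (l == planted_layer && class_separation > 0) {
      mat <- mat + class_means[labels, , drop = FALSE]
    }
    rownames(mat) <- ids
    layer_embeddings(mat, receptor_ids = ids, layer = l - 1L)
  })

  list(embeddings = embeddings, labels = labels)
}

#' Write sequences to a FASTA file
#'
#' Plain-text writer (60-column wrapping) so fixture output is byte-stable.
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  lines <- unlist(lapply(names(sequences), function(id) {
    s <- sequences[[id]]
    body <- substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60), nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readAAStringSet(path)
    return(setNames(as.character(set), names(set)))
  }
  lines <- readLines(path)
  idx <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", lines[idx])
  grp <- cumsum(idx)
  seqs <- vapply(split(lines[!idx], grp[!idx]),
                 function(x) paste(x, collapse = ""), character(1))
  setNames(unname(seqs), ids)
}
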