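#' Parse a variant specification string
#'
#' Accepts the `GENE/D294H` convention — receptor identifier, then one or
#' more comma-separated substitutions of the form reference amino acid,
#' 1-based position, alternate amino acid.
#'
#' @param text Variant string, e.g. `"MC1R/D294H"` or `"GENE/A12V,C30R"`.
#' @return A `variant_spec`: list with `receptor_id` and `substitutions`
#'   (tibble `ref, position, alt`).
#' @examples
#' parse_variant("MC1R/D294H")
#' @export
parse_variant <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !nzchar(parts[1]) || !nzchar(parts[2])) {
    abort(sprintf("Malformed variant '%s'; expected 'ID/XnY'.", text))
  }
  subs <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
  pattern <- "^([A-Za-z])([0-9]+)([A-Za-z])$"
  ok <- grepl(pattern, subs)
  if (!all(ok)) {
    abort(sprintf("Malformed substitution '%s'; expected e.g. 'D294H'.",
                  subs[!ok][1]))
  }
  ref <- toupper(sub(pattern, "\\1", subs))
  alt <- toupper(sub(pattern, "\\3", subs))
  position <- as.integer(sub(pattern, "\\2", subs))
  bad_aa <- setdiff(c(ref, alt), AA_ALPHABET)
  if (length(bad_aa) > 0) {
    abort(sprintf("Non-amino-acid letter(s) in variant: %s.",
                  paste(bad_aa, collapse = ", ")))
  }
  if (any(position < 1)) abort("Substitution positions are 1-based (>= 1).")
  structure(
    list(receptor_id = parts[1],
         substitutions = tibble(ref = ref, position = position, alt = alt)),
    class = "variant_spec"
  )
}

#' @exportS3Method base::print
print.variant_spec <- function(x, ...) {
  cat(sprintf("<variant_spec> %s/%s\n", x$receptor_id,
              paste0(x$substitutions$ref, x$substitutions$position,
                     x$substitutions$alt, collapse = ",")))
  invisible(x)
}

#' Apply substitutions to a sequence
#'
#' Validates each substitution against the supplied canonical sequence
#' (1-based positions; the reference residue must match) and returns the
#' substituted sequence, length preserved.
#'
#' @param sequence Wild-type amino-acid string.
#' @param spec A `variant_spec` from [parse_variant()].
#' @return The variant sequence.
#' @examples
#' apply_substitution("ACD", parse_variant("X/C2W")) # "AWD"
#' @export
apply_substitution <- function(sequence, spec) {
  stopifnot(inherits(spec, "variant_spec"))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(spec$substitutions))) {
    s <- spec$substitutions[i, ]
    if (s$position > length(chars)) {
      abort(sprintf("Position %d out of range (sequence length %d).",
                    s$position, length(chars)))
    }
    if (chars[s$position] != s$ref) {
      abort(sprintf(
        "Reference mismatch at position %d: found '%s', expected '%s'.",
        s$position, chars[s$position], s$ref
      ))
    }
    chars[s$position] <- s$alt
  }
  paste(chars, collapse = "")
}

#' Classify a coupling switch between wild type and variant
#'
#' Coupled means predicted probability strictly above the threshold (0.5).
#' Gain: variant coupled, wild type uncoupled. Loss: wild type coupled,
#' variant uncoupled. Otherwise the wild-type state is retained.
#'
#' @param wt_prob,var_prob Predicted coupling probabilities in \[0, 1\].
#' @param threshold Coupling threshold (default 0.5; exactly the threshold
#'   is uncoupled).
#' @return One of `"gain"`, `"loss"`, `"retained_coupled"`,
#'   `"retained_uncoupled"` (vectorized).
#' @examples
#' call_switch(0.3, 0.7)  # "gain"
#' call_switch(0.5, 0.5)  # "retained_uncoupled"
#' @export
call_switch <- function(wt_prob, var_prob, threshold = 0.5) {
  check_probability(wt_prob, "wt_prob")
  check_probability(var_prob, "var_prob")
  wt_coupled <- wt_prob > threshold
  var_coupled <- var_prob > threshold
  dplyr::case_when(
    !wt_coupled & var_coupled ~ "gain",
    wt_coupled & !var_coupled ~ "loss",
    wt_coupled & var_coupled ~ "retained_coupled",
    TRUE ~ "retained_uncoupled"
  )
}

#' Filter spliceform records by 7TM coverage and expression
#'
#' Retains isoforms whose retained 7TM-segment fraction meets
#' `min_tm_fraction` and whose maximal tissue expression meets `min_tpm`
#' (both comparisons inclusive). Isoforms with unknown 7TM fraction (`NA`)
#' pass the coverage cutoff only when `min_tm_fraction = 0`.
#'
#' @param records Tibble with columns `tm_fraction` (in \[0, 1\] or `NA`)
#'   and `tpm` (>= 0); other columns pass through.
#' @param min_tm_fraction Minimum retained 7TM fraction (e.g. 0.25, 0.5,
#'   0.75, 1).
#' @param min_tpm Minimum expression in TPM (default 1).
#' @return Filtered tibble.
#' @export
filter_isoforms <- function(records, min_tm_fraction = 0, min_tpm = 1) {
  stopifnot(all(c("tm_fraction", "tpm") %in% names(records)),
            min_tm_fraction >= 0, min_tm_fraction <= 1, min_tpm >= 0)
  if (any(records$tpm < 0, na.rm = TRUE)) abort("TPM must be non-negative.")
  dplyr::filter(
    records,
    (ifelse(is.na(.data$tm_fraction), min_tm_fraction == 0,
            .data$tm_fraction >= min_tm_fraction)),
    .data$tpm >= min_tpm
  )
}

#' Fraction of annotated 7TM residues retained by an isoform
#'
#' Counts annotated transmembrane positions of the canonical sequence that
#' are retained (identical residue at the same 1-based position) in the
#' isoform.
#'
#' @param canonical,isoform Amino-acid strings.
#' @param tm_positions Integer positions of the canonical sequence annotated
#'   to TM1-TM7.
#' @return Fraction in \[0, 1\], or `NA` when no annotation is supplied.
#' @export
tm_fraction_retained <- function(canonical, isoform, tm_positions) {
  if (length(tm_positions) == 0) return(NA_real_)
  can <- strsplit(canonical, "", fixed = TRUE)[[1]]
  iso <- strsplit(isoform, "", fixed = TRUE)[[1]]
  retained <- vapply(tm_positions, function(p) {
    p <= length(iso) && p <= length(can) && iso[p] == can[p]
  }, logical(1))
  mean(retained)
}

#' Profile a variant's coupling switches and space trajectory
#'
#' Embeds the wild-type and variant sequences at each model's layer with
#' the shared provider, projects both through each model's stored PCA,
#' predicts coupling probabilities, and calls per-transducer switches; a
#' trajectory in the embedded receptor space is attached when a `space` is
#' supplied.
#'
#' @param wt_sequence Wild-type amino-acid sequence.
#' @param variant Either a `variant_spec` (substitutions applied to
#'   `wt_sequence`) or a full replacement sequence (isoforms).
#' @param models Named list of `trained_coupler` objects (one per
#'   transducer).
#' @param provider Provider key or function (see [resolve_provider()]).
#' @param space Optional `embedded_space` for the trajectory.
#' @return A `variant_profile`: tibble `transducer_id, wt_prob, var_prob,
#'   call` with attribute `trajectory`.
#' @export
profile_variant <- function(wt_sequence, variant, models,
                            provider = "synthetic", space = NULL) {
  stopifnot(length(models) > 0)
  f <- resolve_provider(provider)
  var_sequence <- if (inherits(variant, "variant_spec")) {
    apply_substitution(wt_sequence, variant)
  } else {
    check_sequence(variant)
  }
  check_sequence(wt_sequence)

  calls <- purrr::imap_dfr(models, function(model, id) {
    wt_emb <- f(wt_sequence, model$layer)
    var_emb <- f(var_sequence, model$layer)
    wt_prob <- predict(model, wt_emb, type = "prob")
    var_prob <- predict(model, var_emb, type = "prob")
    tibble(
      transducer_id = id, wt_prob = wt_prob, var_prob = var_prob,
      call = call_switch(wt_prob, var_prob, threshold = model$threshold)
    )
  })
  if (!is.null(space)) {
    attr(calls, "trajectory") <- trajectory(
      space,
      f(wt_sequence, space$layer),
      f(var_sequence, space$layer)
    )
  }
  class(calls) <- c("variant_profile", class(calls))
  calls
}
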