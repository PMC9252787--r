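#' Default transducer vocabulary
#'
#' The 17 G protein / beta-arrestin transducer families the default models
#' cover. The vocabulary is configuration, not a constraint: coupling tables
#' may carry any subset (the three assays profile different transducer sets).
#'
#' @format Character vector of length 17.
#' @export
TRANSDUCERS <- c(
  "GNAS", "GNAL",
  "GNAI1", "GNAI2", "GNAI3", "GoA", "GoB", "GNAZ",
  "GNAQ", "GNA11", "GNA14", "GNA15",
  "GNA12", "GNA13",
  "Barr1", "Barr2", "Barr2-GRK2"
)

assay_threshold <- function(assay) {
  switch(assay, TGF = -1, GEMTA = 0, UCM = 0,
         abort(sprintf("Unknown assay '%s'; expected TGF, GEMTA or UCM.", assay)))
}

#' Construct a coupling matrix
#'
#' Container for continuous receptor-by-transducer binding activities tagged
#' with the assay that produced them: logRAi for the TGF-alpha shedding
#' assay, double-normalized Emax for the GEMTA biosensor assay, or relative
#' activity for the unified coupling map (UCM). Missing measurements are kept
#' as `NA` and excluded from downstream labels.
#'
#' @param values Numeric matrix (receptors x transducers) with row and column
#'   names, `NA` for missing cells.
#' @param assay One of `"TGF"`, `"GEMTA"`, `"UCM"`.
#' @return A `coupling_matrix` object.
#' @export
coupling_matrix <- function(values, assay = c("TGF", "GEMTA", "UCM")) {
  assay <- match.arg(assay)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry receptor row names and transducer column names.")
  }
  if (anyDuplicated(rownames(values))) abort("Duplicate receptor ids.")
  if (anyDuplicated(colnames(values))) abort("Duplicate transducer ids.")
  storage.mode(values) <- "double"
  structure(
    list(values = values, receptor_ids = rownames(values),
         transducer_ids = colnames(values), assay = assay),
    class = "coupling_matrix"
  )
}

#' @exportS3Method base::print
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("<coupling_matrix> %d receptors x %d transducers, assay %s (%d missing)\n",
              nrow(x$values), ncol(x$values), x$assay, sum(is.na(x$values))))
  invisible(x)
}

#' Binarize a continuous binding activity
#'
#' Applies the assay-specific coupling rule with strict inequalities:
#' TGF logRAi > -1, GEMTA double-normalized Emax > 0, UCM relative
#' activity > 0. Boundary values are non-coupled; `NA` propagates as `NA`
#' (missing, excluded from labels).
#'
#' @param value Numeric vector of activities.
#' @param assay One of `"TGF"`, `"GEMTA"`, `"UCM"`.
#' @return Integer vector of labels (1 coupled, 0 non-coupled, `NA` missing).
#' @examples
#' binarize_activity(c(-0.5, -1, -2), "TGF")  # 1 0 0
#' @export
binarize_activity <- function(value, assay) {
  if (!is.character(assay) || length(assay) != 1L) {
    abort("`assay` must be a single string.")
  }
  thr <- assay_threshold(assay)
  if (!is.numeric(value)) abort("`value` must be numeric.")
  if (any(is.infinite(value))) abort("Activities must be finite or NA.")
  as.integer(value > thr)
}

#' Read a coupling table from TSV
#'
#' Tab-delimited UTF-8 with a header row of transducer ids and a first column
#' of receptor ids; empty cells are missing. The assay is always supplied by
#' the caller, never inferred from the data.
#'
#' @param path TSV path.
#' @param assay One of `"TGF"`, `"GEMTA"`, `"UCM"`.
#' @return A [coupling_matrix()].
#' @export
read_coupling_table <- function(path, assay) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    receptor_id = readr::col_character()
  ), progress = FALSE)
  if (names(df)[1] != "receptor_id") {
    names(df)[1] <- "receptor_id"
  }
  if (anyDuplicated(df$receptor_id)) {
    abort(sprintf("Duplicate receptor ids in %s.", path))
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$receptor_id
  coupling_matrix(values, assay = assay)
}

#' Write a coupling table to TSV
#'
#' @param x A [coupling_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coupling_table <- function(x, path) {
  stopifnot(inherits(x, "coupling_matrix"))
  df <- tibble(receptor_id = x$receptor_ids)
  df <- dplyr::bind_cols(df, as_tibble(x$values))
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' Per-transducer binary label vector
#'
#' Applies [binarize_activity()] to one transducer column, dropping missing
#' measurements and preserving receptor order.
#'
#' @param x A [coupling_matrix()].
#' @param transducer Transducer id present in `x`.
#' @return Tibble with columns `receptor_id`, `value`, `label` (0/1),
#'   `transducer_id`, `assay`; one row per receptor with a measurement.
#' @examples
#' cm <- coupling_matrix(
#'   matrix(c(-2, -1, -0.9), ncol = 1,
#'          dimnames = list(c("R1", "R2", "R3"), "GNAS")),
#'   assay = "TGF"
#' )
#' label_vector(cm, "GNAS")$label  # 0 0 1
#' @export
label_vector <- function(x, transducer) {
  stopifnot(inherits(x, "coupling_matrix"))
  if (!transducer %in% x$transducer_ids) {
    abort(sprintf("Unknown transducer id '%s'.", transducer))
  }
  v <- x$values[, transducer]
  keep <- !is.na(v)
  tibble(
    receptor_id = x$receptor_ids[keep],
    value = unname(v[keep]),
    label = binarize_activity(unname(v[keep]), x$assay),
    transducer_id = transducer,
    assay = x$assay
  )
}
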