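#' Protein-level quantification tables
#'
#' A `protein_quant` is a tibble with one row per protein and the columns
#' `protein_id`, `gene_symbol`, `peptide_count`, `protein_fdr`, followed by one
#' numeric intensity column per sample (total precursor ion / LFQ intensity,
#' arbitrary units; `NA` = not detected). The experimental design — which
#' tumour model and tumour type each sample belongs to — travels with the
#' table as the `design` attribute, a tibble with columns `sample`, `model`,
#' `tumor_type` and `replicate`.
#'
#' Invariants enforced at construction: unique `protein_id`s, unique sample
#' identifiers, every sample mapped to exactly one model, every model to
#' exactly one tumour type, and non-negative intensities where present.
#'
#' @param quant A data frame with the metadata columns above plus one numeric
#'   column per sample named in `design$sample`.
#' @param design A data frame with columns `sample`, `model`, `tumor_type`,
#'   `replicate`, or a nested list `list(sample = list(model=, tumor_type=,
#'   replicate=))` as read from a YAML/JSON design map.
#' @return A `protein_quant` tibble.
#' @examples
#' quant <- tibble::tibble(
#'   protein_id = c("P1", "P2"), gene_symbol = c("Col1a1", "Fn1"),
#'   peptide_count = c(5L, 3L), protein_fdr = c(0.001, 0.002),
#'   s1 = c(10, 20), s2 = c(11, NA)
#' )
#' design <- tibble::tibble(
#'   sample = c("s1", "s2"), model = "TC3",
#'   tumor_type = "CD8lo", replicate = 1:2
#' )
#' pq <- protein_quant(quant, design)
#' pq_samples(pq)
#' @export
protein_quant <- function(quant, design) {
  design <- as_design(design)
  quant <- as_tibble(quant)

  meta_cols <- c("protein_id", "gene_symbol", "peptide_count", "protein_fdr")
  missing_meta <- setdiff(meta_cols, names(quant))
  if (length(missing_meta) > 0) {
    abort(paste0("protein_quant is missing required column(s): ",
                 paste(missing_meta, collapse = ", ")),
          class = "matrisig_format_error")
  }
  absent <- setdiff(design$sample, names(quant))
  if (length(absent) > 0) {
    abort(paste0("sample(s) in design absent from table: ",
                 paste(absent, collapse = ", ")),
          class = "matrisig_format_error")
  }
  if (anyDuplicated(quant$protein_id)) {
    dup <- unique(quant$protein_id[duplicated(quant$protein_id)])
    abort(paste0("duplicate protein_id(s): ", paste(head(dup, 5), collapse = ", ")),
          class = "matrisig_validation_error")
  }
  for (s in design$sample) {
    v <- quant[[s]]
    if (!is.numeric(v)) {
      abort(paste0("intensity column '", s, "' is not numeric"),
            class = "matrisig_format_error")
    }
    if (any(v < 0, na.rm = TRUE)) {
      abort(paste0("negative intensity in sample '", s, "'"),
            class = "matrisig_validation_error")
    }
  }
  quant <- quant[, c(meta_cols,
                     setdiff(names(quant), c(meta_cols, design$sample)),
                     design$sample)]
  new_protein_quant(quant, design)
}

## internal constructor: no validation, reattaches class + design
new_protein_quant <- function(quant, design) {
  quant <- as_tibble(quant)
  attr(quant, "design") <- design
  class(quant) <- c("protein_quant", class(tibble()))
  quant
}

#' @rdname protein_quant
#' @param x A `protein_quant`.
#' @export
pq_design <- function(x) {
  d <- attr(x, "design", exact = TRUE)
  if (is.null(d)) abort("object carries no design attribute")
  d
}

#' @rdname protein_quant
#' @export
pq_samples <- function(x) pq_design(x)$sample

#' @rdname protein_quant
#' @export
pq_intensity_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, pq_samples(x), drop = FALSE])
  rownames(m) <- x$protein_id
  m
}

## Replace the intensity block of a protein_quant with a matrix of the same
## shape (used by normalisation).
pq_set_intensities <- function(x, m) {
  stopifnot(nrow(m) == nrow(x), identical(colnames(m), pq_samples(x)))
  for (s in colnames(m)) x[[s]] <- m[, s]
  new_protein_quant(x, pq_design(x))
}

#' Coerce a design map to the canonical design tibble
#'
#' Accepts either a data frame with columns `sample`, `model`, `tumor_type`,
#' `replicate`, or the nested-list form produced by reading a YAML/JSON design
#' map of shape `{sample: {model:, tumor_type:, replicate:}}`.
#'
#' @param design A data frame or named list.
#' @return A tibble with columns `sample`, `model`, `tumor_type`, `replicate`.
#' @export
as_design <- function(design) {
  if (is.data.frame(design)) {
    d <- as_tibble(design)
  } else if (is.list(design)) {
    d <- purrr::imap_dfr(design, function(entry, sample) {
      tibble(sample = sample,
             model = as.character(entry$model),
             tumor_type = as.character(entry$tumor_type),
             replicate = as.integer(entry$replicate %||% NA_integer_))
    })
  } else {
    abort("design must be a data frame or a named list")
  }
  needed <- c("sample", "model", "tumor_type")
  missing <- setdiff(needed, names(d))
  if (length(missing) > 0) {
    abort(paste0("design is missing column(s): ", paste(missing, collapse = ", ")),
          class = "matrisig_format_error")
  }
  if (!"replicate" %in% names(d)) {
    d <- d |>
      dplyr::group_by(.data$model) |>
      dplyr::mutate(replicate = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  if (anyDuplicated(d$sample)) {
    abort("duplicate sample identifiers in design",
          class = "matrisig_validation_error")
  }
  bad_model <- d |>
    dplyr::distinct(.data$model, .data$tumor_type) |>
    dplyr::count(.data$model) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad_model) > 0) {
    abort(paste0("model(s) mapped to more than one tumor_type: ",
                 paste(bad_model$model, collapse = ", ")),
          class = "matrisig_validation_error")
  }
  d[, c("sample", "model", "tumor_type", "replicate")]
}

#' Read a design map from YAML or JSON
#'
#' @param path Path to a YAML or JSON file of shape
#'   `{sample: {model:, tumor_type:, replicate:}}`.
#' @return The design tibble (see [as_design()]).
#' @export
read_design <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_design(jsonlite::read_json(path))
  } else {
    as_design(yaml::read_yaml(path))
  }
}

#' @export
print.protein_quant <- function(x, ...) {
  d <- pq_design(x)
  cat(sprintf("<protein_quant> %d proteins x %d samples (%d models, %d tumor types)\n",
              nrow(x), nrow(d), dplyr::n_distinct(d$model),
              dplyr::n_distinct(d$tumor_type)))
  NextMethod()
}
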