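#' Exclusive and shared matrisome signatures of two tumour types
#'
#' Set algebra over the two tumour-type profiles: proteins detected in both
#' types form the shared matrisome; proteins found in only one type form that
#' type's exclusive signature. Comparison is by gene symbol,
#' case-insensitive. When a reference is supplied, per-set category
#' distributions are attached.
#'
#' @param profile_lo,profile_hi [type_profile()]s of the two tumour types
#'   (conventionally the CD8-low, "cold", and CD8-high, "hot", types).
#' @param reference Optional [matrisome_reference()] for category summaries.
#' @return A `signature_result`: list with `shared`, `exclusive_lo`,
#'   `exclusive_hi` (character vectors), `labels`, and (if a reference was
#'   given) `category_summary`, a named list of [category_distribution()]s.
#' @export
exclusive_signatures <- function(profile_lo, profile_hi, reference = NULL) {
  lo <- profile_lo$proteins
  hi <- profile_hi$proteins
  res <- list(
    shared = intersect_symbols(lo, hi),
    exclusive_lo = setdiff_symbols(lo, hi),
    exclusive_hi = setdiff_symbols(hi, lo),
    labels = c(lo = profile_lo$label, hi = profile_hi$label)
  )
  if (!is.null(reference)) {
    res$category_summary <- purrr::map(
      res[c("shared", "exclusive_lo", "exclusive_hi")],
      ~ category_distribution(.x, reference))
  }
  structure(res, class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf(
    "<signature_result> shared %d | exclusive %s %d | exclusive %s %d\n",
    length(x$shared), x$labels["lo"], length(x$exclusive_lo),
    x$labels["hi"], length(x$exclusive_hi)))
  invisible(x)
}

#' @method tidy signature_result
#' @export
tidy.signature_result <- function(x, reference = NULL, ...) {
  out <- dplyr::bind_rows(
    tibble(gene_symbol = x$shared, membership = "shared"),
    tibble(gene_symbol = x$exclusive_lo, membership = "exclusive_lo"),
    tibble(gene_symbol = x$exclusive_hi, membership = "exclusive_hi")
  )
  if (!is.null(reference)) {
    out <- dplyr::left_join(out,
      annotate_matrisome(out$gene_symbol, reference, quiet = TRUE),
      by = "gene_symbol")
  }
  out
}

#' Core/associated split of a signature
#'
#' Splits an (all-matrisome) protein set into core-matrisome and
#' matrisome-associated members with per-category counts. A member absent
#' from the reference is an error: signatures are matrisome by construction.
#'
#' @param sig Character vector of gene symbols.
#' @param reference A [matrisome_reference()].
#' @return A list with `n_core`, `n_associated` and `counts` (named integer
#'   over the six categories); counts sum to `length(sig)`.
#' @export
signature_category_split <- function(sig, reference) {
  ann <- annotate_matrisome(sig, reference, quiet = TRUE)
  un <- ann$gene_symbol[ann$division == "non-matrisome"]
  if (length(un) > 0) {
    abort(paste0("signature member(s) not in the matrisome reference: ",
                 paste(un, collapse = ", ")),
          class = "matrisig_validation_error")
  }
  dist <- category_distribution(ann)
  list(n_core = sum(dist$counts[core_categories()]),
       n_associated = sum(dist$counts[associated_categories()]),
       counts = dist$counts)
}

#' Write signature membership and Venn counts
#'
#' Writes a TSV with columns `gene_symbol`, `division`, `category`,
#' `membership` and a JSON of the proportional-Venn counts.
#'
#' @param x A `signature_result`.
#' @param dir Output directory.
#' @param reference A [matrisome_reference()] for the annotation columns.
#' @return `dir`, invisibly.
#' @export
write_signatures <- function(x, dir, reference) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tidy(x, reference), file.path(dir, "signatures.tsv"))
  jsonlite::write_json(
    list(shared = length(x$shared),
         exclusive_lo = length(x$exclusive_lo),
         exclusive_hi = length(x$exclusive_hi)),
    file.path(dir, "venn_counts.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
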