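#' Annotate proteins against a matrisome reference
#'
#' Labels every protein with its matrisome `division` and `category`.
#' Matching is by gene symbol, case-insensitive after trimming, taking the
#' first token of `";"`-separated multi-ID cells. Proteins absent from the
#' reference are labelled `non-matrisome` / `none` — never an error, so the
#' annotation always partitions the input.
#'
#' @param x A [protein_quant()] (annotated columns are appended) or a
#'   character vector of gene symbols (an annotation tibble is returned).
#' @param reference A [matrisome_reference()].
#' @param quiet Suppress the matrisome/non-matrisome tally message.
#' @return `x` with `division` and `category` columns, or a tibble
#'   `gene_symbol`, `division`, `category` when `x` is a character vector.
#' @examples
#' ref <- matrisome_reference(tibble::tibble(
#'   gene_symbol = c("Col1a1", "Mmp9"),
#'   division = c("core matrisome", "matrisome-associated"),
#'   category = c("collagens", "ECM regulators")
#' ))
#' annotate_matrisome(c("COL1A1", "Gapdh"), ref, quiet = TRUE)
#' @export
annotate_matrisome <- function(x, reference, quiet = FALSE) {
  lut_key <- normalize_symbol(reference$gene_symbol)

  annotate_vec <- function(genes) {
    idx <- match(normalize_symbol(genes), lut_key)
    tibble(
      gene_symbol = genes,
      division = ifelse(is.na(idx), "non-matrisome", reference$division[idx]),
      category = ifelse(is.na(idx), "none", reference$category[idx])
    )
  }

  if (is.character(x)) {
    ann <- annotate_vec(x)
    if (!quiet) {
      inform(sprintf("annotated %d gene(s): %d matrisome, %d non-matrisome",
                     nrow(ann), sum(ann$division != "non-matrisome"),
                     sum(ann$division == "non-matrisome")))
    }
    return(ann)
  }
  if (!inherits(x, "protein_quant")) {
    abort("x must be a protein_quant or a character vector of gene symbols")
  }
  ann <- annotate_vec(x$gene_symbol)
  out <- x
  out$division <- ann$division
  out$category <- ann$category
  out <- new_protein_quant(
    out[, c(setdiff(names(out), pq_samples(x)), pq_samples(x))],
    pq_design(x))
  if (!quiet) {
    inform(sprintf("annotated %d protein(s): %d matrisome, %d non-matrisome",
                   nrow(out), sum(out$division != "non-matrisome"),
                   sum(out$division == "non-matrisome")))
  }
  out
}

#' Distribution of proteins across matrisome categories
#'
#' Counts annotated proteins per matrisome category and computes the core
#' fraction — the share of the matrisome subset falling in the structural
#' core-matrisome categories (ECM glycoproteins, collagens, proteoglycans).
#' Non-matrisome proteins are excluded from the counts but reported
#' separately.
#'
#' @param x An annotated table (any data frame with a `category` column,
#'   e.g. from [annotate_matrisome()]) or a character vector of gene symbols
#'   (requires `reference`).
#' @param reference A [matrisome_reference()], needed only when `x` is a
#'   character vector.
#' @return A `category_distribution`: list with `counts` (named integer over
#'   the six matrisome categories), `total`, `core_fraction` (`NA` when
#'   `total` is 0) and `n_non_matrisome`.
#' @export
category_distribution <- function(x, reference = NULL) {
  if (is.character(x)) {
    if (is.null(reference)) abort("reference required to annotate gene symbols")
    x <- annotate_matrisome(x, reference, quiet = TRUE)
  }
  if (!"category" %in% names(x)) {
    abort("x must carry a 'category' column (run annotate_matrisome first)")
  }
  cats <- setdiff(matrisome_categories(), "none")
  counts <- setNames(integer(length(cats)), cats)
  tab <- table(factor(x$category[x$category %in% cats], levels = cats))
  counts[names(tab)] <- as.integer(tab)
  total <- sum(counts)
  core <- sum(counts[core_categories()])
  structure(
    list(counts = counts,
         total = total,
         core_fraction = if (total > 0) core / total else NA_real_,
         n_non_matrisome = sum(x$category == "none")),
    class = "category_distribution")
}

#' @export
print.category_distribution <- function(x, ...) {
  cat(sprintf("<category_distribution> %d matrisome protein(s)", x$total))
  if (!is.na(x$core_fraction)) {
    cat(sprintf(", core fraction %.2f", x$core_fraction))
  }
  cat(sprintf(" (+%d non-matrisome)\n", x$n_non_matrisome))
  print(x$counts)
  invisible(x)
}

#' @method tidy category_distribution
#' @export
tidy.category_distribution <- function(x, ...) {
  tibble(category = names(x$counts),
         division = division_for_category(names(x$counts)),
         n = as.integer(x$counts))
}
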