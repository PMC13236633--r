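## Readers and writers for every tabular format the pipeline touches.
## All tables are one-header-row TSV; CSV is accepted via `delim` (or inferred
## from a .csv extension). Parsing is locale-independent (decimal point,
## scientific notation accepted).

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_checked <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "matrisig_format_error")
  }
  readr::read_delim(path, delim = infer_delim(path, delim),
                    show_col_types = FALSE, progress = FALSE,
                    na = c("", "NA", "NaN"))
}

require_columns <- function(tbl, cols, path) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("'", path, "' is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "matrisig_format_error")
  }
}

#' Read a protein-level quantification table
#'
#' Supports two dialects. `generic`: columns `protein_id`, `gene_symbol`,
#' `peptide_count`, `protein_fdr` plus one intensity column named after each
#' sample in the design. `proteingroups`: the MaxQuant proteinGroups layout
#' with columns `Majority protein IDs`, `Gene names`, `Razor + unique
#' peptides` and one `LFQ intensity <sample>` column per sample (`Q-value`,
#' when present, supplies `protein_fdr`; otherwise 0 is recorded, MaxQuant
#' output being FDR-filtered upstream).
#'
#' Missing intensities: both an empty cell and a literal 0 are treated as
#' "not detected" (`NA`), the LFQ convention in which a zero LFQ intensity
#' means absence. Multi-ID gene cells are split on `";"` and the first token
#' kept.
#'
#' @param path Path to the table (TSV, or CSV via `delim`/extension).
#' @param design Design map (see [as_design()]): every sample named there must
#'   have an intensity column in the file.
#' @param dialect `"generic"` or `"proteingroups"`.
#' @param delim Field delimiter override; default infers `","` for `.csv`,
#'   tab otherwise.
#' @return A [protein_quant()] tibble.
#' @export
read_protein_quant <- function(path, design,
                               dialect = c("generic", "proteingroups"),
                               delim = NULL) {
  dialect <- match.arg(dialect)
  design <- as_design(design)
  tbl <- read_table_checked(path, delim)

  if (dialect == "generic") {
    require_columns(tbl, c("protein_id", "gene_symbol", "peptide_count",
                           "protein_fdr", design$sample), path)
    quant <- tbl
  } else {
    require_columns(tbl, c("Majority protein IDs", "Gene names",
                           "Razor + unique peptides",
                           paste("LFQ intensity", design$sample)), path)
    quant <- tibble(
      protein_id = sub(";.*$", "", trimws(tbl[["Majority protein IDs"]])),
      gene_symbol = sub(";.*$", "", trimws(tbl[["Gene names"]])),
      peptide_count = as.integer(tbl[["Razor + unique peptides"]]),
      protein_fdr = if ("Q-value" %in% names(tbl)) {
        as.numeric(tbl[["Q-value"]])
      } else 0
    )
    for (s in design$sample) {
      quant[[s]] <- as.numeric(tbl[[paste("LFQ intensity", s)]])
    }
  }
  quant$gene_symbol <- sub(";.*$", "", trimws(quant$gene_symbol))
  for (s in design$sample) {
    v <- as.numeric(quant[[s]])
    v[!is.na(v) & v == 0] <- NA_real_
    quant[[s]] <- v
  }
  protein_quant(quant, design)
}

#' Write a protein-level quantification table (generic dialect)
#'
#' Missing intensities are written as empty cells. A write-then-read
#' round-trip reproduces intensities to at least 6 significant digits and the
#' identical missingness mask.
#'
#' @param x A [protein_quant()].
#' @param path Output path (TSV, or CSV via extension/`delim`).
#' @param delim Field delimiter override.
#' @return `path`, invisibly.
#' @export
write_protein_quant <- function(x, path, delim = NULL) {
  readr::write_delim(as_tibble(as.data.frame(x)), path,
                     delim = infer_delim(path, delim), na = "")
  invisible(path)
}

#' Read a matrisome reference table
#'
#' A TSV with columns `gene_symbol`, `division`, `category` mapping gene
#' symbols to the matrisome classification. The division/category consistency
#' invariant (core matrisome <-> structural categories, matrisome-associated
#' <-> regulatory categories) is enforced at load; an inconsistent row fails
#' with its row number.
#'
#' @param path Path to the reference TSV.
#' @param delim Field delimiter override.
#' @return A tibble with columns `gene_symbol`, `division`, `category` of
#'   class `matrisome_reference`.
#' @export
read_matrisome_reference <- function(path, delim = NULL) {
  tbl <- read_table_checked(path, delim)
  require_columns(tbl, c("gene_symbol", "division", "category"), path)
  matrisome_reference(tbl)
}

#' Construct/validate a matrisome reference
#'
#' @param tbl A data frame with columns `gene_symbol`, `division`, `category`.
#' @return The validated reference tibble.
#' @export
matrisome_reference <- function(tbl) {
  tbl <- as_tibble(tbl)[, c("gene_symbol", "division", "category")]
  bad_div <- !tbl$division %in% setdiff(matrisome_divisions(), "non-matrisome")
  bad_cat <- !tbl$category %in% setdiff(matrisome_categories(), "none")
  inconsistent <- division_for_category(tbl$category) != tbl$division
  bad <- which(bad_div | bad_cat | inconsistent)
  if (length(bad) > 0) {
    abort(sprintf(
      "inconsistent division/category at row %d: (%s, %s, %s)",
      bad[1], tbl$gene_symbol[bad[1]], tbl$division[bad[1]], tbl$category[bad[1]]),
      class = "matrisig_validation_error")
  }
  if (anyDuplicated(normalize_symbol(tbl$gene_symbol))) {
    abort("duplicate gene_symbol in matrisome reference",
          class = "matrisig_validation_error")
  }
  class(tbl) <- c("matrisome_reference", class(tibble()))
  tbl
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member gene symbols. Duplicate members within a line are de-duplicated
#' with a warning.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (one per set), with set
#'   descriptions in `attr(, "descriptions")`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "matrisig_format_error")
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(trimws(fields))]
    if (length(fields) < 3) {
      abort(sprintf("GMT line %d has fewer than 3 fields", i),
            class = "matrisig_format_error")
    }
    members <- trimws(fields[-(1:2)])
    if (anyDuplicated(members)) {
      warn(sprintf("GMT line %d ('%s'): %d duplicate member(s) removed",
                   i, fields[1], sum(duplicated(members))))
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
    descriptions[fields[1]] <- fields[2]
  }
  attr(sets, "descriptions") <- descriptions
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- purrr::imap_chr(sets, function(members, name) {
    paste(c(name, descriptions[[name]] %||% "na", members), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a clinical survival table
#'
#' A TSV with columns `patient_id`, `time`, `event` plus optional numeric
#' covariate columns (e.g. `stromal_score`). Rows with non-positive or missing
#' time are dropped with a warning; the count of dropped rows is recorded in
#' `attr(, "n_dropped")`. An event value outside \{0, 1\} is an error.
#'
#' @param path Path to the clinical TSV.
#' @param delim Field delimiter override.
#' @return A tibble of typed rows.
#' @export
read_survival_table <- function(path, delim = NULL) {
  tbl <- read_table_checked(path, delim)
  require_columns(tbl, c("patient_id", "time", "event"), path)
  tbl$time <- as.numeric(tbl$time)
  tbl$event <- as.numeric(tbl$event)
  if (any(!tbl$event %in% c(0, 1))) {
    abort("event values must be 0 (censored) or 1 (death observed)",
          class = "matrisig_validation_error")
  }
  bad <- is.na(tbl$time) | tbl$time <= 0
  if (any(bad)) {
    warn(sprintf("%d row(s) with non-positive or missing time dropped", sum(bad)))
    tbl <- tbl[!bad, , drop = FALSE]
  }
  tbl$event <- as.integer(tbl$event)
  out <- as_tibble(tbl)
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Read/write an expression matrix
#'
#' Genes x samples TSV whose first column holds gene symbols and remaining
#' columns one sample each. Duplicate gene rows are an error.
#'
#' @param path Path to the expression TSV.
#' @param delim Field delimiter override.
#' @return A numeric matrix with genes as rownames, samples as colnames.
#' @export
read_expression_matrix <- function(path, delim = NULL) {
  tbl <- read_table_checked(path, delim)
  genes <- as.character(tbl[[1]])
  if (anyDuplicated(genes)) {
    abort("duplicate gene rows in expression matrix",
          class = "matrisig_validation_error")
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' @rdname read_expression_matrix
#' @param m A numeric genes x samples matrix with dimnames.
#' @export
write_expression_matrix <- function(m, path, delim = NULL) {
  tbl <- as_tibble(m, rownames = "gene")
  readr::write_delim(tbl, path, delim = infer_delim(path, delim), na = "")
  invisible(path)
}
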