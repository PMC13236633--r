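#' Identification filters for protein-level tables
#'
#' Keeps proteins established with at least `min_peptides` identified peptides
#' and a protein-level FDR strictly below `max_protein_fdr` (defaults: the
#' two-peptide rule and FDR < 1%).
#'
#' @param x A [protein_quant()].
#' @param min_peptides Minimum distinct identified peptides (default 2).
#' @param max_protein_fdr Exclusive upper bound on protein FDR (default 0.01).
#' @param quiet Suppress the removed-protein tally message.
#' @return The filtered `protein_quant`.
#' @export
filter_identifications <- function(x, min_peptides = 2, max_protein_fdr = 0.01,
                                   quiet = FALSE) {
  keep <- x$peptide_count >= min_peptides & x$protein_fdr < max_protein_fdr
  keep[is.na(keep)] <- FALSE
  if (!quiet) {
    inform(sprintf(
      "identification filters (>=%d peptides, FDR < %g): removed %d of %d proteins",
      min_peptides, max_protein_fdr, sum(!keep), length(keep)))
  }
  new_protein_quant(x[keep, , drop = FALSE], pq_design(x))
}

#' Per-sample detection calls
#'
#' A protein counts as detected in a sample iff its intensity there is
#' present (non-missing; zeros were already mapped to missing at read time)
#' and at least `min_intensity`.
#'
#' @param x A filtered [protein_quant()].
#' @param min_intensity Optional per-sample minimum-intensity floor
#'   (default 0: any non-missing intensity is a detection).
#' @return A logical proteins x samples matrix with the thresholds used in
#'   `attr(, "thresholds")`.
#' @export
detection_matrix <- function(x, min_intensity = 0) {
  m <- pq_intensity_matrix(x)
  d <- !is.na(m) & m >= min_intensity
  attr(d, "thresholds") <- list(min_intensity = min_intensity)
  d
}

new_matrisome_profile <- function(label, proteins, k, n, tumor_type) {
  structure(list(label = label, proteins = proteins,
                 rule = c(k = as.integer(k), n = as.integer(n)),
                 tumor_type = tumor_type),
            class = "matrisome_profile")
}

#' @export
print.matrisome_profile <- function(x, ...) {
  cat(sprintf("<matrisome_profile> %s (%s): %d proteins, rule >=%d of %d replicates\n",
              x$label, x$tumor_type, length(x$proteins), x$rule["k"], x$rule["n"]))
  invisible(x)
}

#' Matrisome profile of one tumour model (k-of-n replicate rule)
#'
#' The matrisome profile of a tumour model is the set of matrisome-annotated
#' proteins detected in at least `k` of its `n` biological replicates
#' (default 3 of 5; the rule is ">= k of the available n", so unequal
#' replicate numbers are supported).
#'
#' @param x An annotated, identification-filtered [protein_quant()]
#'   (see [annotate_matrisome()], [filter_identifications()]).
#' @param model Model label, must appear in the design.
#' @param k Minimum number of replicates a protein must be detected in.
#' @param min_intensity Detection floor, see [detection_matrix()].
#' @return A `matrisome_profile`: label, protein set (gene symbols), the
#'   (k, n) rule used and the model's tumour type.
#' @export
model_profile <- function(x, model, k = 3, min_intensity = 0) {
  design <- pq_design(x)
  if (!model %in% design$model) {
    abort(paste0("unknown model: ", model), class = "matrisig_validation_error")
  }
  if (!"division" %in% names(x)) {
    abort("x must be annotated (run annotate_matrisome first)")
  }
  samples <- design$sample[design$model == model]
  n <- length(samples)
  if (k > n) {
    abort(sprintf("k = %d exceeds the %d available replicates of %s", k, n, model),
          class = "matrisig_validation_error")
  }
  d <- detection_matrix(x, min_intensity)[, samples, drop = FALSE]
  hit <- rowSums(d) >= k & x$division != "non-matrisome"
  proteins <- sort(unique(x$gene_symbol[hit]))
  new_matrisome_profile(model, proteins, k, n,
                        unique(design$tumor_type[design$model == model]))
}

#' Matrisome profile of a tumour type (intersection of its two models)
#'
#' A tumour type's matrisome profile is the set of proteins present in the
#' model profiles of *both* of its models — detected in at least k of n
#' replicates of each.
#'
#' @param profile_a,profile_b The [model_profile()]s of the two models of one
#'   tumour type.
#' @param label Optional label; defaults to the shared tumour type.
#' @return A `matrisome_profile` whose protein set is the intersection.
#' @export
type_profile <- function(profile_a, profile_b, label = NULL) {
  if (!identical(profile_a$tumor_type, profile_b$tumor_type)) {
    abort(sprintf("profiles belong to different tumor types (%s vs %s)",
                  profile_a$tumor_type, profile_b$tumor_type),
          class = "matrisig_validation_error")
  }
  shared <- intersect_symbols(profile_a$proteins, profile_b$proteins)
  new_matrisome_profile(label %||% profile_a$tumor_type, shared,
                        min(profile_a$rule["k"], profile_b$rule["k"]),
                        min(profile_a$rule["n"], profile_b$rule["n"]),
                        profile_a$tumor_type)
}

## case-insensitive set helpers that keep the first-seen original spelling
intersect_symbols <- function(a, b) sort(a[normalize_symbol(a) %in% normalize_symbol(b)])
setdiff_symbols <- function(a, b) sort(a[!normalize_symbol(a) %in% normalize_symbol(b)])

#' All model and tumour-type matrisome profiles of an experiment
#'
#' Convenience wrapper: applies [model_profile()] to every model in the
#' design and [type_profile()] to every tumour type (requiring exactly the
#' models assigned to it in the design).
#'
#' @inheritParams model_profile
#' @return A list with elements `models` and `types`, each a named list of
#'   `matrisome_profile`s.
#' @export
matrisome_profiles <- function(x, k = 3, min_intensity = 0) {
  design <- pq_design(x)
  models <- unique(design$model)
  mp <- purrr::map(setNames(models, models),
                   ~ model_profile(x, .x, k = k, min_intensity = min_intensity))
  types <- design |> dplyr::distinct(.data$tumor_type, .data$model)
  tp <- purrr::map(setNames(unique(types$tumor_type), unique(types$tumor_type)),
                   function(tt) {
    ms <- types$model[types$tumor_type == tt]
    Reduce(type_profile, mp[ms])
  })
  list(models = mp, types = tp)
}

#' Per-sample matrisome detection summary
#'
#' For each sample: the number of matrisome proteins detected and the
#' fraction of them in core-matrisome categories.
#'
#' @inheritParams model_profile
#' @return A tibble with columns `sample`, `model`, `tumor_type`,
#'   `n_matrisome`, `core_fraction`.
#' @export
per_sample_matrisome_counts <- function(x, min_intensity = 0) {
  if (!"division" %in% names(x)) {
    abort("x must be annotated (run annotate_matrisome first)")
  }
  d <- detection_matrix(x, min_intensity)
  design <- pq_design(x)
  is_mat <- x$division != "non-matrisome"
  is_core <- x$division == "core matrisome"
  purrr::map_dfr(design$sample, function(s) {
    det <- d[, s]
    n_mat <- sum(det & is_mat)
    tibble(sample = s,
           model = design$model[design$sample == s],
           tumor_type = design$tumor_type[design$sample == s],
           n_matrisome = n_mat,
           core_fraction = if (n_mat > 0) sum(det & is_core) / n_mat else NA_real_)
  })
}

#' Write matrisome profiles to disk
#'
#' One single-column TSV of gene symbols per profile plus a JSON manifest of
#' the detection rules used.
#'
#' @param profiles Output of [matrisome_profiles()] (or a named list of
#'   `matrisome_profile`s).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- if (all(c("models", "types") %in% names(profiles))) {
    c(profiles$models, profiles$types)
  } else profiles
  manifest <- purrr::map(flat, function(p) {
    readr::write_tsv(tibble(gene_symbol = p$proteins),
                     file.path(dir, paste0("profile_", p$label, ".tsv")))
    list(label = p$label, tumor_type = p$tumor_type,
         k = unname(p$rule["k"]), n = unname(p$rule["n"]),
         size = length(p$proteins))
  })
  jsonlite::write_json(manifest, file.path(dir, "profiles_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
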