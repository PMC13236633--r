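#' Default pipeline parameters
#'
#' @return Named list of every stage parameter with its default: the
#'   identification filters (`min_peptides`, `max_protein_fdr`), the
#'   replicate rule (`k`), normalisation method, and the differential
#'   thresholds (`alpha`, `up`, `down`, test `variant`, `log2_transform`).
#' @export
pipeline_defaults <- function() {
  list(min_peptides = 2, max_protein_fdr = 0.01, k = 3,
       normalize = "total_sum", alpha = 0.05, up = 1.2, down = 0.8,
       variant = "student", log2_transform = FALSE)
}

validate_pipeline_config <- function(config) {
  if (is.null(config$input) && is.null(config$simulate)) {
    abort("config must provide either $input paths or a $simulate block",
          class = "matrisig_validation_error")
  }
  if (!is.null(config$input)) {
    for (f in c("quant", "design", "reference")) {
      path <- config$input[[f]]
      if (is.null(path) || !file.exists(path)) {
        abort(paste0("input path missing or not found: ", f),
              class = "matrisig_validation_error")
      }
    }
  }
  params <- modifyList(pipeline_defaults(), config$params %||% list())
  with(params, {
    if (k < 1) abort("k must be >= 1", class = "matrisig_validation_error")
    if (min_peptides < 0 || max_protein_fdr <= 0 || max_protein_fdr > 1) {
      abort("invalid identification thresholds",
            class = "matrisig_validation_error")
    }
    if (alpha <= 0 || alpha >= 1 || up < 1 || down > 1 || down <= 0) {
      abort("invalid differential thresholds",
            class = "matrisig_validation_error")
    }
  })
  params
}

#' Run the full matrisome-signature pipeline
#'
#' Composes annotate -> identification filters -> k-of-n replicate profiles
#' -> exclusive/shared signatures -> normalisation -> differential abundance
#' -> combined signatures, from a single config, and (optionally) writes all
#' stage outputs plus a machine-readable summary JSON of the headline counts
#' and a run log with parameter provenance. Given the same config and seed
#' the summary is byte-identical across reruns.
#'
#' @param config A list, or path to a YAML file, with entries:
#'   * `input`: `quant`, `design`, `reference` paths (+ optional `dialect`), or
#'   * `simulate`: `scenario` (`"study"` or `"default"`), `deterministic`,
#'     `seed` — generates the data instead;
#'   * `params`: overrides of [pipeline_defaults()];
#'   * `out_dir`: optional output directory.
#' @return (Invisibly) a list with `summary` (headline counts), `profiles`,
#'   `signatures`, `differential`, `combined_lo`, `combined_hi`,
#'   `per_sample`, `quant`, `reference`, and `truth` when simulated.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- validate_pipeline_config(config)
  log_lines <- c("matrisig pipeline run",
                 paste0("parameters: ",
                        jsonlite::toJSON(params, auto_unbox = TRUE)))
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- if (identical(config$simulate$scenario %||% "study", "study")) {
      study_shaped_config(deterministic = config$simulate$deterministic %||% TRUE)
    } else {
      proteomics_config()
    }
    if (params$k > sim_cfg$replicates) {
      abort(sprintf("k = %d exceeds the %d replicates per model",
                    params$k, sim_cfg$replicates),
            class = "matrisig_validation_error")
    }
    sim <- simulate_proteomics(sim_cfg, seed = config$simulate$seed %||% 1)
    quant <- sim$quant
    reference <- sim$reference
    truth <- sim$truth
    log_lines <- c(log_lines,
                   paste0("simulated input, seed ", config$simulate$seed %||% 1))
  } else {
    design <- read_design(config$input$design)
    n_min <- min(table(design$model))
    if (params$k > n_min) {
      abort(sprintf("k = %d exceeds the smallest model's %d replicates",
                    params$k, n_min),
            class = "matrisig_validation_error")
    }
    quant <- read_protein_quant(config$input$quant, design,
                                dialect = config$input$dialect %||% "generic")
    reference <- read_matrisome_reference(config$input$reference)
    log_lines <- c(log_lines, paste0("read input: ", config$input$quant))
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
            class = "matrisig_stage_error", parent = e)
    })
  }

  annotated <- run_stage("annotate",
    annotate_matrisome(quant, reference, quiet = TRUE))
  filtered <- run_stage("filter",
    filter_identifications(annotated, params$min_peptides,
                           params$max_protein_fdr, quiet = TRUE))
  profiles <- run_stage("profiles", matrisome_profiles(filtered, k = params$k))
  per_sample <- run_stage("profiles", per_sample_matrisome_counts(filtered))

  types <- names(profiles$types)
  pair <- infer_type_pair(pq_design(quant)$tumor_type,
                          if ("CD8lo" %in% types) "CD8lo" else NULL,
                          if ("CD8hi" %in% types) "CD8hi" else NULL)
  sig <- run_stage("signatures",
    exclusive_signatures(profiles$types[[pair["lo"]]],
                         profiles$types[[pair["hi"]]], reference))

  normalized <- run_stage("normalize",
    normalize_intensities(filtered, params$normalize))
  diff <- run_stage("diffabund",
    differential_abundance(normalized, sig$shared, alpha = params$alpha,
                           up = params$up, down = params$down,
                           variant = params$variant,
                           log2_transform = params$log2_transform,
                           type_lo = pair["lo"], type_hi = pair["hi"]))
  comb_lo <- combined_signature(sig$exclusive_lo, diff, "lo")
  comb_hi <- combined_signature(sig$exclusive_hi, diff, "hi")

  split_lo <- signature_category_split(sig$exclusive_lo, reference)
  split_hi <- signature_category_split(sig$exclusive_hi, reference)
  summary <- list(
    n_proteins = nrow(quant), n_filtered = nrow(filtered),
    per_sample_matrisome_mean = mean(per_sample$n_matrisome),
    per_sample_core_fraction_mean = mean(per_sample$core_fraction, na.rm = TRUE),
    model_profiles = purrr::map_int(profiles$models, ~ length(.x$proteins)),
    profile_lo = length(profiles$types[[pair["lo"]]]$proteins),
    profile_hi = length(profiles$types[[pair["hi"]]]$proteins),
    shared = length(sig$shared),
    exclusive_lo = length(sig$exclusive_lo),
    exclusive_hi = length(sig$exclusive_hi),
    exclusive_lo_core = split_lo$n_core,
    exclusive_lo_associated = split_lo$n_associated,
    exclusive_hi_core = split_hi$n_core,
    exclusive_hi_associated = split_hi$n_associated,
    n_up_in_lo = sum(diff$call == "up_in_lo", na.rm = TRUE),
    n_up_in_hi = sum(diff$call == "up_in_hi", na.rm = TRUE),
    n_untestable = sum(!diff$testable),
    combined_lo = nrow(comb_lo),
    combined_hi = nrow(comb_hi),
    params = params)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profiles(profiles, file.path(config$out_dir, "profiles"))
    write_signatures(sig, config$out_dir, reference)
    write_volcano(diff, file.path(config$out_dir, "volcano.tsv"))
    readr::write_tsv(per_sample, file.path(config$out_dir, "per_sample.tsv"))
    readr::write_tsv(comb_lo, file.path(config$out_dir, "combined_lo.tsv"))
    readr::write_tsv(comb_hi, file.path(config$out_dir, "combined_hi.tsv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(truth)) {
      write_ground_truth(truth, file.path(config$out_dir, "ground_truth.json"))
    }
    log_lines <- c(log_lines, paste0("outputs written to ", config$out_dir))
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  }

  invisible(list(summary = summary, profiles = profiles, signatures = sig,
                 differential = diff, combined_lo = comb_lo,
                 combined_hi = comb_hi, per_sample = per_sample,
                 quant = quant, reference = reference, truth = truth))
}
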