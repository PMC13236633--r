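## Seeded generators emulating the study design every stage assumes:
## a 4-model x 5-replicate label-free proteomics experiment with planted
## type-exclusive proteins, planted fold changes and MNAR missingness, plus
## expression and survival cohorts with known ground truth.

#' Configuration for the proteomics simulator
#'
#' Encodes a multi-model LFQ experiment: two tumour models per tumour type
#' (default TC3/TC4 = CD8lo, TH2/TH3 = CD8hi), five biological replicates
#' each. Protein roles: `background` (null matrisome proteins detectable
#' everywhere), `differential` (present everywhere, intensity multiplied by
#' `2^|log2fc|` in the favoured type: positive `log2fc` favours the hi type),
#' `exclusive_lo`/`exclusive_hi` (detection probability `p_in` in their own
#' type's samples, `p_out` in the other's), `sporadic` (matrisome filler
#' detected in exactly `sporadic_reps` replicates of every model — below the
#' k-of-n rule, they inflate per-sample counts but never enter profiles),
#' `non-matrisome` background, and optional filter-failing `decoys`.
#'
#' Base abundances are log-normal(`mean_log`, `sd_log`); replicate noise is
#' multiplicative log-normal with coefficient of variation `cv`; detection of
#' non-exclusive proteins is missing-not-at-random, a logistic in
#' log-intensity with the given `detect_midpoint` and `detect_slope`
#' (`detect_midpoint = -Inf` disables missingness). `*_core` counts fix the
#' exact number of core-matrisome members of a role (default: binomial at
#' `core_fraction`).
#'
#' @param models Data frame with columns `model`, `tumor_type`.
#' @param replicates Biological replicates per model.
#' @param n_background,background_core Null shared matrisome proteins.
#' @param n_exclusive_lo,exclusive_lo_core,n_exclusive_hi,exclusive_hi_core
#'   Planted type-exclusive proteins.
#' @param differential_log2fc Vector of planted log2 fold changes (sign picks
#'   the favoured type), one protein each.
#' @param differential_core Exact core count among differential proteins.
#' @param n_sporadic,sporadic_core,sporadic_reps Sporadic filler proteins.
#' @param n_nonmatrisome Non-matrisome background proteins.
#' @param n_decoys Proteins failing the identification filters (1 peptide or
#'   FDR 0.02).
#' @param mean_log,sd_log Log-normal base-abundance parameters.
#' @param cv Within-group coefficient of variation of replicate intensities.
#' @param detect_midpoint,detect_slope Logistic MNAR detection model.
#' @param p_in,p_out Detection probabilities of exclusive proteins in their
#'   own / the other tumour type.
#' @param core_fraction Probability a simulated matrisome protein is core.
#' @return A `proteomics_sim_config` list.
#' @export
proteomics_config <- function(models = tibble(
                                model = c("TC3", "TC4", "TH2", "TH3"),
                                tumor_type = c("CD8lo", "CD8lo", "CD8hi", "CD8hi")),
                              replicates = 5,
                              n_background = 100, background_core = NULL,
                              n_exclusive_lo = 16, exclusive_lo_core = NULL,
                              n_exclusive_hi = 8, exclusive_hi_core = NULL,
                              differential_log2fc = rep(c(-1, 1), each = 6),
                              differential_core = NULL,
                              n_sporadic = 0, sporadic_core = NULL,
                              sporadic_reps = 2,
                              n_nonmatrisome = 25, n_decoys = 0,
                              mean_log = log(1e6), sd_log = 1, cv = 0.2,
                              detect_midpoint = log(1e6) - 3.3, detect_slope = 2,
                              p_in = 0.9, p_out = 0.05,
                              core_fraction = 0.6) {
  cfg <- list(models = as_tibble(models), replicates = as.integer(replicates),
              n_background = n_background, background_core = background_core,
              n_exclusive_lo = n_exclusive_lo, exclusive_lo_core = exclusive_lo_core,
              n_exclusive_hi = n_exclusive_hi, exclusive_hi_core = exclusive_hi_core,
              differential_log2fc = differential_log2fc,
              differential_core = differential_core,
              n_sporadic = n_sporadic, sporadic_core = sporadic_core,
              sporadic_reps = as.integer(sporadic_reps),
              n_nonmatrisome = n_nonmatrisome, n_decoys = n_decoys,
              mean_log = mean_log, sd_log = sd_log, cv = cv,
              detect_midpoint = detect_midpoint, detect_slope = detect_slope,
              p_in = p_in, p_out = p_out, core_fraction = core_fraction)
  validate_proteomics_config(cfg)
  structure(cfg, class = "proteomics_sim_config")
}

validate_proteomics_config <- function(cfg) {
  counts <- c(cfg$n_background, cfg$n_exclusive_lo, cfg$n_exclusive_hi,
              cfg$n_sporadic, cfg$n_nonmatrisome, cfg$n_decoys)
  if (any(counts < 0)) abort("protein counts must be >= 0",
                             class = "matrisig_validation_error")
  if (cfg$replicates < 1) abort("replicates must be >= 1",
                                class = "matrisig_validation_error")
  probs <- c(cfg$p_in, cfg$p_out, cfg$core_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("p_in, p_out and core_fraction must lie in [0, 1]",
          class = "matrisig_validation_error")
  }
  if (cfg$sporadic_reps >= cfg$replicates && cfg$n_sporadic > 0) {
    abort("sporadic_reps must be below the replicate count",
          class = "matrisig_validation_error")
  }
  tt <- unique(cfg$models$tumor_type)
  if (length(tt) != 2) abort("exactly two tumor types are required",
                             class = "matrisig_validation_error")
  invisible(cfg)
}

#' The study-shaped simulation scenario
#'
#' A [proteomics_config()] mirroring the published experiment's structure:
#' 114 shared matrisome proteins (70 core / 44 associated, of which 5 carry a
#' planted 2-fold higher abundance in the lo type and 7 in the hi type), 16
#' lo-exclusive proteins (6 core / 10 associated), 8 hi-exclusive (5 core /
#' 3 associated), and 60 sporadic proteins (35 core / 25 associated) seen in
#' 2 of 5 replicates per model. Under the 3-of-5 rule this yields model and
#' type profiles of 130 (lo) and 122 (hi), per-sample matrisome counts of
#' 154 (lo) / 146 (hi) — mean 150 — and a mean per-sample core fraction of
#' 0.597.
#'
#' With `deterministic = TRUE` detection is exact (`p_in = 1`, `p_out = 0`,
#' no MNAR missingness) and replicate noise is zero, so every planted count
#' is recovered exactly; otherwise the default stochastic detection and 20%
#' CV apply and the counts are recovered approximately.
#'
#' @param deterministic Remove all detection and intensity noise.
#' @return A `proteomics_sim_config`.
#' @export
study_shaped_config <- function(deterministic = TRUE) {
  proteomics_config(
    n_background = 102, background_core = 62,
    n_exclusive_lo = 16, exclusive_lo_core = 6,
    n_exclusive_hi = 8, exclusive_hi_core = 5,
    differential_log2fc = c(rep(-1, 5), rep(1, 7)), differential_core = 8,
    n_sporadic = 60, sporadic_core = 35, sporadic_reps = 2,
    n_nonmatrisome = 40,
    cv = if (deterministic) 0 else 0.2,
    detect_midpoint = if (deterministic) -Inf else log(1e6) - 3.3,
    p_in = if (deterministic) 1 else 0.9,
    p_out = if (deterministic) 0 else 0.05)
}

## categories for n proteins, n_core of them core (binomial when NULL)
draw_categories <- function(n, n_core, core_fraction) {
  if (n == 0) return(character(0))
  n_core <- n_core %||% rbinom(1, n, core_fraction)
  cats <- c(
    sample(rep(core_categories(), length.out = max(n_core, 1))[seq_len(n_core)]),
    sample(rep(associated_categories(), length.out = max(n - n_core, 1))[seq_len(n - n_core)]))
  ## interleave core/associated so deterministic round-robin detection
  ## spreads both divisions evenly across replicates
  cats[order(c(seq_len(n_core) * 2 - 1, seq_len(n - n_core) * 2))]
}

#' Simulate a label-free proteomics experiment with planted truth
#'
#' @param cfg A [proteomics_config()].
#' @param seed Integer seed; the same (config, seed) pair gives bit-identical
#'   output.
#' @return A list: `quant` (a [protein_quant()]), `reference` (the matching
#'   [matrisome_reference()]), and `truth` — the planted ground truth
#'   (exclusive sets, differential table, role and category per protein, and
#'   the config).
#' @export
simulate_proteomics <- function(cfg = proteomics_config(), seed = 1) {
  validate_proteomics_config(cfg)
  set.seed(seed)
  design <- cfg$models |>
    tidyr::crossing(replicate = seq_len(cfg$replicates)) |>
    dplyr::mutate(sample = paste0(.data$model, "_", .data$replicate)) |>
    dplyr::select("sample", "model", "tumor_type", "replicate")
  tt <- unique(cfg$models$tumor_type)
  type_lo <- tt[1]
  type_hi <- tt[2]

  n_diff <- length(cfg$differential_log2fc)
  plan <- dplyr::bind_rows(
    tibble(role = "background",
           category = draw_categories(cfg$n_background, cfg$background_core,
                                      cfg$core_fraction),
           log2fc = 0),
    tibble(role = "differential",
           category = draw_categories(n_diff, cfg$differential_core,
                                      cfg$core_fraction),
           log2fc = cfg$differential_log2fc),
    tibble(role = "exclusive_lo",
           category = draw_categories(cfg$n_exclusive_lo, cfg$exclusive_lo_core,
                                      cfg$core_fraction),
           log2fc = 0),
    tibble(role = "exclusive_hi",
           category = draw_categories(cfg$n_exclusive_hi, cfg$exclusive_hi_core,
                                      cfg$core_fraction),
           log2fc = 0),
    tibble(role = "sporadic",
           category = draw_categories(cfg$n_sporadic, cfg$sporadic_core,
                                      cfg$core_fraction),
           log2fc = 0),
    tibble(role = "non-matrisome",
           category = rep("none", cfg$n_nonmatrisome), log2fc = 0),
    tibble(role = "decoy",
           category = draw_categories(cfg$n_decoys, NULL, cfg$core_fraction),
           log2fc = 0))
  plan$gene <- sprintf("SIM%04d", seq_len(nrow(plan)))
  plan$base <- rlnorm(nrow(plan), cfg$mean_log, cfg$sd_log)

  sd_noise <- if (cfg$cv > 0) sqrt(log(1 + cfg$cv^2)) else 0
  n_p <- nrow(plan)
  m <- matrix(NA_real_, n_p, nrow(design),
              dimnames = list(plan$gene, design$sample))
  ## sporadic proteins: protein j is detected in replicate pair
  ## (j mod R, j mod R + 1) of every model, cycling round the replicates
  spor_idx <- which(plan$role == "sporadic")
  spor_reps <- purrr::map(seq_along(spor_idx), function(j) {
    start <- (j - 1) %% cfg$replicates
    (start + seq_len(cfg$sporadic_reps) - 1) %% cfg$replicates + 1
  })
  for (s in seq_len(nrow(design))) {
    s_type <- design$tumor_type[s]
    favoured <- ifelse(plan$log2fc > 0, type_hi, type_lo)
    fold <- ifelse(plan$log2fc != 0 & s_type == favoured,
                   2^abs(plan$log2fc), 1)
    value <- plan$base * fold *
      (if (sd_noise > 0) exp(rnorm(n_p, 0, sd_noise)) else 1)
    p_det <- plogis(cfg$detect_slope * (log(value) - cfg$detect_midpoint))
    is_lo <- s_type == type_lo
    p_det[plan$role == "exclusive_lo"] <- if (is_lo) cfg$p_in else cfg$p_out
    p_det[plan$role == "exclusive_hi"] <- if (is_lo) cfg$p_out else cfg$p_in
    detected <- runif(n_p) < p_det
    for (k in seq_along(spor_idx)) {
      detected[spor_idx[k]] <- design$replicate[s] %in% spor_reps[[k]]
    }
    m[detected, s] <- value[detected]
  }

  quant <- tibble(
    protein_id = plan$gene,
    gene_symbol = plan$gene,
    peptide_count = ifelse(plan$role == "decoy", 1L,
                           2L + rbinom(n_p, 10, 0.4)),
    protein_fdr = ifelse(plan$role == "decoy", 0.02,
                         runif(n_p, 0, 0.009)))
  for (s in design$sample) quant[[s]] <- m[, s]
  quant <- protein_quant(quant, design)

  ref_rows <- plan[plan$category != "none", c("gene", "category")]
  reference <- matrisome_reference(tibble(
    gene_symbol = ref_rows$gene,
    division = division_for_category(ref_rows$category),
    category = ref_rows$category))

  truth <- list(
    exclusive_lo = plan$gene[plan$role == "exclusive_lo"],
    exclusive_hi = plan$gene[plan$role == "exclusive_hi"],
    differential = tibble(
      gene_symbol = plan$gene[plan$role == "differential"],
      log2fc = plan$log2fc[plan$role == "differential"],
      favours = ifelse(plan$log2fc[plan$role == "differential"] > 0,
                       type_hi, type_lo)),
    shared = plan$gene[plan$role %in% c("background", "differential")],
    roles = plan[, c("gene", "role", "category")],
    type_lo = type_lo, type_hi = type_hi,
    seed = seed, config = unclass(cfg)[setdiff(names(cfg), "models")])
  list(quant = quant, reference = reference, truth = truth)
}

#' Simulate an expression cohort with one latent infiltration factor
#'
#' Every sample carries a latent infiltration level `F ~ N(0,1)`. Genes of
#' the hot-matrisome and CTL sets load on it (`loading * F + N(0,
#' noise_sd^2)`); cold-set and background genes are independent noise with
#' the same marginal variance. The analytic Pearson correlation between the
#' mean expression of two loading sets of sizes m1, m2 —
#' `loading^2 / sqrt((loading^2 + noise_sd^2/m1)(loading^2 + noise_sd^2/m2))`
#' — is recorded in the ground truth as the target the rank-based score
#' correlation should approach.
#'
#' @param n_samples Number of samples.
#' @param hot_set,cold_set,ctl_set Gene symbol vectors (defaults: 20
#'   synthetic genes each).
#' @param loading Factor loading in `[0, 1]`.
#' @param noise_sd Residual standard deviation.
#' @param n_background Independent background genes.
#' @param seed Integer seed.
#' @return A list: `expr` (genes x samples matrix) and `truth` (latent
#'   factor, sets, loading, noise, analytic correlation).
#' @export
simulate_expression_cohort <- function(n_samples = 200,
                                       hot_set = sprintf("HOTG%02d", 1:20),
                                       cold_set = sprintf("COLDG%02d", 1:20),
                                       ctl_set = sprintf("CTLG%02d", 1:20),
                                       loading = 0.6, noise_sd = 0.8,
                                       n_background = 1000, seed = 1) {
  if (loading < 0 || loading > 1) {
    abort("loading must lie in [0, 1]", class = "matrisig_validation_error")
  }
  set.seed(seed)
  genes <- c(hot_set, cold_set, ctl_set, sprintf("BGG%04d", seq_len(n_background)))
  if (anyDuplicated(genes)) {
    abort("gene sets and background must be disjoint",
          class = "matrisig_validation_error")
  }
  f <- rnorm(n_samples)
  marginal_sd <- sqrt(loading^2 + noise_sd^2)
  expr <- matrix(NA_real_, length(genes), n_samples,
                 dimnames = list(genes, sprintf("S%04d", seq_len(n_samples))))
  loads_on_f <- genes %in% c(hot_set, ctl_set)
  for (g in seq_along(genes)) {
    expr[g, ] <- if (loads_on_f[g]) {
      loading * f + rnorm(n_samples, 0, noise_sd)
    } else {
      rnorm(n_samples, 0, marginal_sd)
    }
  }
  analytic <- function(m1, m2) {
    loading^2 / sqrt((loading^2 + noise_sd^2 / m1) * (loading^2 + noise_sd^2 / m2))
  }
  truth <- list(factor = setNames(f, colnames(expr)),
                hot_set = hot_set, cold_set = cold_set, ctl_set = ctl_set,
                loading = loading, noise_sd = noise_sd, seed = seed,
                analytic_hot_ctl = analytic(length(hot_set), length(ctl_set)),
                analytic_cold_ctl = 0)
  list(expr = expr, truth = truth)
}

#' Simulate a survival cohort under a proportional-hazards model
#'
#' Each patient has a latent marker `z ~ N(0,1)` (quartile-stratified into
#' high/low/mid with the high-vs-low indicator as the planted stratum
#' covariate), an independent stromal score `~ N(0,1)`, an exponential event
#' time with hazard `baseline_rate * exp(beta_stratum * high + beta_stromal *
#' stromal)`, and independent exponential censoring at `censor_rate`. An
#' aligned expression matrix is emitted in which `gene_set` genes load on `z`
#' so that ssGSEA scoring recovers the stratification.
#'
#' @param n Number of patients.
#' @param beta_stratum,beta_stromal Planted log hazard ratios.
#' @param baseline_rate,censor_rate Exponential rates (> 0).
#' @param gene_set Marker genes loading on `z` (default 20 synthetic genes).
#' @param n_background Background genes in the aligned expression matrix.
#' @param loading,noise_sd Expression factor model for the marker genes.
#' @param seed Integer seed.
#' @return A list: `clinical` (tibble `patient_id`, `time`, `event`,
#'   `stromal_score`), `expr` (aligned genes x patients matrix), and `truth`
#'   (latent `z`, strata, planted betas, censoring fraction).
#' @export
simulate_survival_cohort <- function(n = 400, beta_stratum = 0.7,
                                     beta_stromal = 0.3,
                                     baseline_rate = 0.1, censor_rate = 0.05,
                                     gene_set = sprintf("SCOREG%02d", 1:20),
                                     n_background = 180,
                                     loading = 0.9, noise_sd = 0.2, seed = 1) {
  if (baseline_rate <= 0 || censor_rate < 0) {
    abort("rates must be positive", class = "matrisig_validation_error")
  }
  set.seed(seed)
  id <- sprintf("P%04d", seq_len(n))
  z <- rnorm(n)
  stromal <- rnorm(n)
  stratum <- quartile_stratify(z)
  x_high <- as.integer(stratum == "high")
  hazard <- baseline_rate * exp(beta_stratum * x_high + beta_stromal * stromal)
  t_event <- rexp(n, hazard)
  t_censor <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  time <- pmin(t_event, t_censor)
  event <- as.integer(t_event <= t_censor)

  genes <- c(gene_set, sprintf("BGG%04d", seq_len(n_background)))
  marginal_sd <- sqrt(loading^2 + noise_sd^2)
  expr <- matrix(rnorm(length(genes) * n, 0, marginal_sd), length(genes), n,
                 dimnames = list(genes, id))
  for (g in seq_along(gene_set)) {
    expr[g, ] <- loading * z + rnorm(n, 0, noise_sd)
  }
  clinical <- tibble(patient_id = id, time = time, event = event,
                     stromal_score = stromal)
  truth <- list(z = setNames(z, id), stratum = setNames(stratum, id),
                beta_stratum = beta_stratum, beta_stromal = beta_stromal,
                baseline_rate = baseline_rate, censor_rate = censor_rate,
                censoring_fraction = mean(event == 0), gene_set = gene_set,
                seed = seed)
  list(clinical = clinical, expr = expr, truth = truth)
}

#' Write a ground-truth manifest beside simulated data
#'
#' @param truth A `truth` list from one of the simulators.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
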