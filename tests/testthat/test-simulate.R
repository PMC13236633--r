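test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_proteomics(proteomics_config(), seed = 99)
  b <- simulate_proteomics(proteomics_config(), seed = 99)
  expect_identical(pq_intensity_matrix(a$quant), pq_intensity_matrix(b$quant))
  expect_identical(a$truth$exclusive_lo, b$truth$exclusive_lo)
  c <- simulate_proteomics(proteomics_config(), seed = 100)
  expect_false(identical(pq_intensity_matrix(a$quant),
                         pq_intensity_matrix(c$quant)))

  e1 <- simulate_expression_cohort(n_samples = 30, seed = 5)
  e2 <- simulate_expression_cohort(n_samples = 30, seed = 5)
  expect_identical(e1$expr, e2$expr)

  s1 <- simulate_survival_cohort(n = 40, seed = 5)
  s2 <- simulate_survival_cohort(n = 40, seed = 5)
  expect_identical(s1$clinical, s2$clinical)
})

test_that("emitted tables satisfy every io-layer validator", {
  sim <- simulate_proteomics(proteomics_config(n_decoys = 5), seed = 3)
  ## re-validating through the public constructors must succeed
  expect_s3_class(protein_quant(tibble::as_tibble(as.data.frame(sim$quant)),
                                pq_design(sim$quant)), "protein_quant")
  expect_s3_class(matrisome_reference(sim$reference), "matrisome_reference")
  ## and survive a disk round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_quant(sim$quant, path)
  back <- read_protein_quant(path, pq_design(sim$quant))
  expect_identical(is.na(pq_intensity_matrix(back)),
                   is.na(pq_intensity_matrix(sim$quant)))
})

test_that("config invariants are validated before any generation", {
  expect_error(proteomics_config(replicates = 0), "replicates",
               class = "matrisig_validation_error")
  expect_error(proteomics_config(n_background = -1), "counts",
               class = "matrisig_validation_error")
  expect_error(proteomics_config(p_in = 1.2), "p_in",
               class = "matrisig_validation_error")
  expect_error(proteomics_config(n_sporadic = 10, sporadic_reps = 5),
               "sporadic_reps", class = "matrisig_validation_error")
  expect_error(simulate_expression_cohort(loading = 1.4), "loading",
               class = "matrisig_validation_error")
  expect_error(simulate_survival_cohort(baseline_rate = 0), "rates",
               class = "matrisig_validation_error")
})

test_that("deterministic detection limit gives exact signature recovery", {
  cfg <- proteomics_config(p_in = 1, p_out = 0, detect_midpoint = -Inf, cv = 0)
  sim <- simulate_proteomics(cfg, seed = 17)
  ann <- annotate_matrisome(
    filter_identifications(sim$quant, quiet = TRUE), sim$reference,
    quiet = TRUE)
  profiles <- matrisome_profiles(ann)
  sig <- exclusive_signatures(profiles$types$CD8lo, profiles$types$CD8hi)
  expect_setequal(sig$exclusive_lo, sim$truth$exclusive_lo)
  expect_setequal(sig$exclusive_hi, sim$truth$exclusive_hi)
  expect_setequal(sig$shared, sim$truth$shared)
})

test_that("decoys are removed by the identification filters, not the profiles", {
  sim <- simulate_proteomics(proteomics_config(n_decoys = 8), seed = 12)
  decoys <- sim$truth$roles$gene[sim$truth$roles$role == "decoy"]
  kept <- filter_identifications(sim$quant, quiet = TRUE)
  expect_length(intersect(kept$gene_symbol, decoys), 0)
  expect_equal(nrow(sim$quant) - nrow(kept), 8)
})

test_that("sporadic proteins inflate per-sample counts but never profiles", {
  cfg <- study_shaped_config(deterministic = TRUE)
  sim <- simulate_proteomics(cfg, seed = 1)
  ann <- annotate_matrisome(
    filter_identifications(sim$quant, quiet = TRUE), sim$reference,
    quiet = TRUE)
  sporadic <- sim$truth$roles$gene[sim$truth$roles$role == "sporadic"]
  profiles <- matrisome_profiles(ann)
  for (p in c(profiles$models, profiles$types)) {
    expect_length(intersect(p$proteins, sporadic), 0)
  }
  ps <- per_sample_matrisome_counts(ann)
  ## every sample sees exactly 24 of the 60 sporadic proteins (2 of 5 reps)
  expect_true(all(ps$n_matrisome[ps$tumor_type == "CD8lo"] == 154))
  expect_true(all(ps$n_matrisome[ps$tumor_type == "CD8hi"] == 146))
})

test_that("expression cohort with zero loading yields uncorrelated scores", {
  sim <- simulate_expression_cohort(n_samples = 200, loading = 0,
                                    noise_sd = 1, seed = 88)
  rho <- signature_ctl_correlation(sim$expr, sim$truth$hot_set,
                                   sim$truth$cold_set, sim$truth$ctl_set)
  expect_lt(abs(rho["hot", "ctl"]), 0.15)
  expect_lt(abs(rho["cold", "ctl"]), 0.15)
})

test_that("survival generator produces the planted censoring behaviour", {
  sim <- simulate_survival_cohort(n = 300, seed = 21)
  expect_true(all(sim$clinical$time > 0))
  expect_true(all(sim$clinical$event %in% 0:1))
  expect_gt(mean(sim$clinical$event), 0.5)  # moderate censoring by default

  heavy <- simulate_survival_cohort(n = 30, censor_rate = 1e6, seed = 4)
  expect_lt(sum(heavy$clinical$event), 2)  # essentially everything censored
  expect_error(cox_fit(dplyr::mutate(heavy$clinical, x = rnorm(30)), "x"),
               "2 events", class = "matrisig_validation_error")
})
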