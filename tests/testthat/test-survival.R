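test_that("quartile stratification follows the type-7 boundary rule", {
  s <- quartile_stratify(1:8)  # Q1 = 2.75, Q3 = 6.25
  expect_identical(as.character(s), c("low", "low", "mid", "mid", "mid", "mid",
                        "high", "high"))
  s4 <- quartile_stratify(c(3, 1, 4, 2))  # Q1 = 1.75, Q3 = 3.25
  expect_identical(as.character(s4), c("mid", "low", "high", "mid"))
  expect_error(quartile_stratify(rep(2, 10)), "identical",
               class = "matrisig_validation_error")
  expect_error(quartile_stratify(1:3), "4 patients",
               class = "matrisig_validation_error")
})

test_that("product-limit estimates match hand computation and limits", {
  km <- km_estimate(c(5, 8, 12), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  censored <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(censored$surv == 1))

  ## no censoring: S equals one minus the empirical CDF at event times
  set.seed(8)
  t <- round(rexp(40, 0.2), 2)
  km2 <- km_estimate(t, rep(1, 40))
  expect_equal(km2$surv, 1 - ecdf(t)(km2$time))

  expect_true(all(diff(km2$surv) <= 0))  # monotone non-increasing
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM agrees with the survival package under censoring and ties", {
  skip_if_not_installed("survival")
  set.seed(13)
  t <- sample(1:12, 60, replace = TRUE)  # many ties, incl. censor-at-event
  e <- rbinom(60, 1, 0.7)
  km <- km_estimate(t, e)
  sf <- summary(survival::survfit(survival::Surv(t, e) ~ 1), times = km$time)
  expect_equal(km$surv, sf$surv, tolerance = 1e-12)
  expect_equal(km$n_risk, sf$n.risk)
})

test_that("log-rank statistic matches the hand-computed O-E/V fixture", {
  ## 6 patients: group a times 1+, 3+, 5c; group b 2+, 4+, 6+
  ## summed over event times: (O_a - E_a) = 4/15, V = 866/900
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, 32 / 433, tolerance = 1e-12)
  expect_equal(lr$df, 1)
  expect_equal(unname(lr$observed["a"]), 2)
  expect_equal(unname(lr$expected["a"]), 26 / 15, tolerance = 1e-12)

  same <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("x", "y"), 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  expect_error(logrank_test(time, event, rep("a", 6)), "2 groups")
  expect_error(logrank_test(time, rep(0, 6), group), "no events")
})

test_that("log-rank agrees with survival::survdiff, including 3 groups", {
  skip_if_not_installed("survival")
  set.seed(19)
  t <- rexp(90, 0.1)
  e <- rbinom(90, 1, 0.8)
  g <- rep(c("a", "b", "c"), 30)
  lr <- logrank_test(t, e, g)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-9)
  expect_equal(lr$df, 2)
})

test_that("Cox solves the single-covariate score equation found by bisection", {
  set.seed(3)
  x <- rep(c(1, 0), each = 10)
  time <- round(rexp(20, exp(0.8 * x) * 0.1), 6)  # tie-free, all events
  fit <- cox_fit(tibble::tibble(time = time, event = 1, x = x), "x")
  expect_equal(fit$coefficients$estimate, oracle_cox_beta(time, rep(1, 20), x),
               tolerance = 1e-7)
  expect_true(fit$converged)
  ## fitted log partial likelihood is at least the null's
  expect_gte(fit$loglik["fitted"], fit$loglik["null"])
})

test_that("Cox matches coxph for Efron and Breslow ties and two covariates", {
  skip_if_not_installed("survival")
  set.seed(29)
  n <- 150
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rnorm(n)
  t <- ceiling(rexp(n, 0.1 * exp(0.6 * x1 + 0.25 * x2)))  # heavy ties
  e <- rbinom(n, 1, 0.75)
  d <- tibble::tibble(time = t, event = e, x1 = x1, x2 = x2)
  for (ties in c("efron", "breslow")) {
    mine <- cox_fit(d, c("x1", "x2"), ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ x1 + x2, data = d,
                           ties = ties)
    expect_equal(mine$coefficients$estimate, unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(mine$coefficients$se, unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
    expect_true(all(mine$coefficients$hazard_ratio > 0))
  }
  ## tie-free data: Efron and Breslow coincide exactly
  d2 <- d
  d2$time <- d$time + runif(n) * 1e-3
  ef <- cox_fit(d2, c("x1", "x2"), ties = "efron")
  br <- cox_fit(d2, c("x1", "x2"), ties = "breslow")
  expect_equal(ef$coefficients$estimate, br$coefficients$estimate,
               tolerance = 1e-9)
})

test_that("Cox guards: null recovery, separation flag, degenerate input", {
  set.seed(55)
  n <- 500
  d <- tibble::tibble(time = rexp(n, 0.1), event = rbinom(n, 1, 0.8),
                      x = rnorm(n))
  fit <- cox_fit(d, "x")
  expect_lt(abs(fit$coefficients$estimate), 2 * fit$coefficients$se)

  sep <- tibble::tibble(time = c(1, 2, 3, 10, 11, 12),
                        event = 1, x = c(1, 1, 1, 0, 0, 0))
  expect_warning(fs <- cox_fit(sep, "x"), "separation|converge")
  expect_true(fs$separation || !fs$converged)

  expect_error(cox_fit(tibble::tibble(time = 1:4, event = c(1, 0, 0, 0),
                                      x = rnorm(4)), "x"),
               "2 events", class = "matrisig_validation_error")
  expect_error(cox_fit(tibble::tibble(time = rexp(10, 1), event = 1,
                                      a = 1:10, b = 2 * (1:10)), c("a", "b")),
               "collinear", class = "matrisig_validation_error")
  expect_error(cox_fit(d, "missing_cov"), "missing_cov")
})

test_that("tidy and glance expose the Cox fit in broom shape", {
  set.seed(6)
  d <- tibble::tibble(time = rexp(80, 0.1), event = rbinom(80, 1, 0.7),
                      x = rnorm(80))
  fit <- cox_fit(d, "x")
  td <- tidy(fit)
  expect_identical(names(td), c("term", "estimate", "se", "hazard_ratio",
                                "statistic", "p_value"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_events, sum(d$event))
})

test_that("score-based survival composition recovers a planted hazard ratio", {
  sim <- simulate_survival_cohort(n = 400, beta_stratum = log(2),
                                  beta_stromal = 0.3, seed = 11)
  res <- signature_score_survival(sim$expr, sim$truth$gene_set, sim$clinical)
  hr <- res$cox$coefficients$hazard_ratio[
    res$cox$coefficients$term == "stratum_high"]
  expect_gt(hr, 1.5)
  expect_lt(hr, 2.7)
  expect_lt(res$logrank$p, 0.01)
  expect_named(res$km, c("high", "low"))
  ## the score stratification must closely track the latent stratification
  agree <- mean(res$data$stratum == sim$truth$stratum[res$data$patient_id])
  expect_gt(agree, 0.9)
})

test_that("survival composition rejects degenerate joins and flat scores", {
  sim <- simulate_survival_cohort(n = 50, seed = 2)
  few <- sim$clinical[1:5, ]
  expect_error(signature_score_survival(sim$expr, sim$truth$gene_set, few),
               "joinable", class = "matrisig_validation_error")

  flat <- sim$expr
  flat[, ] <- 1  # identical expression for everyone -> flat scores
  expect_error(signature_score_survival(flat, sim$truth$gene_set, sim$clinical),
               "identical|degenerate", class = "matrisig_validation_error")
})
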