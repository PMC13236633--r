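#' Quartile stratification of a continuous marker
#'
#' Patients at or above the upper quartile are labelled `high`, at or below
#' the lower quartile `low`, and the interquartile middle `mid` (excluded
#' from two-group contrasts). Quartiles use the linear-interpolation
#' (type-7) quantile rule.
#'
#' @param values Numeric vector, one value per patient (>= 4 values).
#' @return A character vector in \{`"high"`, `"low"`, `"mid"`\} with the
#'   quartiles in `attr(, "quartiles")`.
#' @export
quartile_stratify <- function(values) {
  if (length(values) < 4) {
    abort("at least 4 patients are required for quartile stratification",
          class = "matrisig_validation_error")
  }
  if (any(is.na(values))) {
    abort("missing values in stratification marker",
          class = "matrisig_validation_error")
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  if (diff(range(values)) == 0) {
    abort("all marker values identical: stratification is degenerate",
          class = "matrisig_validation_error")
  }
  out <- dplyr::case_when(values >= q[2] ~ "high",
                          values <= q[1] ~ "low",
                          TRUE ~ "mid")
  attr(out, "quartiles") <- c(q1 = q[1], q3 = q[2])
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)` with `d_i`
#' deaths among `n_i` at risk. Subjects censored at an event time are at risk
#' through that time (censoring is taken to follow events at ties). With no
#' censoring the estimate equals one minus the empirical CDF of the event
#' times.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators, 1 = death observed, 0 = censored.
#' @return A `km_curve` tibble with one row per distinct observed time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv` (S(0) = 1 implicitly
#'   precedes the first row).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) {
    abort("empty survival input", class = "matrisig_validation_error")
  }
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  times <- sort(unique(time))
  n_risk <- vapply(times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(times, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(times, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- tibble(time = times, n_risk = n_risk, n_event = n_event,
                n_censor = n_censor, surv = surv)
  class(out) <- c("km_curve", class(tibble()))
  out
}

#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) as_tibble(as.data.frame(x))

#' Log-rank test for differences in survival between groups
#'
#' At every distinct event time the observed per-group deaths are compared
#' with their expectation under the hypergeometric distribution of deaths
#' across groups at risk; the summed observed-minus-expected vector and its
#' summed covariance give a chi-square statistic with (groups - 1) degrees
#' of freedom.
#'
#' @param time,event As in [km_estimate()].
#' @param group Group label per subject (>= 2 non-empty groups).
#' @return A list with `statistic`, `df`, `p`, and the per-group `observed` /
#'   `expected` event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  levels <- sort(unique(group))
  g <- length(levels)
  if (g < 2) abort("need at least 2 groups", class = "matrisig_validation_error")
  if (any(table(factor(group, levels = levels)) == 0)) {
    abort("empty group", class = "matrisig_validation_error")
  }
  if (sum(event) < 1) {
    abort("no events observed", class = "matrisig_validation_error")
  }
  event_times <- sort(unique(time[event == 1]))
  O <- setNames(numeric(g), levels)
  E <- setNames(numeric(g), levels)
  V <- matrix(0, g, g, dimnames = list(levels, levels))
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    n_j <- vapply(levels, function(l) sum(at_risk & group == l), numeric(1))
    d_j <- vapply(levels, function(l) sum(time == t & event == 1 & group == l),
                  numeric(1))
    O <- O + d_j
    E <- E + d * n_j / n
    if (n > 1) {
      frac <- n_j / n
      V <- V + d * (n - d) / (n - 1) * (diag(frac, g) - outer(frac, frac))
    }
  }
  z <- (O - E)[-g]
  Vsub <- V[-g, -g, drop = FALSE]
  stat <- tryCatch(drop(t(z) %*% solve(Vsub, z)), error = function(e) NA_real_)
  df <- g - 1
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Cox proportional-hazards regression (partial likelihood)
#'
#' Fits `h(t | x) = h0(t) exp(x'beta)` by Newton-Raphson maximisation of the
#' partial likelihood with Efron (default) or Breslow handling of tied event
#' times. Step-halving guarantees the log partial likelihood never decreases
#' across iterations. Non-convergence within `max_iter` iterations and
#' monotone-likelihood separation (any `|beta| > 15`) are flagged, not
#' raised.
#'
#' @param data A data frame with columns `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names (numeric;
#'   a 0/1 stratum indicator should encode the reference level as 0, e.g.
#'   high-vs-low with the lower quartile as reference).
#' @param ties `"efron"` or `"breslow"`.
#' @param max_iter Newton iteration cap (default 100).
#' @param tol Convergence tolerance on the score (default 1e-9).
#' @return A `cox_fit`: coefficient table (`term`, `estimate`, `se`,
#'   `hazard_ratio`, `statistic` (Wald z), `p_value`), `loglik` (null,
#'   fitted), `iter`, `converged`, `separation`, `ties`, `n`, `n_events`.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow"),
                    max_iter = 100, tol = 1e-9) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    abort(paste0("covariate(s) not in data: ", paste(missing_cov, collapse = ", ")),
          class = "matrisig_validation_error")
  }
  keep <- complete.cases(data[, c("time", "event", covariates)])
  data <- data[keep, , drop = FALSE]
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  time <- data$time
  event <- data$event
  if (sum(event) < 2) {
    abort("fewer than 2 events: Cox model cannot be fitted",
          class = "matrisig_validation_error")
  }
  if (qr(scale(X, scale = FALSE))$rank < ncol(X)) {
    abort("collinear covariates", class = "matrisig_validation_error")
  }

  p <- ncol(X)
  beta <- rep(0, p)
  ll_terms <- function(beta) cox_partial_loglik(beta, X, time, event, ties)
  cur <- ll_terms(beta)
  ll0 <- cur$loglik
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(cur$info, cur$score), error = function(e) NULL)
    if (is.null(step)) break
    ## step-halving: the log partial likelihood must not decrease
    scale_f <- 1
    repeat {
      cand <- beta + scale_f * step
      new <- ll_terms(cand)
      if (new$loglik >= cur$loglik - 1e-12 || scale_f < 1e-6) break
      scale_f <- scale_f / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    cur <- new
    if (max(abs(cur$score)) < tol || delta < tol) {
      converged <- TRUE
      break
    }
  }
  separation <- any(abs(beta) > 15)
  if (!converged) warn("Cox model did not converge; returning partial output")
  if (separation) warn("possible separation: |beta| > 15")
  beta <- unname(beta)
  se <- unname(sqrt(diag(solve(cur$info))))
  z <- beta / se
  coef <- tibble(term = covariates, estimate = beta, se = se,
                 hazard_ratio = exp(beta), statistic = z,
                 p_value = 2 * pnorm(-abs(z)))
  structure(list(coefficients = coef,
                 loglik = c(null = ll0, fitted = cur$loglik),
                 iter = iter, converged = converged, separation = separation,
                 ties = ties, n = nrow(X), n_events = sum(event)),
            class = "cox_fit")
}

## Log partial likelihood, score and information at beta.
## Efron: the l-th of d tied deaths sees risk-set mass S_R - (l/d) S_D.
cox_partial_loglik <- function(beta, X, time, event, ties) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  p <- ncol(X)
  loglik <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  for (t in sort(unique(time[event == 1]))) {
    R <- which(time >= t)
    D <- which(time == t & event == 1)
    d <- length(D)
    sR <- sum(w[R]); xR <- colSums(w[R] * X[R, , drop = FALSE])
    qR <- crossprod(sqrt(w[R]) * X[R, , drop = FALSE])
    sD <- sum(w[D]); xD <- colSums(w[D] * X[D, , drop = FALSE])
    qD <- crossprod(sqrt(w[D]) * X[D, , drop = FALSE])
    loglik <- loglik + sum(eta[D])
    for (l in seq_len(d)) {
      frac <- if (ties == "efron") (l - 1) / d else 0
      s <- sR - frac * sD
      xbar <- (xR - frac * xD) / s
      q <- (qR - frac * qD) / s
      loglik <- loglik - log(s)
      score <- score - xbar
      info <- info + q - outer(xbar, xbar)
    }
    ## per-tie xbar already subtracted inside the loop; deaths' own x added here
    score <- score + colSums(X[D, , drop = FALSE])
  }
  list(loglik = loglik, score = score, info = info)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, %s in %d iteration(s)\n",
              x$n, x$n_events, x$ties,
              if (x$converged) "converged" else "NOT converged", x$iter))
  print(x$coefficients)
  invisible(x)
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) x$coefficients

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         loglik_null = unname(x$loglik["null"]),
         loglik = unname(x$loglik["fitted"]),
         iter = x$iter, converged = x$converged, separation = x$separation,
         ties = x$ties)
}

#' Gene-set score survival analysis
#'
#' Composes the survival workflow for one gene set: ssGSEA scores per
#' patient, quartile dichotomisation of the score (upper quartile = `high`,
#' lower quartile = `low`; interquartile patients excluded), Kaplan-Meier
#' curves and log-rank test for high vs low, and a Cox model of high vs low
#' (lower quartile as reference) adjusted for the stromal-score covariate.
#'
#' @param expr Numeric genes x samples matrix; column names must join to
#'   `clinical$patient_id`.
#' @param gene_set Character vector of gene symbols.
#' @param clinical A survival tibble with `patient_id`, `time`, `event` and
#'   (for adjustment) `stromal_score`.
#' @param covariates Adjustment covariates (default `"stromal_score"`);
#'   covariates missing from `clinical` are dropped with a warning.
#' @inheritParams ssgsea_score
#' @param ties Tie handling for [cox_fit()].
#' @return A list with `data` (joined per-patient tibble with `score` and
#'   `stratum`), `km` (named list of [km_estimate()] curves for high/low),
#'   `logrank`, and `cox` (a [cox_fit()] on the high/low subset with the
#'   `stratum_high` indicator).
#' @export
signature_score_survival <- function(expr, gene_set, clinical,
                                     covariates = "stromal_score",
                                     alpha = 0.25, normalize = TRUE,
                                     ties = "efron") {
  shared_ids <- intersect(colnames(expr), clinical$patient_id)
  if (length(shared_ids) < 8) {
    abort(sprintf("only %d patients joinable between expression and clinical data",
                  length(shared_ids)),
          class = "matrisig_validation_error")
  }
  drop_cov <- setdiff(covariates, names(clinical))
  if (length(drop_cov) > 0) {
    warn(paste0("covariate(s) absent from clinical table, dropped: ",
                paste(drop_cov, collapse = ", ")))
    covariates <- setdiff(covariates, drop_cov)
  }
  scores <- ssgsea_score(expr[, shared_ids, drop = FALSE], gene_set,
                         alpha = alpha, normalize = normalize)
  data <- clinical |>
    dplyr::filter(.data$patient_id %in% shared_ids) |>
    dplyr::mutate(score = unname(scores[.data$patient_id]))
  data$stratum <- quartile_stratify(data$score)
  two <- data |>
    dplyr::filter(.data$stratum != "mid") |>
    dplyr::mutate(stratum_high = as.integer(.data$stratum == "high"))
  km <- list(
    high = km_estimate(two$time[two$stratum == "high"],
                       two$event[two$stratum == "high"]),
    low = km_estimate(two$time[two$stratum == "low"],
                      two$event[two$stratum == "low"]))
  lr <- logrank_test(two$time, two$event, two$stratum)
  cox <- cox_fit(two, c("stratum_high", covariates), ties = ties)
  list(data = data, km = km, logrank = lr, cox = cox)
}

#' Write Kaplan-Meier curves and a Cox fit summary
#'
#' @param km Named list of [km_estimate()] curves.
#' @param cox A [cox_fit()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_survival <- function(km, cox, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  curves <- purrr::imap_dfr(km, ~ dplyr::mutate(tidy(.x), group = .y))
  readr::write_tsv(curves, file.path(dir, "km_curves.tsv"))
  readr::write_tsv(tidy(cox), file.path(dir, "cox_fit.tsv"))
  invisible(dir)
}
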