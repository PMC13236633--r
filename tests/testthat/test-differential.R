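## 2 models per type, 5 replicates: the full 10-vs-10 contrast
diff_fixture <- function(m_lo, m_hi, genes) {
  samples <- c(outer(1:5, c("A1", "A2", "B1", "B2"),
                     function(r, mod) paste0(mod, "_", r)))
  m <- cbind(m_lo, m_hi)
  dimnames(m) <- list(genes, samples)
  pq <- make_quant(m, models = c(A1 = "CD8lo", A2 = "CD8lo",
                                 B1 = "CD8hi", B2 = "CD8hi"))
  annotate_matrisome(pq, toy_reference(), quiet = TRUE)
}

test_that("total-sum normalisation scales samples to the median raw sum", {
  m <- matrix(c(40, 60, 80, 120), 2, 2,
              dimnames = list(c("Col1a1", "Fn1"), c("A1_1", "A1_2")))
  pq <- make_quant(m, models = c(A1 = "lo"), n_rep = 2)
  norm <- normalize_intensities(pq, "total_sum")
  # sums 100 and 200, target median 150 -> factors 1.5 and 0.75
  expect_equal(unname(attr(norm, "scale_factors")), c(1.5, 0.75))
  expect_equal(unname(colSums(pq_intensity_matrix(norm))), c(150, 150))

  expect_identical(pq_intensity_matrix(normalize_intensities(pq, "none")),
                   pq_intensity_matrix(pq))

  equal <- make_quant(matrix(c(1, 2, 2, 1), 2, 2,
                             dimnames = list(c("Col1a1", "Fn1"),
                                             c("A1_1", "A1_2"))),
                      models = c(A1 = "lo"), n_rep = 2)
  expect_equal(pq_intensity_matrix(normalize_intensities(equal, "total_sum")),
               pq_intensity_matrix(equal))  # equal sums: fixed point

  m_na <- m; m_na[, 2] <- NA
  pq_na <- make_quant(m_na, models = c(A1 = "lo"), n_rep = 2)
  expect_error(normalize_intensities(pq_na), "all intensities missing")
})

test_that("normalisation preserves missingness", {
  m <- matrix(c(10, NA, 5, 20, 30, NA), 3, 2,
              dimnames = list(c("Col1a1", "Fn1", "Mmp9"), c("A1_1", "A1_2")))
  pq <- make_quant(m, models = c(A1 = "lo"), n_rep = 2)
  norm <- normalize_intensities(pq)
  expect_identical(is.na(pq_intensity_matrix(norm)), is.na(m))
})

test_that("t statistics match stats::t.test for pooled and Welch variants", {
  x <- c(10, 12, 11, 13, 12)
  y <- c(14, 15, 16, 15, 14)
  mine <- student_t_test(x, y, "student")
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter))

  mine_w <- student_t_test(x, y, "welch")
  ref_w <- t.test(x, y, var.equal = FALSE)
  expect_equal(mine_w$t, unname(ref_w$statistic), tolerance = 1e-12)
  expect_equal(mine_w$p, ref_w$p.value, tolerance = 1e-12)
  expect_equal(mine_w$df, unname(ref_w$parameter), tolerance = 1e-9)

  same <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  swapped <- student_t_test(y, x, "student")
  expect_equal(swapped$t, -mine$t)
  expect_equal(swapped$p, mine$p)

  short <- student_t_test(c(1), c(1, 2, 3))
  expect_false(short$testable)
  expect_true(is.na(short$p))
})

test_that("differential calls follow the p-and-ratio contract", {
  set.seed(7)
  # g_up 1.6x in hi, g_dn 0.5x in hi, g_null identical, g_na missing in lo
  m_lo <- rbind(rep(1e6, 10), rep(1e6, 10), rep(1e6, 10), rep(NA, 10))
  m_hi <- rbind(1.6e6 * exp(rnorm(10, 0, 0.02)),
                0.5e6 * exp(rnorm(10, 0, 0.02)),
                rep(1e6, 10),
                rep(1e6, 10))
  m_lo[1:3, ] <- m_lo[1:3, ] * exp(rnorm(30, 0, 0.02))
  ann <- diff_fixture(m_lo, m_hi, c("Postn", "S100a10", "Col1a1", "Fn1"))
  diff <- differential_abundance(ann, c("Postn", "S100a10", "Col1a1", "Fn1"))
  calls <- setNames(diff$call, diff$gene_symbol)
  expect_identical(unname(calls["Postn"]), "up_in_hi")
  expect_identical(unname(calls["S100a10"]), "up_in_lo")
  expect_identical(unname(calls["Col1a1"]), "unchanged")  # ratio 1, p = 1
  expect_true(is.na(calls["Fn1"]))  # untestable: no lo values
  expect_false(diff$testable[diff$gene_symbol == "Fn1"])
  # invariant: every call consistent with its own p and ratio
  p <- attr(diff, "params")
  ok <- diff$testable
  expect_identical(diff$call[ok] == "up_in_hi",
                   unname((diff$p < p$alpha & diff$ratio >= p$up)[ok]))
  expect_identical(diff$call[ok] == "up_in_lo",
                   unname((diff$p < p$alpha & diff$ratio <= p$down)[ok]))
})

test_that("group swap maps calls antisymmetrically and rescaling is invariant", {
  set.seed(91)
  genes <- sprintf("G%02d", 1:30)
  m_lo <- matrix(rlnorm(300, 13, 0.3), 30, 10)
  m_hi <- matrix(rlnorm(300, 13, 0.3), 30, 10)
  ref <- matrisome_reference(tibble::tibble(
    gene_symbol = genes, division = "core matrisome", category = "collagens"))
  samples <- c(outer(1:5, c("A1", "A2", "B1", "B2"),
                     function(r, mod) paste0(mod, "_", r)))
  m <- cbind(m_lo, m_hi); dimnames(m) <- list(genes, samples)
  pq <- annotate_matrisome(
    make_quant(m, models = c(A1 = "CD8lo", A2 = "CD8lo",
                             B1 = "CD8hi", B2 = "CD8hi")), ref, quiet = TRUE)
  d1 <- differential_abundance(pq, genes)
  d2 <- differential_abundance(pq, genes, type_lo = "CD8hi", type_hi = "CD8lo")
  remap <- c(up_in_hi = "up_in_lo", up_in_lo = "up_in_hi",
             unchanged = "unchanged")
  expect_identical(unname(remap[d1$call]), d2$call)
  expect_equal(d2$t, -d1$t)
  expect_equal(d2$p, d1$p)

  scaled <- matrisig:::pq_set_intensities(pq, pq_intensity_matrix(pq) * 7.3)
  d3 <- differential_abundance(scaled, genes)
  expect_identical(d3$call, d1$call)
  expect_equal(d3$p, d1$p, tolerance = 1e-9)
})

test_that("combined signatures union exclusives with directional calls", {
  set.seed(5)
  m_lo <- rbind(rep(2e6, 10) * exp(rnorm(10, 0, 0.02)), rep(1e6, 10))
  m_hi <- rbind(rep(1e6, 10) * exp(rnorm(10, 0, 0.02)), rep(1e6, 10))
  ann <- diff_fixture(m_lo, m_hi, c("S100a10", "Col1a1"))
  diff <- differential_abundance(ann, c("S100a10", "Col1a1"))
  comb <- combined_signature(c("Mmp9", "Anxa1"), diff, "lo")
  expect_setequal(comb$gene_symbol, c("Mmp9", "Anxa1", "S100a10"))
  expect_identical(comb$source[comb$gene_symbol == "S100a10"], "differential")
  expect_false(any(duplicated(comb$gene_symbol)))

  none <- combined_signature(c("Mmp9"), diff, "hi")
  expect_identical(none$gene_symbol, "Mmp9")  # empty differential side
})

test_that("planted fold changes are recovered with near-nominal error rates", {
  ## 2-fold effects at 20% CV, n = 10 per type: sensitivity > 0.9;
  ## planted nulls called at ~alpha (seed-fixed tolerance +/- 0.03)
  set.seed(2024)
  n_eff <- 60; n_null <- 400
  genes <- sprintf("G%03d", 1:(n_eff + n_null))
  sdlog <- sqrt(log(1 + 0.2^2))
  base <- rlnorm(n_eff + n_null, 13, 1)
  fold <- c(rep(2, n_eff), rep(1, n_null))
  m_lo <- base * matrix(exp(rnorm((n_eff + n_null) * 10, 0, sdlog)), ncol = 10)
  m_hi <- (base * fold) *
    matrix(exp(rnorm((n_eff + n_null) * 10, 0, sdlog)), ncol = 10)
  ref <- matrisome_reference(tibble::tibble(
    gene_symbol = genes, division = "core matrisome", category = "collagens"))
  samples <- c(outer(1:5, c("A1", "A2", "B1", "B2"),
                     function(r, mod) paste0(mod, "_", r)))
  m <- cbind(m_lo, m_hi); dimnames(m) <- list(genes, samples)
  pq <- annotate_matrisome(
    make_quant(m, models = c(A1 = "CD8lo", A2 = "CD8lo",
                             B1 = "CD8hi", B2 = "CD8hi")), ref, quiet = TRUE)
  diff <- differential_abundance(pq, genes)
  sens <- mean(diff$call[1:n_eff] == "up_in_hi")
  expect_gt(sens, 0.9)
  false_rate <- mean(diff$p[(n_eff + 1):(n_eff + n_null)] < 0.05)
  expect_lt(abs(false_rate - 0.05), 0.03)
})
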