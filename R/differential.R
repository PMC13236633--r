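#' Normalise label-free intensities across samples
#'
#' `total_sum` (the default, matching normalised total precursor ion
#' intensity quantification): every sample is rescaled so its intensity sum
#' equals the median of the raw per-sample sums. `median_ratio` computes
#' DESeq-style size factors from the median ratio to the per-protein
#' geometric-mean reference (complete rows only). `none` is the identity.
#' Missing values stay missing under every method.
#'
#' @param x A [protein_quant()].
#' @param method `"total_sum"`, `"median_ratio"` or `"none"`.
#' @return The rescaled `protein_quant`, with per-sample scale factors in
#'   `attr(, "scale_factors")`.
#' @export
normalize_intensities <- function(x, method = c("total_sum", "median_ratio", "none")) {
  method <- match.arg(method)
  m <- pq_intensity_matrix(x)
  if (method == "none") {
    out <- x
    attr(out, "scale_factors") <- setNames(rep(1, ncol(m)), colnames(m))
    return(out)
  }
  if (any(colSums(!is.na(m)) == 0)) {
    abort("sample with all intensities missing cannot be normalised",
          class = "matrisig_validation_error")
  }
  if (method == "total_sum") {
    sums <- colSums(m, na.rm = TRUE)
    factors <- median(sums) / sums
  } else {
    complete <- m[complete.cases(m), , drop = FALSE]
    complete <- complete[rowSums(complete > 0) == ncol(complete), , drop = FALSE]
    if (nrow(complete) < 1) {
      abort("median_ratio normalisation needs at least one complete protein row",
            class = "matrisig_validation_error")
    }
    ref <- exp(rowMeans(log(complete)))
    factors <- 1 / apply(complete / ref, 2, median)
  }
  out <- pq_set_intensities(x, sweep(m, 2, factors, `*`))
  attr(out, "scale_factors") <- factors
  out
}

#' Unpaired two-sample t test (Student or Welch)
#'
#' Student: pooled variance, `df = n_x + n_y - 2`. Welch: Satterthwaite
#' degrees of freedom. Two-sided p from the t distribution. With fewer than
#' two non-missing values in either group the comparison is untestable and
#' `NA`s are returned rather than an error. Degenerate zero-variance input
#' yields `t = 0, p = 1` for identical means and `|t| = Inf, p = 0`
#' otherwise.
#'
#' @param x,y Numeric vectors (missing values dropped).
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return A list with `t`, `p`, `df`, and `testable`.
#' @export
student_t_test <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  r <- row_t_test(matrix(c(x, rep(NA, 0)), nrow = 1,
                         ncol = length(x), byrow = TRUE),
                  matrix(y, nrow = 1, ncol = length(y), byrow = TRUE),
                  variant)
  list(t = r$t[1], p = r$p[1], df = r$df[1], testable = r$testable[1])
}

## Vectorised row-wise t test on two matrices with aligned rows.
## Direction: t > 0 when mean(x) > mean(y).
row_t_test <- function(mx, my, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  nx <- rowSums(!is.na(mx))
  ny <- rowSums(!is.na(my))
  mean_x <- rowMeans(mx, na.rm = TRUE)
  mean_y <- rowMeans(my, na.rm = TRUE)
  var_x <- rowSums((mx - mean_x)^2, na.rm = TRUE) / pmax(nx - 1, 1)
  var_y <- rowSums((my - mean_y)^2, na.rm = TRUE) / pmax(ny - 1, 1)
  testable <- nx >= 2 & ny >= 2
  if (variant == "student") {
    df <- nx + ny - 2
    pooled <- ((nx - 1) * var_x + (ny - 1) * var_y) / df
    se <- sqrt(pooled * (1 / nx + 1 / ny))
  } else {
    a <- var_x / nx
    b <- var_y / ny
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / pmax(nx - 1, 1) + b^2 / pmax(ny - 1, 1))
  }
  delta <- mean_x - mean_y
  t <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  p <- ifelse(is.infinite(t), 0, 2 * pt(-abs(t), df))
  p[t == 0] <- 1
  t[!testable] <- NA_real_
  p[!testable] <- NA_real_
  df[!testable] <- NA_real_
  list(t = t, p = p, df = df, testable = testable,
       mean_x = mean_x, mean_y = mean_y, n_x = nx, n_y = ny)
}

infer_type_pair <- function(types, type_lo, type_hi) {
  tt <- unique(types)
  if (is.null(type_lo) || is.null(type_hi)) {
    if (all(c("CD8lo", "CD8hi") %in% tt)) {
      type_lo <- type_lo %||% "CD8lo"
      type_hi <- type_hi %||% "CD8hi"
    } else if (length(tt) == 2) {
      tt <- sort(tt)
      type_lo <- type_lo %||% tt[1]
      type_hi <- type_hi %||% tt[2]
    } else {
      abort("tumor types are ambiguous; supply type_lo and type_hi")
    }
  }
  if (!all(c(type_lo, type_hi) %in% types)) {
    abort("type_lo/type_hi not found in the design",
          class = "matrisig_validation_error")
  }
  c(lo = unname(type_lo), hi = unname(type_hi))
}

#' Differential abundance of shared matrisome proteins between tumour types
#'
#' For each protein of the shared set, compares normalised intensities of all
#' samples of one tumour type against the other with an unpaired t test and
#' calls a protein differential when `p < alpha` *and* the abundance ratio
#' crosses the fold threshold: `up_in_hi` iff `ratio >= up`, `up_in_lo` iff
#' `ratio <= down` (defaults `p < 0.05` and a +/-20% change, i.e. 1.2 / 0.8),
#' where `ratio = mean_hi / mean_lo`. Proteins with fewer than two
#' non-missing values in either group are flagged untestable. Missing values
#' are excluded pairwise; no imputation. A Benjamini-Hochberg `bh_q` column
#' is emitted for transparency but never used for the calls.
#'
#' @param x A normalised, annotated [protein_quant()].
#' @param shared Character vector of shared protein gene symbols (e.g.
#'   `signature_result$shared`); must be a subset of the table's symbols.
#' @param alpha Significance level for the t test (default 0.05).
#' @param up,down Ratio thresholds (default 1.2 and 0.8; the log-symmetric
#'   alternative `down = 1/up` may be passed explicitly).
#' @param variant t-test variant, `"student"` (default) or `"welch"`.
#' @param log2_transform Test on `log2` intensities instead of the raw
#'   normalised scale; the reported `ratio` is then the geometric
#'   (fold-change) ratio `2^(mean_hi - mean_lo)`.
#' @param type_lo,type_hi Tumour-type labels of the two groups; inferred from
#'   the design when it has exactly two types (CD8lo/CD8hi preferred).
#' @return A `differential_result` tibble: `gene_symbol`, `category`,
#'   `mean_lo`, `mean_hi`, `ratio`, `log2_ratio`, `t`, `p`, `bh_q`, `call`,
#'   `testable`; parameters in `attr(, "params")`.
#' @export
differential_abundance <- function(x, shared, alpha = 0.05, up = 1.2, down = 0.8,
                                   variant = c("student", "welch"),
                                   log2_transform = FALSE,
                                   type_lo = NULL, type_hi = NULL) {
  variant <- match.arg(variant)
  design <- pq_design(x)
  pair <- infer_type_pair(design$tumor_type, type_lo, type_hi)

  key <- normalize_symbol(x$gene_symbol)
  idx <- match(normalize_symbol(shared), key)
  if (any(is.na(idx))) {
    abort(paste0("shared protein(s) absent from table: ",
                 paste(shared[is.na(idx)], collapse = ", ")),
          class = "matrisig_validation_error")
  }
  m <- pq_intensity_matrix(x)[idx, , drop = FALSE]
  if (log2_transform) m <- log2(m)
  m_hi <- m[, design$sample[design$tumor_type == pair["hi"]], drop = FALSE]
  m_lo <- m[, design$sample[design$tumor_type == pair["lo"]], drop = FALSE]

  r <- row_t_test(m_hi, m_lo, variant)
  if (log2_transform) {
    mean_lo <- r$mean_y
    mean_hi <- r$mean_x
    ratio <- 2^(mean_hi - mean_lo)
  } else {
    mean_lo <- r$mean_y
    mean_hi <- r$mean_x
    ratio <- mean_hi / mean_lo
  }
  call <- dplyr::case_when(
    !r$testable ~ NA_character_,
    r$p < alpha & ratio >= up ~ "up_in_hi",
    r$p < alpha & ratio <= down ~ "up_in_lo",
    TRUE ~ "unchanged")
  out <- tibble(
    gene_symbol = x$gene_symbol[idx],
    category = if ("category" %in% names(x)) x$category[idx] else NA_character_,
    mean_lo = mean_lo, mean_hi = mean_hi,
    ratio = ratio, log2_ratio = log2(ratio),
    t = r$t, p = r$p,
    bh_q = p.adjust(r$p, method = "BH"),
    call = call, testable = r$testable)
  attr(out, "params") <- list(alpha = alpha, up = up, down = down,
                              variant = variant,
                              log2_transform = log2_transform,
                              type_lo = unname(pair["lo"]),
                              type_hi = unname(pair["hi"]))
  class(out) <- c("differential_result", class(tibble()))
  out
}

#' Combined signature: exclusive proteins plus differential calls
#'
#' The combined signature of a tumour type unions its exclusive protein set
#' with the shared proteins called differentially more abundant in that type.
#'
#' @param exclusive Character vector, the type's exclusive signature.
#' @param diff A [differential_abundance()] result.
#' @param direction `"lo"` or `"hi"`: which tumour type the signature
#'   characterises (selects `up_in_lo` / `up_in_hi` calls).
#' @return A tibble `gene_symbol`, `source` (`"exclusive"` or
#'   `"differential"`), without duplicates.
#' @export
combined_signature <- function(exclusive, diff, direction = c("lo", "hi")) {
  direction <- match.arg(direction)
  wanted <- paste0("up_in_", direction)
  called <- diff$gene_symbol[!is.na(diff$call) & diff$call == wanted]
  out <- dplyr::bind_rows(
    tibble(gene_symbol = exclusive, source = "exclusive"),
    tibble(gene_symbol = called, source = "differential"))
  out[!duplicated(normalize_symbol(out$gene_symbol)), ]
}

#' Write the volcano table
#'
#' @param diff A [differential_abundance()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_volcano <- function(diff, path) {
  readr::write_tsv(as_tibble(as.data.frame(diff)), path, na = "")
  invisible(path)
}
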