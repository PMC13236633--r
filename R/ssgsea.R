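#' Single-sample GSEA enrichment scores
#'
#' Barbie-style ssGSEA: within each sample, genes are ranked by expression
#' (ties get average ranks) and the score is the summed difference between
#' the weighted empirical CDF of the in-set genes (weights `rank^alpha`) and
#' the unweighted empirical CDF of the out-of-set genes, both evaluated as
#' step functions of rank walked from the top of the ranking. Scores are
#' rank-based, hence invariant under any strictly monotone transform of a
#' sample's expression values; a constant (all-tied) sample scores exactly 0.
#'
#' When `normalize = TRUE` (default) scores are divided by the range
#' (max - min) of this gene set's scores across the matrix's samples, the
#' usual ssGSEA normalisation; it is skipped (factor 1) for a single sample
#' or a degenerate zero range.
#'
#' @param expr Numeric genes x samples matrix (rownames = gene symbols).
#' @param gene_set Character vector of member gene symbols (matched
#'   case-insensitively); at least 2 and fewer than all of `expr`'s genes
#'   must be present.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Divide by the across-sample score range (default TRUE).
#' @return A named numeric vector of per-sample scores with attributes
#'   `alpha` and `normalized`.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25, normalize = TRUE) {
  if (is.null(rownames(expr))) abort("expr must have gene rownames")
  key <- normalize_symbol(rownames(expr))
  in_set <- key %in% normalize_symbol(gene_set)
  n_in <- sum(in_set)
  if (n_in < 2 || n_in >= nrow(expr)) {
    missing <- setdiff(normalize_symbol(gene_set), key)
    abort(paste0(
      "gene set must overlap the matrix in >= 2 genes and leave a non-empty ",
      "complement (overlap ", n_in, " of ", nrow(expr), " genes",
      if (length(missing) > 0) {
        paste0("; absent: ", paste(head(missing, 10), collapse = ", "))
      } else "", ")"),
      class = "matrisig_validation_error")
  }
  scores <- apply(expr, 2, ssgsea_sample_score, in_set = in_set, alpha = alpha)
  if (normalize && length(scores) > 1) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "alpha") <- alpha
  attr(scores, "normalized") <- normalize
  scores
}

## One sample's score. Ranks: 1 = lowest expression, N = highest; weights
## rank^alpha over set members. Both ECDFs are evaluated at each gene's rank
## threshold ("fraction at rank >= r_i"), so tied genes share one value and
## an all-tied sample nets exactly 0.
ssgsea_sample_score <- function(v, in_set, alpha) {
  n <- length(v)
  r <- rank(v, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  r_ord <- r[ord]
  in_ord <- in_set[ord]
  w_ord <- ifelse(in_ord, r_ord^alpha, 0)
  cum_in <- cumsum(w_ord)
  cum_out <- cumsum(!in_ord)
  ## ties: every member of a tie group takes the group's closing cumulative
  last_of_group <- rev(!duplicated(rev(r_ord)))
  grp <- cumsum(!duplicated(r_ord))
  cum_in <- (cum_in[last_of_group])[grp]
  cum_out <- (cum_out[last_of_group])[grp]
  sum(cum_in) / sum(w_ord) - sum(cum_out) / (n - sum(in_set))
}

#' Score several gene sets on one expression matrix
#'
#' @param expr Numeric genes x samples matrix.
#' @param sets Named list of gene sets (e.g. from [read_gene_sets()]).
#' @inheritParams ssgsea_score
#' @return A tibble with a `sample` column and one score column per set.
#' @export
score_gene_sets <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  out <- tibble(sample = colnames(expr))
  for (nm in names(sets)) {
    out[[nm]] <- unname(ssgsea_score(expr, sets[[nm]], alpha, normalize))
  }
  out
}

#' Spearman correlation between signature and CTL enrichment scores
#'
#' Scores the hot-matrisome, cold-matrisome and cytotoxic-T-lymphocyte (CTL)
#' gene sets on the same cohort with [ssgsea_score()] and returns all
#' pairwise Spearman correlations of the per-sample score vectors.
#'
#' @param expr Numeric genes x samples matrix with at least 3 samples.
#' @param hot_set,cold_set,ctl_set Character vectors of gene symbols.
#' @inheritParams ssgsea_score
#' @return A 3 x 3 Spearman correlation matrix over (hot, cold, ctl).
#' @export
signature_ctl_correlation <- function(expr, hot_set, cold_set, ctl_set,
                                      alpha = 0.25, normalize = TRUE) {
  if (ncol(expr) < 3) {
    abort("at least 3 samples are required for score correlations",
          class = "matrisig_validation_error")
  }
  s <- cbind(
    hot = ssgsea_score(expr, hot_set, alpha, normalize),
    cold = ssgsea_score(expr, cold_set, alpha, normalize),
    ctl = ssgsea_score(expr, ctl_set, alpha, normalize))
  cor(s, method = "spearman")
}

#' Gene-set overrepresentation (one-sided hypergeometric) test
#'
#' Offline overrepresentation analysis of a query gene set against one
#' annotation set within a finite universe: with `k` genes shared between
#' query and annotation, `p = P[X >= k]` for
#' `X ~ Hypergeometric(|universe|, |annotation|, |query|)`.
#'
#' @param query,annotation,universe Character vectors of gene symbols; query
#'   and annotation must be subsets of the universe.
#' @return A list with `k` (overlap), `p`, and `expected` (the null-mean
#'   overlap).
#' @export
overrepresentation_test <- function(query, annotation, universe) {
  uq <- unique(normalize_symbol(universe))
  q <- unique(normalize_symbol(query))
  a <- unique(normalize_symbol(annotation))
  if (!all(q %in% uq)) {
    abort("query genes must be a subset of the universe",
          class = "matrisig_validation_error")
  }
  if (!all(a %in% uq)) {
    abort("annotation genes must be a subset of the universe",
          class = "matrisig_validation_error")
  }
  k <- length(intersect(q, a))
  p <- phyper(k - 1, length(a), length(uq) - length(a), length(q),
              lower.tail = FALSE)
  list(k = k, p = p, expected = length(q) * length(a) / length(uq))
}
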