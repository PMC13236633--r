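## Independent oracles and small fixture builders shared across tests.

## Brute-force ssGSEA oracle: literal double loop over genes evaluating the
## weighted in-set ECDF and unweighted out-of-set ECDF at every gene's rank.
oracle_ssgsea <- function(expr, gene_set, alpha) {
  in_set <- toupper(rownames(expr)) %in% toupper(gene_set)
  apply(expr, 2, function(v) {
    n <- length(v)
    r <- rank(v, ties.method = "average")
    w_total <- sum(r[in_set]^alpha)
    total <- 0
    for (i in seq_len(n)) {
      num <- sum(r[in_set][r[in_set] >= r[i]]^alpha) / w_total
      den <- sum(r[!in_set] >= r[i]) / sum(!in_set)
      total <- total + num - den
    }
    total
  })
}

## Hypergeometric upper-tail by direct combinatorial summation.
oracle_hyper_tail <- function(k, n_universe, n_annotation, n_query) {
  if (k > min(n_annotation, n_query)) return(0)
  ks <- k:min(n_annotation, n_query)
  sum(choose(n_annotation, ks) *
        choose(n_universe - n_annotation, n_query - ks)) /
    choose(n_universe, n_query)
}

## Cox score equation for a single covariate, written out as the explicit
## partial-likelihood sum (Breslow; exact for tie-free data), solved by
## bisection. Independent of the package's Newton implementation.
oracle_cox_beta <- function(time, event, x) {
  score <- function(beta) {
    s <- 0
    for (t in time[event == 1]) {
      r <- time >= t
      s <- s + x[time == t & event == 1] -
        sum(x[r] * exp(beta * x[r])) / sum(exp(beta * x[r]))
    }
    s
  }
  uniroot(score, c(-10, 10), tol = 1e-12)$root
}

## Small annotated quantification fixture: one tumour type pair, two models
## each, n_rep replicates; intensities supplied as a proteins x samples
## matrix (NA = not detected).
make_quant <- function(intensities, peptide_count = NULL, protein_fdr = NULL,
                       models = c(A1 = "lo", A2 = "lo", B1 = "hi", B2 = "hi"),
                       n_rep = NULL) {
  samples <- colnames(intensities)
  if (is.null(n_rep)) n_rep <- length(samples) / length(models)
  design <- tibble::tibble(
    sample = samples,
    model = rep(names(models), each = n_rep),
    tumor_type = rep(unname(models), each = n_rep),
    replicate = rep(seq_len(n_rep), times = length(models)))
  quant <- tibble::tibble(
    protein_id = rownames(intensities),
    gene_symbol = rownames(intensities),
    peptide_count = peptide_count %||% rep(3L, nrow(intensities)),
    protein_fdr = protein_fdr %||% rep(0.001, nrow(intensities)))
  for (s in samples) quant[[s]] <- intensities[, s]
  protein_quant(quant, design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Reference covering the toy genes used across fixtures.
toy_reference <- function() {
  matrisome_reference(tibble::tibble(
    gene_symbol = c("Col1a1", "Col3a1", "Fn1", "Agrn", "Postn", "Tgfbi",
                    "Mmp9", "Anxa1", "Il1rn", "S100a10"),
    division = c(rep("core matrisome", 6), rep("matrisome-associated", 4)),
    category = c("collagens", "collagens", "ECM glycoproteins",
                 "proteoglycans", "ECM glycoproteins", "ECM glycoproteins",
                 "ECM regulators", "ECM-affiliated proteins",
                 "secreted factors", "ECM-affiliated proteins")))
}

packaged_reference <- function() {
  read_matrisome_reference(
    system.file("extdata", "matrisome_reference.tsv", package = "matrisig"))
}
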