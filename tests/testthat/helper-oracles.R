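# Independent oracles, kept deliberately naive and separate from the
# package's own code paths.

# OLS by explicit normal equations on (x, y).
oracle_ols <- function(x, y) {
  xbar <- sum(x) / length(x)
  ybar <- sum(y) / length(y)
  slope <- sum((x - xbar) * (y - ybar)) / sum((x - xbar)^2)
  intercept <- ybar - slope * xbar
  list(slope = slope, intercept = intercept,
       residuals = y - (intercept + slope * x))
}

# Quartile at fractional position p * (n - 1) on the sorted array, linear
# interpolation between adjacent order statistics.
oracle_quantile <- function(values, p) {
  s <- sort(values)
  h <- p * (length(s) - 1)
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - (lo - 1)) * (s[hi] - s[lo])
}

# Full outlier-rule recomputation: OLS residuals, sorted-array quartiles,
# strict 6D thresholds.
oracle_outliers <- function(loads) {
  fit <- oracle_ols(loads$load_control, loads$load_case)
  r <- fit$residuals
  q1 <- oracle_quantile(r, 0.25)
  q3 <- oracle_quantile(r, 0.75)
  d <- q3 - q1
  list(case = loads$gene[r > q3 + 6 * d],
       control = loads$gene[r < q1 - 6 * d],
       q1 = q1, q3 = q3, d = d)
}

# Hypergeometric upper tail by exhaustive enumeration of all size-n draws
# from a universe of N items whose first K are set members.
oracle_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# A random gene-load table for property tests.
random_load_table <- function(n_genes) {
  data.frame(
    gene = sprintf("R%03d", seq_len(n_genes)),
    load_control = rpois(n_genes, 10),
    load_case = rpois(n_genes, 10) +
      sample(0:1, n_genes, replace = TRUE) * rpois(n_genes, 30),
    stringsAsFactors = FALSE
  )
}

# A load_fit object with prescribed residuals, for testing the calling
# rule in isolation from the regression.
fit_from_residuals <- function(res, genes = sprintf("G%d", seq_along(res))) {
  names(res) <- genes
  q <- quartiles(res)
  d <- unname(q["q3"] - q["q1"])
  structure(
    list(slope = 0, intercept = 0, residuals = res,
         q1 = unname(q["q1"]), q3 = unname(q["q3"]), d = d,
         lower_threshold = unname(q["q1"] - 6 * d),
         upper_threshold = unname(q["q3"] + 6 * d),
         n_genes = length(res),
         loads = data.frame(gene = genes, load_control = 0L,
                            load_case = 0L, stringsAsFactors = FALSE)),
    class = "load_fit")
}

# Write a participant table to a temp TSV and return the path.
write_cohort_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

participants_df <- function(n, phenotype = "normal", age = 70, ...) {
  data.frame(participant_id = sprintf("P%04d", seq_len(n)),
             phenotype_label = rep_len(phenotype, n),
             age_years = rep_len(age, n), ...,
             stringsAsFactors = FALSE)
}

# A small annotated-variant table builder with qualifying defaults.
variants_df <- function(n, gene = "G1", AF_nfe = 0.01, AF_afr = 0.01,
                        cadd = 30, spliceai = 0, utr5_flag = FALSE,
                        carriers_normal = 1, carriers_impaired = 1) {
  data.frame(variant_id = sprintf("chr1:%d:A:G", seq_len(n)),
             gene = gene, AF_nfe = AF_nfe, AF_afr = AF_afr,
             cadd = cadd, spliceai = spliceai, utr5_flag = utr5_flag,
             carriers_normal = carriers_normal,
             carriers_impaired = carriers_impaired,
             stringsAsFactors = FALSE)
}
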