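test_that("gene loads count distinct variants present per group", {
  v <- rbind(
    variants_df(3, gene = "G1", carriers_normal = c(2, 1, 0),
                carriers_impaired = c(0, 1, 5)),
    variants_df(1, gene = "G2", carriers_normal = 0,
                carriers_impaired = 1),
    variants_df(1, gene = "G3", carriers_normal = 0,
                carriers_impaired = 0)
  )
  v$variant_id <- sprintf("chr1:%d:A:G", seq_len(nrow(v)))
  loads <- compute_gene_loads(v)
  expect_equal(loads$gene, c("G1", "G2"))  # G3 absent: no presence
  expect_equal(loads$load_control, c(2L, 0L))
  expect_equal(loads$load_case, c(2L, 1L))

  expect_error(compute_gene_loads(v, control = "typo"), "unknown group")
  empty <- compute_gene_loads(v[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("quartiles interpolate at fractional positions", {
  expect_equal(unname(quartiles(1:5)), c(2, 4))
  expect_equal(unname(quartiles(c(0, 100))), c(25, 75))
  expect_equal(unname(quartiles(rep(3.7, 6))), c(3.7, 3.7))
  expect_error(quartiles(1), "at least 2")
  # agreement with the sorted-array oracle on random draws
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(sample(2:40, 1))
    expect_equal(unname(quartiles(x)),
                 c(oracle_quantile(x, 0.25), oracle_quantile(x, 0.75)))
  }
})

test_that("a perfect linear relation gives zero residuals and no outliers", {
  loads <- data.frame(gene = paste0("G", 1:5), load_control = 0:4,
                      load_case = 2 * (0:4) + 1)
  fit <- fit_load_regression(loads)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(unname(fit$residuals), rep(0, 5), tolerance = 1e-10)
  expect_equal(fit$d, 0)
  calls <- call_outliers(fit)
  expect_length(calls$outliers_case, 0)
  expect_length(calls$outliers_control, 0)
})

test_that("regression rejects degenerate inputs by name", {
  small <- data.frame(gene = c("A", "B"), load_control = c(1, 2),
                      load_case = c(1, 2))
  expect_error(fit_load_regression(small), "at least 3 genes")
  flat <- data.frame(gene = c("A", "B", "C"), load_control = c(2, 2, 2),
                     load_case = c(1, 5, 9))
  expect_error(fit_load_regression(flat), "non-constant")
})

test_that("leverage limits outlier calling on very small tables", {
  # with only 5 genes an extreme point drags the fit and widens D; the
  # oracle confirms no gene clears the 6D thresholds here
  loads <- data.frame(gene = paste0("G", 1:5), load_control = 0:4,
                      load_case = c(0, 2, 4, 6, 100))
  fit <- fit_load_regression(loads)
  orc <- oracle_ols(loads$load_control, loads$load_case)
  expect_equal(fit$slope, orc$slope)
  expect_equal(unname(fit$residuals), orc$residuals, tolerance = 1e-9)
  expect_equal(unname(fit$residuals), c(18.4, 0, -18.4, -36.8, 36.8))
  calls <- call_outliers(fit)
  expect_setequal(calls$outliers_case, oracle_outliers(loads)$case)
  expect_length(calls$outliers_case, 0)

  # residuals sum to zero and the fit is order-invariant
  expect_lt(abs(sum(fit$residuals)), 1e-9 * nrow(loads))
  perm <- fit_load_regression(loads[c(3, 1, 5, 2, 4), , drop = FALSE])
  expect_equal(perm$upper_threshold, fit$upper_threshold)
  expect_equal(sort(names(perm$residuals)), sort(names(fit$residuals)))
})

test_that("an extreme case load stands out against a wide linear background", {
  loads <- data.frame(
    gene = c(paste0("G", 1:30), "SPIKE"),
    load_control = c(1:30, 15),
    load_case = c(2 * (1:30) + rep(c(0, 1, -1), 10), 90))
  calls <- call_outliers(fit_load_regression(loads))
  expect_equal(calls$outliers_case, "SPIKE")
  expect_length(calls$outliers_control, 0)
  expect_setequal(calls$outliers_case, oracle_outliers(loads)$case)
})

test_that("the 6D rule on a frozen residual vector matches hand computation", {
  res <- c(-1, -0.5, 0, 0, 0, 0.5, 1, 100)
  fit <- fit_from_residuals(res)
  expect_equal(fit$q1, -0.125)
  expect_equal(fit$q3, 0.625)
  expect_equal(fit$d, 0.75)
  expect_equal(fit$lower_threshold, -4.625)
  expect_equal(fit$upper_threshold, 5.125)
  calls <- call_outliers(fit)
  expect_equal(calls$outliers_case, "G8")
  expect_length(calls$outliers_control, 0)

  # genes exactly at a threshold are not outliers (strict comparison)
  at <- fit_from_residuals(c(res[-8], 5.125))
  expect_length(call_outliers(at)$outliers_case, 0)
})

test_that("negating residuals swaps the outlier directions", {
  set.seed(31)
  for (i in 1:20) {
    res <- rnorm(sample(8:40, 1))
    res[length(res)] <- res[length(res)] + 50
    f1 <- fit_from_residuals(res)
    f2 <- fit_from_residuals(-res)
    c1 <- call_outliers(f1)
    c2 <- call_outliers(f2)
    expect_setequal(c1$outliers_case, c2$outliers_control)
    expect_setequal(c1$outliers_control, c2$outliers_case)
  }
})

test_that("outlier calls match the brute-force oracle on random tables", {
  set.seed(41)
  for (i in 1:100) {
    loads <- random_load_table(sample(3:50, 1))
    if (length(unique(loads$load_control)) < 2) next
    calls <- call_outliers(fit_load_regression(loads))
    orc <- oracle_outliers(loads)
    expect_setequal(calls$outliers_case, orc$case)
    expect_setequal(calls$outliers_control, orc$control)
  }
})

test_that("one injected extreme gene changes the case list by at most itself", {
  set.seed(51)
  for (i in 1:20) {
    loads <- random_load_table(40)
    fit <- fit_load_regression(loads)
    if (fit$d <= 0) next
    before <- call_outliers(fit)$outliers_case
    spiked <- rbind(loads, data.frame(
      gene = "SPIKE", load_control = median(loads$load_control),
      load_case = 10L * max(loads$load_case)))
    after <- call_outliers(fit_load_regression(spiked))$outliers_case
    expect_lte(length(setdiff(after, c(before, "SPIKE"))) +
               length(setdiff(before, after)), 1)
    expect_true("SPIKE" %in% after)
  }
})

test_that("the annotated outlier table carries residuals and flags", {
  loads <- data.frame(gene = paste0("G", 1:5), load_control = 0:4,
                      load_case = c(0, 2, 4, 6, 100))
  tab <- outlier_table(call_outliers(fit_load_regression(loads)))
  expect_false(any(tab$is_outlier_case))
  expect_false(any(tab$is_outlier_control))
  expect_equal(tab$residual,
               oracle_ols(loads$load_control, loads$load_case)$residuals,
               tolerance = 1e-9)
})
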