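test_that("invalid configurations are rejected with the violated constraints", {
  expect_error(simulation_config(n_genes = 10, n_signal_genes = 8,
                                 n_variable_genes = 5), "exceeds n_genes")
  expect_error(simulation_config(signal_multiplier = 0.5), ">= 1")
  expect_error(simulation_config(misclassification_rate = 1.5), "\\[0, 1\\]")
  err <- tryCatch(simulation_config(signal_multiplier = 0,
                                    misclassification_rate = -1),
                  error = conditionMessage)
  expect_match(err, "signal_multiplier")
  expect_match(err, "misclassification_rate")
})

test_that("cohort simulation is deterministic and flips exactly round(m * n_cases)", {
  cfg <- simulation_config(seed = 9, n_genes = 100, n_controls = 200,
                           n_cases = 150, misclassification_rate = 0.3,
                           n_signal_genes = 10, n_variable_genes = 10)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  expect_equal(a$truth$n_flipped, 45)
  flips <- sum(a$truth$true_phenotype != a$truth$observed_phenotype)
  expect_equal(flips, 45)
  # flips are one-directional: impaired observed as normal
  flipped <- names(a$truth$true_phenotype)[
    a$truth$true_phenotype != a$truth$observed_phenotype]
  expect_true(all(a$truth$true_phenotype[flipped] == "impaired"))
  expect_true(all(a$truth$observed_phenotype[flipped] == "normal"))
  # observed control group = true controls + flipped cases, exactly
  expect_equal(sum(a$truth$observed_phenotype == "normal"), 200 + 45)
  expect_equal(nrow(a$cohort$participants), 350)
})

test_that("misclassification extremes behave as identity and total flip", {
  cfg0 <- simulation_config(seed = 2, n_genes = 50, n_controls = 50,
                            n_cases = 100, misclassification_rate = 0,
                            n_signal_genes = 5, n_variable_genes = 5)
  s0 <- simulate_cohort(cfg0)
  expect_identical(s0$truth$true_phenotype, s0$truth$observed_phenotype)

  cfg1 <- simulation_config(seed = 2, n_genes = 50, n_controls = 50,
                            n_cases = 100, misclassification_rate = 1,
                            n_signal_genes = 5, n_variable_genes = 5)
  s1 <- simulate_cohort(cfg1)
  expect_equal(sum(s1$truth$observed_phenotype == "normal"), 150)
})

test_that("null gene loads concentrate around the baseline rate", {
  cfg <- simulation_config(seed = 17, n_genes = 1000, baseline_rate = 5,
                           n_signal_genes = 0, n_variable_genes = 0,
                           decoy_fraction = 0)
  sim <- simulate_cohort(cfg)
  v <- simulate_variants(cfg, sim$truth)
  loads <- compute_gene_loads(v)
  expect_gt(mean(loads$load_control), 5 * 0.9)
  expect_lt(mean(loads$load_control), 5 * 1.1)
  expect_gt(mean(loads$load_case), 5 * 0.9)
  expect_lt(mean(loads$load_case), 5 * 1.1)
})

test_that("planted signal genes carry the configured case excess", {
  cfg <- simulation_config(seed = 23, n_genes = 300, baseline_rate = 10,
                           n_signal_genes = 30, signal_multiplier = 3,
                           n_variable_genes = 0, decoy_fraction = 0)
  sim <- simulate_cohort(cfg)
  v <- simulate_variants(cfg, sim$truth)
  loads <- compute_gene_loads(v)
  sig <- loads$gene %in% sim$truth$signal_genes
  ratio <- mean(loads$load_case[sig]) / mean(loads$load_control[sig])
  expect_gt(ratio, 3 * 0.8)
  expect_lt(ratio, 3 * 1.2)
  null_ratio <- mean(loads$load_case[!sig]) / mean(loads$load_control[!sig])
  expect_gt(null_ratio, 0.9)
  expect_lt(null_ratio, 1.1)
})

test_that("decoy variants make up the configured share and fail the filter", {
  cfg <- simulation_config(seed = 29, n_genes = 100, baseline_rate = 4,
                           n_signal_genes = 5, n_variable_genes = 5,
                           decoy_fraction = 0.2)
  sim <- simulate_cohort(cfg)
  v <- simulate_variants(cfg, sim$truth)
  res <- apply_filters(v, filter_policy())
  frac_rejected <- nrow(res$rejections) / nrow(v)
  expect_gt(frac_rejected, 0.15)
  expect_lt(frac_rejected, 0.25)
  # the rejected variants are exactly the appended decoy block: every
  # non-decoy variant passes the default policy and vice versa
  pos <- as.integer(sub("chr1:(\\d+):A:G", "\\1", res$rejections$variant_id))
  expect_true(all(pos > nrow(v) - nrow(res$rejections)))
})

test_that("truth-derived gene sets are disjoint and round-trip via GMT", {
  cfg <- simulation_config(seed = 3, n_genes = 200, n_signal_genes = 20,
                           n_variable_genes = 30)
  sim <- simulate_cohort(cfg)
  sets <- make_gene_sets(sim$truth)
  expect_length(sets$deafness, 20)
  expect_length(sets$variable, 30)
  expect_length(intersect(sets$deafness, sets$variable), 0)

  path <- tempfile(fileext = ".gmt")
  write_gene_sets(sets, path)
  expect_equal(load_gene_sets(path), sets)

  no_signal <- sim$truth
  no_signal$signal_genes <- character(0)
  expect_error(make_gene_sets(no_signal), "no signal genes")
})

test_that("a written simulation directory is complete and loadable", {
  cfg <- simulation_config(seed = 4, n_genes = 60, n_controls = 80,
                           n_cases = 80, baseline_rate = 5,
                           n_signal_genes = 5, n_variable_genes = 5)
  dir <- tempfile()
  write_simulation(cfg, dir)
  expect_setequal(list.files(dir), c("cohort.tsv", "variants.tsv",
                                     "gene_sets.gmt", "truth.json"))
  ch <- load_cohort_table(file.path(dir, "cohort.tsv"))
  expect_equal(nrow(ch$participants), 160)
  sets <- load_gene_sets(file.path(dir, "gene_sets.gmt"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(sets$deafness, truth$signal_genes)
})

test_that("flat key-value config files parse into configurations", {
  path <- tempfile()
  writeLines(c("# comment", "seed = 7", "n_genes = 500",
               "baseline_rate: 12", "misclassification_rate = 0.25"),
             path)
  cfg <- read_simulation_config(path)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$n_genes, 500)
  expect_equal(cfg$baseline_rate, 12)
  expect_equal(cfg$misclassification_rate, 0.25)

  writeLines("bogus_key = 1", path)
  expect_error(read_simulation_config(path), "unknown config key")
})
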