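#' Configuration of the synthetic cohort and variant generator
#'
#' The generator emulates the statistical structure the load analysis
#' assumes: two phenotype groups; per-gene counts of distinct qualifying
#' variants drawn from a negative binomial (mean `baseline_rate`,
#' overdispersion `dispersion`, Poisson as `dispersion` approaches 0); a
#' planted set of signal genes whose case-group mean is multiplied by
#' `signal_multiplier`; a planted set of variable genes inflated in both
#' groups by `variable_multiplier`; and one-directional phenotype
#' misclassification in which a fraction `misclassification_rate` of true
#' cases carries the observed label "normal" — the mechanism by which
#' undiagnosed mild disease contaminates a diagnosis-based control group.
#'
#' Defaults describe a biobank-scale study: per-gene qualifying-variant
#' loads in the tens, mild overdispersion, a 4-fold case excess in 20
#' signal genes among 2,000, and a 2-fold both-group excess in 100
#' variable genes.
#'
#' @param seed Integer seed; all generator output is a pure function of
#'   the configuration including the seed.
#' @param n_genes Number of genes.
#' @param n_controls,n_cases True group sizes.
#' @param baseline_rate Expected qualifying variants per gene per group
#'   under the null.
#' @param dispersion Negative-binomial overdispersion `alpha` (variance
#'   `mu + alpha * mu^2`); 0 gives Poisson counts.
#' @param n_signal_genes,signal_multiplier Planted case-excess genes and
#'   their case-group mean multiplier (>= 1).
#' @param n_variable_genes,variable_multiplier Planted both-group-inflated
#'   genes and their multiplier (>= 1).
#' @param misclassification_rate Fraction in \[0, 1\] of true cases whose
#'   observed label is "normal".
#' @param decoy_fraction Fraction of the variant table made of decoy
#'   variants that fail the default filter policy (for filter testing).
#' @param carrier_rate Carrier counts per present variant are
#'   `1 + Poisson(carrier_rate)`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_genes = 2000,
                              n_controls = 1000,
                              n_cases = 1000,
                              baseline_rate = 40,
                              dispersion = 0.02,
                              n_signal_genes = 20,
                              signal_multiplier = 4,
                              n_variable_genes = 100,
                              variable_multiplier = 2,
                              misclassification_rate = 0,
                              decoy_fraction = 0.1,
                              carrier_rate = 0.5) {
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              n_controls = n_controls, n_cases = n_cases,
              baseline_rate = baseline_rate, dispersion = dispersion,
              n_signal_genes = n_signal_genes,
              signal_multiplier = signal_multiplier,
              n_variable_genes = n_variable_genes,
              variable_multiplier = variable_multiplier,
              misclassification_rate = misclassification_rate,
              decoy_fraction = decoy_fraction,
              carrier_rate = carrier_rate)
  problems <- character(0)
  if (cfg$n_signal_genes + cfg$n_variable_genes > cfg$n_genes) {
    problems <- c(problems,
                  "n_signal_genes + n_variable_genes exceeds n_genes")
  }
  if (cfg$signal_multiplier < 1) {
    problems <- c(problems, "signal_multiplier must be >= 1")
  }
  if (cfg$variable_multiplier < 1) {
    problems <- c(problems, "variable_multiplier must be >= 1")
  }
  if (cfg$misclassification_rate < 0 || cfg$misclassification_rate > 1) {
    problems <- c(problems, "misclassification_rate must be in [0, 1]")
  }
  if (cfg$baseline_rate <= 0) {
    problems <- c(problems, "baseline_rate must be positive")
  }
  if (cfg$dispersion < 0) {
    problems <- c(problems, "dispersion must be >= 0")
  }
  if (cfg$decoy_fraction < 0 || cfg$decoy_fraction >= 1) {
    problems <- c(problems, "decoy_fraction must be in [0, 1)")
  }
  if (cfg$n_controls < 1 || cfg$n_cases < 1) {
    problems <- c(problems, "group sizes must be >= 1")
  }
  if (length(problems) > 0) {
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d genes (%d signal x%g, %d variable x%g)\n",
    x$n_genes, x$n_signal_genes, x$signal_multiplier,
    x$n_variable_genes, x$variable_multiplier))
  cat(sprintf(
    "  %d controls / %d cases; baseline %g, dispersion %g, m = %g, seed %d\n",
    x$n_controls, x$n_cases, x$baseline_rate, x$dispersion,
    x$misclassification_rate, x$seed))
  invisible(x)
}

# NB draw that degrades gracefully to Poisson at dispersion 0.
rcount <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate a two-group cohort with phenotype misclassification
#'
#' Generates `n_controls + n_cases` participants. True controls are
#' observed as "normal". Exactly `round(m * n_cases)` true cases, chosen
#' at random, are observed as "normal" (misclassified); the rest as
#' "impaired". Ages, sexes and ancestries are drawn to satisfy the
#' inclusion rules.
#'
#' @param config A `simulation_config`.
#' @return List with `cohort` (a `cohort_design` built on observed
#'   labels) and `truth` (list: `signal_genes`, `variable_genes`,
#'   `true_phenotype`, `observed_phenotype`, both named by participant;
#'   `n_flipped`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- spawn_seeds(config$seed, 2)
  set.seed(seeds[1])
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  signal <- sort(sample(genes, config$n_signal_genes))
  variable <- sort(sample(setdiff(genes, signal), config$n_variable_genes))

  n <- config$n_controls + config$n_cases
  ids <- sprintf("P%06d", seq_len(n))
  true_pheno <- c(rep("normal", config$n_controls),
                  rep("impaired", config$n_cases))
  names(true_pheno) <- ids
  n_flip <- round(config$misclassification_rate * config$n_cases)
  case_ids <- ids[true_pheno == "impaired"]
  flipped <- if (n_flip > 0) sample(case_ids, n_flip) else character(0)
  observed <- true_pheno
  observed[flipped] <- "normal"

  sex <- sample(c("Male", "Female"), n, replace = TRUE)
  participants <- data.frame(
    participant_id = ids,
    phenotype_label = unname(observed),
    age_years = sample(56:90, n, replace = TRUE),
    sex_at_birth = sex,
    gender = sex,
    ancestry = sample(c("European", "African/African American",
                        "East Asian", "South Asian"), n, replace = TRUE,
                      prob = c(0.6, 0.2, 0.1, 0.1)),
    exclusion_flags = "",
    stringsAsFactors = FALSE
  )
  cohort <- cohort_design(participants, name = "synthetic",
                          phenotyping_mode = "diagnostic",
                          maf_mode = "max_population")
  list(cohort = cohort,
       truth = list(signal_genes = signal,
                    variable_genes = variable,
                    true_phenotype = true_pheno,
                    observed_phenotype = observed,
                    n_flipped = n_flip))
}

# Annotation fields for n variants that pass the default filter policy:
# rare in every population and qualifying by exactly one impact route
# (pathogenicity, splice, or 5'UTR), mixed so all branches are exercised.
qualifying_annotations <- function(n) {
  route <- sample(c("cadd", "splice", "utr5"), n, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1))
  data.frame(
    AF_nfe = stats::runif(n, 0, 0.08),
    AF_afr = stats::runif(n, 0, 0.08),
    AF_eas = stats::runif(n, 0, 0.08),
    cadd = ifelse(route == "cadd", stats::runif(n, 20, 45),
                  stats::runif(n, 0, 15)),
    spliceai = ifelse(route == "splice", stats::runif(n, 0.5, 1),
                      stats::runif(n, 0, 0.4)),
    utr5_flag = route == "utr5",
    stringsAsFactors = FALSE
  )
}

# Decoy annotations: half common (max-population AF in (0.10, 0.5)) with
# qualifying scores, half rare but with every impact criterion below
# threshold, so both filter branches reject something.
decoy_annotations <- function(n) {
  common <- seq_len(n) <= ceiling(n / 2)
  data.frame(
    AF_nfe = ifelse(common, stats::runif(n, 0.10, 0.5),
                    stats::runif(n, 0, 0.08)),
    AF_afr = stats::runif(n, 0, 0.08),
    AF_eas = stats::runif(n, 0, 0.08),
    cadd = ifelse(common, stats::runif(n, 20, 45),
                  stats::runif(n, 0, 15)),
    spliceai = ifelse(common, stats::runif(n, 0.5, 1),
                      stats::runif(n, 0, 0.4)),
    utr5_flag = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Simulate an annotated variant table consistent with a cohort truth
#'
#' For each gene and TRUE phenotype group, the number of distinct
#' qualifying variants is drawn from the configured count distribution
#' with mean `baseline_rate` times the gene/group multiplier. Each variant
#' receives `1 + Poisson(carrier_rate)` carriers drawn from its true
#' group; carrier counts per OBSERVED group then follow from the
#' misclassified participants, so case-group variants carried by a
#' mislabelled participant become visible in the observed control group.
#' A further `decoy_fraction` of the table consists of variants that fail
#' the default filter policy.
#'
#' @param config A `simulation_config`.
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @return data.frame in the annotated-variant schema: `variant_id`,
#'   `gene`, `AF_nfe`, `AF_afr`, `AF_eas`, `cadd`, `spliceai`,
#'   `utr5_flag`, `carriers_normal`, `carriers_impaired`.
#' @export
simulate_variants <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- spawn_seeds(config$seed, 2)
  set.seed(seeds[2])
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  mult_ctl <- rep(1, config$n_genes)
  mult_case <- rep(1, config$n_genes)
  is_signal <- genes %in% truth$signal_genes
  is_variable <- genes %in% truth$variable_genes
  mult_case[is_signal] <- config$signal_multiplier
  mult_ctl[is_variable] <- config$variable_multiplier
  mult_case[is_variable] <- config$variable_multiplier

  n_ctl_v <- rcount(config$n_genes, config$baseline_rate * mult_ctl,
                    config$dispersion)
  n_case_v <- rcount(config$n_genes, config$baseline_rate * mult_case,
                     config$dispersion)

  gene_col <- c(rep(genes, n_ctl_v), rep(genes, n_case_v))
  origin <- c(rep("control", sum(n_ctl_v)), rep("case", sum(n_case_v)))
  n_real <- length(gene_col)

  n_decoy <- if (config$decoy_fraction > 0) {
    round(config$decoy_fraction / (1 - config$decoy_fraction) * n_real)
  } else 0
  if (n_decoy > 0) {
    gene_col <- c(gene_col, sample(genes, n_decoy, replace = TRUE))
    origin <- c(origin, sample(c("control", "case"), n_decoy,
                               replace = TRUE))
  }
  n_total <- length(gene_col)

  carriers <- 1 + stats::rpois(n_total, config$carrier_rate)
  flipped_among <- integer(n_total)
  is_case_origin <- origin == "case"
  n_flip <- truth$n_flipped
  if (any(is_case_origin)) {
    # flipped carriers among c draws from the true case group: the flipped
    # participants are a fixed subset of size n_flip out of n_cases
    flipped_among[is_case_origin] <- stats::rhyper(
      sum(is_case_origin), n_flip, config$n_cases - n_flip,
      pmin(carriers[is_case_origin], config$n_cases))
  }
  carriers_normal <- ifelse(is_case_origin, flipped_among, carriers)
  carriers_impaired <- ifelse(is_case_origin, carriers - flipped_among, 0L)

  ann <- rbind(qualifying_annotations(n_real),
               if (n_decoy > 0) decoy_annotations(n_decoy))
  pos <- seq_len(n_total)
  out <- data.frame(
    variant_id = sprintf("chr1:%d:A:G", pos),
    gene = gene_col,
    ann,
    carriers_normal = as.integer(carriers_normal),
    carriers_impaired = as.integer(carriers_impaired),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Gene sets derived from the planted truth
#'
#' Returns the two comparison sets the enrichment stage expects: the
#' planted signal genes as the "deafness" set and the planted
#' both-group-inflated genes as the "variable" set. Disjoint by
#' construction.
#'
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @return Named list of two character vectors: `deafness`, `variable`.
#' @export
make_gene_sets <- function(truth) {
  if (length(truth$signal_genes) == 0) {
    stop("truth has no signal genes", call. = FALSE)
  }
  list(deafness = toupper(truth$signal_genes),
       variable = toupper(truth$variable_genes))
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits `cohort.tsv`, `variants.tsv`, `gene_sets.gmt` and `truth.json`.
#'
#' @param config A `simulation_config`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  variants <- simulate_variants(config, sim$truth)
  write_tsv(sim$cohort$participants, file.path(dir, "cohort.tsv"))
  write_tsv(variants, file.path(dir, "variants.tsv"))
  write_gene_sets(make_gene_sets(sim$truth),
                  file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(
    list(config = unclass(config),
         signal_genes = sim$truth$signal_genes,
         variable_genes = sim$truth$variable_genes,
         n_flipped = sim$truth$n_flipped,
         flipped_ids = names(sim$truth$true_phenotype)[
           sim$truth$true_phenotype != sim$truth$observed_phenotype]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a flat key-value simulation config file
#'
#' One `key = value` (or `key: value`) pair per line, keys matching the
#' [simulation_config()] argument names; `#` starts a comment.
#'
#' @param path File path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("[=:]", lines)])
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  args <- stats::setNames(
    lapply(kv, function(x) as.numeric(x[2])),
    vapply(kv, `[`, character(1), 1))
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(simulation_config, args)
}
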