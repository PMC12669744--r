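#' Run one end-to-end case-control comparison
#'
#' Chains the full pipeline on a cohort and variant table: optional
#' stratum restriction (sex and/or ancestry), variant filtering to the
#' qualifying set, per-gene load computation, the load regression with
#' quartile-distance outlier calling, and hypergeometric enrichment of
#' both directional outlier lists against the supplied gene sets with
#' multiple-testing adjustment across all tests of the run. The universe
#' for enrichment is the set of genes in the load table. Strata in which
#' either phenotype group is below `min_stratum_size` yield a structured
#' skipped record instead of an analysis.
#'
#' @param cohort A `cohort_design` (observed phenotype labels).
#' @param variants Annotated variant data.frame (pre-filter schema).
#' @param sets Named list of gene sets.
#' @param control,case Observed group labels (default `"normal"`,
#'   `"impaired"`).
#' @param policy A `filter_policy`.
#' @param adjust `"bh"` or `"bonferroni"`.
#' @param stratum Optional named list with elements from `sex` (value
#'   `"Male"`/`"Female"`) and `ancestry`; `NULL` analyses all
#'   participants.
#' @param min_stratum_size Minimum participants per phenotype group.
#' @param label Comparison label used in reports.
#' @return An object of class `comparison_result`. If skipped: list with
#'   `skipped = TRUE`, `label`, `reason`. Otherwise `skipped = FALSE`
#'   plus `calls` (an `outlier_calls`), `enrichment` (adjusted
#'   data.frame), `loads`, `filter_rejections`, and a `manifest` list
#'   recording every configuration value.
#' @export
run_comparison <- function(cohort, variants, sets,
                           control = "normal", case = "impaired",
                           policy = filter_policy(), adjust = "bh",
                           stratum = NULL, min_stratum_size = 50,
                           label = "all") {
  stopifnot(inherits(cohort, "cohort_design"))
  if (control == case) stop("control and case labels must differ",
                            call. = FALSE)
  p <- cohort$participants
  if (!is.null(stratum)) {
    if (!is.null(stratum$sex)) {
      p <- p[!is.na(p$sex_at_birth) & p$sex_at_birth == stratum$sex, ,
             drop = FALSE]
    }
    if (!is.null(stratum$ancestry)) {
      p <- p[!is.na(p$ancestry) & p$ancestry == stratum$ancestry, ,
             drop = FALSE]
    }
  }
  group_n <- c(sum(p$phenotype_label == control),
               sum(p$phenotype_label == case))
  if (any(group_n < min_stratum_size)) {
    return(structure(list(skipped = TRUE, label = label,
                          reason = "insufficient participants",
                          group_sizes = group_n),
                     class = "comparison_result"))
  }

  filt <- apply_filters(variants, policy)
  loads <- compute_gene_loads(filt$qualifying, control = control,
                              case = case)
  fit <- fit_load_regression(loads)
  calls <- call_outliers(fit)
  universe <- loads$gene
  enr <- rbind(
    enrich(calls$outliers_case, sets, universe, list_name = "case"),
    enrich(calls$outliers_control, sets, universe, list_name = "control")
  )
  enr <- adjust_pvalues(enr, method = adjust)
  manifest <- list(
    label = label, control = control, case = case,
    stratum = stratum, min_stratum_size = min_stratum_size,
    policy = unclass(policy), adjust = adjust,
    n_participants = nrow(p),
    n_variants_in = nrow(variants),
    n_variants_qualifying = nrow(filt$qualifying),
    n_genes = nrow(loads),
    package_version = as.character(utils::packageVersion("phenoload"))
  )
  structure(list(skipped = FALSE, label = label, calls = calls,
                 enrichment = enr, loads = loads,
                 filter_rejections = filt$rejections,
                 manifest = manifest),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("<comparison_result> %s: skipped (%s)\n", x$label,
                x$reason))
  } else {
    cat(sprintf(
      "<comparison_result> %s: %d case / %d control outliers over %d genes\n",
      x$label, length(x$calls$outliers_case),
      length(x$calls$outliers_control), x$manifest$n_genes))
  }
  invisible(x)
}

# Signal-gene sensitivity of a comparison: recovered fraction of the
# planted case-excess genes among the case-direction outliers.
signal_sensitivity <- function(result, signal_genes) {
  if (result$skipped) return(NA_real_)
  length(intersect(result$calls$outliers_case, signal_genes)) /
    length(signal_genes)
}

#' Sweep the misclassification rate and measure signal degradation
#'
#' For each misclassification level `m` and replicate, generates a fresh
#' synthetic dataset (per-replicate seeds spawned from `config$seed` by a
#' fixed counter scheme), runs the full pipeline, and records outlier
#' counts, signal-gene sensitivity, and the raw and adjusted enrichment
#' p-values for the planted "deafness" (signal) and "variable" sets. The
#' summary reports per-`m` means and the Spearman correlation of mean
#' sensitivity with `m` as the monotone-trend statistic.
#'
#' @param config A `simulation_config`; its `misclassification_rate` is
#'   overridden by the grid.
#' @param m_values Misclassification grid. The default extends to 0.7,
#'   an illustrative heavy-contamination scenario in which a ~48%
#'   prevalence condition appears as only a ~15% diagnosed group.
#' @param replicates Replicates per grid point (default 20).
#' @param policy Filter policy for the pipeline runs.
#' @return An object of class `sweep_result`: list with `results` (one
#'   row per run: `m`, `replicate`, `seed`, `n_outliers_case`,
#'   `n_outliers_control`, `sensitivity`, `deafness_p`, `deafness_adj_p`,
#'   `variable_p`, `variable_adj_p`), `summary` (per-`m` means, including
#'   `mean_neglog10_deafness_adj_p`), and `spearman_rho`.
#' @export
sweep_misclassification <- function(config,
                                    m_values = c(0, 0.1, 0.2, 0.3, 0.4,
                                                 0.5, 0.7),
                                    replicates = 20,
                                    policy = filter_policy()) {
  stopifnot(inherits(config, "simulation_config"),
            all(m_values >= 0 & m_values <= 1), replicates >= 1)
  grid <- expand.grid(replicate = seq_len(replicates), m = m_values,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- spawn_seeds(config$seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$misclassification_rate <- grid$m[i]
    cfg$seed <- seeds[i]
    sim <- simulate_cohort(cfg)
    variants <- simulate_variants(cfg, sim$truth)
    sets <- make_gene_sets(sim$truth)
    res <- run_comparison(sim$cohort, variants, sets, policy = policy,
                          min_stratum_size = 1,
                          label = sprintf("m=%g rep=%d", grid$m[i],
                                          grid$replicate[i]))
    enr <- res$enrichment
    pick <- function(set, col) {
      enr[enr$list_name == "case" & enr$set_name == set, col]
    }
    data.frame(
      m = grid$m[i], replicate = grid$replicate[i], seed = seeds[i],
      n_outliers_case = length(res$calls$outliers_case),
      n_outliers_control = length(res$calls$outliers_control),
      sensitivity = signal_sensitivity(res, sim$truth$signal_genes),
      deafness_p = pick("deafness", "p_value"),
      deafness_adj_p = pick("deafness", "adjusted_p"),
      variable_p = pick("variable", "p_value"),
      variable_adj_p = pick("variable", "adjusted_p"),
      stringsAsFactors = FALSE
    )
  })
  results <- do.call(rbind, rows)
  # adjusted p of 0 would make -log10 infinite; the tail probability is
  # never exactly 0, but clamp against double underflow
  nl10 <- -log10(pmax(results$deafness_adj_p, 1e-300))
  summary <- do.call(rbind, lapply(split(seq_len(nrow(results)),
                                         results$m), function(idx) {
    data.frame(
      m = results$m[idx[1]],
      mean_sensitivity = mean(results$sensitivity[idx]),
      mean_n_outliers_case = mean(results$n_outliers_case[idx]),
      mean_n_outliers_control = mean(results$n_outliers_control[idx]),
      mean_neglog10_deafness_adj_p = mean(nl10[idx]),
      prop_deafness_significant =
        mean(results$deafness_adj_p[idx] < 0.05),
      stringsAsFactors = FALSE
    )
  }))
  summary <- summary[order(summary$m), , drop = FALSE]
  rownames(summary) <- NULL
  rho <- if (nrow(summary) > 1 &&
             stats::sd(summary$mean_sensitivity) > 0) {
    stats::cor(summary$m, summary$mean_sensitivity, method = "spearman")
  } else NA_real_
  structure(list(results = results, summary = summary,
                 spearman_rho = rho, config = config,
                 replicates = replicates),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d m-levels x %d replicates (rho = %s)\n",
              nrow(x$summary), x$replicates,
              format(x$spearman_rho, digits = 3)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Significance markers for one outlier direction of a comparison:
# dagger for the deafness set, asterisk for the variable set.
direction_cell <- function(result, direction) {
  if (result$skipped) return("-")
  n <- length(result$calls[[paste0("outliers_", direction)]])
  enr <- result$enrichment
  list_label <- if (direction == "case") "case" else "control"
  sig <- function(set) {
    rows <- enr$list_name == list_label & enr$set_name == set
    any(rows) && isTRUE(any(enr$significant[rows]))
  }
  paste0(n, if (sig("deafness")) "†" else "",
         if (sig("variable")) "*" else "")
}

#' Render a comparison matrix report
#'
#' Produces a Markdown table (one row per comparison, case- and
#' control-direction outlier counts with significance markers: a dagger
#' for deafness-set enrichment, an asterisk for variable-set enrichment,
#' both at adjusted p < 0.05; skipped strata rendered as "-") and a
#' machine-readable JSON structure.
#'
#' @param results List of `comparison_result` objects (named or
#'   labelled).
#' @param path Optional output path prefix; writes `<path>.md` and
#'   `<path>.json`.
#' @return List with `markdown` (character vector of lines) and `json`
#'   (the structure serialised to JSON), invisibly if `path` given.
#' @export
render_report <- function(results, path = NULL) {
  if (length(results) == 0) stop("no results to report", call. = FALSE)
  if (inherits(results, "comparison_result")) results <- list(results)
  lines <- c(
    "| Comparison | Outliers (case group) | Outliers (control group) |",
    "|---|---|---|")
  entries <- lapply(results, function(r) {
    lines <<- c(lines, sprintf("| %s | %s | %s |", r$label,
                               direction_cell(r, "case"),
                               direction_cell(r, "control")))
    if (r$skipped) {
      list(label = r$label, skipped = TRUE, reason = r$reason)
    } else {
      list(label = r$label, skipped = FALSE,
           outliers_case = r$calls$outliers_case,
           outliers_control = r$calls$outliers_control,
           enrichment = r$enrichment,
           manifest = r$manifest)
    }
  })
  lines <- c(lines, "",
             paste0("† significantly enriched in deafness genes ",
                    "(adj. p < 0.05); * significantly enriched in ",
                    "variable genes (adj. p < 0.05); - insufficient ",
                    "participants."))
  out <- list(markdown = lines, json = entries)
  if (!is.null(path)) {
    writeLines(lines, paste0(path, ".md"))
    jsonlite::write_json(entries, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(out))
  }
  out
}
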