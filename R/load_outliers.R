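#' Per-gene qualifying-variant loads in two phenotype groups
#'
#' The load of a gene in a group is the number of distinct qualifying
#' variants of that gene observed in (i.e. with at least one carrier in)
#' that group. A variant present in both groups counts once in each
#' column; a variant mapped to several genes contributes to each. Genes
#' with zero load in both groups do not appear.
#'
#' @param variants data.frame of qualifying variants with columns
#'   `variant_id`, `gene` and carrier-count columns `carriers_<group>`.
#' @param control Label of the control group (default `"normal"`).
#' @param case Label of the case group (default `"impaired"`).
#' @return data.frame with columns `gene`, `load_control`, `load_case`,
#'   one row per gene, ordered by gene symbol.
#' @export
compute_gene_loads <- function(variants, control = "normal",
                               case = "impaired") {
  check_columns(variants, c("variant_id", "gene"), "variant table")
  ctl_col <- paste0("carriers_", control)
  case_col <- paste0("carriers_", case)
  for (col in c(ctl_col, case_col)) {
    if (!col %in% names(variants)) {
      stop("unknown group label: no column ", col, call. = FALSE)
    }
  }
  if (nrow(variants) == 0) {
    return(data.frame(gene = character(0), load_control = integer(0),
                      load_case = integer(0), stringsAsFactors = FALSE))
  }
  in_ctl <- !is.na(variants[[ctl_col]]) & variants[[ctl_col]] >= 1
  in_case <- !is.na(variants[[case_col]]) & variants[[case_col]] >= 1
  gene <- factor(variants$gene)
  load_control <- tapply(in_ctl, gene, sum)
  load_case <- tapply(in_case, gene, sum)
  out <- data.frame(gene = levels(gene),
                    load_control = as.integer(load_control),
                    load_case = as.integer(load_case),
                    stringsAsFactors = FALSE)
  out <- out[out$load_control + out$load_case > 0, , drop = FALSE]
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' First and third quartiles by linear interpolation
#'
#' Quartile at fractional order-statistic position `p * (n - 1)` with
#' linear interpolation between adjacent order statistics (the convention
#' of [stats::quantile()] type 7, R's default).
#'
#' @param values Numeric vector of at least 2 values.
#' @return Named numeric vector `c(q1 = ..., q3 = ...)`.
#' @export
quartiles <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop("quartiles require at least 2 values", call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(0.25, 0.75), type = 7,
                       names = FALSE)
  c(q1 = q[1], q3 = q[2])
}

#' Fit the case-on-control load regression
#'
#' Ordinary least-squares regression (with intercept) of the case-group
#' load on the control-group load predicts, for each gene, how many
#' qualifying variants would be expected in the case group given the
#' number present in controls. Residual quartiles Q1 and Q3, their
#' distance D = Q3 - Q1, and the outlier thresholds Q1 - 6D and Q3 + 6D
#' are recorded with the fit.
#'
#' @param loads A gene-load data.frame from [compute_gene_loads()] (at
#'   least 3 genes, non-constant control load).
#' @return An object of class `load_fit`: list with `slope`, `intercept`,
#'   `residuals` (named by gene), `q1`, `q3`, `d`, `lower_threshold`,
#'   `upper_threshold`, `n_genes`, and the input `loads`.
#' @export
fit_load_regression <- function(loads) {
  check_columns(loads, c("gene", "load_control", "load_case"),
                "gene-load table")
  if (nrow(loads) < 3) {
    stop("load regression requires at least 3 genes (got ", nrow(loads),
         ")", call. = FALSE)
  }
  if (length(unique(loads$load_control)) < 2) {
    stop("load regression requires non-constant control load",
         call. = FALSE)
  }
  fit <- stats::lm(load_case ~ load_control, data = loads)
  res <- stats::residuals(fit)
  names(res) <- loads$gene
  q <- quartiles(res)
  d <- unname(q["q3"] - q["q1"])
  structure(
    list(slope = unname(stats::coef(fit)["load_control"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         residuals = res,
         q1 = unname(q["q1"]), q3 = unname(q["q3"]), d = d,
         lower_threshold = unname(q["q1"] - 6 * d),
         upper_threshold = unname(q["q3"] + 6 * d),
         n_genes = nrow(loads),
         loads = loads),
    class = "load_fit"
  )
}

#' @export
print.load_fit <- function(x, ...) {
  cat(sprintf("<load_fit> %d genes; case ~ %.4f + %.4f * control\n",
              x$n_genes, x$intercept, x$slope))
  cat(sprintf("  residual Q1 = %.4g, Q3 = %.4g, D = %.4g\n",
              x$q1, x$q3, x$d))
  cat(sprintf("  outlier thresholds: < %.4g or > %.4g\n",
              x$lower_threshold, x$upper_threshold))
  invisible(x)
}

#' Call directional outlier genes from a load regression fit
#'
#' Genes with residuals strictly greater than Q3 + 6D carry excess load in
#' the case group; genes with residuals strictly less than Q1 - 6D carry
#' excess load in the control group (of interest because variants may
#' protect as well as predispose). Genes exactly at a threshold are not
#' outliers; when D = 0 both lists are empty.
#'
#' @param fit A `load_fit` from [fit_load_regression()].
#' @return An object of class `outlier_calls`: list with `outliers_case`,
#'   `outliers_control` (character vectors of gene symbols) and `fit`.
#' @export
call_outliers <- function(fit) {
  stopifnot(inherits(fit, "load_fit"))
  res <- fit$residuals
  structure(
    list(outliers_case = names(res)[res > fit$upper_threshold],
         outliers_control = names(res)[res < fit$lower_threshold],
         fit = fit),
    class = "outlier_calls"
  )
}

#' @export
print.outlier_calls <- function(x, ...) {
  cat(sprintf("<outlier_calls> %d case-group, %d control-group outliers\n",
              length(x$outliers_case), length(x$outliers_control)))
  invisible(x)
}

#' Gene-load table annotated with residuals and outlier flags
#'
#' @param calls An `outlier_calls` object.
#' @return data.frame with columns `gene`, `load_control`, `load_case`,
#'   `residual`, `is_outlier_case`, `is_outlier_control`.
#' @export
outlier_table <- function(calls) {
  stopifnot(inherits(calls, "outlier_calls"))
  loads <- calls$fit$loads
  loads$residual <- unname(calls$fit$residuals[loads$gene])
  loads$is_outlier_case <- loads$gene %in% calls$outliers_case
  loads$is_outlier_control <- loads$gene %in% calls$outliers_control
  loads
}
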