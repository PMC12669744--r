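#' Construct a variant filter policy
#'
#' Qualifying variants are those that are rare (minor allele frequency
#' strictly below `maf_threshold` under the chosen population mode) and of
#' high predicted impact by at least one of three predictor criteria: a
#' phred-scaled pathogenicity score (CADD-style), a splice-impact delta
#' score in \[0, 1\] (SpliceAI-style), or a boolean high-impact 5'UTR flag.
#' The criteria combine by OR. Thresholds default to conventional
#' cut-offs (phred 20, splice delta 0.5) and are fully configurable;
#' conclusions downstream are threshold-parameterised.
#'
#' @param maf_threshold MAF cut-off in (0, 1]; variants qualify with MAF
#'   strictly below it. Default 0.10.
#' @param maf_mode `"nfe"` (use the Non-Finnish European frequency) or
#'   `"max_population"` (use the maximum frequency across all populations
#'   present).
#' @param cadd_min Minimum phred-scaled pathogenicity score. Default 20.
#' @param splice_min Minimum splice-impact delta. Default 0.5.
#' @param use_utr5 Whether the 5'UTR high-impact flag counts as a
#'   qualifying criterion. Default TRUE.
#' @param missing_score_rule How a missing predictor score is resolved for
#'   its own criterion: `"fail_criterion"` (default) or `"pass_criterion"`.
#' @param missing_nfe_rule In `nfe` mode, how a missing NFE frequency is
#'   treated: `"zero"` (default; absence from the reference panel is read
#'   as rarity, with a warning) or `"exclude"` (variant is rejected).
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(maf_threshold = 0.10,
                          maf_mode = c("max_population", "nfe"),
                          cadd_min = 20,
                          splice_min = 0.5,
                          use_utr5 = TRUE,
                          missing_score_rule = c("fail_criterion",
                                                 "pass_criterion"),
                          missing_nfe_rule = c("zero", "exclude")) {
  maf_mode <- match.arg(maf_mode)
  missing_score_rule <- match.arg(missing_score_rule)
  missing_nfe_rule <- match.arg(missing_nfe_rule)
  stopifnot(maf_threshold > 0, maf_threshold <= 1,
            cadd_min >= 0, splice_min >= 0,
            splice_min <= 1 || is.infinite(splice_min))
  if (is.infinite(cadd_min) && is.infinite(splice_min) && !use_utr5) {
    stop("at least one impact criterion must be enabled", call. = FALSE)
  }
  structure(
    list(maf_threshold = maf_threshold, maf_mode = maf_mode,
         cadd_min = cadd_min, splice_min = splice_min,
         use_utr5 = use_utr5,
         missing_score_rule = missing_score_rule,
         missing_nfe_rule = missing_nfe_rule),
    class = "filter_policy"
  )
}

#' @export
print.filter_policy <- function(x, ...) {
  cat(sprintf(
    "<filter_policy> MAF < %g (%s); impact: cadd ≥ %g OR splice ≥ %g%s\n",
    x$maf_threshold, x$maf_mode, x$cadd_min, x$splice_min,
    if (x$use_utr5) " OR utr5 flag" else ""))
  invisible(x)
}

# Population AF columns follow the "AF_<pop>" convention; NFE is "AF_nfe".
af_columns <- function(variants) {
  grep("^AF_", names(variants), value = TRUE)
}

#' Effective minor allele frequency of each variant
#'
#' Under `nfe` mode the Non-Finnish European frequency (column `AF_nfe`)
#' is used; under `max_population` the maximum over all `AF_*` columns
#' present. A missing NFE frequency in `nfe` mode is treated as 0 with a
#' warning by default (configurable to exclusion via the policy).
#'
#' @param variants data.frame of annotated variants with `AF_*` columns.
#' @param mode `"nfe"` or `"max_population"`.
#' @param missing_nfe_rule `"zero"` or `"exclude"`; under `"exclude"` the
#'   returned value is `NA` for variants lacking an NFE frequency, which
#'   [apply_filters()] rejects.
#' @return Numeric vector of allele frequencies in \[0, 1\] (possibly `NA`
#'   under the exclusion rule).
#' @export
effective_maf <- function(variants, mode = c("max_population", "nfe"),
                          missing_nfe_rule = c("zero", "exclude")) {
  mode <- match.arg(mode)
  missing_nfe_rule <- match.arg(missing_nfe_rule)
  cols <- af_columns(variants)
  if (length(cols) == 0) {
    stop("no population allele-frequency (AF_*) columns found", call. = FALSE)
  }
  if (mode == "nfe") {
    if (!"AF_nfe" %in% names(variants)) {
      stop("nfe mode requires an AF_nfe column", call. = FALSE)
    }
    af <- variants$AF_nfe
    if (anyNA(af)) {
      if (missing_nfe_rule == "zero") {
        warning(sum(is.na(af)),
                " variant(s) lack an NFE frequency; treated as 0",
                call. = FALSE)
        af[is.na(af)] <- 0
      }
    }
    af
  } else {
    m <- as.matrix(variants[, cols, drop = FALSE])
    af <- apply(m, 1, function(r) if (all(is.na(r))) NA_real_ else
      max(r, na.rm = TRUE))
    af
  }
}

#' Does each variant pass the impact criteria?
#'
#' A variant passes if any enabled criterion holds: pathogenicity score at
#' or above `cadd_min`, splice score at or above `splice_min`, or a true
#' 5'UTR high-impact flag. A missing score fails (or passes, per policy)
#' only its own criterion.
#'
#' @param variants data.frame with columns `cadd`, `spliceai`,
#'   `utr5_flag` (any may contain `NA`).
#' @param policy A `filter_policy`.
#' @return Logical vector.
#' @export
passes_impact <- function(variants, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  n <- nrow(variants)
  missing_passes <- policy$missing_score_rule == "pass_criterion"
  crit <- function(x, op) {
    if (is.null(x)) x <- rep(NA_real_, n)
    out <- op(x)
    out[is.na(out)] <- missing_passes
    out
  }
  cadd_ok <- crit(variants$cadd, function(x) x >= policy$cadd_min)
  splice_ok <- crit(variants$spliceai, function(x) x >= policy$splice_min)
  utr5 <- variants$utr5_flag
  if (is.null(utr5)) utr5 <- rep(NA, n)
  utr5 <- as.logical(utr5)
  utr5[is.na(utr5)] <- missing_passes
  utr5_ok <- if (policy$use_utr5) utr5 else rep(FALSE, n)
  cadd_ok | splice_ok | utr5_ok
}

#' Filter variants to the qualifying set
#'
#' Applies the MAF rule (strict `<` at the threshold) and then the impact
#' rule. Every input variant ends up either in the qualifying table or in
#' the rejection log with a single reason (MAF checked first); counts are
#' conserved.
#'
#' @param variants data.frame of annotated variants: columns `variant_id`,
#'   `gene`, `AF_*`, `cadd`, `spliceai`, `utr5_flag`, and per-group
#'   carrier-count columns `carriers_*`.
#' @param policy A `filter_policy`.
#' @return List with `qualifying` (data.frame, same schema) and
#'   `rejections` (data.frame of `variant_id`, `gene`, `reason`).
#' @export
apply_filters <- function(variants, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  check_columns(variants, c("variant_id", "gene"), "variant table")
  n <- nrow(variants)
  if (n == 0) {
    return(list(qualifying = variants,
                rejections = data.frame(variant_id = character(0),
                                        gene = character(0),
                                        reason = character(0),
                                        stringsAsFactors = FALSE)))
  }
  af <- effective_maf(variants, policy$maf_mode, policy$missing_nfe_rule)
  reason <- rep(NA_character_, n)
  reason[is.na(af)] <- "MAF unavailable (NFE missing, exclusion rule)"
  maf_fail <- !is.na(af) & af >= policy$maf_threshold
  reason[maf_fail] <- sprintf("MAF ≥ %g", policy$maf_threshold)
  need_impact <- is.na(reason)
  imp <- passes_impact(variants, policy)
  reason[need_impact & !imp] <- "no impact criterion met"
  keep <- is.na(reason)
  list(
    qualifying = variants[keep, , drop = FALSE],
    rejections = data.frame(variant_id = variants$variant_id[!keep],
                            gene = variants$gene[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE)
  )
}
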