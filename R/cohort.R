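#' Construct a cohort design
#'
#' A cohort design bundles the participant table with the two study-level
#' settings that determine how downstream stages behave: the phenotyping
#' mode (how the phenotype labels were obtained) and the allele-frequency
#' mode used when filtering variants. Participants failing inclusion
#' (age at or below the age cutoff, or any exclusion flag) are moved to a
#' rejection log rather than silently dropped.
#'
#' @param participants data.frame with at least `participant_id` and
#'   `phenotype_label` columns; optional `age_years`, `sex_at_birth`,
#'   `gender`, `ancestry`, `exclusion_flags` (semicolon-separated).
#' @param name Cohort name.
#' @param phenotyping_mode One of `"audiometry"`, `"self_report"`,
#'   `"diagnostic"`.
#' @param maf_mode One of `"nfe"`, `"max_population"`; recorded here and
#'   consumed by the variant filter.
#' @param age_min Inclusion requires age strictly greater than this
#'   (default 55). Rows without an age column are not age-filtered.
#' @return An object of class `cohort_design`: a list with elements
#'   `name`, `phenotyping_mode`, `maf_mode`, `participants` (included
#'   rows) and `rejections` (data.frame of `participant_id`, `reason`).
#' @export
cohort_design <- function(participants, name = "cohort",
                          phenotyping_mode = c("audiometry", "self_report",
                                               "diagnostic"),
                          maf_mode = c("nfe", "max_population"),
                          age_min = 55) {
  phenotyping_mode <- match.arg(phenotyping_mode)
  maf_mode <- match.arg(maf_mode)
  check_columns(participants, c("participant_id", "phenotype_label"),
                "cohort table")
  participants$participant_id <- as.character(participants$participant_id)

  dup <- duplicated(participants$participant_id)
  if (any(dup)) {
    stop("duplicate participant_id: ",
         paste(unique(participants$participant_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  bad_label <- !participants$phenotype_label %in% c("normal", "impaired",
                                                    "unknown")
  if (any(bad_label)) {
    stop("phenotype_label must be one of normal/impaired/unknown; found: ",
         paste(unique(participants$phenotype_label[bad_label]),
               collapse = ", "), call. = FALSE)
  }

  reason <- rep(NA_character_, nrow(participants))
  if ("age_years" %in% names(participants)) {
    too_young <- !is.na(participants$age_years) &
      participants$age_years <= age_min
    reason[too_young] <- sprintf("age ≤ %s", age_min)
  }
  if ("exclusion_flags" %in% names(participants)) {
    flagged <- !is.na(participants$exclusion_flags) &
      nzchar(participants$exclusion_flags)
    reason[flagged & is.na(reason)] <-
      paste0("exclusion_flags: ", participants$exclusion_flags[flagged & is.na(reason)])
  }

  rejected <- !is.na(reason)
  rejections <- data.frame(
    participant_id = participants$participant_id[rejected],
    reason = reason[rejected],
    stringsAsFactors = FALSE
  )
  structure(
    list(name = name,
         phenotyping_mode = phenotyping_mode,
         maf_mode = maf_mode,
         participants = participants[!rejected, , drop = FALSE],
         rejections = rejections),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %s: %d participants (%d rejected)\n",
              x$name, nrow(x$participants), nrow(x$rejections)))
  cat(sprintf("  phenotyping: %s; MAF mode: %s\n",
              x$phenotyping_mode, x$maf_mode))
  tab <- table(factor(x$participants$phenotype_label,
                      levels = c("normal", "impaired", "unknown")))
  cat(sprintf("  normal: %d  impaired: %d  unknown: %d\n",
              tab[["normal"]], tab[["impaired"]], tab[["unknown"]]))
  invisible(x)
}

#' Load a cohort table from a delimited file
#'
#' Reads a TSV/CSV participant table and applies the inclusion rules via
#' [cohort_design()]. Rows failing inclusion end up in the design's
#' rejection log; loaded plus rejected always equals the rows in the file.
#'
#' @inheritParams cohort_design
#' @param path Path to a TSV or CSV file with a header.
#' @return A `cohort_design`.
#' @export
load_cohort_table <- function(path, name = basename(path),
                              phenotyping_mode = "self_report",
                              maf_mode = "max_population",
                              age_min = 55) {
  df <- read_delim_table(path)
  cohort_design(df, name = name, phenotyping_mode = phenotyping_mode,
                maf_mode = maf_mode, age_min = age_min)
}

# Canonicalise a recorded gender string against the sex-at-birth value.
# With synonyms enabled, a small configurable table maps common words onto
# the two sex labels before comparison; matching is case-insensitive.
match_gender <- function(sex, gender, synonyms = NULL) {
  if (is.na(sex) || is.na(gender)) return(FALSE)
  g <- gender
  if (!is.null(synonyms)) {
    hit <- match(tolower(g), tolower(names(synonyms)))
    if (!is.na(hit)) g <- synonyms[[hit]]
  }
  tolower(g) == tolower(sex)
}

#' Restrict a cohort to sex-consistent participants
#'
#' For sex-specific analyses, participants are retained only when sex at
#' birth is exactly "Male" or "Female" and the recorded gender matches it.
#' The match rule is strict case-insensitive equality; an optional synonym
#' table (e.g. `c(man = "Male", woman = "Female")`) can be supplied.
#' Missing sex or gender fields are treated as non-matching. The input
#' cohort is not modified, so all-participant analyses are unaffected.
#'
#' @param cohort A `cohort_design`.
#' @param synonyms Named character vector mapping gender words to
#'   `"Male"`/`"Female"`, or `NULL` (default) for strict equality only.
#' @return A `cohort_design` containing the retained participants; the
#'   exclusions are appended to the rejection log with reason
#'   `"sex-inconsistent"`.
#' @export
apply_sex_exclusion <- function(cohort, synonyms = NULL) {
  stopifnot(inherits(cohort, "cohort_design"))
  p <- cohort$participants
  check_columns(p, c("sex_at_birth", "gender"), "cohort table")
  sex_ok <- !is.na(p$sex_at_birth) & p$sex_at_birth %in% c("Male", "Female")
  gender_ok <- vapply(seq_len(nrow(p)), function(i) {
    match_gender(p$sex_at_birth[i], p$gender[i], synonyms)
  }, logical(1))
  keep <- sex_ok & gender_ok
  out <- cohort
  out$participants <- p[keep, , drop = FALSE]
  if (any(!keep)) {
    out$rejections <- rbind(out$rejections, data.frame(
      participant_id = p$participant_id[!keep],
      reason = "sex-inconsistent",
      stringsAsFactors = FALSE
    ))
  }
  out
}

#' Stratify a cohort by sex and/or ancestry
#'
#' Partitions the cohort by the requested variables. Strata in which either
#' phenotype group falls below `min_stratum_size` are returned with
#' `skipped = TRUE` (reason `"insufficient participants"`) so that reports
#' can render them as missing cells rather than analysing them.
#'
#' @param cohort A `cohort_design`. When `by` includes `"sex"` the caller
#'   is expected to have applied [apply_sex_exclusion()] first.
#' @param by Character subset of `c("sex", "ancestry")`; empty means a
#'   single stratum equal to the input.
#' @param min_stratum_size Minimum participants per phenotype group for a
#'   stratum to be analysable (default 50).
#' @return A list of strata; each element is a list with `label`, `cohort`
#'   (a `cohort_design`), `skipped` (logical) and `skip_reason`.
#' @export
stratify <- function(cohort, by = character(0), min_stratum_size = 50) {
  stopifnot(inherits(cohort, "cohort_design"))
  bad <- setdiff(by, c("sex", "ancestry"))
  if (length(bad) > 0) {
    stop("unknown stratification variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- cohort$participants
  if (length(by) == 0) {
    return(list(list(label = "all", cohort = cohort, skipped = FALSE,
                     skip_reason = NA_character_)))
  }
  key_cols <- c(sex = "sex_at_birth", ancestry = "ancestry")[by]
  check_columns(p, unname(key_cols), "cohort table")
  key <- do.call(paste, c(unname(p[, key_cols, drop = FALSE]), sep = "/"))
  lapply(split(seq_len(nrow(p)), key), function(idx) {
    sub <- cohort
    sub$participants <- p[idx, , drop = FALSE]
    counts <- table(factor(sub$participants$phenotype_label,
                           levels = c("normal", "impaired")))
    ok <- all(counts >= min_stratum_size)
    list(label = key[idx[1]], cohort = sub, skipped = !ok,
         skip_reason = if (ok) NA_character_ else "insufficient participants")
  })
}

#' Summarise a cohort's phenotype groups
#'
#' Counts participants per phenotype group (participants labelled
#' `unknown` are excluded from both groups and reported separately) with a
#' per-sex breakdown when sex is recorded, and computes integer
#' percentages of classified participants with half-up rounding — the
#' convention used in published cohort characteristic tables.
#'
#' @param cohort A `cohort_design`.
#' @return An object of class `cohort_summary`: list with `total`
#'   (classified participants), `unknown`, `counts` (named normal /
#'   impaired), `by_sex` (matrix or NULL), and `percent` (named, `NA` when
#'   `total` is zero).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_design"))
  p <- cohort$participants
  classified <- p[p$phenotype_label %in% c("normal", "impaired"), ,
                  drop = FALSE]
  counts <- c(
    normal = sum(classified$phenotype_label == "normal"),
    impaired = sum(classified$phenotype_label == "impaired")
  )
  total <- sum(counts)
  percent <- if (total == 0) {
    c(normal = NA_real_, impaired = NA_real_)
  } else {
    round_half_up(100 * counts / total)
  }
  by_sex <- NULL
  if ("sex_at_birth" %in% names(classified)) {
    by_sex <- table(classified$phenotype_label,
                    classified$sex_at_birth)
  }
  structure(
    list(total = total,
         unknown = sum(p$phenotype_label == "unknown"),
         counts = counts,
         percent = percent,
         by_sex = by_sex),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d classified (%d unknown)\n",
              x$total, x$unknown))
  for (g in names(x$counts)) {
    pct <- if (is.na(x$percent[[g]])) "--" else sprintf("%d%%", x$percent[[g]])
    cat(sprintf("  %-9s %d (%s)\n", g, x$counts[[g]], pct))
  }
  invisible(x)
}
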