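#' Load gene sets from GMT or plain-text files
#'
#' GMT files are tab-separated: set name, description, then member
#' symbols. A file without tab characters is read as a one-symbol-per-line
#' list forming a single set named after the file. Symbols are upper-cased
#' and de-duplicated; duplicates are reported with a warning.
#'
#' @param path File path.
#' @return Named list of character vectors (one per set).
#' @export
load_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("no gene sets found in ", path, call. = FALSE)
  }
  if (any(grepl("\t", lines))) {
    sets <- list()
    for (ln in lines) {
      fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 3) {
        stop("malformed GMT line (need name, description, members): ",
             substr(ln, 1, 60), call. = FALSE)
      }
      members <- toupper(trimws(fields[-(1:2)]))
      members <- members[nzchar(members)]
      ndup <- sum(duplicated(members))
      if (ndup > 0) {
        warning(sprintf("gene set '%s': %d duplicate symbol(s) removed",
                        fields[1], ndup), call. = FALSE)
      }
      members <- unique(members)
      if (length(members) == 0) {
        stop("gene set '", fields[1], "' is empty after parsing",
             call. = FALSE)
      }
      sets[[fields[1]]] <- members
    }
    sets
  } else {
    members <- toupper(trimws(lines))
    members <- members[nzchar(members)]
    ndup <- sum(duplicated(members))
    if (ndup > 0) {
      warning(sprintf("%d duplicate symbol(s) removed", ndup),
              call. = FALSE)
    }
    members <- unique(members)
    if (length(members) == 0) stop("empty gene set file", call. = FALSE)
    out <- list(members)
    names(out) <- tools::file_path_sans_ext(basename(path))
    out
  }
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic gene set", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` gene-set members when `n` genes
#' are drawn uniformly without replacement from a universe of `N` genes
#' containing `K` set members: `P(X >= k)`.
#'
#' @param N Universe size.
#' @param K Set members in the universe.
#' @param n Draw (list) size.
#' @param k Observed overlap.
#' @return Probability in (0, 1].
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (K > N || n > N || k < 0 || k > min(K, n)) {
    stop(sprintf(
      "invalid hypergeometric parameters: N=%s K=%s n=%s k=%s", N, K, n, k),
      call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of a gene list in gene sets
#'
#' One-sided (enrichment-only) test of the overlap between an outlier gene
#' list and each gene set, against a stated universe — the genes that
#' entered the analysis and so could have been called outliers. Set sizes
#' are counted within the universe, not nominally. List members absent
#' from the universe are dropped with a warning.
#'
#' @param gene_list Character vector of gene symbols (e.g. an outlier
#'   list).
#' @param sets Named list of character vectors, as from
#'   [load_gene_sets()].
#' @param universe Character vector of all gene symbols tested.
#' @param list_name Label for the list in the results.
#' @return data.frame with one row per set: `list_name`, `set_name`, `N`,
#'   `K`, `n`, `k`, `p_value`; `adjusted_p` and `significant` are `NA`
#'   until [adjust_pvalues()] is applied.
#' @export
enrich <- function(gene_list, sets, universe, list_name = "list") {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(toupper(universe))
  gene_list <- unique(toupper(gene_list))
  outside <- setdiff(gene_list, universe)
  if (length(outside) > 0) {
    warning(length(outside),
            " list gene(s) absent from the universe were dropped",
            call. = FALSE)
    gene_list <- setdiff(gene_list, outside)
  }
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(toupper(sets[[nm]]), universe)
    K <- length(members)
    k <- length(intersect(gene_list, members))
    data.frame(list_name = list_name, set_name = nm,
               N = N, K = K, n = n, k = k,
               p_value = hypergeometric_tail(N, K, n, k),
               adjusted_p = NA_real_, significant = NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Adjust enrichment p-values across a family of tests
#'
#' Benjamini-Hochberg step-up (default) or Bonferroni across all rows of
#' the supplied results — the family is every (list, set) test in the run.
#' Significance is flagged at adjusted p < `alpha`.
#'
#' @param results data.frame of enrichment results (rows from
#'   [enrich()], possibly rbind-ed).
#' @param method `"bh"` or `"bonferroni"`.
#' @param alpha Significance level for the flag (default 0.05).
#' @return The results with `adjusted_p` and `significant` filled.
#' @export
adjust_pvalues <- function(results, method = c("bh", "bonferroni"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (nrow(results) == 0) stop("no results to adjust", call. = FALSE)
  results$adjusted_p <- stats::p.adjust(
    results$p_value,
    method = if (method == "bh") "BH" else "bonferroni")
  results$significant <- results$adjusted_p < alpha
  results
}
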