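#' Match genes on recombination rate, gene density and expression
#'
#' Selects the "comparable genes" used to build an empirical null for a
#' focal gene's selection statistics: pool genes whose recombination rate,
#' gene density (50-kb window) and expression level each lie within a
#' tolerance of the focal gene's values.  The focal gene itself is always
#' excluded.
#'
#' @param focal A one-row data frame or list with `gene` and the three
#'   covariates `rec_rate`, `gene_density`, `expression`.
#' @param pool Data frame of candidate genes with the same columns.
#' @param tolerances Named numeric vector of absolute tolerances per
#'   covariate; defaults to 0.5 pooled standard deviations of each
#'   covariate (the paper-style "comparable/similar" bands made explicit).
#' @param min_matches Minimum acceptable match count (default 100); fewer
#'   matches sets the `too_few` flag rather than erroring.
#' @return A list of class `gene_match`: `gene`, `matched` (ids), `n`,
#'   `tolerances`, `too_few`.
#' @export
match_genes <- function(focal, pool, tolerances = NULL, min_matches = 100) {
  covs <- c("rec_rate", "gene_density", "expression")
  stopifnot(is.data.frame(pool), all(c("gene", covs) %in% names(pool)))
  focal <- as.list(focal)
  if (!all(covs %in% names(focal))) {
    stop("focal gene must carry covariates: ", paste(covs, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tolerances)) {
    tolerances <- vapply(covs, function(v) 0.5 * stats::sd(pool[[v]]),
                         numeric(1L))
  }
  if (!all(covs %in% names(tolerances))) {
    stop("tolerances must be named for: ", paste(covs, collapse = ", "),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(pool))
  for (v in covs) {
    keep <- keep & abs(pool[[v]] - as.numeric(focal[[v]])) <= tolerances[[v]]
  }
  if (!is.null(focal$gene)) keep <- keep & pool$gene != focal$gene
  ids <- pool$gene[keep]
  structure(list(gene = focal$gene %||% NA_character_, matched = ids,
                 n = length(ids), tolerances = tolerances[covs],
                 too_few = length(ids) < min_matches),
            class = "gene_match")
}

#' @export
print.gene_match <- function(x, ...) {
  cat(sprintf("%d comparable gene(s) for %s%s\n", x$n, x$gene,
              if (x$too_few) "  [warning: fewer than requested]" else ""))
  invisible(x)
}

#' Two-sided empirical p-value against a null sample
#'
#' Rank-based two-sided p with the add-one estimator:
#' `p = min(1, 2 * min((#{x <= obs} + 1)/(n + 1), (#{x >= obs} + 1)/(n + 1)))`.
#' Ties count on both sides and the add-one term keeps p strictly positive.
#' Non-finite null values are dropped (their count is reported via the
#' `n_dropped` attribute).
#'
#' @param observed Observed statistic (finite scalar).
#' @param null_values Numeric vector of null statistics.
#' @return The empirical p-value in (0, 1].
#' @examples
#' empirical_two_sided_p(0, rep(0, 10))        # 1
#' empirical_two_sided_p(-1, seq_len(99))      # 2/100
#' @export
empirical_two_sided_p <- function(observed, null_values) {
  stopifnot(is.numeric(observed), length(observed) == 1L,
            is.finite(observed))
  ok <- is.finite(null_values)
  dropped <- sum(!ok)
  null_values <- null_values[ok]
  n <- length(null_values)
  if (n == 0L) stop("no finite null values to compare against",
                    call. = FALSE)
  lo <- (sum(null_values <= observed) + 1) / (n + 1)
  hi <- (sum(null_values >= observed) + 1) / (n + 1)
  p <- min(1, 2 * min(lo, hi))
  attr(p, "n_dropped") <- dropped
  p
}

#' Covariate-matched empirical null test for a selection statistic
#'
#' Assembles the full "comparable genes" analysis: matches the focal gene
#' on covariates via [match_genes()], takes the chosen statistic (`KaKs` or
#' `PnPs`) of the matched genes as the null distribution, and computes the
#' two-sided empirical p of the focal gene's observed value with
#' [empirical_two_sided_p()].  Genes whose statistic is undefined are
#' dropped from the null and counted.
#'
#' @param focal_gene Gene id of the focal gene.
#' @param mk_results An `mk_result` data frame from [mk_test()] covering
#'   the focal gene and the pool.
#' @param covariates Data frame with `gene`, `rec_rate`, `gene_density`,
#'   `expression`.
#' @param statistic `"KaKs"` or `"PnPs"`.
#' @param tolerances,min_matches Passed to [match_genes()].
#' @return A list of class `empirical_null`: focal id, statistic name,
#'   `observed`, `null_values`, `matched` ids, `n_used`, `n_dropped`,
#'   `too_few`, and the two-sided `p`.
#' @export
mk_empirical_null <- function(focal_gene, mk_results, covariates,
                              statistic = c("KaKs", "PnPs"),
                              tolerances = NULL, min_matches = 100) {
  statistic <- match.arg(statistic)
  stopifnot(is.data.frame(mk_results), is.data.frame(covariates))
  if (!focal_gene %in% mk_results$gene ||
      !focal_gene %in% covariates$gene) {
    stop(sprintf("focal gene '%s' absent from results or covariates",
                 focal_gene), call. = FALSE)
  }
  focal_cov <- covariates[covariates$gene == focal_gene, ][1L, ]
  m <- match_genes(focal_cov, covariates, tolerances = tolerances,
                   min_matches = min_matches)
  observed <- mk_results[[statistic]][mk_results$gene == focal_gene][1L]
  if (is.na(observed)) {
    stop(sprintf("statistic %s is undefined for the focal gene", statistic),
         call. = FALSE)
  }
  null_values <- mk_results[[statistic]][mk_results$gene %in% m$matched]
  p <- empirical_two_sided_p(observed, null_values)
  structure(list(gene = focal_gene, statistic = statistic,
                 observed = observed,
                 null_values = null_values[is.finite(null_values)],
                 matched = m$matched, n_used = sum(is.finite(null_values)),
                 n_dropped = attr(p, "n_dropped"), too_few = m$too_few,
                 tolerances = m$tolerances, p = as.numeric(p)),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("Empirical null for %s of %s\n", x$statistic, x$gene))
  cat(sprintf("  observed = %.4g; null: %d matched genes used (%d undefined dropped)%s\n",
              x$observed, x$n_used, x$n_dropped,
              if (x$too_few) " [few matches]" else ""))
  cat(sprintf("  two-sided empirical p = %.4g\n", x$p))
  invisible(x)
}
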