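#' Mendelian expectation of the mutant-allele frequency in a phenotype pool
#'
#' For a fully penetrant recessive single-locus trait segregating 1:2:1 in
#' an F2, the phenotypically wild-type class is 1/3 homozygous wild type and
#' 2/3 heterozygous, so the mutant allele is at frequency
#' (2/3) x (1/2) = 1/3 in the wild-type pool; the mutant class is entirely
#' homozygous mutant, so the mutant allele is at frequency 1.  These are the
#' 33.3% / 100% expectations against which pooled SNP frequencies are
#' filtered.
#'
#' @param inheritance Inheritance mode; only `"recessive"` is modelled.
#' @param pool `"wild_type"` or `"mutant"`.
#' @return The exact expected mutant-allele frequency (1/3 or 1).
#' @examples
#' expected_pool_frequency("recessive", "wild_type")  # 1/3
#' expected_pool_frequency("recessive", "mutant")     # 1
#' @export
expected_pool_frequency <- function(inheritance = c("recessive"),
                                    pool = c("wild_type", "mutant")) {
  if (!identical(match.arg(inheritance), "recessive")) {
    stop("only recessive inheritance is modelled", call. = FALSE)
  }
  switch(match.arg(pool), wild_type = 1 / 3, mutant = 1)
}

#' Is a substitution an EMS-canonical change?
#'
#' EMS overwhelmingly induces G:C -> A:T transitions, reported on the
#' reference forward strand as G>A or C>T (C>T being the forward-strand
#' image of G>A on the complementary strand).  Vectorised.
#'
#' @param ref,alt Single reference/alternate bases (A/C/G/T).
#' @return Logical vector: `TRUE` iff (ref, alt) is (G, A) or (C, T).
#' @examples
#' is_ems_type(c("G", "C", "A"), c("A", "T", "G"))
#' @export
is_ems_type <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!all(ref %in% DNA_BASES) || !all(alt %in% DNA_BASES)) {
    stop("ref/alt must be unambiguous bases (A, C, G or T)", call. = FALSE)
  }
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

#' Configuration of the three-criterion bulked-segregant SNP filter
#'
#' @param wt_target Expected mutant-allele frequency in the wild-type pool
#'   (default 1/3).
#' @param mu_target Expected frequency in the mutant pool (default 1).
#' @param wt_tol Absolute tolerance around `wt_target`.  The default 0.10
#'   is about two binomial standard deviations of a 1/3 frequency at 100x
#'   depth.
#' @param mu_tol Absolute tolerance below `mu_target` (default 0.05); also
#'   the band used for homozygous/heterozygous pool-genotype calls.
#' @param min_depth Minimum total reads per pool for a call (default 20).
#' @param ems_only Apply the substitution-type criterion (default `TRUE`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(wt_target = 1 / 3, mu_target = 1, wt_tol = 0.10,
                          mu_tol = 0.05, min_depth = 20, ems_only = TRUE) {
  cfg <- list(wt_target = check_prob(wt_target, "wt_target"),
              mu_target = check_prob(mu_target, "mu_target"),
              wt_tol = check_prob(wt_tol, "wt_tol", upper = 1),
              mu_tol = check_prob(mu_tol, "mu_tol", upper = 1),
              min_depth = check_count(min_depth, "min_depth", positive = FALSE),
              ems_only = isTRUE(ems_only))
  structure(cfg, class = "filter_config")
}

#' Call a pooled genotype from pooled read counts
#'
#' Frequency-band calls: a pool is `hom_alt` when its alt frequency is
#' within `mu_tol` of 1, `hom_ref` when within `mu_tol` of 0, `het` when
#' both alleles are credibly present, and `low_depth` below `min_depth`
#' total reads.  Vectorised over depths.
#'
#' @param ref_depth,alt_depth Non-negative read counts.
#' @param config A [filter_config()].
#' @return Character vector in `c("hom_ref", "het", "hom_alt", "low_depth")`.
#' @examples
#' classify_pool_genotype(c(0, 50, 66), c(50, 0, 34))
#' @export
classify_pool_genotype <- function(ref_depth, alt_depth,
                                   config = filter_config()) {
  stopifnot(inherits(config, "filter_config"),
            all(ref_depth >= 0), all(alt_depth >= 0))
  tot <- ref_depth + alt_depth
  freq <- pool_freq(ref_depth, alt_depth)
  out <- rep("het", length(tot))
  out[freq >= config$mu_target - config$mu_tol] <- "hom_alt"
  out[freq <= config$mu_tol] <- "hom_ref"
  out[tot < config$min_depth] <- "low_depth"
  out
}

#' Filter pooled variants for candidate causal EMS mutations
#'
#' Applies the three bulked-segregant criteria to every variant:
#' \enumerate{
#'   \item EMS substitution type (G>A or C>T);
#'   \item heterozygous call in the wild-type pool and homozygous-alternate
#'     call in the mutant pool;
#'   \item pool frequencies matching the Mendelian recessive expectations:
#'     `|wt_freq - wt_target| <= wt_tol` and `mu_freq >= mu_target - mu_tol`.
#' }
#' Criteria 2 and 3 overlap operationally but are flagged independently so
#' the audit trail mirrors the three-criterion screen.
#'
#' @param variants A data frame of pooled variants (as produced by
#'   [simulate_cross()] or [read_pooled_variants()]) or a `pooled_cross`.
#' @param config A [filter_config()].
#' @return A data frame of class `bsa_candidates`: all input variants with
#'   per-criterion logical flags (`ems_pass`, `genotype_pass`, `freq_pass`),
#'   the WT-pool frequency deviation `wt_dev`, and `candidate` (all three
#'   criteria passed).  Rows are ordered candidates first, ascending in
#'   `wt_dev`.
#' @export
filter_candidates <- function(variants, config = filter_config()) {
  if (inherits(variants, "pooled_cross")) variants <- variants$variants
  stopifnot(is.data.frame(variants), inherits(config, "filter_config"))
  need <- c("chrom", "pos", "ref", "alt", "wt_ref_depth", "wt_alt_depth",
            "mu_ref_depth", "mu_alt_depth")
  if (!all(need %in% names(variants))) {
    stop("variants must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  v <- variants
  if (nrow(v) == 0L) {
    v$ems_pass <- logical(0); v$genotype_pass <- logical(0)
    v$freq_pass <- logical(0); v$wt_dev <- numeric(0)
    v$candidate <- logical(0)
    return(structure(v, class = c("bsa_candidates", "data.frame"),
                     config = config))
  }
  if (is.null(v$wt_freq)) v$wt_freq <- pool_freq(v$wt_ref_depth, v$wt_alt_depth)
  if (is.null(v$mu_freq)) v$mu_freq <- pool_freq(v$mu_ref_depth, v$mu_alt_depth)

  v$ems_pass <- if (config$ems_only) is_ems_type(v$ref, v$alt) else
    rep(TRUE, nrow(v))
  wt_call <- classify_pool_genotype(v$wt_ref_depth, v$wt_alt_depth, config)
  mu_call <- classify_pool_genotype(v$mu_ref_depth, v$mu_alt_depth, config)
  v$genotype_pass <- wt_call == "het" & mu_call == "hom_alt"
  v$wt_dev <- abs(v$wt_freq - config$wt_target)
  v$freq_pass <- !is.na(v$wt_freq) & !is.na(v$mu_freq) &
    v$wt_dev <= config$wt_tol &
    v$mu_freq >= config$mu_target - config$mu_tol
  v$candidate <- v$ems_pass & v$genotype_pass & v$freq_pass

  ord <- order(!v$candidate, v$wt_dev, v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  rownames(v) <- NULL
  structure(v, class = c("bsa_candidates", "data.frame"), config = config)
}

#' @export
print.bsa_candidates <- function(x, n = 6L, ...) {
  cat(sprintf("BSA filter: %d / %d variants pass all three criteria\n",
              sum(x$candidate), nrow(x)))
  cat(sprintf("  criterion 1 (EMS type):        %d pass\n", sum(x$ems_pass)))
  cat(sprintf("  criterion 2 (pool genotypes):  %d pass\n",
              sum(x$genotype_pass)))
  cat(sprintf("  criterion 3 (frequency bands): %d pass\n", sum(x$freq_pass)))
  top <- utils::head(x[x$candidate, c("chrom", "pos", "ref", "alt",
                                      "wt_freq", "mu_freq")], n)
  if (nrow(top)) {
    cat("Top candidates (by WT-pool frequency deviation):\n")
    print.data.frame(top, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
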