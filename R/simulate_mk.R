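#' Configuration for simulated per-gene polymorphism/divergence counts
#'
#' Independent-Poisson model of McDonald-Kreitman inputs.  Per gene,
#' `Ps ~ Poisson(theta * l4)` and `Ds ~ Poisson(d * l4)` at neutral
#' synonymous sites, while non-synonymous events are thinned by acceptance
#' factors: `Pn ~ Poisson(theta * l0 * f_poly)` and
#' `Dn ~ Poisson(d * l0 * f_div)`.  `f_poly = f_div = 1` is neutral,
#' values below 1 model purifying selection, `f_div > f_poly` an adaptive
#' excess of fixed differences.
#'
#' The defaults describe a Capsella-like setting: genes of ~600 0-fold and
#' ~200 4-fold sites, per-site neutral diversity 0.02 and divergence to the
#' outgroup 0.10.
#'
#' @param n_genes Number of genes.
#' @param l0,l4 0-fold and 4-fold sites per gene.
#' @param theta Per-site polymorphism rate at neutral (4-fold) sites.
#' @param d Per-site divergence rate at neutral sites.
#' @param f_poly,f_div Relative acceptance of non-synonymous polymorphism
#'   and fixed differences (>= 0).
#' @param f_poly_range Optional length-2 range; per-gene `f_poly` is then
#'   drawn uniformly from it (overriding `f_poly`), creating constraint
#'   heterogeneity across genes.
#' @param covariate_params Named list of `c(mean, sd)` pairs for the three
#'   matching covariates `rec_rate` (cM/Mb), `gene_density` (genes per
#'   50-kb window) and `expression` (log2 expression).
#' @param covariate_effect Strength of the correlation between expression
#'   and per-gene constraint (`-log f_poly`); 0 (default) leaves the
#'   covariates independent of selection.
#' @param seed RNG seed.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_genes = 1000, l0 = 600, l4 = 200,
                             theta = 0.02, d = 0.10,
                             f_poly = 1, f_div = 1, f_poly_range = NULL,
                             covariate_params = list(
                               rec_rate = c(mean = 4, sd = 1),
                               gene_density = c(mean = 10, sd = 3),
                               expression = c(mean = 5, sd = 2)),
                             covariate_effect = 0, seed = NULL) {
  if (theta < 0 || d < 0 || f_poly < 0 || f_div < 0) {
    stop("rates and acceptance factors must be >= 0", call. = FALSE)
  }
  if (!is.null(f_poly_range)) {
    stopifnot(length(f_poly_range) == 2L, all(f_poly_range >= 0),
              f_poly_range[1L] <= f_poly_range[2L])
  }
  structure(list(
    n_genes = check_count(n_genes, "n_genes"),
    l0 = check_count(l0, "l0"), l4 = check_count(l4, "l4"),
    theta = theta, d = d, f_poly = f_poly, f_div = f_div,
    f_poly_range = f_poly_range,
    covariate_params = covariate_params,
    covariate_effect = covariate_effect, seed = seed
  ), class = "selection_config")
}

#' Simulate per-gene MK counts with matchable covariates
#'
#' Draws the four MK cells per gene from the Poisson model of
#' [selection_config()] and attaches covariates (recombination rate, gene
#' density, expression) drawn from the configured normal distributions,
#' truncated at zero.  When `covariate_effect != 0` and per-gene constraint
#' varies (`f_poly_range`), expression is shifted by
#' `covariate_effect * -log(f_poly_gene)` so that covariate matching has
#' signal to exploit.
#'
#' @param config A [selection_config()].
#' @return A list of class `mk_sim` with `counts` (data frame: `gene`,
#'   `Pn`, `Ps`, `Dn`, `Ds`, `L0`, `L4`, `f_poly`), `covariates` (data
#'   frame: `gene`, `rec_rate`, `gene_density`, `expression`) and `config`.
#' @examples
#' sim <- simulate_mk_counts(selection_config(n_genes = 10, seed = 1))
#' head(sim$counts)
#' @export
simulate_mk_counts <- function(config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    fp <- if (is.null(config$f_poly_range)) rep(config$f_poly, n) else
      stats::runif(n, config$f_poly_range[1L], config$f_poly_range[2L])
    counts <- data.frame(
      gene = sprintf("g%04d", seq_len(n)),
      Pn = stats::rpois(n, config$theta * config$l0 * fp),
      Ps = stats::rpois(n, config$theta * config$l4),
      Dn = stats::rpois(n, config$d * config$l0 * config$f_div),
      Ds = stats::rpois(n, config$d * config$l4),
      L0 = config$l0, L4 = config$l4, f_poly = fp,
      stringsAsFactors = FALSE
    )
    cp <- config$covariate_params
    draw <- function(par) pmax(0, stats::rnorm(n, par[["mean"]], par[["sd"]]))
    covariates <- data.frame(
      gene = counts$gene,
      rec_rate = draw(cp$rec_rate),
      gene_density = draw(cp$gene_density),
      expression = draw(cp$expression),
      stringsAsFactors = FALSE
    )
    if (config$covariate_effect != 0) {
      covariates$expression <- pmax(
        0, covariates$expression +
          config$covariate_effect * -log(pmax(fp, 1e-12)))
    }
    structure(list(counts = counts, covariates = covariates,
                   config = config), class = "mk_sim")
  })
}

#' @export
print.mk_sim <- function(x, ...) {
  cat(sprintf("Simulated MK counts: %d genes (l0=%d, l4=%d, theta=%g, d=%g)\n",
              x$config$n_genes, x$config$l0, x$config$l4, x$config$theta,
              x$config$d))
  invisible(x)
}
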