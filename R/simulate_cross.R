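#' Configuration for a simulated phenotype-pooled segregating cross
#'
#' Describes a recessive single-locus EMS mutant cross pooled by phenotype
#' for bulked segregant analysis: F2 genotypes at the focal locus segregate
#' 1:2:1 (three backcrosses clean the genetic background but leave the focal
#' locus segregating), individuals are pooled by fruit phenotype and each
#' pool is sequenced to a fixed depth per site.
#'
#' @param n_f2 Number of F2 individuals in the segregating population.
#' @param pool_size Individuals sampled (without replacement) into each
#'   phenotype pool, or `NULL` to pool every individual of the class.
#'   The default mirrors pools of ~90 plants.
#' @param depth Mean sequencing depth per site and pool.  `Inf` switches to
#'   a deterministic mode in which read frequencies equal their population
#'   expectations exactly (useful for analytic checks).
#' @param n_background_snps Number of non-causal EMS-induced SNPs carried
#'   along as labelled negatives.
#' @param ems_fraction Proportion of background SNPs that are canonical EMS
#'   G>A / C>T changes; these segregate independently of the phenotype
#'   (unlinked).  The complement are non-EMS substitutions given causal-like
#'   pool frequencies, so the substitution-type filter is exercised on its
#'   own.
#' @param error_rate Per-read symmetric miscall probability.
#' @param penetrance Probability that a homozygous mutant shows the mutant
#'   phenotype (1 = fully penetrant recessive).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return An object of class `cross_config`.
#' @seealso [simulate_cross()]
#' @export
cross_config <- function(n_f2 = 600, pool_size = 90, depth = 100,
                         n_background_snps = 1000, ems_fraction = 1,
                         error_rate = 0.001, penetrance = 1, seed = NULL) {
  cfg <- list(
    n_f2 = check_count(n_f2, "n_f2"),
    pool_size = if (is.null(pool_size)) NULL else
      check_count(pool_size, "pool_size"),
    depth = if (is.infinite(depth)) Inf else check_count(depth, "depth"),
    n_background_snps = check_count(n_background_snps, "n_background_snps",
                                    positive = FALSE),
    ems_fraction = check_prob(ems_fraction, "ems_fraction"),
    error_rate = check_prob(error_rate, "error_rate", upper = 0.5),
    penetrance = check_prob(penetrance, "penetrance"),
    seed = seed
  )
  if (cfg$error_rate >= 0.5) stop("'error_rate' must be < 0.5", call. = FALSE)
  if (cfg$penetrance <= 0) stop("'penetrance' must be > 0", call. = FALSE)
  structure(cfg, class = "cross_config")
}

# read counts for one pool: binomial sampling at fixed depth with a
# symmetric miscall error folded into the read-level alt probability
pool_reads <- function(true_freq, depth, error_rate) {
  p_read <- true_freq * (1 - error_rate) + (1 - true_freq) * error_rate
  alt <- stats::rbinom(length(true_freq), depth, p_read)
  cbind(ref = depth - alt, alt = alt)
}

# deterministic infinite-depth representation of an exact frequency f:
# counts f*D and (1-f)*D at a denominator divisible by 3
exact_reads <- function(freq, denom = 3e6) {
  alt <- round(freq * denom)
  cbind(ref = denom - alt, alt = alt)
}

#' Simulate a phenotype-pooled cross for bulked segregant analysis
#'
#' Draws F2 genotypes at the causal locus from the Mendelian 1:2:1
#' distribution, assigns phenotypes under the (by default fully penetrant)
#' recessive rule, samples one pool per phenotype class without
#' replacement, and generates per-site pooled read counts by binomial
#' sampling at the configured depth.  The causal site is a canonical EMS
#' change (G>A or C>T).  Background sites are labelled negatives of two
#' kinds: unlinked EMS-type SNPs (alleles segregate independently of the
#' phenotype, pool frequencies near 1/2) and non-EMS substitutions with
#' causal-like frequencies.
#'
#' With `depth = Inf` the pooled frequencies equal their population
#' expectations exactly: 1/3 in the wild-type pool and 1 in the mutant
#' pool at the causal site.
#'
#' @param config A [cross_config()].
#' @return A list of class `pooled_cross` with elements
#'   \describe{
#'     \item{variants}{data frame of pooled variants (`id`, `chrom`, `pos`,
#'       `ref`, `alt`, per-pool ref/alt depths, `wt_freq`, `mu_freq`) plus
#'       the truth label (`causal`, `unlinked_ems`, `non_ems`).}
#'     \item{causal_id}{identifier of the causal variant.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' x <- simulate_cross(cross_config(n_background_snps = 10, seed = 1))
#' head(x$variants)
#' @export
simulate_cross <- function(config = cross_config()) {
  stopifnot(inherits(config, "cross_config"))
  with_seed(config$seed, {
    n <- config$n_f2
    # genotype = count of mutant alleles: 0/1/2 with probs 1/4, 1/2, 1/4
    geno <- sample(0:2, n, replace = TRUE, prob = c(1, 2, 1) / 4)
    mutant_pheno <- geno == 2L & stats::runif(n) < config$penetrance
    classes <- list(wild_type = which(!mutant_pheno),
                    mutant = which(mutant_pheno))
    ps <- config$pool_size
    pools <- lapply(names(classes), function(cl) {
      idx <- classes[[cl]]
      k <- if (is.null(ps)) length(idx) else ps
      if (k > length(idx)) {
        stop(sprintf(
          "pool_size (%d) exceeds the '%s' phenotype class (%d individuals)",
          k, cl, length(idx)), call. = FALSE)
      }
      idx[sample.int(length(idx), k)]
    })
    names(pools) <- names(classes)
    n_wt <- length(pools$wild_type)
    n_mu <- length(pools$mutant)

    n_bg <- config$n_background_snps
    bg_ems <- if (n_bg > 0) stats::runif(n_bg) < config$ems_fraction else
      logical(0)
    n_total <- 1L + n_bg
    pos <- sort(sample.int(2e7L, n_total))
    causal_slot <- sample.int(n_total, 1L)

    # substitution types
    ems_pairs <- rbind(c("G", "A"), c("C", "T"))
    all_pairs <- do.call(rbind, lapply(DNA_BASES, function(r)
      cbind(r, setdiff(DNA_BASES, r))))
    non_ems_pairs <- all_pairs[!(all_pairs[, 1] == "G" & all_pairs[, 2] == "A") &
                               !(all_pairs[, 1] == "C" & all_pairs[, 2] == "T"), ,
                               drop = FALSE]

    ref <- alt <- character(n_total)
    truth <- character(n_total)
    wt_true <- mu_true <- numeric(n_total)

    inf_depth <- is.infinite(config$depth)
    # causal site
    p <- ems_pairs[sample.int(2L, 1L), ]
    ref[causal_slot] <- p[1L]; alt[causal_slot] <- p[2L]
    truth[causal_slot] <- "causal"
    if (inf_depth) {
      wt_true[causal_slot] <- 1 / 3   # population expectation of the WT pool
      mu_true[causal_slot] <- 1
    } else {
      wt_true[causal_slot] <- sum(geno[pools$wild_type]) / (2 * n_wt)
      mu_true[causal_slot] <- sum(geno[pools$mutant]) / (2 * n_mu)
    }

    bg_slots <- setdiff(seq_len(n_total), causal_slot)
    for (j in seq_len(n_bg)) {
      s <- bg_slots[j]
      if (bg_ems[j]) {
        p <- ems_pairs[sample.int(2L, 1L), ]
        truth[s] <- "unlinked_ems"
        if (inf_depth) {
          wt_true[s] <- mu_true[s] <- 0.5
        } else {
          # unlinked F2 locus: the two alleles of each pooled individual are
          # independent Bernoulli(1/2) draws
          wt_true[s] <- stats::rbinom(1L, 2L * n_wt, 0.5) / (2 * n_wt)
          mu_true[s] <- stats::rbinom(1L, 2L * n_mu, 0.5) / (2 * n_mu)
        }
      } else {
        p <- non_ems_pairs[sample.int(nrow(non_ems_pairs), 1L), ]
        truth[s] <- "non_ems"
        if (inf_depth) {
          wt_true[s] <- 1 / 3
          mu_true[s] <- 1
        } else {
          # causal-like frequencies: only the substitution-type criterion
          # should reject these
          het <- stats::rbinom(1L, n_wt, 2 / 3)
          wt_true[s] <- het / (2 * n_wt)
          mu_true[s] <- 1
        }
      }
      ref[s] <- p[1L]; alt[s] <- p[2L]
    }

    if (inf_depth) {
      wt_reads <- exact_reads(wt_true)
      mu_reads <- exact_reads(mu_true)
    } else {
      wt_reads <- pool_reads(wt_true, config$depth, config$error_rate)
      mu_reads <- pool_reads(mu_true, config$depth, config$error_rate)
    }

    id <- sprintf("chr1_%d", pos)
    variants <- data.frame(
      id = id, chrom = "chr1", pos = pos, ref = ref, alt = alt,
      wt_ref_depth = wt_reads[, "ref"], wt_alt_depth = wt_reads[, "alt"],
      mu_ref_depth = mu_reads[, "ref"], mu_alt_depth = mu_reads[, "alt"],
      stringsAsFactors = FALSE
    )
    variants$wt_freq <- pool_freq(variants$wt_ref_depth, variants$wt_alt_depth)
    variants$mu_freq <- pool_freq(variants$mu_ref_depth, variants$mu_alt_depth)
    variants$truth <- truth

    structure(list(variants = variants, causal_id = id[causal_slot],
                   config = config),
              class = "pooled_cross")
  })
}

# alt-allele frequency; NA when the pool has no coverage
pool_freq <- function(ref_depth, alt_depth) {
  tot <- ref_depth + alt_depth
  ifelse(tot > 0, alt_depth / tot, NA_real_)
}

#' @export
print.pooled_cross <- function(x, ...) {
  cat("Simulated phenotype-pooled cross\n")
  cat(sprintf("  %d variants (%d background), causal site %s (%s>%s)\n",
              nrow(x$variants), nrow(x$variants) - 1L, x$causal_id,
              x$variants$ref[x$variants$truth == "causal"],
              x$variants$alt[x$variants$truth == "causal"]))
  cat(sprintf("  F2 = %d, pool size = %s, depth = %s\n", x$config$n_f2,
              x$config$pool_size %||% "whole class", x$config$depth))
  invisible(x)
}
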