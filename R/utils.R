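# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded generators do not disturb the global stream.
#' A `NULL` seed evaluates `code` under the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# scalar checks used by the config constructors
check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    stop(sprintf("'%s' must be a %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name, upper = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > upper) {
    stop(sprintf("'%s' must lie in [0, %s]", name, upper), call. = FALSE)
  }
  as.numeric(x)
}

DNA_BASES <- c("A", "C", "G", "T")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# reverse complement of a plain character DNA string
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1L]]),
        collapse = "")
}

# split a DNA string into its codons (length must be a multiple of 3)
codons_of <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

# translate an in-frame DNA string; returns the amino-acid vector including
# any stop ("*") codons; translation of trailing partial codons is dropped
translate_codons <- function(cds) {
  cod <- codons_of(substr(cds, 1L, 3L * (nchar(cds) %/% 3L)))
  unname(Biostrings::GENETIC_CODE[cod])
}

# amino acids before the first stop; NA_integer_ if no stop present
aa_before_stop <- function(aa) {
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0L) NA_integer_ else stop_at[1L] - 1L
}
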