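#' Scan protein sequences for the canonical SUMOylation consensus
#'
#' Reports every tetrapeptide window matching the forward consensus
#' psi-K-X-[D/E] (psi a hydrophobic residue, X any residue), the classic
#' SUMO-acceptor context; the acceptor lysine is the second residue of the
#' window.  Overlapping hits are all reported.  The default hydrophobic
#' set is `A, I, L, M, V, F, P, C`; it includes alanine (the AKMD context
#' places A in the psi slot) and excludes glycine.  An inverted consensus
#' [D/E]-X-K-psi can be scanned in addition via `inverted = TRUE`.
#'
#' @param sequences Named character vector of protein sequences (an
#'   `AAStringSet` is accepted).  Windows containing characters outside
#'   the 20 standard amino acids are skipped with a warning.
#' @param psi Hydrophobic (psi) residues, as a single string or character
#'   vector.
#' @param inverted Also scan the inverted consensus (default `FALSE`).
#' @return Data frame of hits, ordered by protein and window start:
#'   `protein`, `k_pos` (1-based acceptor-lysine position), `start`,
#'   `end` (window, 1-based inclusive), `tetrapeptide`, `motif`
#'   (`"forward"`/`"inverted"`), `psi_set`.
#' @examples
#' scan_sumo(c(p1 = "MGGAKMDGG"))
#' @export
scan_sumo <- function(sequences, psi = "AILMVFPC", inverted = FALSE) {
  if (inherits(sequences, "AAStringSet")) {
    sequences <- as.character(sequences)
  }
  stopifnot(is.character(sequences))
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  psi_set <- unique(strsplit(paste(psi, collapse = ""), "")[[1L]])
  psi_str <- paste(sort(psi_set), collapse = "")

  hits <- lapply(names(sequences), function(id) {
    s <- toupper(sequences[[id]])
    n <- nchar(s)
    if (n < 4L) return(NULL)
    ch <- strsplit(s, "")[[1L]]
    bad <- !ch %in% AA20
    if (any(bad)) {
      warning(sprintf("%s: %d non-standard residue(s) skipped", id,
                      sum(bad)), call. = FALSE)
    }
    starts <- seq_len(n - 3L)
    ok_win <- !(bad[starts] | bad[starts + 1L] | bad[starts + 2L] |
                  bad[starts + 3L])
    fwd <- ok_win & ch[starts] %in% psi_set & ch[starts + 1L] == "K" &
      ch[starts + 3L] %in% c("D", "E")
    res <- if (any(fwd)) {
      i <- starts[fwd]
      data.frame(protein = id, k_pos = i + 1L, start = i, end = i + 3L,
                 tetrapeptide = substring(s, i, i + 3L),
                 motif = "forward", stringsAsFactors = FALSE)
    } else NULL
    if (inverted) {
      inv <- ok_win & ch[starts] %in% c("D", "E") &
        ch[starts + 2L] == "K" & ch[starts + 3L] %in% psi_set
      if (any(inv)) {
        i <- starts[inv]
        res <- rbind(res, data.frame(
          protein = id, k_pos = i + 2L, start = i, end = i + 3L,
          tetrapeptide = substring(s, i, i + 3L),
          motif = "inverted", stringsAsFactors = FALSE))
      }
    }
    res
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(protein = character(0), k_pos = integer(0),
                      start = integer(0), end = integer(0),
                      tetrapeptide = character(0), motif = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$protein, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$psi_set <- rep(psi_str, nrow(out))
  out
}

#' Simulate protein sequences seeded with SUMO-consensus motifs
#'
#' Generates random protein sequences and overwrites a Poisson-distributed
#' number of non-overlapping tetrapeptide windows per protein with
#' psi-K-X-[D/E] motifs.  The truth table records every consensus match in
#' the final sequences - seeded and spontaneous alike - so a scanner can
#' be checked for exact recovery.
#'
#' @param n Number of proteins.
#' @param motif_rate Expected number of seeded motifs per protein.
#' @param length Protein length (residues).
#' @param alphabet Residues used for the random background (default the 20
#'   standard amino acids; restrict to study spontaneous matches).
#' @param psi Hydrophobic set used both to build seeded motifs and to
#'   define the truth table.
#' @param seed RNG seed.
#' @return A list of class `protein_sim`: `sequences` (named character),
#'   `truth` (data frame in the format of [scan_sumo()]), `psi`, `config`.
#' @examples
#' sim <- simulate_proteins(3, motif_rate = 1, seed = 1)
#' sim$truth
#' @export
simulate_proteins <- function(n, motif_rate = 1, length = 300,
                              alphabet = AA20, psi = "AILMVFPC",
                              seed = NULL) {
  n <- check_count(n, "n")
  length <- check_count(length, "length")
  if (length < 4L) stop("proteins must be at least 4 residues",
                        call. = FALSE)
  if (motif_rate < 0) stop("motif_rate must be >= 0", call. = FALSE)
  psi_set <- unique(strsplit(paste(psi, collapse = ""), "")[[1L]])
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      ch <- sample(alphabet, length, replace = TRUE)
      k <- stats::rpois(1L, motif_rate)
      if (k > 0L) {
        taken <- integer(0)
        for (m in seq_len(k)) {
          # draw a start that does not overlap previously seeded motifs
          for (try in 1:50) {
            s <- sample.int(length - 3L, 1L)
            if (!any(abs(s - taken) < 4L)) { taken <- c(taken, s); break }
          }
        }
        for (s in taken) {
          ch[s:(s + 3L)] <- c(sample(psi_set, 1L),
                              "K",
                              sample(AA20, 1L),
                              sample(c("D", "E"), 1L))
        }
      }
      paste(ch, collapse = "")
    }, character(1L))
    names(seqs) <- sprintf("prot%03d", seq_len(n))
    # truth recorded by regex lookahead, independently of scan_sumo()
    pat <- sprintf("(?=[%s]K[A-Z][DE])", paste(psi_set, collapse = ""))
    truth <- do.call(rbind, lapply(names(seqs), function(id) {
      at <- gregexpr(pat, seqs[[id]], perl = TRUE)[[1L]]
      at <- at[at > 0L]
      if (length(at) == 0L) return(NULL)
      data.frame(protein = id, k_pos = at + 1L, start = at, end = at + 3L,
                 tetrapeptide = substring(seqs[[id]], at, at + 3L),
                 motif = "forward", stringsAsFactors = FALSE)
    }))
    if (is.null(truth)) {
      truth <- data.frame(protein = character(0), k_pos = integer(0),
                          start = integer(0), end = integer(0),
                          tetrapeptide = character(0), motif = character(0),
                          stringsAsFactors = FALSE)
    }
    truth$psi_set <- rep(paste(sort(psi_set), collapse = ""), nrow(truth))
    structure(list(sequences = seqs, truth = truth,
                   psi = paste(sort(psi_set), collapse = ""),
                   config = list(n = n, motif_rate = motif_rate,
                                 length = length, seed = seed)),
              class = "protein_sim")
  })
}

#' @export
print.protein_sim <- function(x, ...) {
  cat(sprintf("%d simulated protein(s) of %d aa; %d true motif site(s)\n",
              x$config$n, x$config$length, nrow(x$truth)))
  invisible(x)
}
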