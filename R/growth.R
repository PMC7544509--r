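#' Fruit shoulder index
#'
#' The shoulder index is the angle `theta = arctan((L1 - L2)/W)` in
#' degrees, quantifying the outgrowth of the fruit shoulders from the two
#' measured extents `L1`, `L2` and the width `W`.  Symmetric fruits
#' (`L1 = L2`) score 0; the index is positive when `L1 > L2` and odd under
#' swapping `L1` and `L2`.  Vectorised.
#'
#' @param L1,L2 Lengths of the two measured extents (same units).
#' @param W Fruit width (same units, strictly positive).
#' @return The shoulder index in degrees, in (-90, 90).
#' @examples
#' shoulder_index(5, 5, 2)  # 0
#' shoulder_index(4, 2, 2)  # 45
#' @export
shoulder_index <- function(L1, L2, W) {
  if (any(!is.finite(W)) || any(W <= 0)) {
    stop("W must be positive", call. = FALSE)
  }
  atan((L1 - L2) / W) * 180 / pi
}

#' Area of a simple polygon
#'
#' Shoelace formula, `|sum(x_i * y_{i+1} - x_{i+1} * y_i)| / 2`;
#' independent of vertex orientation and of rigid motions.
#'
#' @param polygon An n x 2 matrix of vertices (n >= 3), in order.
#' @return The enclosed area.
#' @export
polygon_area <- function(polygon) {
  p <- as.matrix(polygon)
  if (nrow(p) < 3L) stop("a polygon needs at least 3 vertices",
                         call. = FALSE)
  x <- p[, 1L]; y <- p[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# signed area (positive = counter-clockwise)
signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y) / 2
}

#' Fit the growth tensor of a tracked cell
#'
#' Least-squares affine map from the t0 vertices to the t1 vertices:
#' after centring both vertex sets, solves for the 2 x 2 matrix `A`
#' minimising the summed squared vertex displacement `||Y - X A'||^2`.
#' The principal stretches are the singular values of `A`; growth
#' anisotropy is their ratio `lambda1 / lambda2 >= 1` (or, with
#' `anisotropy_measure = "fractional"`, the normalised difference
#' `(lambda1 - lambda2)/(lambda1 + lambda2)`).  The cell area ratio is
#' computed from the polygon areas, not from `det(A)`, so merged or
#' divided outlines do not bias it.
#'
#' @param track A [cell_track()].
#' @param anisotropy_measure `"ratio"` (default) or `"fractional"`.
#' @return An object of class `growth_result`: `cell_id`, `parent_id`,
#'   `affine` (2 x 2), `translation`, `stretches` (`lambda1 >= lambda2`),
#'   `anisotropy`, `anisotropy_measure`, `area_ratio`, and `rms` (root
#'   mean square vertex residual of the fit).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' fit_growth(cell_track("c", "c", sq, sq * 2))
#' @export
fit_growth <- function(track, anisotropy_measure = c("ratio", "fractional")) {
  stopifnot(inherits(track, "cell_track"))
  anisotropy_measure <- match.arg(anisotropy_measure)
  X <- track$t0; Y <- track$t1
  if (nrow(X) < 3L) stop("need at least 3 corresponding vertices",
                         call. = FALSE)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  XtX <- crossprod(Xc)
  if (rcond(XtX) < 1e-12) {
    stop(sprintf("t0 vertices of cell %s are (nearly) collinear",
                 track$cell_id), call. = FALSE)
  }
  M <- solve(XtX, crossprod(Xc, Yc))   # Y ~ X %*% M
  A <- t(M)
  sv <- svd(A)$d
  anis <- if (anisotropy_measure == "ratio") sv[1L] / sv[2L] else
    (sv[1L] - sv[2L]) / (sv[1L] + sv[2L])
  resid <- Yc - Xc %*% M
  structure(list(
    cell_id = track$cell_id, parent_id = track$parent_id,
    affine = A,
    translation = as.numeric(attr(Yc, "scaled:center") -
                               A %*% attr(Xc, "scaled:center")),
    stretches = sv, anisotropy = anis,
    anisotropy_measure = anisotropy_measure,
    area_ratio = polygon_area(Y) / polygon_area(X),
    rms = sqrt(mean(rowSums(resid^2)))
  ), class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat(sprintf("Growth of cell %s: anisotropy %.4g (%s), area ratio %.4g, RMS %.3g\n",
              x$cell_id, x$anisotropy, x$anisotropy_measure, x$area_ratio,
              x$rms))
  invisible(x)
}

# stitch two polygons sharing one boundary chord; returns the row-index
# vectors into each polygon that build the union, or NULL if not adjacent
stitch_indices <- function(P, Q, tol = 1e-9) {
  key <- function(m) apply(round(m / tol) * tol, 1L, paste, collapse = ",")
  kP <- key(P); kQ <- key(Q)
  n <- nrow(P); m <- nrow(Q)
  for (i in seq_len(n)) {
    i2 <- if (i == n) 1L else i + 1L
    j <- match(kP[i2], kQ)          # chord traversed q -> p in Q
    if (is.na(j)) next
    j2 <- if (j == m) 1L else j + 1L
    if (kQ[j2] == kP[i]) {
      ia <- c(seq_len(n)[-seq_len(i)], seq_len(i))        # starts at i+1
      ib <- c(seq_len(m)[-seq_len(j)], seq_len(m)[seq_len(j)])
      return(list(a = ia, b = ib[-c(1L, m)]))
    }
  }
  NULL
}

#' Merge daughter cells back onto their parent outline
#'
#' Cells that divided between the time points are merged before growth is
#' measured: within each lineage (shared `parent_id`), daughter polygons
#' are united along their shared chord at both time points, rebuilding the
#' vertex correspondence on the outer boundary.  Lineages with a single
#' cell pass through unchanged.
#'
#' @param tracks A list of [cell_track()] objects (e.g. from
#'   [simulate_mesh()] or [read_cell_tracks()]).
#' @return A list of merged `cell_track` objects (class `cell_tracks`),
#'   one per lineage, carrying the parent id.
#' @export
merge_daughters <- function(tracks) {
  stopifnot(is.list(tracks), all(vapply(tracks, inherits, logical(1L),
                                        "cell_track")))
  parents <- vapply(tracks, `[[`, character(1L), "parent_id")
  out <- lapply(unique(parents), function(p) {
    group <- tracks[parents == p]
    if (length(group) == 1L) return(group[[1L]])
    # orient all daughters counter-clockwise (t0 and t1 together)
    group <- lapply(group, function(tr) {
      if (signed_area(tr$t0) < 0) {
        tr$t0 <- tr$t0[rev(seq_len(nrow(tr$t0))), , drop = FALSE]
        tr$t1 <- tr$t1[rev(seq_len(nrow(tr$t1))), , drop = FALSE]
      }
      tr
    })
    merged <- group[[1L]]
    for (tr in group[-1L]) {
      idx <- stitch_indices(merged$t0, tr$t0)
      if (is.null(idx)) {
        stop(sprintf("daughter cells of parent '%s' are not adjacent", p),
             call. = FALSE)
      }
      merged <- cell_track(
        p, p,
        rbind(merged$t0[idx$a, , drop = FALSE],
              tr$t0[idx$b, , drop = FALSE]),
        rbind(merged$t1[idx$a, , drop = FALSE],
              tr$t1[idx$b, , drop = FALSE]))
    }
    merged$cell_id <- p; merged$parent_id <- p
    merged
  })
  structure(out, class = "cell_tracks",
            true_anisotropy = attr(tracks, "true_anisotropy"),
            true_area_ratio = attr(tracks, "true_area_ratio"),
            config = attr(tracks, "config"))
}

#' Per-cell growth statistics for a set of tracks
#'
#' Convenience wrapper: optionally merges daughters ([merge_daughters()]),
#' fits every cell ([fit_growth()]) and returns a tidy table.
#'
#' @param tracks A list of [cell_track()] objects.
#' @param merge Merge daughters first (default `TRUE`).
#' @param anisotropy_measure Passed to [fit_growth()].
#' @return Data frame with `cell_id`, `parent_id`, `anisotropy`,
#'   `area_ratio`, `rms`.
#' @export
measure_growth <- function(tracks, merge = TRUE,
                           anisotropy_measure = c("ratio", "fractional")) {
  anisotropy_measure <- match.arg(anisotropy_measure)
  if (merge) tracks <- merge_daughters(tracks)
  fits <- lapply(tracks, fit_growth, anisotropy_measure = anisotropy_measure)
  data.frame(
    cell_id = vapply(fits, `[[`, character(1L), "cell_id"),
    parent_id = vapply(fits, `[[`, character(1L), "parent_id"),
    anisotropy = vapply(fits, `[[`, numeric(1L), "anisotropy"),
    area_ratio = vapply(fits, `[[`, numeric(1L), "area_ratio"),
    rms = vapply(fits, `[[`, numeric(1L), "rms"),
    stringsAsFactors = FALSE
  )
}

#' Render a per-cell growth heat map on the later time point
#'
#' Draws the t1 polygons filled by the chosen statistic and writes the
#' figure (`.png`, `.svg` or `.pdf` by file extension) together with a
#' sidecar TSV (`<file>.tsv`) recording the plotted value and colour per
#' cell, so figure content can be checked without parsing the image.
#' Values outside `bounds` are clipped to the scale ends and the clip
#' count is reported.
#'
#' @param tracks Cell tracks (merged or not; must match `results`).
#' @param results Data frame from [measure_growth()].
#' @param stat `"anisotropy"` or `"area_ratio"`.
#' @param file Output figure path.
#' @param bounds Optional `c(lo, hi)` colour-scale bounds; defaults to the
#'   data range.
#' @param palette Colour vector for the scale.
#' @return Invisibly, the sidecar data frame (`cell_id`, `value`,
#'   `clipped`, `color`).
#' @export
growth_heatmap <- function(tracks, results,
                           stat = c("anisotropy", "area_ratio"),
                           file, bounds = NULL,
                           palette = grDevices::hcl.colors(100, "viridis")) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  ids <- vapply(tracks, `[[`, character(1L), "cell_id")
  vals <- results[[stat]][match(ids, results$cell_id)]
  if (anyNA(vals)) stop("results missing for some tracked cells",
                        call. = FALSE)
  bounds <- bounds %||% range(vals)
  clipped <- vals < bounds[1L] | vals > bounds[2L]
  if (any(clipped)) {
    message(sum(clipped), " value(s) clipped to the colour-scale bounds")
  }
  v <- pmin(pmax(vals, bounds[1L]), bounds[2L])
  idx <- if (diff(bounds) > 0) {
    1L + floor((v - bounds[1L]) / diff(bounds) * (length(palette) - 1L))
  } else rep(1L, length(v))
  cols <- palette[idx]

  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = 900, height = 900),
         svg = grDevices::svg(file),
         pdf = grDevices::pdf(file),
         stop("unsupported figure format: ", ext, call. = FALSE))
  on.exit(grDevices::dev.off(), add = TRUE)
  allv <- do.call(rbind, lapply(tracks, `[[`, "t1"))
  graphics::plot(NA, xlim = range(allv[, 1L]), ylim = range(allv[, 2L]),
                 asp = 1, xlab = "x", ylab = "y",
                 main = sprintf("%s (t1)", stat))
  for (i in seq_along(tracks)) {
    graphics::polygon(tracks[[i]]$t1, col = cols[i], border = "grey20")
  }
  side <- data.frame(cell_id = ids, value = vals, clipped = clipped,
                     color = cols, stringsAsFactors = FALSE)
  utils::write.table(side, paste0(file, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(side)
}
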