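#' Configuration for a simulated deforming cell mesh
#'
#' A rectangular mesh of unit cells is deformed between two time points by
#' a uniform affine map with principal stretches `stretch_major` and
#' `stretch_minor` applied along axes rotated by `rotation` degrees, plus
#' isotropic Gaussian noise on each vertex.  Every cell therefore has a
#' known true growth anisotropy `stretch_major / stretch_minor` and true
#' area ratio `stretch_major * stretch_minor`.  Cells divide between the
#' time points with probability `division_prob`; daughters are split by a
#' mid-cell chord and share their parent's label.
#'
#' @param grid_shape Integer vector `c(rows, cols)` of the starting mesh.
#' @param n_cells Number of cells used (defaults to the whole grid).
#' @param stretch_major,stretch_minor Principal stretch factors
#'   (`stretch_major >= stretch_minor > 0`).
#' @param rotation Orientation of the major stretch axis, degrees.
#' @param vertex_noise_sd SD of the Gaussian positional noise added to each
#'   deformed vertex, in cell-side units (0.01 = 1% of cell size).
#' @param division_prob Per-cell division probability between time points.
#' @param seed RNG seed.
#' @return An object of class `mesh_config`.
#' @export
mesh_config <- function(grid_shape = c(10, 10), n_cells = NULL,
                        stretch_major = 1.8, stretch_minor = 1.2,
                        rotation = 0, vertex_noise_sd = 0.01,
                        division_prob = 0.1, seed = NULL) {
  stopifnot(length(grid_shape) == 2L)
  grid_shape <- c(check_count(grid_shape[1L], "rows"),
                  check_count(grid_shape[2L], "cols"))
  if (!(stretch_major >= stretch_minor && stretch_minor > 0)) {
    stop("need stretch_major >= stretch_minor > 0", call. = FALSE)
  }
  if (vertex_noise_sd < 0) stop("vertex_noise_sd must be >= 0",
                                call. = FALSE)
  n_max <- prod(grid_shape)
  n_cells <- if (is.null(n_cells)) n_max else check_count(n_cells, "n_cells")
  if (n_cells > n_max) stop("n_cells exceeds the grid", call. = FALSE)
  structure(list(grid_shape = grid_shape, n_cells = n_cells,
                 stretch_major = stretch_major,
                 stretch_minor = stretch_minor, rotation = rotation,
                 vertex_noise_sd = check_prob(vertex_noise_sd,
                                              "vertex_noise_sd",
                                              upper = Inf),
                 division_prob = check_prob(division_prob, "division_prob"),
                 seed = seed),
            class = "mesh_config")
}

#' A lineage-tracked cell between two time points
#'
#' @param cell_id Cell identifier at the later time point.
#' @param parent_id Lineage label shared by daughters of a division.
#' @param t0,t1 Vertex matrices (n x 2) at the earlier and later time
#'   point; rows correspond (positional vertex correspondence).
#' @return An object of class `cell_track`.
#' @export
cell_track <- function(cell_id, parent_id, t0, t1) {
  t0 <- as.matrix(t0); t1 <- as.matrix(t1)
  if (nrow(t0) < 3L || nrow(t1) < 3L) {
    stop("polygons need at least 3 vertices", call. = FALSE)
  }
  if (nrow(t0) != nrow(t1)) {
    stop("t0 and t1 must have corresponding vertices", call. = FALSE)
  }
  structure(list(cell_id = cell_id, parent_id = parent_id,
                 t0 = unname(t0), t1 = unname(t1)),
            class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("Cell %s (parent %s): %d vertices\n", x$cell_id, x$parent_id,
              nrow(x$t0)))
  invisible(x)
}

#' Simulate lineage-tracked cell polygons under a known deformation
#'
#' @param config A [mesh_config()].
#' @return A list of `cell_track` objects (class `cell_tracks`) with
#'   attributes `true_anisotropy`, `true_area_ratio` and `config`.  Noise
#'   is drawn per mesh vertex, so vertices shared between neighbouring
#'   cells (including division-chord endpoints) stay coincident at t1.
#' @examples
#' tracks <- simulate_mesh(mesh_config(grid_shape = c(3, 3), seed = 1))
#' length(tracks)
#' @export
simulate_mesh <- function(config = mesh_config()) {
  stopifnot(inherits(config, "mesh_config"))
  with_seed(config$seed, {
    rows <- config$grid_shape[1L]; cols <- config$grid_shape[2L]
    th <- config$rotation * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    A <- R %*% diag(c(config$stretch_major, config$stretch_minor)) %*% t(R)

    # per-vertex noise, keyed so shared vertices displace together
    noise_env <- new.env(parent = emptyenv())
    vnoise <- function(v) {
      key <- paste(sprintf("%.9f", v), collapse = ",")
      nz <- noise_env[[key]]
      if (is.null(nz)) {
        nz <- stats::rnorm(2L, 0, config$vertex_noise_sd)
        noise_env[[key]] <- nz
      }
      nz
    }
    deform <- function(poly) {
      out <- t(A %*% t(poly))
      if (config$vertex_noise_sd > 0) {
        out <- out + t(apply(poly, 1L, vnoise))
      }
      out
    }

    tracks <- list()
    k <- 0L
    for (r in seq_len(rows)) {
      for (cc in seq_len(cols)) {
        if (k >= config$n_cells) break
        k <- k + 1L
        id <- sprintf("c%02d_%02d", r, cc)
        x0 <- cc - 1; y0 <- r - 1
        square <- rbind(c(x0, y0), c(x0 + 1, y0),
                        c(x0 + 1, y0 + 1), c(x0, y0 + 1))
        if (stats::runif(1L) < config$division_prob) {
          if (stats::runif(1L) < 0.5) {       # vertical chord
            a <- rbind(c(x0, y0), c(x0 + 0.5, y0),
                       c(x0 + 0.5, y0 + 1), c(x0, y0 + 1))
            b <- rbind(c(x0 + 0.5, y0), c(x0 + 1, y0),
                       c(x0 + 1, y0 + 1), c(x0 + 0.5, y0 + 1))
          } else {                            # horizontal chord
            a <- rbind(c(x0, y0), c(x0 + 1, y0),
                       c(x0 + 1, y0 + 0.5), c(x0, y0 + 0.5))
            b <- rbind(c(x0, y0 + 0.5), c(x0 + 1, y0 + 0.5),
                       c(x0 + 1, y0 + 1), c(x0, y0 + 1))
          }
          tracks[[length(tracks) + 1L]] <-
            cell_track(paste0(id, "a"), id, a, deform(a))
          tracks[[length(tracks) + 1L]] <-
            cell_track(paste0(id, "b"), id, b, deform(b))
        } else {
          tracks[[length(tracks) + 1L]] <-
            cell_track(id, id, square, deform(square))
        }
      }
    }
    structure(tracks, class = "cell_tracks",
              true_anisotropy = config$stretch_major / config$stretch_minor,
              true_area_ratio = config$stretch_major * config$stretch_minor,
              config = config)
  })
}

#' @export
print.cell_tracks <- function(x, ...) {
  parents <- vapply(x, `[[`, character(1L), "parent_id")
  cat(sprintf("%d cell track(s) from %d lineage(s); true anisotropy %.3g, true area ratio %.3g\n",
              length(x), length(unique(parents)),
              attr(x, "true_anisotropy"), attr(x, "true_area_ratio")))
  invisible(x)
}
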