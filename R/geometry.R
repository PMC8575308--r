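# Periodic lattice geometry: a ring in one dimension, a torus in two.
# Grid-points are stored in a flat column-major order; in 2-D the first index
# (alpha) varies fastest.

#' Define a periodic lattice
#'
#' @param ndim 1 (ring) or 2 (torus).
#' @param extent positive integer per dimension: ring length `L`, or
#'   `c(Lx, Ly)` for a torus.
#' @param h lattice spacing (patch distance, default 1).
#' @return an object of class `grid_geometry`.
#' @export
#' @examples
#' grid_geometry(1, 50)       # ring of 50 patches
#' grid_geometry(2, c(8, 8))  # 8 x 8 torus
grid_geometry <- function(ndim = 1L, extent = 50L, h = 1) {
  ndim <- as.integer(ndim)
  if (!ndim %in% c(1L, 2L)) stop("`ndim` must be 1 or 2", call. = FALSE)
  extent <- as.integer(extent)
  if (length(extent) != ndim || any(is.na(extent)) || any(extent < 1)) {
    stop("`extent` must give one positive integer per dimension", call. = FALSE)
  }
  if (!is.numeric(h) || length(h) != 1L || h <= 0) {
    stop("`h` must be a single positive number", call. = FALSE)
  }
  structure(list(ndim = ndim, extent = extent, h = as.numeric(h)),
            class = "grid_geometry")
}

#' @export
format.grid_geometry <- function(x, ...) {
  if (x$ndim == 1L) {
    sprintf("ring L = %d", x$extent[1])
  } else {
    sprintf("torus %d x %d", x$extent[1], x$extent[2])
  }
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("Periodic lattice: %s (h = %g)\n", format(x), x$h))
  invisible(x)
}

#' Number of grid-points of a lattice
#' @param geometry a [grid_geometry()].
#' @return integer `M`, the product of the extents.
#' @export
n_points <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  as.integer(prod(geometry$extent))
}

#' Discrete periodic Laplacian
#'
#' Applies the standard three-point (ring) or five-point (torus) stencil with
#' periodic wrap, divided by `h^2`.  The 1-D stencil uses the same `h^2`
#' denominator as the 2-D one (the consistent second-difference
#' discretisation); with the default `h = 1` the distinction is moot.
#' Stencil rows sum to zero, so the output always sums to zero over the grid:
#' diffusion conserves totals.
#'
#' @param field numeric vector of length `M` (flat, column-major in 2-D) or,
#'   in 2-D, an `Lx` x `Ly` matrix.
#' @param geometry a [grid_geometry()].
#' @return numeric object of the same shape as `field`.
#' @export
#' @examples
#' g <- grid_geometry(1, 5)
#' discrete_laplacian(c(1, 0, 0, 0, 0), g) # c(-2, 1, 0, 0, 1)
discrete_laplacian <- function(field, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  M <- n_points(geometry)
  was_matrix <- is.matrix(field)
  if (geometry$ndim == 1L) {
    if (length(field) != M || was_matrix) {
      stop(sprintf("`field` must be a vector of length %d for this ring", M),
           call. = FALSE)
    }
    x <- as.numeric(field)
    L <- geometry$extent[1]
    up <- if (L == 1L) 1L else c(2:L, 1L)
    dn <- if (L == 1L) 1L else c(L, seq_len(L - 1L))
    out <- (x[up] + x[dn] - 2 * x) / geometry$h^2
    return(out)
  }
  Lx <- geometry$extent[1]
  Ly <- geometry$extent[2]
  if (was_matrix) {
    if (nrow(field) != Lx || ncol(field) != Ly) {
      stop(sprintf("`field` must be %d x %d for this torus", Lx, Ly),
           call. = FALSE)
    }
    m <- field
  } else {
    if (length(field) != M) {
      stop(sprintf("`field` must have %d grid-points", M), call. = FALSE)
    }
    m <- matrix(as.numeric(field), Lx, Ly)
  }
  shift <- function(mm, dr, dc) {
    ri <- ((seq_len(Lx) - 1L - dr) %% Lx) + 1L
    ci <- ((seq_len(Ly) - 1L - dc) %% Ly) + 1L
    mm[ri, ci, drop = FALSE]
  }
  lap <- (shift(m, 1, 0) + shift(m, -1, 0) + shift(m, 0, 1) + shift(m, 0, -1) -
            4 * m) / geometry$h^2
  if (was_matrix) lap else as.numeric(lap)
}
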