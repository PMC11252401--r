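#' Construct the unfolded hippocampal flatmap grid
#'
#' The flatmap is the 2D intrinsic coordinate system of the unfolded
#' hippocampus, shared across species: a regular lattice with an
#' anterior-posterior (long) axis and a distal-proximal (short) axis.
#' Vertices are stored in fixed row-major order (all distal-proximal columns
#' of the first anterior-posterior row, then the next row, and so on), and
#' carry bin-center coordinates in `[0, 1]`.
#'
#' Coordinate conventions: `ap_coord` runs from 0 (posterior, tail) to
#' 1 (anterior, head); `pd_coord` runs from 0 (distal, subicular end) to
#' 1 (proximal, dentate-gyrus end).
#'
#' @param n_ap Number of anterior-posterior rows (>= 2).
#' @param n_pd Number of distal-proximal columns (>= 2).
#' @return An object of class `flatmap_grid` with fields `n_ap`, `n_pd`,
#'   `n_vertices`, and per-vertex `ap_coord`, `pd_coord`.
#' @examples
#' g <- make_flatmap_grid(16, 8)
#' head(cbind(g$ap_coord, g$pd_coord))
#' @export
make_flatmap_grid <- function(n_ap, n_pd) {
  n_ap <- check_count(n_ap, "n_ap", min = 2L)
  n_pd <- check_count(n_pd, "n_pd", min = 2L)
  i <- rep(seq_len(n_ap) - 1L, each = n_pd)
  j <- rep(seq_len(n_pd) - 1L, times = n_ap)
  structure(
    list(
      n_ap = n_ap,
      n_pd = n_pd,
      n_vertices = n_ap * n_pd,
      ap_coord = (i + 0.5) / n_ap,
      pd_coord = (j + 0.5) / n_pd
    ),
    class = "flatmap_grid"
  )
}

#' @export
print.flatmap_grid <- function(x, ...) {
  cat(sprintf("<flatmap_grid> %d (AP) x %d (PD) = %d vertices\n",
              x$n_ap, x$n_pd, x$n_vertices))
  invisible(x)
}

#' Row-major vertex index on a flatmap grid
#'
#' @param grid A `flatmap_grid`.
#' @param i Zero-based anterior-posterior row index.
#' @param j Zero-based distal-proximal column index.
#' @return One-based vertex index into the grid's vertex order.
#' @export
flatmap_vertex_index <- function(grid, i, j) {
  stopifnot(inherits(grid, "flatmap_grid"))
  if (any(i < 0 | i >= grid$n_ap) || any(j < 0 | j >= grid$n_pd)) {
    stop_invalid("row/column index out of range")
  }
  as.integer(i * grid$n_pd + j + 1L)
}

#' Optional isotropic Gaussian smoothing on the flatmap grid
#'
#' Smooths a per-vertex map with a separable Gaussian kernel in grid units.
#' This mimics surface smoothing of functional data as a grid approximation;
#' it is off by default throughout the pipeline because physical (mm) kernel
#' widths are mesh-dependent.
#'
#' @param values Per-vertex values in grid row-major order (vector) or a
#'   vertices x time matrix.
#' @param grid A `flatmap_grid`.
#' @param sigma Kernel standard deviation in grid units; `0` returns the
#'   input unchanged.
#' @return Smoothed values with the same shape as the input.
#' @export
smooth_flatmap <- function(values, grid, sigma = 0) {
  stopifnot(inherits(grid, "flatmap_grid"))
  sigma <- check_scalar(sigma, "sigma", lower = 0)
  if (sigma == 0) return(values)
  vec_in <- is.null(dim(values))
  m <- if (vec_in) matrix(values, ncol = 1L) else values
  if (nrow(m) != grid$n_vertices) stop_invalid("values do not match the grid")
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(mat) {
    # reflect-pad so edges keep unit kernel mass
    n <- nrow(mat)
    idx <- c(rev(seq_len(half)), seq_len(n), n + 1L - rev(seq_len(half)))
    idx <- clip(idx, 1L, n)
    padded <- mat[idx, , drop = FALSE]
    out <- mat
    for (r in seq_len(n)) {
      rows <- padded[r:(r + 2L * half), , drop = FALSE]
      out[r, ] <- colSums(rows * k)
    }
    out
  }
  out <- m
  for (tcol in seq_len(ncol(m))) {
    img <- matrix(m[, tcol], nrow = grid$n_pd, ncol = grid$n_ap) # col-major = row-major grid
    img <- smooth_1d(img)          # along PD
    img <- t(smooth_1d(t(img)))    # along AP
    out[, tcol] <- as.vector(img)
  }
  if (vec_in) out[, 1L] else out
}
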