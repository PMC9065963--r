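#' Periodic spatial grid
#'
#' Defines a uniform grid on a periodic domain in one or two dimensions.
#' Coordinates run from 0 to `extent - spacing` along each axis; the point at
#' `extent` is identified with the origin. All model operators (convolution,
#' time integration, continuation) act on fields living on such grids.
#'
#' @param extent Domain length per axis in km (scalar, recycled across axes).
#' @param n Number of grid points per axis (scalar, recycled). Must be >= 8.
#' @param dimension 1 or 2.
#'
#' @return An object of class `spatial_grid`: a list with elements
#'   `dimension`, `extent`, `n`, `spacing` (all per-axis where relevant).
#' @examples
#' g <- spatial_grid(200, 512)
#' g2 <- spatial_grid(300, 256, dimension = 2)
#' @export
spatial_grid <- function(extent, n, dimension = 1) {
  if (!dimension %in% c(1, 2)) {
    stop("`dimension` must be 1 or 2", call. = FALSE)
  }
  extent <- rep_len(as.numeric(extent), dimension)
  n <- rep_len(as.integer(n), dimension)
  if (any(extent <= 0)) stop("`extent` must be positive", call. = FALSE)
  if (any(n < 8)) stop("`n` must be at least 8 points per axis", call. = FALSE)
  structure(
    list(dimension = dimension, extent = extent, n = n, spacing = extent / n),
    class = "spatial_grid"
  )
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf(
    "<spatial_grid> %d-D, extent %s km, %s points, spacing %s km\n",
    x$dimension,
    paste(format(x$extent), collapse = " x "),
    paste(x$n, collapse = " x "),
    paste(format(signif(x$spacing, 4)), collapse = " x ")
  ))
  invisible(x)
}

#' Grid coordinates
#'
#' @param grid A [spatial_grid()].
#' @return For 1-D, a numeric vector of coordinates; for 2-D, a list with
#'   elements `x` and `y`.
#' @export
grid_coords <- function(grid) {
  cs <- lapply(seq_len(grid$dimension), function(a) {
    seq(0, grid$extent[a] - grid$spacing[a], by = grid$spacing[a])
  })
  if (grid$dimension == 1) cs[[1]] else list(x = cs[[1]], y = cs[[2]])
}

# Angular wavenumbers (rad/km) in FFT order for one axis.
fft_wavenumbers <- function(n, extent) {
  2 * pi * c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / extent
}

#' Wavenumber magnitudes of a grid
#'
#' Angular wavenumbers (rad per km) at the discrete Fourier modes of the grid,
#' in FFT storage order. For 2-D grids the magnitude `sqrt(kx^2 + ky^2)` is
#' returned as a matrix.
#'
#' @param grid A [spatial_grid()].
#' @return Numeric vector (1-D) or matrix (2-D) of |k| values.
#' @export
grid_wavenumbers <- function(grid) {
  if (grid$dimension == 1) {
    abs(fft_wavenumbers(grid$n[1], grid$extent[1]))
  } else {
    kx <- fft_wavenumbers(grid$n[1], grid$extent[1])
    ky <- fft_wavenumbers(grid$n[2], grid$extent[2])
    sqrt(outer(kx^2, ky^2, "+"))
  }
}

# Minimum-image (periodic) displacement magnitudes between all grid points
# and the origin, in km. Used for radial binning of autocorrelations.
grid_min_image_dist <- function(grid) {
  axdist <- function(a) {
    i <- 0:(grid$n[a] - 1)
    pmin(i, grid$n[a] - i) * grid$spacing[a]
  }
  if (grid$dimension == 1) {
    axdist(1)
  } else {
    sqrt(outer(axdist(1)^2, axdist(2)^2, "+"))
  }
}

same_grid <- function(a, b) {
  a$dimension == b$dimension && all(a$n == b$n) &&
    all(abs(a$extent - b$extent) < 1e-9 * a$extent)
}
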