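#' Synthetic field generators
#'
#' Seeded generators for initial conditions and for validating the
#' length-scale estimators. All generators are deterministic given their
#' seed; negative draws in noise fields are truncated at zero (negatives are
#' vanishingly rare at the default mean/sd ratio) and the truncated fraction
#' is recorded in the `truncated_fraction` attribute.
#'
#' @name synthetic_fields
NULL

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' @describeIn synthetic_fields Gaussian i.i.d. noise field
#'   `p = mean + sd * N(0,1)`, truncated at zero.
#' @param grid A [spatial_grid()].
#' @param mean,sd Mean and standard deviation, persons/km^2.
#' @param seed Integer seed.
#' @return A population [scalar_field()].
#' @export
field_noise <- function(grid, mean = 8000, sd = 1000, seed = NULL) {
  v <- with_seed(seed, stats::rnorm(prod(grid$n), mean, sd))
  tf <- base::mean(v < 0)
  v[v < 0] <- 0
  if (grid$dimension == 2) v <- matrix(v, grid$n[1], grid$n[2])
  out <- scalar_field(v, grid)
  attr(out, "truncated_fraction") <- tf
  out
}

#' @describeIn synthetic_fields Superposition of cosine modes along x:
#'   `mean + sum_i amplitude_i cos(2 pi x / wavelength_i)`. Wavelengths are
#'   snapped to the nearest harmonic of the periodic extent (with a warning
#'   when the snap is material), so the field is exactly periodic.
#' @param wavelength Wavelengths, km (vectorized with `amplitude`).
#' @param amplitude Amplitudes, persons/km^2.
#' @export
field_cosine <- function(grid, mean = 10000, amplitude = 5000,
                         wavelength = 200 / 7) {
  m <- max(length(amplitude), length(wavelength))
  amplitude <- rep_len(amplitude, m)
  wavelength <- rep_len(wavelength, m)
  L <- grid$extent[1]
  harm <- L / wavelength
  snapped <- pmax(1, round(harm))
  if (any(abs(harm - snapped) > 1e-8)) {
    warning(sprintf(
      "wavelength(s) %s km not commensurate with the %g km periodic extent; snapped to %s km",
      paste(signif(wavelength[abs(harm - snapped) > 1e-8], 5), collapse = ", "), L,
      paste(signif((L / snapped)[abs(harm - snapped) > 1e-8], 5), collapse = ", ")),
      call. = FALSE)
  }
  x <- if (grid$dimension == 1) grid_coords(grid) else grid_coords(grid)$x
  v <- rep(mean, grid$n[1])
  for (i in seq_len(m)) {
    v <- v + amplitude[i] * cos(2 * pi * snapped[i] * x / L)
  }
  v[v < 0] <- 0
  if (grid$dimension == 2) v <- matrix(v, grid$n[1], grid$n[2])
  scalar_field(v, grid)
}

#' @describeIn synthetic_fields Square lattice of Gaussian "cities" with
#'   nearest-neighbour spacing `spacing` km: a planted pattern whose
#'   correlogram peaks at the spacing.
#' @param spacing Lattice spacing, km.
#' @param peak Peak density added by each city, persons/km^2.
#' @param width Gaussian city radius, km.
#' @param background Background density, persons/km^2.
#' @export
field_city_lattice <- function(grid, spacing = 45, peak = 10000, width = 6,
                               background = 1000) {
  if (grid$dimension != 2) stop("city lattice requires a 2-D grid", call. = FALSE)
  ncity <- pmax(1, round(grid$extent / spacing))
  sp <- grid$extent / ncity # snapped so the lattice tiles the periodic domain
  cs <- grid_coords(grid)
  v <- matrix(background, grid$n[1], grid$n[2])
  # separable Gaussian bumps on the periodic lattice
  bump1d <- function(coords, L, nc, s) {
    centers <- (seq_len(nc) - 0.5) * s
    rowSums(vapply(centers, function(c0) {
      d <- abs(coords - c0)
      d <- pmin(d, L - d)
      exp(-d^2 / (2 * width^2))
    }, numeric(length(coords))))
  }
  bx <- bump1d(cs$x, grid$extent[1], ncity[1], sp[1])
  by <- bump1d(cs$y, grid$extent[2], ncity[2], sp[2])
  v <- v + peak * outer(bx, by)
  scalar_field(v, grid)
}

#' @describeIn synthetic_fields Constant `value` on a random `fraction` of
#'   the grid cells, `background` elsewhere (seeded uniform cell selection).
#' @param fraction Fraction of cells seeded.
#' @param value Density on seeded cells, persons/km^2.
#' @export
field_random_patches <- function(grid, fraction = 0.1, value = 200,
                                 background = 0, seed = NULL) {
  n <- prod(grid$n)
  idx <- with_seed(seed, sample.int(n, size = round(fraction * n)))
  v <- rep(background, n)
  v[idx] <- value
  if (grid$dimension == 2) v <- matrix(v, grid$n[1], grid$n[2])
  scalar_field(v, grid)
}

#' Generate a field by name
#'
#' Dispatcher used by the run configuration: `generator` selects one of the
#' `field_*` generators and `args` supplies its parameters.
#'
#' @param grid A [spatial_grid()].
#' @param generator One of `"noise"`, `"cosine_modes"`, `"city_lattice"`,
#'   `"random_patches"`.
#' @param args Named list of generator arguments.
#' @return A [scalar_field()].
#' @export
generate_field <- function(grid, generator, args = list()) {
  fn <- switch(generator,
    noise = field_noise,
    cosine_modes = field_cosine,
    city_lattice = field_city_lattice,
    random_patches = field_random_patches,
    stop("unknown generator: ", generator, call. = FALSE)
  )
  do.call(fn, base::c(list(grid = grid), args))
}

#' Irregular point set with a planted spatial pattern
#'
#' Emulates census-area centroid data: `n` irregular point locations on a
#' rectangular extent, with population values drawn from a planted
#' city-lattice pattern (spacing `pattern_scale` km) plus noise. Useful for
#' validating the point-set path of [moran_correlogram()].
#'
#' @param n Number of points (>= 10).
#' @param extent Domain side length, km.
#' @param pattern_scale Planted inter-city spacing, km.
#' @param clustering In \[0, 1): fraction by which points are pulled toward
#'   the planted city centres (0 = uniform scatter).
#' @param noise_sd Value noise standard deviation, persons/km^2.
#' @param seed Integer seed.
#' @return Tibble with columns `x`, `y` (km) and `value` (persons/km^2).
#' @export
lsoa_like_points <- function(n, extent = 200, pattern_scale = 45,
                             clustering = 0.15, noise_sd = 500, seed = NULL) {
  if (n < 10) stop("need at least 10 points", call. = FALSE)
  with_seed(seed, {
    x <- stats::runif(n, 0, extent)
    y <- stats::runif(n, 0, extent)
    ncity <- max(1, round(extent / pattern_scale))
    sp <- extent / ncity
    centers <- (seq_len(ncity) - 0.5) * sp
    if (clustering > 0) {
      nearest <- function(u) centers[pmax(1, pmin(ncity, round(u / sp + 0.5)))]
      x <- x + clustering * (nearest(x) - x)
      y <- y + clustering * (nearest(y) - y)
    }
    # radial Gaussian bump around the nearest planted city centre
    ax <- function(u) {
      d <- abs(outer(u, centers, "-"))
      apply(pmin(d, extent - d), 1, min)
    }
    d2 <- ax(x)^2 + ax(y)^2
    value <- 1000 + 10000 * exp(-d2 / (2 * (pattern_scale / 6)^2)) +
      stats::rnorm(n, 0, noise_sd)
    tibble::tibble(x = x, y = y, value = pmax(value, 0))
  })
}
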