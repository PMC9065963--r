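#' Service carrying capacity sigma(P)
#'
#' The maximal service land fraction supportable by a (nonlocally weighted)
#' population density P: `sigma(P) = 1 - exp(-(P/lambda)^mu)`. It vanishes at
#' zero population, saturates at 1, and is sigmoidal for `mu > 1`: at low
#' population the fixed costs of a business barely pay off, then a tipping
#' point steepens the response, which finally levels off near saturation.
#'
#' @param P Nonlocal population density, persons/km^2; nonnegative,
#'   vectorized.
#' @param params A [model_params()] (only `lambda` and `mu` are used).
#' @return Capacity fraction values in \[0, 1).
#' @examples
#' service_capacity(20000, model_params()) # 1 - 1/e
#' @export
service_capacity <- function(P, params) {
  if (any(P < 0)) stop("population must be nonnegative", call. = FALSE)
  1 - exp(-(P / params$lambda)^params$mu)
}

#' Slope of the service carrying capacity
#'
#' `sigma'(p) = (mu/lambda) (p/lambda)^(mu-1) exp(-(p/lambda)^mu)`, in
#' km^2/person. Strictly positive for p > 0; zero at p = 0 when mu > 1.
#'
#' @inheritParams service_capacity
#' @param p Population density, persons/km^2; nonnegative, vectorized.
#' @return Derivative values, km^2/person.
#' @export
service_capacity_prime <- function(p, params) {
  if (any(p < 0)) stop("population must be nonnegative", call. = FALSE)
  u <- p / params$lambda
  (params$mu / params$lambda) * u^(params$mu - 1) * exp(-u^params$mu)
}

#' Residential attractiveness field
#'
#' `A = (w_p1 * s) (1 - s)`: a location is attractive if services are
#' available nearby (nonlocal average of s under the kernel w_p1) but not if
#' the location itself is saturated with services. When the preferred
#' distance `a_p > 0` the shifted-sum kernel is used, so peak attractiveness
#' sits a distance `a_p` away from service concentrations.
#'
#' @param s Service fraction field ([scalar_field()], values in \[0, 1\]).
#' @param params A [model_params()].
#' @return Attractiveness as a [scalar_field()] (role `"derived"`).
#' @export
attractiveness <- function(s, params) {
  stopifnot(inherits(s, "scalar_field"))
  if (min(s$values) < -1e-9 || max(s$values) > 1 + 1e-9) {
    stop("service fraction outside [0, 1]", call. = FALSE)
  }
  S <- convolve_periodic(s, kernel_w_p1(params, s$grid$dimension))
  scalar_field(S$values * (1 - s$values), s$grid, role = "derived")
}

#' Population movement rate dp/dt (movement only)
#'
#' The net migration rate: people move from y to x at a rate proportional to
#' the attractiveness of x, the population at y, and a kernel `w_p2` of the
#' distance moved. The antisymmetry of the exchange makes the spatial
#' integral of the output exactly zero (total population is conserved by
#' movement):
#' `dp/dt = D [ A (w_p2 * p) - p (w_p2 * A) ]`.
#'
#' @param p Population field.
#' @param s Service field on the same grid.
#' @param params A [model_params()].
#' @return Rate field, persons/km^2/yr.
#' @export
movement_rhs <- function(p, s, params) {
  stopifnot(inherits(p, "scalar_field"), inherits(s, "scalar_field"))
  if (!same_grid(p$grid, s$grid)) stop("fields on different grids", call. = FALSE)
  A <- attractiveness(s, params)
  wp2 <- kernel_w_p2(params, p$grid$dimension)
  conv_p <- convolve_periodic(p, wp2)
  conv_A <- convolve_periodic(A, wp2)
  scalar_field(
    params$D * (A$values * conv_p$values - p$values * conv_A$values),
    p$grid, role = "derived"
  )
}

#' Service dynamics ds/dt
#'
#' Base variant: `(f + g s)(sigma(P) - s)` with `P = w_s * p` — innovators
#' (rate f) and imitators (rate g s) close the gap between service provision
#' and its carrying capacity.
#'
#' Competition/growth variants: `(H(x) f + g s) x` with
#' `x = sigma(P) - (s + alpha1 p)`; residents take space away from services,
#' and the Heaviside gate `H` (convention `H(x) = 1` iff `x > 0`) switches
#' innovation off when there is no spare capacity, making s = 0 an invariant
#' lower bound.
#'
#' @inheritParams movement_rhs
#' @return Rate field, 1/yr.
#' @export
service_rhs <- function(p, s, params) {
  stopifnot(inherits(p, "scalar_field"), inherits(s, "scalar_field"))
  if (!same_grid(p$grid, s$grid)) stop("fields on different grids", call. = FALSE)
  validate_field(s)
  P <- convolve_periodic(p, kernel_w_s(params, p$grid$dimension))
  sig <- service_capacity(pmax(P$values, 0), params)
  out <- if (params$variant == "base") {
    (params$f + params$g * s$values) * (sig - s$values)
  } else {
    x <- sig - (s$values + params$alpha1 * p$values)
    ((x > 0) * params$f + params$g * s$values) * x
  }
  scalar_field(out, p$grid, role = "derived")
}

#' Population dynamics dp/dt
#'
#' Movement ([movement_rhs()]) plus, under the growth variant, logistic
#' growth with service crowding: `r p (1 - (p + alpha2 s)/c)`.
#'
#' @inheritParams movement_rhs
#' @return Rate field, persons/km^2/yr.
#' @export
population_rhs <- function(p, s, params) {
  out <- movement_rhs(p, s, params)
  if (params$variant == "growth") {
    out$values <- out$values +
      params$r * p$values * (1 - (p$values + params$alpha2 * s$values) / params$c)
  }
  out
}

## ---- fast internal RHS ----------------------------------------------------
## The integrator evaluates the RHS thousands of times; the packed-FFT core
## below computes all four convolutions with 5 FFTs by exploiting that the
## transforms of two real fields can be extracted from one complex FFT, and
## two real inverse transforms can share one inverse FFT.

# Precompute kernel transforms and index maps for a grid.
make_rhs_core <- function(params, grid) {
  km <- grid_wavenumbers(grid)
  pre <- list(
    what_p1 = kernel_hat(kernel_w_p1(params, grid$dimension), km),
    what_p2 = kernel_hat(kernel_w_p2(params, grid$dimension), km),
    what_s = kernel_hat(kernel_w_s(params, grid$dimension), km),
    n = prod(grid$n),
    rev1 = base::c(1L, if (grid$n[1] > 1) grid$n[1]:2L),
    rev2 = if (grid$dimension == 2) base::c(1L, grid$n[2]:2L) else NULL,
    params = params,
    grid = grid
  )
  pre
}

# dp/dt and ds/dt on raw arrays. Returns list(dp, ds).
rhs_core <- function(p, s, pre) {
  pm <- pre$params
  Z <- stats::fft(s + 1i * p)
  Zr <- if (is.null(pre$rev2)) Conj(Z[pre$rev1]) else Conj(Z[pre$rev1, pre$rev2])
  sh <- (Z + Zr) / 2
  ph <- (Z - Zr) / (2i)
  S <- Re(stats::fft(pre$what_p1 * sh, inverse = TRUE)) / pre$n
  A <- S * (1 - s)
  Ah <- stats::fft(A)
  Y <- stats::fft(pre$what_p2 * ph + 1i * (pre$what_s * ph), inverse = TRUE) / pre$n
  conv_p2_p <- Re(Y)
  P <- Im(Y)
  conv_p2_A <- Re(stats::fft(pre$what_p2 * Ah, inverse = TRUE)) / pre$n
  dp <- pm$D * (A * conv_p2_p - p * conv_p2_A)
  if (pm$variant == "growth") {
    dp <- dp + pm$r * p * (1 - (p + pm$alpha2 * s) / pm$c)
  }
  sig <- service_capacity(pmax(P, 0), pm)
  ds <- if (pm$variant == "base") {
    (pm$f + pm$g * s) * (sig - s)
  } else {
    x <- sig - (s + pm$alpha1 * p)
    ((x > 0) * pm$f + pm$g * s) * x
  }
  list(dp = dp, ds = ds)
}
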