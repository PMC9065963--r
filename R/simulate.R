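#' Integrate the coupled population-service dynamics
#'
#' Advances the fields (p, s) in time on a periodic grid under the selected
#' model variant. Two integrators are available: an adaptive embedded
#' Runge-Kutta pair (`"ode45"`, via deSolve; the nonlocal terms are nonstiff
#' at the default rates, all of order <= 2 per year) and a fixed-step
#' classical RK4 (`"rk4"`), which is the faster choice for large 2-D runs and
#' serves as a cross-check on the adaptive path.
#'
#' Total population is conserved exactly (to roundoff) by the movement
#' operator for the base and competition variants; the conserved-mass trace
#' is recorded with each snapshot. Field bounds (p >= 0, s in \[0, 1\]) are
#' enforced: overshoot within `invariant_tol` (relative) is clipped,
#' anything larger raises an integration error.
#'
#' Time-varying parameters are supported through `schedule`, a data frame
#' with columns `time`, `parameter`, `value`; each named parameter follows
#' the piecewise-linear interpolant of its (time, value) pairs (constant
#' beyond the first/last knot). Kernel transforms are rebuilt whenever the
#' schedule is active.
#'
#' @param params A [model_params()].
#' @param p0 Initial population [scalar_field()].
#' @param s0 Initial service [scalar_field()]; default
#'   `sigma(w_s * p0)`, the local capacity of the smoothed population.
#' @param t_end Final time, years.
#' @param dt_out Snapshot interval, years (default `t_end / 10`).
#' @param method `"ode45"` or `"rk4"`.
#' @param dt Fixed step for `"rk4"`, years.
#' @param rtol,atol Tolerances for `"ode45"`.
#' @param schedule Optional data frame (`time`, `parameter`, `value`).
#' @param invariant_tol Relative bound-overshoot tolerance.
#' @return An object of class `state_history`: list with `times`, `p` and `s`
#'   (lists of [scalar_field()]s), `mass` (mean population per snapshot),
#'   `params`, `grid`, `method`.
#' @examples
#' g <- spatial_grid(200, 64)
#' p0 <- field_noise(g, mean = 8000, sd = 1000, seed = 1)
#' h <- simulate_model(model_params(), p0, t_end = 5, method = "rk4", dt = 0.1)
#' dplyr::last(h$mass) - h$mass[1] # conserved
#' @export
simulate_model <- function(params, p0, s0 = NULL, t_end, dt_out = t_end / 10,
                           method = base::c("ode45", "rk4"), dt = 0.01,
                           rtol = 1e-6, atol = 1e-8, schedule = NULL,
                           invariant_tol = 1e-8) {
  method <- match.arg(method)
  stopifnot(inherits(params, "model_params"), inherits(p0, "scalar_field"))
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  grid <- p0$grid
  if (is.null(s0)) {
    P <- convolve_periodic(p0, kernel_w_s(params, grid$dimension))
    s0 <- scalar_field(service_capacity(pmax(P$values, 0), params), grid,
                       role = "service")
  }
  if (!same_grid(grid, s0$grid)) stop("p0 and s0 grids differ", call. = FALSE)
  validate_field(p0); validate_field(s0)

  param_fun <- make_param_fun(params, schedule)
  times <- seq(0, t_end, by = dt_out)
  if (dplyr::last(times) < t_end) times <- base::c(times, t_end)

  if (method == "rk4") {
    out <- integrate_rk4(param_fun, grid, p0$values, s0$values, times, dt,
                         invariant_tol, static = is.null(schedule))
  } else {
    out <- integrate_ode45(param_fun, grid, p0$values, s0$values, times,
                           rtol, atol, invariant_tol, static = is.null(schedule))
  }
  structure(list(
    times = times,
    p = lapply(out$p, scalar_field, grid = grid, role = "population"),
    s = lapply(out$s, scalar_field, grid = grid, role = "service"),
    mass = vapply(out$p, mean, numeric(1)),
    params = params, grid = grid,
    method = list(method = method, dt = dt, rtol = rtol, atol = atol)
  ), class = "state_history")
}

make_param_fun <- function(params, schedule) {
  if (is.null(schedule)) return(function(t) params)
  schedule <- as.data.frame(schedule)
  need <- base::c("time", "parameter", "value")
  if (!all(need %in% names(schedule))) {
    stop("`schedule` needs columns time, parameter, value", call. = FALSE)
  }
  known <- setdiff(names(unclass(params)), "variant")
  bad <- setdiff(unique(schedule$parameter), known)
  if (length(bad)) {
    stop("schedule refers to unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  interps <- lapply(split(schedule, schedule$parameter), function(d) {
    if (nrow(d) == 1) {
      local({v <- d$value; function(t) v})
    } else {
      stats::approxfun(d$time, d$value, rule = 2)
    }
  })
  function(t) {
    ov <- lapply(interps, function(f) f(t))
    update_params(params, ov)
  }
}

# Enforce p >= 0, s in [0, 1]: clip small overshoot, error on blow-up.
enforce_bounds <- function(p, s, tol) {
  pscale <- max(abs(p), 1)
  if (min(p) < -tol * pscale || min(s) < -tol || max(s) > 1 + tol) {
    stop("integration violated field bounds beyond tolerance ",
         "(blow-up; reduce dt or tighten tolerances)", call. = FALSE)
  }
  p[p < 0] <- 0
  s[s < 0] <- 0
  s[s > 1] <- 1
  list(p = p, s = s)
}

integrate_rk4 <- function(param_fun, grid, p, s, times, dt, invariant_tol,
                          static) {
  pre <- make_rhs_core(param_fun(times[1]), grid)
  core <- function(t, p, s) {
    if (!static) pre <- make_rhs_core(param_fun(t), grid)
    rhs_core(p, s, pre)
  }
  psnaps <- list(p); ssnaps <- list(s)
  t <- times[1]
  for (i in seq_along(times)[-1]) {
    target <- times[i]
    while (t < target - 1e-12) {
      h <- min(dt, target - t)
      k1 <- core(t, p, s)
      k2 <- core(t + h / 2, p + h / 2 * k1$dp, s + h / 2 * k1$ds)
      k3 <- core(t + h / 2, p + h / 2 * k2$dp, s + h / 2 * k2$ds)
      k4 <- core(t + h, p + h * k3$dp, s + h * k3$ds)
      p <- p + h / 6 * (k1$dp + 2 * k2$dp + 2 * k3$dp + k4$dp)
      s <- s + h / 6 * (k1$ds + 2 * k2$ds + 2 * k3$ds + k4$ds)
      b <- enforce_bounds(p, s, invariant_tol)
      p <- b$p; s <- b$s
      t <- t + h
    }
    psnaps[[i]] <- p; ssnaps[[i]] <- s
  }
  list(p = psnaps, s = ssnaps)
}

integrate_ode45 <- function(param_fun, grid, p, s, times, rtol, atol,
                            invariant_tol, static) {
  n <- prod(grid$n)
  pre <- make_rhs_core(param_fun(times[1]), grid)
  shape <- function(v) {
    if (grid$dimension == 2) matrix(v, grid$n[1], grid$n[2]) else v
  }
  func <- function(t, y, parms) {
    if (!static) pre <- make_rhs_core(param_fun(t), grid)
    d <- rhs_core(shape(y[1:n]), shape(y[(n + 1):(2 * n)]), pre)
    list(base::c(as.vector(d$dp), as.vector(d$ds)))
  }
  sol <- deSolve::ode(y = base::c(as.vector(p), as.vector(s)), times = times,
                      func = func, parms = NULL, method = "ode45",
                      rtol = rtol, atol = atol)
  psnaps <- list(); ssnaps <- list()
  for (i in seq_along(times)) {
    b <- enforce_bounds(shape(sol[i, 2:(n + 1)]),
                        shape(sol[i, (n + 2):(2 * n + 1)]), invariant_tol)
    psnaps[[i]] <- b$p; ssnaps[[i]] <- b$s
  }
  list(p = psnaps, s = ssnaps)
}

#' @export
print.state_history <- function(x, ...) {
  cat(sprintf("<state_history> %s variant, %d snapshots over %g yr, %d-D grid (%s)\n",
              x$params$variant, length(x$times), dplyr::last(x$times),
              x$grid$dimension, paste(x$grid$n, collapse = "x")))
  cat(sprintf("  mean population: %.6g -> %.6g pe/km2\n",
              x$mass[1], dplyr::last(x$mass)))
  invisible(x)
}

#' Final fields of a simulation
#' @param history A `state_history` from [simulate_model()].
#' @return List with [scalar_field()]s `p` and `s`.
#' @export
final_state <- function(history) {
  n <- length(history$times)
  list(p = history$p[[n]], s = history$s[[n]])
}

#' Metastable multi-bump scenario
#'
#' One-dimensional base-model run started on a seven-bump cosine
#' (`p(x,0) = 10000 + 5000 cos(7 pi x / 100)` on a 200 km domain, with
#' `s(x,0) = sigma(p(x,0))`). The seven-bump steady state is metastable: it
#' persists for centuries before coarsening into fewer, larger bumps; the
#' transition itself occurs on millennial timescales, so long horizons must
#' be requested explicitly via `t_end`.
#'
#' @param params A base-variant [model_params()].
#' @param t_end Horizon in years (default 300; the coarsening transition
#'   needs far longer).
#' @param n Grid points (default 512 on 200 km).
#' @param ... Passed to [simulate_model()].
#' @return A `state_history`.
#' @export
scenario_metastable <- function(params = model_params(), t_end = 300,
                                n = 512, ...) {
  grid <- spatial_grid(200, n)
  x <- grid_coords(grid)
  p0 <- scalar_field(10000 + 5000 * cos(7 * pi * x / 100), grid)
  s0 <- scalar_field(service_capacity(p0$values, params), grid,
                     role = "service")
  simulate_model(params, p0, s0, t_end = t_end, method = "rk4", dt = 0.05, ...)
}

#' Two-dimensional growth scenario
#'
#' Growth-variant run from a sparse seed: `p0 = 200` on a random 10% of the
#' grid cells (seeded), zero elsewhere. Population first grows
#' quasi-uniformly toward carrying capacity, then city-scale clusters form,
#' and finally short-wavelength out-of-phase structure (service cores ringed
#' by population) appears within clusters.
#'
#' @param seed Integer seed for the initial cell selection.
#' @param params A growth-variant [model_params()].
#' @param t_end Horizon, years.
#' @param extent,n Grid specification (km, points per axis).
#' @param dt RK4 step, years.
#' @param ... Passed to [simulate_model()].
#' @return A `state_history`.
#' @export
scenario_growth_2d <- function(seed, params = model_params("growth"),
                               t_end = 250, extent = 300, n = 256,
                               dt = 0.1, ...) {
  grid <- spatial_grid(extent, n, dimension = 2)
  p0 <- field_random_patches(grid, fraction = 0.1, value = 200, seed = seed)
  simulate_model(params, p0, t_end = t_end, method = "rk4", dt = dt, ...)
}

#' @export
as_tibble.state_history <- function(x, ...) {
  purrr::map_dfr(seq_along(x$times), function(i) {
    d <- as_tibble(x$p[[i]])
    d$s <- as.vector(x$s[[i]]$values)
    names(d)[names(d) == "value"] <- "p"
    d$time <- x$times[i]
    d
  })
}

#' Plot simulation snapshots
#' @param object A `state_history`.
#' @param which `"p"` or `"s"`.
#' @param ... Unused.
#' @return A ggplot object faceted by snapshot time.
#' @export
autoplot.state_history <- function(object, which = base::c("p", "s"), ...) {
  which <- match.arg(which)
  d <- as_tibble(object)
  d$value <- d[[which]]
  if (object$grid$dimension == 1) {
    ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$value, group = .data$time,
                                    colour = .data$time)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "x (km)", y = which, colour = "t (yr)")
  } else {
    ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::facet_wrap(~time) +
      ggplot2::scale_fill_viridis_c(name = which) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (km)", y = "y (km)")
  }
}
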