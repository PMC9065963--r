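#' Homogeneous steady state
#'
#' Spatially constant fixed point (p0, s0) of the selected variant.
#' \describe{
#'   \item{base}{p0 = pbar (set by the conserved mean population),
#'     s0 = sigma(p0).}
#'   \item{competition}{p0 = pbar; s0 = sigma(p0) - alpha1 p0 when positive,
#'     otherwise the services-extinct branch s0 = 0 (competition for space
#'     starves services of demand).}
#'   \item{growth}{`pbar` is ignored: p0 solves
#'     p0 + alpha2 max(0, sigma(p0) - alpha1 p0) = c, with
#'     s0 = max(0, sigma(p0) - alpha1 p0).}
#' }
#'
#' @param params A [model_params()].
#' @param pbar Mean population density, persons/km^2 (base/competition).
#' @return An object of class `homogeneous_state`: list with `p0`, `s0`,
#'   `variant`, and logical `extinct` (s0 = 0 branch with strictly negative
#'   capacity deficit).
#' @examples
#' homogeneous_state(model_params(), pbar = 8000)
#' homogeneous_state(model_params("growth"))
#' @export
homogeneous_state <- function(params, pbar = NULL) {
  if (params$variant != "growth") {
    if (is.null(pbar) || pbar <= 0) {
      stop("`pbar` must be a positive mean population density", call. = FALSE)
    }
    p0 <- pbar
  } else {
    fn <- function(p) {
      p + params$alpha2 * max(0, service_capacity(p, params) -
                                params$alpha1 * p) - params$c
    }
    upper <- params$c * (1 + params$alpha2 / params$c) + params$alpha2
    if (fn(1e-12) > 0 || fn(upper) < 0) {
      stop("no homogeneous steady state found for the growth variant in ",
           "(0, c + alpha2]", call. = FALSE)
    }
    p0 <- stats::uniroot(fn, base::c(1e-12, upper), tol = 1e-12)$root
    # polish: uniroot tol is on x; tighten by a few Newton-free bisections
    lo <- p0 * (1 - 1e-6); hi <- p0 * (1 + 1e-6)
    if (fn(lo) < 0 && fn(hi) > 0) {
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (fn(mid) < 0) lo <- mid else hi <- mid
      }
      p0 <- (lo + hi) / 2
    }
  }
  raw <- service_capacity(p0, params) - params$alpha1 * p0
  s0 <- max(0, raw)
  structure(list(p0 = p0, s0 = s0, variant = params$variant,
                 extinct = raw <= 0 && params$variant != "base"),
            class = "homogeneous_state")
}

#' @export
print.homogeneous_state <- function(x, ...) {
  cat(sprintf("<homogeneous_state> %s: p0=%.6g pe/km2, s0=%.6g%s\n",
              x$variant, x$p0, x$s0, if (x$extinct) " (services extinct)" else ""))
  invisible(x)
}

#' Per-wavenumber stability matrix J(k)
#'
#' The 2x2 matrix governing the linear growth of a sinusoidal perturbation
#' `(p, s) = (p0, s0) + eps (pc, sc) exp(i k x)` about the homogeneous state.
#' Entries (base/competition, with `alpha1 = 0` for base):
#' \preformatted{
#' J11 = -D s0 (1 - s0) (1 - w_hat_p2(k))
#' J12 =  D p0 (1 - w_hat_p2(k)) ((1 - s0) w_hat_p1(k) - s0)
#' J21 =  (f + g s0) (sigma'(p0) w_hat_s(k) - alpha1)
#' J22 = -(f + g s0)
#' }
#' The growth variant subtracts `r p0 / c` from J11 and `r alpha2 p0 / c`
#' from J12. On the services-extinct competition branch (s0 = 0 with a
#' strict capacity deficit) the Heaviside gate shuts innovation, so the
#' second row becomes `(0, g (sigma(p0) - alpha1 p0))`.
#'
#' @param state A [homogeneous_state()].
#' @param params The [model_params()] that produced it.
#' @param k Angular wavenumber, rad/km (scalar).
#' @return A 2x2 numeric matrix.
#' @export
stability_matrix <- function(state, params, k) {
  p0 <- state$p0; s0 <- state$s0
  wp1 <- kernel_hat(kernel_w_p1(params), k)
  wp2 <- kernel_hat(kernel_w_p2(params), k)
  ws <- kernel_hat(kernel_w_s(params), k)
  J11 <- -params$D * s0 * (1 - s0) * (1 - wp2)
  J12 <- params$D * p0 * (1 - wp2) * ((1 - s0) * wp1 - s0)
  if (params$variant == "growth") {
    J11 <- J11 - params$r * p0 / params$c
    J12 <- J12 - params$r * params$alpha2 * p0 / params$c
  }
  if (isTRUE(state$extinct)) {
    J21 <- 0
    J22 <- params$g * (service_capacity(p0, params) - params$alpha1 * p0)
  } else {
    fg <- params$f + params$g * s0
    J21 <- fg * (service_capacity_prime(p0, params) * ws - params$alpha1)
    J22 <- -fg
  }
  matrix(base::c(J11, J21, J12, J22), 2, 2)
}

# Leading eigenvalue and phase label of a 2x2 stability matrix.
# Returns c(growth, phase_code): 1 in_phase, -1 out_of_phase, 0 neutral,
# 2 oscillatory.
leading_mode <- function(J, tol = 1e-12) {
  tr <- J[1, 1] + J[2, 2]
  det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- tr^2 - 4 * det
  if (disc < 0) {
    return(base::c(tr / 2, 2))
  }
  lam <- (tr + sqrt(disc)) / 2
  # eigenvector from the better-conditioned row
  if (abs(J[1, 2]) >= abs(J[2, 1])) {
    v <- base::c(J[1, 2], lam - J[1, 1])
  } else {
    v <- base::c(lam - J[2, 2], J[2, 1])
  }
  scale <- max(abs(v))
  phase <- if (scale == 0 || min(abs(v)) / scale < tol) {
    0
  } else if (prod(sign(v)) > 0) 1 else -1
  base::c(lam, phase)
}

phase_labels <- base::c("-1" = "out_of_phase", "0" = "neutral",
                        "1" = "in_phase", "2" = "oscillatory")

#' Dispersion relation
#'
#' Leading linear growth rate Re lambda+(k) of sinusoidal perturbations about
#' the homogeneous state, over a grid of angular wavenumbers, with each mode
#' classified by the sign structure of its eigenvector: population and
#' service perturbations growing together (`in_phase`), in opposition
#' (`out_of_phase`), a complex leading pair (`oscillatory`), or an
#' eigenvector with a vanishing component (`neutral`).
#'
#' @param params A [model_params()].
#' @param pbar Mean population density (ignored for the growth variant).
#' @param k Positive, sorted angular wavenumbers, rad/km. Default: 512 points
#'   on (0, 3], covering both the ~0.1 rad/km city scale and the
#'   ~1.2-1.6 rad/km out-of-phase scale.
#' @return An object of class `dispersion_relation`: list with `curve`
#'   (tibble: k, wavelength, growth_rate, phase), `dominant` (list: k, rate,
#'   wavelength, phase — parabolically refined local maximum; NULL if no
#'   unstable mode), `state`, `params`.
#' @examples
#' d <- dispersion_relation(model_params(), pbar = 8000)
#' glance(d)
#' @export
dispersion_relation <- function(params, pbar = NULL,
                                k = seq(3 / 512, 3, length.out = 512)) {
  if (!length(k)) stop("empty wavenumber grid", call. = FALSE)
  if (any(k <= 0) || is.unsorted(k)) {
    stop("`k` must be positive and sorted", call. = FALSE)
  }
  state <- homogeneous_state(params, pbar)
  modes <- vapply(k, function(kk) leading_mode(stability_matrix(state, params, kk)),
                  numeric(2))
  growth <- modes[1, ]
  phase <- unname(phase_labels[as.character(modes[2, ])])
  curve <- tibble::tibble(k = k, wavelength = 2 * pi / k,
                          growth_rate = growth, phase = phase)
  dominant <- NULL
  i <- which.max(growth)
  if (growth[i] > 0) {
    ks <- k[i]; gs <- growth[i]
    if (i > 1 && i < length(k)) {
      # parabolic refinement through the three points around the maximum
      y <- growth[(i - 1):(i + 1)]; xk <- k[(i - 1):(i + 1)]
      denom <- (y[1] - 2 * y[2] + y[3])
      if (denom < 0) {
        ks <- xk[2] - 0.5 * (xk[3] - xk[1]) / 2 * (y[3] - y[1]) / denom
        gs <- max(gs, y[2] - (y[3] - y[1])^2 / (8 * denom))
      }
    }
    dominant <- list(k = ks, rate = gs, wavelength = 2 * pi / ks,
                     phase = phase[i])
  }
  structure(list(curve = curve, dominant = dominant, state = state,
                 params = params, pbar = state$p0),
            class = "dispersion_relation")
}

#' @export
print.dispersion_relation <- function(x, ...) {
  cat(sprintf("<dispersion_relation> %s variant, p0=%.5g, s0=%.5g\n",
              x$params$variant, x$state$p0, x$state$s0))
  if (is.null(x$dominant)) {
    cat("  no unstable modes\n")
  } else {
    cat(sprintf("  dominant mode: k*=%.4g rad/km (wavelength %.3g km), rate %.4g 1/yr, %s\n",
                x$dominant$k, x$dominant$wavelength, x$dominant$rate,
                x$dominant$phase))
  }
  invisible(x)
}

#' Contiguous unstable wavenumber bands
#'
#' Splits the positive-growth part of a dispersion relation into contiguous
#' bands and reports the peak of each — used to read off the coexisting
#' in-phase (city-scale) and out-of-phase (within-city) instabilities of the
#' competition model.
#'
#' @param disp A [dispersion_relation()].
#' @return Tibble with one row per band: `k_lo`, `k_hi`, `k_peak`,
#'   `wavelength`, `growth_rate`, `phase` (phase at the band peak).
#' @export
unstable_bands <- function(disp) {
  cv <- disp$curve
  un <- cv$growth_rate > 0
  if (!any(un)) {
    return(tibble::tibble(k_lo = numeric(), k_hi = numeric(),
                          k_peak = numeric(), wavelength = numeric(),
                          growth_rate = numeric(), phase = character()))
  }
  id <- cumsum(base::c(1, diff(un) != 0))
  bands <- split(seq_along(un)[un], id[un])
  purrr::map_dfr(bands, function(ix) {
    pk <- ix[which.max(cv$growth_rate[ix])]
    tibble::tibble(k_lo = cv$k[min(ix)], k_hi = cv$k[max(ix)],
                   k_peak = cv$k[pk], wavelength = cv$wavelength[pk],
                   growth_rate = cv$growth_rate[pk], phase = cv$phase[pk])
  })
}

#' Analytic instability condition (base variant)
#'
#' The homogeneous state of the base model is unstable to some spatial
#' perturbation if and only if
#' `s0 (1 - s0) / (p0 sigma'(p0)) + s0 < 1 - s0`.
#' Instability then occurs exactly in a window (0, k_c): only sufficiently
#' long wavelengths destabilize.
#'
#' @param params A base-variant [model_params()].
#' @param pbar Mean population density.
#' @return Logical.
#' @export
is_pattern_unstable <- function(params, pbar) {
  if (params$variant != "base") {
    stop("the closed-form instability condition applies to the base variant",
         call. = FALSE)
  }
  st <- homogeneous_state(params, pbar)
  s0 <- st$s0
  s0 * (1 - s0) / (st$p0 * service_capacity_prime(st$p0, params)) + s0 <
    1 - s0
}

#' Critical wavenumber k_c (base variant)
#'
#' Upper edge of the unstable window (0, k_c): the wavenumber at which the
#' determinant of J(k) changes sign, found by bracketed root search.
#'
#' @inheritParams is_pattern_unstable
#' @param k_max Upper end of the initial search bracket, rad/km.
#' @return k_c in rad/km.
#' @export
critical_wavenumber <- function(params, pbar, k_max = 10) {
  if (!is_pattern_unstable(params, pbar)) {
    stop("homogeneous state is stable: no unstable window", call. = FALSE)
  }
  st <- homogeneous_state(params, pbar)
  detJ <- function(k) det(stability_matrix(st, params, k))
  lo <- 1e-8
  if (detJ(lo) >= 0) {
    # det -> 0 as k -> 0; step inward until inside the unstable window
    lo <- 1e-4
    while (detJ(lo) >= 0 && lo < k_max) lo <- lo * 2
  }
  hi <- lo * 2
  while (detJ(hi) < 0 && hi < k_max) hi <- hi * 2
  if (detJ(hi) < 0) stop("no sign change up to k_max", call. = FALSE)
  stats::uniroot(detJ, base::c(lo, hi), tol = 1e-12)$root
}

#' Turing bifurcation point of the base model
#'
#' Where the instability condition holds with equality. For the capacity
#' function `sigma(P) = 1 - exp(-(P/lambda)^mu)` the bifurcation value of s0
#' solves `s0 = mu (2 s0 - 1) ln(1 - s0)`, which has a root in (0, 1/2) for
#' `mu > 1`; the population scale follows by inverting sigma:
#' `p0 = lambda (-ln(1 - s0))^(1/mu)`. States with p0 above this value are
#' stable to all spatial perturbations; below it a window of long
#' wavelengths is unstable.
#'
#' @param params A [model_params()] (only `mu` and `lambda` are used).
#' @return List with `s0` and `p0` at the bifurcation.
#' @examples
#' bifurcation_point(model_params()) # s0 ~ 0.366, p0 ~ 15 400
#' @export
bifurcation_point <- function(params) {
  mu <- params$mu
  if (mu <= 1) {
    stop(if (mu < 1) "`mu` must be >= 1" else
      "mu = 1 is degenerate: the bifurcation root collapses to s0 = 0",
      call. = FALSE)
  }
  h <- function(s) s - mu * (2 * s - 1) * log(1 - s)
  lo <- 1e-8; hi <- 0.5 - 1e-12
  if (h(lo) >= 0) stop("no bifurcation root bracketed", call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (h(mid) < 0) lo <- mid else hi <- mid
  }
  s0 <- (lo + hi) / 2
  p0 <- params$lambda * (-log(1 - s0))^(1 / mu)
  list(s0 = s0, p0 = p0)
}

#' Critical population for service survival under competition
#'
#' Smallest positive population density at which demand matches the space
#' taken by residents: the first root of `sigma(p) = alpha1 p`. Below it the
#' competition model's homogeneous state has no services (s0 = 0).
#'
#' @param params A competition- or growth-variant [model_params()].
#' @return Threshold population density, persons/km^2.
#' @examples
#' competition_threshold(model_params("competition")) # ~ 11 500
#' @export
competition_threshold <- function(params) {
  if (params$alpha1 <= 0) {
    stop("requires alpha1 > 0 (competition or growth variant)", call. = FALSE)
  }
  fn <- function(p) service_capacity(p, params) - params$alpha1 * p
  # scan upward for the first sign change (sigma - alpha1 p < 0 near 0 for mu > 1)
  ps <- seq(1, 10 * params$lambda, length.out = 4096)
  v <- fn(ps)
  i <- which(v[-1] > 0 & v[-length(v)] <= 0)[1]
  if (is.na(i)) stop("services never viable: sigma(p) < alpha1 p everywhere",
                     call. = FALSE)
  stats::uniroot(fn, base::c(ps[i], ps[i + 1]), tol = 1e-10)$root
}

#' Linear phase diagram over (alpha1, a_p)
#'
#' Classifies each cell of a competition-parameter grid by the dispersion
#' relation at the homogeneous state: `stable` (no unstable mode),
#' `in_phase` / `out_of_phase` (phase of the dominant unstable mode), or
#' `services_extinct` (sigma(p0) <= alpha1 p0, so the homogeneous state has
#' no services).
#'
#' @param params A [model_params()] providing all other parameter values.
#' @param pbar Mean population density at which to classify.
#' @param alpha1 Vector of competition values, km^2/person.
#' @param a_p Vector of preferred-distance values, km.
#' @param k Wavenumber grid passed to [dispersion_relation()].
#' @return Tibble with columns `alpha1`, `a_p`, `label`, `k_peak`,
#'   `growth_rate`.
#' @export
phase_diagram <- function(params, pbar, alpha1, a_p,
                          k = seq(3 / 256, 3, length.out = 256)) {
  base_args <- unclass(params)
  base_args$variant <- "competition"
  cells <- tidyr::expand_grid(alpha1 = alpha1, a_p = a_p)
  res <- purrr::pmap_dfr(cells, function(alpha1, a_p) {
    args <- base_args
    args$alpha1 <- alpha1
    args$a_p <- a_p
    pm <- do.call(model_params, args)
    st <- homogeneous_state(pm, pbar)
    if (st$extinct || st$s0 == 0) {
      return(tibble::tibble(label = "services_extinct",
                            k_peak = NA_real_, growth_rate = NA_real_))
    }
    d <- dispersion_relation(pm, pbar, k)
    if (is.null(d$dominant)) {
      tibble::tibble(label = "stable", k_peak = NA_real_, growth_rate = NA_real_)
    } else {
      tibble::tibble(label = d$dominant$phase, k_peak = d$dominant$k,
                     growth_rate = d$dominant$rate)
    }
  })
  dplyr::bind_cols(cells, res)
}
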