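#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dispersion relation
#'
#' @param x A [dispersion_relation()].
#' @param ... Unused.
#' @return Tibble with columns `k`, `wavelength`, `growth_rate`, `phase`.
#' @export
tidy.dispersion_relation <- function(x, ...) x$curve

#' One-row summary of a dispersion relation
#'
#' @param x A [dispersion_relation()].
#' @param ... Unused.
#' @return Tibble with `p0`, `s0`, `unstable` (any positive growth),
#'   `k_star`, `max_growth_rate`, `dominant_wavelength`, `dominant_phase`,
#'   `n_bands`.
#' @export
glance.dispersion_relation <- function(x, ...) {
  bands <- unstable_bands(x)
  tibble::tibble(
    p0 = x$state$p0, s0 = x$state$s0,
    unstable = !is.null(x$dominant),
    k_star = if (is.null(x$dominant)) NA_real_ else x$dominant$k,
    max_growth_rate = if (is.null(x$dominant)) max(x$curve$growth_rate)
      else x$dominant$rate,
    dominant_wavelength = if (is.null(x$dominant)) NA_real_
      else x$dominant$wavelength,
    dominant_phase = if (is.null(x$dominant)) NA_character_
      else x$dominant$phase,
    n_bands = nrow(bands)
  )
}

#' @export
as_tibble.dispersion_relation <- function(x, ...) x$curve

#' Plot a dispersion relation
#' @param object A [dispersion_relation()].
#' @param ... Unused.
#' @return A ggplot of growth rate against wavenumber, coloured by phase.
#' @export
autoplot.dispersion_relation <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$k, .data$growth_rate,
                               colour = .data$phase, group = 1)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavenumber k (rad/km)", y = "growth rate (1/yr)")
}

#' Tidy a continuation branch
#' @param x A `continuation_branch`.
#' @param ... Unused.
#' @return The branch points tibble.
#' @export
tidy.continuation_branch <- function(x, ...) x$points

#' One-row summary of a continuation branch
#' @param x A `continuation_branch`.
#' @param ... Unused.
#' @return Tibble with `n_points`, `pbar_min`, `pbar_max`,
#'   `max_stable_pbar`, `n_stable`.
#' @export
glance.continuation_branch <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x$points),
    pbar_min = min(x$points$pbar),
    pbar_max = max(x$points$pbar),
    max_stable_pbar = if (any(x$points$stable)) max_stable_pbar(x) else NA_real_,
    n_stable = sum(x$points$stable)
  )
}

#' Tidy a correlogram
#' @param x A `correlogram`.
#' @param ... Unused.
#' @return The curve tibble.
#' @export
tidy.correlogram <- function(x, ...) x$curve

#' One-row summary of a correlogram
#' @param x A `correlogram`.
#' @param ... Passed to [dominant_length()].
#' @return Tibble with `n_bins`, `bin_width`, `dominant_length`, `n_peaks`.
#' @export
glance.correlogram <- function(x, ...) {
  est <- dominant_length(x, ...)
  tibble::tibble(n_bins = nrow(x$curve), bin_width = x$bin_width,
                 dominant_length = est$dominant_length,
                 n_peaks = nrow(est$peaks))
}

#' Tidy a simulation history
#' @param x A `state_history`.
#' @param ... Unused.
#' @return Long tibble with coordinates, `p`, `s` and `time`.
#' @export
tidy.state_history <- function(x, ...) as_tibble(x)

#' One-row summary of a simulation history
#' @param x A `state_history`.
#' @param ... Unused.
#' @return Tibble with `t_end`, `n_snapshots`, initial and final mean
#'   population, relative mass drift, and final field ranges.
#' @export
glance.state_history <- function(x, ...) {
  fin <- final_state(x)
  tibble::tibble(
    t_end = dplyr::last(x$times),
    n_snapshots = length(x$times),
    mass_initial = x$mass[1],
    mass_final = dplyr::last(x$mass),
    mass_drift = abs(dplyr::last(x$mass) - x$mass[1]) / x$mass[1],
    p_max = max(fin$p$values),
    s_max = max(fin$s$values)
  )
}
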