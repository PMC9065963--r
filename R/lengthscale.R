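#' Distance-binned Moran correlogram
#'
#' Spatial autocorrelation as a function of separation distance: for each
#' distance bin `[d, d + bin_width)` the classic Moran's I is computed with
#' binary weights `w_ij = 1` iff the pair (i, j) falls in the bin:
#' \deqn{I = \frac{N}{\sum_{ij} w_{ij}}
#'   \frac{\sum_{ij} w_{ij} (x_i - \bar x)(x_j - \bar x)}{\sum_i (x_i - \bar x)^2}.}
#' The first prominent peak of I(d) estimates the dominant inter-cluster
#' length scale (see [dominant_length()]).
#'
#' Two input paths share this interface:
#' \itemize{
#'   \item a data frame of irregular points (columns `x`, `y`, `value`; or
#'     `x`, `value` for 1-D), using direct pair enumeration with Euclidean
#'     distances;
#'   \item a [scalar_field()] on a periodic grid, where pair enumeration is
#'     replaced by an FFT autocorrelation binned by minimum-image radius
#'     (identical to pair enumeration with periodic distances, at a fraction
#'     of the cost). Set `periodic = FALSE` to treat the grid centres as an
#'     ordinary point set instead.
#' }
#'
#' @param x A [scalar_field()] or a data frame of points.
#' @param bin_width Bin width, km (the default 1 km matches grouping
#'   centroid pairs as 0-1 km, 1-2 km, ...).
#' @param max_distance Largest separation considered, km. Defaults to half
#'   the domain extent (gridded) or half the maximum pair distance (points).
#' @param ... Passed to methods.
#' @return An object of class `correlogram`: tibble-backed curve with columns
#'   `distance` (bin centre, km), `moran_i`, `n_pairs` (ordered pairs; bins
#'   with none give `NA`).
#' @examples
#' g <- spatial_grid(200, 64)
#' f <- field_cosine(g, mean = 0, amplitude = 1, wavelength = 50)
#' cg <- moran_correlogram(f, bin_width = 2)
#' dominant_length(cg)
#' @export
moran_correlogram <- function(x, bin_width = 1, max_distance = NULL, ...) {
  UseMethod("moran_correlogram")
}

new_correlogram <- function(distance, moran_i, n_pairs, bin_width, method) {
  structure(list(
    curve = tibble::tibble(distance = distance, moran_i = moran_i,
                           n_pairs = n_pairs),
    bin_width = bin_width, method = method
  ), class = "correlogram")
}

#' @rdname moran_correlogram
#' @param periodic Use the FFT minimum-image path (gridded input only).
#' @export
moran_correlogram.scalar_field <- function(x, bin_width = 1,
                                           max_distance = NULL,
                                           periodic = TRUE, ...) {
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  grid <- x$grid
  if (is.null(max_distance)) max_distance <- min(grid$extent) / 2
  if (max_distance > min(grid$extent) / 2 + 1e-9) {
    stop("`max_distance` must not exceed half the domain extent", call. = FALSE)
  }
  if (!periodic) {
    d <- as_tibble(x)
    if (grid$dimension == 1) d$y <- NULL
    return(moran_correlogram(d, bin_width, max_distance))
  }
  z <- x$values - mean(x$values)
  ss <- sum(z^2)
  if (ss == 0) stop("field has zero variance", call. = FALSE)
  n <- prod(grid$n)
  # circular autocorrelation: C(offset) = sum_i z_i z_{i+offset}
  C <- Re(stats::fft(abs(stats::fft(z))^2, inverse = TRUE)) / n
  dist <- grid_min_image_dist(grid)
  keep <- dist > 0 & dist < max_distance
  bin <- floor(dist[keep] / bin_width)
  S <- rowsum(as.vector(C[keep]), bin)
  cnt <- rowsum(rep(1, sum(keep)), bin)
  bins <- as.integer(rownames(S))
  full <- seq(0, max(bins))
  moran <- rep(NA_real_, length(full))
  npairs <- rep(0, length(full))
  moran[bins + 1] <- S[, 1] / (cnt[, 1] * ss)
  npairs[bins + 1] <- cnt[, 1] * n
  new_correlogram((full + 0.5) * bin_width, moran, npairs, bin_width,
                  "fft_periodic")
}

#' @rdname moran_correlogram
#' @export
moran_correlogram.data.frame <- function(x, bin_width = 1,
                                         max_distance = NULL, ...) {
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  if (!"value" %in% names(x) || !"x" %in% names(x)) {
    stop("point input needs columns x (and optionally y) and value",
         call. = FALSE)
  }
  if (nrow(x) < 3) stop("need at least 3 points", call. = FALSE)
  z <- x$value - mean(x$value)
  ss <- sum(z^2)
  if (ss == 0) stop("point values have zero variance", call. = FALSE)
  coords <- if ("y" %in% names(x)) cbind(x$x, x$y) else cbind(x$x)
  dmat <- as.matrix(stats::dist(coords))
  if (is.null(max_distance)) max_distance <- max(dmat) / 2
  n <- nrow(x)
  keep <- upper.tri(dmat) & dmat < max_distance
  bin <- floor(dmat[keep] / bin_width)
  zz <- tcrossprod(z)[keep]
  S <- rowsum(zz, bin)
  cnt <- rowsum(rep(1, length(bin)), bin)
  bins <- as.integer(rownames(S))
  full <- seq(0, max(bins))
  moran <- rep(NA_real_, length(full))
  npairs <- rep(0, length(full))
  # ordered pairs: double the upper triangle
  moran[bins + 1] <- n * (2 * S[, 1]) / ((2 * cnt[, 1]) * ss)
  npairs[bins + 1] <- 2 * cnt[, 1]
  new_correlogram((full + 0.5) * bin_width, moran, npairs, bin_width, "pairs")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> %d bins of %g km (%s)\n", nrow(x$curve),
              x$bin_width, x$method))
  print(x$curve, n = 5)
  invisible(x)
}

#' @export
as_tibble.correlogram <- function(x, ...) x$curve

#' Plot a Moran correlogram
#' @param object A `correlogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlogram <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$distance, .data$moran_i)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "separation distance (km)", y = "Moran's I")
}

#' Dominant length from a correlogram
#'
#' Location of the first local maximum of I(d) beyond `min_distance` whose
#' prominence (height above the higher of the bracketing minima) reaches
#' `prominence`. The short-range self-correlation decay is excluded by
#' `min_distance`; the peak location is refined by parabolic interpolation
#' across the adjacent bins. Additional qualifying peaks are reported as
#' secondary.
#'
#' @param curve A `correlogram` (or its curve tibble with columns `distance`,
#'   `moran_i`).
#' @param min_distance Smallest distance searched, km.
#' @param prominence Minimum peak prominence, in I units.
#' @return An object of class `length_scale_estimate`: list with
#'   `dominant_length` (km; `NA` if no qualifying peak), `peaks` (tibble:
#'   `distance`, `refined`, `moran_i`, `prominence`), `method`, `curve`.
#' @export
dominant_length <- function(curve, min_distance = 5, prominence = 0.02) {
  cv <- if (inherits(curve, "correlogram")) curve$curve else
    tibble::as_tibble(curve)
  ok <- is.finite(cv$moran_i)
  d <- cv$distance[ok]
  v <- cv$moran_i[ok]
  if (sum(d > min_distance) < 3) {
    stop("need at least 3 bins beyond `min_distance`", call. = FALSE)
  }
  m <- length(v)
  peaks <- tibble::tibble(distance = numeric(), refined = numeric(),
                          moran_i = numeric(), prominence = numeric())
  if (m >= 3) {
    for (i in 2:(m - 1)) {
      if (d[i] <= min_distance) next
      if (v[i] > v[i - 1] && v[i] >= v[i + 1]) {
        # prominence: drop to the lowest point before re-reaching this height
        left <- v[seq_len(i - 1)]
        jl <- rev(which(left >= v[i]))
        lmin <- min(left[seq(if (length(jl)) jl[1] else 1, i - 1)])
        right <- v[seq(i + 1, m)]
        jr <- which(right >= v[i])
        rmin <- min(right[seq_len(if (length(jr)) jr[1] else length(right))])
        prom <- v[i] - max(lmin, rmin)
        if (prom >= prominence) {
          refined <- d[i]
          denom <- v[i - 1] - 2 * v[i] + v[i + 1]
          if (denom < 0) {
            refined <- d[i] - 0.5 * (d[i + 1] - d[i - 1]) / 2 *
              (v[i + 1] - v[i - 1]) / denom
          }
          peaks <- dplyr::bind_rows(peaks, tibble::tibble(
            distance = d[i], refined = refined, moran_i = v[i],
            prominence = prom))
        }
      }
    }
  }
  structure(list(
    dominant_length = if (nrow(peaks)) peaks$refined[1] else NA_real_,
    peaks = peaks, method = "moran",
    curve = cv
  ), class = "length_scale_estimate")
}

#' @export
print.length_scale_estimate <- function(x, ...) {
  if (is.na(x$dominant_length)) {
    cat("<length_scale_estimate> no qualifying peak\n")
  } else {
    cat(sprintf("<length_scale_estimate> dominant length %.4g km (%s)\n",
                x$dominant_length, x$method))
    if (nrow(x$peaks) > 1) {
      cat("  secondary peaks at:",
          paste(signif(x$peaks$refined[-1], 4), collapse = ", "), "km\n")
    }
  }
  invisible(x)
}

#' Power spectrum of a transect
#'
#' Discrete Fourier analysis of a uniformly sampled line through a
#' population field: the mean-removed series is decomposed into sinusoids
#' and the squared transform magnitude is reported per wavelength
#' (`wavelength = line length / harmonic`). The dominant wavelength is the
#' power argmax; it is flagged prominent when the peak power exceeds
#' `prominence_factor` times the mean spectral power, which white noise
#' essentially never attains.
#'
#' @param values Numeric vector of at least 16 uniformly spaced samples.
#' @param spacing Sample spacing, km.
#' @param prominence_factor Peak-to-mean power ratio required to call the
#'   dominant wavelength prominent.
#' @return An object of class `power_spectrum`: list with `curve` (tibble:
#'   `harmonic`, `wavelength`, `power`), `dominant_wavelength`, `prominent`.
#' @examples
#' x <- seq(0, 199, by = 1)
#' ps <- transect_power_spectrum(cos(2 * pi * x / 50), spacing = 1)
#' ps$dominant_wavelength # 50
#' @export
transect_power_spectrum <- function(values, spacing,
                                    prominence_factor = 10) {
  if (length(values) < 16) stop("need at least 16 samples", call. = FALSE)
  if (spacing <= 0) stop("`spacing` must be positive", call. = FALSE)
  z <- values - mean(values)
  if (all(z == 0)) stop("constant series has no spectrum", call. = FALSE)
  n <- length(z)
  hmax <- n %/% 2
  power <- Mod(stats::fft(z))[2:(hmax + 1)]^2
  wavelength <- n * spacing / seq_len(hmax)
  i <- which.max(power)
  structure(list(
    curve = tibble::tibble(harmonic = seq_len(hmax), wavelength = wavelength,
                           power = power),
    dominant_wavelength = wavelength[i],
    prominent = power[i] > prominence_factor * mean(power)
  ), class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> dominant wavelength %.4g km (%sprominent)\n",
              x$dominant_wavelength, if (x$prominent) "" else "not "))
  invisible(x)
}

#' @export
as_tibble.power_spectrum <- function(x, ...) x$curve

#' Plot a transect power spectrum
#' @param object A `power_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_spectrum <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$wavelength, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "wavelength (km)", y = "power")
}
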