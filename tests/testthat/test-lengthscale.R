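test_that("correlogram of a 1-D cosine tracks cos(k d)", {
  g <- spatial_grid(180, 180)
  f <- field_cosine(g, mean = 100, amplitude = 10, wavelength = 45)
  cg <- moran_correlogram(f, bin_width = 1, max_distance = 90)
  est <- dominant_length(cg)
  expect_equal(est$dominant_length, 45, tolerance = 1 / 45)
  # first trough near half the wavelength
  cv <- cg$curve
  trough <- cv$distance[which.min(cv$moran_i[cv$distance < 30])]
  expect_equal(trough, 22.5, tolerance = 0.1)
})

test_that("FFT periodic correlogram matches brute-force pair enumeration", {
  g <- spatial_grid(40, 16, dimension = 2)
  set.seed(23)
  v <- matrix(rnorm(256, 50, 10), 16, 16)
  f <- scalar_field(v, g, role = "derived")
  cg <- moran_correlogram(f, bin_width = 2, max_distance = 20)

  # oracle: explicit double loop over cell pairs with min-image distances
  cs <- grid_coords(g)
  xx <- rep(cs$x, times = 16); yy <- rep(cs$y, each = 16)
  z <- as.vector(v) - mean(v)
  n <- length(z)
  num <- den <- numeric(nrow(cg$curve))
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    dx <- min(abs(xx[i] - xx[j]), 40 - abs(xx[i] - xx[j]))
    dy <- min(abs(yy[i] - yy[j]), 40 - abs(yy[i] - yy[j]))
    d <- sqrt(dx^2 + dy^2)
    if (d >= 20) next
    b <- floor(d / 2) + 1
    num[b] <- num[b] + z[i] * z[j]
    den[b] <- den[b] + 1
  }
  oracle <- n * (num / den) / sum(z^2)
  ok <- den > 0
  expect_equal(cg$curve$moran_i[ok], oracle[ok], tolerance = 1e-10)
  expect_equal(cg$curve$n_pairs[ok], den[ok])
})

test_that("iid noise shows no spatial autocorrelation beyond sampling error", {
  g <- spatial_grid(100, 48, dimension = 2)
  f <- field_noise(g, mean = 1000, sd = 100, seed = 99)
  cg <- moran_correlogram(f, bin_width = 1)
  cv <- cg$curve[cg$curve$n_pairs > 0, ]
  expect_true(all(abs(cv$moran_i) < 3 / sqrt(cv$n_pairs / 2) + 1 / prod(g$n)))
  expect_true(is.na(dominant_length(cg)$dominant_length))
})

test_that("Moran's I is invariant under affine value transforms", {
  g <- spatial_grid(60, 24, dimension = 2)
  f <- field_city_lattice(g, spacing = 20, peak = 500, width = 3,
                          background = 50)
  c1 <- moran_correlogram(f, bin_width = 2)
  f2 <- scalar_field(-3.5 * f$values + 777, g, role = "derived")
  c2 <- moran_correlogram(f2, bin_width = 2)
  expect_equal(c1$curve$moran_i, c2$curve$moran_i, tolerance = 1e-12)
})

test_that("field and point-set paths agree when the field is read as points", {
  g <- spatial_grid(60, 16, dimension = 2)
  f <- field_city_lattice(g, spacing = 30, peak = 800, width = 4,
                          background = 10)
  via_field <- moran_correlogram(f, bin_width = 3, max_distance = 25,
                                 periodic = FALSE)
  pts <- as_tibble(f)
  via_points <- moran_correlogram(pts, bin_width = 3, max_distance = 25)
  expect_equal(via_field$curve$moran_i, via_points$curve$moran_i,
               tolerance = 1e-12)
})

test_that("dominant_length picks the first prominent peak and lists secondary", {
  d <- seq(0.5, 80.5, by = 1)
  curve <- tibble::tibble(
    distance = d,
    moran_i = 0.3 * exp(-(d - 43)^2 / 18) + 0.2 * exp(-(d - 58)^2 / 18)
  )
  est <- dominant_length(curve)
  expect_equal(est$dominant_length, 43, tolerance = 0.1)
  expect_gte(nrow(est$peaks), 2)
  expect_equal(est$peaks$refined[2], 58, tolerance = 0.15)

  flat <- tibble::tibble(distance = seq(0.5, 40.5, 1),
                         moran_i = exp(-seq(0.5, 40.5, 1) / 10))
  expect_true(is.na(dominant_length(flat)$dominant_length))

  single <- tibble::tibble(distance = c(10, 20, 30, 40, 45, 50, 60),
                           moran_i = c(-0.2, -0.1, 0, 0.15, 0.2, 0.15, 0))
  expect_equal(dominant_length(single)$dominant_length, 45, tolerance = 1)
})

test_that("transect spectrum finds planted wavelengths and flags noise", {
  x <- seq(0, 199)
  ps <- transect_power_spectrum(cos(2 * pi * x / 50), spacing = 1)
  expect_equal(ps$dominant_wavelength, 50)
  expect_true(ps$prominent)

  two <- 2 * cos(2 * pi * x / 40) + 1 * cos(2 * pi * x / 20)
  ps2 <- transect_power_spectrum(two, spacing = 1)
  expect_equal(ps2$dominant_wavelength, 40)

  # white noise: dominant peak essentially never prominent
  flagged <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    transect_power_spectrum(rnorm(256), spacing = 1)$prominent
  }, logical(1))
  expect_lte(sum(flagged), 5)

  expect_error(transect_power_spectrum(rep(1, 32), 1), "constant")
  expect_error(transect_power_spectrum(rnorm(8), 1), "16")
})

test_that("planted length scales are recovered by both estimators", {
  # 180 km domain is commensurate with all three planted wavelengths
  for (L in c(20, 45, 60)) {
    hits_m <- hits_f <- 0
    nseed <- 20
    for (sd in seq_len(nseed)) {
      gl <- spatial_grid(180, 180)
      f <- field_cosine(gl, mean = 1000, amplitude = 400, wavelength = L)
      set.seed(sd)
      noisy <- scalar_field(pmax(f$values + rnorm(180, 0, 100), 0), gl)
      est <- dominant_length(moran_correlogram(noisy, bin_width = 1),
                             min_distance = 5)
      if (!is.na(est$dominant_length) &&
          abs(est$dominant_length - L) <= 1.5) hits_m <- hits_m + 1
      ps <- transect_power_spectrum(noisy$values, spacing = 1)
      # within one harmonic of the planted mode
      harm <- 180 / L
      if (abs(ps$dominant_wavelength - L) <=
          180 / (harm - 1) - L + 1e-9) hits_f <- hits_f + 1
    }
    expect_gte(hits_m / nseed, 0.95)
    expect_gte(hits_f / nseed, 0.95)
  }
})

test_that("degenerate inputs raise explicit errors", {
  g <- spatial_grid(50, 16, dimension = 2)
  flat <- scalar_field(matrix(5, 16, 16), g, role = "derived")
  expect_error(moran_correlogram(flat), "zero variance")
  expect_error(moran_correlogram(flat, bin_width = 1, max_distance = 100),
               "half the domain")
  pts <- tibble::tibble(x = runif(20), y = runif(20), value = 1)
  expect_error(moran_correlogram(pts), "zero variance")
})
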