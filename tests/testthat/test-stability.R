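test_that("homogeneous states satisfy their defining equations", {
  pm <- params_base()
  st <- homogeneous_state(pm, pbar = 8000)
  expect_equal(st$s0, 1 - exp(-0.4^3), tolerance = 1e-12)
  expect_equal(st$s0, 0.06199, tolerance = 1e-3)

  # below the competition threshold services go extinct
  pmc <- params_comp()
  stc <- homogeneous_state(pmc, pbar = 5000)
  expect_equal(stc$s0, 0)
  expect_true(stc$extinct)
  st2 <- homogeneous_state(pmc, pbar = 14000)
  expect_equal(st2$s0,
               service_capacity(14000, pmc) - pmc$alpha1 * 14000,
               tolerance = 1e-12)

  # choosing c = p0 + alpha2 s0 keeps the competition state under growth
  pmg <- params_growth(c = st2$p0 + 1e5 * st2$s0)
  stg <- homogeneous_state(pmg)
  expect_equal(stg$p0, st2$p0, tolerance = 1e-8)
  expect_equal(stg$s0, st2$s0, tolerance = 1e-8)

  expect_error(homogeneous_state(pm), "pbar")
})

test_that("stability matrix at k = 0 has the neutral mass mode (base)", {
  pm <- params_base()
  st <- homogeneous_state(pm, 8000)
  J <- stability_matrix(st, pm, 0)
  ev <- sort(Re(eigen(J)$values))
  expect_equal(ev[2], 0, tolerance = 1e-14)
  expect_equal(ev[1], -(pm$f + pm$g * st$s0), tolerance = 1e-12)
})

test_that("analytic Jacobian matches mode-projected finite differences", {
  g <- grid_1d(n = 128)
  ks <- 2 * pi * c(3, 10, 30) / g$extent[1]
  cases <- list(
    list(pm = params_base(), pbar = 8000),
    list(pm = params_comp(), pbar = 13000),
    list(pm = params_growth(), pbar = NULL)
  )
  for (cs in cases) {
    st <- homogeneous_state(cs$pm, cs$pbar)
    # expand on the smooth supply-deficit branch (see helper); evaluate the
    # analytic matrix at the same expansion point
    st_eval <- st
    if (cs$pm$variant != "base") st_eval$s0 <- st$s0 - 1e-4
    for (k in ks) {
      Ja <- stability_matrix(st_eval, cs$pm, k)
      Jfd <- fd_jacobian_at_k(cs$pm, st, k, g)
      expect_lt(max(abs(Ja - Jfd)) / max(abs(Ja)), 1e-6)
    }
  }
})

test_that("base-model dispersion reproduces the known instability window", {
  pm <- params_base()

  d8 <- dispersion_relation(pm, 8000)
  expect_false(is.null(d8$dominant))
  expect_gt(d8$dominant$k, 0.13)
  expect_lt(d8$dominant$k, 0.15)
  expect_gt(d8$dominant$wavelength, 42)
  expect_lt(d8$dominant$wavelength, 48)
  expect_equal(d8$dominant$rate, 0.047, tolerance = 0.05)
  expect_equal(d8$dominant$phase, "in_phase")

  # at the bifurcation mean population the curve is tangent to zero at k -> 0
  d15 <- dispersion_relation(pm, 15360)
  expect_lt(max(d15$curve$growth_rate), 2e-4)
  expect_gt(max(d15$curve$growth_rate), -2e-4)

  # well above it every mode decays
  d20 <- dispersion_relation(pm, 20000)
  expect_true(all(d20$curve$growth_rate < 0))

  # dominant wavelength grows with mean population toward the bifurcation
  wl <- vapply(c(8000, 10000, 12000, 14000), function(pb) {
    dispersion_relation(pm, pb)$dominant$wavelength
  }, numeric(1))
  expect_true(all(diff(wl) > 0))
})

test_that("closed-form instability condition agrees with the dispersion sweep", {
  pm <- params_base()
  expect_true(is_pattern_unstable(pm, 8000))
  expect_false(is_pattern_unstable(pm, 20000))
  expect_error(is_pattern_unstable(params_comp(), 8000), "base")

  set.seed(21)
  k <- seq(1e-3, 3, length.out = 400)
  for (i in 1:25) {
    pmi <- model_params(mu = runif(1, 1.2, 5),
                        lambda = runif(1, 10000, 30000),
                        D = runif(1, 0.5, 4))
    pbar <- runif(1, 2000, 25000)
    pred <- is_pattern_unstable(pmi, pbar)
    disp <- dispersion_relation(pmi, pbar, k)
    expect_identical(pred, any(disp$curve$growth_rate > 1e-12),
                     info = sprintf("mu=%.3g pbar=%.0f", pmi$mu, pbar))
  }
})

test_that("unstable window is a single interval (0, k_c)", {
  pm <- params_base()
  kc <- critical_wavenumber(pm, 8000)
  expect_gt(kc, 0.15)
  expect_lt(kc, 1)
  k <- seq(1e-3, 3, length.out = 600)
  gr <- dispersion_relation(pm, 8000, k)$curve$growth_rate
  expect_true(all((gr > 0) == (k < kc)))

  # no re-entrant instability across +/- 50% parameter perturbations
  set.seed(31)
  for (i in 1:10) {
    sc <- function() runif(1, 0.5, 1.5)
    pmi <- model_params(D = 2 * sc(), f = 0.05 * sc(), g = 2 * sc(),
                        beta_s = 5 * sc(), beta_p1 = 1 * sc(),
                        beta_p2 = 10 * sc())
    if (!is_pattern_unstable(pmi, 8000)) next
    kci <- critical_wavenumber(pmi, 8000)
    gri <- dispersion_relation(pmi, 8000, k)$curve$growth_rate
    expect_true(all((gri > 1e-12) == (k < kci)))
  }

  # k_c shrinks to zero approaching the bifurcation from below
  bp <- bifurcation_point(pm)
  expect_lt(critical_wavenumber(pm, bp$p0 * 0.999), 0.05)
  expect_error(critical_wavenumber(pm, 20000), "stable")
})

test_that("bifurcation point matches the printed values and small-mu limits", {
  bp <- bifurcation_point(model_params())
  expect_equal(bp$s0, 0.37, tolerance = 0.02)
  expect_equal(bp$p0, 15360, tolerance = 0.02)
  # residual of the defining equation
  expect_lt(abs(bp$s0 - 3 * (2 * bp$s0 - 1) * log(1 - bp$s0)), 1e-12)

  bp15 <- bifurcation_point(model_params(mu = 1.5))
  expect_equal(bp15$s0, 0.20, tolerance = 0.02)

  # s0* -> 0 as mu -> 1+
  expect_lt(bifurcation_point(model_params(mu = 1.01))$s0, 0.02)
  expect_error(bifurcation_point(model_params(mu = 1)), "degenerate")

  # equality of the instability condition at the bifurcation point
  pm <- model_params()
  st <- homogeneous_state(pm, bp$p0)
  lhs <- st$s0 * (1 - st$s0) / (st$p0 * service_capacity_prime(st$p0, pm)) +
    st$s0
  expect_equal(lhs, 1 - st$s0, tolerance = 1e-8)
  expect_true(is_pattern_unstable(pm, bp$p0 * 0.999))
  expect_false(is_pattern_unstable(pm, bp$p0 * 1.001))
})

test_that("competition threshold matches the printed value", {
  thr <- competition_threshold(params_comp())
  expect_equal(thr, 11500, tolerance = 0.01)
  pm <- params_comp()
  expect_lt(abs(service_capacity(thr, pm) - pm$alpha1 * thr), 1e-9)
  expect_error(competition_threshold(params_base()), "alpha1")
})

test_that("competition model shows coexisting in- and out-of-phase bands", {
  pm <- params_comp()
  d <- dispersion_relation(pm, 12000)
  bands <- unstable_bands(d)
  expect_gte(nrow(bands), 2)
  expect_identical(bands$phase[1], "in_phase")
  expect_identical(dplyr::last(bands$phase), "out_of_phase")
  # city-scale band ~50 km, within-city band ~4-5 km
  expect_gt(bands$wavelength[1], 40)
  expect_lt(bands$wavelength[1], 60)
  oo <- dplyr::last(bands$wavelength)
  expect_gt(oo, 3)
  expect_lt(oo, 6)
})

test_that("phase diagram classification matches the linear theory", {
  pm <- params_comp()
  pbar <- 16000 # homogeneous base state stable at alpha1 = a_p = 0
  expect_false(is_pattern_unstable(params_base(), pbar))
  pd <- phase_diagram(pm, pbar,
                      alpha1 = c(0, 5e-6, 1.3e-5, 2.4e-5, 4e-5),
                      a_p = c(0, 0.75, 1.5, 2.75))
  expect_identical(pd$label[pd$alpha1 == 0 & pd$a_p == 0], "stable")
  # out-of-phase requires both alpha1 > 0 and a_p > 0
  expect_false(any(pd$label[pd$alpha1 == 0 | pd$a_p == 0] == "out_of_phase"))
  # excessive competition kills services entirely
  expect_true(all(pd$label[pd$alpha1 == 4e-5] == "services_extinct"))
  expect_setequal(unique(pd$label),
                  intersect(unique(pd$label),
                            c("stable", "in_phase", "out_of_phase",
                              "services_extinct")))
  # and some out-of-phase cells exist where both ingredients are present
  expect_true(any(pd$label[pd$alpha1 > 0 & pd$a_p > 0] == "out_of_phase"))
})
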