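test_that("service carrying capacity matches closed-form values", {
  pm <- params_base()
  expect_equal(service_capacity(0, pm), 0)
  expect_equal(service_capacity(pm$lambda, pm), 1 - exp(-1), tolerance = 1e-12)
  # London-ward calibration: mean density 8400 with mu = 3.2 gives s ~ 0.06
  pm32 <- params_base(mu = 3.2)
  expect_equal(service_capacity(8400, pm32), 0.060, tolerance = 1e-2)
  expect_error(service_capacity(-5, pm), "nonnegative")
  # monotone, bounded in [0, 1)
  p <- seq(0, 1e5, length.out = 200)
  v <- service_capacity(p, pm)
  expect_true(all(diff(v) >= 0) && all(v >= 0) && all(v <= 1))
  expect_true(all(diff(service_capacity(seq(0, 4e4, length.out = 50), pm)) > 0))
})

test_that("capacity slope matches closed form and finite differences", {
  pm <- params_base()
  expect_equal(service_capacity_prime(pm$lambda, pm),
               (3 / 20000) * exp(-1), tolerance = 1e-12)
  expect_equal(service_capacity_prime(0, pm), 0)
  h <- 1e-3
  fd <- (service_capacity(8000 + h, pm) - service_capacity(8000 - h, pm)) / (2 * h)
  expect_equal(service_capacity_prime(8000, pm), fd, tolerance = 1e-6)
  expect_true(all(service_capacity_prime(seq(1, 1e5, length.out = 50), pm) > 0))
})

test_that("attractiveness handles homogeneous and saturated services", {
  g <- grid_1d()
  pm <- params_base()
  for (s0 in c(0, 0.3, 1)) {
    s <- scalar_field(rep(s0, g$n[1]), g, role = "service")
    A <- attractiveness(s, pm)
    expect_equal(A$values, rep(s0 * (1 - s0), g$n[1]), tolerance = 1e-12)
  }
  bad <- scalar_field(rep(1.5, g$n[1]), g, role = "derived")
  expect_error(attractiveness(bad, pm), "\\[0, 1\\]")
})

test_that("movement conserves population and vanishes at homogeneity", {
  g <- grid_1d()
  pm <- params_base()
  p <- scalar_field(rep(8000, g$n[1]), g)
  s <- scalar_field(rep(0.3, g$n[1]), g, role = "service")
  expect_equal(movement_rhs(p, s, pm)$values, rep(0, g$n[1]), tolerance = 1e-12)

  set.seed(3)
  x <- grid_coords(g)
  pv <- 8000 + 2000 * sin(2 * pi * x / 200) + rnorm(g$n[1], 0, 100)
  sv <- pmin(pmax(0.1 + 0.05 * cos(2 * pi * 3 * x / 200), 0), 1)
  p <- scalar_field(pmax(pv, 0), g)
  s <- scalar_field(sv, g, role = "service")
  out <- movement_rhs(p, s, pm)
  expect_lt(abs(sum(out$values)), 1e-9 * sum(p$values))
})

test_that("service dynamics match direct evaluation in each variant", {
  g <- grid_1d()
  n <- g$n[1]
  pm <- params_base()
  p <- scalar_field(rep(8000, n), g)

  # at s = sigma(P) the base drive vanishes
  s_eq <- scalar_field(rep(service_capacity(8000, pm), n), g, role = "service")
  expect_equal(service_rhs(p, s_eq, pm)$values, rep(0, n), tolerance = 1e-12)

  # innovation from bare ground: f * sigma(8000)
  s0 <- scalar_field(rep(0, n), g, role = "service")
  expect_equal(service_rhs(p, s0, pm)$values,
               rep(0.05 * (1 - exp(-0.4^3)), n), tolerance = 1e-12)
  expect_equal(service_rhs(p, s0, pm)$values[1], 3.10e-3, tolerance = 1e-2)

  # competition: Heaviside gate shuts innovation below the threshold
  pmc <- params_comp()
  p_low <- scalar_field(rep(5000, n), g)
  out <- service_rhs(p_low, s0, pmc)
  expect_true(service_capacity(5000, pmc) < pmc$alpha1 * 5000)
  expect_equal(out$values, rep(0, n))

  # bound preservation: drive >= 0 wherever s = 0, <= 0 wherever s = 1
  set.seed(5)
  pv <- pmax(8000 + 3000 * rnorm(n), 0)
  p_r <- scalar_field(pv, g)
  sv <- rep(0.5, n); sv[1:10] <- 0; sv[11:20] <- 1
  s_r <- scalar_field(sv, g, role = "service")
  for (pmx in list(pm, pmc)) {
    d <- service_rhs(p_r, s_r, pmx)$values
    expect_true(all(d[1:10] >= 0))
    expect_true(all(d[11:20] <= 0))
  }
})

test_that("growth variant has the predicted homogeneous fixed point", {
  pm <- params_growth()
  st <- homogeneous_state(pm)
  expect_equal(st$p0, 1.16e4, tolerance = 1e-2)
  expect_equal(st$s0, 3.9e-3, tolerance = 5e-2)
  # both defining residuals vanish
  expect_lt(abs(st$p0 + pm$alpha2 * st$s0 - pm$c), 1e-6)
  expect_lt(abs(service_capacity(st$p0, pm) - pm$alpha1 * st$p0 - st$s0), 1e-10)

  g <- grid_1d()
  n <- g$n[1]
  p <- scalar_field(rep(st$p0, n), g)
  s <- scalar_field(rep(st$s0, n), g, role = "service")
  expect_equal(population_rhs(p, s, pm)$values, rep(0, n), tolerance = 1e-10)
  expect_equal(service_rhs(p, s, pm)$values, rep(0, n), tolerance = 1e-12)

  # p = c, s = 0: logistic and movement terms both vanish
  p_c <- scalar_field(rep(pm$c, n), g)
  s_0 <- scalar_field(rep(0, n), g, role = "service")
  expect_equal(population_rhs(p_c, s_0, pm)$values, rep(0, n), tolerance = 1e-12)
})

test_that("mass is conserved for arbitrary fields in non-growth variants", {
  g <- grid_2d(n = 24)
  set.seed(9)
  pv <- matrix(pmax(rnorm(24^2, 8000, 2500), 0), 24, 24)
  sv <- matrix(runif(24^2, 0, 0.8), 24, 24)
  p <- scalar_field(pv, g)
  s <- scalar_field(sv, g, role = "service")
  for (pm in list(params_base(), params_comp())) {
    out <- population_rhs(p, s, pm)
    expect_lt(abs(sum(out$values)), 1e-9 * sum(pv))
  }
})

test_that("fast integrator core agrees with the public RHS functions", {
  g <- grid_2d(n = 16)
  set.seed(13)
  pv <- matrix(pmax(rnorm(256, 9000, 2000), 0), 16, 16)
  sv <- matrix(runif(256, 0.01, 0.5), 16, 16)
  p <- scalar_field(pv, g)
  s <- scalar_field(sv, g, role = "service")
  for (pm in list(params_base(), params_comp(), params_growth())) {
    pre <- urbanpattern:::make_rhs_core(pm, g)
    fast <- urbanpattern:::rhs_core(pv, sv, pre)
    expect_equal(fast$dp, population_rhs(p, s, pm)$values, tolerance = 1e-11)
    expect_equal(fast$ds, service_rhs(p, s, pm)$values, tolerance = 1e-11)
  }
})

test_that("parameter validation rejects inadmissible values", {
  expect_error(model_params(mu = 0.8), "mu")
  expect_error(model_params(D = -1), "positive")
  expect_error(model_params("base", alpha1 = 1e-5), "base variant")
  expect_error(urbanpattern:::update_params(model_params(), list(zeta = 1)),
               "unknown parameter")
})
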