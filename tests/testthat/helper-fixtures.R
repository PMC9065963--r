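# Shared fixtures: small grids and default parameter sets.

grid_1d <- function(extent = 200, n = 128) spatial_grid(extent, n)
grid_2d <- function(extent = 200, n = 32) spatial_grid(extent, n, dimension = 2)

params_base <- function(...) model_params("base", ...)
params_comp <- function(...) model_params("competition", ...)
params_growth <- function(...) model_params("growth", ...)

# Brute-force periodic convolution by direct quadrature (the independent
# oracle for the spectral path). Samples the kernel profile over all periodic
# images within `images` domain widths.
conv_quadrature_1d <- function(values, grid, spec, images = 3) {
  n <- grid$n[1]
  dx <- grid$spacing[1]
  x <- grid_coords(grid)
  out <- numeric(n)
  shifts <- (-images:images) * grid$extent[1]
  for (i in seq_len(n)) {
    d <- x[i] - x
    w <- rowSums(vapply(shifts, function(s0) kernel_profile(spec, d + s0),
                        numeric(n)))
    out[i] <- sum(w * values) * dx
  }
  out
}

# Mode-projected finite-difference linearization: perturb the homogeneous
# state along cos(kx) in p and s separately and project the RHS back onto
# the mode. Central differences. Returns the 2x2 Jacobian estimate.
#
# The competition/growth service equation is nonsmooth exactly at supply-
# demand balance (the Heaviside innovation gate), so for those variants the
# expansion point is shifted a distance `shift` onto the smooth supply-
# deficit branch (the branch whose linearization the per-mode stability
# matrix represents); the shift contributes O(g * shift) ~ 2e-4 absolute,
# far below the comparison tolerance of 1e-6 * max|J|.
fd_jacobian_at_k <- function(params, state, k, grid, eps_p = 1e-3,
                             eps_s = 1e-6, shift = 1e-4) {
  x <- grid_coords(grid)
  mode <- cos(k * x)
  proj <- function(fv) 2 * sum(fv * mode) / length(mode)
  evalrhs <- function(pv, sv) {
    p <- scalar_field(pv, grid)
    s <- scalar_field(pmin(pmax(sv, 0), 1), grid, role = "service")
    list(dp = population_rhs(p, s, params)$values,
         ds = service_rhs(p, s, params)$values)
  }
  p0 <- state$p0
  s0 <- state$s0 - if (params$variant == "base") 0 else shift
  col_p <- {
    up <- evalrhs(p0 + eps_p * mode, rep(s0, length(mode)))
    dn <- evalrhs(p0 - eps_p * mode, rep(s0, length(mode)))
    c(proj(up$dp - dn$dp), proj(up$ds - dn$ds)) / (2 * eps_p)
  }
  col_s <- {
    up <- evalrhs(rep(p0, length(mode)), s0 + eps_s * mode)
    dn <- evalrhs(rep(p0, length(mode)), s0 - eps_s * mode)
    c(proj(up$dp - dn$dp), proj(up$ds - dn$ds)) / (2 * eps_s)
  }
  cbind(col_p, col_s, deparse.level = 0)
}
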