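## Numerical continuation of patterned steady states in the mean population.
##
## The steady problem on an N-point periodic 1-D grid has two structural
## degeneracies: total population is conserved (the movement equations sum to
## zero), and solutions are translation invariant. Both are removed by (i)
## restricting to the even (cosine-symmetric) subspace -- the natural phase
## condition for this reflection-symmetric problem -- and (ii) replacing one
## redundant movement equation with the mean-population constraint
## mean(p) = pbar. The service equation is imposed through its smooth zero
## set sigma(w_s * p) - s - alpha1 p = 0 (equivalent to ds/dt = 0 away from
## extinct services, and far better conditioned for Newton than the
## (f + g s)-weighted form). A secant (pseudo-arclength) predictor lets
## branches go around folds. Stability is judged from the eigenvalues of the
## full dynamic linearization on the whole grid (odd perturbations included),
## ignoring the two structural neutral modes.

# circulant convolution matrix for a kernel on a 1-D grid
conv_matrix <- function(spec, grid) {
  n <- grid$n[1]
  what <- kernel_hat(spec, abs(fft_wavenumbers(n, grid$extent[1])))
  wcol <- Re(stats::fft(what, inverse = TRUE)) / n
  idx <- (outer(0:(n - 1), 0:(n - 1), "-") %% n) + 1
  matrix(wcol[idx], n, n)
}

# steady-state residual: list(F1 = dp/dt, F2 = sigma(P) - s - alpha1 p)
steady_residual <- function(p, s, pre) {
  pm <- pre$params
  d <- rhs_core(p, s, pre)
  P <- Re(stats::fft(pre$what_s * stats::fft(p), inverse = TRUE)) / pre$n
  F2 <- service_capacity(pmax(P, 0), pm) - s - pm$alpha1 * p
  list(F1 = d$dp, F2 = F2)
}

# analytic Jacobian blocks of (F1, F2) wrt (p, s) on the full grid
steady_jacobian_blocks <- function(p, s, params, mats) {
  Wp1 <- mats$Wp1; Wp2 <- mats$Wp2; Ws <- mats$Ws
  S <- as.vector(Wp1 %*% s)
  A <- S * (1 - s)
  conv_p <- as.vector(Wp2 %*% p)
  conv_A <- as.vector(Wp2 %*% A)
  P <- as.vector(Ws %*% p)
  D <- params$D
  # dF1/dp
  A11 <- D * (A * Wp2)
  diag(A11) <- diag(A11) - D * conv_A
  # dA/ds, then dF1/ds
  MA <- (1 - s) * Wp1
  diag(MA) <- diag(MA) - S
  A12 <- D * (conv_p * MA - p * (Wp2 %*% MA))
  if (params$variant == "growth") {
    diag(A11) <- diag(A11) +
      params$r * (1 - (2 * p + params$alpha2 * s) / params$c)
    A12 <- A12 - diag(params$r * params$alpha2 * p / params$c, length(p))
  }
  # dF2/dp, dF2/ds
  A21 <- service_capacity_prime(pmax(P, 0), params) * Ws
  diag(A21) <- diag(A21) - params$alpha1
  A22 <- -diag(length(p))
  list(A11 = A11, A12 = A12, A21 = A21, A22 = A22, A = A, P = P)
}

# dynamic Jacobian (d(dp/dt, ds/dt)/d(p, s)) at a steady state
dynamic_jacobian <- function(p, s, params, mats, blocks) {
  fg <- params$f + params$g * s
  J21 <- fg * (service_capacity_prime(pmax(blocks$P, 0), params) * mats$Ws)
  diag(J21) <- diag(J21) - fg * params$alpha1
  J22 <- diag(-fg)
  rbind(cbind(blocks$A11, blocks$A12), cbind(J21, J22))
}

# fold an N-column block to the M = N/2 + 1 even-subspace columns
fold_cols <- function(B, n) {
  m <- n / 2 + 1
  R <- B[, 1:m, drop = FALSE]
  R[, 2:(m - 1)] <- R[, 2:(m - 1)] + B[, n:(m + 1), drop = FALSE]
  R
}

expand_even <- function(u, n) {
  m <- n / 2 + 1
  u[base::c(1:m, (m - 1):2)]
}

#' Locate a patterned steady state
#'
#' Newton solve of the steady-state system at fixed mean population, starting
#' from a supplied guess (for instance a simulation endpoint or a cosine
#' ansatz). The solution is restricted to the even-symmetric subspace of the
#' periodic domain, so the guess should be (approximately) even about x = 0.
#'
#' @param p Initial population guess ([scalar_field()] on a 1-D grid).
#' @param params A base- or competition-variant [model_params()].
#' @param s Initial service guess; default `sigma(w_s * p)`.
#' @param pbar Mean population to impose; defaults to `mean(p)`.
#' @param tol Convergence tolerance on the scaled residual.
#' @param max_iter Newton iteration cap.
#' @param relax_years Optional pre-relaxation by time integration before the
#'   Newton solve (helps far-from-steady guesses).
#' @return List with [scalar_field()]s `p`, `s`, the imposed `pbar`, and the
#'   final scaled `residual`.
#' @export
find_steady <- function(p, params, s = NULL, pbar = NULL, tol = 1e-11,
                        max_iter = 40, relax_years = 0) {
  stopifnot(inherits(p, "scalar_field"))
  grid <- p$grid
  if (grid$dimension != 1) stop("continuation operates on 1-D grids", call. = FALSE)
  if (params$variant == "growth") {
    stop("steady-state continuation in pbar applies to the base and ",
         "competition variants (growth fixes the mean itself)", call. = FALSE)
  }
  if (is.null(pbar)) pbar <- field_mean(p)
  if (relax_years > 0) {
    h <- simulate_model(params, p, s, t_end = relax_years, method = "rk4",
                        dt = 0.05)
    fin <- final_state(h)
    p <- fin$p; s <- fin$s
  }
  if (is.null(s)) {
    P <- convolve_periodic(p, kernel_w_s(params, 1))
    s <- scalar_field(service_capacity(pmax(P$values, 0), params), grid,
                      role = "service")
  }
  mats <- list(Wp1 = conv_matrix(kernel_w_p1(params), grid),
               Wp2 = conv_matrix(kernel_w_p2(params), grid),
               Ws = conv_matrix(kernel_w_s(params), grid))
  pre <- make_rhs_core(params, grid)
  n <- grid$n[1]; m <- n / 2 + 1
  ur <- base::c(p$values[1:m], s$values[1:m])
  out <- newton_steady(ur, pbar, params, grid, mats, pre, tol, max_iter)
  if (!out$converged) stop("Newton failed to converge to a steady state",
                           call. = FALSE)
  pv <- expand_even(out$u[1:m], n)
  sv <- expand_even(out$u[(m + 1):(2 * m)], n)
  list(p = scalar_field(pv, grid), s = scalar_field(sv, grid, role = "service"),
       pbar = pbar, residual = out$res)
}

# scaled residual norm used for convergence decisions
residual_norm <- function(F1, F2, pscale) {
  max(max(abs(F1)) / pscale, max(abs(F2)))
}

# Newton corrector at fixed pbar on the reduced even subspace
newton_steady <- function(ur, pbar, params, grid, mats, pre, tol, max_iter) {
  n <- grid$n[1]; m <- n / 2 + 1
  wmean <- base::c(1, rep(2, m - 2), 1) / n
  pscale <- max(abs(pbar), 1)
  for (it in seq_len(max_iter)) {
    p <- expand_even(ur[1:m], n)
    s <- expand_even(ur[(m + 1):(2 * m)], n)
    res <- steady_residual(p, s, pre)
    G <- base::c(res$F1[1:m] / pscale, res$F2[1:m])
    G[1] <- sum(wmean * ur[1:m]) / pscale - pbar / pscale
    rn <- max(abs(base::c(res$F1[2:m] / pscale, res$F2[1:m], G[1])))
    if (rn < tol) {
      full <- residual_norm(res$F1, res$F2, pscale)
      return(list(u = ur, converged = TRUE, res = full))
    }
    bl <- steady_jacobian_blocks(p, s, params, mats)
    J <- rbind(
      cbind(fold_cols(bl$A11[1:m, , drop = FALSE], n) / pscale,
            fold_cols(bl$A12[1:m, , drop = FALSE], n) / pscale),
      cbind(fold_cols(bl$A21[1:m, , drop = FALSE], n),
            fold_cols(bl$A22[1:m, , drop = FALSE], n))
    )
    J[1, ] <- base::c(wmean / pscale, rep(0, m))
    step <- tryCatch(solve(J, -G), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(u = ur, converged = FALSE, res = Inf))
    }
    ur <- ur + step
    ur[(m + 1):(2 * m)] <- pmin(pmax(ur[(m + 1):(2 * m)], 0), 1)
    ur[1:m] <- pmax(ur[1:m], 0)
  }
  list(u = ur, converged = FALSE, res = Inf)
}

# corrector for the pseudo-arclength system (unknowns u_r and pbar)
newton_arclength <- function(y, tangent, y_pred, scale_vec, params, grid,
                             mats, pre, tol, max_iter) {
  n <- grid$n[1]; m <- n / 2 + 1
  wmean <- base::c(1, rep(2, m - 2), 1) / n
  pscale <- scale_vec[length(scale_vec)]
  for (it in seq_len(max_iter)) {
    ur <- y[1:(2 * m)]; pbar <- y[2 * m + 1]
    p <- expand_even(ur[1:m], n)
    s <- expand_even(ur[(m + 1):(2 * m)], n)
    res <- steady_residual(p, s, pre)
    G <- base::c(res$F1[1:m] / pscale, res$F2[1:m])
    G[1] <- (sum(wmean * ur[1:m]) - pbar) / pscale
    arc <- sum(tangent * (y - y_pred) / scale_vec)
    rn <- max(abs(base::c(res$F1[2:m] / pscale, res$F2[1:m], G[1], arc)))
    if (rn < tol) {
      return(list(y = y, converged = TRUE, iters = it,
                  res = residual_norm(res$F1, res$F2, pscale)))
    }
    bl <- steady_jacobian_blocks(p, s, params, mats)
    J <- rbind(
      cbind(fold_cols(bl$A11[1:m, , drop = FALSE], n) / pscale,
            fold_cols(bl$A12[1:m, , drop = FALSE], n) / pscale),
      cbind(fold_cols(bl$A21[1:m, , drop = FALSE], n),
            fold_cols(bl$A22[1:m, , drop = FALSE], n))
    )
    J[1, ] <- base::c(wmean / pscale, rep(0, m))
    dGdpbar <- base::c(-1 / pscale, rep(0, 2 * m - 1))
    Jaug <- rbind(cbind(J, dGdpbar), tangent / scale_vec)
    step <- tryCatch(unname(solve(Jaug, -base::c(G, arc))),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(y = y, converged = FALSE, iters = it, res = Inf))
    }
    y <- unname(y + step)
    y[(m + 1):(2 * m)] <- pmin(pmax(y[(m + 1):(2 * m)], 0), 1)
  }
  list(y = y, converged = FALSE, iters = max_iter, res = Inf)
}

# stability of a steady state from the full dynamic linearization
steady_stability <- function(p, s, params, mats, neutral_tol = 1e-8) {
  bl <- steady_jacobian_blocks(p, s, params, mats)
  J <- dynamic_jacobian(p, s, params, mats, bl)
  ev <- Re(eigen(J, only.values = TRUE)$values)
  structural <- abs(ev) < neutral_tol
  # at most two structural neutral modes (mass conservation, translation)
  drop <- which(structural)[seq_len(min(2, sum(structural)))]
  lead <- if (length(drop)) max(ev[-drop]) else max(ev)
  list(stable = lead < neutral_tol, leading = lead)
}

#' Continue a branch of patterned steady states
#'
#' Pseudo-arclength continuation of a steady state in the mean population
#' pbar. The corrector is a Newton iteration on the even-subspace steady
#' system augmented with the mean-population constraint and the arclength
#' condition; the secant predictor traverses folds. Each accepted point is
#' re-verified by direct evaluation of the dynamics and classified as stable
#' or unstable from the eigenvalues of the full linearization (the two
#' structural neutral modes — conserved mass and translation — are ignored).
#'
#' @param start Output of [find_steady()] (a converged steady state), or a
#'   list with [scalar_field()]s `p` and `s`.
#' @param params A base- or competition-variant [model_params()].
#' @param pbar_range Numeric length-2: continuation stops when pbar leaves
#'   this interval.
#' @param step Initial pbar step (persons/km^2); also the arclength scale.
#' @param max_step Largest allowed step.
#' @param min_step Smallest step before declaring the branch ended.
#' @param max_steps Cap on accepted points.
#' @param tol Newton tolerance on the scaled residual.
#' @return An object of class `continuation_branch`: list with `points`
#'   (tibble: `pbar`, `max_p`, `min_p`, `max_s`, `stable`, `leading_re`,
#'   `residual`), `fields` (list of (p, s) field pairs), `params`, `grid`.
#' @export
continue_branch <- function(start, params, pbar_range, step = 150,
                            max_step = 400, min_step = 1, max_steps = 400,
                            tol = 1e-11) {
  p <- start$p; s <- start$s
  stopifnot(inherits(p, "scalar_field"), inherits(s, "scalar_field"))
  grid <- p$grid
  if (grid$dimension != 1) stop("continuation operates on 1-D grids", call. = FALSE)
  n <- grid$n[1]; m <- n / 2 + 1
  mats <- list(Wp1 = conv_matrix(kernel_w_p1(params), grid),
               Wp2 = conv_matrix(kernel_w_p2(params), grid),
               Ws = conv_matrix(kernel_w_s(params), grid))
  pre <- make_rhs_core(params, grid)
  pbar0 <- field_mean(p)
  pscale <- max(abs(pbar0), 1)
  scale_vec <- base::c(rep(pscale, m), rep(1, m), pscale)

  record <- function(ur, pbar, res) {
    pv <- expand_even(ur[1:m], n)
    sv <- expand_even(ur[(m + 1):(2 * m)], n)
    st <- steady_stability(pv, sv, params, mats)
    list(
      row = tibble::tibble(pbar = pbar, max_p = max(pv), min_p = min(pv),
                           max_s = max(sv), stable = st$stable,
                           leading_re = st$leading, residual = res),
      fields = list(p = scalar_field(pv, grid),
                    s = scalar_field(sv, grid, role = "service"))
    )
  }

  # converge the starting point at its own pbar
  ur <- base::c(p$values[1:m], s$values[1:m])
  o <- newton_steady(ur, pbar0, params, grid, mats, pre, tol, 40)
  if (!o$converged) stop("starting state did not converge", call. = FALSE)
  pts <- list(); flds <- list()
  r <- record(o$u, pbar0, o$res)
  pts[[1]] <- r$row; flds[[1]] <- r$fields
  y0 <- base::c(o$u, pbar0)

  # second point by natural continuation
  dir <- if (mean(pbar_range) >= pbar0) 1 else -1
  h <- step
  repeat {
    o2 <- newton_steady(o$u, pbar0 + dir * h, params, grid, mats, pre, tol, 40)
    if (o2$converged) break
    h <- h / 2
    if (h < min_step) stop("could not take the first continuation step",
                           call. = FALSE)
  }
  r <- record(o2$u, pbar0 + dir * h, o2$res)
  pts[[2]] <- r$row; flds[[2]] <- r$fields
  y1 <- base::c(o2$u, pbar0 + dir * h)

  # arclength steps live in the scaled metric used for the tangent
  secant <- (y1 - y0) / scale_vec
  ds <- sqrt(sum(secant^2))
  ds_max <- ds * max_step / h
  ds_min <- ds * min_step / h
  for (i in seq_len(max_steps)) {
    tangent <- (y1 - y0) / scale_vec
    tl <- sqrt(sum(tangent^2))
    if (tl == 0) break
    tangent <- tangent / tl
    repeat {
      y_pred <- y1 + ds * tangent * scale_vec
      oc <- newton_arclength(y_pred, tangent, y_pred, scale_vec, params,
                             grid, mats, pre, tol, 12)
      if (oc$converged) break
      ds <- ds / 2
      if (ds < ds_min) break
    }
    if (!oc$converged) break
    y0 <- y1; y1 <- oc$y
    pbar <- y1[2 * m + 1]
    r <- record(y1[1:(2 * m)], pbar, oc$res)
    pts[[length(pts) + 1]] <- r$row
    flds[[length(flds) + 1]] <- r$fields
    if (oc$iters <= 4) ds <- min(ds * 1.3, ds_max)
    if (pbar < min(pbar_range) || pbar > max(pbar_range)) break
    # stop if the pattern has collapsed onto the homogeneous state
    if (r$row$max_p - r$row$min_p < 1e-6 * pscale) break
  }

  structure(list(points = dplyr::bind_rows(pts), fields = flds,
                 params = params, grid = grid),
            class = "continuation_branch")
}

#' @export
print.continuation_branch <- function(x, ...) {
  cat(sprintf("<continuation_branch> %d points, pbar in [%.5g, %.5g], %d stable\n",
              nrow(x$points), min(x$points$pbar), max(x$points$pbar),
              sum(x$points$stable)))
  invisible(x)
}

#' Largest mean population with a stable patterned state
#'
#' Scans a continuation branch for the largest pbar at which the patterned
#' state is stable. When that point sits at a fold (pbar locally maximal
#' along the branch), the fold location is refined by a parabolic fit of
#' pbar against arclength index through the turning point.
#'
#' @param branch A `continuation_branch`.
#' @return The pbar value, persons/km^2.
#' @export
max_stable_pbar <- function(branch) {
  pts <- branch$points
  if (!any(pts$stable)) stop("branch has no stable points", call. = FALSE)
  i <- which(pts$stable)[which.max(pts$pbar[pts$stable])]
  pb <- pts$pbar[i]
  if (i > 1 && i < nrow(pts)) {
    y <- pts$pbar[(i - 1):(i + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom < 0 && y[2] >= y[1] && y[2] >= y[3]) {
      delta <- 0.5 * (y[1] - y[3]) / denom
      pb <- y[2] - 0.25 * (y[1] - y[3]) * delta
    }
  } else if (i == nrow(pts)) {
    warning("branch ends while still stable: reported value is a range end",
            call. = FALSE)
  }
  pb
}

#' @export
as_tibble.continuation_branch <- function(x, ...) x$points

#' Plot a continuation branch
#' @param object A `continuation_branch`.
#' @param ... Unused.
#' @return A ggplot of max(p) against pbar, thick where stable.
#' @export
autoplot.continuation_branch <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$pbar, .data$max_p,
                               linewidth = .data$stable)) +
    ggplot2::geom_path() +
    ggplot2::scale_linewidth_manual(values = base::c(`TRUE` = 1.2, `FALSE` = 0.4),
                                    name = "stable") +
    ggplot2::labs(x = "mean population (pe/km2)", y = "max p (pe/km2)")
}
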