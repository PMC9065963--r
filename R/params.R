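#' Model parameters
#'
#' Bundles the rate, shape and kernel parameters of the coupled
#' population-service model, for one of three variants:
#' \describe{
#'   \item{`base`}{Conserved total population; services relax towards the
#'     carrying capacity sigma(P).}
#'   \item{`competition`}{Adds competition for space (each person removes
#'     `alpha1` km^2 of service potential) and a preferred distance `a_p` from
#'     services via the shifted-sum kernel.}
#'   \item{`growth`}{Competition variant plus logistic population growth at
#'     rate `r` towards carrying capacity `c`, with services crowding
#'     population through `alpha2`.}
#' }
#'
#' Defaults are calibrated to UK data: kernel scales from typical travel
#' distances (`beta_p1` = 1 km walk to local services, `beta_s` = 5 km trip to
#' shops, `beta_p2` = 10 km house move), `lambda` and `mu` from London ward
#' population/service-fraction levels, and rates `D`, `f`, `g` from
#' migration-flow and business-formation timescales.
#'
#' @param variant `"base"`, `"competition"` or `"growth"`.
#' @param D Population movement rate, 1/yr.
#' @param f Service innovator rate, 1/yr.
#' @param g Service imitator rate, 1/yr.
#' @param lambda Population scale of the service carrying capacity,
#'   persons/km^2.
#' @param mu Shape (steepness) of the carrying capacity; must be >= 1 (for
#'   `mu < 1` the slope of the capacity diverges at zero population and the
#'   linear analysis breaks down).
#' @param beta_s,beta_p1,beta_p2 Kernel length scales, km.
#' @param a_p Preferred population-service distance, km (competition/growth;
#'   forced to 0 under the base variant).
#' @param alpha1 Space each person removes from services, km^2/person
#'   (competition/growth; forced to 0 under the base variant).
#' @param alpha2 Crowding of population by services, persons/km^2 (growth).
#' @param r Intrinsic population growth rate, 1/yr (growth).
#' @param c Population carrying capacity, persons/km^2 (growth).
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params()
#' model_params("competition")
#' model_params("growth", c = 12000)
#' @export
model_params <- function(variant = "base",
                         D = 2, f = 0.05, g = 2,
                         lambda = 20000, mu = 3,
                         beta_s = 5, beta_p1 = 1, beta_p2 = 10,
                         a_p = NULL, alpha1 = NULL,
                         alpha2 = 1e5, r = 0.05, c = 12000) {
  variant <- match.arg(variant, base::c("base", "competition", "growth"))
  if (is.null(a_p)) a_p <- if (variant == "base") 0 else 1.5
  if (is.null(alpha1)) alpha1 <- if (variant == "base") 0 else 1.5e-5
  if (variant == "base" && (a_p != 0 || alpha1 != 0)) {
    stop("the base variant requires a_p = 0 and alpha1 = 0", call. = FALSE)
  }
  num <- list(D = D, f = f, g = g, lambda = lambda, mu = mu, beta_s = beta_s,
              beta_p1 = beta_p1, beta_p2 = beta_p2, a_p = a_p,
              alpha1 = alpha1, alpha2 = alpha2, r = r, c = c)
  bad <- names(num)[!vapply(num, function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))]
  if (length(bad)) {
    stop("parameters must be finite scalars: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pos <- base::c("D", "f", "g", "lambda", "beta_s", "beta_p1", "beta_p2")
  if (variant == "growth") pos <- base::c(pos, "r", "c", "alpha2")
  bad <- pos[vapply(pos, function(nm) num[[nm]] <= 0, logical(1))]
  if (length(bad)) {
    stop("parameters must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (mu < 1) {
    stop("`mu` must be >= 1: for mu < 1 the carrying-capacity slope is ",
         "unbounded at zero population", call. = FALSE)
  }
  if (a_p < 0 || alpha1 < 0) {
    stop("`a_p` and `alpha1` must be nonnegative", call. = FALSE)
  }
  structure(base::c(num, list(variant = variant)), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> variant=%s\n", x$variant))
  cat(sprintf("  rates (1/yr): D=%g f=%g g=%g", x$D, x$f, x$g))
  if (x$variant == "growth") cat(sprintf(" r=%g", x$r))
  cat("\n")
  cat(sprintf("  capacity: lambda=%g pe/km2, mu=%g\n", x$lambda, x$mu))
  cat(sprintf("  kernels (km): beta_s=%g beta_p1=%g beta_p2=%g a_p=%g\n",
              x$beta_s, x$beta_p1, x$beta_p2, x$a_p))
  if (x$variant != "base") {
    cat(sprintf("  competition: alpha1=%g km2/pe", x$alpha1))
    if (x$variant == "growth") {
      cat(sprintf(", alpha2=%g pe/km2, c=%g pe/km2", x$alpha2, x$c))
    }
    cat("\n")
  }
  invisible(x)
}

# Kernel specs implied by the parameters.
kernel_w_p1 <- function(params, dimension = 1) {
  if (params$a_p > 0) {
    kernel_spec("shifted_sum", params$beta_p1, params$a_p, dimension)
  } else {
    kernel_spec("gaussian", params$beta_p1, dimension = dimension)
  }
}
kernel_w_p2 <- function(params, dimension = 1) {
  kernel_spec("gaussian", params$beta_p2, dimension = dimension)
}
kernel_w_s <- function(params, dimension = 1) {
  kernel_spec("gaussian", params$beta_s, dimension = dimension)
}

# Override numeric parameters by name, revalidating.
update_params <- function(params, overrides) {
  if (!length(overrides)) return(params)
  known <- setdiff(names(unclass(params)), "variant")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  args <- unclass(params)
  args[names(overrides)] <- overrides
  do.call(model_params, args)
}
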