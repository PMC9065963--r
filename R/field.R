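#' Scalar field on a periodic grid
#'
#' A scalar field holds either population density p (persons per km^2) or the
#' service land fraction s (dimensionless, in \[0, 1\]) sampled on a periodic
#' [spatial_grid()].
#'
#' @param values Numeric vector (1-D grid) or matrix (2-D grid, `n[1]` rows =
#'   x, `n[2]` columns = y) of field values.
#' @param grid A [spatial_grid()].
#' @param role One of `"population"`, `"service"`, `"derived"`. Determines
#'   which admissibility bounds [validate_field()] enforces.
#'
#' @return An object of class `scalar_field`.
#' @examples
#' g <- spatial_grid(200, 64)
#' f <- scalar_field(8000 + 100 * cos(2 * pi * grid_coords(g) / 200), g)
#' field_mean(f)
#' @export
scalar_field <- function(values, grid, role = c("population", "service", "derived")) {
  role <- match.arg(role)
  if (grid$dimension == 1) {
    values <- as.numeric(values)
    if (length(values) != grid$n[1]) {
      stop("values length does not match grid size", call. = FALSE)
    }
  } else {
    if (!is.matrix(values) || !all(dim(values) == grid$n)) {
      stop("values must be an n1 x n2 matrix matching the grid", call. = FALSE)
    }
  }
  structure(list(values = values, grid = grid, role = role),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> role=%s on %d-D grid (%s pts), range [%.4g, %.4g], mean %.6g\n",
              x$role, x$grid$dimension, paste(x$grid$n, collapse = "x"),
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' Spatial mean of a field
#' @param field A [scalar_field()].
#' @return The mean of the field values (equals the domain integral divided by
#'   the domain area, since the grid is uniform).
#' @export
field_mean <- function(field) mean(field$values)

#' Check field admissibility bounds
#'
#' Population fields must be nonnegative; service fields must lie in
#' \[0, 1\]. A tolerance absorbs integrator roundoff.
#'
#' @param field A [scalar_field()].
#' @param tol Permitted overshoot beyond the bounds.
#' @return The field, invisibly; errors if bounds are violated.
#' @export
validate_field <- function(field, tol = 1e-9) {
  v <- field$values
  if (field$role == "population" && min(v) < -tol * max(abs(v), 1)) {
    stop("population field has negative values beyond tolerance", call. = FALSE)
  }
  if (field$role == "service" && (min(v) < -tol || max(v) > 1 + tol)) {
    stop("service field outside [0, 1] beyond tolerance", call. = FALSE)
  }
  invisible(field)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @export
as_tibble.scalar_field <- function(x, ...) {
  vals <- x$values
  if (x$grid$dimension == 1) {
    tibble::tibble(x = grid_coords(x$grid), value = as.vector(vals))
  } else {
    cs <- grid_coords(x$grid)
    n2 <- x$grid$n[2]
    n1 <- x$grid$n[1]
    tibble::tibble(
      x = rep(cs$x, times = n2),
      y = rep(cs$y, each = n1),
      value = as.vector(vals)
    )
  }
}

#' Plot a scalar field
#'
#' Line plot for 1-D fields, raster for 2-D fields.
#'
#' @param object A [scalar_field()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.scalar_field <- function(object, ...) {
  d <- as_tibble(object)
  if (object$grid$dimension == 1) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$value)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "x (km)", y = object$role)
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = object$role) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (km)", y = "y (km)")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
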