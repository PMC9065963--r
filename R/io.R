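#' Write a field as delimited text
#'
#' Plain-text interchange format: `# key: value` header lines carrying the
#' grid metadata (dimension, extent, points, spacing, units, role), followed
#' by the values at 17 significant digits (losslessly round-trippable). 1-D
#' fields are written one value per line; 2-D fields as whitespace-delimited
#' rows, with rows indexed by x and columns by y (row-major in x).
#'
#' @param field A [scalar_field()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  g <- field$grid
  hdr <- base::c(
    sprintf("# dimension: %d", g$dimension),
    sprintf("# extent_km: %s", paste(format(g$extent, digits = 17), collapse = " ")),
    sprintf("# points: %s", paste(g$n, collapse = " ")),
    sprintf("# spacing_km: %s", paste(format(g$spacing, digits = 17), collapse = " ")),
    sprintf("# role: %s", field$role),
    sprintf("# units: %s", if (field$role == "population") "persons_per_km2" else "fraction")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (g$dimension == 1) {
    writeLines(format(field$values, digits = 17, trim = TRUE), con)
  } else {
    utils::write.table(
      matrix(format(field$values, digits = 17, trim = TRUE), g$n[1], g$n[2]),
      con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a field written by [write_field()]
#'
#' @param path File path.
#' @return A [scalar_field()].
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  kv <- list()
  for (h in hdr) {
    mt <- regmatches(h, regexec("^#\\s*([a-zA-Z_]+):\\s*(.*)$", h))[[1]]
    if (length(mt) != 3) stop("malformed header line: ", h, call. = FALSE)
    kv[[mt[2]]] <- mt[3]
  }
  need <- base::c("dimension", "extent_km", "points", "role")
  miss <- setdiff(need, names(kv))
  if (length(miss)) {
    stop("field file missing header(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dimension <- as.integer(kv$dimension)
  extent <- as.numeric(strsplit(trimws(kv$extent_km), "\\s+")[[1]])
  npts <- as.integer(strsplit(trimws(kv$points), "\\s+")[[1]])
  grid <- spatial_grid(extent, npts, dimension)
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  vals <- scan(text = body, quiet = TRUE)
  if (length(vals) != prod(npts)) {
    stop(sprintf("expected %d values, found %d", prod(npts), length(vals)),
         call. = FALSE)
  }
  if (dimension == 2) {
    # write.table wrote one x-row per line, columns indexed by y
    vals <- matrix(vals, npts[1], npts[2], byrow = TRUE)
  }
  scalar_field(vals, grid, role = kv$role)
}

#' Write an analysis curve as delimited text
#'
#' Dispersion-relation curves, correlograms, power spectra and continuation
#' branches are all tabular; this writes their tibble form as
#' tab-separated text with a header row.
#'
#' @param x A result object with an [as_tibble()] method, or a data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, path) {
  d <- if (is.data.frame(x)) x else as_tibble(x)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
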