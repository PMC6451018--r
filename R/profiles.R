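#' Density profile container
#'
#' A steady-state density profile: an ordered grid of positions
#' `x` in `[0, 1]` with densities `rho(x)`, the shifted field
#' `phi(x) = 2 rho(x) - 1`, and a tag recording which route produced it.
#' The discrete site convention used throughout the package maps site
#' `i` of an `N`-site lattice to `x_i = (i - 1)/(N - 1)`, so both boundary
#' conditions sit on real sites.
#'
#' @param x strictly increasing positions in `[0, 1]`.
#' @param rho densities at `x`; exactly one of `rho`, `phi` must be given.
#' @param phi shifted field at `x`.
#' @param source one of `"simulation"`, `"meanfield_lattice"`,
#'   `"meanfield_continuum"`, `"rg_analytic"`, `"exact_master"`.
#' @param stderr optional per-point standard errors (simulation profiles).
#' @return An object of class `density_profile`: a data frame with columns
#'   `x`, `rho`, `phi`, `source` (and `stderr` when supplied).
#' @export
density_profile <- function(x, rho = NULL, phi = NULL, source, stderr = NULL) {
  sources <- c("simulation", "meanfield_lattice", "meanfield_continuum",
               "rg_analytic", "exact_master")
  source <- match.arg(source, sources)
  if (is.null(rho) == is.null(phi))
    stop("supply exactly one of `rho` and `phi`")
  if (any(!is.finite(x)) || any(diff(x) <= 0))
    stop("`x` must be finite and strictly increasing")
  if (min(x) < 0 || max(x) > 1) stop("`x` must lie in [0, 1]")
  if (is.null(rho)) rho <- rho_from_phi(phi) else phi <- phi_from_rho(rho)
  if (length(rho) != length(x)) stop("`x` and the density must match in length")
  out <- data.frame(x = as.numeric(x), rho = as.numeric(rho),
                    phi = as.numeric(phi), source = source,
                    stringsAsFactors = FALSE)
  if (!is.null(stderr)) {
    if (length(stderr) != length(x) || any(stderr[is.finite(stderr)] < 0))
      stop("`stderr` must be a non-negative vector matching `x`")
    out$stderr <- as.numeric(stderr)
  }
  class(out) <- c("density_profile", "data.frame")
  out
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile: %d points, source = %s>\n",
              nrow(x), x$source[1]))
  cat(sprintf("  x in [%g, %g]; rho in [%.4f, %.4f]\n",
              min(x$x), max(x$x), min(x$rho), max(x$rho)))
  invisible(x)
}

#' Interpolate a profile's phi field at arbitrary positions
#'
#' Piecewise-linear interpolation (no spline overshoot at shocks).
#'
#' @param profile a [density_profile()].
#' @param x_out positions inside the profile's grid range.
#' @return Numeric vector of `phi` values at `x_out`.
#' @export
profile_phi_at <- function(profile, x_out) {
  approx(profile$x, profile$phi, xout = x_out, rule = 1)$y
}

#' Write / read a profile as TSV
#'
#' Columns `x`, `rho`, `phi`, `source` (plus `stderr` when present), with a
#' header row; full double precision.
#'
#' @param profile a [density_profile()].
#' @param path file path.
#' @return `write_profile_tsv` returns `path` invisibly; `read_profile_tsv`
#'   returns the reconstructed [density_profile()].
#' @export
write_profile_tsv <- function(profile, path) {
  df <- as.data.frame(profile)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("x", "rho", "phi", "source")
  if (!all(need %in% names(df)))
    stop("profile TSV must have columns x, rho, phi, source")
  density_profile(df$x, rho = df$rho, source = df$source[1],
                  stderr = df$stderr)
}
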