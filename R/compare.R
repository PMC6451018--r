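#' Discrepancy metrics between two density profiles
#'
#' Interpolates both profiles (piecewise-linearly, to avoid overshoot at
#' shocks) onto the union of their grids restricted to `x_window` and
#' reports symmetric discrepancy metrics on `phi`: the maximum absolute
#' difference (`l_inf`), the root-mean-square difference (`l2`), the offset
#' between shock positions when both profiles have an interior sign change
#' (`shock_offset`), and — when either profile carries a `stderr` column —
#' the fraction of compared points at which the two profiles agree within
#' three standard errors (`frac_within_3se`).
#'
#' @param a,b [density_profile()] objects whose grids cover `x_window`.
#' @param x_window numeric length-2 window of positions to compare on.
#' @return A list of class `comparison_report` with fields `l_inf`, `l2`,
#'   `shock_offset`, `frac_within_3se`, `n_points`, `x_window`.
#' @export
compare_profiles <- function(a, b, x_window = c(0, 1)) {
  stopifnot(inherits(a, "density_profile"), inherits(b, "density_profile"))
  lo <- max(x_window[1], min(a$x), min(b$x))
  hi <- min(x_window[2], max(a$x), max(b$x))
  if (lo >= hi) stop("profiles do not overlap on the requested window")
  grid <- sort(unique(c(a$x[a$x >= lo & a$x <= hi],
                        b$x[b$x >= lo & b$x <= hi], lo, hi)))
  pa <- profile_phi_at(a, grid)
  pb <- profile_phi_at(b, grid)
  d <- pa - pb
  se <- NULL
  if (!is.null(a$stderr)) se <- approx(a$x, a$stderr, grid, rule = 2)$y
  if (!is.null(b$stderr))  {
    se_b <- approx(b$x, b$stderr, grid, rule = 2)$y
    se <- if (is.null(se)) se_b else sqrt(se^2 + se_b^2)
  }
  frac3 <- if (!is.null(se)) mean(abs(d) <= 3 * 2 * se) else NA_real_
  # factor 2: stderr is on rho, differences are on phi = 2 rho - 1

  sa <- find_shock_position(a)
  sb <- find_shock_position(b)
  offset <- if (!is.null(sa) && !is.null(sb)) abs(sa$x0 - sb$x0) else NA_real_

  structure(list(l_inf = max(abs(d)), l2 = sqrt(mean(d^2)),
                 shock_offset = offset, frac_within_3se = frac3,
                 n_points = length(grid), x_window = c(lo, hi)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison on [%.3g, %.3g], %d pts: L_inf = %.4g, L2 = %.4g",
              x$x_window[1], x$x_window[2], x$n_points, x$l_inf, x$l2))
  if (!is.na(x$shock_offset)) cat(sprintf(", shock offset = %.4g", x$shock_offset))
  if (!is.na(x$frac_within_3se))
    cat(sprintf(", %.1f%% within 3 SE", 100 * x$frac_within_3se))
  cat(">\n")
  invisible(x)
}

#' Collapse residual across profiles at different epsilon
#'
#' Applies [collapse_transform()] to each profile with its own fitted
#' constants, interpolates all collapse curves onto a common `x_tilde` grid
#' inside `xt_window`, and returns the maximum pairwise L-infinity
#' difference. Small residuals certify the predicted `epsilon`-independent
#' master curve.
#'
#' @param profiles list of [density_profile()] objects.
#' @param constants_list list of [fit_constants()] results, one per profile.
#' @param xt_window inner-coordinate window (default `c(-20, 20)`).
#' @param n_grid number of `x_tilde` evaluation points.
#' @return A list with `residual` (max pairwise L-inf), `pairwise` matrix,
#'   and the common `x_tilde` grid.
#' @export
collapse_residual <- function(profiles, constants_list,
                              xt_window = c(-20, 20), n_grid = 201L) {
  stopifnot(length(profiles) == length(constants_list), length(profiles) >= 2)
  curves <- Map(collapse_transform, profiles, constants_list)
  lo <- max(vapply(curves, function(cv) min(cv$x_tilde), numeric(1)), xt_window[1])
  hi <- min(vapply(curves, function(cv) max(cv$x_tilde), numeric(1)), xt_window[2])
  if (lo >= hi) stop("collapse curves do not overlap in x_tilde")
  grid <- seq(lo, hi, length.out = n_grid)
  vals <- vapply(curves,
                 function(cv) approx(cv$x_tilde, cv$scaled_phi, grid, rule = 1)$y,
                 numeric(n_grid))
  m <- length(profiles)
  pw <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    pw[i, j] <- pw[j, i] <- max(abs(vals[, i] - vals[, j]), na.rm = TRUE)
  list(residual = max(pw), pairwise = pw, x_tilde = grid)
}
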