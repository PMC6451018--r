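#' Mean-field time derivatives on the lattice
#'
#' Right-hand side of the factorized site equations
#' `d rho_i/dt = rho_{i-1}(1 - rho_i) - rho_i(1 - rho_{i+1})
#'   + omega_a (1 - rho_i) - omega_d rho_i`,
#' with the injection form `alpha (1 - rho_1)` replacing the inflow at site 1
#' and the withdrawal form `beta rho_N` replacing the outflow at site `N`.
#' A zero vector certifies a steady state.
#'
#' @param rho density vector of length `N`.
#' @param params a [model_params()] object.
#' @return Numeric vector `d rho / d t` of length `N`.
#' @export
meanfield_residual <- function(rho, params) {
  N <- params$N
  stopifnot(length(rho) == N)
  inflow <- c(params$alpha * (1 - rho[1]), rho[-N] * (1 - rho[-1]))
  outflow <- c(rho[-N] * (1 - rho[-1]), params$beta * rho[N])
  inflow - outflow + params$omega_a * (1 - rho) - params$omega_d * rho
}

# tridiagonal Jacobian of meanfield_residual as a Matrix::bandSparse
meanfield_jacobian <- function(rho, params) {
  N <- params$N
  lower <- (1 - rho[-1])                       # d f_i / d rho_{i-1}, i = 2..N
  upper <- rho[-N]                             # d f_i / d rho_{i+1}, i = 1..N-1
  diag_in <- c(-params$alpha, -rho[-N])        # inflow part
  diag_out <- c(-(1 - rho[-1]), -params$beta)  # outflow part
  diag_lk <- -(params$omega_a + params$omega_d)
  Matrix::bandSparse(N, N, k = -1:1,
                     diagonals = list(lower, diag_in + diag_out + diag_lk, upper))
}

newton_polish <- function(rho, params, tol, max_iter = 40L) {
  res <- meanfield_residual(rho, params)
  rnorm0 <- max(abs(res))
  for (it in seq_len(max_iter)) {
    if (max(abs(res)) < tol)
      return(list(rho = rho, residual = max(abs(res)), converged = TRUE))
    J <- meanfield_jacobian(rho, params)
    step <- tryCatch(as.numeric(Matrix::solve(J, -res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    ok <- FALSE
    for (h in 1:12) {
      cand <- rho + lambda * step
      if (all(cand > -1e-6 & cand < 1 + 1e-6)) {
        rc <- meanfield_residual(cand, params)
        if (max(abs(rc)) < max(abs(res))) {
          rho <- cand; res <- rc; ok <- TRUE; break
        }
      }
      lambda <- lambda / 2
    }
    if (!ok) break
  }
  list(rho = rho, residual = max(abs(res)), converged = max(abs(res)) < tol,
       start_residual = rnorm0)
}

#' Steady state of the lattice mean-field equations
#'
#' Finds the fixed point of the `N` coupled factorized equations (see
#' [meanfield_residual()]) by pseudo-time relaxation — integration of the
#' stiff ODE system with a banded-Jacobian implicit integrator — followed by
#' a damped Newton polish to drive the residual below `tol`. Relaxation is
#' robust for arbitrarily small `epsilon = 1/(2N)` where continuation-based
#' boundary-value solvers stall, and is therefore the primary route to the
#' small-`epsilon` steady state.
#'
#' @param params a [model_params()] object with `N >= 3`.
#' @param tol maximum absolute steady-state residual (default `1e-10`;
#'   profiles feed subtraction-heavy comparisons downstream).
#' @param max_time cap on the accumulated pseudo-time (default `5e5`).
#' @param rho_init optional initial density vector (defaults to the linear
#'   ramp from `alpha` to `gamma`).
#' @return A [density_profile()] with `source = "meanfield_lattice"` and
#'   attribute `"residual"` carrying the certified residual.
#' @export
#' @examples
#' # alpha = gamma = rho_LK: the flat profile is an exact fixed point
#' p <- scaled_model_params(alpha = 0.6, gamma = 0.6, Omega = 0.3, r = 0.2, N = 50)
#' prof <- solve_meanfield_lattice(p)
#' max(abs(prof$rho - 0.6))
solve_meanfield_lattice <- function(params, tol = 1e-10, max_time = 5e5,
                                    rho_init = NULL) {
  stopifnot(inherits(params, "tasep_params"))
  N <- params$N
  if (N < 3) stop("lattice mean-field solver needs N >= 3")
  rho <- if (is.null(rho_init)) {
    params$alpha + (params$gamma - params$alpha) * (seq_len(N) - 1) / (N - 1)
  } else {
    stopifnot(length(rho_init) == N)
    as.numeric(rho_init)
  }

  deriv <- function(t, y, parms) list(meanfield_residual(y, params))
  t_done <- 0
  chunk <- max(200, N)
  repeat {
    np <- newton_polish(rho, params, tol)
    if (np$converged && all(np$rho >= -1e-9 & np$rho <= 1 + 1e-9) &&
        max(abs(np$rho - rho)) < 0.05) {
      rho <- pmin(pmax(np$rho, 0), 1)
      prof <- density_profile(x = (seq_len(N) - 1) / (N - 1), rho = rho,
                              source = "meanfield_lattice")
      attr(prof, "residual") <- max(abs(meanfield_residual(rho, params)))
      attr(prof, "pseudo_time") <- t_done
      return(prof)
    }
    if (t_done >= max_time)
      stop(sprintf(paste0("lattice mean-field relaxation did not reach tol = %g ",
                          "within max_time = %g (final residual %.3e)"),
                   tol, max_time, np$residual))
    sol <- deSolve::lsoda(y = rho, times = c(0, chunk), func = deriv,
                          parms = NULL, jactype = "bandint",
                          bandup = 1L, banddown = 1L,
                          rtol = 1e-8, atol = 1e-10)
    rho <- pmin(pmax(as.numeric(sol[nrow(sol), -1]), 0), 1)
    t_done <- t_done + chunk
    chunk <- min(2 * chunk, max_time - t_done + 1)
  }
}

#' Steady state of the singular continuum equation by collocation
#'
#' Solves the two-point boundary-value problem
#' `epsilon rho'' + (2 rho - 1) rho' + Omega (rho_LK - rho) = 0` with
#' `rho(0) = alpha`, `rho(1) = gamma`, by second-order central differences
#' and damped Newton iteration, using continuation in `epsilon`: the problem
#' is solved at the largest value of `epsilon_schedule` first and each
#' solution seeds the next smaller value, ending at `target_epsilon`. This is
#' practical at moderate `epsilon`; for very small `epsilon` use
#' [solve_meanfield_lattice()], which does not require resolving the layer
#' on a global grid.
#'
#' @param params a [model_params()] object (supplies `alpha`, `gamma`,
#'   `Omega`, `rho_LK`; its `N` is ignored here).
#' @param target_epsilon the singular parameter `epsilon > 0` to solve at.
#' @param epsilon_schedule strictly decreasing continuation sequence ending
#'   at `target_epsilon`; default a geometric ladder from
#'   `max(0.1, target_epsilon)` with ratio 1/2.
#' @param n_grid number of collocation points (default resolves the layer,
#'   `h <= epsilon/4`, capped at 20001).
#' @param tol Newton residual tolerance on the discretized equations.
#' @return A [density_profile()] with `source = "meanfield_continuum"` and a
#'   `"residual"` attribute.
#' @export
solve_continuum_bvp <- function(params, target_epsilon,
                                epsilon_schedule = NULL, n_grid = NULL,
                                tol = 1e-10) {
  stopifnot(inherits(params, "tasep_params"))
  if (!is.numeric(target_epsilon) || target_epsilon <= 0)
    stop("`target_epsilon` must be > 0")
  rho_lk <- if (is.na(params$rho_LK)) 0.5 else params$rho_LK
  Omega <- params$Omega
  if (is.null(epsilon_schedule)) {
    epsilon_schedule <- target_epsilon
    while (epsilon_schedule[1] < 0.1)
      epsilon_schedule <- c(min(2 * epsilon_schedule[1], 0.1), epsilon_schedule)
  }
  if (any(diff(epsilon_schedule) >= 0) ||
      abs(epsilon_schedule[length(epsilon_schedule)] - target_epsilon) > 0)
    stop("`epsilon_schedule` must strictly decrease and end at target_epsilon")
  if (is.null(n_grid))
    n_grid <- min(20001L, max(1001L, ceiling(4 / target_epsilon) + 1L))
  M <- as.integer(n_grid)
  x <- seq(0, 1, length.out = M)
  h <- x[2] - x[1]
  rho <- params$alpha + (params$gamma - params$alpha) * x

  bvp_res <- function(rho, eps) {
    j <- 2:(M - 1)
    d2 <- (rho[j - 1] - 2 * rho[j] + rho[j + 1]) / h^2
    d1 <- (rho[j + 1] - rho[j - 1]) / (2 * h)
    c(rho[1] - params$alpha,
      eps * d2 + (2 * rho[j] - 1) * d1 + Omega * (rho_lk - rho[j]),
      rho[M] - params$gamma)
  }
  bvp_jac <- function(rho, eps) {
    j <- 2:(M - 1)
    d1 <- (rho[j + 1] - rho[j - 1]) / (2 * h)
    lower <- c(eps / h^2 - (2 * rho[j] - 1) / (2 * h), 0)
    diagm <- c(1, -2 * eps / h^2 + 2 * d1 - Omega, 1)
    upper <- c(0, eps / h^2 + (2 * rho[j] - 1) / (2 * h))
    Matrix::bandSparse(M, M, k = -1:1, diagonals = list(lower, diagm, upper))
  }

  for (eps in epsilon_schedule) {
    converged <- FALSE
    res <- bvp_res(rho, eps)
    # the FD residual cannot beat the round-off floor of the eps/h^2 terms
    tol_eff <- max(tol, 10 * .Machine$double.eps * (eps / h^2 + 1 / h))
    for (it in 1:60) {
      if (max(abs(res)) < tol_eff) { converged <- TRUE; break }
      step <- as.numeric(Matrix::solve(bvp_jac(rho, eps), -res))
      lambda <- 1
      improved <- FALSE
      for (hlv in 1:15) {
        cand <- rho + lambda * step
        rc <- bvp_res(cand, eps)
        if (max(abs(rc)) < max(abs(res))) {
          rho <- cand; res <- rc; improved <- TRUE; break
        }
        lambda <- lambda / 2
      }
      if (!improved) break
    }
    if (!converged)
      stop(sprintf(paste0("continuation stalled at epsilon = %g ",
                          "(residual %.3e); try solve_meanfield_lattice for ",
                          "smaller epsilon"), eps, max(abs(res))))
  }
  rho <- pmin(pmax(rho, 0), 1)
  prof <- density_profile(x = x, rho = rho, source = "meanfield_continuum")
  attr(prof, "residual") <- max(abs(bvp_res(rho, target_epsilon)))
  prof
}

#' Locate the shock (phi zero crossing) in a profile
#'
#' Finds sign changes of `phi = 2 rho - 1`, interpolates each crossing
#' linearly between the bracketing grid points, and — if several crossings
#' exist — returns the one with the steepest slope, flagging the
#' multiplicity. The width estimate is the distance over which `phi`
#' traverses the central 76% of its jump across the steep region (for a
#' `tanh` layer of width parameter `p` this is about `4 epsilon / p`),
#' which distinguishes an `O(epsilon)` boundary layer or interior shock
#' from smooth bulk variation.
#'
#' @param profile a [density_profile()] with at least 3 points.
#' @return `NULL` when `phi` has constant sign; otherwise a list of class
#'   `shock_location` with `x0`, `width_estimate`, `slope`, `n_crossings`
#'   and `multiple`.
#' @export
find_shock_position <- function(profile) {
  if (nrow(profile) < 3) stop("profile must have at least 3 points")
  x <- profile$x; phi <- profile$phi
  s <- phi[-length(phi)] * phi[-1]
  idx <- which(s < 0 | (phi[-length(phi)] == 0 & phi[-1] != 0))
  if (!length(idx)) {
    if (any(phi == 0) && !all(phi == 0)) idx <- which(phi == 0)[1] else return(NULL)
  }
  cross <- lapply(idx, function(i) {
    if (phi[i] == 0) return(list(x0 = x[i], slope = (phi[i + 1] - phi[i]) / (x[i + 1] - x[i]), i = i))
    x0 <- x[i] - phi[i] * (x[i + 1] - x[i]) / (phi[i + 1] - phi[i])
    list(x0 = x0, slope = (phi[i + 1] - phi[i]) / (x[i + 1] - x[i]), i = i)
  })
  slopes <- vapply(cross, function(cr) abs(cr$slope), numeric(1))
  best <- cross[[which.max(slopes)]]

  # Layer width: delimit the steep region as the points where the local
  # slope falls below 10% of the crossing slope, take the phi jump across
  # it, and measure the distance over which phi traverses the central 76%
  # of that jump (for a tanh layer of width parameter p this is ~ 4 eps/p).
  i0 <- best$i
  seg_slopes <- diff(phi) / diff(x)
  thresh <- 0.1 * abs(best$slope)
  el <- i0
  while (el > 1 && abs(seg_slopes[el - 1]) >= thresh) el <- el - 1
  er <- i0 + 1L
  while (er < length(x) && abs(seg_slopes[er]) >= thresh) er <- er + 1L
  lo_val <- phi[el]; hi_val <- phi[er]
  mid <- (hi_val + lo_val) / 2
  lev <- 0.38 * (hi_val - lo_val)      # signed: carries the jump direction
  cross_level <- function(target) {
    yy <- phi[el:er] - mid
    xx <- x[el:er]
    dd <- yy - target
    hit <- which(dd[-length(dd)] * dd[-1] <= 0)
    if (!length(hit)) return(NA_real_)
    j <- hit[1]
    xx[j] + (target - yy[j]) * (xx[j + 1] - xx[j]) / (yy[j + 1] - yy[j])
  }
  wl <- cross_level(-lev)
  wr <- cross_level(lev)
  width <- if (is.na(wl) || is.na(wr)) NA_real_ else abs(wr - wl)

  structure(list(x0 = best$x0, width_estimate = width, slope = best$slope,
                 n_crossings = length(idx), multiple = length(idx) > 1L),
            class = "shock_location")
}

#' @export
print.shock_location <- function(x, ...) {
  cat(sprintf("<shock at x0 = %.6f, width ~ %.3g, slope %.3g%s>\n",
              x$x0, x$width_estimate, x$slope,
              if (x$multiple) sprintf(" (%d crossings)", x$n_crossings) else ""))
  invisible(x)
}
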