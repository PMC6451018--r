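#' Model parameters for TASEP with Langmuir kinetics
#'
#' Collects the microscopic rates of the open totally asymmetric exclusion
#' process with on-off (Langmuir) kinetics and derives the scaled quantities
#' that control the continuum steady state: the boundary density
#' `gamma = 1 - beta`, the lattice spacing `a = 1/N`, the singular parameter
#' `epsilon = 1/(2N)`, the scaled kinetic rate `Omega = (omega_a + omega_d) N`,
#' the kinetic asymmetry `r = (omega_a - omega_d)/(omega_a + omega_d)` and the
#' Langmuir density `rho_LK = omega_a/(omega_a + omega_d)`.
#'
#' @param alpha injection rate at site 1, in units of the hop rate; in `[0, 1]`.
#' @param beta withdrawal rate at site `N`; exactly one of `beta`, `gamma`
#'   must be given.
#' @param gamma boundary density at `x = 1`, `gamma = 1 - beta`.
#' @param omega_a adsorption (attachment) rate per empty site.
#' @param omega_d evaporation (detachment) rate per occupied site.
#' @param N number of lattice sites, integer `>= 2`.
#'
#' @return An object of class `tasep_params`: a list with the supplied rates
#'   and all derived fields (`gamma`, `a`, `epsilon`, `Omega`, `r`, `rho_LK`).
#'   `r` and `rho_LK` are `NA` when `omega_a = omega_d = 0`.
#' @seealso [scaled_model_params()] to construct from `(Omega, r, N)` instead.
#' @export
#' @examples
#' p <- model_params(alpha = 0.45, gamma = 0.66,
#'                   omega_a = 1e-4, omega_d = 1e-4, N = 1000)
#' p$Omega  # 0.2
#' p$r      # 0
model_params <- function(alpha, beta = NULL, gamma = NULL,
                         omega_a = 0, omega_d = 0, N) {
  if (!is.null(beta) && !is.null(gamma))
    stop("supply exactly one of `beta` and `gamma` (gamma = 1 - beta)")
  if (is.null(beta) && is.null(gamma))
    stop("one of `beta` or `gamma` is required")
  if (is.null(beta)) beta <- 1 - gamma
  gamma <- 1 - beta
  check_scalar <- function(x, nm, lo = 0, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("`%s` must be a finite numeric scalar", nm))
    if (x < lo || x > hi)
      stop(sprintf("`%s` = %g outside [%g, %g]", nm, x, lo, hi))
  }
  check_scalar(alpha, "alpha", 0, 1)
  check_scalar(beta, "beta", 0, 1)
  check_scalar(omega_a, "omega_a")
  check_scalar(omega_d, "omega_d")
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("`N` must be an integer >= 2")
  N <- as.integer(N)
  w <- omega_a + omega_d
  structure(list(
    alpha = alpha, beta = beta, gamma = gamma,
    omega_a = omega_a, omega_d = omega_d, N = N,
    a = 1 / N, epsilon = 1 / (2 * N),
    Omega = w * N,
    r = if (w > 0) (omega_a - omega_d) / w else NA_real_,
    rho_LK = if (w > 0) omega_a / w else NA_real_
  ), class = "tasep_params")
}

#' Model parameters from the scaled variables
#'
#' Inverts the map `(omega_a, omega_d) -> (Omega, r)` at given `N`:
#' `omega_a = Omega (1 + r) / (2N)`, `omega_d = Omega (1 - r) / (2N)`.
#'
#' @inheritParams model_params
#' @param Omega scaled kinetic rate `(omega_a + omega_d) N`, `>= 0`.
#' @param r kinetic asymmetry in `[-1, 1]`; `r = 2 rho_LK - 1`.
#' @return A `tasep_params` object.
#' @export
scaled_model_params <- function(alpha, beta = NULL, gamma = NULL,
                                Omega, r = 0, N) {
  if (!is.numeric(Omega) || Omega < 0) stop("`Omega` must be >= 0")
  if (!is.numeric(r) || abs(r) > 1) stop("`r` must lie in [-1, 1]")
  model_params(alpha, beta = beta, gamma = gamma,
               omega_a = Omega * (1 + r) / (2 * N),
               omega_d = Omega * (1 - r) / (2 * N), N = N)
}

#' @export
print.tasep_params <- function(x, ...) {
  cat("TASEP-LK parameters\n")
  cat(sprintf("  alpha = %g, beta = %g (gamma = %g), N = %d\n",
              x$alpha, x$beta, x$gamma, x$N))
  cat(sprintf("  omega_a = %g, omega_d = %g\n", x$omega_a, x$omega_d))
  cat(sprintf("  Omega = %g, r = %g, rho_LK = %g, epsilon = %g\n",
              x$Omega, x$r, x$rho_LK, x$epsilon))
  invisible(x)
}

#' Read model parameters from a JSON configuration
#'
#' Schema: `{"alpha": num, "beta": num | "gamma": num, "omega_a": num,
#' "omega_d": num, "N": int}`. `beta` and `gamma` are mutually exclusive and
#' unknown keys are rejected.
#'
#' @param path path to a JSON file, or a named list already parsed.
#' @return A `tasep_params` object.
#' @export
params_from_json <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  if (!is.list(cfg)) stop("configuration must be a JSON object")
  allowed <- c("alpha", "beta", "gamma", "omega_a", "omega_d", "N")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  model_params(alpha = cfg$alpha, beta = cfg$beta, gamma = cfg$gamma,
               omega_a = cfg$omega_a %||% 0, omega_d = cfg$omega_d %||% 0,
               N = cfg$N)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify the steady-state phase at r = 0
#'
#' For symmetric Langmuir kinetics (`r = 0`) in the high-`gamma` corner of the
#' phase diagram (`gamma > 1/2 + Omega/2`), the low-density phase borders the
#' shock phase on `gamma = 1 - Omega/2 - alpha` and the shock phase borders
#' the high-density phase on `gamma = 1 + Omega/2 - alpha`. Writing
#' `s = alpha + gamma`, the label is `LD` for `s < 1 - Omega/2`, `SHOCK` for
#' `1 - Omega/2 < s < 1 + Omega/2`, and `HD` for `s > 1 + Omega/2`.
#'
#' Outside the region where those boundaries are established
#' (`gamma <= 1/2 + Omega/2`) the function refuses to extrapolate and returns
#' `"OUT_OF_REGION"`.
#'
#' @param alpha,gamma boundary densities, each in `[0, 1]`.
#' @param Omega scaled kinetic rate, `>= 0`.
#' @param tol tolerance for the boundary labels: equality of
#'   `alpha + gamma` with `1 -/+ Omega/2` within `tol` yields
#'   `"BOUNDARY_LD_SHOCK"` / `"BOUNDARY_SHOCK_HD"`.
#' @return A single character label among `"LD"`, `"SHOCK"`, `"HD"`,
#'   `"BOUNDARY_LD_SHOCK"`, `"BOUNDARY_SHOCK_HD"`, `"OUT_OF_REGION"`.
#' @export
#' @examples
#' classify_phase(0.45, 0.66, 0.2)  # "HD"
#' classify_phase(0.30, 0.70, 0.2)  # "SHOCK"
classify_phase <- function(alpha, gamma, Omega, tol = 1e-9) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]")
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1)
    stop("`gamma` must lie in [0, 1]")
  if (!is.numeric(Omega) || Omega < 0) stop("`Omega` must be >= 0")
  if (gamma <= 0.5 + Omega / 2) return("OUT_OF_REGION")
  s <- alpha + gamma
  lo <- 1 - Omega / 2
  hi <- 1 + Omega / 2
  if (abs(s - lo) <= tol) return("BOUNDARY_LD_SHOCK")
  if (abs(s - hi) <= tol) return("BOUNDARY_SHOCK_HD")
  if (s < lo) return("LD")
  if (s > hi) return("HD")
  "SHOCK"
}

#' Density/field transforms
#'
#' The continuum analysis works with the shifted field `phi = 2 rho - 1`,
#' which is antisymmetric about half filling. These helpers map between the
#' two representations.
#'
#' @param rho densities in `[0, 1]`.
#' @param phi shifted field values in `[-1, 1]`.
#' @return The transformed numeric vector.
#' @export
phi_from_rho <- function(rho) {
  if (any(!is.finite(rho)) || any(rho < 0 | rho > 1))
    stop("`rho` must lie in [0, 1]")
  2 * rho - 1
}

#' @rdname phi_from_rho
#' @export
rho_from_phi <- function(phi) {
  if (any(!is.finite(phi)) || any(phi < -1 | phi > 1))
    stop("`phi` must lie in [-1, 1]")
  (phi + 1) / 2
}
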