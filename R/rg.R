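#' Boundary-layer kernel and zeroth-order layer solution
#'
#' `bl_psi(p, x_tilde)` is the layer kernel `tanh(p x_tilde / 2)`;
#' `phi0(p, k, x_tilde)` is the zeroth-order boundary-layer solution
#' `p tanh[(p/2)(x_tilde + k)]`, characterized by the width parameter `p`
#' and the center offset `k` in inner units `x_tilde = x / epsilon`.
#'
#' @param p layer amplitude/width parameter.
#' @param k center offset in inner units.
#' @param x_tilde inner coordinate.
#' @return Numeric vector of field values.
#' @export
bl_psi <- function(p, x_tilde) tanh(p * x_tilde / 2)

#' @rdname bl_psi
#' @export
phi0 <- function(p, k, x_tilde) p * tanh((p / 2) * (x_tilde + k))

#' Naive first-order perturbative solution and its mu-split form
#'
#' The straightforward expansion of the inner equation in `epsilon` produces,
#' at first order, a secular term growing linearly in `x_tilde`:
#' `phi = p psi - epsilon ((r - p)/p) Omega x_tilde psi` (+ regular terms),
#' with `psi = tanh(p x_tilde / 2)`. Introducing an arbitrary length scale
#' `mu` splits the secular piece into a bounded `(x_tilde - mu)` part and a
#' `mu`-proportional part that is subsequently absorbed into a renormalized
#' width. The regular remainder is not evaluated here; the two printed forms
#' agree identically for any `mu`.
#'
#' @param p zeroth-order width parameter, nonzero.
#' @param x_tilde inner coordinate (vectorized).
#' @param Omega scaled kinetic rate.
#' @param r kinetic asymmetry.
#' @param epsilon singular parameter.
#' @param mu arbitrary length scale in inner units.
#' @return A list of class `perturbative_solution`: `phi0_part`,
#'   `divergent_part`, `mu_split_parts` (three-term list whose sum equals
#'   `phi0_part + divergent_part` identically), and `total`.
#' @export
naive_first_order <- function(p, x_tilde, Omega, r, epsilon, mu = 0) {
  if (!is.numeric(p) || p == 0) stop("degenerate boundary layer: p must be nonzero")
  psi <- bl_psi(p, x_tilde)
  pref <- epsilon * (r - p) / p * Omega
  div_part <- -pref * x_tilde * psi
  parts <- list(zeroth = p * psi,
                bounded = -pref * (x_tilde - mu) * psi,
                mu_term = -pref * mu * psi)
  structure(list(phi0_part = p * psi, divergent_part = div_part,
                 mu_split_parts = parts,
                 total = p * psi + div_part),
            class = "perturbative_solution")
}

#' Renormalized (divergence-free) first-order profile
#'
#' The first-order inner solution after absorbing the secular divergence into
#' the renormalized width `p_r = p - epsilon a1(mu)` with
#' `a1 = (mu / p_r)(r - p_r) Omega`:
#' \deqn{\phi = p_r \psi + \varepsilon \frac{\mu}{2}(r - p_r)
#'   \frac{\Omega \tilde x}{\cosh^2(p_r \tilde x / 2)}
#'   - \varepsilon \frac{r - p_r}{p_r}\psi\, \Omega (\tilde x - \mu),}
#' with `psi = tanh(p_r x_tilde / 2)`. Every term is bounded for
#' `mu ~ x_tilde`; composed with the flow of `p_r(mu)` (see [rg_flow()]) the
#' result is independent of `mu` up to `O(epsilon^2)`.
#'
#' @param p_r renormalized width parameter at scale `mu`, nonzero.
#' @inheritParams naive_first_order
#' @return Numeric vector of `phi` values.
#' @export
renormalized_profile <- function(p_r, mu, x_tilde, Omega, r, epsilon) {
  if (!is.numeric(p_r) || p_r == 0) stop("degenerate boundary layer: p_r must be nonzero")
  psi <- bl_psi(p_r, x_tilde)
  p_r * psi +
    epsilon * (mu / 2) * (r - p_r) * Omega * x_tilde / cosh(p_r * x_tilde / 2)^2 -
    epsilon * (r - p_r) / p_r * psi * Omega * (x_tilde - mu)
}

#' Renormalization-group flow of the layer width
#'
#' Integrates `d p_r / d mu = -epsilon Omega (r - p_r) / p_r`. For `r = 0`
#' the solution is exactly `p_r(mu) = Omega epsilon mu + c`; for small `r`
#' it is `Omega epsilon mu + c - r log(Omega epsilon mu + c)` up to
#' `O(lambda^2)` with `lambda = epsilon Omega r`. Rewritten with `mu` as the
#' outer position, the flow is the `epsilon = 0` bulk equation in the
#' `phi` variable, which is what lets the layer solution reconstruct the
#' global profile.
#'
#' @param p_r_init initial width at `mu_span[1]`, nonzero.
#' @param mu_span increasing vector of `mu` values (at least first/last).
#' @inheritParams naive_first_order
#' @param n_out number of output points when `mu_span` has length 2.
#' @return A data frame with columns `mu` and `p_r`.
#' @export
rg_flow <- function(p_r_init, mu_span, epsilon, Omega, r = 0, n_out = 201L) {
  if (p_r_init == 0) stop("singular flow: p_r_init must be nonzero")
  mus <- if (length(mu_span) == 2L) seq(mu_span[1], mu_span[2], length.out = n_out)
         else mu_span
  f <- function(mu, y, parms) {
    if (abs(y[1]) < 1e-12)
      stop(sprintf("singular flow: p_r reached 0 near mu = %g", mu))
    list(-epsilon * Omega * (r - y[1]) / y[1])
  }
  sol <- deSolve::ode(y = c(p_r = p_r_init), times = mus, func = f,
                      parms = NULL, rtol = 1e-12, atol = 1e-14)
  data.frame(mu = sol[, 1], p_r = sol[, 2])
}

#' Fitted constants of the global RG profile
#'
#' Pins the resummed profile to the boundary conditions `rho(0) = alpha`,
#' `rho(1) = gamma` for the three phases (at `r = 0`; `r != 0` is handled by
#' the same two-condition construction applied to the `r != 0` amplitude and
#' is an extension beyond the symmetric-kinetics worked cases):
#'
#' * `HD` — the layer sits at `x = 0`; the saturated bulk at `x = 1` gives
#'   `C + Omega - r log(C + Omega) = 2 gamma - 1` (at `r = 0`, simply
#'   `C = 2 gamma - 1 - Omega`), and the layer center `x0 = epsilon k`
#'   follows from the boundary value `phi(0) = 2 alpha - 1`, i.e. a
#'   bracketed root solve of `C tanh(C k / 2) = 1 - 2 alpha`.
#' * `LD` — particle-hole mirror: bulk anchored at `x = 0`
#'   (`C - r log(C) = 2 alpha - 1`), layer at `x = 1` fixed by
#'   `phi(1) = 2 gamma - 1`.
#' * `SHOCK` — the profile is antisymmetric about the shock,
#'   `phi(x0 + d) = -phi(x0 - d)`, with amplitude `C + Omega |x - x0|`;
#'   equating the two saturated bulk branches gives
#'   `x0 = 1/2 + (1 - alpha - gamma)/Omega` (so `x0 = 1/2` exactly when
#'   `alpha + gamma = 1`) and the `x = 1` condition gives
#'   `C = 2 gamma - 1 - Omega (1 - x0)`.
#'
#' @param params a [model_params()] object (or one from
#'   [scaled_model_params()]).
#' @param phase `"auto"` (classify from the parameters) or one of `"LD"`,
#'   `"HD"`, `"SHOCK"`.
#' @param epsilon_eff effective `epsilon` used when evaluating the profile;
#'   defaults to the nominal `1/(2N)`. Exposed because higher-order
#'   corrections can make the best-fitting effective width differ from the
#'   nominal value at moderate `epsilon`.
#' @return An object of class `rg_constants`: list with `C`, `x0`, `k`
#'   (`= x0 / epsilon_eff` for layer phases), `epsilon_eff`, `phase`,
#'   `Omega`, `r`.
#' @export
#' @examples
#' p <- scaled_model_params(alpha = 0.45, gamma = 0.66, Omega = 0.2, r = 0, N = 500)
#' fit_constants(p)$C  # 0.12
fit_constants <- function(params, phase = "auto", epsilon_eff = NULL) {
  stopifnot(inherits(params, "tasep_params"))
  alpha <- params$alpha; gamma <- params$gamma
  Omega <- params$Omega
  r <- if (is.na(params$r)) 0 else params$r
  eps <- epsilon_eff %||% params$epsilon
  if (phase == "auto") {
    phase <- classify_phase(alpha, gamma, Omega)
    if (!phase %in% c("LD", "HD", "SHOCK"))
      stop("automatic phase classification gave '", phase,
           "'; supply `phase` explicitly")
  }
  phase <- match.arg(phase, c("LD", "HD", "SHOCK"))
  amp_of_base <- function(base) {
    if (r == 0) return(base)
    if (any(base <= 0)) stop("non-positive log argument in r != 0 amplitude")
    base - r * log(base)
  }
  solve_C_from_amp <- function(target, base_shift) {
    # solve amp_of_base(C + base_shift) = target for C; for r > 0 the map
    # b -> b - r log(b) has its minimum r - r log(r) at b = r, so the branch
    # continuous in r -> 0 is the one with b > r
    if (r == 0) return(target - base_shift)
    b_lo <- if (r > 0) r * (1 + 1e-9) else 1e-12
    if (r > 0 && amp_of_base(b_lo) > target)
      stop("no bulk amplitude solves the r != 0 boundary condition: ",
           "minimum attainable amplitude ", signif(amp_of_base(r), 4),
           " exceeds the target ", signif(target, 4))
    g <- function(C) amp_of_base(C + base_shift) - target
    uniroot(g, lower = b_lo - base_shift,
            upper = target + abs(r) * 60 + 1, tol = 1e-14)$root
  }

  if (phase == "HD") {
    C <- solve_C_from_amp(2 * gamma - 1, Omega)
    if (C <= 0) stop("HD fit failed: bulk amplitude C = ", signif(C, 4),
                     " is not positive (wrong phase assignment?)")
    A0 <- amp_of_base(C)
    if (abs(2 * alpha - 1) >= A0)
      stop("no solution: |2 alpha - 1| = ", abs(2 * alpha - 1),
           " >= layer amplitude ", signif(A0, 4),
           "; the boundary value cannot be met by the layer")
    # phi(0) = A0 tanh(-A0 k / 2) = 2 alpha - 1  =>  A0 tanh(A0 k/2) = 1 - 2 alpha
    g <- function(k) A0 * tanh(A0 * k / 2) - (1 - 2 * alpha)
    k <- uniroot(g, lower = -200, upper = 200, tol = 1e-12)$root
    x0 <- eps * k
  } else if (phase == "LD") {
    C <- if (r == 0) 2 * alpha - 1 else {
      g <- function(C) amp_of_base(C) - (2 * alpha - 1)
      uniroot(g, lower = 1e-12, upper = 2, tol = 1e-14,
              extendInt = "no")$root
    }
    if (r == 0 && C >= 0)
      stop("LD fit failed: bulk amplitude C = ", signif(C, 4),
           " is not negative (wrong phase assignment?)")
    A1 <- amp_of_base(C + Omega)
    if (abs(2 * gamma - 1) >= abs(A1))
      stop("no solution: |2 gamma - 1| >= layer amplitude ", signif(abs(A1), 4))
    # phi(1) = A1 tanh(A1 (1 - x0) / (2 eps)) = 2 gamma - 1; k1 = (1 - x0)/eps
    g <- function(k1) A1 * tanh(A1 * k1 / 2) - (2 * gamma - 1)
    k1 <- uniroot(g, lower = -200, upper = 200, tol = 1e-12)$root
    x0 <- 1 - eps * k1
    k <- k1
  } else { # SHOCK
    if (Omega <= 0) stop("shock fit requires Omega > 0")
    x0 <- 0.5 + (1 - alpha - gamma) / Omega
    if (x0 <= 0 || x0 >= 1)
      stop("no interior shock: computed x0 = ", signif(x0, 4),
           " lies outside (0, 1) (wrong phase assignment?)")
    C <- solve_C_from_amp(2 * gamma - 1, Omega * (1 - x0))
    if (C <= 0) stop("shock fit failed: C = ", signif(C, 4), " not positive")
    k <- NA_real_
  }
  structure(list(C = C, x0 = x0, k = k, epsilon_eff = eps, phase = phase,
                 Omega = Omega, r = r),
            class = "rg_constants")
}

#' @export
print.rg_constants <- function(x, ...) {
  cat(sprintf("<rg_constants [%s]: C = %.6g, x0 = %.6g, k = %.6g, epsilon_eff = %g>\n",
              x$phase, x$C, x$x0, x$k, x$epsilon_eff))
  invisible(x)
}

# amplitude of the global profile at outer position x
rg_amplitude <- function(x, constants) {
  s <- if (constants$phase == "SHOCK") abs(x - constants$x0) else x
  base <- constants$C + constants$Omega * s
  if (constants$r == 0) return(base)
  if (any(base <= 0)) {
    bad <- x[base <= 0][1]
    stop("non-positive logarithm argument in the r != 0 amplitude at x = ",
         signif(bad, 6))
  }
  base - constants$r * log(base)
}

#' Global RG-resummed density profile
#'
#' The closed-form profile obtained by solving the RG flow and substituting
#' `mu = x_tilde`: `phi(x) = A(x) tanh[A(x) (x - x0) / (2 epsilon_eff)]`,
#' where for symmetric kinetics (`r = 0`) the amplitude is `A(x) = C + Omega x`
#' for the layer phases (`A(x) = C + Omega |x - x0|` for the antisymmetric
#' shock construction), and for `r != 0` the amplitude is
#' `A = B - r log(B)` with `B` the corresponding `r = 0` base. The formula
#' interpolates between the boundary layer (`C tanh(C x_tilde / 2)` as
#' `x -> x0`) and the bulk branch (`A(x)` itself once the `tanh` saturates).
#'
#' @param x outer positions in `[0, 1]` (vectorized).
#' @param constants an [fit_constants()] result (or compatible list with
#'   `C`, `x0`, `epsilon_eff`, `phase`, `Omega`, `r`).
#' @return Numeric vector of `phi` values.
#' @export
global_profile <- function(x, constants) {
  A <- rg_amplitude(x, constants)
  x_tilde <- (x - constants$x0) / constants$epsilon_eff
  A * tanh(A * x_tilde / 2)
}

#' Evaluate the global RG profile on a grid as a density profile
#'
#' @inheritParams global_profile
#' @param n number of grid points on `[0, 1]`.
#' @return A [density_profile()] with `source = "rg_analytic"`.
#' @export
rg_profile_grid <- function(constants, n = 1001L, x = NULL) {
  if (is.null(x)) x <- seq(0, 1, length.out = n)
  phi <- pmin(pmax(global_profile(x, constants), -1), 1)
  density_profile(x = x, phi = phi, source = "rg_analytic")
}

#' Scaling-collapse transform
#'
#' Maps a profile onto the predicted master curve: plotted against the inner
#' coordinate `x_tilde = (x - x0) / epsilon_eff`, the ratio
#' `phi(x) / A(x)` of profiles at different `epsilon` but identical
#' `(alpha, gamma, Omega, r)` collapses onto `tanh(A x_tilde / 2)`
#' (approximately `tanh(C x_tilde / 2)` in the layer region).
#'
#' @param profile a [density_profile()].
#' @param constants the fitted [fit_constants()] for the profile's
#'   parameters (its `epsilon_eff` and `x0` define the inner coordinate).
#' @return A data frame with columns `x_tilde` and `scaled_phi`.
#' @export
collapse_transform <- function(profile, constants) {
  A <- rg_amplitude(profile$x, constants)
  if (any(abs(A) < 1e-12))
    stop("degenerate scaling: amplitude C + Omega x vanishes on the grid")
  data.frame(x_tilde = (profile$x - constants$x0) / constants$epsilon_eff,
             scaled_phi = profile$phi / A)
}
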