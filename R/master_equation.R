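#' Exact stationary density from the full master equation (small N)
#'
#' Enumerates all `2^N` occupancy configurations of the open TASEP-LK chain,
#' assembles the generator of the continuous-time Markov chain (injection at
#' site 1 with rate `alpha` when empty, unit-rate hops onto empty forward
#' sites, withdrawal at site `N` with rate `beta`, adsorption with rate
#' `omega_a` on every empty site and evaporation with rate `omega_d` on every
#' occupied site), solves for the stationary distribution, and returns the
#' exact site densities `<tau_i>`. No factorization approximation is made,
#' so this serves as a brute-force oracle for the stochastic simulator.
#'
#' @param params a [model_params()] object with `N <= max_N`.
#' @param max_N size guard on the `2^N` enumeration (default 12).
#' @return A [density_profile()] with `source = "exact_master"`.
#' @export
#' @examples
#' p <- model_params(alpha = 1, beta = 1, N = 2)
#' exact_master_steady_state(p)$rho  # c(3, 2)/5
exact_master_steady_state <- function(params, max_N = 12L) {
  stopifnot(inherits(params, "tasep_params"))
  N <- params$N
  if (N > max_N)
    stop(sprintf("N = %d too large for exact enumeration (max_N = %d)", N, max_N))
  if (params$alpha <= 0 && params$omega_a <= 0 &&
      params$beta <= 0 && params$omega_d <= 0)
    stop("all rates are zero: the chain has no dynamics")
  M <- 2L^N
  bit <- 2L^(0:(N - 1L))  # site i <-> bit i-1

  # occupancy matrix: occ[s, i] for state index s = 1..M (config s-1)
  states <- 0:(M - 1L)
  occ <- matrix(0L, M, N)
  for (i in seq_len(N)) occ[, i] <- bitwAnd(states, bit[i]) %/% bit[i]

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(from, to, rate) {
    if (rate <= 0 || !length(from)) return(invisible())
    ii <<- c(ii, from); jj <<- c(jj, to)
    vv <<- c(vv, rep(rate, length(from)))
  }
  s1 <- states + 1L
  # injection at site 1 / withdrawal at site N
  add(s1[occ[, 1] == 0L], s1[occ[, 1] == 0L] + bit[1], params$alpha)
  add(s1[occ[, N] == 1L], s1[occ[, N] == 1L] - bit[N], params$beta)
  # hops i -> i+1
  for (i in seq_len(N - 1L)) {
    ok <- occ[, i] == 1L & occ[, i + 1L] == 0L
    add(s1[ok], s1[ok] - bit[i] + bit[i + 1L], 1)
  }
  # Langmuir kinetics on every site
  for (i in seq_len(N)) {
    e <- occ[, i] == 0L
    add(s1[e], s1[e] + bit[i], params$omega_a)
    add(s1[!e], s1[!e] - bit[i], params$omega_d)
  }

  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(M, M))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  # stationary distribution: pi^T Q = 0, sum(pi) = 1
  A <- Matrix::t(Q)
  A[M, ] <- 1
  b <- c(rep(0, M - 1L), 1)
  pi_s <- as.numeric(Matrix::solve(A, b))
  if (any(pi_s < -1e-10))
    stop("internal check failed: stationary solve produced negative mass")
  pi_s <- pmax(pi_s, 0); pi_s <- pi_s / sum(pi_s)

  rho <- as.numeric(crossprod(occ, pi_s))
  density_profile(x = (seq_len(N) - 1) / (N - 1), rho = pmin(pmax(rho, 0), 1),
                  source = "exact_master")
}
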