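# Inverting p*tanh[(p/2) x] = p/2 for p = 0.12 with an independent
# root-finder (bisection on tanh(0.06 x) = 0.5) gives x = 2 atanh(0.5)/0.12;
# the layer solution must return exactly half its amplitude there.
test_that("zeroth-order layer solution has the tanh form and limits", {
  expect_equal(phi0(0.37, 1.4, x_tilde = -1.4), 0)
  expect_equal(phi0(0.3, 0, x_tilde = 1e6), 0.3, tolerance = 1e-12)
  # negative p: the kink is inverted, phi0 -> |p| as x_tilde -> +Inf
  expect_equal(phi0(-0.3, 0, x_tilde = 1e6), 0.3, tolerance = 1e-12)
  x_half <- 2 * atanh(0.5) / 0.12
  expect_equal(phi0(0.12, 0, x_half), 0.06, tolerance = 1e-12)
  expect_equal(bl_psi(0.4, 3), tanh(0.6))
})

test_that("the mu-split of the first-order solution is an exact identity", {
  set.seed(6)
  for (i in 1:20) {
    p <- runif(1, -1, 1); if (abs(p) < 0.05) p <- 0.3
    sol <- naive_first_order(p, x_tilde = runif(5, -50, 50),
                             Omega = runif(1, 0, 0.5), r = runif(1, -0.9, 0.9),
                             epsilon = 10^runif(1, -4, -1), mu = runif(1, -20, 20))
    split_sum <- Reduce(`+`, sol$mu_split_parts)
    expect_equal(split_sum, sol$phi0_part + sol$divergent_part,
                 tolerance = 1e-14)
  }
  # r = p kills the secular term entirely
  sol <- naive_first_order(0.25, x_tilde = c(-10, 3, 200), Omega = 0.2,
                           r = 0.25, epsilon = 0.01)
  expect_equal(sol$divergent_part, c(0, 0, 0))
  expect_error(naive_first_order(0, 1, 0.2, 0, 0.01), "p must be nonzero")
  # direct evaluation of the secular term, cross-checked by hand:
  # -eps ((r - p)/p) Omega x psi with p = 0.3, r = 0, eps = 0.01, x = 100
  sol2 <- naive_first_order(0.3, 100, Omega = 0.2, r = 0, epsilon = 0.01)
  expect_equal(sol2$divergent_part, 0.01 * 0.2 * 100 * tanh(15),
               tolerance = 1e-14)
})

test_that("the renormalized profile is bounded and degenerates correctly", {
  expect_equal(renormalized_profile(0.3, mu = 7, x_tilde = 0,
                                    Omega = 0.2, r = 0, epsilon = 0.01), 0)
  # r = p_r: both correction terms vanish
  xt <- c(-30, -1, 2, 50)
  expect_equal(renormalized_profile(0.25, 5, xt, 0.2, r = 0.25, epsilon = 0.01),
               0.25 * tanh(0.25 * xt / 2), tolerance = 1e-14)
  expect_error(renormalized_profile(0, 5, 1, 0.2, 0, 0.01), "p_r")
  # all terms stay bounded as x_tilde grows with mu ~ x_tilde
  xt <- 10^(2:5)
  vals <- renormalized_profile(0.3, mu = xt, x_tilde = xt, Omega = 0.2,
                               r = 0, epsilon = 1e-3)
  expect_true(all(abs(vals) < 1))
})

test_that("the RG flow matches its closed-form solutions", {
  # r = 0: p_r(mu) = Omega eps mu + c exactly
  fl <- rg_flow(0.12, c(0, 2000), epsilon = 5e-4, Omega = 0.2, r = 0)
  expect_equal(fl$p_r, 0.2 * 5e-4 * fl$mu + 0.12, tolerance = 1e-9)
  # eps = 0: frozen width
  fl0 <- rg_flow(0.4, c(0, 100), epsilon = 0, Omega = 0.2, r = 0.3)
  expect_equal(fl0$p_r, rep(0.4, nrow(fl0)), tolerance = 1e-12)
  # r != 0: Omega eps mu + c - r log(Omega eps mu + c) holds to O(r^2):
  # halving r must quarter the worst deviation (Richardson check)
  dev_r <- function(r) {
    c0 <- 0.3; eps <- 1e-3
    fl <- rg_flow(c0 - r * log(c0), c(0, 1000), epsilon = eps, Omega = 0.2, r = r)
    lin <- 0.2 * eps * fl$mu + c0
    max(abs(fl$p_r - (lin - r * log(lin))))
  }
  ratio <- dev_r(0.1) / dev_r(0.05)
  expect_gt(ratio, 3); expect_lt(ratio, 5)
  expect_error(rg_flow(0, c(0, 1), 1e-3, 0.2), "singular")
})

test_that("flow and bulk equation are the same equation in disguise", {
  # substituting p_r(x/eps) into the eps = 0 bulk equation
  # phi phi' + Omega (r - phi) = 0 (outer units) gives a zero residual
  eps <- 1e-3; Omega <- 0.2; r <- 0.15
  fl <- rg_flow(0.35, c(0, 1 / eps), epsilon = eps, Omega = Omega, r = r,
                n_out = 501)
  x <- fl$mu * eps
  dpdx <- diff(fl$p_r) / diff(x)
  mid <- (fl$p_r[-1] + fl$p_r[-nrow(fl)]) / 2
  resid <- mid * dpdx + Omega * (r - mid)
  expect_lt(max(abs(resid)), 1e-3)  # central-difference error only
})

test_that("composed with the flow, the profile is mu-independent to O(eps^2)", {
  dphi_dmu <- function(eps) {
    f <- function(m) {
      pr <- rg_flow(0.25, c(0, m), epsilon = eps, Omega = 0.2, r = 0,
                    n_out = 2)$p_r[2]
      renormalized_profile(pr, m, x_tilde = 3, Omega = 0.2, r = 0,
                           epsilon = eps)
    }
    (f(5.05) - f(4.95)) / 0.1
  }
  d <- vapply(c(1e-2, 1e-3, 1e-4), dphi_dmu, numeric(1))
  slopes <- diff(log(abs(d))) / log(10)
  expect_true(all(abs(slopes + 2) < 0.15))
})

test_that("constants fitting reproduces the worked boundary-condition solves", {
  # high density: saturated bulk at x = 1 gives C + Omega = 2 gamma - 1
  hd <- fit_constants(hd_params(500))
  expect_equal(hd$C, 0.12, tolerance = 1e-12)
  # the layer equation C tanh(C k / 2) = 1 - 2 alpha is satisfied at the root
  expect_equal(hd$C * tanh(hd$C * hd$k / 2), 0.1, tolerance = 1e-12)
  expect_equal(hd$k, 2 / 0.12 * atanh(0.1 / 0.12), tolerance = 1e-9)
  expect_equal(hd$x0, hd$epsilon_eff * hd$k)
  expect_equal(global_profile(0, hd), -0.1, tolerance = 1e-12)  # BC at x = 0
  expect_equal(global_profile(1, hd), 0.32, tolerance = 1e-12)  # BC at x = 1

  # symmetric shock: C + Omega (1 - x0) = 2 gamma - 1 with x0 = 1/2
  sh <- fit_constants(shock_params(500))
  expect_equal(sh$C, 0.3, tolerance = 1e-12)
  expect_equal(sh$x0, 0.5, tolerance = 1e-12)
  # off-symmetric but inside the band: x0 from the bulk-branch matching
  sh2 <- fit_constants(scaled_model_params(alpha = 0.34, gamma = 0.7,
                                           Omega = 0.2, r = 0, N = 500))
  expect_equal(sh2$x0, 0.5 + (1 - 1.04) / 0.2, tolerance = 1e-12)
  expect_equal(global_profile(1, sh2), 0.4, tolerance = 1e-10)

  # low density: mirror fit, layer at x = 1
  ld <- fit_constants(ld_params(500))
  expect_equal(ld$C, -0.8)
  expect_equal(global_profile(1, ld), 0.4, tolerance = 1e-10)
  expect_lt(abs(global_profile(0.4, ld) - (-0.8 + 0.2 * 0.4)), 1e-8)

  # failure modes name the problem
  expect_error(fit_constants(scaled_model_params(alpha = 0.05, gamma = 0.66,
                                                 Omega = 0.2, r = 0, N = 100),
                             phase = "HD"), "cannot be met")
  expect_error(fit_constants(scaled_model_params(alpha = 0.45, gamma = 0.55,
                                                 Omega = 0.2, r = 0, N = 100)),
               "OUT_OF_REGION")
})

test_that("the asymmetric-kinetics profile reduces to the symmetric one at r = 0", {
  p <- hd_params(500)
  c0 <- fit_constants(p)
  x <- seq(0, 1, length.out = 301)
  manual <- (c0$C + 0.2 * x) * tanh((c0$C + 0.2 * x) * (x - c0$x0) /
                                      (2 * c0$epsilon_eff))
  expect_equal(global_profile(x, c0), manual, tolerance = 1e-14)
  # r != 0 amplitude carries the logarithmic correction
  pr <- scaled_model_params(alpha = 0.45, gamma = 0.66, Omega = 0.2, r = 0.05,
                            N = 500)
  cr <- fit_constants(pr, phase = "HD")
  base <- cr$C + 0.2
  expect_equal(base - 0.05 * log(base), 0.32, tolerance = 1e-10)
  expect_gt(base, 0.05)  # the branch continuous in r -> 0 is selected
  # and r = 0.1 admits no amplitude (minimum of b - r log b exceeds 0.32)
  expect_error(fit_constants(scaled_model_params(alpha = 0.45, gamma = 0.66,
                                                 Omega = 0.2, r = 0.1, N = 500),
                             phase = "HD"), "minimum attainable")
  # continuity in r: small r stays close to the r = 0 profile
  pr2 <- scaled_model_params(alpha = 0.45, gamma = 0.66, Omega = 0.2, r = 1e-8,
                             N = 500)
  cr2 <- fit_constants(pr2, phase = "HD")
  expect_equal(global_profile(x, cr2), global_profile(x, c0), tolerance = 1e-6)
  # log-argument domain error is raised with the offending x
  bad <- list(C = -0.1, x0 = 0, epsilon_eff = 1e-3, phase = "HD",
              Omega = 0.2, r = 0.1)
  expect_error(global_profile(0.2, bad), "non-positive log")
})

test_that("shock profiles are antisymmetric about the shock position", {
  sh <- fit_constants(shock_params(500))
  d <- seq(0, 0.45, length.out = 100)
  expect_equal(global_profile(0.5 + d, sh), -global_profile(0.5 - d, sh),
               tolerance = 1e-14)
})

test_that("bulk and layer limits of the global profile are recovered", {
  hd <- fit_constants(hd_params(500))
  x <- seq(0.2, 1, length.out = 50)
  # tanh saturated: phi -> C + Omega x (linear bulk)
  expect_equal(global_profile(x, hd), hd$C + 0.2 * x, tolerance = 1e-10)
  # near x0 the layer is C tanh(C x_tilde / 2) to leading order
  xt <- seq(-3, 3, length.out = 25)
  x_near <- hd$x0 + hd$epsilon_eff * xt
  expect_lt(max(abs(global_profile(x_near, hd) - hd$C * tanh(hd$C * xt / 2))),
            5e-3)
})

test_that("RG profiles at very different epsilon collapse on the master curve", {
  p <- hd_params(500)
  eps_set <- c(1e-3, 1e-5, 1e-9)
  curves <- lapply(eps_set, function(e) {
    cst <- fit_constants(p, epsilon_eff = e)
    xt <- seq(-20, 20, length.out = 401)
    x <- pmin(pmax(cst$x0 + e * xt, 0), 1)
    list(cst = cst, val = collapse_transform(
      rg_profile_grid(cst, x = unique(x)), cst))
  })
  A0 <- curves[[1]]$cst$C + 0.2 * curves[[1]]$cst$x0
  for (cv in curves) {
    keep <- abs(cv$val$x_tilde) <= 20
    master <- tanh(A0 * cv$val$x_tilde[keep] / 2)
    expect_lt(max(abs(cv$val$scaled_phi[keep] - master)), 0.02)
  }
  # master curve passes through 0 at x_tilde = 0
  expect_equal(global_profile(curves[[1]]$cst$x0, curves[[1]]$cst), 0)
})
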