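# symmetric unsaturated parameterization: closed-form steady state
# a* = f rho_a mu_i / (mu_a rho_i), i* = rho_i a*^2 / mu_i  (n_coop = 2)
sym_params <- function(f = 1) network_params(n_coop = 2, f_knockdown = f)

test_that("reaction rates match direct substitution", {
  p <- sym_params()
  expect_equal(unname(mbw_rhs(1, 1, p)), c(0, 0), tolerance = 1e-9)

  # without basal production the zero state is absorbing
  expect_equal(unname(mbw_rhs(0, 1, p))[1], 0)

  # halving total production at the symmetric state
  r <- mbw_rhs(1, 1, sym_params(f = 0.5))
  expect_equal(unname(r), c(-0.5, 0), tolerance = 1e-9)

  expect_error(mbw_rhs(Inf, 1, p), "finite")
  expect_error(mbw_rhs(1, NA_real_, p), "finite")
})

test_that("steady state matches the closed form in the unsaturated limit", {
  st <- steady_state(sym_params())
  expect_equal(st$a_star, 1, tolerance = 1e-8)
  expect_equal(st$i_star, 1, tolerance = 1e-8)
  expect_false(st$trivial_only)

  st5 <- steady_state(sym_params(f = 0.5))
  expect_equal(st5$a_star, 0.5, tolerance = 1e-8)
  expect_equal(st5$i_star, 0.25, tolerance = 1e-8)

  # general closed form at random rates, sigma = kappa = 0, n = 2
  set.seed(401)
  for (j in 1:20) {
    p <- network_params(rho_a = runif(1, 0.3, 3), rho_i = runif(1, 0.3, 3),
                        mu_a = runif(1, 0.3, 3), mu_i = runif(1, 0.3, 3),
                        n_coop = 2, f_knockdown = runif(1, 0.2, 1))
    a_cf <- p$f_knockdown * p$rho_a * p$mu_i / (p$mu_a * p$rho_i)
    i_cf <- p$rho_i * a_cf^2 / p$mu_i
    st <- steady_state(p)
    expect_equal(st$a_star, a_cf, tolerance = 1e-8)
    expect_equal(st$i_star, i_cf, tolerance = 1e-8)
    expect_lt(st$residual, 1e-10 * max(1, a_cf))
  }
})

test_that("steady state reports trivial-only when no positive root exists", {
  # no basal activator production and too-weak autocatalysis against a
  # high basal inhibitor floor: only a = 0 remains
  p <- network_params(sigma_a = 0, sigma_i = 5, rho_a = 0.1, rho_i = 1,
                      mu_a = 2, mu_i = 1, kappa = 1, n_coop = 2)
  st <- steady_state(p)
  expect_true(st$trivial_only)
  expect_equal(st$a_star, 0)
  expect_equal(st$i_star, p$sigma_i / p$mu_i)

  rep <- linear_stability(p)
  expect_false(rep$turing_unstable)
  expect_equal(nrow(tidy(rep)), 0)
})

test_that("knockdown fold changes obey FC_i = FC_a^n and its inversion", {
  p <- sym_params()
  kd <- knockdown_foldchange(p, f = c(1, 1 / 3))
  expect_equal(kd$FC_a, c(1, 3), tolerance = 1e-8)
  expect_equal(kd$FC_i, c(1, 9), tolerance = 1e-8)

  # cooperativity required for a 19-fold repressor collapse from a 3-fold
  # activator knockdown: n = ln(19)/ln(3)
  n19 <- log(19) / log(3)
  p19 <- network_params(n_coop = n19)
  f3 <- 3^(-(n19 - 1))  # FC_a = f^{-1/(n-1)} inverted for FC_a = 3
  kd19 <- knockdown_foldchange(p19, f3)
  expect_equal(kd19$FC_a, 3, tolerance = 1e-6)
  expect_equal(kd19$FC_i, 19, tolerance = 1e-5)
  expect_equal(n19, 2.68, tolerance = 0.01)
})

test_that("knockdown is monotone and amplifying across random parameter draws", {
  set.seed(402)
  n_draws <- 200
  viol_mono <- 0L
  viol_amp <- 0L
  for (j in seq_len(n_draws)) {
    p <- random_params()
    f_grid <- sort(runif(3, 0.05, 1))
    states <- lapply(f_grid, function(f) {
      steady_state(update_params(p, f_knockdown = f))
    })
    a <- vapply(states, function(s) s$a_star, numeric(1))
    i <- vapply(states, function(s) s$i_star, numeric(1))
    if (any(diff(a) < -1e-7 * pmax(a[-1], 1)) ||
        any(diff(i) < -1e-7 * pmax(i[-1], 1))) {
      viol_mono <- viol_mono + 1L
    }
    # amplification in the sigma = 0 limit
    p0 <- update_params(p, sigma_a = 0, sigma_i = 0, kappa = 0)
    base <- steady_state(p0)
    if (!base$trivial_only) {
      kd <- knockdown_foldchange(p0, runif(1, 0.1, 0.95))
      if (!kd$collapsed && kd$FC_i < kd$FC_a * (1 - 1e-7)) {
        viol_amp <- viol_amp + 1L
      }
    }
  }
  expect_equal(viol_mono, 0L)
  expect_equal(viol_amp, 0L)
})

test_that("time integration settles onto the stable steady state", {
  # (1, 1) is a stable fixed point of this asymmetric parameterization
  p <- network_params(rho_a = 1, rho_i = 2, mu_a = 1, mu_i = 2, n_coop = 2)
  st <- steady_state(p)
  expect_equal(c(st$a_star, st$i_star), c(1, 1), tolerance = 1e-8)

  # starting at the fixed point: stays there
  tr0 <- integrate_ode(p, init = c(a = 1, i = 1), t_end = 10, dt = 0.1)
  expect_lt(max(abs(tr0$a - 1)), 1e-6)
  expect_lt(max(abs(tr0$i - 1)), 1e-6)

  # 1% perturbation decays back
  tr <- integrate_ode(p, init = c(a = 1.01, i = 0.99), t_end = 50, dt = 0.1)
  n <- nrow(tr)
  expect_lt(abs(tr$a[n] - 1), 1e-6)
  expect_lt(abs(tr$i[n] - 1), 1e-6)
  expect_true(all(tr$a >= 0 & tr$i >= 0))

  # knockdown switched on mid-run: relaxes to the perturbed steady state
  p5 <- update_params(p, f_knockdown = 0.5)
  st5 <- steady_state(p5)
  tr2 <- integrate_ode(p5, init = c(a = tr$a[n], i = tr$i[n]),
                       t_end = 60, dt = 0.1)
  expect_equal(tr2$a[nrow(tr2)], st5$a_star, tolerance = 1e-6)
  expect_equal(tr2$i[nrow(tr2)], st5$i_star, tolerance = 1e-6)
  expect_equal(c(st5$a_star, st5$i_star), c(0.5, 0.25), tolerance = 1e-8)

  expect_error(integrate_ode(p, t_end = 1, dt = 0), "dt")
  expect_error(integrate_ode(p, init = c(a = -1, i = 1)), "non-negative")
})

test_that("dispersion relation reduces to the well-mixed Jacobian at k = 0", {
  p <- turing_fixture()
  rep <- linear_stability(p, k_grid = c(0, seq(0.5, 4, by = 0.5)))
  st <- steady_state(p)
  J <- mbw_jacobian(st$a_star, st$i_star, p)
  expect_equal(tidy(rep)$growth_rate[1],
               max(Re(eigen(J)$values)), tolerance = 1e-10)
  expect_equal(glance(rep)$trace_J, sum(diag(J)))
  expect_equal(glance(rep)$det_J, det(J))
})

test_that("equal diffusivities never yield a Turing instability", {
  # exhaustive over a fixture grid of stable homogeneous states
  for (sa in c(0.02, 0.05, 0.1, 0.3, 0.5, 1)) {
    for (D in c(0.1, 1, 6)) {
      p <- update_params(petal_params(sigma_a = sa), D_a = D, D_i = D)
      rep <- linear_stability(p, seq(0, 6, length.out = 121))
      g <- glance(rep)
      if (isTRUE(g$trace_J < 0 && g$det_J > 0)) {
        expect_false(rep$turing_unstable)
        expect_true(all(tidy(rep)$growth_rate[tidy(rep)$k > 0] < 1e-12))
      }
    }
  }
})

test_that("the classical large-D_i/D_a regime is Turing-unstable with finite k_max", {
  rep <- linear_stability(turing_fixture(), seq(0, 6, length.out = 301))
  expect_true(rep$turing_unstable)
  expect_gt(rep$k_max, 0)
  expect_lt(rep$k_max, 6)
  expect_lt(glance(rep)$trace_J, 0)
  expect_gt(glance(rep)$det_J, 0)

  path <- withr::local_tempfile(fileext = ".csv")
  write_stability_report(rep, path)
  back <- utils::read.csv(path)
  expect_equal(back$growth_rate, tidy(rep)$growth_rate)
})
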