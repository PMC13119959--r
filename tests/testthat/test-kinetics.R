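test_that("Monod uptake hits its anchor points and saturates", {
  mp <- baseline_mp()
  expect_identical(specific_uptake(0, mp), 0)
  expect_equal(specific_uptake(mp$K_S, mp), mp$qS_max / 2)
  # S = 100 K_S: qS_max * 100 / 101
  expect_equal(specific_uptake(100 * mp$K_S, mp), 10 * 100 / 101,
               tolerance = 1e-12)
  expect_error(specific_uptake(-1, mp), "S must be")
})

test_that("Monod uptake is monotone and bounded over random parameter draws", {
  set.seed(11)
  for (i in 1:25) {
    mp <- microbial_params(qS_max = runif(1, 0.5, 50),
                           K_S = runif(1, 0.01, 5))
    S <- sort(runif(20, 0, 100))
    q <- specific_uptake(S, mp)
    expect_true(all(diff(q) >= 0))
    expect_true(all(q >= 0 & q <= mp$qS_max))
  }
})

test_that("Hill toxicity factor is 1 at zero, 1/2 at K_inh, and decreasing", {
  mp <- baseline_mp()
  expect_identical(toxicity_factor(0, mp), 1)
  expect_equal(toxicity_factor(2 * mp$K_inh, mp), 0.2)
  # half-inhibition at K_inh for every (K_inh, n_inh) combination
  for (K in c(1e-4, 0.01, 0.5, 10)) for (n in c(1, 1.5, 2, 4)) {
    expect_equal(toxicity_factor(K, microbial_params(K_inh = K, n_inh = n)),
                 0.5)
  }
  P <- seq(0, 0.1, length.out = 50)
  expect_true(all(diff(toxicity_factor(P, mp)) < 0))
  expect_error(toxicity_factor(-0.1, mp), "P_tot")
})

test_that("effective growth rate combines yield, uptake and toxicity", {
  mp <- baseline_mp()
  expect_identical(growth_rate(anolyte_state(S = 0, P_ox = 0.05), mp), 0)
  # saturated, uninhibited: mu -> Y_XS * qS_max = 0.9 / h
  expect_equal(growth_rate(anolyte_state(S = 1e6), mp), 0.9,
               tolerance = 1e-6)
  # at P_tot = K_inh growth is halved
  expect_equal(growth_rate(anolyte_state(S = 1e6, P_red = mp$K_inh), mp),
               0.45, tolerance = 1e-6)
})

test_that("growth rate is monotone in substrate and anti-monotone in phenazine", {
  set.seed(23)
  for (i in 1:20) {
    mp <- microbial_params(qS_max = runif(1, 1, 20), K_S = runif(1, 0.01, 1),
                           K_inh = runif(1, 0.001, 0.1),
                           n_inh = runif(1, 1, 4))
    S <- sort(runif(10, 0, 50))
    mu_S <- vapply(S, function(s)
      growth_rate(anolyte_state(S = s, P_red = 0.005), mp), numeric(1))
    expect_true(all(diff(mu_S) >= 0))
    P <- sort(runif(10, 0, 0.2))
    mu_P <- vapply(P, function(p)
      growth_rate(anolyte_state(S = 10, P_red = p), mp), numeric(1))
    expect_true(all(diff(mu_P) <= 0))
  }
})

test_that("Luedeking-Piret production rate has the right structure", {
  mp <- baseline_mp()
  expect_identical(production_rate(0.5, 0, mp), 0)
  expect_identical(production_rate(0, 1, mp), 0)  # beta_P = 0 default
  expect_equal(production_rate(0.9, 1.0, microbial_params(alpha_P = 0.03)),
               0.027)
  mp_b <- microbial_params(beta_P = 0.002)
  expect_equal(production_rate(0, 2, mp_b), 0.004)
  expect_error(production_rate(-0.1, 1, mp), "mu")
})

test_that("microbial derivatives: fixed point, baseline values, zero-growth production", {
  mp <- baseline_mp()
  d0 <- microbial_derivatives(anolyte_state(X = 0, S = 0), 0, mp)
  expect_identical(unname(d0), c(0, 0, 0, 0))
  # baseline Monod at S = 10, K_S = 0.1: qS = 10*10/10.1, mu = 0.09*qS
  d <- microbial_derivatives(anolyte_state(X = 0.1, S = 10), 0, mp)
  expect_equal(d[["dX"]], 0.09 * (10 * 10 / 10.1) * 0.1, tolerance = 1e-12)
  expect_equal(d[["dX"]], 0.0891089, tolerance = 1e-6)
  expect_equal(d[["dS"]], -0.990099, tolerance = 1e-6)
  # with beta_P = 0 and S = 0, production ceases with growth
  dz <- microbial_derivatives(anolyte_state(X = 1, S = 0, P_red = 0.01), 0.1, mp)
  expect_equal(dz[["dP_red"]] + dz[["dP_ox"]], -mp$k_deg * 0.01)
})

test_that("total-phenazine balance holds to machine precision for any electrode flux", {
  set.seed(37)
  for (i in 1:50) {
    mp <- microbial_params(alpha_P = runif(1, 0, 0.3),
                           beta_P = runif(1, 0, 0.01),
                           k_deg = runif(1, 0, 0.1))
    st <- anolyte_state(X = runif(1, 0, 2), S = runif(1, 0, 30),
                        P_red = runif(1, 0, 0.1), P_ox = runif(1, 0, 0.1))
    v <- runif(1, -1, 1)  # negative during recharge
    d <- microbial_derivatives(st, v, mp)
    lhs <- d[["dP_red"]] + d[["dP_ox"]]
    rhs <- production_rate(growth_rate(st, mp), st$X, mp) -
      mp$k_deg * p_total(st)
    # the electrode flux must cancel exactly: residue at rounding level only
    expect_lt(abs(lhs - rhs), 1e-13)
  }
})
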