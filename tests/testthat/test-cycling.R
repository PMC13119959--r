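test_that("cycling parameter validation enforces the protocol invariants", {
  expect_error(cycling_params(V_min = 0), "V_min")
  expect_error(cycling_params(t_recharge = -1), "durations")
  expect_error(cycling_params(n_cycles = 0), "n_cycles")
  expect_silent(cycling_params())
})

test_that("a mediator-free, sterile discharge yields a zero-capacity record", {
  res <- run_discharge(anolyte_state(X = 0, S = 0), baseline_mp(),
                       baseline_ep(), cycling_params(), dt = 0.01)
  expect_equal(res$record$Q_k_Ah_m2, 0)
  expect_identical(res$record$end_reason, "time_limit")
})

test_that("discharge capacity equals the trajectory's cumulative-charge increment", {
  res <- run_discharge(anolyte_state(X = 0.05, S = 20, P_red = 0.01),
                       baseline_mp(), baseline_ep(), cycling_params(),
                       dt = 0.01)
  tr <- res$trajectory
  expect_identical(res$record$Q_k_Ah_m2, tr$cumulative_charge[nrow(tr)])
  expect_lte(res$record$discharge_duration_h,
             cycling_params()$t_discharge_max)
})

test_that("a state already below the cut-off gives a valid zero-capacity cutoff record", {
  # P_red = 0.2 mmol/L: j = 2.14 A/m2, ohmic drop > 1 V >> E_oc - V_min
  res <- run_discharge(anolyte_state(X = 0.05, S = 20, P_red = 0.2,
                                     P_ox = 0.05),
                       baseline_mp(), baseline_ep(), cycling_params(),
                       dt = 0.01)
  expect_identical(res$record$end_reason, "voltage_cutoff")
  expect_equal(res$record$Q_k_Ah_m2, 0)
  expect_equal(nrow(res$trajectory), 1L)
})

test_that("the voltage cut-off fires at the hand-computed Nernst ratio", {
  # with a deep concentration floor the ratio P_ox/P_red can actually reach
  # the cut-off value exp((E_cath - E0 - V_min - j R) / (RT/nF))
  ep <- electro_params(nernst_floor = 1e-30)
  cp <- cycling_params(t_discharge_max = 5)
  st <- anolyte_state(X = 0, S = 0, P_red = 0.05, P_ox = 0.05)
  res <- run_discharge(st, baseline_mp(), ep, cp, dt = 0.01)
  expect_identical(res$record$end_reason, "voltage_cutoff")
  tr <- res$trajectory
  n <- nrow(tr)
  expect_lt(tr$V_cell[n], cp$V_min)
  # one Euler step's voltage change bounds the overshoot
  expect_gt(tr$V_cell[n], cp$V_min - (tr$V_cell[n - 1] - tr$V_cell[n]) -
              1e-12)
  # hand-computed crossing condition: nernst-term + ohmic loss = E_oc - V_min
  nernst <- ep$R_gas * ep$T_K / (ep$n_e * ep$F_C)
  lhs <- nernst * log(tr$P_ox[n] / tr$P_red[n]) +
    tr$j_A_m2[n] * ep$R_ohm
  expect_equal(lhs, ep$E_cath - ep$E0_an - cp$V_min,
               tolerance = 0.01)
})

test_that("recharge is conservative at k_deg = 0 and respects pool exhaustion", {
  mp0 <- microbial_params(k_deg = 0)
  ep <- baseline_ep()
  cp <- cycling_params(j_charge = 0.02, t_recharge = 2)
  # null recharge leaves the state unchanged
  cp0 <- cycling_params(j_charge = 0, t_recharge = 2)
  st <- anolyte_state(X = 0.1, S = 5, P_red = 0.01, P_ox = 0.03)
  same <- run_recharge(st, mp0, ep, cp0, dt = 0.01)
  expect_equal(c(same$X, same$S, same$P_red, same$P_ox),
               c(st$X, st$S, st$P_red, st$P_ox))
  # ample P_ox: transferred charge is |v_ch| * t_recharge = 0.0746 mmol/L
  st2 <- anolyte_state(X = 0.1, S = 5, P_red = 0, P_ox = 0.2)
  out <- run_recharge(st2, mp0, ep, cp, dt = 0.01)
  dP <- -recharge_flux(0.02, ep) * 2
  expect_equal(out$P_red, dP, tolerance = 1e-10)
  expect_equal(out$P_red, 0.0746, tolerance = 1e-3)
  expect_equal(st2$P_ox - out$P_ox, dP, tolerance = 1e-10)
  # scarce P_ox: flux truncates, nothing is created or lost
  st3 <- anolyte_state(X = 0.1, S = 5, P_red = 0, P_ox = 0.001)
  out3 <- run_recharge(st3, mp0, ep, cp, dt = 0.01)
  expect_gte(out3$P_ox, 0)
  expect_equal(out3$P_red + out3$P_ox, 0.001, tolerance = 1e-12)
  expect_equal(out3$P_red, 0.001, tolerance = 1e-6)
})

test_that("one cycle is exactly a discharge followed by a recharge", {
  mp <- baseline_mp(); ep <- baseline_ep()
  cp <- cycling_params(n_cycles = 1)
  init <- anolyte_state(X = 0.05, S = 20, P_ox = 0.02)
  recs <- run_cycling(init, mp, ep, cp, dt = 0.01)
  expect_equal(nrow(recs), 1L)
  manual <- run_discharge(init, mp, ep, cp, dt = 0.01)
  expect_equal(recs$Q_k_Ah_m2, manual$record$Q_k_Ah_m2)
  expect_equal(recs$end_P_ox, manual$record$end_P_ox)
})

test_that("an extraction-dominated discharge shows monotone current decline after its peak", {
  # substrate-spent reactor: oxidation at the anode outpaces replenishment,
  # so current decays continuously as the reduced pool is consumed
  res <- run_discharge(anolyte_state(X = 0.5, S = 0, P_red = 0.01,
                                     P_ox = 0.01),
                       baseline_mp(), baseline_ep(), cycling_params(),
                       dt = 0.01)
  j <- res$trajectory$j_A_m2
  pk <- which.max(j)
  expect_true(all(diff(j[pk:length(j)]) <= 1e-15))
})

test_that("cycle records carry strictly positive durations and linked end states", {
  recs <- run_cycling(anolyte_state(X = 0.05, S = 20), baseline_mp(),
                      baseline_ep(), cycling_params(n_cycles = 3), dt = 0.02,
                      keep_trajectories = TRUE)
  expect_equal(recs$cycle, 1:3)
  expect_true(all(recs$Q_k_Ah_m2 >= 0))
  trajs <- attr(recs, "trajectories")
  expect_length(trajs, 3L)
  # each discharge starts where the previous recharge ended (time is global)
  expect_true(all(diff(vapply(trajs, function(tr) tr$t[1], numeric(1))) > 0))
})
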