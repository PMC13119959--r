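test_that("an empty reactor is a fixed point of the Euler step in every mode", {
  mp <- baseline_mp(); ep <- baseline_ep()
  st <- anolyte_state(X = 0, S = 0)
  for (mode in c("discharge", "recharge", "open_circuit")) {
    nxt <- euler_step(st, 0.01, mp, ep, mode = mode)
    expect_equal(c(nxt$X, nxt$S, nxt$P_red, nxt$P_ox), c(0, 0, 0, 0))
    expect_equal(nxt$t, 0.01)
  }
})

test_that("one discharge step conserves total phenazine up to production when k_deg = 0", {
  mp <- microbial_params(k_deg = 0)
  ep <- baseline_ep()
  st <- anolyte_state(X = 0.3, S = 10, P_red = 0.004, P_ox = 0.002)
  dt <- 0.01
  nxt <- euler_step(st, dt, mp, ep, mode = "discharge")
  gain <- p_total(nxt) - p_total(st)
  expect_equal(gain, production_rate(growth_rate(st, mp), st$X, mp) * dt,
               tolerance = 1e-12)
})

test_that("a recharge step moves the hand-computed charge from P_ox to P_red", {
  mp <- microbial_params(k_deg = 0)
  ep <- baseline_ep()
  st <- anolyte_state(X = 0.1, S = 5, P_red = 0, P_ox = 0.05)
  nxt <- euler_step(st, 0.01, mp, ep, mode = "recharge", j_charge = 0.02)
  dP <- -recharge_flux(0.02, ep) * 0.01
  expect_equal(nxt$P_red, dP, tolerance = 1e-12)
  expect_equal(nxt$P_red, 3.73e-4, tolerance = 1e-2)
  expect_equal(st$P_ox - nxt$P_ox, dP, tolerance = 1e-12)
  # biomass and substrate are frozen during recharge
  expect_identical(nxt$X, st$X)
  expect_identical(nxt$S, st$S)
})

test_that("step sizes above the recommended range are flagged", {
  mp <- baseline_mp(); ep <- baseline_ep()
  withr::with_options(list(biobattery.verbosity = "warn"), {
    expect_message(euler_step(anolyte_state(), 0.1, mp, ep), "0.05")
  })
  expect_error(euler_step(anolyte_state(), -0.01, mp, ep), "positive")
})

test_that("batch simulation of a sterile reactor is flat and times out", {
  traj <- simulate_batch(anolyte_state(X = 0, S = 0), baseline_mp(),
                         baseline_ep(), termination_spec(t_max = 2), dt = 0.01)
  expect_identical(termination_reason(traj), "max_time")
  expect_true(all(traj$X == 0 & traj$S == 0 & traj$P_tot == 0 &
                    traj$j_A_m2 == 0))
  expect_equal(max(traj$t), 2)
})

test_that("baseline batch is structurally monotone and essentially unclamped", {
  traj <- baseline_batch()
  expect_true(all(diff(traj$X) >= 0))        # no death/maintenance term
  expect_true(all(diff(traj$S) <= 0))
  expect_true(all(diff(traj$t) > 0))
  expect_lte(attr(traj, "clamp_max"), 1e-6)  # clamping never masks dynamics
  expect_true(all(diff(traj$cumulative_charge) >= 0))
})

test_that("cumulative charge equals the flux integral through the unit conversion", {
  traj <- simulate_batch(anolyte_state(), baseline_mp(), baseline_ep(),
                         termination_spec(t_max = 20), dt = 0.02)
  n <- nrow(traj)
  expect_equal(traj$cumulative_charge[n],
               j_factor(baseline_ep()) * trapz(traj$t, traj$v_elec),
               tolerance = 1e-13)
})

test_that("halving the step changes the terminal state by far less than 0.5%", {
  mp <- baseline_mp(); ep <- baseline_ep()
  term <- termination_spec(t_max = 50)
  a <- simulate_batch(anolyte_state(), mp, ep, term, dt = 0.01)
  b <- simulate_batch(anolyte_state(), mp, ep, term, dt = 0.005)
  fa <- a[nrow(a), c("X", "S", "P_red", "P_ox")]
  fb <- b[nrow(b), c("X", "S", "P_red", "P_ox")]
  expect_true(all(rel_dev(unlist(fa), unlist(fb), scale = 1e-6) < 0.005))
})

test_that("with toxicity and degradation off, total phenazine tracks biomass growth exactly", {
  # closed-form Luedeking-Piret relation: P_tot(t) = alpha_P (X(t) - X0)
  mp <- microbial_params(K_inh = Inf, k_deg = 0)
  traj <- simulate_batch(anolyte_state(), mp, baseline_ep(),
                         termination_spec(t_max = 10), dt = 0.01)
  expect_equal(traj$P_tot, mp$alpha_P * (traj$X - traj$X[1]),
               tolerance = 1e-12)
})

test_that("toxicity and substrate-floor termination fire with the trigger satisfied", {
  mp <- baseline_mp(); ep <- baseline_ep()
  tox <- simulate_batch(anolyte_state(X = 0.5, S = 20),
                        microbial_params(alpha_P = 0.3), ep,
                        termination_spec(t_max = 200, P_tox_stop = 0.05),
                        dt = 0.01)
  expect_identical(termination_reason(tox), "toxicity")
  expect_gte(tox$P_tot[nrow(tox)], 0.05)
  sub <- simulate_batch(anolyte_state(), mp, ep,
                        termination_spec(t_max = 200, substrate_floor = 1),
                        dt = 0.01)
  expect_identical(termination_reason(sub), "substrate_floor")
  expect_lte(sub$S[nrow(sub)], 1)
})

test_that("summary metrics reproduce closed-form integrals", {
  # constant current 0.01 A/m2 for 2 h
  flat <- data.frame(t = seq(0, 2, 0.1), j_A_m2 = 0.01)
  sm <- summary_metrics(flat)
  expect_equal(sm$avg_j_A_m2, 0.01)
  expect_equal(sm$cumulative_charge_Ah_m2, 0.02)
  # triangular ramp 0 -> 0.1 over 10 h averages to 0.05
  tri <- data.frame(t = seq(0, 10, 0.01), j_A_m2 = 0.01 * seq(0, 10, 0.01))
  expect_equal(summary_metrics(tri)$avg_j_A_m2, 0.05, tolerance = 1e-12)
  expect_equal(summary_metrics(tri)$peak_j_A_m2, 0.1)
  # zero-current trajectory
  z <- data.frame(t = c(0, 1), j_A_m2 = c(0, 0))
  smz <- summary_metrics(z)
  expect_true(all(unlist(smz[c("avg_j_A_m2", "peak_j_A_m2",
                               "cumulative_charge_Ah_m2")]) == 0))
})

test_that("trajectory writer emits the schema and is bit-reproducible", {
  traj <- simulate_batch(anolyte_state(), baseline_mp(), baseline_ep(),
                         termination_spec(t_max = 1), dt = 0.01)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectory(traj, f1)
  write_trajectory(traj, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  hdr <- names(utils::read.csv(f1, nrows = 1))
  expect_identical(hdr, c("t", "X", "S", "P_red", "P_ox", "P_tot", "v_elec",
                          "j_A_m2", "j_mA_cm2", "E_an", "E_oc", "V_cell",
                          "cumulative_charge"))
  meta <- jsonlite::read_json(paste0(f1, ".meta.json"))
  expect_identical(meta$termination_reason, "max_time")
  expect_true(nzchar(meta$run_id))
  expect_equal(meta$microbial_params$qS_max, 10)
})
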