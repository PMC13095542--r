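# Core circuit: elastance, pump law, valves, suction, RHS, simulation.

test_that("elastance waveform spans [Emin, Emax] with peak at end-systole", {
  p <- circulation_params()
  t <- sort(c(seq(0, 0.8, by = 1e-3), p$chambers$LV$ts_frac * 0.8))
  E <- elastance_waveform(t, p$chambers$LV, T = 0.8)
  expect_equal(max(E), 2.5, tolerance = 1e-9)   # published LV peak
  expect_equal(min(E), 0.05, tolerance = 1e-12)
  t_peak <- t[which.max(E)]
  expect_equal(t_peak, p$chambers$LV$ts_frac * 0.8, tolerance = 2e-3)
  # periodicity over two cycles
  expect_equal(elastance_waveform(t + 0.8, p$chambers$LV, 0.8), E,
               tolerance = 1e-12)
  # degenerate activation: Emax = Emin gives a constant
  flat <- chamber_params("LV", 0.4, 0.4, 5)
  expect_equal(elastance_waveform(t, flat, 0.8), rep(0.4, length(t)))
  expect_error(elastance_waveform(0.1, p$chambers$LV, T = -1), "T")
})

test_that("chamber pressure is linear in stressed volume", {
  lv <- chamber_params("LV", 2.5, 0.05, V0 = 5)
  expect_equal(chamber_pressure(5, lv, 2.5), 0)
  expect_equal(chamber_pressure(45, lv, 2.5), 100)     # hand substitution
  expect_equal(chamber_pressure(85, lv, 2.5),
               2 * chamber_pressure(45, lv, 2.5))      # linearity
})

test_that("pump law reproduces the quadratic exactly", {
  hm3 <- pump_presets("heartmate3")
  ch6 <- pump_presets("corheart6")
  expect_identical(pump_pressure_head(0, 0, hm3), 0)
  expect_equal(pump_pressure_head(0, 1000, hm3), 7.3, tolerance = 1e-12)
  expect_equal(pump_pressure_head(50, 3000, ch6),
               4.82e-3 * 2500 + 6.66e-5 * 150000 + 7.2e-6 * 9e6,
               tolerance = 1e-12)                       # 86.84 mmHg
  # machine-precision agreement with the explicit formula on a grid
  Q <- seq(0, 200, by = 10)
  expect_equal(pump_pressure_head(Q, 5000, ch6),
               ch6$Ka * Q^2 + ch6$Kb * Q * 5000 + ch6$Kc * 5000^2)
  # monotone in speed at fixed flow over the operating range, both pumps
  for (pm in list(hm3, ch6)) {
    H <- pump_pressure_head(80, seq(1000, 9000, by = 250), pm)
    expect_true(all(diff(H) > 0))
  }
})

test_that("valve behaves as a smoothed diode", {
  expect_equal(valve_flow(0), 0)
  expect_lt(abs(valve_flow(-20)), 1e-3)             # reverse leak
  expect_equal(valve_flow(10, R_open = 0.005), 2000, tolerance = 1e-3)
  # transition is monotone in the drop
  dP <- seq(-1, 1, by = 0.01)
  expect_true(all(diff(valve_flow(dP)) >= 0))
})

test_that("suction resistance has a continuous knee and monotone growth", {
  pm <- pump_presets("heartmate3")
  thr <- pm$suction_threshold
  expect_equal(suction_resistance(thr + 50, pm), pm$R_in)
  expect_equal(suction_resistance(thr, pm), pm$R_in)        # continuity
  r1 <- suction_resistance(thr - 2, pm)
  r2 <- suction_resistance(thr - 5, pm)
  expect_gt(r1, pm$R_in)
  expect_gt(r2, r1)
  expect_equal(r2 - r1, pm$suction_gain * 3)                # linear law
})

test_that("circuit RHS conserves volume and is quiescent at equilibrium", {
  p <- circulation_params()
  set.seed(1)
  for (rep in 1:5) {
    y <- initial_state(p) * runif(13, 0.5, 1.5)
    dy <- circuit_rhs(y, t = runif(1, 0, 0.8), p)
    expect_lt(abs(sum(dy[1:12])), 1e-10 * max(abs(dy)))  # closed loop
  }
  # all node pressures equal at a time of known elastance -> no flow
  t0 <- 0.6  # ventricular diastole, atria not yet active
  P0 <- 10
  y <- numeric(13)
  for (i in seq_along(CHAMBER_NAMES)) {
    ch <- p$chambers[[CHAMBER_NAMES[i]]]
    E <- elastance_waveform(t0, ch, p$T)
    y[i] <- ch$V0 + P0 / E
  }
  for (i in seq_along(SEGMENT_NAMES)) {
    sg <- p$segments[[SEGMENT_NAMES[i]]]
    y[4 + i] <- sg$V0 + P0 * sg$C
  }
  dy <- circuit_rhs(y, t0, p)
  expect_lt(max(abs(dy)), 1e-8)
  expect_error(circuit_rhs(c(y[-1], NaN), 0, p), "non-finite")
})

test_that("simulation conserves blood volume and reaches a periodic state", {
  r <- base_simulation()
  total <- rowSums(r$volumes)
  expect_lt(max(abs(total - 900)) / 900, 1e-3)
  w <- detect_steady_state(r)
  expect_lt(w$residual, 1e-2)
  # flow continuity: cycle-mean inflow = outflow at the aortic node
  i <- w$idx
  expect_equal(mean(r$flows[i, "AV"]), mean(r$flows[i, "AOBR"]),
               tolerance = 1e-2)
})

test_that("pump at zero speed with clamped cannulae matches no pump", {
  sv <- solver_config(t_end = 20)
  r0 <- simulate_lpm(circulation_params(), sv)
  pm <- pump_model("clamped", -1.8e-3, -1.2e-5, 7.3e-6, R_in = 2000,
                   L_in = 20)
  r1 <- simulate_lpm(circulation_params(pump = pm, speed = 0), sv)
  i <- detect_steady_state(r0)$idx
  expect_equal(r1$pressures[i, ], r0$pressures[i, ], tolerance = 2e-3)
})

test_that("power balance holds over a steady cycle", {
  # chamber boundary work equals resistive dissipation in a closed loop
  r <- base_simulation()
  i <- detect_steady_state(r)$idx
  dt <- diff(r$time[i][1:2])
  p <- r$params
  work <- 0
  for (ch in CHAMBER_NAMES) {
    dV <- c(diff(r$volumes[i, ch]), 0)
    work <- work - sum(r$pressures[i, ch] * dV)      # work done BY chamber
  }
  flows <- cbind(
    TV = r$flows[i, "TV"], PV = r$flows[i, "PV"], MV = r$flows[i, "MV"],
    AV = r$flows[i, "AV"], AOBR = r$flows[i, "AOBR"])
  seg_R <- vapply(p$segments, function(s) s$R, 0)
  q_seg <- cbind(
    SAT = (r$pressures[i, "SAT"] - r$pressures[i, "SAR"]) / seg_R["SAT"],
    SAR = (r$pressures[i, "SAR"] - r$pressures[i, "SVN"]) / seg_R["SAR"],
    SVN = (r$pressures[i, "SVN"] - r$pressures[i, "RA"]) / seg_R["SVN"],
    PAS = (r$pressures[i, "PAS"] - r$pressures[i, "PAT"]) / seg_R["PAS"],
    PAT = (r$pressures[i, "PAT"] - r$pressures[i, "PCP"]) / seg_R["PAT"],
    PCP = (r$pressures[i, "PCP"] - r$pressures[i, "PVN"]) / seg_R["PCP"],
    PVN = (r$pressures[i, "PVN"] - r$pressures[i, "LA"]) / seg_R["PVN"])
  dissip <- sum(q_seg^2 %*% seg_R[colnames(q_seg)]) * dt +
    sum(r$flows[i, "AOBR"]^2) * seg_R["AO"] * dt
  # valve dissipation from drop * flow
  dP_v <- cbind(r$pressures[i, "RA"] - r$pressures[i, "RV"],
                r$pressures[i, "RV"] - r$pressures[i, "PAS"],
                r$pressures[i, "LA"] - r$pressures[i, "LV"],
                r$pressures[i, "LV"] - r$pressures[i, "AO"])
  dissip <- dissip + sum(dP_v * flows[, c("TV", "PV", "MV", "AV")]) * dt
  expect_equal(work, unname(dissip), tolerance = 0.05)
})

test_that("steady-state window is a full aligned cycle", {
  r <- base_simulation()
  w <- detect_steady_state(r)
  expect_equal(r$time[w$idx[1]], w$t0, tolerance = 1e-6)
  expect_lte(w$t0 + w$T, 60 + 1e-9)
  expect_equal(diff(range(r$time[w$idx])), 0.8 - 1 / r$solver$fs,
               tolerance = 1e-6)
  # a period that does not divide t_end still yields a full window
  r2 <- simulate_lpm(circulation_params(T = 0.7), solver_config(t_end = 10))
  w2 <- detect_steady_state(r2)
  expect_equal(w2$t0 %% 0.7, 0, tolerance = 1e-9)
  expect_lte(w2$t0 + 0.7, 10)
  # converged run has a smaller residual than the first cycles
  early <- list(time = r2$time, volumes = r2$volumes,
                pressures = r2$pressures, params = r2$params)
  idx1 <- which(r2$time >= 0.7 & r2$time < 1.4)
  idx0 <- which(r2$time >= 0.0 & r2$time < 0.7)
  n <- min(length(idx0), length(idx1))
  tr <- cbind(r2$pressures, r2$volumes)
  res_first <- max(sqrt(colSums((tr[idx1[1:n], ] - tr[idx0[1:n], ])^2)) /
                     pmax(sqrt(colSums(tr[idx1[1:n], ]^2)), 1e-12))
  expect_lt(w2$residual, res_first)
  expect_error(detect_steady_state(
    simulate_lpm(circulation_params(), solver_config(t_end = 2))), "three")
})

test_that("negative-volume blow-up aborts with the offending node", {
  p <- circulation_params(TBV = 400)   # severe hypovolemia
  p$segments$PAT$C <- 1e-4             # force a collapse
  expect_error(simulate_lpm(p, solver_config(t_end = 5)),
               "volume at node")
})

test_that("Emax round trip through the simulated end-systolic point", {
  r <- base_simulation()
  p <- r$params
  w <- detect_steady_state(r)
  t_es <- w$t0 + p$chambers$LV$ts_frac * p$T
  E <- elastance_waveform(t_es, p$chambers$LV, p$T)
  V <- approx(r$time, r$volumes[, "LV"], t_es)$y
  P <- E * (V - p$chambers$LV$V0)
  expect_equal(emax_bridge(P, V, p$chambers$LV$V0), 2.5, tolerance = 1e-3)
})
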