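# Reduced-order circulation: elastance waveforms, valve laws, closed-loop
# integration, and clinical metrics.

test_that("two-Hill elastance hits Emin at its origin and Emax at its peak", {
  params <- circulation_params()
  tg <- seq(0, params$T, length.out = 1e5)
  for (e in list(params$E_lv, params$E_la)) {
    expect_equal(elastance(e$phase_shift, e), e$Emin)
    expect_lt(abs(max(elastance(tg + e$phase_shift, e)) - e$Emax) / e$Emax,
              1e-6)
  }
})

test_that("two-Hill values match a direct evaluation of the sigmoid product", {
  params <- circulation_params()
  e <- params$E_lv
  t <- params$T / 2
  g1 <- (t / e$tau1)^e$m1
  g2 <- (t / e$tau2)^e$m2
  expect_equal(elastance(t, e),
               e$k * (g1 / (1 + g1)) * (1 / (1 + g2)) + e$Emin)
})

test_that("the atrial waveform is the delayed two-Hill waveform", {
  params <- circulation_params()
  T <- params$T
  withr::with_seed(4, {
    t <- runif(5, 0, 3 * T)
    expect_equal(la_elastance(t + T, params), la_elastance(t, params))
  })
  expect_equal(la_elastance(0.85 * T, params), params$la$Emin)
  # modular arithmetic: value at 0 equals the unshifted waveform at 0.15 T
  unshifted <- two_hill_elastance(params$la$Emin, params$la$Emax,
                                  params$la$tau1_frac * T,
                                  params$la$tau2_frac * T,
                                  params$la$m1, params$la$m2, T)
  expect_equal(la_elastance(0, params), elastance(0.15 * T, unshifted))
})

test_that("the mitral diode is one-way and continuous at equality", {
  expect_equal(mitral_flow(8, 80, 0.005), 0)
  expect_equal(mitral_flow(85, 80, 0.005), 1000)
  expect_equal(mitral_flow(80, 80, 0.005), 0)
})

test_that("aortic orifice flow solves the series quadratic", {
  params <- circulation_params(Rlvot = 0, Rc = 0)
  v <- valve_surrogate("orifice", EOA_cm2 = 1.5)
  expect_equal(solve_aortic_flow(80, 90, params, v, open = TRUE), 0)
  expect_equal(solve_aortic_flow(80, 90, params, v, open = FALSE), 0)
  # pure orifice: Q = 51.6 EOA sqrt(dP)
  expect_equal(solve_aortic_flow(89.62, 80, params, v, open = TRUE),
               51.6 * 1.5 * sqrt(9.62))

  # brute-force bracketing root oracle on random positive parameters
  withr::with_seed(21, {
    for (i in 1:20) {
      pr <- circulation_params(Rlvot = runif(1, 0, 0.05),
                               Rc = runif(1, 0, 0.1))
      vv <- valve_surrogate("orifice", EOA_cm2 = runif(1, 0.5, 4),
                            R = runif(1, 0, 0.05))
      dP <- runif(1, 1, 120)
      Q <- solve_aortic_flow(80 + dP, 80, pr, vv, open = TRUE)
      f <- function(q) (q / (51.6 * vv$EOA_cm2))^2 +
        (pr$Rlvot + pr$Rc + vv$R) * q - dP
      Qo <- uniroot(f, c(0, 1e6), tol = 1e-12)$root
      expect_lt(abs(Q - Qo) / Qo, 1e-10)
    }
  })
})

test_that("waveform identities of the lumped network hold", {
  sim <- quick_sim()
  wf <- sim$waveforms
  # P_Ao = P_Wk + Q_Ao Rc and P_LVOT = P_LV - Q_Ao Rlvot at every sample
  expect_equal(wf$P_Ao_mmHg, wf$P_Wk_mmHg + wf$Q_LVOT_mLs * 0.042)
  expect_equal(wf$P_LVOT_mmHg, wf$P_LV_mmHg - wf$Q_LVOT_mLs * 0.0043)
  expect_true(all(wf$Q_MV_mLs >= 0))
  expect_true(all(wf$Q_LVOT_mLs >= 0))
  expect_true(all(is.finite(as.matrix(wf[, -1]))))
})

test_that("a Windkessel fed constant flow settles at Q (Rc + Rp)", {
  params <- circulation_params()
  Q <- 100
  # hold the valve open with the ventricular pressure that delivers Q
  # through the resistive path; at P_Wk = Q Rp the Windkessel is at
  # equilibrium and the outlet sits at Q (Rc + Rp)
  P_wk <- Q * params$Rp
  P_lv <- P_wk + Q * (params$Rlvot + params$Rc)
  drv <- tavsim:::rom_deriv(V_LA = 1, V_LV = P_lv, P_Wk = P_wk,
                            E_la = 0.08, E_lv = 1, params,
                            valve_surrogate("ideal_diode", R = 0),
                            mv_open = FALSE, av_open = TRUE)
  expect_equal(drv[3], 0)
  expect_equal(P_wk + Q * params$Rc, Q * (params$Rc + params$Rp))
})

test_that("with both valves shut the ventricle is isovolumic", {
  params <- circulation_params()
  v <- valve_surrogate("orifice", EOA_cm2 = 1.5)
  drv <- tavsim:::rom_deriv(V_LA = 100, V_LV = 120, P_Wk = 80,
                            E_la = 0.08, E_lv = 0.05, params, v,
                            mv_open = FALSE, av_open = FALSE)
  expect_equal(drv[2], 0)
  expect_equal(drv[1], params$Qvein)
})

test_that("the periodic orbit conserves mass within 1%", {
  sim <- simulate_circulation(circulation_params(),
                              valve_surrogate("orifice", EOA_cm2 = 1.5),
                              n_cycles = 80, dt = 5e-4, tol_mmHg = 0.02)
  m <- cycle_metrics(sim)
  inflow <- circulation_params()$Qvein * circulation_params()$T
  expect_lt(abs(m$SV_mL - inflow) / inflow, 0.01)
})

test_that("a huge orifice with no resistance removes the systolic gradient", {
  params <- circulation_params(Rlvot = 0, Rc = 0)
  sim <- quick_sim(params, valve_surrogate("orifice", EOA_cm2 = 100))
  m <- cycle_metrics(sim)
  expect_lt(m$mean_systolic_dP_mmHg, 0.05)
})

test_that("halving the step changes stroke volume by < 0.1%", {
  sv <- vapply(c(5e-4, 2.5e-4), function(dt) {
    cycle_metrics(quick_sim(dt = dt))$SV_mL
  }, numeric(1))
  expect_lt(abs(sv[2] - sv[1]) / sv[1], 1e-3)
})

test_that("identical configurations give identical waveforms", {
  s1 <- quick_sim(n_cycles = 3)
  s2 <- quick_sim(n_cycles = 3)
  expect_identical(s1$waveforms, s2$waveforms)
})

test_that("afterload and orifice area move the hemodynamics as expected", {
  mean_pao <- vapply(c(0.7, 1.1), function(rp) {
    sim <- quick_sim(circulation_params(Rp = rp))
    wf <- dplyr::filter(sim$waveforms, cycle == max(cycle))
    mean(wf$P_Ao_mmHg)
  }, numeric(1))
  expect_gt(mean_pao[2], mean_pao[1])

  dps <- vapply(c(2.0, 1.0), function(eoa) {
    cycle_metrics(quick_sim(valve = valve_surrogate("orifice",
                                                    EOA_cm2 = eoa)))$
      mean_systolic_dP_mmHg
  }, numeric(1))
  expect_gt(dps[2], dps[1])
})

test_that("cycle metrics reduce to closed forms on a rectangular pulse", {
  T <- 1
  dt <- 1e-3
  t <- seq(0, T - dt, by = dt)
  sys <- t < 0.4
  Q <- ifelse(sys, 200, 0)
  wf <- tibble::tibble(
    t_s = t, cycle = 1L,
    P_LA_mmHg = 10, P_LV_mmHg = 100,
    P_LVOT_mmHg = ifelse(sys, 100, 5), P_Ao_mmHg = ifelse(sys, 90, 80),
    P_Wk_mmHg = 80, Q_MV_mLs = 0, Q_LVOT_mLs = Q, av_open = sys
  )
  sim <- structure(list(waveforms = wf, params = list(T = T), dt = dt,
                        converged = TRUE, residual_mmHg = 0),
                   class = "rom_sim")
  m <- cycle_metrics(sim)
  expect_equal(m$SV_mL, sum(Q) * dt)
  expect_equal(m$CO_Lmin, m$SV_mL * 60 / T / 1000)
  expect_equal(m$mean_systolic_dP_mmHg, 10)
  expect_equal(m$peak_diastolic_dP_mmHg, 75)
  expect_equal(m$EOA_cm2, 200 / (51.6 * sqrt(10)))
})

test_that("the synthetic ejection pulse has the stated closed forms", {
  w <- synth_flow_waveform(SV = 45.32, t_ej = 0.31, T = 0.7836, dt = 1e-4)
  expect_lt(abs(sum(w$Q_mLs) * 1e-4 - 45.32) / 45.32, 1e-4)
  expect_equal(max(w$Q_mLs), pi * 45.32 / (2 * 0.31), tolerance = 1e-6)
  expect_true(all(w$Q_mLs[w$t_s >= 0.31] == 0))
})

test_that("prescribed-flow comparison follows the orifice law", {
  flow <- synth_flow_waveform(SV = 45.32, t_ej = 0.31, T = 0.7836)
  zero <- flow
  zero$Q_mLs <- 0
  res0 <- prescribed_flow_experiment(
    zero, list(a = valve_surrogate("orifice", EOA_cm2 = 1.5)))
  expect_true(all(res0$waveforms$dP_mmHg == 0))

  res <- prescribed_flow_experiment(flow, list(
    big = valve_surrogate("orifice", EOA_cm2 = 1.5),
    half = valve_surrogate("orifice", EOA_cm2 = 0.75)
  ))
  dp <- res$metrics$mean_systolic_dP_mmHg
  expect_equal(dp[2] / dp[1], 4) # halved EOA quadruples the gradient
  # the continuity EOA recovers the orifice parameter exactly
  expect_equal(res$metrics$EOA_cm2, c(1.5, 0.75))
})
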