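# Reduced-order left-heart circulation: two-Hill time-varying elastance
# chambers, lagged diode mitral valve, lumped aortic valve surrogate
# (diode + Gorlin orifice), and a three-element Windkessel afterload.
#
# Units: pressures mmHg, flows mL/s, volumes mL, times s,
# elastances mmHg/mL, resistances mmHg.s/mL, compliance mL/mmHg.

GORLIN_K <- 51.6 # Gorlin constant: Q [mL/s] = 51.6 * EOA [cm^2] * sqrt(dP [mmHg])

#' Two-Hill time-varying elastance waveform
#'
#' Chamber contraction is parameterized by the product of two Hill-type
#' sigmoids: `E(t) = k * (g1/(1+g1)) * (1/(1+g2)) + Emin` with
#' `g1 = (t/tau1)^m1`, `g2 = (t/tau2)^m2`. The scale `k` is normalized
#' numerically (fine-grid maximum over one period, cached in the object) so
#' that the waveform's maximum equals `Emax` and its minimum `Emin`.
#'
#' @param Emin,Emax Minimum and maximum elastance (mmHg/mL), `Emax > Emin > 0`.
#' @param tau1,tau2 Rise and relaxation time constants (s), `0 < tau1 < tau2`.
#' @param m1,m2 Hill exponents (dimensionless, > 0).
#' @param T Cardiac period (s).
#' @param phase_shift Time offset (s): the waveform is evaluated at
#'   `(t - phase_shift) mod T`.
#' @param n_norm Grid size for the numerical normalization of `k`.
#' @return An object of class `two_hill` with the cached normalization `k`.
#' @examples
#' e <- two_hill_elastance(0.01, 0.1191, 0.0725 * 0.8512, 0.4503 * 0.8512,
#'                         2.7463, 21.5683, T = 0.8512)
#' max(elastance(seq(0, 0.8512, length.out = 1e5), e)) # ~0.1191
#' @export
two_hill_elastance <- function(Emin, Emax, tau1, tau2, m1, m2, T,
                               phase_shift = 0, n_norm = 1e5) {
  stopifnot(Emax > Emin, Emin > 0, tau1 > 0, tau2 > tau1, m1 > 0, m2 > 0,
            T > 0)
  e <- structure(
    list(Emin = Emin, Emax = Emax, tau1 = tau1, tau2 = tau2,
         m1 = m1, m2 = m2, T = T, phase_shift = phase_shift, k = 1),
    class = "two_hill"
  )
  tg <- seq(0, T, length.out = n_norm)
  e$k <- (Emax - Emin) / max(two_hill_shape(tg, e))
  e
}

# unnormalized double-sigmoid shape on local time in [0, T)
two_hill_shape <- function(tl, e) {
  g1 <- (tl / e$tau1)^e$m1
  g2 <- (tl / e$tau2)^e$m2
  (g1 / (1 + g1)) * (1 / (1 + g2))
}

#' Evaluate a two-Hill elastance waveform
#'
#' @param t Time(s) in seconds (any real; the waveform is `T`-periodic).
#' @param e A `two_hill` object.
#' @return Elastance values (mmHg/mL), same length as `t`.
#' @export
elastance <- function(t, e) {
  stopifnot(inherits(e, "two_hill"))
  tl <- (t - e$phase_shift) %% e$T
  e$k * two_hill_shape(tl, e) + e$Emin
}

#' Parameter set for the closed-loop circulation model
#'
#' Defaults are a published human systemic calibration used for TAVR boundary
#' conditions: constant pulmonary venous inflow, two-Hill elastances for the
#' left atrium (LA, delayed by `la_shift_frac * T`) and left ventricle (LV),
#' mitral and LVOT (left ventricular outflow tract) resistances, and a
#' three-element Windkessel (characteristic resistance `Rc`, peripheral
#' resistance `Rp`, compliance `Cwk`).
#'
#' @param Qvein_Lmin Pulmonary venous inflow (L/min).
#' @param Rmv,Rlvot,Rc,Rp Resistances (mmHg.s/mL).
#' @param Cwk Windkessel compliance (mL/mmHg).
#' @param T Cardiac period (s).
#' @param lv,la Named lists of two-Hill parameters (`Emin`, `Emax`, `tau1_frac`,
#'   `tau2_frac`, `m1`, `m2`; time constants as fractions of `T`).
#' @param la_shift_frac LA phase shift as a fraction of `T`.
#' @param la_shift_mode `"delay"` (default) shifts the LA waveform later by
#'   `la_shift_frac * T`; `"advance"` shifts it earlier (the alternative
#'   sign convention).
#' @return An object of class `circulation_params` carrying the scalar
#'   constants plus built `two_hill` objects `E_lv` and `E_la`.
#' @export
circulation_params <- function(Qvein_Lmin = 5.8,
                               Rmv = 0.005, Rlvot = 0.0043,
                               Rc = 0.042, Rp = 0.9046, Cwk = 1.9504,
                               T = 0.8512,
                               lv = list(Emin = 0.01, Emax = 0.1191,
                                         tau1_frac = 0.0725,
                                         tau2_frac = 0.4503,
                                         m1 = 2.7463, m2 = 21.5683),
                               la = list(Emin = 0.08, Emax = 0.17,
                                         tau1_frac = 0.1150,
                                         tau2_frac = 0.1882,
                                         m1 = 1.32, m2 = 13.1),
                               la_shift_frac = 0.85,
                               la_shift_mode = c("delay", "advance")) {
  la_shift_mode <- match.arg(la_shift_mode)
  stopifnot(Qvein_Lmin > 0, Rmv >= 0, Rlvot >= 0, Rc >= 0, Rp > 0,
            Cwk > 0, T > 0)
  shift <- la_shift_frac * T * if (la_shift_mode == "delay") 1 else -1
  structure(
    list(
      Qvein = Qvein_Lmin * 1000 / 60, # mL/s
      Rmv = Rmv, Rlvot = Rlvot, Rc = Rc, Rp = Rp, Cwk = Cwk, T = T,
      lv = lv, la = la, la_shift_frac = la_shift_frac,
      la_shift_mode = la_shift_mode,
      E_lv = two_hill_elastance(lv$Emin, lv$Emax, lv$tau1_frac * T,
                                lv$tau2_frac * T, lv$m1, lv$m2, T),
      E_la = two_hill_elastance(la$Emin, la$Emax, la$tau1_frac * T,
                                la$tau2_frac * T, la$m1, la$m2, T,
                                phase_shift = shift)
    ),
    class = "circulation_params"
  )
}

#' Left-atrial elastance at time t
#'
#' Convenience accessor: the LA two-Hill waveform including its phase shift
#' relative to the LV waveform.
#'
#' @param t Time(s) in seconds.
#' @param params A `circulation_params` object.
#' @return Elastance values (mmHg/mL).
#' @export
la_elastance <- function(t, params) {
  stopifnot(inherits(params, "circulation_params"))
  elastance(t, params$E_la)
}

#' Lumped aortic-valve surrogate
#'
#' A stand-in for a resolved fluid--structure valve: a lagged diode in
#' series with either a Gorlin orifice (`dP = (Q / (51.6 EOA))^2`), a linear
#' resistance, or an ideal diode (no pressure loss beyond the series
#' resistances).
#'
#' @param kind `"orifice"`, `"linear_resistance"`, or `"ideal_diode"`.
#' @param EOA_cm2 Effective orifice area (cm^2), required for the orifice
#'   kind.
#' @param R Series resistance (mmHg.s/mL); the resistance for the linear
#'   kind, an optional extra series term for the orifice kind.
#' @return An object of class `valve_surrogate`.
#' @export
valve_surrogate <- function(kind = c("orifice", "linear_resistance",
                                     "ideal_diode"),
                            EOA_cm2 = NULL, R = 0) {
  kind <- match.arg(kind)
  if (kind == "orifice") {
    stopifnot(!is.null(EOA_cm2), EOA_cm2 > 0)
  }
  stopifnot(R >= 0)
  structure(list(kind = kind, EOA_cm2 = EOA_cm2, R = R,
                 gorlin_constant = GORLIN_K),
            class = "valve_surrogate")
}

#' Mitral diode flow
#'
#' `Q_MV = 0` when `P_LA <= P_LV`, else `(P_LA - P_LV) / Rmv`; continuous at
#' equality.
#'
#' @param P_LA,P_LV Atrial and ventricular pressures (mmHg).
#' @param Rmv Mitral resistance (mmHg.s/mL, > 0).
#' @return Flow (mL/s), vectorized.
#' @export
mitral_flow <- function(P_LA, P_LV, Rmv) {
  stopifnot(Rmv > 0)
  pmax(P_LA - P_LV, 0) / Rmv
}

#' Aortic flow through the valve surrogate
#'
#' With the valve open, solves the series pressure balance
#' `P_LV - P_Wk = (Q / (51.6 EOA))^2 + (Rlvot + Rc + R) Q` for the
#' nonnegative root (closed-form quadratic for the orifice kind); with the
#' valve closed or a nonpositive driving pressure, returns 0.
#'
#' @param P_LV,P_Wk Ventricular and Windkessel pressures (mmHg).
#' @param params A `circulation_params` object.
#' @param valve A `valve_surrogate`.
#' @param open Logical: valve state for this step (lagged, set by the
#'   integrator from the previous step's pressures).
#' @return Flow (mL/s, >= 0).
#' @export
solve_aortic_flow <- function(P_LV, P_Wk, params, valve, open = TRUE) {
  if (!open) return(0)
  dP <- P_LV - P_Wk
  if (dP <= 0) return(0)
  Rser <- params$Rlvot + params$Rc + valve$R
  if (valve$kind == "orifice") {
    a <- 1 / (GORLIN_K * valve$EOA_cm2)^2
    # a Q^2 + Rser Q - dP = 0, positive root
    (-Rser + sqrt(Rser^2 + 4 * a * dP)) / (2 * a)
  } else {
    if (Rser <= 0) stop("ideal diode with zero total series resistance")
    dP / Rser
  }
}

# time derivatives of (V_LA, V_LV, P_Wk) at given elastances and flows.
# V here are the volume-like states V = C(t) P, so the chamber balances
# integrate exactly as written.
rom_deriv <- function(V_LA, V_LV, P_Wk, E_la, E_lv, params, valve,
                      mv_open, av_open) {
  P_LA <- V_LA * E_la
  P_LV <- V_LV * E_lv
  Q_MV <- if (mv_open) mitral_flow(P_LA, P_LV, params$Rmv) else 0
  Q_Ao <- solve_aortic_flow(P_LV, P_Wk, params, valve, av_open)
  c(params$Qvein - Q_MV,
    Q_MV - Q_Ao,
    (Q_Ao - P_Wk / params$Rp) / params$Cwk)
}

#' Integrate the closed-loop circulation to periodic steady state
#'
#' Classical fixed-step 4-stage Runge--Kutta on the volume-like states
#' `V = C(t) P` of the two chambers plus the Windkessel pressure. Both
#' valve states are lagged: updated once per step from the previous step's
#' pressures (mitral open iff `P_LA > P_LV`; aortic open iff
#' `P_LV > P_Wk`), then held through the RK stages. Integration stops at
#' the first cycle whose aortic pressure trace differs from the previous
#' cycle by less than `tol_mmHg` (max norm), or after `n_cycles`.
#'
#' @param params A `circulation_params` object.
#' @param valve A `valve_surrogate` (default: orifice at the device's
#'   reported 1.50 cm^2 effective area).
#' @param n_cycles Maximum number of cardiac cycles (>= 2).
#' @param dt Time step (s), <= 1e-3; snapped so that the period is an
#'   integer number of steps.
#' @param init Named list of initial conditions `P_Wk`, `P_LA`, `P_LV`
#'   (mmHg); chamber volumes are derived from the elastances at t = 0.
#' @return An object of class `rom_sim`: list with `waveforms` (tibble
#'   `t_s, cycle, P_LA_mmHg, P_LV_mmHg, P_LVOT_mmHg, P_Ao_mmHg, P_Wk_mmHg,
#'   Q_MV_mLs, Q_LVOT_mLs, mv_open, av_open`), `converged`, `residual_mmHg`
#'   (final cycle-to-cycle max aortic pressure change), `n_cycles_run`,
#'   `dt`, `params`, `valve`. Supports `tidy()`, `glance()`, `autoplot()`.
#' @export
simulate_circulation <- function(params, valve = valve_surrogate("orifice",
                                                                 EOA_cm2 = 1.5),
                                 n_cycles = 20, dt = 1e-4,
                                 init = list(P_Wk = 80, P_LA = 10,
                                             P_LV = 8),
                                 tol_mmHg = 0.5) {
  stopifnot(inherits(params, "circulation_params"),
            inherits(valve, "valve_surrogate"),
            n_cycles >= 2, dt <= 1e-3, dt > 0)
  spc <- max(2L, as.integer(round(params$T / dt)))
  dt <- params$T / spc # snap: integer steps per cycle
  # elastances precomputed on the half-step grid of one period (periodic)
  th <- (seq_len(2L * spc) - 1L) * (dt / 2)
  Ela_g <- elastance(th, params$E_la)
  Elv_g <- elastance(th, params$E_lv)

  n_steps <- spc * n_cycles
  out <- matrix(NA_real_, n_steps + 1L, 9L)
  V_LA <- init$P_LA / Ela_g[1]
  V_LV <- init$P_LV / Elv_g[1]
  P_Wk <- init$P_Wk
  P_LA <- init$P_LA
  P_LV <- init$P_LV
  converged <- FALSE
  residual <- Inf
  cyc_prev <- NULL
  step_done <- n_steps

  for (s in seq_len(n_steps)) {
    mv_open <- P_LA > P_LV
    av_open <- P_LV > P_Wk
    i0 <- 2L * ((s - 1L) %% spc) + 1L # grid index of t
    ih <- i0 + 1L                     # t + dt/2
    i1 <- if (i0 + 2L > 2L * spc) 1L else i0 + 2L # t + dt (periodic)

    # record state at start of step
    Q_Ao <- solve_aortic_flow(P_LV, P_Wk, params, valve, av_open)
    Q_MV <- if (mv_open) mitral_flow(P_LA, P_LV, params$Rmv) else 0
    out[s, ] <- c((s - 1L) * dt, P_LA, P_LV, P_LV - Q_Ao * params$Rlvot,
                  P_Wk + Q_Ao * params$Rc, P_Wk, Q_MV, Q_Ao, av_open)

    k1 <- rom_deriv(V_LA, V_LV, P_Wk, Ela_g[i0], Elv_g[i0], params, valve,
                    mv_open, av_open)
    k2 <- rom_deriv(V_LA + dt / 2 * k1[1], V_LV + dt / 2 * k1[2],
                    P_Wk + dt / 2 * k1[3], Ela_g[ih], Elv_g[ih], params,
                    valve, mv_open, av_open)
    k3 <- rom_deriv(V_LA + dt / 2 * k2[1], V_LV + dt / 2 * k2[2],
                    P_Wk + dt / 2 * k2[3], Ela_g[ih], Elv_g[ih], params,
                    valve, mv_open, av_open)
    k4 <- rom_deriv(V_LA + dt * k3[1], V_LV + dt * k3[2],
                    P_Wk + dt * k3[3], Ela_g[i1], Elv_g[i1], params,
                    valve, mv_open, av_open)
    V_LA <- V_LA + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    V_LV <- V_LV + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    P_Wk <- P_Wk + dt / 6 * (k1[3] + 2 * k2[3] + 2 * k3[3] + k4[3])
    if (!all(is.finite(c(V_LA, V_LV, P_Wk)))) {
      stop("circulation state became non-finite at t = ", (s - 1L) * dt,
           " s; reduce dt")
    }
    P_LA <- V_LA * Ela_g[i1]
    P_LV <- V_LV * Elv_g[i1]

    if (s %% spc == 0L) { # end of a cycle: periodic-orbit test on P_Ao
      cyc <- out[(s - spc + 1L):s, 5L]
      if (!is.null(cyc_prev)) {
        residual <- max(abs(cyc - cyc_prev))
        if (residual < tol_mmHg) {
          converged <- TRUE
          step_done <- s
          break
        }
      }
      cyc_prev <- cyc
    }
  }

  out <- out[seq_len(step_done), , drop = FALSE]
  wf <- tibble::tibble(
    t_s = out[, 1], cycle = ((seq_len(step_done) - 1L) %/% spc) + 1L,
    P_LA_mmHg = out[, 2], P_LV_mmHg = out[, 3], P_LVOT_mmHg = out[, 4],
    P_Ao_mmHg = out[, 5], P_Wk_mmHg = out[, 6],
    Q_MV_mLs = out[, 7], Q_LVOT_mLs = out[, 8], av_open = out[, 9] > 0
  )
  structure(
    list(waveforms = wf, converged = converged, residual_mmHg = residual,
         n_cycles_run = step_done %/% spc, dt = dt,
         steps_per_cycle = spc, params = params, valve = valve),
    class = "rom_sim"
  )
}

#' @export
print.rom_sim <- function(x, ...) {
  cat(sprintf("<rom_sim>  %d cycles (dt = %g s), %s (residual %.3g mmHg)\n",
              x$n_cycles_run, x$dt,
              if (x$converged) "converged" else "NOT converged",
              x$residual_mmHg))
  invisible(x)
}

#' Clinical metrics over the final cycle of a circulation run
#'
#' Stroke volume `SV` is the integral of aortic flow over the final cycle;
#' cardiac output `CO = SV * 60 / T`. Systole is the set of samples with
#' positive aortic flow: the mean systolic transvalvular pressure
#' difference averages `P_LVOT - P_Ao` there, and the peak diastolic
#' pressure difference is the maximum of `P_Ao - P_LVOT` over closed-valve
#' samples. The effective orifice area follows the simplified continuity
#' (Gorlin-type) convention `EOA = Q_rms,systole / (51.6 sqrt(mean
#' systolic dP))`.
#'
#' @param sim An `rom_sim` from [simulate_circulation()].
#' @return A one-row tibble: `SV_mL`, `CO_Lmin`, `mean_systolic_dP_mmHg`,
#'   `peak_diastolic_dP_mmHg`, `EOA_cm2`, `cycle`, `converged`,
#'   `residual_mmHg`.
#' @export
cycle_metrics <- function(sim) {
  stopifnot(inherits(sim, "rom_sim"))
  wf <- dplyr::filter(sim$waveforms, .data$cycle == max(.data$cycle))
  T <- sim$params$T
  dt <- sim$dt
  Q <- wf$Q_LVOT_mLs
  sys <- Q > 0
  if (!any(sys)) stop("no ejection samples in the final cycle")
  SV <- sum(Q) * dt
  dP <- wf$P_LVOT_mmHg - wf$P_Ao_mmHg
  mean_sys_dP <- mean(dP[sys])
  dia <- !sys
  peak_dia_dP <- if (any(dia)) max(-dP[dia]) else NA_real_
  Q_rms <- sqrt(mean(Q[sys]^2))
  tibble::tibble(
    SV_mL = SV,
    CO_Lmin = SV * 60 / T / 1000,
    mean_systolic_dP_mmHg = mean_sys_dP,
    peak_diastolic_dP_mmHg = peak_dia_dP,
    EOA_cm2 = Q_rms / (GORLIN_K * sqrt(mean_sys_dP)),
    cycle = max(wf$cycle),
    converged = sim$converged,
    residual_mmHg = sim$residual_mmHg
  )
}

#' @rdname cycle_metrics
#' @param x An `rom_sim` object.
#' @param ... Unused.
#' @method glance rom_sim
#' @export
glance.rom_sim <- function(x, ...) cycle_metrics(x)

#' Tidy the waveforms of a circulation run
#'
#' @param x An `rom_sim` object.
#' @param ... Unused.
#' @return Long tibble `t_s, cycle, variable, value`.
#' @method tidy rom_sim
#' @export
tidy.rom_sim <- function(x, ...) {
  tidyr::pivot_longer(x$waveforms,
                      cols = -c("t_s", "cycle", "av_open"),
                      names_to = "variable", values_to = "value")
}

#' Synthetic systolic flow-rate waveform
#'
#' A half-sine ejection pulse on `[0, t_ej]`, zero for the rest of the
#' cycle, scaled so the integral equals the stroke volume exactly
#' (peak value `pi * SV / (2 t_ej)`). A stand-in for measured transvalvular
#' flow waveforms in prescribed-flow experiments.
#'
#' @param SV Stroke volume (mL).
#' @param t_ej Ejection time (s), `0 < t_ej < T`.
#' @param T Cycle period (s).
#' @param dt Sample spacing (s).
#' @return Tibble `t_s, Q_mLs` over one period.
#' @export
synth_flow_waveform <- function(SV, t_ej, T, dt = 1e-3) {
  stopifnot(SV > 0, t_ej > 0, t_ej < T)
  t <- seq(0, T - dt / 2, by = dt)
  Qp <- pi * SV / (2 * t_ej)
  Q <- ifelse(t < t_ej, Qp * sin(pi * t / t_ej), 0)
  tibble::tibble(t_s = t, Q_mLs = Q)
}

#' Prescribed-flow valve comparison
#'
#' Drives each valve surrogate with a common flow-rate waveform and reports
#' the transvalvular pressure-difference waveform and summary metrics, as
#' in bench-style pre/post-TAVR comparisons. For an orifice surrogate
#' `dP = (Q / (51.6 EOA))^2 + Q R`; for a linear one `dP = Q R`.
#'
#' @param flow Tibble with columns `t_s`, `Q_mLs` (uniformly sampled,
#'   `Q >= 0`).
#' @param valves Named list of `valve_surrogate` objects.
#' @return List with `waveforms` (tibble `t_s, valve, Q_mLs, dP_mmHg`) and
#'   `metrics` (tibble `valve, mean_systolic_dP_mmHg, EOA_cm2`, one row per
#'   valve; EOA via the same Gorlin-type continuity convention as
#'   [cycle_metrics()]).
#' @export
prescribed_flow_experiment <- function(flow, valves) {
  stopifnot(all(c("t_s", "Q_mLs") %in% names(flow)),
            all(flow$Q_mLs >= 0), length(valves) >= 1)
  if (is.null(names(valves)) || any(names(valves) == "")) {
    names(valves) <- paste0("valve", seq_along(valves))
  }
  wf <- purrr::imap_dfr(valves, function(v, nm) {
    Q <- flow$Q_mLs
    dP <- if (v$kind == "orifice") {
      (Q / (GORLIN_K * v$EOA_cm2))^2 + Q * v$R
    } else {
      Q * v$R
    }
    tibble::tibble(t_s = flow$t_s, valve = nm, Q_mLs = Q, dP_mmHg = dP)
  })
  metrics <- wf |>
    dplyr::filter(.data$Q_mLs > 0) |>
    dplyr::group_by(.data$valve) |>
    dplyr::summarise(
      mean_systolic_dP_mmHg = mean(.data$dP_mmHg),
      EOA_cm2 = sqrt(mean(.data$Q_mLs^2)) /
        (GORLIN_K * sqrt(mean(.data$dP_mmHg))),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$valve, names(valves)))
  list(waveforms = wf, metrics = metrics)
}
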