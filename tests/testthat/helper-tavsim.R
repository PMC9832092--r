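# shared helpers: random admissible deformations, random rotations

random_deformation <- function(scale = 0.1) {
  repeat {
    F <- diag(3) + scale * matrix(stats::rnorm(9), 3, 3)
    if (det(F) > 0.3) return(F)
  }
}

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# central finite differences of the total strain energy wrt F
fd_pk_stress <- function(F, p, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (strain_energy(kinematics(Fp), p)$psi -
                    strain_energy(kinematics(Fm), p)$psi) / (2 * h)
    }
  }
  P
}

# a deliberately small, fast circulation run
quick_sim <- function(params = circulation_params(), valve = NULL,
                      n_cycles = 6, dt = 5e-4, tol = 1e-9) {
  if (is.null(valve)) valve <- valve_surrogate("orifice", EOA_cm2 = 1.5)
  simulate_circulation(params, valve, n_cycles = n_cycles, dt = dt,
                       tol_mmHg = tol)
}
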