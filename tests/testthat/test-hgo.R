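# Tissue model: kinematics, energy, stresses, biaxial response, fitting.

test_that("kinematics computes the isochoric split correctly", {
  d <- kinematics(diag(3))
  expect_equal(d$J, 1)
  expect_equal(d$I1bar, 3)

  d <- kinematics(diag(c(2, 1, 1)))
  expect_equal(d$J, 2)
  expect_equal(d$I1bar, 6 * 2^(-2 / 3))

  lam <- 1.2
  d <- kinematics(diag(c(lam, lam^-0.5, lam^-0.5)))
  expect_equal(d$J, 1)
  expect_equal(d$I1bar, lam^2 + 2 / lam)

  # I1bar invariant under uniform scaling of F
  F <- random_deformation()
  expect_equal(kinematics(2.7 * F)$I1bar, kinematics(F)$I1bar)

  expect_error(kinematics(diag(c(-1, 1, 1))), "determinant")
  expect_error(kinematics(matrix(0, 3, 3)), "determinant")
})

test_that("fiber invariant is tension-only and needs a unit direction", {
  f0 <- c(1, 0, 0)
  expect_equal(fiber_invariant(kinematics(diag(3)), f0), 1)
  lam <- 0.8 # shortened fiber: clamped at 1
  expect_equal(
    fiber_invariant(kinematics(diag(c(lam, lam^-0.5, lam^-0.5))), f0), 1)
  lam <- 1.1
  expect_equal(
    fiber_invariant(kinematics(diag(c(lam, lam^-0.5, lam^-0.5))), f0),
    lam^2)
  expect_error(fiber_invariant(kinematics(diag(3)), c(1, 1, 0)), "unit")
})

test_that("fiber families sit symmetrically about the mean direction", {
  fd <- fiber_directions(0, 0)
  expect_equal(fd[1, ], c(1, 0, 0))
  expect_equal(fd[2, ], c(1, 0, 0))

  ang <- function(v) atan2(v[2], v[1]) * 180 / pi
  fd <- fiber_directions(45, 7.81)
  expect_equal(ang(fd[1, ]), 37.19)
  expect_equal(ang(fd[2, ]), 52.81)
  fd <- fiber_directions(90, 26.21)
  expect_equal(ang(fd[1, ]), 63.79)
  expect_equal(ang(fd[2, ]), 116.21)
  expect_equal(rowSums(fd^2), c(1, 1))
})

test_that("strain energy vanishes at the reference and splits as W + U", {
  p <- hgo_porcine_pericardium()
  e <- strain_energy(kinematics(diag(3)), p)
  expect_equal(e$W, 0)
  expect_equal(e$U, 0)

  # both fibers shortened: fiber term contributes nothing
  p0 <- hgo_params(p$C10, p$C01, 0, p$k2, p$theta_deg, p$beta / 1000,
                   mean_fiber_deg = 0)
  p_mean0 <- hgo_porcine_pericardium(mean_fiber_deg = 0)
  F <- diag(c(0.9, 0.9, 1 / 0.81))
  expect_equal(strain_energy(kinematics(F), p_mean0)$W,
               strain_energy(kinematics(F), p0)$W)

  # volumetric stabilization closed form at J = 2 (beta = 5.840 MPa)
  e <- strain_energy(kinematics(diag(c(2, 1, 1))), p)
  expect_equal(e$U, 5840 * (2 * log(2) - 1))
})

test_that("first PK stress is the analytic gradient of the energy", {
  p <- hgo_porcine_pericardium()
  expect_equal(first_pk_stress(kinematics(diag(3)), p), matrix(0, 3, 3))

  withr::with_seed(11, {
    for (i in 1:100) {
      F <- random_deformation()
      P <- first_pk_stress(kinematics(F), p)
      Pfd <- fd_pk_stress(F, p)
      expect_lt(max(abs(P - Pfd)) / max(abs(P)), 1e-6)
    }
  })
})

test_that("energy is objective under superposed rotations", {
  p <- hgo_native_leaflet()
  withr::with_seed(7, {
    F <- random_deformation()
    psi <- strain_energy(kinematics(F), p)$psi
    for (i in 1:20) {
      Q <- random_rotation()
      expect_equal(strain_energy(kinematics(Q %*% F), p)$psi, psi,
                   tolerance = 1e-12)
    }
  })
})

test_that("Cauchy push-forward and von Mises closed forms hold", {
  d <- kinematics(diag(3))
  st <- cauchy_and_von_mises(d, matrix(0, 3, 3))
  expect_equal(st$sigma, matrix(0, 3, 3))
  expect_equal(st$von_mises, 0)

  # hydrostatic state has zero von Mises intensity
  st <- cauchy_and_von_mises(d, 7.3 * diag(3))
  expect_equal(st$von_mises, 0)

  # uniaxial state: von Mises equals the single stress component
  P <- matrix(0, 3, 3)
  P[1, 1] <- 42
  st <- cauchy_and_von_mises(d, P)
  expect_equal(st$von_mises, 42)
})

test_that("plane-stress biaxial response matches the tensor machinery", {
  p <- hgo_porcine_pericardium()
  expect_equal(unlist(biaxial_plane_stress(1, 1, p)[, 3:4]),
               c(sigma11_kPa = 0, sigma22_kPa = 0))

  # cross-check the closed form against kinematics -> P -> sigma
  withr::with_seed(5, {
    for (i in 1:10) {
      l1 <- runif(1, 1.0, 1.2)
      l2 <- runif(1, 1.0, 1.2)
      d <- kinematics(diag(c(l1, l2, 1 / (l1 * l2))))
      st <- cauchy_and_von_mises(d, first_pk_stress(d, p))
      sig <- st$sigma - diag(st$sigma[3, 3], 3) # plane-stress multiplier
      b <- biaxial_plane_stress(l1, l2, p)
      expect_equal(sig[1, 1], b$sigma11_kPa, tolerance = 1e-9)
      expect_equal(sig[2, 2], b$sigma22_kPa, tolerance = 1e-9)
    }
  })
})

test_that("fiber reinforcement biases stress toward the fiber axis", {
  p <- hgo_porcine_pericardium(mean_fiber_deg = 0)
  b <- biaxial_plane_stress(1.15, 1.15, p)
  expect_gt(b$sigma11_kPa, b$sigma22_kPa)
})

test_that("biaxial stresses equal derivatives of the reduced energy", {
  # sigma_ii = lambda_i dW/dlambda_i for the incompressibility-reduced
  # energy w(l1, l2) under plane stress
  p <- hgo_porcine_pericardium()
  w <- function(l1, l2) {
    strain_energy(kinematics(diag(c(l1, l2, 1 / (l1 * l2)))), p)$W
  }
  h <- 1e-6
  withr::with_seed(9, {
    for (i in 1:8) {
      l1 <- runif(1, 1.02, 1.2)
      l2 <- runif(1, 1.02, 1.2)
      s11 <- l1 * (w(l1 + h, l2) - w(l1 - h, l2)) / (2 * h)
      s22 <- l2 * (w(l1, l2 + h) - w(l1, l2 - h)) / (2 * h)
      b <- biaxial_plane_stress(l1, l2, p)
      expect_equal(b$sigma11_kPa, s11,
                   tolerance = 1e-6 * max(1, abs(s11)))
      expect_equal(b$sigma22_kPa, s22,
                   tolerance = 1e-6 * max(1, abs(s22)))
    }
  })
})

test_that("synthetic biaxial datasets are reproducible and noise-calibrated", {
  p <- hgo_porcine_pericardium()
  d0 <- generate_biaxial_dataset(p, noise_sd = 0)
  m <- biaxial_plane_stress(d0$lambda1, d0$lambda2, p)
  expect_equal(d0$sigma11_kPa, m$sigma11_kPa)
  expect_equal(d0$sigma22_kPa, m$sigma22_kPa)

  d1 <- generate_biaxial_dataset(p, noise_sd = 2, seed = 33)
  d2 <- generate_biaxial_dataset(p, noise_sd = 2, seed = 33)
  expect_identical(d1, d2)

  # additive-noise residual SD recovers the configured level (n = 800)
  res <- c(d1$sigma11_kPa - m$sigma11_kPa, d1$sigma22_kPa - m$sigma22_kPa)
  expect_lt(abs(sd(res) - 2) / 2, 0.15)
})

test_that("noise-free fitting recovers both published tissue rows within 1%", {
  for (p in list(hgo_porcine_pericardium(), hgo_native_leaflet())) {
    d <- generate_biaxial_dataset(p)
    f <- fit_hgo(d, mean_fiber_deg = p$mean_fiber_deg,
                 beta_MPa = p$beta / 1000)
    expect_true(f$converged)
    expect_lt(abs(f$params$C10 - p$C10) / p$C10, 0.01)
    expect_lt(abs(f$params$k2 - p$k2) / p$k2, 0.01)
    expect_lt(abs(f$params$C01 - p$C01) / p$C01, 0.01)
    expect_lt(abs(f$params$theta_deg - p$theta_deg) / p$theta_deg, 0.01)
  }
})

test_that("fitting is robust to measurement noise and idempotent", {
  p <- hgo_porcine_pericardium()
  dn <- generate_biaxial_dataset(p, noise_sd = 0.05, seed = 1,
                                 noise_type = "multiplicative")
  fn <- fit_hgo(dn, mean_fiber_deg = 45, beta_MPa = 5.84)
  expect_lt(abs(fn$params$C10 - p$C10) / p$C10, 0.10)
  expect_lt(abs(fn$params$k2 - p$k2) / p$k2, 0.10)

  # refitting data generated from a fit's own parameters reproduces them
  d2 <- generate_biaxial_dataset(fn$params, noise_sd = 0)
  f2 <- fit_hgo(d2, mean_fiber_deg = 45, beta_MPa = 5.84)
  expect_lt(abs(f2$params$C10 - fn$params$C10) / fn$params$C10, 1e-4)
  expect_lt(abs(f2$params$k2 - fn$params$k2) / fn$params$k2, 1e-4)
})

test_that("tidy and glance summarize a fit", {
  p <- hgo_porcine_pericardium()
  f <- fit_hgo(generate_biaxial_dataset(p), mean_fiber_deg = 45,
               beta_MPa = 5.84)
  td <- generics::tidy(f)
  expect_setequal(td$term,
                  c("C10", "C01", "k1", "k2", "theta", "beta", "mean_fiber"))
  gl <- generics::glance(f)
  expect_true(gl$converged)
  expect_equal(gl$n_obs, 400L)
})

test_that("stenotic stiffening scales only C10 and composes", {
  p <- hgo_native_leaflet()
  ps <- stenotic_stiffening(p)
  expect_equal(ps$C10, 146.3)
  expect_equal(ps[-1], p[-1])
  expect_equal(stenotic_stiffening(p, 1), p)
  expect_equal(stenotic_stiffening(stenotic_stiffening(p, 10), 100),
               stenotic_stiffening(p, 1000))
})

test_that("extreme exponents are capped, not silently infinite", {
  p <- hgo_params(1, 5, 1, 500, 10, 1)
  e <- strain_energy(kinematics(diag(c(2, 1, 0.5))), p)
  expect_true(is.finite(e$psi))
  expect_true(attr(e, "capped"))
})
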