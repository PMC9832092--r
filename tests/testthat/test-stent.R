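# Stent frame: lattice synthesis, elastic forces, crimping, self-expansion.

test_that("the synthesized lattice is at equilibrium with the right size", {
  fr <- synthesize_frame(n_circumferential = 12, n_rows = 4,
                         diameter_mm = 26)
  expect_equal(nrow(fr$nodes), 12 * (4 + 1))
  expect_equal(diameter_metrics(fr)$diameter_mm, 26)
  expect_equal(max(abs(elastic_forces(fr))), 0)
  expect_equal(elastic_energy(fr), 0)
  expect_error(synthesize_frame(n_circumferential = 2), "n_circumferential")
})

test_that("an isolated stretched spring obeys Hooke's law", {
  k <- 120
  L0 <- 1
  net <- elastic_network(rbind(c(0, 0, 0), c(1.5 * L0, 0, 0)),
                         springs = data.frame(i = 1, j = 2, k = k, L0 = L0))
  F <- network_forces(net)
  expect_equal(F[1, ], c(k * 0.5 * L0, 0, 0))
  expect_equal(F[2, ], -F[1, ])
  expect_error(
    network_forces(net, rbind(c(0, 0, 0), c(0, 0, 0))), "coincident")
})

test_that("elastic forces equal finite differences of the energy", {
  fr <- synthesize_frame()
  withr::with_seed(13, {
    x <- fr$nodes + 0.03 * matrix(rnorm(length(fr$nodes)), nrow(fr$nodes))
  })
  F <- network_forces(fr, x)
  h <- 1e-6
  for (idx in list(c(1, 1), c(17, 2), c(42, 3))) {
    xp <- x; xp[idx[1], idx[2]] <- xp[idx[1], idx[2]] + h
    xm <- x; xm[idx[1], idx[2]] <- xm[idx[1], idx[2]] - h
    fd <- -(network_energy(fr, xp) - network_energy(fr, xm)) / (2 * h)
    expect_lt(abs(F[idx[1], idx[2]] - fd) / max(abs(F)), 1e-6)
  }
})

test_that("energy is invariant under rigid motions", {
  fr <- synthesize_frame()
  withr::with_seed(17, {
    x <- fr$nodes + 0.05 * matrix(rnorm(length(fr$nodes)), nrow(fr$nodes))
    E <- network_energy(fr, x)
    for (i in 1:5) {
      Q <- random_rotation()
      shift <- rnorm(3)
      xr <- sweep(x %*% t(Q), 2, -shift)
      expect_equal(network_energy(fr, xr), E, tolerance = 1e-9)
    }
  })
})

test_that("a crimper wider than the frame leaves it untouched", {
  fr <- synthesize_frame()
  cr <- crimp(fr, crimper(stop_radius_cm = 2))
  expect_equal(cr$frame$nodes, fr$nodes)
  expect_equal(cr$penetration_cm, 0)
})

test_that("crimping reaches the commanded capsule diameter", {
  fr <- synthesize_frame()
  cr <- crimp(fr, crimper(stop_radius_cm = 0.2875)) # 17.25 Fr target
  fr_final <- utils::tail(cr$trajectory$diameter_Fr, 1)
  expect_lt(abs(fr_final - 17.25) / 17.25, 0.05)
  # penetration bounded by the tether compliance
  expect_lt(cr$penetration_cm, 0.01)
  # crimper radius decreases monotonically at the commanded speed
  expect_true(all(diff(cr$trajectory$crimper_radius_cm) <= 0))
})

test_that("overdamped relaxation monotonically dissipates energy", {
  fr <- synthesize_frame()
  cr <- crimp(fr, crimper(stop_radius_cm = 0.8))
  ex <- release_and_expand(cr$frame, t_max = 0.5)
  en <- ex$trajectory$energy_erg
  expect_true(all(diff(en) <= 1e-9 * en[1]))
})

test_that("a released frame self-expands back to its reference shape", {
  fr <- synthesize_frame()
  cr <- crimp(fr, crimper(stop_radius_cm = 0.2875))
  ex <- release_and_expand(cr$frame)
  expect_true(ex$converged)
  d <- diameter_metrics(ex$frame)$diameter_mm
  expect_lt(abs(d - 26) / 26, 0.01)
  expect_lt(ex$max_force_dyne,
            1e-6 * max(fr$springs$k) * mean(fr$springs$L0))

  # idempotence: expanding an expanded frame changes nothing
  ex2 <- release_and_expand(ex$frame)
  expect_lt(max(abs(ex2$frame$nodes - ex$frame$nodes)), 1e-4)

  # path independence: a shallower crimp relaxes to the same endpoint
  cr2 <- crimp(fr, crimper(stop_radius_cm = 0.9))
  ex3 <- release_and_expand(cr2$frame)
  expect_lt(max(abs(ex3$frame$nodes - ex$frame$nodes)), 1e-2)
})

test_that("diameter metrics convert correctly and scale linearly", {
  x <- cbind(c(0.2875, -0.2875), 0, 0) # 5.75 mm across
  dm <- diameter_metrics(x)
  expect_equal(dm$diameter_mm, 5.75)
  expect_equal(dm$diameter_Fr, 17.25)
  expect_equal(diameter_metrics(2.5 * x)$diameter_mm, 2.5 * 5.75)
  fr <- synthesize_frame(diameter_mm = 26)
  expect_equal(diameter_metrics(fr)$diameter_Fr, 78)
})
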