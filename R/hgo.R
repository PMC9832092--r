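# Fiber-reinforced hyperelastic (modified HGO) tissue model:
# kinematics, strain energy, stresses, planar-biaxial response, and fitting.
#
# Canonical stress unit throughout this module is kPa. Constructor inputs use
# the mixed units the constants are conventionally reported in (C10 in kPa,
# k1 and beta in MPa) and are converted on entry (1 MPa = 1000 kPa).

EXP_CAP <- 50 # cap on exponent arguments; fitting explores extreme k2

# guarded exponential: exp(a) up to the cap, then its tangent line. C1
# continuous, so the analytic stress (which uses exp(pmin(a, cap)), the
# exact derivative of this function) stays consistent with the energy.
guarded_exp <- function(a) {
  ifelse(a <= EXP_CAP, exp(pmin(a, EXP_CAP)),
         exp(EXP_CAP) * (1 + (a - EXP_CAP)))
}

#' Constitutive parameters for the modified HGO tissue model
#'
#' Bundles the constants of the modified Holzapfel--Gasser--Ogden (HGO)
#' strain-energy function used for valve leaflet and pericardial tissue:
#' an exponential isotropic matrix term `C10 (exp(C01 (I1b - 3)) - 1)`, two
#' tension-only fiber families `k1/(2 k2) (exp(k2 (I4* - 1)^2) - 1)`, and a
#' volumetric stabilization `beta (J ln J - J + 1)`.
#'
#' @param C10_kPa Isotropic stiffness (kPa), > 0.
#' @param C01 Dimensionless isotropic exponent coefficient, >= 0.
#' @param k1_MPa Fiber stiffness (MPa), >= 0.
#' @param k2 Dimensionless fiber exponent, > 0.
#' @param theta_deg Fiber half-dispersion angle (degrees): the two fiber
#'   families lie at `mean_fiber_deg +/- theta_deg` in the material plane.
#' @param beta_MPa Volumetric stabilization stiffness (MPa), > 0.
#' @param mean_fiber_deg Mean fiber direction (degrees) in the material
#'   1--2 plane, measured from axis 1.
#' @return An object of class `hgo_params` with all stresses stored in kPa
#'   (`C10`, `k1`, `beta`) plus `C01`, `k2`, `theta_deg`, `mean_fiber_deg`.
#' @examples
#' p <- hgo_params(15.14, 13.48, 0.1526, 107.3, 7.81, 5.840, 45)
#' p$k1 # 152.6 kPa
#' @export
hgo_params <- function(C10_kPa, C01, k1_MPa, k2, theta_deg, beta_MPa,
                       mean_fiber_deg = 0) {
  stopifnot(
    is.finite(C10_kPa), C10_kPa > 0,
    is.finite(C01), C01 >= 0,
    is.finite(k1_MPa), k1_MPa >= 0,
    is.finite(k2), k2 > 0,
    is.finite(beta_MPa), beta_MPa > 0,
    is.finite(theta_deg), theta_deg >= 0, theta_deg < 90,
    is.finite(mean_fiber_deg)
  )
  structure(
    list(
      C10 = C10_kPa, C01 = C01,
      k1 = 1000 * k1_MPa, k2 = k2,
      theta_deg = theta_deg,
      beta = 1000 * beta_MPa,
      mean_fiber_deg = mean_fiber_deg
    ),
    class = "hgo_params"
  )
}

#' @export
print.hgo_params <- function(x, ...) {
  cat("<hgo_params>  (canonical unit: kPa)\n")
  cat(sprintf("  C10 = %g kPa   C01 = %g\n", x$C10, x$C01))
  cat(sprintf("  k1  = %g kPa   k2  = %g\n", x$k1, x$k2))
  cat(sprintf("  theta = %g deg about mean fiber direction %g deg\n",
              x$theta_deg, x$mean_fiber_deg))
  cat(sprintf("  beta = %g kPa (volumetric stabilization)\n", x$beta))
  invisible(x)
}

#' Reference parameter sets for valve tissues
#'
#' Published best-fit constants for healthy native aortic valve leaflet
#' tissue (mean fiber direction commissure-to-commissure, taken as axis 1)
#' and for glutaraldehyde-fixed porcine pericardium as used in
#' self-expanding TAV leaflets and sealing skirts (mean fiber direction 45
#' degrees for the leaflets).
#'
#' @param mean_fiber_deg Mean fiber direction override (degrees).
#' @return An `hgo_params` object.
#' @export
hgo_native_leaflet <- function(mean_fiber_deg = 0) {
  hgo_params(0.1463, 26.21, 0.007072, 147.5, 26.21, 141.0, mean_fiber_deg)
}

#' @rdname hgo_native_leaflet
#' @export
hgo_porcine_pericardium <- function(mean_fiber_deg = 45) {
  hgo_params(15.14, 13.48, 0.1526, 107.3, 7.81, 5.840, mean_fiber_deg)
}

#' Stiffen a parameter set to emulate calcific stenosis
#'
#' Severe aortic stenosis is emulated by scaling the isotropic stiffness
#' `C10` (by default a thousandfold); all other constants are unchanged.
#'
#' @param p An `hgo_params` object.
#' @param factor Positive multiplier applied to `C10`.
#' @return A stiffened `hgo_params` object.
#' @export
stenotic_stiffening <- function(p, factor = 1e3) {
  stopifnot(inherits(p, "hgo_params"), is.finite(factor), factor > 0)
  p$C10 <- p$C10 * factor
  p
}

#' Kinematic quantities of a deformation gradient
#'
#' Computes the isochoric/volumetric split of a deformation gradient F:
#' `J = det F`, `Fbar = J^(-1/3) F`, the modified right Cauchy--Green tensor
#' `Cbar = t(Fbar) %*% Fbar` and its first invariant `I1bar = tr(Cbar)`.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @return A list of class `deformation` with elements `F`, `J`, `Fbar`,
#'   `Cbar`, `I1bar`, `Finv_t` (inverse transpose of F).
#' @examples
#' kinematics(diag(3))$I1bar # 3
#' @export
kinematics <- function(F) {
  F <- as.matrix(F)
  stopifnot(is.numeric(F), all(dim(F) == c(3L, 3L)), all(is.finite(F)))
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    stop("deformation gradient must have positive determinant (J = ",
         format(J), ")")
  }
  Fbar <- J^(-1 / 3) * F
  Cbar <- crossprod(Fbar)
  structure(
    list(F = F, J = J, Fbar = Fbar, Cbar = Cbar,
         I1bar = sum(diag(Cbar)), Finv_t = t(solve(F))),
    class = "deformation"
  )
}

#' Tension-only fiber stretch invariant
#'
#' `I4* = max(f0 . Cbar f0, 1)`: the squared isochoric fiber stretch,
#' clamped at 1 so shortened fibers carry no load.
#'
#' @param def A `deformation` from [kinematics()].
#' @param f0 Unit reference fiber direction (length-3 vector).
#' @return Scalar `I4*` (>= 1).
#' @export
fiber_invariant <- function(def, f0) {
  stopifnot(inherits(def, "deformation"), length(f0) == 3L)
  if (abs(sqrt(sum(f0^2)) - 1) > 1e-8) {
    stop("fiber direction f0 must be a unit vector")
  }
  max(drop(crossprod(f0, def$Cbar %*% f0)), 1)
}

#' In-plane fiber family directions
#'
#' The two equally weighted fiber families lie in the material 1--2 plane at
#' `mean_angle +/- theta` from axis 1.
#'
#' @param mean_angle Mean fiber direction (degrees).
#' @param theta Half-dispersion angle (degrees).
#' @return 2x3 matrix; rows are unit vectors.
#' @export
fiber_directions <- function(mean_angle, theta) {
  stopifnot(is.finite(mean_angle), is.finite(theta))
  a <- (c(mean_angle - theta, mean_angle + theta)) * pi / 180
  cbind(cos(a), sin(a), 0)
}

# isotropic and fiber energy-derivative coefficients, exponent-guarded.
# Returns W1 = dW/dI1bar and per-family W4 = dW/dI4*, with a capped flag.
hgo_coefs <- function(def, p) {
  fdir <- fiber_directions(p$mean_fiber_deg, p$theta_deg)
  I4 <- vapply(1:2, function(i) {
    drop(crossprod(fdir[i, ], def$Cbar %*% fdir[i, ]))
  }, numeric(1))
  I4s <- pmax(I4, 1)
  a1 <- p$C01 * (def$I1bar - 3)
  a4 <- p$k2 * (I4s - 1)^2
  list(
    fdir = fdir, I4 = I4, I4s = I4s,
    W1 = p$C10 * p$C01 * exp(min(a1, EXP_CAP)),
    W4 = ifelse(I4 > 1, p$k1 * (I4s - 1) * exp(pmin(a4, EXP_CAP)), 0),
    a1 = a1, a4 = a4,
    capped = a1 > EXP_CAP || any(a4 > EXP_CAP)
  )
}

#' Strain energy of the modified HGO model
#'
#' Evaluates the isochoric energy `W(Fbar)` and volumetric stabilization
#' `U(J)` (both kPa). Exponential arguments beyond 50 are continued
#' linearly (a C1 guard against overflow while fitting explores extreme
#' exponents, keeping energy and stress mutually consistent); guarded
#' evaluations carry attribute `capped = TRUE`.
#'
#' @param def A `deformation` from [kinematics()].
#' @param p An `hgo_params` object.
#' @return Named list `W`, `U`, `psi = W + U` (kPa) with attribute `capped`.
#' @export
strain_energy <- function(def, p) {
  stopifnot(inherits(def, "deformation"), inherits(p, "hgo_params"))
  co <- hgo_coefs(def, p)
  W_iso <- p$C10 * (guarded_exp(co$a1) - 1)
  W_fib <- if (p$k1 > 0) {
    p$k1 / (2 * p$k2) * sum(guarded_exp(co$a4) - 1)
  } else {
    0
  }
  U <- p$beta * (def$J * log(def$J) - def$J + 1)
  structure(list(W = W_iso + W_fib, U = U, psi = W_iso + W_fib + U),
            capped = co$capped)
}

#' First Piola--Kirchhoff stress
#'
#' Analytic derivative `P = dPsi/dF` of the modified HGO energy, including
#' the isochoric projection induced by the `Fbar = J^(-1/3) F` dependence and
#' the volumetric term `U'(J) J F^(-T)`.
#'
#' @inheritParams strain_energy
#' @return 3x3 first Piola--Kirchhoff stress (kPa).
#' @export
first_pk_stress <- function(def, p) {
  stopifnot(inherits(def, "deformation"), inherits(p, "hgo_params"))
  co <- hgo_coefs(def, p)
  Pbar <- 2 * co$W1 * def$Fbar
  for (i in 1:2) {
    if (co$W4[i] > 0) {
      f0 <- co$fdir[i, ]
      Pbar <- Pbar + 2 * co$W4[i] * (def$Fbar %*% tcrossprod(f0))
    }
  }
  P_iso <- def$J^(-1 / 3) * Pbar - (sum(Pbar * def$Fbar) / 3) * def$Finv_t
  P_vol <- p$beta * def$J * log(def$J) * def$Finv_t
  P_iso + P_vol
}

#' Cauchy stress and von Mises intensity
#'
#' Pushes a first Piola--Kirchhoff stress forward to the Cauchy stress
#' `sigma = J^-1 P t(F)` (symmetrized to suppress round-off asymmetry) and
#' computes the von Mises intensity from its deviator.
#'
#' @param def A `deformation` from [kinematics()].
#' @param P 3x3 first Piola--Kirchhoff stress.
#' @return List with `sigma` (3x3, kPa) and `von_mises` (scalar, kPa).
#' @export
cauchy_and_von_mises <- function(def, P) {
  stopifnot(inherits(def, "deformation"), all(dim(P) == c(3L, 3L)))
  sigma <- (P %*% t(def$F)) / def$J
  sigma <- (sigma + t(sigma)) / 2
  s <- sigma - diag(mean(diag(sigma)), 3)
  list(sigma = sigma, von_mises = sqrt(1.5 * sum(s^2)))
}

#' Planar-biaxial plane-stress response
#'
#' In-plane Cauchy stresses for a biaxial stretch state `(lambda1, lambda2)`
#' under exact incompressibility (`lambda3 = 1/(lambda1 lambda2)`, so the
#' volumetric term vanishes) and plane stress (`sigma33 = 0` enforced via a
#' pressure-like multiplier). Fibers lie in the 1--2 plane at
#' `mean_fiber_deg +/- theta_deg`. Vectorized over stretches.
#'
#' @param lambda1,lambda2 In-plane stretches (> 0), recycled to a common
#'   length.
#' @param p An `hgo_params` object.
#' @return A tibble with columns `lambda1`, `lambda2`, `sigma11_kPa`,
#'   `sigma22_kPa`.
#' @examples
#' biaxial_plane_stress(1.1, 1.1, hgo_porcine_pericardium())
#' @export
biaxial_plane_stress <- function(lambda1, lambda2, p) {
  stopifnot(inherits(p, "hgo_params"), all(lambda1 > 0), all(lambda2 > 0))
  n <- max(length(lambda1), length(lambda2))
  l1 <- rep_len(lambda1, n)
  l2 <- rep_len(lambda2, n)
  l3 <- 1 / (l1 * l2)
  I1 <- l1^2 + l2^2 + l3^2
  W1 <- p$C10 * p$C01 * exp(pmin(p$C01 * (I1 - 3), EXP_CAP))
  s11 <- 2 * W1 * (l1^2 - l3^2)
  s22 <- 2 * W1 * (l2^2 - l3^2)
  ang <- (p$mean_fiber_deg + c(-1, 1) * p$theta_deg) * pi / 180
  for (a in ang) {
    ca2 <- cos(a)^2
    sa2 <- sin(a)^2
    I4 <- l1^2 * ca2 + l2^2 * sa2
    e <- pmax(I4 - 1, 0)
    W4 <- p$k1 * e * exp(pmin(p$k2 * e^2, EXP_CAP))
    s11 <- s11 + 2 * W4 * l1^2 * ca2
    s22 <- s22 + 2 * W4 * l2^2 * sa2
  }
  tibble::tibble(lambda1 = l1, lambda2 = l2,
                 sigma11_kPa = s11, sigma22_kPa = s22)
}

#' Generate a synthetic planar-biaxial dataset
#'
#' Emulates a planar biaxial tensile test: evaluates the plane-stress
#' response of `p` on a grid of stretch pairs and optionally adds
#' measurement noise. With `noise_sd = 0` the dataset equals the model
#' response exactly; with a seed the dataset is reproducible.
#'
#' @param p An `hgo_params` object (the "true" tissue).
#' @param stretch_grid Numeric vector of stretches; the protocol takes all
#'   pairs `(lambda1, lambda2)` from `expand.grid(stretch_grid,
#'   stretch_grid)`. Default: 20 values in the physiologic range 1--1.25.
#' @param noise_sd Noise level. For `noise_type = "additive"` the standard
#'   deviation in kPa; for `"multiplicative"` the relative standard
#'   deviation (e.g. `0.05` for 5 percent).
#' @param seed Integer RNG seed (used locally; the global RNG state is
#'   restored).
#' @param noise_type `"additive"` or `"multiplicative"`.
#' @return A tibble `lambda1, lambda2, sigma11_kPa, sigma22_kPa` with
#'   attributes `protocol`, `noise_sd`, `noise_type`, `seed`.
#' @export
generate_biaxial_dataset <- function(p,
                                     stretch_grid = seq(1.0, 1.25,
                                                        length.out = 20),
                                     noise_sd = 0, seed = 1L,
                                     noise_type = c("additive",
                                                    "multiplicative")) {
  noise_type <- match.arg(noise_type)
  stopifnot(inherits(p, "hgo_params"), noise_sd >= 0,
            all(stretch_grid > 0))
  g <- expand.grid(lambda1 = stretch_grid, lambda2 = stretch_grid)
  d <- biaxial_plane_stress(g$lambda1, g$lambda2, p)
  if (noise_sd > 0) {
    d <- withr::with_seed(as.integer(seed), {
      n <- nrow(d)
      if (noise_type == "additive") {
        d$sigma11_kPa <- d$sigma11_kPa + stats::rnorm(n, sd = noise_sd)
        d$sigma22_kPa <- d$sigma22_kPa + stats::rnorm(n, sd = noise_sd)
      } else {
        d$sigma11_kPa <- d$sigma11_kPa * (1 + stats::rnorm(n, sd = noise_sd))
        d$sigma22_kPa <- d$sigma22_kPa * (1 + stats::rnorm(n, sd = noise_sd))
      }
      d
    })
  }
  attr(d, "protocol") <- "biaxial-grid"
  attr(d, "noise_sd") <- noise_sd
  attr(d, "noise_type") <- noise_type
  attr(d, "seed") <- as.integer(seed)
  d
}

# internal: map unconstrained optimizer parameters to physical constants
hgo_fit_decode <- function(par, template) {
  p <- template
  p$C10 <- exp(par[1])
  p$C01 <- exp(par[2])
  p$k1 <- exp(par[3])
  p$k2 <- exp(par[4])
  p$theta_deg <- 90 * stats::plogis(par[5])
  p
}

hgo_fit_encode <- function(p) {
  c(log(p$C10), log(p$C01), log(p$k1), log(p$k2),
    stats::qlogis(min(max(p$theta_deg / 90, 1e-6), 1 - 1e-6)))
}

#' Fit the modified HGO model to planar-biaxial data
#'
#' Weighted least squares over the stacked `(sigma11, sigma22)` residuals,
#' by Levenberg--Marquardt with a fixed 8-point log-spaced multi-start on
#' `(k1, k2)` to escape the exponential model's local minima. The free
#' parameters are `C10`, `C01`, `k1`, `k2` and the dispersion angle
#' `theta`; positivity and `0 < theta < 90` are enforced by a log /
#' logistic reparameterization. The mean fiber direction is protocol
#' information (specimen mounting) and is held fixed, as is `beta`, which
#' is not identifiable from incompressible plane-stress data.
#'
#' @param data A tibble/data.frame with columns `lambda1`, `lambda2`,
#'   `sigma11_kPa`, `sigma22_kPa` (e.g. from
#'   [generate_biaxial_dataset()] or [read_biaxial_csv()]).
#' @param mean_fiber_deg Known mean fiber direction of the specimen
#'   (degrees).
#' @param beta_MPa Volumetric stabilization to carry into the returned
#'   parameter set (not fitted).
#' @param weights Optional per-row weights (recycled to both stress
#'   components), multiplied into the weighting-scheme weights.
#' @param weighting `"relative"` (default) scales each residual by
#'   `1 / (|sigma_obs| + delta)` with `delta` a small floor tied to the
#'   median stress magnitude -- necessary because the exponential model's
#'   stresses span many decades over a biaxial grid, and without it the
#'   softest (low-stretch) response that identifies `C10` carries no
#'   weight; `"absolute"` uses raw residuals.
#' @param init Optional `hgo_params` used as an additional start.
#' @return An object of class `hgo_fit`: a list with `params`
#'   (`hgo_params`), `residual_norm`, `converged`, `n_obs`, `starts`
#'   (per-start diagnostics tibble), `data`. Supports [generics::tidy()]
#'   and [generics::glance()].
#' @export
fit_hgo <- function(data, mean_fiber_deg = 0, beta_MPa = 1,
                    weights = NULL,
                    weighting = c("relative", "absolute"), init = NULL) {
  weighting <- match.arg(weighting)
  need <- c("lambda1", "lambda2", "sigma11_kPa", "sigma22_kPa")
  stopifnot(all(need %in% names(data)))
  n <- nrow(data)
  if (n < 3 * 5) {
    stop("need at least 3x more data rows than the 5 free parameters")
  }
  w <- if (is.null(weights)) rep(1, n) else rep_len(weights, n)
  sw <- sqrt(w)
  if (weighting == "relative") {
    delta <- 1e-3 * stats::median(abs(c(data$sigma11_kPa,
                                        data$sigma22_kPa))) + 1e-12
    sw11 <- sw / (abs(data$sigma11_kPa) + delta)
    sw22 <- sw / (abs(data$sigma22_kPa) + delta)
  } else {
    sw11 <- sw22 <- sw
  }
  template <- hgo_params(1, 1, 1e-3, 1, 10, beta_MPa,
                         mean_fiber_deg = mean_fiber_deg)

  resid_fn <- function(par) {
    p <- hgo_fit_decode(par, template)
    m <- biaxial_plane_stress(data$lambda1, data$lambda2, p)
    c(sw11 * (m$sigma11_kPa - data$sigma11_kPa),
      sw22 * (m$sigma22_kPa - data$sigma22_kPa))
  }

  # fixed multi-start schedule: 8 log-spaced (k1, k2) pairs spanning soft,
  # weakly nonlinear to stiff, strongly nonlinear fiber responses
  sc <- stats::median(abs(c(data$sigma11_kPa, data$sigma22_kPa)))
  sc <- max(sc, 1e-3)
  k1_starts <- 10^seq(0, 3, length.out = 8)   # kPa
  k2_starts <- 10^seq(0.5, 2.5, length.out = 8)
  starts <- lapply(seq_len(8), function(i) {
    c(log(sc / 5), log(5), log(k1_starts[i]), log(k2_starts[i]),
      stats::qlogis(10 / 90))
  })
  if (!is.null(init)) starts <- c(starts, list(hgo_fit_encode(init)))

  fits <- lapply(starts, function(s) {
    tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL
    )
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all fitting starts failed")
  fits <- fits[ok]
  rn <- vapply(fits, function(f) sqrt(sum(f$fvec^2)), numeric(1))
  best <- fits[[which.min(rn)]]
  params <- hgo_fit_decode(best$par, template)
  converged <- best$info %in% 1:4
  if (!converged) {
    warning("HGO fit did not formally converge; best candidate returned ",
            "(info = ", best$info, ")")
  }
  start_tbl <- tibble::tibble(
    start = seq_along(fits),
    k1_start_kPa = vapply(starts[ok], function(s) exp(s[3]), numeric(1)),
    k2_start = vapply(starts[ok], function(s) exp(s[4]), numeric(1)),
    residual_norm = rn,
    info = vapply(fits, function(f) f$info, numeric(1))
  )
  structure(
    list(params = params, residual_norm = min(rn), converged = converged,
         n_obs = n, starts = start_tbl, data = data),
    class = "hgo_fit"
  )
}

#' @export
print.hgo_fit <- function(x, ...) {
  cat(sprintf("<hgo_fit>  %d observations, residual norm %.4g kPa%s\n",
              x$n_obs, x$residual_norm,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$params)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an HGO fit
#'
#' @param x An `hgo_fit` object.
#' @param ... Unused.
#' @return One row per fitted or fixed parameter with its estimate and unit.
#' @method tidy hgo_fit
#' @export
tidy.hgo_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("C10", "C01", "k1", "k2", "theta", "beta", "mean_fiber"),
    estimate = c(p$C10, p$C01, p$k1, p$k2, p$theta_deg, p$beta,
                 p$mean_fiber_deg),
    unit = c("kPa", "", "kPa", "", "deg", "kPa", "deg"),
    fitted = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

#' @rdname tidy.hgo_fit
#' @method glance hgo_fit
#' @export
glance.hgo_fit <- function(x, ...) {
  tibble::tibble(
    residual_norm = x$residual_norm,
    rmse = x$residual_norm / sqrt(2 * x$n_obs),
    n_obs = x$n_obs,
    converged = x$converged,
    n_starts = nrow(x$starts)
  )
}
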