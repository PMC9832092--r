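# Self-expanding stent frame: idealized diamond-cell beam/spring lattice,
# radial crimping by a moving penalty crimper, and overdamped self-expansion.
# CGS units (cm, dyne, erg, s); diameters reported in mm and French
# (1 Fr = 1/3 mm).

#' Synthesize an idealized diamond-cell stent frame
#'
#' Builds a cylindrical diamond-cell lattice standing in for a
#' self-expanding TAV stent frame: `n_rows + 1` rings of
#' `n_circumferential` Lagrangian nodes with alternating angular offsets,
#' diagonal springs forming the diamond cells, hoop springs along each
#' ring, and discrete-curvature beams along the axial zigzag chains and
#' around each ring. Rest lengths and rest curvatures are taken from the
#' generated geometry, so the nominal configuration is exactly force-free.
#'
#' The default spring/beam constants are not device measurements; they are
#' chosen so that the crimped frame's stored energy drives re-expansion on
#' a ~0.1 s timescale under the default damping (see the package vignette).
#'
#' @param n_circumferential Nodes per ring (>= 3).
#' @param n_rows Number of cell rows (>= 1); the lattice has `n_rows + 1`
#'   rings, hence `n_circumferential * (n_rows + 1)` nodes.
#' @param diameter_mm Nominal outer diameter (mm); default the 26 mm
#'   device size.
#' @param height_mm Frame height (mm).
#' @param k_spring Spring stiffness (dyne/cm).
#' @param k_beam Beam (curvature penalty) stiffness (dyne/cm).
#' @param damping Overdamped drag coefficient (dyne.s/cm).
#' @return An object of class `stent_frame` (also `elastic_network`) with
#'   reference positions in `ref_nodes`.
#' @export
synthesize_frame <- function(n_circumferential = 12, n_rows = 4,
                             diameter_mm = 26, height_mm = 40,
                             k_spring = 2e5, k_beam = 1e6,
                             damping = 2e4) {
  stopifnot(n_circumferential >= 3, n_rows >= 1, diameter_mm > 0,
            height_mm > 0, k_spring > 0, k_beam >= 0, damping > 0)
  nc <- as.integer(n_circumferential)
  nl <- as.integer(n_rows) + 1L # rings
  R <- diameter_mm / 20 # cm
  H <- height_mm / 10   # cm
  dz <- H / n_rows

  id <- function(j, i) j * nc + ((i - 1L) %% nc) + 1L # j in 0..nl-1, i 1-based
  nodes <- matrix(0, nc * nl, 3)
  for (j in 0:(nl - 1L)) {
    ang <- 2 * pi * ((seq_len(nc) - 1) + 0.5 * (j %% 2)) / nc
    nodes[id(j, seq_len(nc)), ] <- cbind(R * cos(ang), R * sin(ang), j * dz)
  }

  si <- sj <- integer(0)
  for (j in 0:(nl - 2L)) {
    i <- seq_len(nc)
    si <- c(si, id(j, i), id(j, i))
    if (j %% 2 == 0) {
      sj <- c(sj, id(j + 1L, i), id(j + 1L, i - 1L))
    } else {
      sj <- c(sj, id(j + 1L, i), id(j + 1L, i + 1L))
    }
  }
  for (j in 0:(nl - 1L)) { # circumferential (hoop) springs
    i <- seq_len(nc)
    si <- c(si, id(j, i))
    sj <- c(sj, id(j, i + 1L))
  }
  L0 <- sqrt(rowSums((nodes[sj, , drop = FALSE] -
                        nodes[si, , drop = FALSE])^2))
  springs <- data.frame(i = si, j = sj, k = k_spring, L0 = L0)

  ba <- bb <- bc <- integer(0)
  if (nl >= 3L) { # axial zigzag chains
    for (j in 1:(nl - 2L)) {
      i <- seq_len(nc)
      ba <- c(ba, id(j - 1L, i)); bb <- c(bb, id(j, i))
      bc <- c(bc, id(j + 1L, i))
    }
  }
  for (j in 0:(nl - 1L)) { # circumferential rings
    i <- seq_len(nc)
    ba <- c(ba, id(j, i - 1L)); bb <- c(bb, id(j, i)); bc <- c(bc, id(j, i + 1L))
  }
  beams <- data.frame(a = ba, b = bb, c = bc, kb = k_beam)

  net <- elastic_network(nodes, springs, beams)
  net$ref_nodes <- nodes
  net$damping <- damping
  net$n_circumferential <- nc
  net$n_rows <- as.integer(n_rows)
  class(net) <- c("stent_frame", class(net))
  net
}

#' @export
print.stent_frame <- function(x, ...) {
  dm <- diameter_metrics(x)
  cat(sprintf(paste0("<stent_frame>  %d nodes (%d x %d rings), ",
                     "%d springs, %d beams\n"),
              nrow(x$nodes), x$n_circumferential, x$n_rows + 1L,
              nrow(x$springs), nrow(x$beams)))
  cat(sprintf("  diameter %.2f mm (%.2f Fr), elastic energy %.3g erg\n",
              dm$diameter_mm, dm$diameter_Fr, elastic_energy(x)))
  invisible(x)
}

#' Elastic forces and energy of a stent frame
#'
#' Thin wrappers over the shared network library: total elastic energy
#' (erg) and per-node force vectors (dyne, the negative energy gradient).
#'
#' @param frame A `stent_frame`.
#' @param x Optional node position matrix (defaults to the frame's current
#'   nodes).
#' @return `elastic_forces`: an n x 3 matrix of forces; `elastic_energy`:
#'   a scalar.
#' @export
elastic_forces <- function(frame, x = frame$nodes) network_forces(frame, x)

#' @rdname elastic_forces
#' @export
elastic_energy <- function(frame, x = frame$nodes) network_energy(frame, x)

#' Radial crimping device
#'
#' A cylindrical crimper contracting at constant radial speed; nodes caught
#' outside its current radius are tethered back to it with a stiff radial
#' penalty (the kinematic equivalent of the tethered-point crimping device
#' used with fluid-mediated contact).
#'
#' @param stop_radius_cm Final crimper radius (cm, > 0).
#' @param radial_speed_cms Inward radial speed (cm/s); default 50.
#' @param tether_stiffness Penalty stiffness (dyne/cm); default 3.0e8.
#' @return An object of class `crimper`.
#' @export
crimper <- function(stop_radius_cm, radial_speed_cms = 50,
                    tether_stiffness = 3e8) {
  stopifnot(stop_radius_cm > 0, radial_speed_cms > 0, tether_stiffness > 0)
  structure(list(stop_radius = stop_radius_cm, speed = radial_speed_cms,
                 k_tether = tether_stiffness),
            class = "crimper")
}

# stability-bounded explicit-Euler step for the overdamped dynamics:
# dt = damping / (4 * k_max) with k_max a bound on the local stiffness
stent_dt <- function(frame, extra_k = 0) {
  k_max <- extra_k
  if (nrow(frame$springs)) k_max <- k_max + 2 * max(frame$springs$k)
  if (nrow(frame$beams)) k_max <- k_max + 6 * max(frame$beams$kb)
  frame$damping / (4 * k_max)
}

# radial penalty force of the crimper at radius rc on positions x
crimper_force <- function(x, rc, kt) {
  r <- sqrt(x[, 1]^2 + x[, 2]^2)
  out <- pmax(r - rc, 0)
  F <- matrix(0, nrow(x), 3)
  hit <- out > 0
  if (any(hit)) {
    fmag <- -kt * out[hit] / r[hit]
    F[hit, 1] <- fmag * x[hit, 1]
    F[hit, 2] <- fmag * x[hit, 2]
  }
  F
}

#' Crimp a stent frame
#'
#' Overdamped (first-order) dynamics while the crimper radius contracts at
#' constant speed from the frame's current maximum radius down to its stop
#' radius, followed by a settling phase with the crimper static. The
#' achievable penetration past the crimper is bounded by the tether
#' compliance (elastic force / tether stiffness).
#'
#' @param frame A `stent_frame`.
#' @param crimp A `crimper`; its stop radius must be smaller than the
#'   frame's current radius.
#' @param dt Time step (s); defaults to the stability bound
#'   `damping / (4 k_max)` including the tether stiffness.
#' @param settle_time Extra integration time (s) after the crimper stops.
#' @param save_every Save a trajectory row every this many steps.
#' @return An object of class `crimp_result`: list with `frame` (crimped),
#'   `trajectory` (tibble `t_s, crimper_radius_cm, diameter_mm,
#'   diameter_Fr, energy_erg`), `penetration_cm`, `dt`.
#' @export
crimp <- function(frame, crimp, dt = NULL, settle_time = 0.01,
                  save_every = 25L) {
  stopifnot(inherits(frame, "stent_frame"), inherits(crimp, "crimper"))
  x <- frame$nodes
  r0 <- max(sqrt(x[, 1]^2 + x[, 2]^2))
  if (crimp$stop_radius >= r0) {
    # crimper never engages the frame
    traj <- tibble::tibble(t_s = 0, crimper_radius_cm = crimp$stop_radius,
                           diameter_mm = diameter_metrics(frame)$diameter_mm,
                           diameter_Fr = diameter_metrics(frame)$diameter_Fr,
                           energy_erg = elastic_energy(frame))
    return(structure(list(frame = frame, trajectory = traj,
                          penetration_cm = 0, dt = NA_real_),
                     class = "crimp_result"))
  }
  if (is.null(dt)) dt <- stent_dt(frame, extra_k = crimp$k_tether)
  gam <- frame$damping
  t_travel <- (r0 - crimp$stop_radius) / crimp$speed
  n_steps <- ceiling((t_travel + settle_time) / dt)
  traj <- vector("list", n_steps %/% save_every + 2L)
  ti <- 1L
  E0 <- NULL
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    rc <- max(r0 - crimp$speed * t, crimp$stop_radius)
    F <- network_forces(frame, x) + crimper_force(x, rc, crimp$k_tether)
    x <- x + (dt / gam) * F
    if (s %% save_every == 0L || s == n_steps) {
      E <- network_energy(frame, x)
      if (!is.finite(E)) {
        stop("crimping dynamics unstable (non-finite energy); retry with dt <= ",
             format(dt / 4))
      }
      if (is.null(E0)) E0 <- max(E, 1)
      if (E > 1e6 * E0) {
        stop("crimping dynamics unstable (energy blow-up); retry with dt <= ",
             format(dt / 4))
      }
      dm <- diameter_metrics(x)
      traj[[ti]] <- tibble::tibble(t_s = t, crimper_radius_cm = rc,
                                   diameter_mm = dm$diameter_mm,
                                   diameter_Fr = dm$diameter_Fr,
                                   energy_erg = E)
      ti <- ti + 1L
    }
  }
  frame$nodes <- x
  r_end <- max(sqrt(x[, 1]^2 + x[, 2]^2))
  structure(
    list(frame = frame, trajectory = dplyr::bind_rows(traj),
         penetration_cm = max(r_end - crimp$stop_radius, 0), dt = dt),
    class = "crimp_result"
  )
}

#' Release a frame and let it self-expand
#'
#' Overdamped relaxation with no crimper: the stored elastic energy drives
#' the frame back toward its force-free reference configuration (the
#' self-expansion of a shape-set frame, without temperature dependence).
#' Integration stops when the maximum per-node force drops below `tol_force`
#' or after `t_max` seconds.
#'
#' @param frame A `stent_frame` in any deformed state.
#' @param dt Time step (s); defaults to the stability bound.
#' @param t_max Maximum simulated time (s).
#' @param tol_force Convergence threshold on the max node force (dyne).
#' @param save_every Save a trajectory row every this many steps.
#' @return An object of class `expand_result`: list with `frame`
#'   (equilibrated), `trajectory`, `converged`, `max_force_dyne`, `dt`.
#' @export
release_and_expand <- function(frame, dt = NULL, t_max = 10,
                               tol_force = NULL, save_every = 10L) {
  stopifnot(inherits(frame, "stent_frame"))
  if (is.null(dt)) dt <- stent_dt(frame)
  if (is.null(tol_force)) {
    # a millionth of the network's force scale k * L
    tol_force <- 1e-6 * max(frame$springs$k) * mean(frame$springs$L0)
  }
  gam <- frame$damping
  x <- frame$nodes
  n_steps <- ceiling(t_max / dt)
  traj <- list()
  ti <- 1L
  converged <- FALSE
  fmax <- Inf
  for (s in seq_len(n_steps)) {
    F <- network_forces(frame, x)
    fmax <- max(abs(F))
    if (s %% save_every == 1L || fmax < tol_force) {
      dm <- diameter_metrics(x)
      traj[[ti]] <- tibble::tibble(t_s = (s - 1) * dt,
                                   diameter_mm = dm$diameter_mm,
                                   diameter_Fr = dm$diameter_Fr,
                                   energy_erg = network_energy(frame, x),
                                   max_force_dyne = fmax)
      ti <- ti + 1L
    }
    if (fmax < tol_force) {
      converged <- TRUE
      break
    }
    x <- x + (dt / gam) * F
    if (!all(is.finite(x))) {
      stop("expansion dynamics unstable; retry with dt <= ", format(dt / 4))
    }
  }
  frame$nodes <- x
  structure(
    list(frame = frame, trajectory = dplyr::bind_rows(traj),
         converged = converged, max_force_dyne = fmax, dt = dt),
    class = "expand_result"
  )
}

#' Diameter of a stent frame
#'
#' Diameter measured about the fixed z-axis of the generated lattice (no
#' axis refitting): twice the maximum radial node distance. French size
#' uses 1 Fr = 1/3 mm.
#'
#' @param frame A `stent_frame`, or an n x 3 node matrix.
#' @return A one-row tibble `diameter_mm, diameter_Fr`.
#' @export
diameter_metrics <- function(frame) {
  x <- if (inherits(frame, "elastic_network")) frame$nodes else as.matrix(frame)
  d_cm <- 2 * max(sqrt(x[, 1]^2 + x[, 2]^2))
  tibble::tibble(diameter_mm = 10 * d_cm, diameter_Fr = 30 * d_cm)
}
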