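# Shared Lagrangian spring/beam/tether network: energies and forces.
# Dimension-agnostic (2D for the immersed-boundary demos, 3D for the stent
# frame). All quantities CGS: positions cm, stiffnesses dyne/cm, energies erg.
#
# Energy terms:
#   springs : k/2 (|x_j - x_i| - L0)^2
#   beams   : kb/2 (|x_a - 2 x_b + x_c| - |d0|)^2  (discrete curvature
#             penalty against the rest second-difference magnitude |d0|;
#             magnitude-based so the energy is rigid-motion invariant)
#   tethers : kt/2 |x_i - target_i|^2

#' Construct an elastic point network
#'
#' A Lagrangian structure made of point masses connected by linear springs,
#' discrete-curvature beams (a penalty on the magnitude of the second
#' difference relative to its rest magnitude, which keeps the energy
#' invariant under rigid motions), and optional tethers to fixed target
#' points. Used both for the stent frame and for immersed-boundary
#' structures.
#'
#' @param nodes n x d matrix of positions (cm), d = 2 or 3.
#' @param springs Data frame with integer columns `i`, `j`, stiffness `k`
#'   (dyne/cm) and rest length `L0` (cm); may have zero rows.
#' @param beams Data frame with integer columns `a`, `b`, `c` and stiffness
#'   `kb` (dyne/cm); rest second differences are stored as a matrix
#'   attribute and default to the construction geometry.
#' @param beam_rest Optional nrow(beams) x d matrix of rest second
#'   differences `d0`; defaults to the values at `nodes` (so the given
#'   configuration is curvature-neutral).
#' @param tethers Data frame with integer column `node`, stiffness `kt`,
#'   plus a target matrix given via `tether_targets`.
#' @param tether_targets Optional nrow(tethers) x d matrix of anchor points.
#' @return An object of class `elastic_network`.
#' @export
elastic_network <- function(nodes, springs = NULL, beams = NULL,
                            beam_rest = NULL, tethers = NULL,
                            tether_targets = NULL) {
  nodes <- as.matrix(nodes)
  n <- nrow(nodes)
  d <- ncol(nodes)
  stopifnot(d %in% c(2L, 3L), n >= 1)
  if (is.null(springs)) {
    springs <- data.frame(i = integer(), j = integer(), k = numeric(),
                          L0 = numeric())
  }
  if (is.null(beams)) {
    beams <- data.frame(a = integer(), b = integer(), c = integer(),
                        kb = numeric())
  }
  if (is.null(tethers)) {
    tethers <- data.frame(node = integer(), kt = numeric())
    tether_targets <- matrix(0, 0, d)
  }
  idx <- c(springs$i, springs$j, beams$a, beams$b, beams$c, tethers$node)
  if (length(idx) && (min(idx) < 1 || max(idx) > n)) {
    stop("connectivity references node indices outside 1..", n)
  }
  if (nrow(beams) && is.null(beam_rest)) {
    beam_rest <- nodes[beams$a, , drop = FALSE] -
      2 * nodes[beams$b, , drop = FALSE] + nodes[beams$c, , drop = FALSE]
  }
  if (nrow(beams) == 0L) beam_rest <- matrix(0, 0, d)
  structure(
    list(nodes = nodes, dim = d, springs = springs, beams = beams,
         beam_rest = as.matrix(beam_rest), tethers = tethers,
         tether_targets = as.matrix(tether_targets)),
    class = "elastic_network"
  )
}

# accumulate per-row contributions `val` (m x d) onto rows `idx` of an n x d
# zero matrix
accum_rows <- function(n, d, idx, val) {
  out <- matrix(0, n, d)
  if (length(idx) == 0L) return(out)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Elastic energy of a network configuration
#'
#' @param net An `elastic_network`.
#' @param x Optional n x d position matrix (defaults to `net$nodes`).
#' @return Total elastic energy (erg).
#' @export
network_energy <- function(net, x = net$nodes) {
  stopifnot(inherits(net, "elastic_network"))
  x <- as.matrix(x)
  E <- 0
  if (nrow(net$springs)) {
    dvec <- x[net$springs$j, , drop = FALSE] - x[net$springs$i, , drop = FALSE]
    L <- sqrt(rowSums(dvec^2))
    E <- E + sum(net$springs$k / 2 * (L - net$springs$L0)^2)
  }
  if (nrow(net$beams)) {
    dd <- x[net$beams$a, , drop = FALSE] - 2 * x[net$beams$b, , drop = FALSE] +
      x[net$beams$c, , drop = FALSE]
    r0 <- sqrt(rowSums(net$beam_rest^2))
    E <- E + sum(net$beams$kb / 2 * (sqrt(rowSums(dd^2)) - r0)^2)
  }
  if (nrow(net$tethers)) {
    dd <- x[net$tethers$node, , drop = FALSE] - net$tether_targets
    E <- E + sum(net$tethers$kt / 2 * rowSums(dd^2))
  }
  E
}

#' Elastic forces of a network configuration
#'
#' The negative gradient of [network_energy()] with respect to the node
#' positions.
#'
#' @inheritParams network_energy
#' @return n x d matrix of forces (dyne).
#' @export
network_forces <- function(net, x = net$nodes) {
  stopifnot(inherits(net, "elastic_network"))
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  F <- matrix(0, n, d)
  if (nrow(net$springs)) {
    dvec <- x[net$springs$j, , drop = FALSE] - x[net$springs$i, , drop = FALSE]
    L <- sqrt(rowSums(dvec^2))
    if (any(L < 1e-12)) stop("coincident nodes in a spring segment")
    fmag <- net$springs$k * (L - net$springs$L0) / L # tension > 0 pulls ends
    fv <- dvec * fmag
    F <- F + accum_rows(n, d, net$springs$i, fv)
    F <- F - accum_rows(n, d, net$springs$j, fv)
  }
  if (nrow(net$beams)) {
    dd <- x[net$beams$a, , drop = FALSE] - 2 * x[net$beams$b, , drop = FALSE] +
      x[net$beams$c, , drop = FALSE]
    r <- sqrt(rowSums(dd^2))
    r0 <- sqrt(rowSums(net$beam_rest^2))
    # dE/dd = kb (r - r0) d / r; the direction is undefined only in the
    # measure-zero case r = 0 with r0 > 0, where the force is dropped
    fac <- ifelse(r > 1e-14, net$beams$kb * (r - r0) / r, 0)
    dd <- dd * fac
    F <- F - accum_rows(n, d, net$beams$a, dd)
    F <- F + accum_rows(n, d, net$beams$b, 2 * dd)
    F <- F - accum_rows(n, d, net$beams$c, dd)
  }
  if (nrow(net$tethers)) {
    dd <- (x[net$tethers$node, , drop = FALSE] - net$tether_targets) *
      net$tethers$kt
    F <- F - accum_rows(n, d, net$tethers$node, dd)
  }
  F
}
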