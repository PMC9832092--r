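# Configuration, file formats, and unit conversions.
#
# Unit systems by module: mmHg-mL-s for the circulation, CGS (cm, dyne) for
# the stent frame and fluid solver, kPa for tissue stresses. JSON keys are
# unit-suffixed; conversions use 1 mmHg = 1333.22 dyn/cm^2 and 1 Fr = 1/3 mm.

#' Unit conversions
#'
#' Pressure between mmHg and dyn/cm^2 (1 mmHg = 1333.22 dyn/cm^2) and
#' catheter diameter between millimetres and French (1 Fr = 1/3 mm).
#'
#' @param x Numeric values.
#' @return Converted values.
#' @export
mmHg_to_dyn_cm2 <- function(x) x * 1333.22

#' @rdname mmHg_to_dyn_cm2
#' @export
dyn_cm2_to_mmHg <- function(x) x / 1333.22

#' @rdname mmHg_to_dyn_cm2
#' @export
mm_to_Fr <- function(x) 3 * x

#' @rdname mmHg_to_dyn_cm2
#' @export
Fr_to_mm <- function(x) x / 3

# strict JSON object reader: exactly the expected keys, no more, no less
read_json_strict <- function(path, required, optional = character(0)) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    stop("config ", path, " is missing required key(s): ",
         paste(missing, collapse = ", "),
         " (keys must carry their unit suffix)")
  }
  unknown <- setdiff(names(obj), c(required, optional))
  if (length(unknown)) {
    stop("config ", path, " has unknown key(s): ",
         paste(unknown, collapse = ", "))
  }
  obj
}

#' Read and write HGO parameter files
#'
#' JSON with explicit unit-suffixed keys: `C10_kPa`, `C01`, `k1_MPa`, `k2`,
#' `theta_deg`, `beta_MPa`, `mean_fiber_deg`. Unknown keys and missing
#' (unit-suffixed) keys are hard errors.
#'
#' @param path File path.
#' @return `read_hgo_params`: an `hgo_params` object.
#' @export
read_hgo_params <- function(path) {
  keys <- c("C10_kPa", "C01", "k1_MPa", "k2", "theta_deg", "beta_MPa")
  obj <- read_json_strict(path, keys, optional = "mean_fiber_deg")
  hgo_params(obj$C10_kPa, obj$C01, obj$k1_MPa, obj$k2, obj$theta_deg,
             obj$beta_MPa,
             mean_fiber_deg = if (is.null(obj$mean_fiber_deg)) 0 else
               obj$mean_fiber_deg)
}

#' @rdname read_hgo_params
#' @param p An `hgo_params` object.
#' @export
write_hgo_params <- function(p, path) {
  stopifnot(inherits(p, "hgo_params"))
  jsonlite::write_json(
    list(C10_kPa = p$C10, C01 = p$C01, k1_MPa = p$k1 / 1000, k2 = p$k2,
         theta_deg = p$theta_deg, beta_MPa = p$beta / 1000,
         mean_fiber_deg = p$mean_fiber_deg),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write circulation parameter files
#'
#' JSON with unit-suffixed scalar keys (`Qvein_Lmin`, `Rmv_mmHg_s_per_mL`,
#' `Rlvot_mmHg_s_per_mL`, `Rc_mmHg_s_per_mL`, `Rp_mmHg_s_per_mL`,
#' `Cwk_mL_per_mmHg`, `T_s`, `la_shift_frac`, `la_shift_mode`) and two
#' elastance objects `lv`, `la` with keys `Emin_mmHg_per_mL`,
#' `Emax_mmHg_per_mL`, `tau1_frac`, `tau2_frac`, `m1`, `m2`.
#'
#' @param path File path.
#' @return `read_circulation_params`: a `circulation_params` object.
#' @export
read_circulation_params <- function(path) {
  keys <- c("Qvein_Lmin", "Rmv_mmHg_s_per_mL", "Rlvot_mmHg_s_per_mL",
            "Rc_mmHg_s_per_mL", "Rp_mmHg_s_per_mL", "Cwk_mL_per_mmHg",
            "T_s", "lv", "la")
  obj <- read_json_strict(path, keys,
                          optional = c("la_shift_frac", "la_shift_mode"))
  ekeys <- c("Emin_mmHg_per_mL", "Emax_mmHg_per_mL", "tau1_frac",
             "tau2_frac", "m1", "m2")
  for (side in c("lv", "la")) {
    miss <- setdiff(ekeys, names(obj[[side]]))
    if (length(miss)) {
      stop("config ", path, ": elastance '", side,
           "' is missing key(s): ", paste(miss, collapse = ", "))
    }
  }
  eh <- function(e) list(Emin = e$Emin_mmHg_per_mL, Emax = e$Emax_mmHg_per_mL,
                         tau1_frac = e$tau1_frac, tau2_frac = e$tau2_frac,
                         m1 = e$m1, m2 = e$m2)
  circulation_params(
    Qvein_Lmin = obj$Qvein_Lmin, Rmv = obj$Rmv_mmHg_s_per_mL,
    Rlvot = obj$Rlvot_mmHg_s_per_mL, Rc = obj$Rc_mmHg_s_per_mL,
    Rp = obj$Rp_mmHg_s_per_mL, Cwk = obj$Cwk_mL_per_mmHg, T = obj$T_s,
    lv = eh(obj$lv), la = eh(obj$la),
    la_shift_frac = if (is.null(obj$la_shift_frac)) 0.85 else
      obj$la_shift_frac,
    la_shift_mode = if (is.null(obj$la_shift_mode)) "delay" else
      obj$la_shift_mode
  )
}

#' @rdname read_circulation_params
#' @param params A `circulation_params` object.
#' @export
write_circulation_params <- function(params, path) {
  stopifnot(inherits(params, "circulation_params"))
  eh <- function(e) list(Emin_mmHg_per_mL = e$Emin,
                         Emax_mmHg_per_mL = e$Emax,
                         tau1_frac = e$tau1_frac, tau2_frac = e$tau2_frac,
                         m1 = e$m1, m2 = e$m2)
  jsonlite::write_json(
    list(Qvein_Lmin = params$Qvein * 60 / 1000,
         Rmv_mmHg_s_per_mL = params$Rmv,
         Rlvot_mmHg_s_per_mL = params$Rlvot,
         Rc_mmHg_s_per_mL = params$Rc, Rp_mmHg_s_per_mL = params$Rp,
         Cwk_mL_per_mmHg = params$Cwk, T_s = params$T,
         la_shift_frac = params$la_shift_frac,
         la_shift_mode = params$la_shift_mode,
         lv = eh(params$lv), la = eh(params$la)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write valve surrogate files
#'
#' JSON: a single object, or a named collection of objects, with keys
#' `kind`, `EOA_cm2` (orifice kind), `R_mmHg_s_per_mL`.
#'
#' @param path File path.
#' @return A `valve_surrogate`, or a named list of them.
#' @export
read_valve_surrogates <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(o) {
    valve_surrogate(kind = o$kind,
                    EOA_cm2 = o$EOA_cm2,
                    R = if (is.null(o$R_mmHg_s_per_mL)) 0 else
                      o$R_mmHg_s_per_mL)
  }
  if (!is.null(obj$kind)) mk(obj) else lapply(obj, mk)
}

#' @rdname read_valve_surrogates
#' @param valves A `valve_surrogate` or named list of them.
#' @export
write_valve_surrogates <- function(valves, path) {
  dump1 <- function(v) list(kind = v$kind, EOA_cm2 = v$EOA_cm2,
                            R_mmHg_s_per_mL = v$R)
  out <- if (inherits(valves, "valve_surrogate")) dump1(valves) else
    lapply(valves, dump1)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write waveform and biaxial CSV tables
#'
#' Waveforms use the header `t_s,P_LA_mmHg,P_LV_mmHg,P_LVOT_mmHg,
#' P_Ao_mmHg,P_Wk_mmHg,Q_MV_mLs,Q_LVOT_mLs`; biaxial tables use
#' `lambda1,lambda2,sigma11_kPa,sigma22_kPa`; flow waveforms use
#' `t_s,Q_mLs`. Values are written at full double precision.
#'
#' @param x A tibble (or `rom_sim` for `write_waveforms`).
#' @param path File path.
#' @return The tibble read, or (writers) the path, invisibly.
#' @export
write_waveforms <- function(x, path) {
  wf <- if (inherits(x, "rom_sim")) x$waveforms else x
  cols <- c("t_s", "P_LA_mmHg", "P_LV_mmHg", "P_LVOT_mmHg", "P_Ao_mmHg",
            "P_Wk_mmHg", "Q_MV_mLs", "Q_LVOT_mLs")
  write_csv_full_precision(wf[, cols], path)
  invisible(path)
}

# write a numeric table at 17 significant digits (round-trip exact)
write_csv_full_precision <- function(x, path) {
  df <- as.data.frame(lapply(as.data.frame(x), function(col) {
    if (is.numeric(col)) format(col, digits = 17, trim = TRUE) else col
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname write_waveforms
#' @export
write_biaxial_csv <- function(x, path) {
  write_csv_full_precision(
    x[, c("lambda1", "lambda2", "sigma11_kPa", "sigma22_kPa")], path)
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_biaxial_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname write_waveforms
#' @export
read_flow_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write a metrics JSON with provenance
#'
#' Serializes a one-row metrics tibble (or named list) together with
#' convergence flags and a hash of the resolved configuration, so repeated
#' identical runs are byte-identical and traceable.
#'
#' @param metrics Named list or one-row data frame.
#' @param path Output path.
#' @param config Optional configuration object to hash into the manifest.
#' @return The path, invisibly.
#' @export
write_metrics_json <- function(metrics, path, config = NULL) {
  m <- as.list(metrics)
  if (!is.null(config)) m$config_hash <- rlang::hash(config)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write VTK legacy geometry files
#'
#' `write_vtk_polydata` writes points plus polyline connectivity (ASCII VTK
#' legacy "POLYDATA"), suitable for stent frames and immersed structures;
#' `write_vtk_structured_points` writes one or more cell-centered scalar
#' fields on a uniform grid (ASCII "STRUCTURED_POINTS").
#'
#' @param points n x 2 or n x 3 coordinate matrix (cm); 2D points get z = 0.
#' @param lines List of integer vectors (1-based point indices per
#'   polyline).
#' @param path Output path.
#' @param title Dataset title line.
#' @return The path, invisibly.
#' @export
write_vtk_polydata <- function(points, lines = list(), path,
                               title = "tavsim geometry") {
  points <- as.matrix(points)
  if (ncol(points) == 2) points <- cbind(points, 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(points))), con)
  writeLines(apply(points, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")), con)
  if (length(lines)) {
    sz <- sum(vapply(lines, length, integer(1)) + 1L)
    writeLines(sprintf("LINES %d %d", length(lines), sz), con)
    writeLines(vapply(lines, function(l)
      paste(c(length(l), l - 1L), collapse = " "), character(1)), con)
  }
  invisible(path)
}

#' @rdname write_vtk_polydata
#' @param fields Named list of n x m matrices (cell-centered scalars).
#' @param h Grid spacing (cm).
#' @param origin Length-2 origin (cm).
#' @export
write_vtk_structured_points <- function(fields, h, path, origin = c(0, 0),
                                        title = "tavsim field") {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  dims <- dim(fields[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", dims[1], dims[2]),
               sprintf("ORIGIN %g %g 0", origin[1], origin[2]),
               sprintf("SPACING %g %g 1", h, h),
               sprintf("POINT_DATA %d", prod(dims))), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(fields[[nm]]), digits = 17, trim = TRUE),
               con)
  }
  invisible(path)
}

#' Export a stent frame as VTK polylines
#'
#' Writes the frame's nodes with one polyline per spring segment.
#'
#' @param frame A `stent_frame`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_frame_vtk <- function(frame, path) {
  stopifnot(inherits(frame, "stent_frame"))
  lines <- lapply(seq_len(nrow(frame$springs)), function(r)
    c(frame$springs$i[r], frame$springs$j[r]))
  write_vtk_polydata(frame$nodes, lines, path, title = "stent frame")
}
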