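# Tensile rheology: stress-strain construction, incremental moduli,
# stress-relaxation strength and plastic deformation.
#
# Unit conventions: force is stored in newtons, stress in kPa, lengths in
# the units of the raw records (displacement mm, L0 cm). The classical
# gram-force formulation sigma[gf/cm^2] = rho * L0 * (1 + eps) * T[gf] / W
# collapses, with 1 gf = 9.80665 mN and 1 gf/cm^2 = 0.0980665 kPa, to
# sigma[kPa] = 10 * (1 + eps) * T[N] / A0[cm^2], A0 = W / (rho * L0).

GF_PER_N <- 1000 / 9.80665   # gram-force per newton
KPA_PER_GF_CM2 <- 0.0980665  # kPa per gf/cm^2

#' Engineering strain from crosshead displacement
#'
#' Strain is the fractional extension beyond the just-taut initial length,
#' eps = displacement / L0.
#'
#' @param displacement Displacement from the initial length, mm (vectorised).
#' @param L0 Initial strip length, cm.
#' @return Dimensionless strain, same length as `displacement`.
#' @examples
#' strain_from_displacement(5, 1)  # 0.5
#' @export
strain_from_displacement <- function(displacement, L0) {
  if (!is.numeric(L0) || length(L0) != 1L || !is.finite(L0) || L0 <= 0) {
    stop_invalid_geometry("initial length `L0` must be a positive number")
  }
  (displacement / 10) / L0
}

#' Lagrangian wall stress from tensile force
#'
#' Converts force to stress over the current (strained) cross-section,
#' assuming incompressibility: the unstressed cross-section A0 is recovered
#' gravimetrically as W / (rho * L0) and shrinks by 1/(1 + eps) under
#' stretch, so sigma = (1 + eps) * T / A0. Computed through the gram-force
#' route (T in gf, sigma in gf/cm^2) and converted to kPa with exact
#' constants.
#'
#' @param T_N Tensile force in newtons (vectorised).
#' @param strain Engineering strain (scalar or same length as `T_N`).
#' @param geometry A [strip_geometry()].
#' @return Stress in kPa.
#' @export
stress_from_tension <- function(T_N, strain, geometry) {
  stopifnot(inherits(geometry, "strip_geometry"))
  if (geometry$weight <= 0) stop_invalid_geometry("strip weight must be positive")
  if (any(strain < -1e-12)) {
    stop_aorta("aortamech_invalid_input", "strain must be non-negative")
  }
  T_gf <- T_N * GF_PER_N
  sigma_gf_cm2 <- geometry$rho * geometry$L0 * (1 + strain) * T_gf / geometry$weight
  sigma_gf_cm2 * KPA_PER_GF_CM2
}

# Inverse map used by the simulator: tension (N) carried at stress sigma (kPa).
tension_from_stress <- function(sigma_kPa, strain, geometry) {
  sigma_kPa * cross_section_cm2(geometry) / (10 * (1 + strain))
}

#' Build a stress-strain curve from a loading ramp
#'
#' Detects the onset of loading (the point where the strip becomes taut) as
#' the first sample whose force exceeds `force_threshold`, re-zeroes the
#' displacement there, and applies [strain_from_displacement()] and
#' [stress_from_tension()] element-wise. This mirrors the bench convention
#' of taking the initial length as the maximum length at which tension just
#' exceeds 0 N.
#'
#' @param trace A [tensile_trace()] of phase `ramp_load`.
#' @param geometry A [strip_geometry()].
#' @param force_threshold Onset threshold in newtons.
#' @return An object of class `stress_strain_curve` with fields `strain`,
#'   `stress` (kPa), `tension` (N) and the onset index/displacement.
#' @export
build_stress_strain <- function(trace, geometry, force_threshold = 0.001) {
  stopifnot(inherits(trace, "tensile_trace"))
  if (trace$phase != "ramp_load") {
    stop_aorta("aortamech_wrong_phase",
               sprintf("expected a ramp_load trace, got %s", trace$phase))
  }
  onset <- which(trace$force > force_threshold)[1]
  if (is.na(onset) || (length(trace$time) - onset + 1L) < 2L) {
    stop_aorta("aortamech_insufficient_data",
               "fewer than 2 samples above the onset threshold")
  }
  idx <- onset:length(trace$time)
  disp <- trace$displacement[idx] - trace$displacement[onset]
  strain <- strain_from_displacement(pmax(disp, 0), geometry$L0)
  tension <- trace$force[idx]
  stress <- stress_from_tension(tension, strain, geometry)
  structure(
    list(strain = strain, stress = stress, tension = tension,
         onset_index = onset, onset_displacement = trace$displacement[onset]),
    class = "stress_strain_curve"
  )
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf(
    "Stress-strain curve: %d samples, strain 0..%.3f, peak stress %.1f kPa\n",
    length(x$strain), max(x$strain), max(x$stress)))
  invisible(x)
}

#' Incremental elastic modulus at a strain level
#'
#' The local wall stiffness, taken as the mean gradient of the stress-strain
#' curve over a symmetric strain window: E = (sigma(c + w) - sigma(c - w)) /
#' (2w) with the endpoint stresses linearly interpolated between samples.
#' The conventional centres are 0.25, 0.50 and 0.75 (low, medium and high
#' physiological strain) with a half-window of 0.05.
#'
#' @param curve A [build_stress_strain()] result.
#' @param center_strain Centre of the strain window.
#' @param half_window Half-width of the window (default 0.05).
#' @return Modulus in kPa.
#' @export
incremental_modulus <- function(curve, center_strain, half_window = 0.05) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  lo <- center_strain - half_window
  hi <- center_strain + half_window
  smax <- max(curve$strain)
  smin <- min(curve$strain)
  if (hi > smax + 1e-12 || lo < smin - 1e-12) {
    stop_aorta("aortamech_out_of_range",
               sprintf("window [%.3f, %.3f] outside curve range [%.3f, %.3f]",
                       lo, hi, smin, smax),
               max_strain = smax)
  }
  s_lo <- interp_last(curve$strain, curve$stress, lo)
  s_hi <- interp_last(curve$strain, curve$stress, hi)
  (s_hi - s_lo) / (2 * half_window)
}

#' Stress-relaxation strength over a hold
#'
#' After the rapid stretch to the hold strain, the stress decays from its
#' peak tau0 towards a plateau. Relaxation strength is the percentage drop
#' over the hold: (tau0 - tau_end) / tau0 * 100, with tau0 the maximum
#' stress in the trace and tau_end the stress at peak time + `hold_duration`
#' (linearly interpolated; if the trace ends within one sample interval of
#' the nominal end, the last sample is used with a warning).
#'
#' @param trace A [tensile_trace()] of phase `step_hold`.
#' @param geometry A [strip_geometry()].
#' @param hold_duration Hold length in seconds (default 300).
#' @return A list with `tau0` and `tau_end` (kPa) and `strength` (percent).
#' @export
relaxation_strength <- function(trace, geometry, hold_duration = 300) {
  stopifnot(inherits(trace, "tensile_trace"))
  if (trace$phase != "step_hold") {
    stop_aorta("aortamech_wrong_phase",
               sprintf("expected a step_hold trace, got %s", trace$phase))
  }
  strain <- strain_from_displacement(pmax(trace$displacement, 0), geometry$L0)
  stress <- stress_from_tension(pmax(trace$force, 0), strain, geometry)
  ipk <- which.max(stress)
  tau0 <- stress[ipk]
  if (tau0 <= 0) {
    stop_aorta("aortamech_degenerate_trace", "peak stress is not positive")
  }
  t_end <- trace$time[ipk] + hold_duration
  t_last <- trace$time[length(trace$time)]
  dt <- stats::median(diff(trace$time))
  if (t_end > t_last) {
    if (t_end - t_last <= dt + 1e-9) {
      warning("trace ends within one sample of the nominal hold end; ",
              "using the last sample")
      tau_end <- stress[length(stress)]
    } else {
      stop_aorta("aortamech_insufficient_data",
                 sprintf("trace covers %.1f s after the peak; %g s needed",
                         t_last - trace$time[ipk], hold_duration))
    }
  } else {
    tau_end <- stats::approx(trace$time, stress, xout = t_end)$y
  }
  list(tau0 = tau0, tau_end = tau_end,
       strength = (tau0 - tau_end) / tau0 * 100)
}

#' Plastic (residual) deformation from a recovery re-stretch
#'
#' Five minutes after unloading, the strip is slowly re-stretched; the
#' displacement at which force first exceeds `force_threshold` is the
#' residual elongation the strip failed to recover. Returns 0 when the
#' force already exceeds the threshold at zero displacement (full recoil)
#' and `NA` (not detected) when the force never reaches the threshold.
#'
#' @param recovery_probe A [tensile_trace()] of phase `recovery_probe`.
#' @param force_threshold Detection threshold in newtons; defaults to the
#'   onset threshold used for initial-length detection.
#' @return Plastic deformation in mm, 0, or `NA_real_` if not detected.
#' @export
plastic_deformation <- function(recovery_probe, force_threshold = 0.001) {
  stopifnot(inherits(recovery_probe, "tensile_trace"))
  if (recovery_probe$phase != "recovery_probe") {
    stop_aorta("aortamech_wrong_phase",
               sprintf("expected a recovery_probe trace, got %s",
                       recovery_probe$phase))
  }
  f <- recovery_probe$force
  d <- recovery_probe$displacement
  above <- which(f > force_threshold)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1L || d[i] <= 0) return(0)
  # linear interpolation between the straddling samples
  f0 <- f[i - 1L]; f1 <- f[i]
  d0 <- d[i - 1L]; d1 <- d[i]
  if (f1 == f0) return(d1)
  d0 + (force_threshold - f0) / (f1 - f0) * (d1 - d0)
}

#' Per-specimen rheology summary
#'
#' Runs the full trace-level analysis for one specimen: stress-strain curve
#' and incremental moduli from the loading ramp, relaxation strength from
#' the step-and-hold, plastic deformation from the recovery probe, plus the
#' gravimetric wall geometry.
#'
#' @param traces Named list with elements `ramp_load`, `step_hold` and
#'   optionally `recovery_probe` (each a [tensile_trace()]).
#' @param geometry A [strip_geometry()].
#' @param moduli_at Strain centres for the incremental moduli.
#' @param force_threshold Onset / plastic detection threshold, N.
#' @return A one-row data.frame with columns `E_025`, `E_050`, `E_075`
#'   (kPa), `relaxation_strength` (percent), `plastic_deformation` (mm),
#'   `thickness_um`, `internal_radius_mm`, `internal_diameter_mm`,
#'   `cross_section_mm2`, `weight_per_area_mg_cm2`.
#' @export
rheology_summary <- function(traces, geometry,
                             moduli_at = c(0.25, 0.50, 0.75),
                             force_threshold = 0.001) {
  curve <- build_stress_strain(traces$ramp_load, geometry,
                               force_threshold = force_threshold)
  E <- vapply(moduli_at, function(c0) {
    tryCatch(incremental_modulus(curve, c0),
             aortamech_out_of_range = function(e) NA_real_)
  }, numeric(1))
  relax <- if (!is.null(traces$step_hold)) {
    relaxation_strength(traces$step_hold, geometry)$strength
  } else NA_real_
  plast <- if (!is.null(traces$recovery_probe)) {
    plastic_deformation(traces$recovery_probe, force_threshold)
  } else NA_real_
  wg <- wall_geometry_summary(geometry)
  out <- data.frame(
    E_025 = E[1], E_050 = E[2], E_075 = E[3],
    relaxation_strength = relax,
    plastic_deformation = plast,
    thickness_um = wall_thickness(geometry),
    internal_radius_mm = wg$internal_radius,
    internal_diameter_mm = wg$internal_diameter,
    cross_section_mm2 = wg$cross_section_area,
    weight_per_area_mg_cm2 = wg$weight_per_area
  )
  rownames(out) <- NULL
  out
}
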