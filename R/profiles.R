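# Study-condition profiles for the synthetic-data generator: constitutive
# parameters of the quasi-linear viscoelastic (QLV) strip model, the
# two-phase tensile protocol, and per-group geometry / histology profiles.

#' Constitutive parameters of the simulated wall strip
#'
#' The simulator uses a quasi-linear viscoelastic model: a nonlinear
#' elastic backbone sigma_e(eps) = A1 (exp(B1 eps) - 1) + A2 (exp(B2 eps)
#' - 1) (two exponential terms: a compliant elastin-dominated term and a
#' steep collagen-recruitment term) convolved with a reduced relaxation
#' function G(t) = g_inf + sum_i g_i exp(-t / tau_i), g_inf = 1 - sum(g_i).
#'
#' The defaults are calibrated so that a mean-geometry control strip run
#' through the default protocol yields incremental moduli near 100 kPa at
#' strain 0.25, doubling at 0.50 and tripling again at 0.75, and a
#' 5-minute relaxation strength near 8%.
#'
#' @param A Backbone scales, kPa (length 2).
#' @param B Backbone exponents, dimensionless (length 2).
#' @param prony_g Relaxation weights (sum < 1).
#' @param prony_tau Relaxation time constants, s.
#' @param plastic_offset Residual elongation programmed into the recovery
#'   probe, mm (>= 0).
#' @return An object of class `constitutive_params`.
#' @export
constitutive_params <- function(A = c(20.312, 0.0068285),
                                B = c(2.4133, 10.2468),
                                prony_g = c(0.055, 0.045),
                                prony_tau = c(15, 250),
                                plastic_offset = 0) {
  if (length(A) != length(B) || any(A <= 0) || any(B <= 0)) {
    stop_aorta("aortamech_invalid_input",
               "backbone A and B must be positive and of equal length")
  }
  if (length(prony_g) != length(prony_tau) ||
      any(prony_g <= 0 & length(prony_g) > 0) ||
      any(prony_tau <= 0 & length(prony_tau) > 0)) {
    stop_aorta("aortamech_invalid_input", "invalid Prony series")
  }
  if (sum(prony_g) >= 1) {
    stop_aorta("aortamech_invalid_input",
               "sum of Prony weights must be < 1 (g_inf > 0)")
  }
  if (plastic_offset < 0) {
    stop_aorta("aortamech_invalid_input", "plastic_offset must be >= 0")
  }
  structure(list(A = A, B = B, prony_g = prony_g, prony_tau = prony_tau,
                 plastic_offset = plastic_offset),
            class = "constitutive_params")
}

# Elastic backbone stress (kPa) and its reduced relaxation function.
backbone_stress <- function(params, eps) {
  s <- 0
  for (i in seq_along(params$A)) {
    s <- s + params$A[i] * (exp(params$B[i] * eps) - 1)
  }
  s
}

reduced_relaxation <- function(params, t) {
  g_inf <- 1 - sum(params$prony_g)
  g <- rep(g_inf, length(t))
  for (i in seq_along(params$prony_g)) {
    g <- g + params$prony_g[i] * exp(-t / params$prony_tau[i])
  }
  g
}

#' Two-phase tensile protocol settings
#'
#' Phase 1: slow ramp (default 4.2 mm/min) until the force reaches
#' `ramp_target_force` (about 1 N), immediate unload at the same speed,
#' then a 5-minute recovery at the initial length followed by a slow
#' re-stretch probing plastic deformation. Phase 2: fast stretch (default
#' 83.3 mm/min) to `step_strain` (50% of the initial length) sustained for
#' `hold` seconds.
#'
#' @param ramp_speed Phase-1 crosshead speed, mm/min.
#' @param ramp_target_force Phase-1 force target, N.
#' @param step_speed Phase-2 crosshead speed, mm/min.
#' @param step_strain Phase-2 strain target, dimensionless.
#' @param hold Phase-2 hold duration, s.
#' @param recovery Recovery time before the plastic probe, s.
#' @param sampling_rate Instrument sampling rate, Hz.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(ramp_speed = 4.2, ramp_target_force = 1.0,
                          step_speed = 83.3, step_strain = 0.5,
                          hold = 300, recovery = 300, sampling_rate = 10) {
  vals <- c(ramp_speed, ramp_target_force, step_speed, step_strain,
            hold, recovery, sampling_rate)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_aorta("aortamech_invalid_input",
               "all protocol settings must be positive")
  }
  structure(list(ramp_speed = ramp_speed,
                 ramp_target_force = ramp_target_force,
                 step_speed = step_speed, step_strain = step_strain,
                 hold = hold, recovery = recovery,
                 sampling_rate = sampling_rate),
            class = "protocol_spec")
}

#' Per-group simulation profile
#'
#' Describes one study arm: the distributions geometry is drawn from
#' (truncated normals, mean and SD), the constitutive defaults, and the
#' histology ground truth (component fractions of the frame and the
#' expected nucleus count per HE frame). Between-specimen SDs for the
#' tabulated geometry variables derive from the reported standard errors
#' via SD = SE * sqrt(6).
#'
#' @param group Group label (`"FLT"`, `"AGC"`, `"VIV"` or custom).
#' @param body_weight_g,L0_cm,width_cm,thickness_um,internal_diameter_mm
#'   Two-element `c(mean, sd)` vectors.
#' @param constitutive A [constitutive_params()] (group default; the
#'   plastic offset applies to its mean via `plastic_offset_mm`).
#' @param plastic_offset_mm `c(mean, sd)` of the residual elongation.
#' @param backbone_cv,relax_cv Between-specimen coefficients of variation
#'   applied multiplicatively to the backbone scale and Prony weights.
#' @param frac_smc,frac_elastin,frac_collagen `c(mean, sd)` component
#'   fractions in percent of the frame.
#' @param nuclei_per_frame `c(mean, sd)` expected nucleus count per HE
#'   frame.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(group,
                          body_weight_g, L0_cm = c(0.8, 0.05),
                          width_cm = c(0.3, 0.01),
                          thickness_um, internal_diameter_mm,
                          constitutive = constitutive_params(),
                          plastic_offset_mm = c(0, 0),
                          backbone_cv = 0.10, relax_cv = 0.20,
                          frac_smc, frac_elastin = c(30, 2.5),
                          frac_collagen = c(20, 2.5),
                          nuclei_per_frame) {
  as_ms <- function(x) {
    if (length(x) == 1L) x <- c(x, 0)
    if (length(x) != 2L || x[1] < 0 || x[2] < 0) {
      stop_aorta("aortamech_invalid_input",
                 "profile entries must be c(mean, sd) with sd >= 0")
    }
    x
  }
  structure(list(
    group = group,
    body_weight_g = as_ms(body_weight_g), L0_cm = as_ms(L0_cm),
    width_cm = as_ms(width_cm), thickness_um = as_ms(thickness_um),
    internal_diameter_mm = as_ms(internal_diameter_mm),
    constitutive = constitutive,
    plastic_offset_mm = as_ms(plastic_offset_mm),
    backbone_cv = backbone_cv, relax_cv = relax_cv,
    frac_smc = as_ms(frac_smc), frac_elastin = as_ms(frac_elastin),
    frac_collagen = as_ms(frac_collagen),
    nuclei_per_frame = as_ms(nuclei_per_frame)
  ), class = "group_profile")
}

#' Default study-arm profiles
#'
#' The three arms of the flight study: FLT (spaceflight), AGC
#' (asynchronous ground control) and VIV (vivarium control). Geometry
#' means follow the tabulated group values (body weight; internal diameter
#' from the circumferential strip width; wall thickness from the
#' gravimetric estimate); the FLT arm differs from the controls only in
#' geometry (thinner, narrower, lighter), a nonzero plastic offset, a
#' smaller smooth-muscle fraction and a lower nucleus density. Constitutive
#' stress parameters are common to all arms, so stress-strain curves are
#' statistically indistinguishable across arms while tensile force is not.
#'
#' @return Named list of [group_profile()] objects (`FLT`, `AGC`, `VIV`).
#' @export
default_group_profiles <- function() {
  list(
    FLT = group_profile(
      "FLT",
      body_weight_g = c(40.0, 12.49),
      thickness_um = c(133.3, 21.8),
      internal_diameter_mm = c(1.08, 0.098),
      plastic_offset_mm = c(0.12, 0.0735),
      frac_smc = c(35, 2.5),
      nuclei_per_frame = c(134.3, 8.8)
    ),
    AGC = group_profile(
      "AGC",
      body_weight_g = c(77.5, 5.14),
      thickness_um = c(193.4, 14.1),
      internal_diameter_mm = c(1.32, 0.049),
      frac_smc = c(45, 2.5),
      nuclei_per_frame = c(179.3, 13.5)
    ),
    VIV = group_profile(
      "VIV",
      body_weight_g = c(83.0, 4.16),
      thickness_um = c(188.4, 22.3),
      internal_diameter_mm = c(1.31, 0.098),
      frac_smc = c(45, 2.5),
      nuclei_per_frame = c(166.2, 12.7)
    )
  )
}
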