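# Shared fixtures built in code.

# Mean-geometry control strip (thickness ~ mean of the two control arms).
control_geometry <- function(h_um = 190.9, L0 = 0.8, wd = 0.3) {
  strip_geometry(L0, wd, 1.06 * L0 * wd * h_um * 1e-4,
                 circ_length = pi * 1.315 / 10)
}

# A stress-strain curve object from closed-form stress sigma(eps).
curve_from_function <- function(sigma_fun, eps_max = 1, n = 2001) {
  eps <- seq(0, eps_max, length.out = n)
  structure(list(strain = eps, stress = sigma_fun(eps),
                 tension = rep(NA_real_, n)),
            class = "stress_strain_curve")
}

# Step-and-hold trace carrying an analytic reduced-relaxation response:
# near-instant step to eps = 0.5, then force ~ G(t) after the step.
analytic_hold_trace <- function(geometry, G_fun, sigma_e = 100,
                                hold = 310, dt = 0.1) {
  L0_mm <- geometry$L0 * 10
  d_target <- 0.5 * L0_mm
  t <- seq(0, hold, by = dt)
  disp <- rep(d_target, length(t))
  sigma <- sigma_e * G_fun(t)
  force <- sigma * (geometry$weight / (geometry$rho * geometry$L0)) /
    (10 * (1 + 0.5))
  tensile_trace(c(-dt, t), c(0, disp), c(0, force), phase = "step_hold")
}

# Small study-arm profiles for fast pipeline tests: low nucleus density so
# small frames stay renderable.
tiny_profiles <- function() {
  p <- default_group_profiles()
  for (g in names(p)) p[[g]]$nuclei_per_frame <- c(20, 3)
  p
}
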