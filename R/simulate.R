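# Synthetic-data generator: specimen sampling, QLV tensile-protocol
# simulation, and stained-section field rendering with exact ground truth.

#' Draw one specimen from a group profile
#'
#' Geometry is drawn from truncated normals (mean +/- 3 SD, strictly
#' positive); the strip weight is derived gravimetrically from the drawn
#' thickness (W = rho * L0 * Wd * h) so that thickness, weight per area and
#' cross-section stay mutually consistent. Constitutive parameters receive
#' seeded multiplicative between-specimen jitter; the plastic offset and
#' histology ground truth (component fractions, expected nuclei per frame)
#' are drawn from the profile distributions.
#'
#' @param profile A [group_profile()].
#' @param specimen_id Identifier for the specimen.
#' @param seed Integer seed (`NULL` for the current RNG stream).
#' @return A list with `record` (one-row data.frame of metadata),
#'   `geometry` ([strip_geometry()]), `params` ([constitutive_params()])
#'   and `histology` (list of true fractions and nucleus intensity).
#' @export
sample_specimen <- function(profile, specimen_id = profile$group, seed = NULL) {
  stopifnot(inherits(profile, "group_profile"))
  with_seed(seed, {
    draw <- function(ms) rtruncnorm_pos(1, ms[1], ms[2])
    L0 <- draw(profile$L0_cm)
    wd <- draw(profile$width_cm)
    h_um <- draw(profile$thickness_um)
    d_mm <- draw(profile$internal_diameter_mm)
    bw <- draw(profile$body_weight_g)
    rho <- profile$constitutive$rho %||% 1.06
    weight <- rho * L0 * wd * (h_um * 1e-4)
    circ <- pi * d_mm / 10                    # mm -> cm
    geometry <- strip_geometry(L0 = L0, width = wd, weight = weight,
                               circ_length = circ, rho = rho)
    base <- profile$constitutive
    bb_jit <- exp(rnorm(1, 0, profile$backbone_cv))
    rx_jit <- exp(rnorm(1, 0, profile$relax_cv))
    g <- base$prony_g * rx_jit
    if (sum(g) >= 0.99) g <- g * 0.99 / sum(g)
    offset <- if (profile$plastic_offset_mm[1] > 0) {
      rtruncnorm_pos(1, profile$plastic_offset_mm[1],
                     profile$plastic_offset_mm[2])
    } else 0
    params <- constitutive_params(A = base$A * bb_jit, B = base$B,
                                  prony_g = g, prony_tau = base$prony_tau,
                                  plastic_offset = offset)
    fr_smc <- draw(profile$frac_smc)
    fr_ela <- draw(profile$frac_elastin)
    fr_col <- draw(profile$frac_collagen)
    tot <- fr_smc + fr_ela + fr_col
    if (tot > 95) {  # keep some background in the frame
      sc <- 95 / tot
      fr_smc <- fr_smc * sc; fr_ela <- fr_ela * sc; fr_col <- fr_col * sc
    }
    histology <- list(
      frac_smc = fr_smc, frac_elastin = fr_ela, frac_collagen = fr_col,
      nuclei_per_frame = rtruncnorm_pos(1, profile$nuclei_per_frame[1],
                                        profile$nuclei_per_frame[2])
    )
    record <- data.frame(
      specimen_id = specimen_id, group = profile$group,
      L0_cm = L0, width_cm = wd, weight_g = weight,
      circ_length_cm = circ, body_weight_g = bw,
      stringsAsFactors = FALSE
    )
    list(record = record, geometry = geometry, params = params,
         histology = histology)
  })
}

# --- QLV core ---------------------------------------------------------------
#
# Discretized hereditary convolution sigma(t) = int G(t - s) dsigma_e/ds ds
# with piecewise-linear sigma_e increments and an exact exponential-decay
# recursion per Prony term:
#   hist_i(n+1) = exp(-dt/tau_i) hist_i(n)
#               + g_i * dSigma_e * (1 - exp(-dt/tau_i)) / (dt/tau_i)
#   sigma(n+1)  = g_inf * sigma_e(n+1) + sum_i hist_i(n+1)
# `state` carries the per-term history so phases can be chained.

qlv_init_state <- function(params, eps0) {
  list(hist = rep(0, length(params$prony_g)),
       sigma_e_prev = backbone_stress(params, eps0))
}

qlv_step_response <- function(params, eps_seq, dt, state) {
  g_inf <- 1 - sum(params$prony_g)
  ntau <- length(params$prony_g)
  decay <- if (ntau) exp(-dt / params$prony_tau) else numeric(0)
  relax_w <- if (ntau) {
    params$prony_g * (1 - decay) / (dt / params$prony_tau)
  } else numeric(0)
  sigma <- numeric(length(eps_seq))
  hist <- state$hist
  se_prev <- state$sigma_e_prev
  for (n in seq_along(eps_seq)) {
    se <- backbone_stress(params, eps_seq[n])
    dse <- se - se_prev
    if (ntau) hist <- hist * decay + relax_w * dse
    sigma[n] <- g_inf * se + sum(hist)
    se_prev <- se
  }
  list(sigma = sigma, state = list(hist = hist, sigma_e_prev = se_prev))
}

# Pre-strain at which the fully relaxed strip carries the just-taut
# pre-tension (the bench definition of the initial length: the maximum
# length where tension just exceeds 0 N).
solve_pre_strain <- function(params, geometry, pretension_N) {
  g_inf <- 1 - sum(params$prony_g)
  target <- pretension_N * 10 / cross_section_cm2(geometry)  # sigma (kPa)
  f <- function(e) g_inf * backbone_stress(params, e) - target
  stats::uniroot(f, c(0, 2), tol = 1e-12)$root
}

#' Simulate the two-phase tensile protocol for one strip
#'
#' Runs the quasi-linear viscoelastic strip model through the full bench
#' protocol and returns instrument-like traces: `ramp_load` (slow stretch
#' until the force target), `unload` (return to initial length),
#' `recovery_probe` (slow re-stretch after the recovery period, probing
#' plastic deformation) and `step_hold` (fast stretch to the hold strain
#' plus the 5-minute hold). The strip carries a small "just-taut"
#' pre-tension at zero displacement, mirroring how the initial length is
#' set on the bench; the programmed plastic offset shifts the zero-force
#' length for every phase after the first loading. Optional measurement
#' noise is multiplicative Gaussian on force plus one additive offset per
#' trace, both seeded.
#'
#' @param geometry A [strip_geometry()].
#' @param params A [constitutive_params()].
#' @param protocol A [protocol_spec()].
#' @param seed Integer seed for the noise draws.
#' @param noise_sd Multiplicative force-noise SD (0 disables).
#' @param offset_sd SD of the per-trace additive force offset, N.
#' @param pretension_N Just-taut tension at zero displacement, N.
#' @param max_strain Safety cap on ramp strain if the force target is
#'   never reached.
#' @return Named list of [tensile_trace()] objects.
#' @export
simulate_protocol <- function(geometry, params, protocol = protocol_spec(),
                              seed = NULL, noise_sd = 0.005,
                              offset_sd = 2e-5, pretension_N = 0.0015,
                              max_strain = 1.6) {
  stopifnot(inherits(geometry, "strip_geometry"),
            inherits(params, "constitutive_params"),
            inherits(protocol, "protocol_spec"))
  dt <- 1 / protocol$sampling_rate
  L0_mm <- geometry$L0 * 10
  eps0 <- solve_pre_strain(params, geometry, pretension_N)
  p_mm <- params$plastic_offset

  # material strain for a displacement (mm), with optional slack offset
  eps_of <- function(disp_mm, offset_mm = 0) {
    eps0 + pmax(disp_mm - offset_mm, 0) / L0_mm
  }
  force_of <- function(sigma, disp_mm, offset_mm = 0) {
    eps_meas <- pmax(disp_mm - offset_mm, 0) / L0_mm
    f <- sigma * cross_section_cm2(geometry) / (10 * (1 + eps_meas))
    f[disp_mm < offset_mm] <- 0   # slack strip carries no force
    pmax(f, 0)
  }

  with_seed(seed, {
    noisy <- function(f) {
      if (noise_sd > 0) f <- f * (1 + rnorm(length(f), 0, noise_sd))
      if (offset_sd > 0) f <- f + rnorm(1, 0, offset_sd)
      f
    }

    # Phase 1a: loading ramp until the force target
    v_ramp <- protocol$ramp_speed / 60          # mm/s
    n_ramp <- ceiling(max_strain * L0_mm / (v_ramp * dt))
    t_ramp <- seq_len(n_ramp) * dt
    d_ramp <- v_ramp * t_ramp
    st <- qlv_init_state(params, eps0)
    resp <- qlv_step_response(params, eps_of(d_ramp), dt, st)
    f_ramp <- force_of(resp$sigma, d_ramp)
    k <- which(f_ramp >= protocol$ramp_target_force)[1]
    if (is.na(k)) k <- n_ramp
    ramp <- tensile_trace(c(0, t_ramp[1:k]), c(0, d_ramp[1:k]),
                          noisy(c(force_of(backbone_stress(params, eps0) *
                                             (1 - sum(params$prony_g)), 0),
                                  f_ramp[1:k])),
                          phase = "ramp_load")
    # state at the truncation point (recompute up to k to get exact state)
    resp_k <- qlv_step_response(params, eps_of(d_ramp[1:k]), dt, st)

    # Phase 1b: unload back to the initial length at the same speed;
    # the plastic offset develops at the force peak.
    n_unl <- ceiling(d_ramp[k] / (v_ramp * dt))
    d_unl <- pmax(d_ramp[k] - v_ramp * seq_len(n_unl) * dt, 0)
    resp_u <- qlv_step_response(params, eps_of(d_unl, p_mm), dt, resp_k$state)
    unload <- tensile_trace(t_ramp[k] + seq_len(n_unl) * dt, d_unl,
                            noisy(force_of(resp_u$sigma, d_unl, p_mm)),
                            phase = "unload")

    # Phase 1c: recovery, then the slow plastic probe from a relaxed state
    v_probe <- v_ramp
    probe_cap_mm <- max(1.0, p_mm + 0.5)
    n_pr <- ceiling(probe_cap_mm / (v_probe * dt))
    t_pr <- seq_len(n_pr) * dt
    d_pr <- v_probe * t_pr
    resp_p <- qlv_step_response(params, eps_of(d_pr, p_mm), dt,
                                qlv_init_state(params, eps0))
    f_pr <- force_of(resp_p$sigma, d_pr, p_mm)
    kp <- which(f_pr >= 0.05)[1]
    if (is.na(kp)) kp <- n_pr
    # relaxed just-taut tension at zero displacement (zero if slack)
    sig0 <- (1 - sum(params$prony_g)) * backbone_stress(params, eps0)
    probe <- tensile_trace(c(0, t_pr[1:kp]), c(0, d_pr[1:kp]),
                           noisy(c(force_of(sig0, 0, p_mm), f_pr[1:kp])),
                           phase = "recovery_probe")

    # Phase 2: fast stretch to the hold strain + hold
    v_step <- protocol$step_speed / 60
    d_target <- protocol$step_strain * L0_mm
    n_up <- ceiling(d_target / (v_step * dt))
    d_up <- pmin(v_step * seq_len(n_up) * dt, d_target)
    n_hold <- ceiling((protocol$hold + 10) / dt)
    d_step <- c(d_up, rep(d_target, n_hold))
    t_step <- seq_along(d_step) * dt
    resp_s <- qlv_step_response(params, eps_of(d_step, p_mm), dt,
                                qlv_init_state(params, eps0))
    step <- tensile_trace(c(0, t_step), c(0, d_step),
                          noisy(c(force_of(sig0, 0, p_mm),
                                  force_of(resp_s$sigma, d_step, p_mm))),
                          phase = "step_hold")

    list(ramp_load = ramp, unload = unload, recovery_probe = probe,
         step_hold = step)
  })
}

# --- Stained-section renderers ---------------------------------------------

# Reference colors (8-bit RGB) used by the renderers.
RENDER_COLORS <- list(
  elastin = c(30, 28, 28),      # near-black lamellae
  collagen = c(185, 40, 55),    # red fiber strands
  smc = c(200, 170, 60),        # yellow interlamellar bands
  evg_background = c(235, 225, 220),
  nucleus = c(80, 70, 160),     # blue-violet
  he_background = c(243, 205, 210)  # eosin pink
)

paint_image <- function(label, palette, noise_sd, clip = c(0, 255)) {
  d <- dim(label)
  px <- array(0, c(d[1], d[2], 3))
  for (cls in names(palette)) {
    sel <- label == cls
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[sel] <- palette[[cls]][ch]
      px[, , ch] <- plane
    }
  }
  if (noise_sd > 0) {
    px <- px + array(rnorm(length(px), 0, noise_sd), dim(px))
  }
  pmin(pmax(round(px), clip[1]), clip[2])
}

#' Render a synthetic EVG-stained field with known composition
#'
#' Draws a lamellar media: wavy near-black elastin lamellae alternating
#' with yellow smooth-muscle bands and red collagen strands on a pale
#' background, arranged as a sinusoidally warped banding pattern whose
#' band widths are proportional to the requested fractions. The exact
#' painted pixel fractions are returned as ground truth (they differ from
#' the request only by rasterization).
#'
#' @param fractions List/vector with `smc`, `elastin`, `collagen` percent
#'   of the frame (summing to <= 100; the remainder is background).
#' @param size Frame side length in pixels.
#' @param microns_per_pixel Pixel scale.
#' @param seed Integer seed (waviness phases and pixel noise).
#' @param noise_sd Per-channel Gaussian pixel noise SD (8-bit units).
#' @param field_id Field identifier.
#' @return List with `image` ([field_image()]) and `truth` (exact painted
#'   percentages `pct_smc`, `pct_elastin`, `pct_collagen`).
#' @export
simulate_evg_field <- function(fractions, size = 256, microns_per_pixel = 1.6,
                               seed = NULL, noise_sd = 4,
                               field_id = "evg") {
  f_smc <- fractions[["smc"]] / 100
  f_ela <- fractions[["elastin"]] / 100
  f_col <- fractions[["collagen"]] / 100
  if (min(f_smc, f_ela, f_col) < 0 || f_smc + f_ela + f_col > 1) {
    stop_aorta("aortamech_invalid_input",
               "fractions must be non-negative and sum to <= 100%")
  }
  with_seed(seed, {
    y <- matrix(seq_len(size), size, size)
    x <- matrix(seq_len(size), size, size, byrow = TRUE)
    period <- 32
    warp <- 3.0 * sin(2 * pi * x / 96 + runif(1, 0, 2 * pi)) +
      1.5 * sin(2 * pi * x / 23 + runif(1, 0, 2 * pi))
    tpos <- (y + warp) %% period / period   # position within one lamellar unit
    # band order within a unit: elastin | smc | collagen | background
    label <- matrix("background", size, size)
    label[tpos < f_ela + f_smc + f_col] <- "collagen"
    label[tpos < f_ela + f_smc] <- "smc"
    label[tpos < f_ela] <- "elastin"
    px <- paint_image(label, RENDER_COLORS[c("elastin", "smc", "collagen")],
                      noise_sd = 0)
    # background color fill for unpainted pixels, then shared pixel noise
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[label == "background"] <- RENDER_COLORS$evg_background[ch]
      px[, , ch] <- plane
    }
    if (noise_sd > 0) {
      px <- pmin(pmax(round(px + array(rnorm(length(px), 0, noise_sd),
                                       dim(px))), 0), 255)
    }
    truth <- list(
      pct_smc = 100 * sum(label == "smc") / size^2,
      pct_elastin = 100 * sum(label == "elastin") / size^2,
      pct_collagen = 100 * sum(label == "collagen") / size^2
    )
    list(image = field_image(px, stain = "EVG",
                             microns_per_pixel = microns_per_pixel,
                             field_id = field_id),
         truth = truth)
  })
}

#' Render a synthetic HE-stained field with a known nucleus count
#'
#' Places N ~ Poisson(`nuclei_mean`) blue-violet elliptical nuclei on an
#' eosin-pink background by rejection sampling with a separation margin,
#' so rendered nuclei never touch (a labeled segmentation recovers the
#' count exactly). Fails with a density error if placement does not
#' succeed within `max_attempts`.
#'
#' @param nuclei_mean Expected nucleus count for the frame.
#' @param size Frame side length in pixels.
#' @param microns_per_pixel Pixel scale.
#' @param seed Integer seed.
#' @param noise_sd Per-channel pixel noise SD.
#' @param radius_range Semi-axis range of the nucleus ellipses, px.
#' @param max_attempts Rejection-sampling attempt budget.
#' @param field_id Field identifier.
#' @return List with `image` ([field_image()]) and `count` (true N).
#' @export
simulate_he_field <- function(nuclei_mean, size = 256, microns_per_pixel = 1.6,
                              seed = NULL, noise_sd = 4,
                              radius_range = c(3.5, 6), max_attempts = 1e4,
                              field_id = "he") {
  with_seed(seed, {
    n <- stats::rpois(1, nuclei_mean)
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    attempts <- 0
    margin <- 3
    while (nrow(centers) < n) {
      attempts <- attempts + 1
      if (attempts > max_attempts) {
        stop_aorta("aortamech_density_too_high",
                   sprintf("placed %d of %d nuclei in %d attempts",
                           nrow(centers), n, max_attempts))
      }
      a <- runif(1, radius_range[1], radius_range[2])
      cx <- runif(1, a + 2, size - a - 1)
      cy <- runif(1, a + 2, size - a - 1)
      if (nrow(centers)) {
        dd <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(dd < radii + a + margin)) next
      }
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, a)
    }
    label <- matrix(FALSE, size, size)
    if (n > 0) {
      for (i in seq_len(n)) {
        a <- radii[i]
        b <- runif(1, radius_range[1], min(a, radius_range[2]))
        th <- runif(1, 0, pi)
        cx <- centers[i, 1]; cy <- centers[i, 2]
        xr <- max(1, floor(cx - a)):min(size, ceiling(cx + a))
        yr <- max(1, floor(cy - a)):min(size, ceiling(cy + a))
        gx <- matrix(xr, length(yr), length(xr), byrow = TRUE) - cx
        gy <- matrix(yr, length(yr), length(xr)) - cy
        u <- gx * cos(th) + gy * sin(th)
        v <- -gx * sin(th) + gy * cos(th)
        inside <- (u / a)^2 + (v / b)^2 <= 1
        label[yr, xr] <- label[yr, xr] | inside
      }
    }
    px <- array(0, c(size, size, 3))
    for (ch in 1:3) {
      plane <- matrix(RENDER_COLORS$he_background[ch], size, size)
      plane[label] <- RENDER_COLORS$nucleus[ch]
      px[, , ch] <- plane
    }
    if (noise_sd > 0) {
      px <- pmin(pmax(round(px + array(rnorm(length(px), 0, noise_sd),
                                       dim(px))), 0), 255)
    }
    list(image = field_image(px, stain = "HE",
                             microns_per_pixel = microns_per_pixel,
                             field_id = field_id),
         count = n)
  })
}

#' Generate a complete synthetic study bundle
#'
#' Draws `n_per_group` specimens per study arm, simulates the full tensile
#' protocol and renders EVG/HE fields for each, and writes a pipeline-ready
#' directory tree: `metadata.csv`, `traces/<specimen>/<phase>.csv`,
#' `images/<specimen>/<stain>_<field>.png`, `ground_truth.json` and
#' `provenance.json`. Fully deterministic given `seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_per_group Specimens per arm (default 6).
#' @param seed Integer seed.
#' @param profiles Named list of [group_profile()]s.
#' @param protocol A [protocol_spec()].
#' @param n_evg_fields,n_he_fields Fields rendered per specimen.
#' @param write_images Set `FALSE` to skip PNG output (traces and ground
#'   truth only).
#' @param image_size Field side length in pixels.
#' @return `out_dir`, invisibly.
#' @export
generate_study <- function(out_dir, n_per_group = 6, seed = 1,
                           profiles = default_group_profiles(),
                           protocol = protocol_spec(),
                           n_evg_fields = 2, n_he_fields = 3,
                           write_images = TRUE, image_size = 256) {
  if (n_per_group < 2) {
    stop_aorta("aortamech_invalid_input", "n_per_group must be >= 2")
  }
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop_aorta("aortamech_io", sprintf("cannot create %s", out_dir))
  }
  meta <- list(); truth <- list()
  for (gname in names(profiles)) {
    profile <- profiles[[gname]]
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_%02d", gname, i)
      spec <- sample_specimen(profile, specimen_id = sid,
                              seed = derive_seed(seed, gname, i, "geom"))
      meta[[sid]] <- spec$record
      traces <- simulate_protocol(spec$geometry, spec$params, protocol,
                                  seed = derive_seed(seed, gname, i, "trace"))
      tdir <- file.path(out_dir, "traces", sid)
      dir.create(tdir, showWarnings = FALSE, recursive = TRUE)
      for (ph in names(traces)) {
        write_trace_csv(traces[[ph]], file.path(tdir, paste0(ph, ".csv")))
      }
      idir <- file.path(out_dir, "images", sid)
      evg_truth <- list(); he_counts <- integer(0)
      if (write_images) dir.create(idir, showWarnings = FALSE, recursive = TRUE)
      for (k in seq_len(n_evg_fields)) {
        fld <- simulate_evg_field(
          list(smc = spec$histology$frac_smc,
               elastin = spec$histology$frac_elastin,
               collagen = spec$histology$frac_collagen),
          size = image_size,
          seed = derive_seed(seed, gname, i, "evg", k),
          field_id = sprintf("%s_evg_%d", sid, k))
        evg_truth[[k]] <- fld$truth
        if (write_images) {
          write_field_png(fld$image, file.path(idir, sprintf("EVG_%d.png", k)))
        }
      }
      for (k in seq_len(n_he_fields)) {
        fld <- simulate_he_field(
          spec$histology$nuclei_per_frame, size = image_size,
          seed = derive_seed(seed, gname, i, "he", k),
          field_id = sprintf("%s_he_%d", sid, k))
        he_counts <- c(he_counts, fld$count)
        if (write_images) {
          write_field_png(fld$image, file.path(idir, sprintf("HE_%d.png", k)))
        }
      }
      truth[[sid]] <- list(
        group = gname,
        thickness_um = wall_thickness(spec$geometry),
        plastic_offset_mm = spec$params$plastic_offset,
        frac_smc = spec$histology$frac_smc,
        frac_elastin = spec$histology$frac_elastin,
        frac_collagen = spec$histology$frac_collagen,
        evg_painted = evg_truth,
        he_counts = he_counts
      )
    }
  }
  meta_df <- do.call(rbind, meta)
  con <- file(file.path(out_dir, "metadata.csv"), "wb")
  utils::write.csv(meta_df, con, row.names = FALSE, quote = FALSE)
  close(con)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  prov <- list(seed = seed, n_per_group = n_per_group,
               protocol = unclass(protocol),
               groups = names(profiles),
               n_evg_fields = n_evg_fields, n_he_fields = n_he_fields,
               image_size = image_size)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
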