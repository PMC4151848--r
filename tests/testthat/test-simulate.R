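test_that("specimen sampling is deterministic and respects the profile", {
  prof <- default_group_profiles()$FLT
  a <- sample_specimen(prof, seed = 123)
  b <- sample_specimen(prof, seed = 123)
  expect_identical(a, b)
  c <- sample_specimen(prof, seed = 124)
  expect_false(identical(a$geometry, c$geometry))
})

test_that("sampled internal diameter concentrates on the profile mean", {
  prof <- default_group_profiles()$FLT
  set.seed(600)
  ms <- prof$internal_diameter_mm
  d <- aortamech:::rtruncnorm_pos(20000, ms[1], ms[2])
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 1.08), 3 * se)
})

test_that("control thickness is about 1.45x the flight thickness", {
  p <- default_group_profiles()
  ctrl <- mean(c(p$AGC$thickness_um[1], p$VIV$thickness_um[1]))
  expect_equal(ctrl / p$FLT$thickness_um[1], 1.43, tolerance = 0.03)
})

test_that("the elastic limit degenerates to a reversible strip", {
  g <- control_geometry()
  par_el <- constitutive_params(prony_g = numeric(0), prony_tau = numeric(0))
  tr <- simulate_protocol(g, par_el, seed = 1, noise_sd = 0, offset_sd = 0)
  # unload retraces load: compare force at matched displacements
  ld <- tr$ramp_load; ul <- tr$unload
  sel <- ul$displacement > 0.5
  f_ld <- approx(ld$displacement, ld$force, xout = ul$displacement[sel])$y
  expect_lt(max(abs(f_ld - ul$force[sel]) / pmax(f_ld, 0.01)), 1e-6)
  expect_lt(abs(relaxation_strength(tr$step_hold, g)$strength), 1e-6)
  expect_equal(plastic_deformation(tr$recovery_probe), 0)
})

test_that("viscoelastic loading shows non-negative hysteresis", {
  g <- control_geometry()
  tr <- simulate_protocol(g, constitutive_params(), seed = 2,
                          noise_sd = 0, offset_sd = 0)
  ld <- tr$ramp_load; ul <- tr$unload
  sel <- ul$displacement > 1 & ul$displacement < max(ld$displacement) - 0.5
  f_ld <- approx(ld$displacement, ld$force, xout = ul$displacement[sel])$y
  expect_true(all(ul$force[sel] <= f_ld + 1e-9))
})

test_that("one-term Prony relaxation is recovered across time constants", {
  g <- control_geometry()
  # near-instant step (the regime of the step-response closed form)
  fast <- protocol_spec(step_speed = 6000)
  for (tau in c(30, 60, 120)) {
    par1 <- constitutive_params(prony_g = 0.08, prony_tau = tau)
    tr <- simulate_protocol(g, par1, protocol = fast, seed = 3,
                            noise_sd = 0, offset_sd = 0)
    got <- relaxation_strength(tr$step_hold, g)$strength
    closed_form <- (1 - (0.92 + 0.08 * exp(-300 / tau))) * 100
    expect_lt(abs(got - closed_form), 0.5)
  }
})

test_that("phase-2 peak strain is half the initial length", {
  g <- control_geometry()
  tr <- simulate_protocol(g, constitutive_params(), seed = 4)
  peak <- max(strain_from_displacement(tr$step_hold$displacement, g$L0))
  expect_equal(peak, 0.5, tolerance = 1e-6)
})

test_that("thinner strips carry less force at equal stress", {
  parms <- constitutive_params()
  thick <- control_geometry(h_um = 190)
  thin <- control_geometry(h_um = 133)
  tr_thick <- simulate_protocol(thick, parms, seed = 5, noise_sd = 0,
                                offset_sd = 0)
  tr_thin <- simulate_protocol(thin, parms, seed = 5, noise_sd = 0,
                               offset_sd = 0)
  cv_thick <- build_stress_strain(tr_thick$ramp_load, thick)
  cv_thin <- build_stress_strain(tr_thin$ramp_load, thin)
  for (s in seq(0.3, 0.75, 0.15)) {
    f_thick <- approx(cv_thick$strain, cv_thick$tension, xout = s)$y
    f_thin <- approx(cv_thin$strain, cv_thin$tension, xout = s)$y
    expect_lt(f_thin, f_thick)
    # force ratio tracks the weight ratio; stress curves nearly coincide
    # (small residual: the just-taut initial-length convention pre-strains
    # thin strips slightly more than thick ones)
    expect_equal(f_thin / f_thick, thin$weight / thick$weight,
                 tolerance = 0.12)
    s_thick <- approx(cv_thick$strain, cv_thick$stress, xout = s)$y
    s_thin <- approx(cv_thin$strain, cv_thin$stress, xout = s)$y
    expect_equal(s_thin / s_thick, 1, tolerance = 0.12)
  }
})

test_that("simulated traces are deterministic given the seed", {
  g <- control_geometry()
  t1 <- simulate_protocol(g, constitutive_params(), seed = 11)
  t2 <- simulate_protocol(g, constitutive_params(), seed = 11)
  expect_identical(t1, t2)
})

test_that("renderers are deterministic and respect requested truth", {
  f1 <- simulate_evg_field(list(smc = 35, elastin = 30, collagen = 20),
                           seed = 9)
  f2 <- simulate_evg_field(list(smc = 35, elastin = 30, collagen = 20),
                           seed = 9)
  expect_identical(f1, f2)
  z <- simulate_evg_field(list(smc = 40, elastin = 30, collagen = 0),
                          seed = 10)
  expect_equal(z$truth$pct_collagen, 0)
  masks <- classify_evg_pixels(z$image)
  expect_lt(100 * sum(masks$collagen) / length(masks$collagen), 0.5)
  h1 <- simulate_he_field(100, seed = 12)
  h2 <- simulate_he_field(100, seed = 12)
  expect_identical(h1, h2)
  h0 <- simulate_he_field(0, seed = 13)
  expect_equal(h0$count, 0)
  expect_equal(count_nuclei(segment_nuclei(h0$image)), 0)
  expect_error(simulate_he_field(5000, size = 64, seed = 14),
               class = "aortamech_density_too_high")
})

test_that("group differences in thickness and SMC are reliably flagged", {
  profiles <- default_group_profiles()
  n_studies <- 20
  flags_thickness <- flags_smc <- flags_ela <- flags_col <- logical(n_studies)
  for (s in seq_len(n_studies)) {
    vals <- list()
    for (gname in names(profiles)) {
      th <- smc <- ela <- col <- numeric(6)
      for (i in 1:6) {
        sp <- sample_specimen(profiles[[gname]],
                              seed = aortamech:::derive_seed(7000 + s, gname, i))
        th[i] <- wall_thickness(sp$geometry)
        fld <- simulate_evg_field(
          list(smc = sp$histology$frac_smc,
               elastin = sp$histology$frac_elastin,
               collagen = sp$histology$frac_collagen),
          seed = aortamech:::derive_seed(7000 + s, gname, i, "evg"))
        fr <- area_fractions(classify_evg_pixels(fld$image))
        smc[i] <- fr$pct_smc; ela[i] <- fr$pct_elastin; col[i] <- fr$pct_collagen
      }
      vals[[gname]] <- list(th = th, smc = smc, ela = ela, col = col)
    }
    flag_flt <- function(field) {
      sch <- scheffe_pairwise(lapply(vals, `[[`, field))
      flt <- sch[sch$group1 == "FLT" | sch$group2 == "FLT", ]
      all(flt$p < 0.05)
    }
    fiber_flag <- function(fd) {
      any(scheffe_pairwise(lapply(vals, `[[`, fd))$p < 0.05)
    }
    flags_thickness[s] <- flag_flt("th")
    flags_smc[s] <- flag_flt("smc")
    flags_ela[s] <- fiber_flag("ela")
    flags_col[s] <- fiber_flag("col")
  }
  expect_gte(mean(flags_thickness), 0.9)
  expect_gte(mean(flags_smc), 0.9)
  expect_lte(mean(flags_ela), 0.1)
  expect_lte(mean(flags_col), 0.1)
})
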