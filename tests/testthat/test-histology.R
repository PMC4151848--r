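solid_image <- function(rgb, size = 32, stain = "EVG") {
  px <- array(0, c(size, size, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  field_image(px, stain = stain)
}

ref_colors <- aortamech:::RENDER_COLORS

test_that("single-class images classify entirely into that class", {
  for (cls in c("smc", "elastin", "collagen")) {
    img <- solid_image(ref_colors[[cls]])
    masks <- classify_evg_pixels(img)
    expect_true(all(masks[[cls]]))
    fr <- area_fractions(masks)
    expect_equal(fr[[paste0("pct_", cls)]], 100)
  }
  expect_error(classify_evg_pixels(solid_image(c(0, 0, 0), stain = "HE")),
               class = "aortamech_wrong_stain")
})

test_that("every pixel belongs to exactly one class", {
  fld <- simulate_evg_field(list(smc = 40, elastin = 30, collagen = 20),
                            seed = 3)
  masks <- classify_evg_pixels(fld$image)
  total <- masks$smc + masks$elastin + masks$collagen + masks$nuclei +
    masks$background
  expect_true(all(total == 1))
})

test_that("elastin reference color survives 10% channel noise", {
  set.seed(31)
  for (i in 1:25) {
    noisy <- ref_colors$elastin * (1 + runif(3, -0.1, 0.1))
    masks <- classify_evg_pixels(solid_image(noisy))
    expect_true(all(masks$elastin))
  }
  # yellow stays in the smooth-muscle class at renderer-level noise
  for (i in 1:25) {
    noisy <- ref_colors$smc * (1 + runif(3, -0.05, 0.05))
    masks <- classify_evg_pixels(solid_image(pmin(noisy, 255)))
    expect_true(all(masks$smc))
  }
})

test_that("area fractions are ratios of pixel counts", {
  m <- matrix(FALSE, 100, 100)
  m[1:25, 1:100] <- TRUE                      # 2500 px of 10000
  masks <- structure(list(smc = m, elastin = !m & FALSE, collagen = m & FALSE,
                          nuclei = m & FALSE, background = !m),
                     class = "component_masks")
  fr <- area_fractions(masks)
  expect_equal(fr$pct_smc, 25.0)
  expect_equal(fr$pct_elastin, 0)
  expect_error(area_fractions(masks, matrix(FALSE, 100, 100)),
               class = "aortamech_degenerate_field")
})

test_that("fractions are invariant under 90-degree rotation", {
  fld <- simulate_evg_field(list(smc = 35, elastin = 30, collagen = 20),
                            seed = 8)
  masks <- classify_evg_pixels(fld$image)
  fr <- area_fractions(masks)
  rot <- function(m) t(m)[, nrow(m):1]
  masks_r <- structure(lapply(masks, rot), class = "component_masks")
  fr_r <- area_fractions(masks_r)
  expect_equal(fr_r, fr, tolerance = 1e-12)
})

test_that("rendered EVG fields are recovered within 2 percentage points", {
  req <- list(smc = 40, elastin = 30, collagen = 20)
  for (seed in 1:5) {
    fld <- simulate_evg_field(req, seed = seed)
    fr <- area_fractions(classify_evg_pixels(fld$image))
    expect_lt(abs(fr$pct_smc - req$smc), 2)
    expect_lt(abs(fr$pct_elastin - req$elastin), 2)
    expect_lt(abs(fr$pct_collagen - req$collagen), 2)
    # painter's own count stays within rasterization of the request
    expect_lt(abs(fld$truth$pct_smc - req$smc), 1)
  }
})

test_that("segmentation is deterministic for identical input", {
  fld <- simulate_evg_field(list(smc = 40, elastin = 30, collagen = 20),
                            seed = 17)
  m1 <- classify_evg_pixels(fld$image)
  m2 <- classify_evg_pixels(fld$image)
  expect_identical(m1, m2)
})

test_that("nucleus segmentation counts rendered nuclei exactly", {
  blank <- solid_image(ref_colors$he_background, size = 64, stain = "HE")
  expect_equal(count_nuclei(segment_nuclei(blank)), 0)
  for (seed in 1:4) {
    fld <- simulate_he_field(150, seed = seed)
    lab <- segment_nuclei(fld$image)
    expect_equal(count_nuclei(lab), fld$count)
  }
  expect_error(segment_nuclei(solid_image(c(0, 0, 0), stain = "EVG")),
               class = "aortamech_wrong_stain")
})

test_that("count is monotone in rendered nucleus number", {
  counts <- vapply(c(20, 80, 150), function(n) {
    fld <- simulate_he_field(n, seed = 41)
    count_nuclei(segment_nuclei(fld$image))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("touching nuclei merge into one component", {
  size <- 40
  px <- array(0, c(size, size, 3))
  for (ch in 1:3) px[, , ch] <- ref_colors$he_background[ch]
  # two overlapping discs
  for (c0 in list(c(15, 18), c(15, 26))) {
    for (x in 1:size) for (y in 1:size) {
      if ((x - c0[1])^2 + (y - c0[2])^2 <= 36) {
        px[y, x, ] <- ref_colors$nucleus
      }
    }
  }
  img <- field_image(px, stain = "HE")
  expect_equal(count_nuclei(segment_nuclei(img)), 1)
})

test_that("diagonally touching blobs count as one (8-connectivity)", {
  size <- 30
  px <- array(0, c(size, size, 3))
  for (ch in 1:3) px[, , ch] <- ref_colors$he_background[ch]
  # two 6x6 squares meeting only at a corner
  px[5:10, 5:10, 1] <- ref_colors$nucleus[1]
  px[5:10, 5:10, 2] <- ref_colors$nucleus[2]
  px[5:10, 5:10, 3] <- ref_colors$nucleus[3]
  px[11:16, 11:16, 1] <- ref_colors$nucleus[1]
  px[11:16, 11:16, 2] <- ref_colors$nucleus[2]
  px[11:16, 11:16, 3] <- ref_colors$nucleus[3]
  img <- field_image(px, stain = "HE")
  expect_equal(count_nuclei(segment_nuclei(img, min_area_px = 10)), 1)
})

test_that("field averaging is a plain mean, invariant to order", {
  counts <- list(130, 135, 138)
  s <- summarize_fields(counts, "HE")
  expect_equal(s$nuclei_count, mean(c(130, 135, 138)))
  expect_equal(s$n_fields, 3)
  s_perm <- summarize_fields(counts[c(3, 1, 2)], "HE")
  expect_equal(s_perm$nuclei_count, s$nuclei_count)
  one <- list(list(pct_smc = 40, pct_elastin = 30, pct_collagen = 20))
  expect_warning(s1 <- summarize_fields(one, "EVG"), "conventional")
  expect_equal(s1$pct_smc, 40)
  expect_error(summarize_fields(list(), "HE"),
               class = "aortamech_invalid_input")
})

test_that("field images round-trip through PNG", {
  fld <- simulate_evg_field(list(smc = 40, elastin = 30, collagen = 20),
                            size = 64, seed = 2)
  path <- withr::local_tempfile(fileext = ".png")
  write_field_png(fld$image, path)
  back <- read_field_png(path, "EVG")
  expect_equal(back$pixels, fld$image$pixels)
})
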