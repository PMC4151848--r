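# Histomorphometry: HSV color segmentation of EVG-stained fields into
# smooth muscle / elastin / collagen, nucleus segmentation and counting in
# HE-stained fields, and per-specimen field averaging.

#' Microscopic field image
#'
#' Wraps one RGB field sampled from a stained section, with its stain and
#' pixel scale. Pixels are stored as a height x width x 3 numeric array on
#' the 0..255 scale (8-bit).
#'
#' @param pixels height x width x 3 array, values in 0..255.
#' @param stain `"EVG"` (Elastica-van Gieson: elastin black, collagen red,
#'   smooth muscle yellow) or `"HE"` (hematoxylin-eosin: nuclei blue-violet).
#' @param microns_per_pixel Pixel scale, micrometres.
#' @param field_id Identifier for the field.
#' @return An object of class `field_image`.
#' @export
field_image <- function(pixels, stain = c("EVG", "HE"),
                        microns_per_pixel = 1, field_id = "field") {
  stain <- match.arg(stain)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_aorta("aortamech_invalid_image",
               "`pixels` must be a height x width x 3 array")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop_aorta("aortamech_invalid_image", "pixel values must lie in 0..255")
  }
  if (microns_per_pixel <= 0) {
    stop_aorta("aortamech_invalid_image", "`microns_per_pixel` must be positive")
  }
  structure(list(pixels = pixels, stain = stain,
                 microns_per_pixel = microns_per_pixel, field_id = field_id),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Field image [%s] %s: %d x %d px at %.2f um/px\n",
              x$stain, x$field_id, d[1], d[2], x$microns_per_pixel))
  invisible(x)
}

#' Read / write a field image as PNG
#'
#' @param path PNG path.
#' @param stain,microns_per_pixel,field_id Passed to [field_image()].
#' @return A [field_image()] (read) or `path` invisibly (write).
#' @export
read_field_png <- function(path, stain, microns_per_pixel = 1,
                           field_id = basename(path)) {
  if (!file.exists(path)) {
    stop_aorta("aortamech_io", sprintf("image not found: %s", path))
  }
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L && dim(arr)[3] >= 3L) arr <- arr[, , 1:3]
  field_image(round(arr * 255), stain = stain,
              microns_per_pixel = microns_per_pixel, field_id = field_id)
}

#' @rdname read_field_png
#' @param image A [field_image()].
#' @export
write_field_png <- function(image, path) {
  stopifnot(inherits(image, "field_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Default HSV thresholds for stain segmentation
#'
#' Hue in degrees (0..360), saturation ("purity") and value ("intensity")
#' in 0..1. EVG: elastin is near-black (low value), collagen sits in the
#' red hue band, smooth muscle in the yellow band; near-black pixels are
#' classified as elastin before any hue test because hue is unstable at low
#' intensity. HE nuclei occupy the blue-violet band.
#'
#' @return A named list of threshold settings; override any element and
#'   pass the result to the segmentation functions.
#' @export
default_color_thresholds <- function() {
  list(
    elastin_value_max = 0.25,
    collagen_hue = c(330, 20),   # wraps through 0
    collagen_sat_min = 0.3,
    smc_hue = c(40, 70),
    smc_sat_min = 0.2,
    nuclei_hue = c(200, 290),
    nuclei_sat_min = 0.25
  )
}

# HSV planes (h in degrees, s, v in 0..1) for a field image.
image_hsv <- function(image) {
  d <- dim(image$pixels)
  rgb <- matrix(aperm(image$pixels, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

hue_in_band <- function(h, band) {
  if (band[1] <= band[2]) h >= band[1] & h <= band[2]
  else h >= band[1] | h <= band[2]   # band wrapping through 0 degrees
}

#' Classify EVG pixels into wall components
#'
#' Assigns every pixel of an EVG-stained field to exactly one of elastin,
#' collagen, smooth muscle or background by hue/saturation/value rules
#' (see [default_color_thresholds()]). Precedence: the elastin intensity
#' test wins over the hue tests; collagen is tested before smooth muscle.
#'
#' @param image A [field_image()] with stain `"EVG"`.
#' @param thresholds Threshold list as from [default_color_thresholds()].
#' @return A list of class `component_masks` with mutually exclusive
#'   logical matrices `smc`, `elastin`, `collagen`, `nuclei` (all `FALSE`
#'   for EVG) and `background`.
#' @export
classify_evg_pixels <- function(image, thresholds = default_color_thresholds()) {
  stopifnot(inherits(image, "field_image"))
  if (image$stain != "EVG") {
    stop_aorta("aortamech_wrong_stain",
               sprintf("EVG classification applied to a %s image", image$stain))
  }
  hsv <- image_hsv(image)
  elastin <- hsv$v < thresholds$elastin_value_max
  collagen <- !elastin & hue_in_band(hsv$h, thresholds$collagen_hue) &
    hsv$s > thresholds$collagen_sat_min
  smc <- !elastin & !collagen & hue_in_band(hsv$h, thresholds$smc_hue) &
    hsv$s > thresholds$smc_sat_min
  background <- !(elastin | collagen | smc)
  structure(list(smc = smc, elastin = elastin, collagen = collagen,
                 nuclei = matrix(FALSE, nrow(elastin), ncol(elastin)),
                 background = background),
            class = "component_masks")
}

#' Component area fractions of the sectional area
#'
#' Each component's area as a percentage of the entire sectional area
#' (`tissue_extent`); by default the whole frame.
#'
#' @param masks A `component_masks` list from [classify_evg_pixels()].
#' @param tissue_extent Logical matrix marking the sectional area.
#' @return A list with `pct_smc`, `pct_elastin`, `pct_collagen`.
#' @export
area_fractions <- function(masks, tissue_extent = NULL) {
  stopifnot(inherits(masks, "component_masks"))
  if (is.null(tissue_extent)) {
    tissue_extent <- matrix(TRUE, nrow(masks$smc), ncol(masks$smc))
  }
  total <- sum(tissue_extent)
  if (total == 0) {
    stop_aorta("aortamech_degenerate_field", "empty tissue extent")
  }
  list(
    pct_smc = 100 * sum(masks$smc & tissue_extent) / total,
    pct_elastin = 100 * sum(masks$elastin & tissue_extent) / total,
    pct_collagen = 100 * sum(masks$collagen & tissue_extent) / total
  )
}

# Merge 4-connected labels that touch diagonally, giving 8-connectivity.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  nlab <- max(lab)
  if (nlab == 0 || nrow(pairs) == 0) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Segment nuclei in an HE-stained field
#'
#' Thresholds the blue-violet hue band, labels 8-connected components and
#' discards components smaller than `min_area_px`. Touching nuclei merge
#' into a single component (no watershed splitting), mirroring frame-level
#' counting of visibly distinct nuclei.
#'
#' @param image A [field_image()] with stain `"HE"`.
#' @param thresholds Threshold list as from [default_color_thresholds()].
#' @param min_area_px Minimum component area in pixels.
#' @return An integer label matrix (0 = background), class `nuclei_labels`.
#' @export
segment_nuclei <- function(image, thresholds = default_color_thresholds(),
                           min_area_px = 30) {
  stopifnot(inherits(image, "field_image"))
  if (image$stain != "HE") {
    stop_aorta("aortamech_wrong_stain",
               sprintf("nucleus segmentation applied to a %s image", image$stain))
  }
  hsv <- image_hsv(image)
  mask <- hue_in_band(hsv$h, thresholds$nuclei_hue) &
    hsv$s > thresholds$nuclei_sat_min
  lab <- merge_diagonal_labels(EBImage::bwlabel(mask * 1))
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_area_px)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  structure(lab, class = c("nuclei_labels", class(lab)))
}

#' Count segmented nuclei
#'
#' @param labels Label matrix from [segment_nuclei()].
#' @return Number of distinct nuclei.
#' @export
count_nuclei <- function(labels) {
  max(0L, max(unclass(labels)))
}

#' Average histomorphometry over microscopic fields
#'
#' Arithmetic mean of each per-field quantity across the fields measured
#' for one specimen. Warns when fewer fields are supplied than the
#' conventional minimum (2 for EVG fractions, 3 for HE counts).
#'
#' @param fields A list of per-field results: for EVG, lists with
#'   `pct_smc`, `pct_elastin`, `pct_collagen`; for HE, numeric nucleus
#'   counts or lists with `nuclei_count`.
#' @param stain `"EVG"` or `"HE"`.
#' @return A list of class `composition_summary` with the averaged
#'   quantities and `n_fields`.
#' @export
summarize_fields <- function(fields, stain = c("EVG", "HE")) {
  stain <- match.arg(stain)
  if (!length(fields)) {
    stop_aorta("aortamech_invalid_input", "no fields supplied")
  }
  n <- length(fields)
  minimum <- if (stain == "EVG") 2L else 3L
  if (n < minimum) {
    warning(sprintf("%d %s field(s) supplied; %d are conventional",
                    n, stain, minimum))
  }
  out <- if (stain == "EVG") {
    list(
      pct_smc = mean(vapply(fields, function(f) f$pct_smc, numeric(1))),
      pct_elastin = mean(vapply(fields, function(f) f$pct_elastin, numeric(1))),
      pct_collagen = mean(vapply(fields, function(f) f$pct_collagen, numeric(1))),
      nuclei_count = NA_real_, n_fields = n
    )
  } else {
    counts <- vapply(fields, function(f) {
      if (is.list(f)) f$nuclei_count else as.numeric(f)
    }, numeric(1))
    list(pct_smc = NA_real_, pct_elastin = NA_real_, pct_collagen = NA_real_,
         nuclei_count = mean(counts), n_fields = n)
  }
  structure(out, class = "composition_summary")
}
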