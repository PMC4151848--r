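# Study-level orchestration: run the trace and image analyses over a data
# bundle, assemble per-specimen tables, compare groups and print a
# Table-1-style report.

#' Per-pup reference measurements packaged with the package
#'
#' Body weight, aorta weight per unit luminal area, wall cross-sectional
#' area and internal diameter for the six pups of each of the three study
#' arms, as a long data.frame (`variable`, `group`, `pup`, `value`). These
#' are the printed per-animal values of the flight study's summary table
#' and let the statistical surface be exercised without any synthesis.
#'
#' @return A data.frame with 72 rows.
#' @export
reference_pup_data <- function() {
  path <- system.file("extdata", "table1_pups.csv", package = "aortamech")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Group statistics for every variable of a long measurement table
#'
#' @param data Long data.frame with columns `variable`, `group`, `value`.
#' @return Named list of [group_compare()] results, one per variable.
#' @export
compare_all_variables <- function(data) {
  stopifnot(all(c("variable", "group", "value") %in% names(data)))
  vars <- unique(data$variable)
  out <- lapply(vars, function(v) {
    d <- data[data$variable == v & !is.na(data$value), ]
    counts <- table(d$group)
    if (length(counts) < 2L || any(counts < 2L)) return(NULL)
    group_compare(d$value, d$group, variable = v)
  })
  names(out) <- vars
  out[!vapply(out, is.null, logical(1))]
}

#' Analyze a study bundle end to end
#'
#' Reads the metadata table, runs the tensile-trace analysis
#' ([rheology_summary()]) for every specimen with traces, runs the image
#' analysis ([classify_evg_pixels()], [segment_nuclei()]) for every
#' specimen with field images, and computes group statistics for every
#' measured variable. Missing images degrade gracefully to a
#' rheology-only report with a warning; a malformed specimen aborts with a
#' listing of the affected specimens.
#'
#' @param dir Bundle directory (layout as written by [generate_study()]).
#' @param out_dir Optional directory for report files; when given, a
#'   per-specimen CSV (`specimens.csv`), a per-variable JSON
#'   (`group_stats.json`) and the formatted summary (`report.txt`) are
#'   written there.
#' @param thresholds Color thresholds for the image stage.
#' @return An object of class `study_report`: list with `specimens` (wide
#'   per-specimen data.frame), `comparisons` (per-variable
#'   [group_compare()] results) and `n_groups`.
#' @export
analyze_study <- function(dir, out_dir = NULL,
                          thresholds = default_color_thresholds()) {
  meta <- read_specimen_metadata(file.path(dir, "metadata.csv"))
  if (!nrow(meta)) {
    stop_aorta("aortamech_invalid_input", "metadata table is empty")
  }
  errors <- character(0)
  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sid <- meta$specimen_id[i]
    row <- tryCatch(
      analyze_one_specimen(dir, meta[i, ], thresholds),
      error = function(e) {
        errors <<- c(errors, sprintf("%s: %s", sid, conditionMessage(e)))
        NULL
      })
    rows[[i]] <- row
  }
  if (length(errors)) {
    stop_aorta("aortamech_specimen_errors",
               paste(c("specimen analysis failed:", errors), collapse = "\n  "))
  }
  specimens <- do.call(rbind, rows)
  num_vars <- setdiff(names(specimens), c("specimen_id", "group"))
  long <- do.call(rbind, lapply(num_vars, function(v) {
    data.frame(variable = v, group = specimens$group,
               value = specimens[[v]], stringsAsFactors = FALSE)
  }))
  comparisons <- compare_all_variables(long)
  report <- structure(list(specimens = specimens, comparisons = comparisons,
                           n_groups = length(unique(meta$group))),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

analyze_one_specimen <- function(dir, meta_row, thresholds) {
  sid <- meta_row$specimen_id
  geometry <- geometry_from_metadata(meta_row)
  tdir <- file.path(dir, "traces", sid)
  rheo <- if (dir.exists(tdir)) {
    traces <- list()
    for (ph in c("ramp_load", "step_hold", "recovery_probe")) {
      f <- file.path(tdir, paste0(ph, ".csv"))
      if (file.exists(f)) traces[[ph]] <- read_trace_csv(f, phase = ph)
    }
    if (is.null(traces$ramp_load)) {
      stop_aorta("aortamech_io", sprintf("no ramp_load trace for %s", sid))
    }
    rheology_summary(traces, geometry)
  } else {
    # geometry-only record (e.g. tabulated studies without raw traces)
    wg <- wall_geometry_summary(geometry)
    data.frame(E_025 = NA_real_, E_050 = NA_real_, E_075 = NA_real_,
               relaxation_strength = NA_real_, plastic_deformation = NA_real_,
               thickness_um = wall_thickness(geometry),
               internal_radius_mm = wg$internal_radius,
               internal_diameter_mm = wg$internal_diameter,
               cross_section_mm2 = wg$cross_section_area,
               weight_per_area_mg_cm2 = wg$weight_per_area)
  }
  idir <- file.path(dir, "images", sid)
  comp <- if (dir.exists(idir)) {
    evg_files <- list.files(idir, pattern = "^EVG_.*\\.png$", full.names = TRUE)
    he_files <- list.files(idir, pattern = "^HE_.*\\.png$", full.names = TRUE)
    evg <- lapply(evg_files, function(f) {
      area_fractions(classify_evg_pixels(read_field_png(f, "EVG"), thresholds))
    })
    he <- lapply(he_files, function(f) {
      count_nuclei(segment_nuclei(read_field_png(f, "HE"), thresholds))
    })
    evg_sum <- if (length(evg)) {
      suppressWarnings(summarize_fields(evg, "EVG"))
    } else NULL
    he_sum <- if (length(he)) {
      suppressWarnings(summarize_fields(he, "HE"))
    } else NULL
    data.frame(
      pct_smc = evg_sum$pct_smc %||% NA_real_,
      pct_elastin = evg_sum$pct_elastin %||% NA_real_,
      pct_collagen = evg_sum$pct_collagen %||% NA_real_,
      nuclei_count = he_sum$nuclei_count %||% NA_real_
    )
  } else {
    data.frame(pct_smc = NA_real_, pct_elastin = NA_real_,
               pct_collagen = NA_real_, nuclei_count = NA_real_)
  }
  cbind(data.frame(specimen_id = sid, group = meta_row$group,
                   body_weight_g = meta_row$body_weight_g,
                   stringsAsFactors = FALSE),
        rheo, comp)
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$specimens, file.path(out_dir, "specimens.csv"),
                   row.names = FALSE)
  stats_json <- lapply(report$comparisons, function(gc) {
    list(variable = gc$variable,
         groups = gc$summary,
         anova = gc$anova[c("F", "df_between", "df_within", "p")],
         scheffe = gc$scheffe)
  })
  jsonlite::write_json(stats_json, file.path(out_dir, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(report_table(report), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Format a study report as a fixed-width summary table
#'
#' One row per variable and group with mean, SE and n; significance stars
#' from the Scheffe comparisons are appended to the mean, with `a`
#' marking FLT-versus-AGC and `b` FLT-versus-VIV contrasts, as in the
#' conventional group-summary layout.
#'
#' @param report A `study_report` from [analyze_study()].
#' @return Character vector of report lines (also works with `writeLines`).
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "study_report"))
  lines <- c(sprintf("%-28s %-6s %10s %8s %4s  %s",
                     "variable", "group", "mean", "SE", "n", "signif"))
  for (gc in report$comparisons) {
    sch <- gc$scheffe
    for (r in seq_len(nrow(gc$summary))) {
      g <- gc$summary$group[r]
      marks <- character(0)
      if (g == "FLT") {
        star_a <- sch[(sch$group1 == "FLT" & sch$group2 == "AGC") |
                        (sch$group2 == "FLT" & sch$group1 == "AGC"), "stars"]
        star_b <- sch[(sch$group1 == "FLT" & sch$group2 == "VIV") |
                        (sch$group2 == "FLT" & sch$group1 == "VIV"), "stars"]
        marks <- c(
          if (length(star_a) && star_a[1] != "ns") paste0(star_a[1], "a"),
          if (length(star_b) && star_b[1] != "ns") paste0(star_b[1], "b")
        )
      }
      lines <- c(lines, sprintf(
        "%-28s %-6s %10.3f %8.3f %4d  %s",
        gc$variable, g, gc$summary$mean[r], gc$summary$se[r],
        gc$summary$n[r], paste(marks, collapse = ",")))
    }
  }
  lines
}

#' @export
print.study_report <- function(x, ...) {
  writeLines(report_table(x))
  invisible(x)
}

#' Analyze the packaged reference pup table
#'
#' Runs the full statistical surface (mean +/- SE, ANOVA, Scheffe) over
#' the packaged per-pup reference measurements.
#'
#' @return Named list of [group_compare()] results.
#' @export
analyze_reference_pups <- function() {
  compare_all_variables(reference_pup_data())
}
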