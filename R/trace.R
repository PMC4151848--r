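#' Sampled tensile-test trace for one protocol phase
#'
#' A trace is the instrument record of one phase of the two-phase tensile
#' protocol: the slow loading ramp (`ramp_load`), the return to initial
#' length (`unload`), the slow re-stretch used to probe plastic deformation
#' after the 5-minute recovery (`recovery_probe`), and the rapid stretch to
#' 50% strain followed by a 5-minute hold (`step_hold`).
#'
#' @param time Sample times in seconds, strictly increasing.
#' @param displacement Crosshead displacement from the initial length, mm.
#' @param force Tensile force, newtons.
#' @param phase One of `"ramp_load"`, `"unload"`, `"recovery_probe"`,
#'   `"step_hold"`.
#' @return An object of class `tensile_trace`.
#' @export
tensile_trace <- function(time, displacement, force,
                          phase = c("ramp_load", "unload", "recovery_probe",
                                    "step_hold")) {
  phase <- match.arg(phase)
  n <- length(time)
  if (n < 2L || length(displacement) != n || length(force) != n) {
    stop_aorta("aortamech_invalid_trace",
               "time, displacement and force must have equal length >= 2")
  }
  if (any(diff(time) <= 0)) {
    stop_aorta("aortamech_invalid_trace", "time must be strictly increasing")
  }
  if (phase %in% c("ramp_load", "step_hold") && any(displacement < -1e-9)) {
    stop_aorta("aortamech_invalid_trace",
               sprintf("displacement must be non-negative during %s", phase))
  }
  structure(
    list(time = as.numeric(time), displacement = as.numeric(displacement),
         force = as.numeric(force), phase = phase),
    class = "tensile_trace"
  )
}

#' @export
print.tensile_trace <- function(x, ...) {
  cat(sprintf("Tensile trace [%s]: %d samples over %.1f s, peak force %.4g N\n",
              x$phase, length(x$time), diff(range(x$time)), max(x$force)))
  invisible(x)
}

#' Read a tensile trace from delimited text
#'
#' Trace files carry columns `time_s, displacement_mm, force_N` (header
#' required, `#` comment lines ignored, comma or tab delimited). A file may
#' hold one phase, named via `phase`, or several phases distinguished by a
#' `phase` column, in which case a named list of traces is returned.
#'
#' @param path Path to the trace file.
#' @param phase Phase label to assign when the file has no `phase` column.
#' @return A [tensile_trace()] or a named list of them.
#' @export
read_trace_csv <- function(path, phase = NULL) {
  if (!file.exists(path)) {
    stop_aorta("aortamech_io", sprintf("trace file not found: %s", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "displacement_mm", "force_N")
  if (!all(need %in% names(df))) {
    stop_aorta("aortamech_io",
               sprintf("trace file %s lacks columns %s", path,
                       paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if ("phase" %in% names(df)) {
    phases <- split(df, df$phase)
    return(lapply(phases, function(d) {
      tensile_trace(d$time_s, d$displacement_mm, d$force_N,
                    phase = d$phase[1])
    }))
  }
  if (is.null(phase)) {
    stop_aorta("aortamech_io",
               "file has no `phase` column; supply `phase=` explicitly")
  }
  tensile_trace(df$time_s, df$displacement_mm, df$force_N, phase = phase)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 20L)
  first <- first[!startsWith(first, "#")][1]
  if (grepl("\t", first)) "\t" else ","
}

#' Write a tensile trace to CSV
#'
#' @param trace A [tensile_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "tensile_trace"))
  df <- data.frame(time_s = trace$time, displacement_mm = trace$displacement,
                   force_N = trace$force)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the specimen metadata table
#'
#' Expects columns `specimen_id, group, L0_cm, width_cm, weight_g,
#' circ_length_cm, body_weight_g`; `group` is one of FLT (spaceflight),
#' AGC (asynchronous ground control), VIV (vivarium control).
#'
#' @param path Path to the metadata CSV.
#' @return A data.frame, one row per specimen.
#' @export
read_specimen_metadata <- function(path) {
  if (!file.exists(path)) {
    stop_aorta("aortamech_io", sprintf("metadata file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("specimen_id", "group", "L0_cm", "width_cm", "weight_g",
            "circ_length_cm", "body_weight_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_aorta("aortamech_io",
               sprintf("metadata lacks columns: %s", paste(miss, collapse = ", ")))
  }
  df
}

# Geometry object for one metadata row.
geometry_from_metadata <- function(row) {
  strip_geometry(L0 = row$L0_cm, width = row$width_cm, weight = row$weight_g,
                 circ_length = row$circ_length_cm)
}
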