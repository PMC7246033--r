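# Chromatogram traces and their on-disk format.
#
# One trace = one HPLC run of one immunoprecipitated sample: a strictly
# increasing elution-time grid (minutes, <= 30 min at 0.4 mL/min) and the UV
# absorbance read at 280 nm (mAU). Files are plain text: `# key: value`
# header lines for identity/metadata, then two comma-separated columns.

#' Construct a chromatogram trace
#'
#' @param time_min Strictly increasing elution times in minutes (0--30).
#' @param absorbance_mAU UV absorbance at 280 nm, in mAU; same length as
#'   `time_min`, all values finite.
#' @param antibody Antibody name (a panel entry), or [NEG_CONTROL] for the
#'   negative-control channel.
#' @param arm One of `"treated"`, `"control"`, `"negative_control"`.
#' @param timepoint_h Culture time in hours (12, 24 or 48); `NA` for the
#'   negative-control channel.
#' @param replicate Positive integer replicate index.
#' @param sample_id Free-text sample identifier; defaults to a composite of
#'   the identity fields.
#' @param wavelength_nm,flow_mL_min Detector wavelength and column flow rate
#'   (defaults 280 nm, 0.4 mL/min).
#' @return An object of class `hplc_trace`: a list with the identity fields,
#'   the metadata, and `$data`, a tibble of `time_min` and `absorbance_mAU`.
#' @examples
#' tr <- hplc_trace(seq(0, 30, by = 0.5), rep(1, 61),
#'   antibody = "Ki-67", arm = "treated", timepoint_h = 24, replicate = 1
#' )
#' @export
hplc_trace <- function(time_min, absorbance_mAU, antibody, arm,
                       timepoint_h = NA_real_, replicate = 1L,
                       sample_id = NULL, wavelength_nm = 280, flow_mL_min = 0.4) {
  time_min <- as.numeric(time_min)
  absorbance_mAU <- as.numeric(absorbance_mAU)
  arm <- match.arg(arm, ARM_LEVELS)
  if (length(time_min) < 2 || length(absorbance_mAU) < 2) {
    stop_iphplc("a trace needs at least 2 samples (got %d)", length(time_min))
  }
  if (length(time_min) != length(absorbance_mAU)) {
    stop_iphplc(
      "time and absorbance lengths differ (%d vs %d)",
      length(time_min), length(absorbance_mAU)
    )
  }
  if (any(!is.finite(time_min)) || any(diff(time_min) <= 0)) {
    stop_iphplc("trace time grid must be finite and strictly increasing")
  }
  if (time_min[1] < 0 || (time_min[length(time_min)] - time_min[1]) > 30 + 1e-9) {
    stop_iphplc("trace duration must lie within the 30-minute run")
  }
  if (any(!is.finite(absorbance_mAU))) {
    stop_iphplc("trace absorbance values must all be finite")
  }
  if (!is.character(antibody) || length(antibody) != 1L || !nzchar(antibody)) {
    stop_iphplc("`antibody` must be a non-empty string")
  }
  if (!is.na(timepoint_h)) {
    timepoint_h <- as.numeric(timepoint_h)
    assert_finite_scalar(timepoint_h, "timepoint_h")
  }
  if (!is_count(replicate) || replicate < 1) {
    stop_iphplc("`replicate` must be a positive integer")
  }
  if (is.null(sample_id)) {
    sample_id <- paste(antibody, arm,
      ifelse(is.na(timepoint_h), "NA", timepoint_h), replicate,
      sep = "_"
    )
  }
  structure(
    list(
      sample_id = sample_id,
      antibody = antibody,
      arm = arm,
      timepoint_h = as.numeric(timepoint_h),
      replicate = as.integer(replicate),
      wavelength_nm = wavelength_nm,
      flow_mL_min = flow_mL_min,
      data = tibble::tibble(time_min = time_min, absorbance_mAU = absorbance_mAU)
    ),
    class = "hplc_trace"
  )
}

#' @export
print.hplc_trace <- function(x, ...) {
  cat(sprintf(
    "<hplc_trace> %s [%s%s, replicate %d]: %d points over %.2f-%.2f min, %g nm\n",
    x$antibody, x$arm,
    if (is.na(x$timepoint_h)) "" else sprintf(", %g h", x$timepoint_h),
    x$replicate, nrow(x$data),
    min(x$data$time_min), max(x$data$time_min), x$wavelength_nm
  ))
  invisible(x)
}

#' @export
format.hplc_trace <- function(x, ...) {
  sprintf("<hplc_trace %s/%s>", x$antibody, x$arm)
}

trace_header_fields <- c(
  "sample_id", "antibody", "arm", "timepoint_h", "replicate",
  "wavelength_nm", "flow_mL_min"
)

#' Write a chromatogram trace file
#'
#' Plain-text format: `# key: value` header lines for the identity and
#' metadata fields, a `time_min,absorbance_mAU` column header, then one CSV
#' row per point (decimal point, C locale). Numeric round-trip error through
#' [read_trace()] is below 1e-6 relative.
#'
#' @param trace An `hplc_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "hplc_trace")) stop_iphplc("`trace` must be an hplc_trace")
  header <- vapply(trace_header_fields, function(f) {
    sprintf("# %s: %s", f, as.character(trace[[f]]))
  }, character(1))
  body <- sprintf(
    "%.10g,%.10g",
    trace$data$time_min, trace$data$absorbance_mAU
  )
  writeLines(c(header, "time_min,absorbance_mAU", body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a chromatogram trace file
#'
#' Parses the format written by [write_trace()]: comment/header lines
#' starting with `#` (of which `# key: value` pairs populate identity and
#' metadata), then two delimited numeric columns interpreted as minutes and
#' mAU regardless of column naming. The result is validated like
#' [hplc_trace()].
#'
#' @param path Trace file path.
#' @return A validated `hplc_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_iphplc("trace file does not exist: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!is_comment]
  body <- body[nzchar(trimws(body))]
  if (length(body) > 0 && grepl("[A-Za-z]", body[1])) body <- body[-1] # column header
  if (length(body) < 2) stop_iphplc("trace file %s has fewer than 2 data rows", path)
  parts <- strsplit(body, "[,;\t]")
  n_fields <- lengths(parts)
  if (any(n_fields < 2)) {
    stop_iphplc("trace file %s: malformed data row %d", path, which(n_fields < 2)[1])
  }
  time_min <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  absorbance <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (any(is.na(time_min)) || any(is.na(absorbance))) {
    stop_iphplc("trace file %s contains non-numeric data values", path)
  }
  for (f in c("antibody", "arm")) {
    if (is.null(meta[[f]])) stop_iphplc("trace file %s is missing identity field '%s'", path, f)
  }
  tp <- meta$timepoint_h
  tp <- if (is.null(tp) || tp %in% c("NA", "")) NA_real_ else as.numeric(tp)
  hplc_trace(
    time_min = time_min,
    absorbance_mAU = absorbance,
    antibody = meta$antibody,
    arm = meta$arm,
    timepoint_h = tp,
    replicate = as.integer(meta$replicate %||% 1L),
    sample_id = meta$sample_id,
    wavelength_nm = as.numeric(meta$wavelength_nm %||% 280),
    flow_mL_min = as.numeric(meta$flow_mL_min %||% 0.4)
  )
}

#' Read a cohort manifest
#'
#' A manifest lists one trace file per (antibody, arm, timepoint, replicate):
#' CSV with columns `path, sample_id, antibody, arm, timepoint_h, replicate`.
#' Relative `path` entries are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return Tibble of the manifest rows with resolved paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_iphplc("manifest does not exist: %s", path)
  mf <- readr::read_csv(
    path,
    col_types = readr::cols(
      path = readr::col_character(),
      sample_id = readr::col_character(),
      antibody = readr::col_character(),
      arm = readr::col_character(),
      timepoint_h = readr::col_double(),
      replicate = readr::col_integer()
    ),
    progress = FALSE
  )
  bad <- setdiff(unique(mf$arm), ARM_LEVELS)
  if (length(bad) > 0) stop_iphplc("manifest contains unknown arm(s): %s", paste(bad, collapse = ", "))
  base <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", mf$path)
  mf$path[rel] <- file.path(base, mf$path[rel])
  mf
}

#' Plot a chromatogram trace
#'
#' @param object An `hplc_trace`.
#' @param ... Unused.
#' @return A ggplot of absorbance (mAU) against elution time (min).
#' @method autoplot hplc_trace
#' @export
autoplot.hplc_trace <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_min, y = .data$absorbance_mAU)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Elution time (min)", y = "Absorbance at 280 nm (mAU)",
      title = object$sample_id
    ) +
    ggplot2::theme_minimal()
}
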