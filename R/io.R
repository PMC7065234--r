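#' Read a mass spectrum
#'
#' Reads either two-column whitespace/tab-delimited text (m/z, intensity;
#' `#` comment lines and an optional header line are skipped) or an mzML file
#' (first MS1 scan, via the mzR Bioconductor package). The result is validated:
#' strictly increasing m/z, non-negative intensities.
#'
#' @param path File path.
#' @param format `"two_column"` or `"mzML"`.
#' @return A [mass_spectrum()].
#' @export
read_spectrum <- function(path, format = c("two_column", "mzML")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_input(sprintf("Spectrum file does not exist: %s", path))
  }
  if (format == "mzML") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      abort_input("Reading mzML requires the mzR package.")
    }
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle), add = TRUE)
    if (length(mzR::header(handle)$seqNum) == 0) {
      abort_input(sprintf("mzML file holds no spectra: %s", path))
    }
    p <- mzR::peaks(handle, 1)
    return(mass_spectrum(p[, 1], p[, 2]))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    abort_input(sprintf("Spectrum file is empty: %s", path))
  }
  fields <- strsplit(trimws(lines), "[\t ,]+")
  # tolerate a single header line of non-numeric column names
  first_numeric <- suppressWarnings(as.numeric(fields[[1]][1]))
  if (is.na(first_numeric)) {
    fields <- fields[-1]
    line_no <- line_no[-1]
    if (length(fields) == 0) {
      abort_input(sprintf("Spectrum file has a header but no data: %s", path))
    }
  }
  bad_n <- which(lengths(fields) < 2)
  if (length(bad_n) > 0) {
    abort_input(sprintf("Line %d of %s has fewer than 2 columns.",
                        line_no[bad_n[1]], path))
  }
  mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1)))
  intensity <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  bad <- which(is.na(mz) | is.na(intensity))
  if (length(bad) > 0) {
    abort_input(sprintf("Line %d of %s is not numeric.", line_no[bad[1]], path))
  }
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    i <- which(diff(mz) <= 0)[1] + 1L
    abort_input(sprintf("m/z not strictly increasing at line %d of %s.",
                        line_no[i], path))
  }
  if (any(intensity < 0)) {
    i <- which(intensity < 0)[1]
    abort_input(sprintf("Negative intensity at line %d of %s.",
                        line_no[i], path))
  }
  mass_spectrum(mz, intensity)
}

#' Write a mass spectrum
#'
#' Writes two-column tab-delimited text (m/z, intensity) or a minimal
#' single-scan mzML file (via mzR).
#'
#' @param spectrum A [mass_spectrum()].
#' @param path Output path.
#' @param format `"two_column"` or `"mzML"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("two_column", "mzML")) {
  format <- match.arg(format)
  if (format == "two_column") {
    readr::write_tsv(spectrum[, c("mz", "intensity")], path, col_names = FALSE)
    return(invisible(path))
  }
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort_input("Writing mzML requires the mzR package.")
  }
  mz <- spectrum$mz
  int <- spectrum$intensity
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = length(mz), totIonCurrent = sum(int), retentionTime = 0,
    basePeakMZ = mz[which.max(int)], basePeakIntensity = max(int),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(mz), highMZ = max(mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_
  )
  mzR::writeMSData(list(cbind(mz, int)), file = path, header = hdr)
  invisible(path)
}

#' Read contact/binding traces from CSV
#'
#' Expects columns `frame`, `site_id`, `time_ns`, and exactly one of `state`
#' (0/1) or `distance_nm`. Frame spacing must be uniform within every site
#' (missing frames surface as non-uniform spacing and are rejected, naming the
#' offending site).
#'
#' @param path CSV path.
#' @return A `contact_trace` tibble.
#' @export
read_contact_table <- function(path) {
  if (!file.exists(path)) {
    abort_input(sprintf("Contact table does not exist: %s", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("frame", "site_id", "time_ns")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_input(sprintf("Contact table lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  has_state <- "state" %in% names(df)
  has_dist <- "distance_nm" %in% names(df)
  if (has_state && has_dist) {
    abort_input("Contact table mixes `state` and `distance_nm`; use one.")
  }
  if (!has_state && !has_dist) {
    abort_input("Contact table needs a `state` or `distance_nm` column.")
  }
  if (has_state && !all(df$state %in% c(0, 1))) {
    abort_input("`state` must be binary (0/1).")
  }
  if (has_dist && any(df$distance_nm < 0)) {
    abort_input("`distance_nm` must be non-negative.")
  }
  df <- arrange(df, .data$site_id, .data$frame)
  dt <- NULL
  for (sid in unique(df$site_id)) {
    tt <- df$time_ns[df$site_id == sid]
    d <- diff(tt)
    if (length(d) == 0 || any(d <= 0) || max(abs(d - d[1])) > 1e-9 * d[1] + 1e-12) {
      abort_input(sprintf("Non-uniform frame spacing for site '%s' in %s.",
                          sid, path))
    }
    if (is.null(dt)) dt <- d[1]
    else if (abs(dt - d[1]) > 1e-9 * dt) {
      abort_input(sprintf("Site '%s' uses a different frame spacing.", sid))
    }
  }
  new_contact_trace(df, dt_ns = dt)
}

#' Write contact/binding traces to CSV
#'
#' @param trace A `contact_trace` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(trace, path) {
  readr::write_csv(as_tibble(trace), path, progress = FALSE)
  invisible(path)
}
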