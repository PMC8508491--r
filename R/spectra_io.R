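#' Construct a centroided mass spectrum
#'
#' A `spectrum` holds one collision-voltage step's centroided peak list:
#' m/z values (Thomson) with non-negative intensities, the collision-cell
#' voltage difference (delta CV, volts) at which it was recorded, a free-text
#' label and a metadata list.
#'
#' @param mz Numeric vector of m/z values, strictly ascending after
#'   duplicate merging.
#' @param intensity Numeric vector of non-negative intensities, same length.
#' @param delta_cv Collision-cell voltage difference in volts (>= 0).
#' @param label Free-text label (e.g. replicate/condition).
#' @param metadata Named list of additional key-value metadata.
#' @return An object of class `spectrum`: a list with elements `mz`,
#'   `intensity`, `delta_cv`, `label`, `metadata`.
#' @export
new_spectrum <- function(mz, intensity, delta_cv, label = "", metadata = list()) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (length(mz) == 0L)
    stop("empty peak set: a spectrum needs at least one peak", call. = FALSE)
  if (anyNA(mz) || anyNA(intensity))
    stop("mz/intensity must not contain NA", call. = FALSE)
  if (any(intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (!is.numeric(delta_cv) || length(delta_cv) != 1L || is.na(delta_cv) || delta_cv < 0)
    stop("delta_cv must be a single non-negative number", call. = FALSE)
  ## merge coincident m/z by intensity sum, then sort ascending
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(mz = mz, intensity = intensity,
                 delta_cv = as.numeric(delta_cv),
                 label = label, metadata = metadata),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d peaks, m/z %.2f-%.2f, delta CV %.2f V%s\n",
              length(x$mz), min(x$mz), max(x$mz), x$delta_cv,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Read a two-column peak-list text file
#'
#' The native input format: one peak per line, m/z and intensity separated
#' by whitespace or a comma; lines starting with `#` are comments.
#' Duplicate m/z values are merged by intensity sum.
#'
#' @param source Path to a peak-list file, or a character vector of lines.
#' @param delta_cv Collision-cell voltage difference (volts) for this file.
#' @param label Optional label stored on the spectrum.
#' @return A [new_spectrum()] object.
#' @export
load_peak_list <- function(source, delta_cv, label = "") {
  lines <- if (length(source) == 1L && file.exists(source)) readLines(source) else as.character(source)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("empty peak list: no data lines found", call. = FALSE)
  fields <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  bad_n <- vapply(fields, length, 1L) < 2L
  if (any(bad_n))
    stop(sprintf("malformed peak-list line %d: expected two numeric columns",
                 idx[which(bad_n)[1]]), call. = FALSE)
  mz  <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  int <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad <- is.na(mz) | is.na(int)
  if (any(bad))
    stop(sprintf("malformed numeric field on line %d", idx[which(bad)[1]]),
         call. = FALSE)
  new_spectrum(mz, int, delta_cv, label = label)
}

#' Write a spectrum back to the two-column peak-list format
#'
#' @param spectrum A [new_spectrum()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum"))
  header <- sprintf("# delta_cv=%s label=%s", format(spectrum$delta_cv), spectrum$label)
  body <- sprintf("%.10g %.10g", spectrum$mz, spectrum$intensity)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a manifest mapping peak-list files to voltage steps
#'
#' A manifest is a CSV with columns `file`, `delta_cv` and optionally
#' `replicate` (defaults to 1). Relative file paths are resolved against
#' the manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @return A data frame with columns `file`, `delta_cv`, `replicate`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("file", "delta_cv") %in% names(m)))
    stop("manifest must have columns 'file' and 'delta_cv'", call. = FALSE)
  if (is.null(m$replicate)) m$replicate <- 1L
  rel <- !file.exists(m$file)
  m$file[rel] <- file.path(dirname(path), m$file[rel])
  m[, c("file", "delta_cv", "replicate")]
}

#' Savitzky-Golay smoothing of a centroided peak list
#'
#' Applies the Savitzky-Golay filter `cycles` times in sequence. Because
#' centroided peak lists are not uniformly spaced while the filter assumes
#' uniform sampling, intensities are first resampled by linear interpolation
#' onto a uniform m/z grid at the median peak spacing, filtered, and mapped
#' back to the original m/z positions. Even window lengths are rounded up
#' to the next odd integer (with a warning), mirroring vendor-software
#' window conventions while keeping the filter well defined.
#'
#' @param spectrum A [new_spectrum()] object.
#' @param window Filter window length in points; even values are rounded up.
#' @param polyorder Polynomial order of the filter (must be < window).
#' @param cycles Number of sequential filter passes (>= 1).
#' @return A new `spectrum` with smoothed intensities (clamped at 0);
#'   `metadata$smoothing` records the parameters actually used.
#' @export
smooth_spectrum <- function(spectrum, window = 13L, polyorder = 2L, cycles = 1L) {
  stopifnot(inherits(spectrum, "spectrum"))
  window <- as.integer(window); polyorder <- as.integer(polyorder); cycles <- as.integer(cycles)
  if (cycles < 1L) stop("cycles must be >= 1", call. = FALSE)
  if (window %% 2L == 0L) {
    window <- window + 1L
    warning(sprintf("even smoothing window rounded up to %d points", window),
            call. = FALSE)
  }
  if (window <= polyorder)
    stop("window must exceed polyorder", call. = FALSE)
  if (length(spectrum$mz) < window)
    stop("spectrum has fewer points than the smoothing window", call. = FALSE)
  dmz <- stats::median(diff(spectrum$mz))
  grid <- seq(min(spectrum$mz), max(spectrum$mz), by = dmz)
  y <- stats::approx(spectrum$mz, spectrum$intensity, xout = grid, rule = 2)$y
  for (i in seq_len(cycles)) y <- signal::sgolayfilt(y, p = polyorder, n = window)
  out <- stats::approx(grid, y, xout = spectrum$mz, rule = 2)$y
  md <- spectrum$metadata
  md$smoothing <- list(window = window, polyorder = polyorder, cycles = cycles)
  new_spectrum(spectrum$mz, pmax(out, 0), spectrum$delta_cv,
               label = spectrum$label, metadata = md)
}

#' Define a molecular species observed in the spectra
#'
#' @param name Species name (e.g. `"complex"`, `"protein"`, `"peptide"`).
#' @param mass Average molecular mass in Da (> 0).
#' @param charge_range Integer vector of charge states (all >= 1); only the
#'   range endpoints matter.
#' @param role Either `"educt"` (the intact complex) or `"product"`.
#' @return An object of class `species_definition`.
#' @export
species_definition <- function(name, mass, charge_range, role = c("product", "educt")) {
  role <- match.arg(role)
  charge_range <- sort(unique(as.integer(charge_range)))
  if (!is.numeric(mass) || mass <= 0) stop("mass must be > 0", call. = FALSE)
  if (length(charge_range) == 0L || any(charge_range < 1L))
    stop("charge_range must be a non-empty set of charges >= 1", call. = FALSE)
  structure(list(name = name, mass = as.numeric(mass),
                 charge_range = charge_range, role = role),
            class = "species_definition")
}

#' Theoretical m/z of a charge state
#'
#' @param mass Neutral average mass (Da).
#' @param charge Charge state (positive integer).
#' @param proton_mass Proton mass in Da.
#' @return (mass + charge * proton_mass) / charge.
#' @export
expected_mz <- function(mass, charge, proton_mass = .const$proton) {
  (mass + charge * proton_mass) / charge
}

#' Assign a species' charge-state series in a spectrum
#'
#' For each charge in the species' charge range, computes the expected m/z
#' and records the highest peak within `mz_tolerance` of it (apex-height
#' matching, since downstream analysis propagates signal heights). Absence
#' of a peak is recorded as height 0, not an error.
#'
#' @param spectrum A [new_spectrum()] object.
#' @param species A [species_definition()].
#' @param proton_mass Proton mass (Da).
#' @param mz_tolerance Matching half-window in Thomson (> 0).
#' @return A data frame with one row per charge: `species`, `charge`,
#'   `expected_mz`, `matched_mz` (NA when no peak found), `height`.
#' @export
assign_charge_series <- function(spectrum, species,
                                 proton_mass = .const$proton,
                                 mz_tolerance = 0.5) {
  stopifnot(inherits(spectrum, "spectrum"), inherits(species, "species_definition"))
  if (mz_tolerance <= 0) stop("mz_tolerance must be > 0", call. = FALSE)
  zs <- seq(min(species$charge_range), max(species$charge_range))
  rows <- lapply(zs, function(z) {
    em <- expected_mz(species$mass, z, proton_mass)
    inwin <- which(abs(spectrum$mz - em) <= mz_tolerance)
    if (length(inwin) == 0L)
      return(data.frame(species = species$name, charge = z, expected_mz = em,
                        matched_mz = NA_real_, height = 0))
    best <- inwin[which.max(spectrum$intensity[inwin])]
    data.frame(species = species$name, charge = z, expected_mz = em,
               matched_mz = spectrum$mz[best], height = spectrum$intensity[best])
  })
  do.call(rbind, rows)
}
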