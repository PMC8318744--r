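#' Construct an absorption spectrum
#'
#' A spectrum is one absorbance trace on a wavelength grid: the fundamental
#' I/O unit of the package. Rows are sorted by wavelength at construction;
#' duplicate wavelengths are an error (averaging would hide an ambiguous
#' input).
#'
#' @param wavelengths Numeric vector of wavelengths (nm), length >= 2.
#' @param absorbances Numeric vector of absorbances (AU), same length.
#'   Negative values are permitted (baseline noise) but flagged by
#'   [validate_spectrum()].
#' @param label Free-text identifier.
#' @return An object of class `kf_spectrum` with elements `wavelengths`,
#'   `absorbances`, `label`.
#' @export
#' @examples
#' s <- kf_spectrum(c(220, 221, 222), c(0.10, 0.12, 0.11), "demo")
#' s$wavelengths
kf_spectrum <- function(wavelengths, absorbances, label = "spectrum") {
  if (!is.numeric(wavelengths) || !is.numeric(absorbances))
    stop("wavelengths and absorbances must be numeric", call. = FALSE)
  if (length(wavelengths) != length(absorbances))
    stop("wavelengths and absorbances must have equal length", call. = FALSE)
  if (length(wavelengths) < 2)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelengths must be finite", call. = FALSE)
  if (anyNA(absorbances) || any(!is.finite(absorbances)))
    stop("absorbances must be finite (no NA/NaN/Inf)", call. = FALSE)
  o <- order(wavelengths)
  wavelengths <- as.numeric(wavelengths[o])
  absorbances <- as.numeric(absorbances[o])
  if (any(diff(wavelengths) == 0))
    stop("duplicate wavelengths in spectrum '", label,
         "'; refusing to average", call. = FALSE)
  structure(list(wavelengths = wavelengths, absorbances = absorbances,
                 label = as.character(label)[1]),
            class = "kf_spectrum")
}

#' @export
print.kf_spectrum <- function(x, ...) {
  cat(sprintf("<kf_spectrum '%s': %d points, %.4g-%.4g nm, A in [%.4g, %.4g] AU>\n",
              x$label, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              min(x$absorbances), max(x$absorbances)))
  invisible(x)
}

#' @export
length.kf_spectrum <- function(x) length(x$wavelengths)

#' Validate a spectrum and report soft issues
#'
#' Hard invariants (finite values, strictly increasing grid, length) are
#' enforced by [kf_spectrum()]; this reports conditions that are legal but
#' worth a look, currently negative absorbances.
#'
#' @param s A `kf_spectrum`.
#' @return Character vector of messages (length 0 when clean), invisibly.
#' @export
validate_spectrum <- function(s) {
  stopifnot(inherits(s, "kf_spectrum"))
  msgs <- character(0)
  if (any(s$absorbances < 0))
    msgs <- c(msgs, sprintf("%d negative absorbance value(s) in '%s'",
                            sum(s$absorbances < 0), s$label))
  invisible(msgs)
}

#' Read a spectrum from a two-column text file
#'
#' Expects comma-separated text (dot decimal, UTF-8) with columns
#' wavelength (nm) and absorbance (AU); one optional header line is
#' auto-detected. Rows may appear in any order.
#'
#' @param path Path to the file.
#' @param sep Field separator (default comma).
#' @param label Spectrum label; defaults to the file stem.
#' @return A `kf_spectrum`, sorted by wavelength.
#' @export
read_spectrum <- function(path, sep = ",", label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0)
    stop("insufficient data in ", path, ": empty file", call. = FALSE)
  first <- strsplit(trimws(lines[keep[1]]), sep, fixed = TRUE)[[1]]
  has_header <- length(first) >= 2 &&
    (is.na(suppressWarnings(as.numeric(trimws(first[1])))) ||
     is.na(suppressWarnings(as.numeric(trimws(first[2])))))
  data_idx <- if (has_header) keep[-1] else keep
  if (length(data_idx) < 2)
    stop("insufficient data in ", path, ": need at least 2 rows, got ",
         length(data_idx), call. = FALSE)
  n <- length(data_idx)
  wl <- numeric(n); ab <- numeric(n)
  for (i in seq_len(n)) {
    ln <- data_idx[i]
    fields <- trimws(strsplit(trimws(lines[ln]), sep, fixed = TRUE)[[1]])
    if (length(fields) < 2)
      stop("malformed row at line ", ln, " of ", path,
           ": expected 2 fields", call. = FALSE)
    v <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(v))
      stop("malformed row at line ", ln, " of ", path,
           ": non-numeric value '", fields[which(is.na(v))[1]], "'",
           call. = FALSE)
    wl[i] <- v[1]; ab[i] <- v[2]
  }
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  kf_spectrum(wl, ab, label)
}

#' Write a spectrum to a two-column CSV file
#'
#' Values are written with enough digits that a read-back reproduces the
#' doubles exactly (round-trip identity to 1e-12 and beyond).
#'
#' @param s A `kf_spectrum`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "kf_spectrum"))
  lines <- c("wavelength_nm,absorbance",
             sprintf("%.17g,%.17g", s$wavelengths, s$absorbances))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Collect spectra onto a validated common wavelength grid
#'
#' All instrument spectra in one study are expected on a single grid; by
#' default a mismatch is an error naming the offending spectra. With
#' `interpolate = TRUE`, spectra are linearly interpolated onto the first
#' spectrum's grid; extrapolation is refused.
#'
#' @param spectra List of `kf_spectrum` objects (length >= 1).
#' @param interpolate Allow linear interpolation onto the first grid?
#' @param tol Grid-match tolerance in nm (default 1e-9).
#' @return A `kf_spectrum_set`: list with `spectra` and the shared `grid`.
#' @export
align_to_grid <- function(spectra, interpolate = FALSE, tol = 1e-9) {
  if (inherits(spectra, "kf_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, inherits, logical(1), "kf_spectrum")))
  grid <- spectra[[1]]$wavelengths
  same <- vapply(spectra, function(s) {
    length(s$wavelengths) == length(grid) &&
      all(abs(s$wavelengths - grid) <= tol)
  }, logical(1))
  if (all(same)) {
    out <- spectra
  } else if (!interpolate) {
    bad <- vapply(spectra[!same], `[[`, character(1), "label")
    stop("wavelength grid mismatch (interpolation disabled) for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  } else {
    out <- lapply(spectra, function(s) {
      if (min(s$wavelengths) - tol > min(grid) ||
          max(s$wavelengths) + tol < max(grid))
        stop("interpolation would extrapolate spectrum '", s$label,
             "' beyond its measured range", call. = FALSE)
      a <- stats::approx(s$wavelengths, s$absorbances, xout = grid,
                         method = "linear", rule = 1)$y
      kf_spectrum(grid, a, s$label)
    })
  }
  structure(list(spectra = out, grid = grid), class = "kf_spectrum_set")
}

#' @export
print.kf_spectrum_set <- function(x, ...) {
  cat(sprintf("<kf_spectrum_set: %d spectra on %d-point grid %.4g-%.4g nm>\n",
              length(x$spectra), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}
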