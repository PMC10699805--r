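#' Construct a spectrum object
#'
#' A spectrum is a wavelength-gridded curve: donor emission (arbitrary
#' units), acceptor absorbance (dimensionless), or molar extinction
#' (M^-1 cm^-1). The wavelength grid must be strictly increasing.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param value Numeric vector of spectral values, same length as
#'   `wavelength_nm`, all finite.
#' @param kind One of `"emission"`, `"absorbance"`, `"extinction"`.
#' @param pH_tag Optional condition label (e.g. `"pH8"`).
#' @return An object of class `fret_spectrum`: a data.frame with columns
#'   `wavelength_nm` and `value`, plus `kind` and `pH_tag` attributes.
#' @export
spectrum <- function(wavelength_nm, value,
                     kind = c("emission", "absorbance", "extinction"),
                     pH_tag = NA_character_) {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value))
    stop("wavelength and value must have the same length", call. = FALSE)
  if (length(wavelength_nm) < 2L)
    stop("a spectrum needs at least two grid points", call. = FALSE)
  if (anyNA(wavelength_nm) || any(!is.finite(value)))
    stop("spectrum values must be finite", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (kind == "emission" && any(value < 0))
    stop("emission values must be non-negative", call. = FALSE)
  out <- data.frame(wavelength_nm = wavelength_nm, value = value)
  attr(out, "kind") <- kind
  attr(out, "pH_tag") <- pH_tag
  class(out) <- c("fret_spectrum", "data.frame")
  out
}

#' Read a spectrum from a two-column CSV
#'
#' The file must have a header and two numeric columns
#' (`wavelength_nm,value`). Rows are sorted ascending by wavelength;
#' duplicate wavelengths are rejected.
#'
#' @param path Path to the CSV file.
#' @inheritParams spectrum
#' @return A [spectrum()] object.
#' @export
read_spectrum <- function(path, kind = c("emission", "absorbance", "extinction"),
                          pH_tag = NA_character_) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("spectrum file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE)
  if (ncol(df) < 2L)
    stop("spectrum file must have two columns: ", path, call. = FALSE)
  wl <- suppressWarnings(as.numeric(df[[1L]]))
  v <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(wl) || anyNA(v))
    stop("non-numeric rows in spectrum file: ", path, call. = FALSE)
  if (anyDuplicated(wl))
    stop("duplicate wavelengths in spectrum file: ", path, call. = FALSE)
  ord <- order(wl)
  spectrum(wl[ord], v[ord], kind = kind, pH_tag = pH_tag)
}

#' Write a spectrum to CSV
#'
#' @param spec A [spectrum()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "fret_spectrum"))
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert absorbance spectra to a molar extinction spectrum
#'
#' Applies Beer-Lambert: epsilon(lambda) = A(lambda) / (c * l). Replicate
#' absorbance spectra measured on the same grid are averaged pointwise
#' before conversion, matching the practice of measuring a metal-chelate
#' absorbance at least three times and averaging.
#'
#' @param specs A single absorbance [spectrum()] or a list of replicate
#'   absorbance spectra on identical grids.
#' @param concentration Molar concentration of the absorbing species
#'   (mol/L), > 0.
#' @param pathlength Optical path length in cm, > 0 (default 1).
#' @return An extinction [spectrum()] in M^-1 cm^-1.
#' @export
extinction_from_absorbance <- function(specs, concentration, pathlength = 1) {
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      concentration <= 0)
    stop("concentration must be a single positive number", call. = FALSE)
  if (!is.numeric(pathlength) || length(pathlength) != 1L || pathlength <= 0)
    stop("pathlength must be a single positive number", call. = FALSE)
  if (inherits(specs, "fret_spectrum")) specs <- list(specs)
  stopifnot(length(specs) >= 1L)
  for (s in specs) {
    stopifnot(inherits(s, "fret_spectrum"))
    if (attr(s, "kind") != "absorbance")
      stop("extinction_from_absorbance expects absorbance spectra",
           call. = FALSE)
    if (!identical(s$wavelength_nm, specs[[1L]]$wavelength_nm))
      stop("replicate spectra must share one wavelength grid", call. = FALSE)
  }
  a_bar <- rowMeans(vapply(specs, function(s) s$value,
                           numeric(nrow(specs[[1L]]))))
  spectrum(specs[[1L]]$wavelength_nm, a_bar / (concentration * pathlength),
           kind = "extinction", pH_tag = attr(specs[[1L]], "pH_tag"))
}

#' Donor-acceptor spectral overlap integral J
#'
#' Computes
#' \deqn{J = \frac{\int f_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\,
#'   d\lambda}{\int f_D(\lambda)\,d\lambda}}
#' where \eqn{f_D} is the donor emission and \eqn{\varepsilon_A} the
#' acceptor molar extinction. The donor emission is unit-area normalized
#' inside the integral, so raw emission units never matter. Integration is
#' trapezoidal on the intersection of the two grids, with the coarser
#' spectrum linearly interpolated onto the finer one (no extrapolation).
#'
#' @param donor Emission [spectrum()].
#' @param acceptor Extinction [spectrum()] (M^-1 cm^-1).
#' @return J in M^-1 cm^-1 nm^4.
#' @export
overlap_integral <- function(donor, acceptor) {
  stopifnot(inherits(donor, "fret_spectrum"), inherits(acceptor, "fret_spectrum"))
  if (attr(donor, "kind") != "emission")
    stop("donor must be an emission spectrum", call. = FALSE)
  if (attr(acceptor, "kind") != "extinction")
    stop("acceptor must be an extinction spectrum", call. = FALSE)
  lo <- max(min(donor$wavelength_nm), min(acceptor$wavelength_nm))
  hi <- min(max(donor$wavelength_nm), max(acceptor$wavelength_nm))
  if (hi <= lo)
    stop("donor and acceptor grids do not overlap", call. = FALSE)
  # integrate on the union of both grids restricted to the intersection,
  # so neither band shape is coarsened
  grid <- sort(unique(c(donor$wavelength_nm, acceptor$wavelength_nm)))
  grid <- grid[grid >= lo & grid <= hi]
  fd <- stats::approx(donor$wavelength_nm, donor$value, xout = grid)$y
  ea <- stats::approx(acceptor$wavelength_nm, acceptor$value, xout = grid)$y
  num <- trapz(grid, fd * ea * grid^4)
  # donor normalization over its full band, not just the intersection
  den <- trapz(donor$wavelength_nm, donor$value)
  if (den <= 0) stop("donor emission integrates to zero", call. = FALSE)
  num / den
}

# trapezoidal rule on an (unequally spaced) grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Assemble a Forster calibration
#'
#' Bundles the photophysical constants that enter the Forster radius:
#' donor quantum yield Q, orientation factor kappa^2, refractive index
#' eta, overlap integral J and the unit-scaling constant C. Defaults are
#' the values appropriate for the L-ANAP donor in stabilization buffer:
#' Q = 0.22, kappa^2 = 2/3 (dynamic isotropic orientation), eta = 1.33.
#'
#' @param J Overlap integral in M^-1 cm^-1 nm^4 (>= 0).
#' @param Q Donor quantum yield, in (0, 1].
#' @param kappa2 Orientation factor kappa^2, in (0, 4].
#' @param eta Refractive index of the medium, > 1.
#' @param C Scaling constant giving R0 in Angstrom for J in
#'   M^-1 cm^-1 nm^4; the standard value is 0.2108.
#' @param pH_tag Optional condition label.
#' @return A `fret_calibration` list with fields `Q`, `kappa2`, `eta`,
#'   `J`, `C`, `R0` (NA until [forster_radius()] is applied), `pH_tag`.
#' @export
fret_calibration <- function(J, Q = 0.22, kappa2 = 2 / 3, eta = 1.33,
                             C = 0.2108, pH_tag = NA_character_) {
  if (!is.finite(J) || J < 0) stop("J must be non-negative", call. = FALSE)
  if (Q <= 0 || Q > 1) stop("Q must be in (0, 1]", call. = FALSE)
  if (kappa2 <= 0 || kappa2 > 4) stop("kappa2 must be in (0, 4]", call. = FALSE)
  if (eta <= 1) stop("eta must exceed 1", call. = FALSE)
  structure(
    list(Q = Q, kappa2 = kappa2, eta = eta, J = J, C = C,
         R0 = NA_real_, pH_tag = pH_tag),
    class = "fret_calibration")
}

#' Forster radius from a calibration
#'
#' \deqn{R_0 = C\,(J\,Q\,\eta^{-4}\,\kappa^2)^{1/6}}
#' R0 is the donor-acceptor distance at which energy transfer is 50%.
#'
#' @param cal A [fret_calibration()] (R0 unset).
#' @return The calibration with `R0` filled in (Angstrom).
#' @export
forster_radius <- function(cal) {
  stopifnot(inherits(cal, "fret_calibration"))
  cal$R0 <- cal$C * (cal$J * cal$Q * cal$eta^-4 * cal$kappa2)^(1 / 6)
  cal
}

#' @export
print.fret_calibration <- function(x, ...) {
  cat("FRET calibration", if (!is.na(x$pH_tag)) paste0("(", x$pH_tag, ")"), "\n")
  cat(sprintf("  Q = %.3g  kappa2 = %.4g  eta = %.3g  C = %.4g\n",
              x$Q, x$kappa2, x$eta, x$C))
  cat(sprintf("  J = %.6g M^-1 cm^-1 nm^4\n", x$J))
  cat(sprintf("  R0 = %s Angstrom\n",
              if (is.na(x$R0)) "<unset>" else sprintf("%.2f", x$R0)))
  invisible(x)
}

#' Write a calibration to YAML
#'
#' @param cal A [fret_calibration()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "fret_calibration"))
  yaml::write_yaml(unclass(cal), path)
  invisible(path)
}
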