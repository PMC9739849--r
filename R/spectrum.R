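# Spectral prefactors, atomic units (hbar = 1, h = 2*pi, eps0 = 1/(4*pi)).
# Absorption: Gamma_A = |mu|^2 / (6 eps0 c hbar^2) is the Einstein B
# coefficient over c; the extinction signal carries an extra photon-energy
# factor h*nu. Emission: Gamma_E = 8*pi*h*|mu|^2 / (6 eps0 hbar^2) with the
# spontaneous-emission frequency factor (nu/c)^3.
spectral_const <- function(kind) {
  switch(kind,
         absorption = 1 / (6 * au_constants$eps0_au * au_constants$c_au),
         emission = 8 * pi * au_constants$h_au / (6 * au_constants$eps0_au),
         stop("unknown spectrum kind ", kind))
}

spectral_freq_factor <- function(kind, nu) {
  switch(kind,
         absorption = au_constants$h_au * nu,
         emission = (nu / au_constants$c_au)^3)
}

#' Bin per-frame vertical transitions into a band
#'
#' Collects per-frame vertical transition frequencies and squared transition
#' dipoles into uniform frequency bins, recording per-bin counts and mean
#' squared dipole. The electronic band frequency `nu_el` is the center of
#' the bin maximizing the constructed spectral intensity
#' (count x mean |mu|^2 x frequency prefactor).
#'
#' @param nu per-frame vertical transition frequencies (a.u.)
#' @param mu2 per-frame squared transition dipole norms (a.u.)
#' @param bin_width bin width (frequency a.u.)
#' @param kind "absorption" or "emission"
#' @param sigma Gaussian broadening width (frequency a.u.)
#' @return object of class `vertical_band`
#' @export
bin_vertical <- function(nu, mu2, bin_width, kind = c("absorption", "emission"),
                         sigma = 4e-4) {
  kind <- match.arg(kind)
  if (length(nu) < 1) stop("bin_vertical: empty input")
  if (length(mu2) != length(nu)) stop("bin_vertical: nu/mu2 length mismatch")
  if (bin_width <= 0) stop("bin_vertical: bin_width must be positive")
  if (sigma <= 0) stop("bin_vertical: sigma must be positive")
  idx <- floor(nu / bin_width)
  centers <- (sort(unique(idx)) + 0.5) * bin_width
  key <- match(idx, sort(unique(idx)))
  counts <- tabulate(key, nbins = length(centers))
  mean_mu2 <- as.vector(tapply(mu2, factor(key, levels = seq_along(centers)),
                               mean))
  wt <- counts * mean_mu2 * spectral_freq_factor(kind, centers)
  structure(list(bin_centers = centers, counts = counts, mean_mu2 = mean_mu2,
                 Nf = length(nu), kind = kind,
                 nu_el = centers[which.max(wt)], sigma = sigma,
                 bin_width = bin_width),
            class = "vertical_band")
}

#' @export
print.vertical_band <- function(x, ...) {
  cat(sprintf(
    "Vertical %s band: %d frames in %d bins, nu_el = %.6g a.u. (%.3f eV)\n",
    x$kind, x$Nf, length(x$bin_centers), x$nu_el, freq_au_to_ev(x$nu_el)))
  invisible(x)
}

# evaluate the broadened vertical intensity of a band at arbitrary nu values
band_intensity <- function(band, nu) {
  A <- spectral_const(band$kind) * band$mean_mu2 * band$counts / band$Nf
  out <- numeric(length(nu))
  s <- band$sigma
  for (b in seq_along(band$bin_centers)) {
    out <- out + A[b] * stats::dnorm(nu, band$bin_centers[b], s)
  }
  out * spectral_freq_factor(band$kind, nu)
}

default_grid <- function(lo, hi, sigma) {
  seq(lo - 8 * sigma, hi + 8 * sigma, by = sigma / 5)
}

new_spectrum <- function(grid, intensity, kind, sigma, provenance = list()) {
  structure(list(grid = grid, intensity = pmax(intensity, 0), kind = kind,
                 sigma = sigma, provenance = provenance),
            class = "pmm_spectrum")
}

#' Vertical electronic spectrum of a binned band
#'
#' Sums, over occupied bins, the bin prefactor times the frame fraction
#' times a unit-area Gaussian centered at the bin frequency, with the
#' kind-dependent frequency factor evaluated at the running frequency.
#'
#' @param band a `vertical_band`
#' @param grid optional frequency grid (a.u.); default spans the band
#'   plus/minus 6 sigma at sigma/5 spacing
#' @return a `pmm_spectrum`
#' @export
vertical_spectrum <- function(band, grid = NULL) {
  stopifnot(inherits(band, "vertical_band"))
  if (is.null(grid))
    grid <- default_grid(min(band$bin_centers), max(band$bin_centers),
                         band$sigma)
  new_spectrum(grid, band_intensity(band, grid), band$kind, band$sigma,
               provenance = list(list(kind = band$kind, nu_el = band$nu_el,
                                      Nf = band$Nf, vibronic = FALSE)))
}

#' 0-0 correction shift
#'
#' Shift added to every unperturbed vibronic frequency of an electronic
#' transition so the calculated 0-0 line matches the experimental gas-phase
#' value.
#'
#' @param nu_calc_00 calculated unperturbed 0-0 frequency (a.u.)
#' @param nu_exp_00 experimental gas-phase 0-0 frequency (a.u.)
#' @return the shift `nu_exp_00 - nu_calc_00` (a.u.)
#' @export
correct_00 <- function(nu_calc_00, nu_exp_00) {
  stopifnot(nu_calc_00 > 0, nu_exp_00 > 0)
  nu_exp_00 - nu_calc_00
}

#' Vibronic spectrum from a vertical band and enumerated transitions
#'
#' Each vibronic transition contributes a copy of the vertical spectrum
#' scaled by its squared overlap and rigidly translated so its maximum sits
#' at nu_m = nu_m0 + nu_el - nu_el0, where nu_m0 = nu_00 + offset for
#' absorption (offset below the 0-0 line for emission). Since the vertical
#' maximum sits at nu_el, the translation of each copy is nu_m0 - nu_el0.
#'
#' @param band the sub-ensemble `vertical_band`
#' @param transitions a `transition_set` for the matching state pair
#' @param nu_el0 unperturbed vertical electronic frequency (a.u.)
#' @param nu_00 unperturbed (0-0-corrected) 0-0 frequency (a.u.)
#' @param grid optional output grid (a.u.)
#' @param chunk internal evaluation chunk size
#' @return a `pmm_spectrum`
#' @export
vibronic_spectrum <- function(band, transitions, nu_el0, nu_00, grid = NULL,
                              chunk = 512L) {
  stopifnot(inherits(band, "vertical_band"),
            inherits(transitions, "transition_set"))
  if (length(transitions$fc2) == 0)
    stop("vibronic_spectrum: empty transition set")
  sgn <- if (band$kind == "absorption") 1 else -1
  num0 <- nu_00 + sgn * transitions$nu0
  delta <- num0 - nu_el0
  if (is.null(grid))
    grid <- default_grid(min(band$bin_centers) + min(delta),
                         max(band$bin_centers) + max(delta), band$sigma)
  out <- numeric(length(grid))
  m <- length(delta)
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    for (j in lo:hi) {
      out <- out + transitions$fc2[j] * band_intensity(band, grid - delta[j])
    }
  }
  new_spectrum(grid, out, band$kind, band$sigma,
               provenance = list(list(kind = band$kind, nu_el = band$nu_el,
                                      Nf = band$Nf, vibronic = TRUE,
                                      n_transitions = m,
                                      captured = transitions$captured,
                                      nu_00 = nu_00, nu_el0 = nu_el0)))
}

#' Weighted combination of spectra on a common grid
#'
#' Spectra on differing grids are resampled onto the grid of the first by
#' linear interpolation (zero outside their support); provenance entries are
#' concatenated with the weights attached.
#'
#' @param spectra list of `pmm_spectrum` objects
#' @param weights non-negative weights, one per spectrum
#' @return a `pmm_spectrum`
#' @export
combine_spectra <- function(spectra, weights) {
  if (length(spectra) != length(weights))
    stop("combine_spectra: weight length mismatch")
  if (any(weights < 0)) stop("combine_spectra: negative weight")
  lo <- min(vapply(spectra, function(s) min(s$grid), 0))
  hi <- max(vapply(spectra, function(s) max(s$grid), 0))
  step <- diff(spectra[[1]]$grid[1:2])
  grid <- if (abs(lo - min(spectra[[1]]$grid)) < step / 2 &&
              abs(hi - max(spectra[[1]]$grid)) < step / 2) spectra[[1]]$grid
  else seq(lo, hi, by = step)
  total <- numeric(length(grid))
  prov <- list()
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    y <- if (length(s$grid) == length(grid) && all(s$grid == grid)) s$intensity
    else stats::approx(s$grid, s$intensity, xout = grid, yleft = 0,
                       yright = 0)$y
    total <- total + weights[i] * y
    prov <- c(prov, lapply(s$provenance, function(p) {
      p$weight <- weights[i]; p
    }))
  }
  new_spectrum(grid, total, spectra[[1]]$kind, spectra[[1]]$sigma, prov)
}

#' Normalize a spectrum to unit peak intensity
#'
#' @param spectrum a `pmm_spectrum`
#' @return the spectrum divided by its maximum
#' @export
normalize_peak <- function(spectrum) {
  stopifnot(inherits(spectrum, "pmm_spectrum"))
  m <- max(spectrum$intensity)
  if (m <= 0) stop("normalize_peak: all-zero spectrum")
  spectrum$intensity <- spectrum$intensity / m
  spectrum
}

#' Integrated intensity of a spectrum (trapezoid rule over the grid)
#' @param spectrum a `pmm_spectrum`
#' @return the integral over the frequency grid
#' @export
spectrum_integral <- function(spectrum) {
  g <- spectrum$grid; y <- spectrum$intensity
  sum(diff(g) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.pmm_spectrum <- function(x, ...) {
  pk <- x$grid[which.max(x$intensity)]
  cat(sprintf(
    "%s spectrum: %d grid points, peak at %.6g a.u. (%.3f eV, %.1f nm)\n",
    x$kind, length(x$grid), pk, freq_au_to_ev(pk),
    freq_au_to_nm(pk)))
  cat(sprintf("  integral %.6g, %d provenance entr%s\n", spectrum_integral(x),
              length(x$provenance), if (length(x$provenance) == 1) "y" else "ies"))
  invisible(x)
}

#' @export
plot.pmm_spectrum <- function(x, xunit = c("eV", "nm", "au"), ...) {
  xunit <- match.arg(xunit)
  xs <- switch(xunit, eV = freq_au_to_ev(x$grid), nm = freq_au_to_nm(x$grid),
               au = x$grid)
  graphics::plot(xs, x$intensity, type = "l",
                 xlab = switch(xunit, eV = "energy (eV)",
                               nm = "wavelength (nm)", au = "frequency (a.u.)"),
                 ylab = if (x$kind == "absorption") "extinction (a.u.)"
                 else "emission signal (arb.)", ...)
  invisible(x)
}

#' Export a spectrum as TSV (energy in eV, wavelength in nm, intensity)
#'
#' Provenance is written as header comment lines.
#'
#' @param spectrum a `pmm_spectrum`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "pmm_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s sigma_au=%.8g", spectrum$kind, spectrum$sigma),
             con)
  for (p in spectrum$provenance) {
    writeLines(paste0("# ", paste(names(p), vapply(p, function(v)
      paste(format(v, digits = 10), collapse = ","), ""), sep = "=",
      collapse = " ")), con)
  }
  writeLines("energy_eV\twavelength_nm\tintensity", con)
  writeLines(sprintf("%.8f\t%.4f\t%.10g", freq_au_to_ev(spectrum$grid),
                     freq_au_to_nm(spectrum$grid), spectrum$intensity), con)
  invisible(path)
}
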