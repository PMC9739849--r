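#' Physical constants in atomic units
#'
#' All internal computation uses Hartree atomic units (energy in Hartree,
#' length in Bohr, charge in e, mass in electron masses, hbar = 1,
#' 4*pi*eps0 = 1). "Frequency atomic units" means nu in units of Eh/hbar
#' divided by 2*pi, so that the photon energy is E = h*nu = 2*pi*nu Hartree.
#'
#' @format A named list with elements
#'   `hartree_ev` (eV per Hartree), `bohr_nm` (nm per Bohr),
#'   `amu_me` (electron masses per a.m.u.), `kB` (Hartree/K),
#'   `c_au` (speed of light, a.u.), `h_au` (Planck constant, a.u. = 2*pi),
#'   `eps0_au` (vacuum permittivity, a.u. = 1/(4*pi)),
#'   `ev_nm` (eV * nm product for photon wavelength conversion),
#'   `hartree_cm1` (cm^-1 per Hartree).
#' @export
au_constants <- list(
  hartree_ev  = 27.211386245988,
  bohr_nm     = 0.052917721090380,
  amu_me      = 1822.888486209,
  kB          = 3.166811563e-6,
  c_au        = 137.035999084,
  h_au        = 2 * pi,
  eps0_au     = 1 / (4 * pi),
  ev_nm       = 1239.841984,
  hartree_cm1 = 219474.6313632
)

#' Convert a Gaussian width in frequency atomic units to photon energy in eV
#'
#' The broadening width sigma used in constructing spectra is quoted in
#' frequency atomic units; its photon-energy equivalent is E = h * nu.
#'
#' @param sigma_freq_au width(s) in frequency atomic units (Eh/(hbar*2*pi))
#' @return energy in eV
#' @examples
#' sigma_to_energy(0.0004) # approximately 0.068 eV
#' @export
sigma_to_energy <- function(sigma_freq_au) {
  stopifnot(is.numeric(sigma_freq_au), all(sigma_freq_au >= 0))
  au_constants$h_au * sigma_freq_au * au_constants$hartree_ev
}

#' Convert photon energies in eV to frequency atomic units
#' @param energy_ev energy in eV
#' @return frequency in atomic units
#' @export
energy_ev_to_freq_au <- function(energy_ev) {
  energy_ev / (au_constants$h_au * au_constants$hartree_ev)
}

# frequency a.u. -> photon energy eV
freq_au_to_ev <- function(nu) au_constants$h_au * nu * au_constants$hartree_ev

# frequency a.u. -> wavelength nm
freq_au_to_nm <- function(nu) au_constants$ev_nm / freq_au_to_ev(nu)

# vibrational angular frequency omega (a.u.) from Hessian eigenvalue (a.u.)
# carries the sign of the curvature: negative eigenvalue -> negative "frequency"
eig_to_freq_au <- function(lambda) sign(lambda) * sqrt(abs(lambda)) / (2 * pi)

#' Number of frames obtained by periodic subsampling of a trajectory
#'
#' @param duration_ns trajectory length in nanoseconds
#' @param interval_ps sampling interval in picoseconds
#' @return integer frame count
#' @examples
#' sampling_frame_count(400, 20) # 20000
#' @export
sampling_frame_count <- function(duration_ns, interval_ps) {
  stopifnot(duration_ns > 0, interval_ps > 0)
  as.integer(round(duration_ns * 1000 / interval_ps))
}
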