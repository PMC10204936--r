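#' Tissue optical properties
#'
#' Container for baseline absorption and reduced scattering per wavelength.
#' Defaults are typical adult head values used by the simulator.
#'
#' @param mua_mm absorption coefficient per wavelength (mm^-1).
#' @param musp_mm reduced scattering coefficient per wavelength (mm^-1).
#' @param n_index tissue refractive index.
#' @param wavelengths_nm the wavelengths the entries refer to.
#' @return an `optical_properties` list.
#' @export
optical_properties <- function(mua_mm = c(0.01, 0.01),
                               musp_mm = c(1.0, 1.0),
                               n_index = 1.4,
                               wavelengths_nm = c(690, 830)) {
  if (any(mua_mm <= 0) || any(musp_mm <= 0) || n_index < 1)
    stopf("non-physical optical properties")
  if (any(musp_mm < 10 * mua_mm))
    stopf("diffusion approximation requires musp >> mua")
  structure(list(mua_mm = mua_mm, musp_mm = musp_mm, n_index = n_index,
                 wavelengths_nm = wavelengths_nm),
            class = "optical_properties")
}

# Effective reflection parameter for the extrapolated-boundary condition
# (Haskell et al. polynomial approximation in the refractive index).
boundary_A <- function(n) {
  r_eff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + r_eff) / (1 - r_eff)
}

#' Frequency-domain semi-infinite photon-density-wave response
#'
#' Complex reflectance of an intensity-modulated point source on a
#' semi-infinite homogeneous medium, using the diffusion approximation with
#' an extrapolated boundary (image-source construction).  Returns the
#' demodulated amplitude and phase a frequency-domain system measures at a
#' given source-detector separation.  Amplitude decreases and phase
#' increases monotonically with separation; at zero modulation frequency the
#' phase vanishes (continuous-wave limit).
#'
#' @param sds_mm source-detector separation(s) in mm (> 0).
#' @param mua_mm,musp_mm absorption / reduced scattering (mm^-1), scalars.
#' @param n_index refractive index.
#' @param mod_freq_hz modulation frequency in Hz (141e6 for the emulated
#'   system).
#' @return a list with vectors `amplitude` (a.u.) and `phase` (radians).
#' @export
fd_semiinfinite_response <- function(sds_mm, mua_mm = 0.01, musp_mm = 1.0,
                                     n_index = 1.4, mod_freq_hz = 141e6) {
  if (any(sds_mm <= 0)) stopf("sds_mm must be positive")
  if (mua_mm <= 0 || musp_mm <= 0) stopf("non-physical optical properties")
  D <- 1 / (3 * (mua_mm + musp_mm))
  c_n <- 2.99792458e11 / n_index              # mm / s in the medium
  omega <- 2 * pi * mod_freq_hz
  k <- sqrt(complex(real = mua_mm, imaginary = -omega / c_n) / D)
  if (Re(k) < 0) k <- -k                       # decaying branch
  z0 <- 1 / (mua_mm + musp_mm)
  zb <- 2 * boundary_A(n_index) * D
  r1 <- sqrt(sds_mm^2 + z0^2)
  r2 <- sqrt(sds_mm^2 + (z0 + 2 * zb)^2)
  phi <- (exp(-k * r1) / r1 - exp(-k * r2) / r2) / (4 * pi * D)
  list(amplitude = Mod(phi), phase = Arg(phi))
}

#' Effective optical pathlength and phase sensitivity
#'
#' Sensitivity of the semi-infinite frequency-domain measurement to a small
#' global absorption change: `pathlength_mm` is -d ln(amplitude) / d mua
#' (the mean partial pathlength in mm that converts an absorption change to
#' an optical-density change), and `dphase_dmua` is the corresponding phase
#' derivative (radians per mm^-1).  Both are evaluated by central
#' differences on the closed-form model.
#'
#' @inheritParams fd_semiinfinite_response
#' @return list with vectors `pathlength_mm` and `dphase_dmua`.
#' @export
mua_sensitivity <- function(sds_mm, mua_mm = 0.01, musp_mm = 1.0,
                            n_index = 1.4, mod_freq_hz = 141e6) {
  h <- 1e-5
  lo <- fd_semiinfinite_response(sds_mm, mua_mm - h, musp_mm, n_index, mod_freq_hz)
  hi <- fd_semiinfinite_response(sds_mm, mua_mm + h, musp_mm, n_index, mod_freq_hz)
  list(
    pathlength_mm = -(log(hi$amplitude) - log(lo$amplitude)) / (2 * h),
    dphase_dmua = (hi$phase - lo$phase) / (2 * h)
  )
}

#' Haemoglobin extinction coefficients
#'
#' Decadic (log10) specific extinction coefficients of oxy- and
#' deoxy-haemoglobin at the system wavelengths, in mm^-1 per micromolar,
#' from the standard compiled tabulations.  Multiply by `log(10)` where a
#' natural-log absorption coefficient is required.
#'
#' @param wavelengths_nm wavelengths to return; only 690 and 830 nm are
#'   tabulated here.
#' @return a matrix `[wavelength, chromophore]` with columns HbO, Hb.
#' @export
extinction_coefficients <- function(wavelengths_nm = c(690, 830)) {
  tab <- rbind(
    `690` = c(HbO = 2.7600e-05, Hb = 2.0520e-04),
    `830` = c(HbO = 9.7400e-05, Hb = 6.9304e-05)
  )
  key <- as.character(wavelengths_nm)
  if (!all(key %in% rownames(tab)))
    stopf("extinction coefficients tabulated only at 690 and 830 nm")
  tab[key, , drop = FALSE]
}
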