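## Standard phase-contrast CTF.  The aberration phase is
## chi(s) = pi * lambda_e * dz * s^2 - (pi/2) * Cs * lambda_e^3 * s^4
## with s the spatial frequency in 1/A, dz the defocus (positive =
## underfocus) and Cs the spherical aberration; amplitude contrast A mixes
## in a cosine term: CTF(s) = -( sqrt(1 - A^2) sin(chi) + A cos(chi) ).

## Relativistic electron wavelength in Angstrom for voltage in kV.
.electronWavelength <- function(voltageKv) {
  v <- voltageKv * 1e3
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Evaluate the contrast transfer function
#'
#' @param s spatial frequency in 1/Angstrom (vector OK).
#' @param ctf a [CTFParams-class]; when `enabled` is FALSE returns 1.
#' @return CTF values in \[-1, 1\].
#' @export
ctfValue <- function(s, ctf) {
  if (!ctf@enabled) return(rep(1, length(s)))
  lam <- .electronWavelength(ctf@voltage)
  dz <- ctf@defocus * 1e4           # micrometre -> Angstrom
  cs <- ctf@sphericalAberration * 1e7  # millimetre -> Angstrom
  chi <- pi * lam * dz * s^2 - (pi / 2) * cs * lam^3 * s^4
  a <- ctf@amplitudeContrast
  -(sqrt(1 - a^2) * sin(chi) + a * cos(chi))
}

## CTF evaluated on the full 2D image lattice (vector over pixels).
.ctfImage <- function(ctf, n, voxel) {
  if (!ctf@enabled) return(rep(1, n * n))
  g <- .gridGeometry(n, 2L)
  as.vector(ctfValue(as.vector(g$r) / (n * voxel), ctf))
}
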