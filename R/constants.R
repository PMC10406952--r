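# Unit system: lengths in Angstrom, times in ps, energies in kJ/mol, charges in e.

#' Physical constants used throughout the package
#'
#' `ke_coulomb` is the Coulomb prefactor 1/(4 pi eps0) expressed in
#' kJ A / (mol e^2); `kB` is Boltzmann's constant in kJ/(mol K).
#'
#' @format Named numeric constants.
#' @name hydrashell-constants
#' @keywords internal
NULL

.ke_coulomb <- 1389.35458   # kJ * A / (mol * e^2)
.kB <- 0.008314462618       # kJ / (mol * K)

#' Rigid water geometry and charge conventions
#'
#' Default rigid four-site water geometry: O-H bond length 0.9572 A, H-O-H
#' angle 104.52 degrees, massless charge site (M) on the bisector 0.1546 A
#' from the oxygen. Charges: +0.5564 e on each hydrogen, -1.1128 e on the M
#' site, neutral oxygen. The oxygen carries the Lennard-Jones centre
#' (sigma 3.1589 A, epsilon 0.7749 kJ/mol). These are the published
#' TIP4P/2005 values.
#'
#' @return A list with elements `r_oh` (A), `theta_hoh` (degrees), `r_om`
#'   (A), `q_h`, `q_m`, `q_o` (e), `lj_sigma` (A), `lj_epsilon` (kJ/mol).
#' @export
#' @examples
#' water_model()$r_oh
water_model <- function() {
  list(r_oh = 0.9572, theta_hoh = 104.52, r_om = 0.1546,
       q_h = 0.5564, q_m = -1.1128, q_o = 0,
       lj_sigma = 3.1589, lj_epsilon = 0.7749)
}
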