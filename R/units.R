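#' Unit constants
#'
#' Single source for the unit conversions used throughout the package.
#' Mechanical energies are carried in pN.nm and folding free energies in
#' kcal/mol; 1 kcal/mol = 6.948 pN.nm, so kT at 25 C (4.114 pN.nm) is
#' 0.592 kcal/mol.
#'
#' @format Named numeric constants:
#' \describe{
#'   \item{kT_25C_pNnm}{thermal energy at 25 C, pN.nm}
#'   \item{pNnm_per_kcalmol}{pN.nm per kcal/mol}
#' }
#' @name units
NULL

#' @rdname units
#' @export
kT_25C_pNnm <- 4.114

#' @rdname units
#' @export
pNnm_per_kcalmol <- 6.948

#' Convert energies between pN.nm and kcal/mol
#'
#' @param x numeric vector of energies.
#' @return converted numeric vector.
#' @export
pNnm_to_kcalmol <- function(x) x / pNnm_per_kcalmol

#' @rdname pNnm_to_kcalmol
#' @export
kcalmol_to_pNnm <- function(x) x * pNnm_per_kcalmol
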