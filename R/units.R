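#' Physical constants used throughout the package
#'
#' All lengths are in nm, energies in kJ/mol, charges in elementary charge
#' units, times in ps (simulation) or ns/us (analysis), temperatures in K.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kJ/(mol K): 0.0083145.}
#'   \item{NA_mol}{Avogadro's number, 1/mol.}
#'   \item{R_gas}{Universal gas constant, kJ/(mol K) (identical to kB in
#'     molar units).}
#'   \item{debye_prefactor_nm}{Debye length prefactor for water at 298 K:
#'     lambda_D = 0.304 nm / sqrt(I in M) for a monovalent salt.}
#' }
#' @export
cg_constants <- list(
  kB = 0.0083145,
  NA_mol = 6.02214076e23,
  R_gas = 0.0083145,
  debye_prefactor_nm = 0.304
)

# concentration (mM) -> number density (nm^-3)
mM_to_nm3 <- function(conc_mM) conc_mM * 1e-3 * cg_constants$NA_mol * 1e-24

# number density (nm^-3) -> concentration (mM)
nm3_to_mM <- function(rho) rho / (1e-3 * cg_constants$NA_mol * 1e-24)
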