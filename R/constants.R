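#' Physical constants used throughout the package
#'
#' Returns the fixed table of physical constants (CODATA 2018 values) used by
#' every numerical routine in the package. Keeping them in one table makes the
#' unit conversions auditable.
#'
#' @return A named list:
#' \describe{
#'   \item{e_C}{elementary charge, C}
#'   \item{eps0_F_m}{vacuum permittivity, F/m}
#'   \item{N_A}{Avogadro constant, 1/mol}
#'   \item{kB_J_K}{Boltzmann constant, J/K}
#'   \item{R_kcal_mol_K}{molar gas constant, kcal/(mol K)}
#'   \item{debye_Cm}{1 Debye in C m}
#'   \item{eA_to_debye}{1 e Angstrom expressed in Debye}
#' }
#' @examples
#' physicalConstants()$eA_to_debye  # ~4.80320
#' @export
physicalConstants <- function() {
  e  <- 1.602176634e-19
  db <- 3.33564e-30
  list(
    e_C           = e,
    eps0_F_m      = 8.8541878128e-12,
    N_A           = 6.02214076e23,
    kB_J_K        = 1.380649e-23,
    R_kcal_mol_K  = 1.380649e-23 * 6.02214076e23 / 4184,
    debye_Cm      = db,
    eA_to_debye   = e * 1e-10 / db
  )
}

## internal shorthand (evaluated once at load)
.const <- physicalConstants()
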