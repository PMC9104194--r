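# Physical constants (CODATA 2018). Kept internal and immutable; all
# computations in the package are SI.
.const <- list(
  mu0  = 4e-7 * pi,        # magnetic permeability of free space, T m / A
  g    = 9.80665,          # standard gravitational acceleration, m / s^2
  kB   = 1.380649e-23,     # Boltzmann constant, J / K
  NA_  = 6.02214076e23,    # Avogadro constant, 1 / mol
  muB  = 9.2740100783e-24  # Bohr magneton, J / T
)

#' Physical constants used by the MagLev model
#'
#' Returns the fixed CODATA values used throughout the package
#' (`mu0`, `g`, `kB`, `NA_`, `muB`), all in SI units.
#'
#' @return Named list of constants.
#' @export
maglev_constants <- function() .const
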