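#' Physical constants used throughout the package
#'
#' CODATA 2018 values, pinned in one place. Units: SI except where noted.
#'
#' @format A named list with elements
#' \describe{
#'   \item{R}{molar gas constant, J/(mol K)}
#'   \item{h}{Planck constant, J s}
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{eps0}{vacuum permittivity, F/m}
#' }
#' @export
bds_constants <- list(
  R    = 8.314462618,
  h    = 6.62607015e-34,
  kB   = 1.380649e-23,
  eps0 = 8.8541878128e-12
)

# S/cm -> S/m. Conductivities are stored in S/cm (the convention of the BDS
# literature, e.g. sigma_dc ~ 1e-10 .. 1e-15 S/cm near Tg) and converted to SI
# exactly here, nowhere else.
.sigma_cgs_to_si <- function(sigma_s_per_cm) 100 * sigma_s_per_cm

.LN10 <- log(10)
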