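#' Physical constants for the radon and methane budget
#'
#' Constants are exposed both as accessor functions and as a machine-readable
#' table ([constants_table()]), so that every unit conversion used by the
#' pipeline is inspectable.
#'
#' @name constants
NULL

RN_HALF_LIFE_D <- 3.82          # 222Rn half-life [d]
CH4_MOLAR_MASS <- 16.04         # [mg mmol^-1]
CM_H_TO_M_D <- 0.24             # 1 cm h^-1 = 0.24 m d^-1, the single k unit conversion
CH4_ATM_PPM <- 1.9              # default atmospheric CH4 mixing ratio [ppm]
R_ATM_M3 <- 8.20573660809596e-5 # gas constant [m3 atm K^-1 mol^-1]

#' Radioactive decay constant of radon-222
#'
#' lambda = ln(2) / 3.82 d = 0.18145 d^-1.
#'
#' @return Decay rate in d^-1.
#' @examples
#' rn_decay_constant()
#' exp(-rn_decay_constant() * 3.82)  # one half-life -> 0.5
#' @export
rn_decay_constant <- function() log(2) / RN_HALF_LIFE_D

#' Machine-readable table of the physical constants in use
#'
#' @return A tibble with columns `name`, `value`, `unit`, `note`.
#' @export
constants_table <- function() {
  tibble(
    name = c(
      "rn_half_life", "rn_decay_constant", "ch4_molar_mass",
      "cm_h_to_m_d", "ch4_atm_ppm", "gas_constant"
    ),
    value = c(
      RN_HALF_LIFE_D, rn_decay_constant(), CH4_MOLAR_MASS,
      CM_H_TO_M_D, CH4_ATM_PPM, R_ATM_M3
    ),
    unit = c("d", "d-1", "mg mmol-1", "(m d-1) per (cm h-1)", "ppm",
             "m3 atm K-1 mol-1"),
    note = c(
      "radon-222 half-life",
      "ln(2)/half-life",
      "methane molar mass",
      "gas transfer velocity unit conversion",
      "default atmospheric CH4 mixing ratio",
      "ideal gas constant"
    )
  )
}
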