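#' Species order used throughout the package
#'
#' All concentration vectors/matrices are indexed in this fixed order:
#' prothrombin (PT), antithrombin (AT), thrombin (Th), fibrinogen (Fg),
#' free fibrin (Fn), bounded fibrin (Fb). Concentrations are in micromolar
#' (uM); lengths, times and stresses are SI (m, s, Pa).
#'
#' @export
SPECIES <- c("PT", "AT", "Th", "Fg", "Fn", "Fb")

#' Reaction-network parameters
#'
#' Rate constants and switching thresholds of the reduced coagulation model:
#' thrombin is produced from prothrombin near thrombogenic wires and
#' neutralized by antithrombin; fibrin is cleaved from fibrinogen by thrombin
#' and, independently, where shear stress exceeds a threshold; free fibrin
#' adheres to wires and to already-bounded fibrin.
#'
#' The supplementary parameter tables of the originating experiments are not
#' public; the defaults below are of literature-consistent magnitude and were
#' scaled once so that accumulation dynamics complete within seconds of
#' simulated time at desk-scale resolution (see the methods vignette). Every
#' value is overridable here or via the YAML config.
#'
#' @param Kwt wire-stimulated thrombin production rate (1/s)
#' @param Kat antithrombin inhibition rate (1/(uM s))
#' @param Kth thrombin-stimulated fibrin production rate (1/s)
#' @param Km  Michaelis-type fibrinogen saturation constant (uM); enters the
#'   thrombin pathway as C_Th * C_Fg / (Km + C_Fg)
#' @param Kss shear-stimulated fibrin production rate (1/s)
#' @param Kwa wire-adhesion rate of free fibrin (1/s)
#' @param Kb  fibrin-fibrin adhesion rate (1/(uM s))
#' @param tau0 shear-stress threshold (Pa)
#' @param r0  wire-distance threshold (m)
#' @param n_hill Hill exponent controlling switch steepness (>= 1)
#' @param wire_switch_literal if TRUE use the literal increasing switch
#'   phi(r/r0) for the wire terms instead of the default proximity form
#'   1 - phi(r/r0) which is ~1 on the wire and ->0 far away
#' @return object of class `reaction_params`
#' @export
reaction_params <- function(Kwt = 2.0, Kat = 0.5, Kth = 2.0, Km = 1.0,
                            Kss = 2.0, Kwa = 50.0, Kb = 2.0,
                            tau0 = 2.0, r0 = 2e-5, n_hill = 4,
                            wire_switch_literal = FALSE) {
  p <- list(Kwt = Kwt, Kat = Kat, Kth = Kth, Km = Km, Kss = Kss,
            Kwa = Kwa, Kb = Kb, tau0 = tau0, r0 = r0, n_hill = n_hill,
            wire_switch_literal = isTRUE(wire_switch_literal))
  rates <- c("Kwt", "Kat", "Kth", "Kss", "Kwa", "Kb")
  for (nm in rates)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("reaction_params: '", nm, "' must be a single non-negative number")
  for (nm in c("Km", "tau0", "r0"))
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("reaction_params: '", nm, "' must be > 0")
  if (p$n_hill < 1) stop("reaction_params: 'n_hill' must be >= 1")
  class(p) <- "reaction_params"
  p
}

#' Fluid properties
#'
#' @param rho plasma density (kg/m^3)
#' @param mu  dynamic viscosity (Pa s)
#' @return object of class `fluid_properties`
#' @export
fluid_properties <- function(rho = 1030, mu = 1.3e-3) {
  if (rho <= 0 || mu <= 0) stop("fluid_properties: rho and mu must be > 0")
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Darcy porosity parameters
#'
#' The accumulated clot acts on the flow through a momentum sink
#' F = -pi_coeff * phi(C_Fb / Cfb0) * u, where phi is the Hill switch.
#'
#' @param pi_coeff porosity parameter, inverse permeability scale (kg/(m^3 s))
#' @param Cfb0 bounded-fibrin threshold (uM) below which the force vanishes
#' @param n_hill Hill exponent of the switch
#' @return object of class `porosity_params`
#' @export
porosity_params <- function(pi_coeff = 2e6, Cfb0 = 0.05, n_hill = 4) {
  if (pi_coeff < 0) stop("porosity_params: pi_coeff must be >= 0")
  if (Cfb0 <= 0) stop("porosity_params: Cfb0 must be > 0")
  structure(list(pi_coeff = pi_coeff, Cfb0 = Cfb0, n_hill = n_hill),
            class = "porosity_params")
}

#' Per-species diffusivities
#'
#' Plasma proteins have diffusivities of order 5e-11 m^2/s; the bounded
#' species Fb is not transported at all (its diffusivity is ignored).
#'
#' @param D scalar or named 6-vector of diffusivities (m^2/s)
#' @return named numeric vector over [SPECIES]
#' @export
species_diffusivities <- function(D = 5e-11) {
  if (length(D) == 1L) D <- rep(D, 6L)
  if (is.null(names(D))) names(D) <- SPECIES
  D <- D[SPECIES]
  if (any(is.na(D)) || any(D < 0)) stop("diffusivities must be >= 0 for all species")
  D[["Fb"]] <- 0
  D
}

#' Physiologic inlet concentrations (uM)
#'
#' Prothrombin 1.4 uM, antithrombin 2.41 uM, fibrinogen 7.0 uM; thrombin and
#' both fibrin species enter at zero.
#'
#' @param PT,AT,Fg inlet concentrations (uM)
#' @return named numeric vector over [SPECIES]
#' @export
inlet_concentrations <- function(PT = 1.4, AT = 2.41, Fg = 7.0) {
  c(PT = PT, AT = AT, Th = 0, Fg = Fg, Fn = 0, Fb = 0)
}

#' Convert a fibrinogen mass concentration to molarity
#'
#' @param mg_dl concentration in mg/dl
#' @param mw molecular weight of fibrinogen (g/mol), default 340 kDa
#' @return concentration in uM
#' @export
fibrinogen_mg_dl_to_uM <- function(mg_dl, mw = 340000) {
  # mg/dl -> g/L is /100; g/L -> mol/L is /mw; mol/L -> uM is *1e6
  mg_dl / 100 / mw * 1e6
}
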