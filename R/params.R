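#' Microbial kinetic and toxicity parameters
#'
#' Constructs the parameter set of the microbial module: Monod substrate
#' uptake, biomass yield, Luedeking-Piret phenazine production, first-order
#' mediator degradation and Hill-type growth inhibition by total phenazine.
#' Defaults are the aerobic glucose-grown \emph{E. coli} baseline used
#' throughout the package.
#'
#' @param qS_max Maximum specific substrate uptake rate, mmol gDW^-1 h^-1.
#' @param K_S Substrate half-saturation constant, mmol L^-1.
#' @param Y_XS Biomass yield on substrate, gDW mmol^-1.
#' @param alpha_P Growth-associated phenazine yield, mmol gDW^-1.
#' @param beta_P Non-growth-associated phenazine production rate,
#'   mmol gDW^-1 h^-1. Production is primarily growth-associated, so the
#'   default is 0; the term is exposed for constitutive-producer designs.
#' @param k_deg First-order phenazine degradation rate constant, h^-1
#'   (0 disables degradation). Applies equally to the reduced and oxidized
#'   pools.
#' @param K_inh Total-phenazine concentration at half-maximal growth
#'   inhibition, mmol L^-1 (default 0.01, i.e. 10 uM, the pyocyanin-informed
#'   scale). `Inf` disables toxicity.
#' @param n_inh Hill coefficient of inhibition (>= 1), dimensionless.
#'
#' @return An object of class `microbial_params` (a validated named list).
#' @examples
#' mp <- microbial_params()
#' specific_uptake(mp$K_S, mp)  # half of qS_max
#' @export
microbial_params <- function(qS_max = 10, K_S = 0.10, Y_XS = 0.09,
                             alpha_P = 0.03, beta_P = 0, k_deg = 0.01,
                             K_inh = 0.01, n_inh = 2) {
  p <- list(qS_max = qS_max, K_S = K_S, Y_XS = Y_XS, alpha_P = alpha_P,
            beta_P = beta_P, k_deg = k_deg, K_inh = K_inh, n_inh = n_inh)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("microbial_params: '", nm, "' must be a single finite number")
  }
  strict_pos <- c("qS_max", "K_S", "Y_XS", "K_inh", "n_inh")
  for (nm in strict_pos)
    if (p[[nm]] <= 0) stop("microbial_params: '", nm, "' must be > 0")
  # production and degradation may be switched off entirely
  for (nm in c("alpha_P", "beta_P", "k_deg"))
    if (p[[nm]] < 0) stop("microbial_params: '", nm, "' must be >= 0")
  if (p$n_inh < 1) stop("microbial_params: 'n_inh' must be >= 1")
  # K_inh = Inf is allowed (toxicity off); everything else must be finite
  for (nm in setdiff(names(p), "K_inh"))
    if (!is.finite(p[[nm]])) stop("microbial_params: '", nm, "' must be finite")
  structure(p, class = "microbial_params")
}

#' Electrochemical half-cell parameters
#'
#' Constants of the anolyte half-cell: lumped first-order electrode oxidation
#' of reduced phenazine, volumetric electrode area, Nernstian anode potential
#' of the two-electron phenazine couple, an ideal fixed-potential cathode, and
#' a single area-specific ohmic resistance. Defaults are representative of a
#' porous carbon-felt electrode in an aqueous phenazine cell.
#'
#' @param k_elec Lumped electrode oxidation rate constant, h^-1.
#' @param A Electrode area per anolyte volume, m^2 L^-1.
#' @param n_e Electrons per phenazine redox event (integer >= 1).
#' @param E0_an Standard anode potential, V vs SHE.
#' @param E_cath Fixed cathode potential, V vs SHE.
#' @param R_ohm Area-specific ohmic resistance, Ohm m^2.
#' @param T_K Temperature, K.
#' @param F_C Faraday constant, C mol^-1.
#' @param R_gas Universal gas constant, J mol^-1 K^-1.
#' @param nernst_floor Concentration floor (mmol L^-1) applied inside the
#'   Nernst log ratio so the anode potential stays finite when one pool is
#'   empty, e.g. at startup.
#'
#' @return An object of class `electro_params`.
#' @examples
#' ep <- electro_params()
#' cell_voltage(anode_potential(0.01, 0.01, ep), 0, ep)  # E_oc = 1.00 V
#' @export
electro_params <- function(k_elec = 20, A = 0.10, n_e = 2L, E0_an = -0.10,
                           E_cath = 0.90, R_ohm = 0.50, T_K = 298.15,
                           F_C = 96485, R_gas = 8.314, nernst_floor = 1e-9) {
  p <- list(k_elec = k_elec, A = A, n_e = as.numeric(n_e), E0_an = E0_an,
            E_cath = E_cath, R_ohm = R_ohm, T_K = T_K, F_C = F_C,
            R_gas = R_gas, nernst_floor = nernst_floor)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("electro_params: '", nm, "' must be a single finite number")
  }
  for (nm in c("k_elec", "A", "R_ohm", "T_K", "F_C", "R_gas", "nernst_floor"))
    if (p[[nm]] <= 0) stop("electro_params: '", nm, "' must be > 0")
  if (p$n_e < 1 || p$n_e != round(p$n_e))
    stop("electro_params: 'n_e' must be an integer >= 1")
  structure(p, class = "electro_params")
}

#' Instantaneous anolyte state
#'
#' A snapshot of the well-mixed anolyte: elapsed time, biomass, substrate and
#' the two phenazine redox pools, all per unit anolyte volume.
#'
#' @param t Elapsed time, h.
#' @param X Biomass concentration, gDW L^-1.
#' @param S Substrate concentration, mmol L^-1.
#' @param P_red Reduced phenazine concentration, mmol L^-1.
#' @param P_ox Oxidized phenazine concentration, mmol L^-1.
#'
#' @return An object of class `anolyte_state`.
#' @seealso [p_total()]
#' @examples
#' st <- anolyte_state(X = 0.05, S = 20)
#' p_total(st)
#' @export
anolyte_state <- function(t = 0, X = 0.05, S = 20, P_red = 0, P_ox = 0) {
  s <- list(t = t, X = X, S = S, P_red = P_red, P_ox = P_ox)
  for (nm in names(s)) {
    v <- s[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("anolyte_state: '", nm, "' must be a single finite number")
  }
  for (nm in c("X", "S", "P_red", "P_ox"))
    if (s[[nm]] < 0) stop("anolyte_state: '", nm, "' must be >= 0")
  structure(s, class = "anolyte_state")
}

#' Total phenazine concentration of a state
#'
#' @param state An [anolyte_state()].
#' @return P_red + P_ox, mmol L^-1.
#' @export
p_total <- function(state) state$P_red + state$P_ox

#' @export
print.microbial_params <- function(x, ...) {
  cat("Microbial parameters (Monod / Luedeking-Piret / Hill toxicity):\n")
  for (nm in names(x)) cat(sprintf("  %-8s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.electro_params <- function(x, ...) {
  cat("Electrochemical half-cell parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.anolyte_state <- function(x, ...) {
  cat(sprintf(
    "Anolyte state at t = %g h: X = %g gDW/L, S = %g mmol/L, P_red = %g, P_ox = %g (P_tot = %g mmol/L)\n",
    x$t, x$X, x$S, x$P_red, x$P_ox, x$P_red + x$P_ox))
  invisible(x)
}
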