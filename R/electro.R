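#' Electrode oxidation flux of reduced phenazine
#'
#' First-order lumped electrode kinetics: v_elec = k_elec * P_red, where
#' `k_elec` summarises mass-transfer and heterogeneous electron-transfer
#' limitations at the anode.
#'
#' @param P_red Reduced phenazine concentration, mmol L^-1 (>= 0).
#' @param e An [electro_params()].
#' @return Volumetric flux v_elec, mmol L^-1 h^-1.
#' @export
electrode_flux <- function(P_red, e) {
  if (any(P_red < 0)) stop("electrode_flux: P_red must be >= 0")
  e$k_elec * P_red
}

#' Current density from volumetric electrode flux
#'
#' Converts the volumetric flux (mmol of mediator per litre of anolyte per
#' hour) to a current density on the electrode,
#' j = n_e * F * v_elec / (A * 1000 * 3600) in A m^-2: the factor 1000
#' converts mmol to mol, 3600 converts per-hour to per-second, and division
#' by the volumetric electrode area A (m^2 L^-1) normalises per electrode
#' area. The sign of `j` follows the sign of `v_elec`.
#'
#' @param v_elec Volumetric flux, mmol L^-1 h^-1 (vectorised).
#' @param e An [electro_params()].
#' @return Current density j, A m^-2.
#' @seealso [recharge_flux()] (exact inverse, up to sign), [j_mA_cm2()]
#' @export
current_density <- function(v_elec, e) {
  e$n_e * e$F_C * v_elec / (e$A * 1000 * 3600)
}

#' Convert current density from A m^-2 to mA cm^-2
#'
#' 1 A m^-2 = 0.1 mA cm^-2. Reporting helper used in all outputs.
#'
#' @param j_A_m2 Current density in A m^-2.
#' @return Current density in mA cm^-2.
#' @export
j_mA_cm2 <- function(j_A_m2) j_A_m2 * 0.1

#' Nernstian anode potential of the phenazine couple
#'
#' E_an = E0_an + (R T / (n_e F)) * ln(P_ox / P_red), evaluated on
#' floor-protected concentrations max(P, nernst_floor) so the potential stays
#' finite when a pool is empty (e.g. at startup). When both pools are below
#' the floor the redox state is undefined and E0_an is returned with a
#' warning-level log message.
#'
#' @param P_ox Oxidized phenazine, mmol L^-1 (vectorised, >= 0).
#' @param P_red Reduced phenazine, mmol L^-1 (vectorised, >= 0).
#' @param e An [electro_params()].
#' @return Anode potential E_an, V vs SHE.
#' @export
anode_potential <- function(P_ox, P_red, e) {
  if (any(P_ox < 0) || any(P_red < 0))
    stop("anode_potential: concentrations must be >= 0")
  eps <- e$nernst_floor
  both_empty <- P_ox < eps & P_red < eps
  if (any(both_empty))
    bb_log("warn", "anode_potential: both phenazine pools below the ",
           "concentration floor (", sum(both_empty),
           " state(s)); returning E0_an for an undefined redox state")
  E <- e$E0_an + (e$R_gas * e$T_K / (e$n_e * e$F_C)) *
    log(pmax(P_ox, eps) / pmax(P_red, eps))
  E[both_empty] <- e$E0_an
  E
}

#' Open-circuit and terminal cell voltage
#'
#' E_oc = E_cath - E_an; V_cell = E_oc - j * R_ohm. The cathode is an ideal
#' counter-electrode at fixed potential and the only loss term is the lumped
#' area-specific ohmic resistance, so V_cell falls linearly in j with slope
#' -R_ohm.
#'
#' @param E_an Anode potential, V vs SHE (vectorised).
#' @param j Current density, A m^-2 (vectorised).
#' @param e An [electro_params()].
#' @return A list with components `E_oc` and `V_cell`, V.
#' @export
cell_voltage <- function(E_an, j, e) {
  E_oc <- e$E_cath - E_an
  list(E_oc = E_oc, V_cell = E_oc - j * e$R_ohm)
}

#' Volumetric flux equivalent of an imposed charging current
#'
#' During recharge a constant current density `j_charge` is imposed in the
#' opposite direction; the equivalent volumetric mediator flux is
#' v_elec = -j_charge * A * 1000 * 3600 / (n_e * F), the exact inverse of
#' [current_density()], with the negative sign indicating reduction of P_ox
#' to P_red.
#'
#' @param j_charge Imposed charging current density, A m^-2 (>= 0).
#' @param e An [electro_params()].
#' @return Volumetric flux, mmol L^-1 h^-1 (<= 0).
#' @export
recharge_flux <- function(j_charge, e) {
  if (any(j_charge < 0)) stop("recharge_flux: j_charge must be >= 0")
  -j_charge * e$A * 1000 * 3600 / (e$n_e * e$F_C)
}

#' Electrical observables for a set of states
#'
#' Evaluates flux, current density (both unit systems), anode potential and
#' cell voltages for vectors of pool concentrations; used to decorate
#' simulated trajectories.
#'
#' @param P_red,P_ox Phenazine pools, mmol L^-1 (vectorised).
#' @param v_elec Volumetric electrode flux, mmol L^-1 h^-1 (vectorised;
#'   signed during recharge).
#' @param e An [electro_params()].
#' @return A data.frame with columns `v_elec`, `j_A_m2`, `j_mA_cm2`, `E_an`,
#'   `E_oc`, `V_cell`.
#' @export
electrical_observables <- function(P_red, P_ox, v_elec, e) {
  j <- current_density(v_elec, e)
  E_an <- anode_potential(P_ox, P_red, e)
  cv <- cell_voltage(E_an, j, e)
  data.frame(v_elec = v_elec, j_A_m2 = j, j_mA_cm2 = j_mA_cm2(j),
             E_an = E_an, E_oc = cv$E_oc, V_cell = cv$V_cell)
}
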