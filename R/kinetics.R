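#' Monod specific substrate uptake rate
#'
#' qS = qS_max * S / (K_S + S). Saturates at `qS_max` and is monotone
#' non-decreasing in `S`.
#'
#' @param S Substrate concentration, mmol L^-1 (vectorised, >= 0).
#' @param p A [microbial_params()].
#' @return Specific uptake rate qS, mmol gDW^-1 h^-1.
#' @export
specific_uptake <- function(S, p) {
  if (any(S < 0)) stop("specific_uptake: S must be >= 0")
  p$qS_max * S / (p$K_S + S)
}

#' Hill-type toxicity factor
#'
#' Growth inhibition by total phenazine, 1 / (1 + (P_tot/K_inh)^n_inh).
#' Equals 1 in the absence of phenazine, 1/2 at `K_inh`, and decreases
#' sigmoidally toward 0; multiplies the base growth rate only.
#'
#' @param P_tot Total phenazine concentration, mmol L^-1 (vectorised, >= 0).
#' @param p A [microbial_params()].
#' @return Dimensionless factor in (0, 1].
#' @export
toxicity_factor <- function(P_tot, p) {
  if (any(P_tot < 0)) stop("toxicity_factor: P_tot must be >= 0")
  1 / (1 + (P_tot / p$K_inh)^p$n_inh)
}

#' Effective (toxicity-scaled) specific growth rate
#'
#' mu = Y_XS * qS(S) * f_tox(P_tot). The base growth rate Y_XS * qS is scaled
#' by the Hill toxicity factor, so 0 <= mu <= Y_XS * qS_max.
#'
#' @param state An [anolyte_state()].
#' @param p A [microbial_params()].
#' @return Effective growth rate mu, h^-1.
#' @export
growth_rate <- function(state, p) {
  p$Y_XS * specific_uptake(state$S, p) * toxicity_factor(p_total(state), p)
}

#' Luedeking-Piret phenazine production rate
#'
#' r_prod = (alpha_P * mu + beta_P) * X; primarily growth-associated, with an
#' optional constitutive term beta_P (0 by default).
#'
#' @param mu Effective growth rate, h^-1 (>= 0).
#' @param X Biomass concentration, gDW L^-1 (>= 0).
#' @param p A [microbial_params()].
#' @return Volumetric production rate, mmol L^-1 h^-1.
#' @export
production_rate <- function(mu, X, p) {
  if (any(mu < 0)) stop("production_rate: mu must be >= 0")
  if (any(X < 0)) stop("production_rate: X must be >= 0")
  (p$alpha_P * mu + p$beta_P) * X
}

#' Time derivatives of the microbial subsystem
#'
#' The coupled balances of the well-mixed anolyte:
#' \deqn{dX/dt = \mu X, \quad dS/dt = -q_S X,}
#' \deqn{dP_{red}/dt = r_{prod} - v_{elec} - k_{deg} P_{red}, \quad
#'       dP_{ox}/dt = v_{elec} - k_{deg} P_{ox}.}
#' The electrode flux `v_elec` may be negative (net reduction during
#' recharge); it cancels in the total-phenazine balance, so
#' d(P_red + P_ox)/dt = r_prod - k_deg * (P_red + P_ox) for any flux.
#'
#' @param state An [anolyte_state()].
#' @param v_elec Volumetric electrode flux, mmol L^-1 h^-1 (any sign).
#' @param p A [microbial_params()].
#' @return Named numeric vector `c(dX, dS, dP_red, dP_ox)`.
#' @export
microbial_derivatives <- function(state, v_elec, p) {
  qS <- specific_uptake(state$S, p)
  mu <- p$Y_XS * qS * toxicity_factor(p_total(state), p)
  r_prod <- production_rate(mu, state$X, p)
  c(dX = mu * state$X,
    dS = -qS * state$X,
    dP_red = r_prod - v_elec - p$k_deg * state$P_red,
    dP_ox = v_elec - p$k_deg * state$P_ox)
}
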