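#' @title Ionic flux laws of the smooth muscle cell model
#' @description
#' The three-variable cell model balances ten concentration currents
#' (all in uM/s).  Extracellular influx: a constant non-selective cation
#' current `Phi_A`, a store-operated current `Phi_S(zeta)`, a
#' voltage-operated current `Phi_V(eta)` and reverse-mode Na+/Ca2+
#' exchange `Phi_N(chi, eta)`.  Store exchange: SERCA uptake
#' `Phi_B(chi)`, Ca2+-induced Ca2+ release `Phi_C(chi, zeta)` and a
#' linear leak `Phi_L(zeta)`.  Membrane efflux and potential-shaping
#' currents: ATPase extrusion `Phi_D(chi, eta)` and the Cl-/K+ fluxes
#' `Phi_Cl`, `Phi_K`, which vanish at their reversal potentials.
#' All functions are vectorized over cells.
#' @name cell-fluxes
NULL

# Hill-type saturation gate; a zero half-point means a fully open gate
# (the tabulated Ca2+ sensitivities of the Cl-/K+ channels default to 0 uM).
ca_gate <- function(chi, K) {
  if (length(K) == 1L && K == 0) return(rep(1, length(chi)))
  chi / (chi + K)
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Extracellular Ca2+ influx currents
#'
#' @param state a [cell_state()] or a list/data.frame with vectors
#'   `chi`, `zeta`, `eta`.
#' @param p a [cell_params()] object (fields may be per-cell vectors).
#' @return List with components `Phi_A`, `Phi_S`, `Phi_V`, `Phi_N`
#'   (uM/s).
#' @export
extracellular_influx <- function(state, p) {
  chi <- state[["chi"]]; zeta <- state[["zeta"]]; eta <- state[["eta"]]
  if (!all(is.finite(chi), is.finite(zeta), is.finite(eta))) {
    stop("non-finite cell state: integration blow-up")
  }
  n <- max(length(chi), length(p$Phi_A))
  list(
    Phi_A = rep_len(p$Phi_A, n),
    Phi_S = p$A_S * p$zeta_S^2 / (p$zeta_S^2 + zeta^2),
    Phi_V = p$E_Ca * (p$z_Ca1 - eta) * logistic((eta - p$z_Ca2) / p$R_Ca),
    Phi_N = p$E_NCX * ca_gate(chi, p$x_NCX) * (eta - p$z_NCX)
  )
}

#' Sarcoplasmic reticulum exchange currents
#'
#' SERCA uptake is a Hill sigmoid of cytosolic Ca2+ (exponent `n_SR`,
#' half-point `x_SR`); CICR combines a store-load sigmoid (exponent
#' `m_Ry`, half-point `y_Ry`) with a cytosolic activation sigmoid
#' (exponent `p_Ry`, half-point `x_Ry`); leak is linear in store load.
#'
#' @inheritParams extracellular_influx
#' @return List with components `Phi_B`, `Phi_C`, `Phi_L` (uM/s).
#' @export
store_exchange <- function(state, p, check = TRUE) {
  chi <- state[["chi"]]; zeta <- state[["zeta"]]
  # tolerance admits round-off transients of an embedded integrator stage
  if (check && (any(chi < -1e-9) || any(zeta < -1e-9))) {
    stop("negative concentration passed to store_exchange")
  }
  list(
    Phi_B = p$B_SR * chi^p$n_SR / (chi^p$n_SR + p$x_SR^p$n_SR),
    Phi_C = p$C_Ry * (zeta^p$m_Ry / (zeta^p$m_Ry + p$y_Ry^p$m_Ry)) *
      (chi^p$p_Ry / (chi^p$p_Ry + p$x_Ry^p$p_Ry)),
    Phi_L = p$L_SR * zeta
  )
}

#' Membrane efflux currents
#'
#' @inheritParams extracellular_influx
#' @return List with components `Phi_D`, `Phi_Cl`, `Phi_K` (uM/s).
#' @export
membrane_efflux <- function(state, p) {
  chi <- state[["chi"]]; eta <- state[["eta"]]
  if (!all(is.finite(chi), is.finite(eta))) {
    stop("non-finite cell state: integration blow-up")
  }
  list(
    Phi_D = p$D_EX * chi^p$k_Ex * (1 + (eta - p$z_Ex) / p$R_Ex),
    Phi_Cl = p$E_Cl * ca_gate(chi, p$x_Cl) * (eta - p$z_Cl),
    Phi_K = p$E_K * ca_gate(chi, p$beta_K) * (eta - p$z_K) *
      logistic((eta - p$z_Ca3) / p$R_K)
  )
}

#' All ten concentration currents at once
#'
#' @inheritParams extracellular_influx
#' @return List with the ten flux components.
#' @export
flux_vector <- function(state, p, check = TRUE) {
  c(extracellular_influx(state, p),
    store_exchange(state, p, check = check),
    membrane_efflux(state, p))
}

#' Net gap-junctional exchange currents
#'
#' Net Ca2+ and voltage exchange of every cell with its neighbours,
#' linear in the state differences: `J_i = alpha * sum_j (s_j - s_i)`
#' over the adjacency list.  Pairwise antisymmetry makes the currents
#' sum to zero over the whole network.
#'
#' @param values per-cell numeric vector (chi or eta).
#' @param adjacency list of integer neighbour-index vectors.
#' @param alpha diffusivity (1/s).
#' @return per-cell net current vector.
#' @export
coupling_current <- function(values, adjacency, alpha) {
  n <- length(values)
  if (length(adjacency) != n) stop("adjacency length != number of cells")
  if (alpha == 0) return(numeric(n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- adjacency[[i]]
    if (length(nb)) {
      if (any(nb < 1L | nb > n)) stop("dangling neighbour index for cell ", i)
      out[i] <- alpha * sum(values[nb] - values[i])
    }
  }
  out
}

#' Right-hand side of the cell network ODE system
#'
#' Time derivatives of (chi, zeta, eta) for every cell, combining the
#' ionic fluxes with (frozen) gap-junctional coupling currents:
#' \deqn{\dot\chi = \Phi_A + \Phi_S + \Phi_V + \Phi_N - \Phi_B + \Phi_C
#'   + \Phi_L - \Phi_D + \tilde J_{Ca}}
#' \deqn{\dot\zeta = \Phi_B - \Phi_C - \Phi_L}
#' \deqn{\dot\eta = \gamma(\Phi_V - \Phi_N - \Phi_{Cl} - \Phi_K)
#'   + \tilde J_V}
#' The scaling factor `gamma` converts the net charge-carrying ion
#' movement into a membrane-potential rate; depolarizing currents
#' (voltage-gated Ca2+ entry, Cl- efflux below its reversal) enter with
#' positive sign, repolarizing ones (K+ efflux, electrogenic exchanger)
#' negatively.
#'
#' @param state list with per-cell vectors `chi`, `zeta`, `eta`.
#' @param p [cell_params()]; `Phi_A` may be a per-cell vector.
#' @param J_Ca,J_V per-cell frozen coupling currents (default 0).
#' @return List of per-cell derivative vectors `dchi`, `dzeta`, `deta`.
#' @export
cell_rhs <- function(state, p, J_Ca = 0, J_V = 0, check = TRUE) {
  fl <- flux_vector(state, p, check = check)
  dchi <- fl$Phi_A + fl$Phi_S + fl$Phi_V + fl$Phi_N -
    fl$Phi_B + fl$Phi_C + fl$Phi_L - fl$Phi_D + J_Ca
  dzeta <- fl$Phi_B - fl$Phi_C - fl$Phi_L
  deta <- p$gamma * (fl$Phi_V - fl$Phi_N - fl$Phi_Cl - fl$Phi_K) + J_V
  list(dchi = dchi, dzeta = dzeta, deta = deta)
}
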