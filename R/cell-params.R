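#' Ionic model parameters for one smooth muscle cell
#'
#' Returns the reference parameter set of the three-variable smooth muscle
#' cell model: cytosolic Ca2+ concentration `chi` (uM), sarcoplasmic
#' reticulum Ca2+ `zeta` (uM) and membrane potential `eta` (V).  Units are
#' kept exactly as tabulated (uM, V, s); there is no internal unit
#' conversion, so parameter sets are copy-verifiable against the reference
#' table.
#'
#' @param ... named overrides of any default parameter.
#' @return An object of class `cell_params`: a named list with fields
#'   \describe{
#'     \item{Phi_A}{Ca2+ influx via non-selective cation channels (uM/s).}
#'     \item{L_SR}{store leak rate constant (1/s).}
#'     \item{gamma}{scaling of net ion movement into membrane-potential
#'       rate (V/uM).}
#'     \item{A_S, zeta_S}{store-operated channel amplitude (1/s) and store
#'       half-point (uM).}
#'     \item{E_Ca, z_Ca1, z_Ca2, R_Ca}{voltage-operated channel conductance
#'       (uM/(V s)), reversal potential (V), activation half-point (V) and
#'       slope (V).}
#'     \item{E_NCX, z_NCX, x_NCX}{Na+/Ca2+ exchanger conductance
#'       (uM/(V s)), reversal potential (V) and Ca2+ half-activation (uM).}
#'     \item{B_SR, x_SR, n_SR}{SERCA uptake rate (uM/s), half-point (uM)
#'       and Hill coefficient.}
#'     \item{C_Ry, y_Ry, x_Ry, m_Ry, p_Ry}{CICR release rate (uM/s), store
#'       efflux half-point (uM), cytosolic activation half-point (uM) and
#'       the two Hill coefficients.}
#'     \item{D_EX, z_Ex, R_Ex, k_Ex}{plasmalemmal Ca2+-ATPase extrusion
#'       rate (uM/s), voltage offset (V), voltage slope (V) and
#'       concentration exponent.}
#'     \item{E_Cl, z_Cl, x_Cl}{Cl- channel conductance (uM/(V s)),
#'       reversal potential (V) and Ca2+ sensitivity (uM).}
#'     \item{E_K, z_K, z_Ca3, R_K, beta_K}{K+ efflux conductance
#'       (uM/(V s)), reversal potential (V), activation half-point (V),
#'       slope (V) and Ca2+ sensitivity (uM).}
#'     \item{alpha_C, alpha_V}{intercellular Ca2+ and voltage diffusivity
#'       (1/s).}
#'   }
#' @export
#' @examples
#' p <- cell_params(Phi_A = 0.8)
#' p$Phi_A
cell_params <- function(...) {
  p <- list(
    Phi_A = 0.6,   # Ca2+ influx via NSCC (uM/s)
    L_SR  = 0.025, # SR leak rate constant (1/s)
    gamma = 1.0,   # scaling factor (V/uM)
    A_S    = 0.0,  # SOCC amplitude (1/s)
    zeta_S = 4.0,  # SOCC store half-point (uM)
    E_Ca  = 12.0,    # VOCC conductance (uM/(V s))
    z_Ca1 = 0.13,    # VOCC reversal potential (V)
    z_Ca2 = -0.024,  # VOCC activation half-point (V)
    R_Ca  = 0.0085,  # VOCC activation slope (V)
    E_NCX = 43.8,  # NCX conductance (uM/(V s))
    z_NCX = -0.04, # NCX reversal potential (V)
    x_NCX = 0.5,   # NCX Ca2+ half-activation (uM)
    B_SR = 400.0, # SERCA uptake rate (uM/s)
    x_SR = 4.4,   # SERCA half-point (uM)
    n_SR = 2L,    # SERCA Hill coefficient
    C_Ry = 1250.0, # CICR rate (uM/s)
    y_Ry = 8.9,    # CICR store efflux half-point (uM)
    x_Ry = 0.9,    # CICR cytosolic activation half-point (uM)
    m_Ry = 2L,     # CICR store Hill coefficient
    p_Ry = 4L,     # CICR cytosolic Hill coefficient
    D_EX = 6.25, # extrusion ATPase rate (uM/s)
    z_Ex = -0.1, # extrusion voltage offset (V)
    R_Ex = 0.25, # extrusion voltage slope (V)
    k_Ex = 2L,   # extrusion concentration exponent
    E_Cl = 65.0,   # Cl- conductance (uM/(V s))
    z_Cl = -0.025, # Cl- reversal potential (V)
    x_Cl = 0.0,    # Cl- Ca2+ sensitivity (uM)
    E_K    = 43.0,   # K+ conductance (uM/(V s))
    z_K    = -0.095, # K+ reversal potential (V)
    z_Ca3  = -0.027, # K+ activation half-point (V)
    R_K    = 0.012,  # K+ activation slope (V)
    beta_K = 0.0,    # K+ Ca2+ sensitivity (uM)
    alpha_C = 1.0, # intercellular Ca2+ diffusivity (1/s)
    alpha_V = 1.0  # intercellular voltage diffusivity (1/s)
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) {
      stop("unknown cell parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(ov)] <- ov
  }
  validate_cell_params(p)
  class(p) <- "cell_params"
  p
}

validate_cell_params <- function(p) {
  nn <- c("L_SR", "A_S", "E_Ca", "E_NCX", "B_SR", "C_Ry", "D_EX", "E_Cl",
          "E_K", "alpha_C", "alpha_V", "x_SR", "y_Ry", "x_Ry", "x_NCX")
  for (f in nn) {
    if (any(p[[f]] < 0)) stop("cell parameter ", f, " must be >= 0")
  }
  for (f in c("n_SR", "m_Ry", "p_Ry")) {
    v <- p[[f]]
    if (any(v <= 0) || any(v != round(v))) {
      stop("Hill exponent ", f, " must be a positive integer")
    }
  }
  invisible(p)
}

#' Initial state of one smooth muscle cell
#'
#' Reference initial conditions: chi = 0.1 uM, zeta = 0.2 uM,
#' eta = -0.02 V.
#'
#' @param chi cytosolic Ca2+ concentration (uM).
#' @param zeta store Ca2+ concentration (uM).
#' @param eta membrane potential (V).
#' @return Named numeric vector of class `cell_state`.
#' @export
cell_state <- function(chi = 0.1, zeta = 0.2, eta = -0.02) {
  if (!all(is.finite(c(chi, zeta, eta)))) stop("cell state must be finite")
  if (chi < 0 || zeta < 0) stop("concentrations must be non-negative")
  s <- c(chi = chi, zeta = zeta, eta = eta)
  class(s) <- "cell_state"
  s
}
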