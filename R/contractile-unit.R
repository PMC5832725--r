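#' Contractile-unit parameters
#'
#' Mechanochemical constants of the filament-sliding contractile unit
#' (CU): `alpha_a`/`beta_a` set the mobility of the chemically driven
#' sliding (force balance), `kappa_AMp` scales the power-stroke driving
#' stress of a phosphorylated cross-bridge and `kappa_AM` the
#' force-bearing capacity of the latch bridge in extension, `u_opt` and
#' `s_overlap` parameterize the parabolic filament-overlap function,
#' and `mu_a` is the active shear modulus shared with the tissue model.
#'
#' @param ... named overrides of the defaults (alpha_a = 26.68 kPa,
#'   beta_a = 0.00833 1/s, kappa_AMp = 203.71 kPa, kappa_AM = 61.14
#'   kPa, u_opt = 0.48, s_overlap = 0.4255, mu_a = 5301 kPa).
#' @return Object of class `cu_params`.
#' @export
cu_params <- function(...) {
  p <- list(alpha_a = 26.68, beta_a = 0.00833, kappa_AMp = 203.71,
            kappa_AM = 61.14, u_opt = 0.48, s_overlap = 0.4255,
            mu_a = 5301.0)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown CU parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  if (any(unlist(p) <= 0)) stop("CU parameters must be positive")
  class(p) <- "cu_params"
  p
}

#' Contractile-unit state at one Gauss point
#'
#' Filament sliding is normalized to the reference CU length and is
#' negative in contraction.  It decomposes into a chemical component
#' `u_fs_c` (power-stroke driven, evolved by the force balance) and a
#' mechanical component `u_fs_m` (externally driven; identically zero
#' under the isometric protocols, kept as a tracked field so the
#' closure `u_fs = u_fs_c + u_fs_m` is explicit).
#'
#' @param u_fs_c,u_fs_m sliding components (dimensionless).
#' @param lam CU stretch (ratio of current to reference CU length).
#' @return Object of class `cu_state` with fields `u_fs_c`, `u_fs_m`,
#'   `u_fs`, `lam`.
#' @export
cu_state <- function(u_fs_c = 0, u_fs_m = 0, lam = 1) {
  stopifnot(lam > 0)
  structure(list(u_fs_c = u_fs_c, u_fs_m = u_fs_m,
                 u_fs = u_fs_c + u_fs_m, lam = lam),
            class = "cu_state")
}

#' Average elastic elongation of the attached cross-bridges
#'
#' \deqn{\bar u_e = \lambda - 1 - u_{fs}} (normalized to the reference
#' CU length; negative in contraction).  Zero in the reference
#' configuration and strictly increasing in the stretch.
#'
#' @param lam CU stretch (> 0), vectorized.
#' @param u_fs relative filament sliding.
#' @return elastic elongation (dimensionless).
#' @export
elastic_elongation <- function(lam, u_fs) {
  if (any(lam <= 0)) stop("lam must be > 0")
  lam - 1 - u_fs
}

#' Relative filament overlap
#'
#' Parabola in the filament sliding with vertex at `u_fs = -u_opt`
#' (the overlap optimum is reached while contracting) and half-width
#' `s_overlap`, clamped at zero where the parabola is negative:
#' \deqn{L(u_{fs}) = \max\{0,\; 1 - ((u_{fs} + u_{opt})/s)^2\}.}
#'
#' @param u_fs relative filament sliding, vectorized.
#' @param p a [cu_params()].
#' @return overlap fraction in [0, 1].
#' @export
overlap <- function(u_fs, p) {
  pmax(0, 1 - ((u_fs + p$u_opt) / p$s_overlap)^2)
}

#' Cross-bridge driving stress
#'
#' The internal stress driving filament sliding depends on the
#' contraction/relaxation regime of the CU: in contraction only the
#' cycling phosphorylated bridges drive,
#' `P_c = kappa_AMp * n_AMp`; in extension the dephosphorylated latch
#' bridges additionally bear force,
#' `P_c = kappa_AMp * n_AMp + kappa_AM * n_AM`.
#'
#' @param s a [cb_state()] or list with `n_AMp`, `n_AM` (vectorized).
#' @param regime `"contraction"` or `"extension"`.
#' @param p a [cu_params()].
#' @return driving stress (kPa).
#' @export
driving_stress <- function(s, regime = c("contraction", "extension"), p) {
  regime <- match.arg(regime)
  n_AMp <- if (is.list(s)) s$n_AMp else s[["n_AMp"]]
  n_AM <- if (is.list(s)) s$n_AM else s[["n_AM"]]
  out <- p$kappa_AMp * n_AMp
  if (regime == "extension") out <- out + p$kappa_AM * n_AM
  out
}

#' Filament-sliding resistance stress
#'
#' The (averaged) first Piola-Kirchhoff stress borne by the CU,
#' proportional to the active shear modulus, the attached fraction and
#' the filament overlap:
#' \deqn{P_a = \mu_a\,L(u_{fs})\,(n_{AMp}+n_{AM})\,\bar u_e.}
#'
#' @param lam CU stretch, vectorized.
#' @param u_fs relative filament sliding.
#' @param n_AMp,n_AM attached fractions.
#' @param p a [cu_params()].
#' @return stress (kPa).
#' @export
filament_stress <- function(lam, u_fs, n_AMp, n_AM, p) {
  p$mu_a * overlap(u_fs, p) * (n_AMp + n_AM) *
    elastic_elongation(lam, u_fs)
}

# Stick-slip selection of the sliding rate (1/s).  The regime is found
# by trial: the contraction branch applies if it predicts shortening,
# the extension branch if it predicts lengthening; otherwise the CU is
# stuck at the case boundary.  The selected rate is continuous in the
# driving quantities.
ufs_rate <- function(P_a, n_AMp, n_AM, p) {
  mob <- p$beta_a / p$alpha_a
  r_con <- mob * (P_a - p$kappa_AMp * n_AMp)
  r_ext <- mob * (P_a - (p$kappa_AMp * n_AMp + p$kappa_AM * n_AM))
  ifelse(r_con <= 0, r_con, pmax(r_ext, 0))
}

#' Forward-Euler update of the chemical sliding component
#'
#' The chemical component of the filament sliding evolves by the force
#' balance between the filament resistance `P_a` and the regime-
#' dependent driving stress `P_c`:
#' \deqn{\dot u_{fs}^c = (\beta_a/\alpha_a)\,(P_a - P_c),}
#' evaluated with the deformed configuration (stretch `lam`) of the
#' previous continuum step (lagged coupling).  Stationary when the
#' driving stress exactly balances the resistance, and inert when no
#' bridges are attached.
#'
#' @param u_fs_c current chemical sliding component (vectorized).
#' @param lam_prev CU stretch of the previous continuum step.
#' @param n_AMp,n_AM attached fractions.
#' @param dt_cell step (s).
#' @param p a [cu_params()].
#' @param u_fs_m mechanical sliding component (default 0).
#' @return updated `u_fs_c`.
#' @export
evolve_ufs_c <- function(u_fs_c, lam_prev, n_AMp, n_AM, dt_cell, p,
                         u_fs_m = 0) {
  u_fs <- u_fs_c + u_fs_m
  P_a <- filament_stress(lam_prev, u_fs, n_AMp, n_AM, p)
  rate <- ufs_rate(P_a, n_AMp, n_AM, p)
  if (any(abs(rate) * dt_cell > 0.05)) {
    stop("filament sliding step too large; reduce dt_cell")
  }
  u_fs_c + dt_cell * rate
}

#' Active free energy and its fibre-invariant derivatives
#'
#' Active free energy of the CU,
#' \deqn{\Psi_a = \tfrac{\mu_a}{2} L(u_{fs}) (n_{AMp}+n_{AM})
#'   (\lambda - 1 - u_{fs})^2,\qquad \lambda = \sqrt{\bar I_4},}
#' with analytic first and second derivatives with respect to the
#' (isochoric) fourth invariant, chain-ruled through the stretch.
#' These derivatives are what the tissue stress and consistent tangent
#' consume.
#'
#' @param I4 fibre invariant (> 0), vectorized.
#' @param u_fs relative filament sliding.
#' @param n_AMp,n_AM attached fractions.
#' @param p a [cu_params()].
#' @return list with `psi` (kPa), `dI4` (kPa), `d2I4` (kPa).
#' @export
active_energy_derivs <- function(I4, u_fs, n_AMp, n_AM, p) {
  if (any(I4 <= 0)) stop("kinematic error: I4 must be > 0")
  lam <- sqrt(I4)
  cfac <- 0.5 * p$mu_a * overlap(u_fs, p) * (n_AMp + n_AM)
  ue <- lam - 1 - u_fs
  list(psi = cfac * ue^2,
       dI4 = cfac * ue / lam,
       d2I4 = cfac * (1 + u_fs) / (2 * lam^3))
}
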