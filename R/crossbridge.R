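#' Cross-bridge kinetic parameters
#'
#' Rate constants of the four-state actin-myosin cycle: tau_0 scales
#' the Ca2+-dependent phosphorylation rate (its saturation constant is
#' chi_0, enhanced by the dimensionless coefficient theta), tau_2 is
#' dephosphorylation, tau_3/tau_4 attach/detach the phosphorylated
#' bridge and tau_5 detaches the latch bridge.
#'
#' @param ... named overrides of the defaults
#'   (tau_0 = 1.7, tau_2 = 0.5, tau_3 = 0.4, tau_4 = 0.1, tau_5 = 1.0 1/s;
#'   chi_0 = 0.6 uM; theta = 1).
#' @return Object of class `cb_params`.
#' @export
cb_params <- function(...) {
  p <- list(tau_0 = 1.7, tau_2 = 0.5, tau_3 = 0.4, tau_4 = 0.1, tau_5 = 1.0,
            chi_0 = 0.6, theta = 1.0)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown CB parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  if (any(unlist(p) < 0)) stop("CB parameters must be >= 0")
  class(p) <- "cb_params"
  p
}

#' Cross-bridge state
#'
#' Fractions of the four cross-bridge states.  Conservation
#' `n_M + n_Mp + n_AMp + n_AM = 1` is structural: `n_M` is stored
#' implicitly as one minus the other three.
#'
#' @param n_Mp,n_AMp,n_AM fractions of phosphorylated (detached),
#'   attached phosphorylated and attached dephosphorylated (latch)
#'   bridges.  Default is the detached initial condition
#'   `n_M = n_Mp = 0.5`.
#' @return Named numeric vector `c(n_Mp, n_AMp, n_AM)` of class
#'   `cb_state`; use [cb_fractions()] for all four fractions.
#' @export
cb_state <- function(n_Mp = 0.5, n_AMp = 0, n_AM = 0) {
  s <- c(n_Mp = n_Mp, n_AMp = n_AMp, n_AM = n_AM)
  if (any(s < -1e-9) || sum(s) > 1 + 1e-9) stop("invalid CB fractions")
  class(s) <- "cb_state"
  s
}

#' All four cross-bridge fractions (including the implicit n_M)
#'
#' @param s a [cb_state()] (or matrix with columns n_Mp, n_AMp, n_AM).
#' @return Named vector/matrix including `n_M = 1 - n_Mp - n_AMp - n_AM`.
#' @export
cb_fractions <- function(s) {
  if (is.matrix(s)) {
    cbind(n_M = 1 - rowSums(s), s)
  } else {
    c(n_M = 1 - sum(unclass(s)), unclass(s))
  }
}

# Declarative transition edge list of the four-state cycle.  Each row is
# one arrow of the kinetic scheme: phosphorylation (rate tau1, Ca2+
# dependent) acts on both detached and attached bridges,
# dephosphorylation (tau_2) likewise, tau_3/tau_4 attach/detach the
# phosphorylated bridge, and tau_5 releases the dephosphorylated latch
# bridge back to free myosin.
cb_edges <- function(tau1, p) {
  data.frame(
    from = c("n_M", "n_Mp", "n_Mp", "n_AMp", "n_AMp", "n_AM", "n_AM"),
    to   = c("n_Mp", "n_M", "n_AMp", "n_Mp", "n_AM", "n_AMp", "n_M"),
    rate = c(tau1, p$tau_2, p$tau_3, p$tau_4, p$tau_2, tau1, p$tau_5)
  )
}

#' Generator matrix of the cross-bridge kinetics
#'
#' Builds the 4x4 rate matrix `A` with `d n/dt = A n` over the state
#' order (n_M, n_Mp, n_AMp, n_AM) from the declarative edge list, so
#' the transition graph is auditable.  Columns sum to zero (closed
#' system).
#'
#' @param tau1 phosphorylation rate (1/s), see [tau1()].
#' @param p a [cb_params()].
#' @return 4x4 numeric matrix.
#' @export
cb_rate_matrix <- function(tau1, p) {
  states <- c("n_M", "n_Mp", "n_AMp", "n_AM")
  A <- matrix(0, 4, 4, dimnames = list(states, states))
  e <- cb_edges(tau1, p)
  for (k in seq_len(nrow(e))) {
    A[e$to[k], e$from[k]] <- A[e$to[k], e$from[k]] + e$rate[k]
    A[e$from[k], e$from[k]] <- A[e$from[k], e$from[k]] - e$rate[k]
  }
  A
}

#' Ca2+-dependent phosphorylation rate
#'
#' Saturating (quartic Hill) function of cytosolic Ca2+ with scale
#' `tau_0`, saturation constant `chi_0` and the multiplicative
#' enhancement coefficient `theta`:
#' \deqn{\tau_1(\chi) = \theta\,\tau_0\,\chi^4 / (\chi^4 + \chi_0^4).}
#' Vanishes at `chi = 0` (no Ca2+, no phosphorylation drive).
#'
#' @param chi cytosolic Ca2+ (uM), vectorized.
#' @param p a [cb_params()]; `theta` may be a per-cell vector.
#' @return rate (1/s).
#' @export
tau1 <- function(chi, p) {
  if (any(chi < 0)) stop("chi must be >= 0")
  p$theta * p$tau_0 * chi^4 / (chi^4 + p$chi_0^4)
}

#' Time derivatives of the cross-bridge fractions
#'
#' Linear kinetics over the transition graph; the four derivatives sum
#' to zero exactly.
#'
#' @param s a [cb_state()] (three independent fractions).
#' @param tau1_val phosphorylation rate (1/s).
#' @param p a [cb_params()].
#' @return named vector of the four derivatives
#'   (dn_M, dn_Mp, dn_AMp, dn_AM).
#' @export
cb_rhs <- function(s, tau1_val, p) {
  n <- cb_fractions(s)
  A <- cb_rate_matrix(tau1_val, p)
  drop(A %*% n)
}

# Vectorized over cells: S is an n x 3 matrix (n_Mp, n_AMp, n_AM),
# tau1v a per-cell rate vector.  Returns the derivative matrix for the
# three independent fractions; n_M stays implicit.
cb_rhs_matrix <- function(S, tau1v, p) {
  n_Mp <- S[, 1L]; n_AMp <- S[, 2L]; n_AM <- S[, 3L]
  n_M <- 1 - n_Mp - n_AMp - n_AM
  cbind(
    tau1v * n_M - (p$tau_2 + p$tau_3) * n_Mp + p$tau_4 * n_AMp,
    p$tau_3 * n_Mp - (p$tau_4 + p$tau_2) * n_AMp + tau1v * n_AM,
    p$tau_2 * n_AMp - (tau1v + p$tau_5) * n_AM
  )
}

#' Advance cross-bridge fractions by one forward-Euler step
#'
#' Conservation is preserved exactly by construction (n_M implicit);
#' a guard rejects steps that push any fraction outside [0, 1] beyond
#' 1e-9.
#'
#' @param s a [cb_state()] or an n x 3 matrix (per-cell rows).
#' @param chi cytosolic Ca2+ (uM), scalar or per-cell.
#' @param dt_cell step (s).
#' @param p a [cb_params()].
#' @return updated state of the same shape.
#' @export
step_cb <- function(s, chi, dt_cell, p) {
  S <- if (is.matrix(s)) s else matrix(unclass(s), 1L, 3L)
  tv <- tau1(chi, p)
  S1 <- S + dt_cell * cb_rhs_matrix(S, tv, p)
  nM1 <- 1 - rowSums(S1)
  if (min(S1, nM1) < -1e-9 || max(S1, nM1) > 1 + 1e-9) {
    stop("CB fraction left [0,1]: reduce dt_cell (dt = ", dt_cell, ")")
  }
  if (is.matrix(s)) S1 else {
    out <- drop(S1); names(out) <- c("n_Mp", "n_AMp", "n_AM")
    class(out) <- "cb_state"
    out
  }
}

#' Steady-state cross-bridge fractions at constant Ca2+
#'
#' Solves the nullspace of the rate matrix (the zero-eigenvalue
#' eigenvector normalized to total fraction one).
#'
#' @param chi cytosolic Ca2+ (uM).
#' @param p a [cb_params()].
#' @return named vector of the four steady fractions.
#' @export
cb_steady_state <- function(chi, p) {
  A <- cb_rate_matrix(tau1(chi, p), p)
  # replace one balance row by the conservation constraint
  M <- rbind(A[1:3, ], rep(1, 4))
  b <- c(0, 0, 0, 1)
  x <- solve(M, b)
  names(x) <- rownames(A)
  x
}
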