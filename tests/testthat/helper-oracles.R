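# Independent re-implementations used as test oracles.  These are
# deliberately written in a different style (scalar, closed-form,
# no shared code) from the package internals they check.

# --- ionic flux laws, second transcription -------------------------------
oracle_fluxes <- function(chi, zeta, eta, p) {
  sig <- function(v, v0, slope) 1 / (1 + exp(-(v - v0) / slope))
  gate <- function(c, K) if (K == 0) 1 else c / (c + K)
  list(
    Phi_A = p$Phi_A,
    Phi_S = p$A_S * p$zeta_S^2 / (p$zeta_S^2 + zeta^2),
    Phi_V = p$E_Ca * (p$z_Ca1 - eta) * sig(eta, p$z_Ca2, p$R_Ca),
    Phi_N = p$E_NCX * gate(chi, p$x_NCX) * (eta - p$z_NCX),
    Phi_B = p$B_SR * chi^p$n_SR / (chi^p$n_SR + p$x_SR^p$n_SR),
    Phi_C = p$C_Ry * (zeta^p$m_Ry / (zeta^p$m_Ry + p$y_Ry^p$m_Ry)) *
      (chi^p$p_Ry / (chi^p$p_Ry + p$x_Ry^p$p_Ry)),
    Phi_L = p$L_SR * zeta,
    Phi_D = p$D_EX * chi^p$k_Ex * (1 + (eta - p$z_Ex) / p$R_Ex),
    Phi_Cl = p$E_Cl * gate(chi, p$x_Cl) * (eta - p$z_Cl),
    Phi_K = p$E_K * gate(chi, p$beta_K) * (eta - p$z_K) *
      sig(eta, p$z_Ca3, p$R_K)
  )
}

oracle_rhs <- function(y, p, J_Ca = 0, J_V = 0) {
  f <- oracle_fluxes(y[1], y[2], y[3], p)
  c(f$Phi_A + f$Phi_S + f$Phi_V + f$Phi_N - f$Phi_B + f$Phi_C + f$Phi_L -
      f$Phi_D + J_Ca,
    f$Phi_B - f$Phi_C - f$Phi_L,
    p$gamma * (f$Phi_V - f$Phi_N - f$Phi_Cl - f$Phi_K) + J_V)
}

# classical fixed-step RK4 on one cell
oracle_rk4 <- function(y0, p, t_end, dt) {
  n <- round(t_end / dt)
  y <- y0
  out <- matrix(NA_real_, n + 1L, 3)
  out[1L, ] <- y
  for (k in seq_len(n)) {
    k1 <- oracle_rhs(y, p)
    k2 <- oracle_rhs(y + dt / 2 * k1, p)
    k3 <- oracle_rhs(y + dt / 2 * k2, p)
    k4 <- oracle_rhs(y + dt * k3, p)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[k + 1L, ] <- y
  }
  out
}

# --- cross-bridge oracle: Ca2+-dependent phosphorylation rate ------------
oracle_tau1 <- function(chi, p) p$theta * p$tau_0 * chi^4 / (chi^4 + p$chi_0^4)

# --- contractile-unit algebra, second transcription ----------------------
oracle_overlap <- function(u, p) {
  v <- 1 - ((u + p$u_opt) / p$s_overlap)^2
  if (v < 0) 0 else v
}

oracle_active_psi <- function(I4, u_fs, n_att, p) {
  lam <- sqrt(I4)
  0.5 * p$mu_a * oracle_overlap(u_fs, p) * n_att * (lam - 1 - u_fs)^2
}

# --- uniaxial strip: reduced two-variable energy minimization ------------
# fibre along x; F = diag(lx, q, q); returns the first Piola stress
# component P_x = d(psi_total)/d(lx) at the laterally relaxed state
# (envelope theorem), by central differences of the reduced energy.
oracle_strip_energy <- function(lx, q, tp, cfac = 0, u_fs = 0) {
  fr <- function(x, eps = 0.02) if (x <= 0) 0 else x^3 / (x^2 + eps^2)
  J <- lx * q^2
  I1 <- lx^2 + 2 * q^2
  I4 <- lx^2
  I1b <- J^(-2 / 3) * I1
  I4b <- J^(-2 / 3) * I4
  s <- fr(I4b - 1)
  psi <- tp$mu_p / 2 * (I1b - 3) +
    tp$c_p1 / (2 * tp$c_p2) * (exp(tp$c_p2 * s^2) - 1) +
    tp$kappa / 4 * (J^2 - 1 - 2 * log(J)) +
    cfac * (sqrt(I4b) - 1 - u_fs)^2
  psi
}

oracle_strip_P <- function(lx, tp, cfac = 0, u_fs = 0) {
  en <- function(l) {
    q <- stats::optimize(function(q) oracle_strip_energy(l, q, tp, cfac, u_fs),
                         c(0.3, 2.5), tol = 1e-12)$minimum
    oracle_strip_energy(l, q, tp, cfac, u_fs)
  }
  h <- 1e-4   # fourth-order central difference (envelope theorem in q)
  (en(lx - 2 * h) - 8 * en(lx - h) + 8 * en(lx + h) - en(lx + 2 * h)) /
    (12 * h)
}

# --- oscillation utilities ----------------------------------------------
# times of local maxima of a series (quadratic refinement not needed)
peak_times <- function(t, x) {
  n <- length(x)
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  thr <- min(x) + 0.3 * (max(x) - min(x))
  t[i[x[i] > thr]]
}

# Kuramoto order parameter from per-cell peak trains, averaged over a
# common evaluation window
order_parameter <- function(t_eval, peak_list) {
  phases <- sapply(peak_list, function(pk) {
    if (length(pk) < 2) return(rep(NA_real_, length(t_eval)))
    idx <- findInterval(t_eval, pk)
    ph <- rep(NA_real_, length(t_eval))
    ok <- idx >= 1 & idx < length(pk)
    ph[ok] <- 2 * pi * (idx[ok] +
      (t_eval[ok] - pk[idx[ok]]) / (pk[idx[ok] + 1L] - pk[idx[ok]]))
    ph
  })
  r <- apply(phases, 1, function(ph) {
    if (any(is.na(ph))) return(NA_real_)
    Mod(mean(exp(1i * ph)))
  })
  mean(r, na.rm = TRUE)
}

# mean peak-to-trough amplitude of the oscillatory tail of a series
osc_amplitude <- function(t, x, window = 0.5) {
  keep <- t >= stats::quantile(t, 1 - window)
  diff(range(x[keep]))
}
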