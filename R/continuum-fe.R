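#' Tissue structural parameters
#'
#' Passive and volumetric constants of the fibre-reinforced
#' hyperelastic media model: an isotropic neo-Hookean matrix (shear
#' modulus `mu_p`), one exponentially stiffening fibre family aligned
#' circumferentially (`c_p1`, `c_p2`), a volumetric penalty with bulk
#' modulus `kappa`, and the active shear modulus `mu_a` shared with the
#' contractile-unit model.
#'
#' The tabulated bulk modulus (4 kPa) is of the same order as the
#' passive shear moduli, so incompressibility is enforced only weakly
#' at the defaults: converged states show per-element |J - 1| of
#' order tens of percent at working stresses.  `kappa` is
#' configurable, and volume errors shrink monotonically as it is
#' scaled up (penalty-method property).
#'
#' @param ... named overrides of the defaults (kappa = 4 kPa,
#'   mu_a = 5301 kPa, mu_p = 0.84 kPa, c_p1 = 3.15 kPa, c_p2 = 0.035).
#' @return Object of class `tissue_params`.
#' @export
tissue_params <- function(...) {
  p <- list(kappa = 4.0, mu_a = 5301.0, mu_p = 0.84, c_p1 = 3.15,
            c_p2 = 0.035)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown tissue parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  if (p$kappa <= 0 || p$mu_p <= 0 || p$c_p1 < 0) {
    stop("kappa and mu_p must be > 0; c_p1 must be >= 0")
  }
  class(p) <- "tissue_params"
  p
}

# 2x2x2 Gauss quadrature and trilinear shape gradients on [-1,1]^3.
# Local node order: (-,-,-),(+,-,-),(+,+,-),(-,+,-) then the z+ copies.
gauss_hex8 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    s <- c(-1, 1, 1, -1, -1, 1, 1, -1)
    t <- c(-1, -1, 1, 1, -1, -1, 1, 1)
    u <- c(-1, -1, -1, -1, 1, 1, 1, 1)
    g <- 1 / sqrt(3)
    pts <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g),
                                 ze = c(-g, g)))
    dN <- vector("list", 8)
    N <- matrix(0, 8, 8)
    for (q in seq_len(8)) {
      xi <- pts[q, 1]; et <- pts[q, 2]; ze <- pts[q, 3]
      N[q, ] <- (1 + s * xi) * (1 + t * et) * (1 + u * ze) / 8
      dN[[q]] <- cbind(s * (1 + t * et) * (1 + u * ze),
                       t * (1 + s * xi) * (1 + u * ze),
                       u * (1 + s * xi) * (1 + t * et)) / 8
    }
    cache <<- list(pts = pts, w = rep(1, 8), N = N, dN = dN)
    cache
  }
})

# Voigt bookkeeping: pairs (11, 22, 33, 12, 23, 13); strain-like
# vectors carry engineering (doubled) shear components.
.vi <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(2, 3), c(1, 3))

t2v <- function(S) S[.vi]

# C2-smooth positive-part ramp used by the tension-only fibre term
fibre_ramp <- function(x, eps = 0.02) {
  if (x <= 0) return(list(s = 0, s1 = 0, s2 = 0))
  D <- x^2 + eps^2
  list(s = x^3 / D,
       s1 = (x^4 + 3 * eps^2 * x^2) / D^2,
       s2 = 2 * eps^2 * x * (3 * eps^2 - x^2) / D^3)
}

icsym66 <- function(Ci) {
  # (Ci_ik Ci_jl + Ci_il Ci_jk)/2 in Voigt 6x6 (rows m=(i,j), cols n=(k,l))
  (Ci[.vi[, 1], .vi[, 1]] * Ci[.vi[, 2], .vi[, 2]] +
     Ci[.vi[, 1], .vi[, 2]] * Ci[.vi[, 2], .vi[, 1]]) / 2
}

#' Deformation kinematics at a Gauss point
#'
#' Computes the deformation gradient, its determinant, the deviatoric
#' right Cauchy-Green tensor and the (isochoric) fibre invariant
#' `I4_bar = a0 . C_bar a0` with stretch `lam = sqrt(I4_bar)`.
#'
#' @param X 8 x 3 reference nodal coordinates of the element (mm).
#' @param u 8 x 3 nodal displacements (mm).
#' @param gp Gauss point index (1..8).
#' @param a0 unit fibre direction at the point.
#' @param elem element id used in the inversion diagnostic.
#' @return list with `F`, `J`, `C`, `C_bar`, `I4_bar`, `lam`, `gradN`
#'   (8 x 3 shape gradients wrt X), `detJ0` (reference Jacobian).
#' @export
kinematics_at_gp <- function(X, u, gp, a0, elem = NA) {
  q <- gauss_hex8()
  dN <- q$dN[[gp]]
  Jm <- t(dN) %*% X           # dX/dxi
  dJ0 <- det(Jm)
  if (dJ0 <= 0) stop("degenerate reference element ", elem)
  # Jm[k, j] = dX_j/dxi_k, so dN/dX = dN * inv(Jm)^T
  gradN <- dN %*% t(solve(Jm))
  F <- diag(3) + t(u) %*% gradN
  J <- det(F)
  if (J <= 0) stop("element inversion (J <= 0) in element ", elem)
  C <- t(F) %*% F
  C_bar <- J^(-2 / 3) * C
  I4b <- drop(a0 %*% C_bar %*% a0)
  list(F = F, J = J, C = C, C_bar = C_bar, I4_bar = I4b,
       lam = sqrt(I4b), gradN = gradN, detJ0 = dJ0)
}

#' Isochoric energy, stress and tangent at a material point
#'
#' Passive part:
#' \deqn{\Psi_p = \tfrac{\mu_p}{2}(\bar I_1 - 3) +
#'   \tfrac{c_{p1}}{2 c_{p2}}\left[e^{c_{p2}(\bar I_4 - 1)^2} - 1\right]}
#' plus an optional active contribution supplied through its fibre-
#' invariant derivatives (`psi4_a`, `psi44_a`).  Returns the second
#' Piola-Kirchhoff stress and the material tangent (Voigt 6x6) of the
#' isochoric terms.
#'
#' @param C right Cauchy-Green tensor (3 x 3).
#' @param a0 unit fibre direction.
#' @param tp a [tissue_params()].
#' @param psi4_a,psi44_a active first/second derivatives of the free
#'   energy wrt the isochoric fourth invariant (kPa); default 0.
#' @return list with `psi` (isochoric energy density, kPa), `S` (3 x 3)
#'   and `CC` (6 x 6 Voigt).
#' @export
isochoric_stress <- function(C, a0, tp, psi4_a = 0, psi44_a = 0) {
  J2 <- det(C)
  if (J2 <= 0) stop("non-positive det(C)")
  J <- sqrt(J2)
  J23 <- J^(-2 / 3)
  Ci <- solve(C)
  A <- tcrossprod(a0)
  I1 <- sum(diag(C))
  I4 <- drop(a0 %*% C %*% a0)
  I1b <- J23 * I1
  I4b <- J23 * I4
  # tension-only fibre family with a C2-smooth engagement ramp
  # s(x) = x^3/(x^2 + eps^2) for x = I4b - 1 > 0, else 0: exactly zero
  # in compression, asymptotically linear in tension, smooth tangent
  sm <- fibre_ramp(I4b - 1)
  e4 <- exp(tp$c_p2 * sm$s^2)
  if (!is.finite(e4)) stop("overflow in exponential fibre term (I4_bar = ",
                           signif(I4b, 5), ")")
  psi <- tp$mu_p / 2 * (I1b - 3) + tp$c_p1 / (2 * tp$c_p2) * (e4 - 1)
  psi1 <- tp$mu_p / 2
  psi4 <- tp$c_p1 * sm$s * sm$s1 * e4 + psi4_a
  psi44 <- tp$c_p1 * e4 * (sm$s1^2 + sm$s * sm$s2 +
                             2 * tp$c_p2 * sm$s^2 * sm$s1^2) + psi44_a
  G1 <- J23 * (diag(3) - (I1 / 3) * Ci)
  G4 <- J23 * (A - (I4 / 3) * Ci)
  S <- 2 * (psi1 * G1 + psi4 * G4)
  ICs <- icsym66(Ci)
  civ <- t2v(Ci)
  H1 <- -J23 / 3 * (outer(civ, t2v(diag(3))) + outer(t2v(diag(3)), civ)) +
    J23 * I1 / 9 * outer(civ, civ) + J23 * I1 / 3 * ICs
  H4 <- -J23 / 3 * (outer(civ, t2v(A)) + outer(t2v(A), civ)) +
    J23 * I4 / 9 * outer(civ, civ) + J23 * I4 / 3 * ICs
  CC <- 4 * (psi44 * outer(t2v(G4), t2v(G4)) + psi1 * H1 + psi4 * H4)
  list(psi = psi, S = S, CC = CC)
}

#' Total stress and tangent at a material point
#'
#' Additive split: isochoric passive + active (through the fibre
#' derivatives) + volumetric pressure term `S_vol = p J C^-1`.  With
#' zero active derivatives this reduces exactly to the passive
#' response.
#'
#' @inheritParams isochoric_stress
#' @param pbar pressure (kPa); element-constant in the Q1/P0 scheme.
#' @return list with `S` and `CC` (pressure-rank-one term excluded; it
#'   is assembled at element level).
#' @export
total_stress <- function(C, a0, tp, pbar, psi4_a = 0, psi44_a = 0) {
  iso <- isochoric_stress(C, a0, tp, psi4_a, psi44_a)
  J <- sqrt(det(C))
  Ci <- solve(C)
  S <- iso$S + pbar * J * Ci
  civ <- t2v(Ci)
  CC <- iso$CC + pbar * J * (outer(civ, civ) - 2 * icsym66(Ci))
  list(S = S, CC = CC, psi = iso$psi)
}

# Characteristic displacement scale for continuation step sizing
mesh_dscale <- function(mesh) {
  if (!is.null(mesh$geom)) return(mesh$geom$inner_diameter / 2)
  if (!is.null(mesh$length)) return(mesh$length / 2)
  diff(range(mesh$nodes[, 1])) / 2
}

# Unit fibre direction field: the mesh may carry its own (e.g. axial
# for strips); rings default to the circumferential tangent.
mesh_fibre_fun <- function(mesh) {
  if (!is.null(mesh$fibre)) mesh$fibre else fibre_dir
}

# Circumferential unit fibre direction at reference position x
fibre_dir <- function(x) {
  r <- sqrt(x[1]^2 + x[2]^2)
  if (r < 1e-12) return(c(0, 1, 0))
  c(-x[2], x[1], 0) / r
}

# Strain-displacement matrix (6 x 24): dE_voigt = B du, engineering
# shear convention, total Lagrangian.
bmat_tl <- function(F, gradN) {
  B <- matrix(0, 6, 24)
  B[1, ] <- outer(F[, 1], gradN[, 1])
  B[2, ] <- outer(F[, 2], gradN[, 2])
  B[3, ] <- outer(F[, 3], gradN[, 3])
  B[4, ] <- outer(F[, 1], gradN[, 2]) + outer(F[, 2], gradN[, 1])
  B[5, ] <- outer(F[, 2], gradN[, 3]) + outer(F[, 3], gradN[, 2])
  B[6, ] <- outer(F[, 1], gradN[, 3]) + outer(F[, 3], gradN[, 1])
  B
}

# First/second fibre-invariant derivatives of the active energy for a
# given prefactor cfac = mu_a * overlap(u_fs) * (n_AMp + n_AM) / 2.
active_pair <- function(I4b, u_fs, cfac) {
  lam <- sqrt(I4b)
  ue <- lam - 1 - u_fs
  c(cfac * ue / lam, cfac * (1 + u_fs) / (2 * lam^3))
}

# Element residual and stiffness for the Q1/P0 mean-dilatation scheme
# (reference R engine; the compiled kernel mirrors it).
# active: NULL or list(cfac = 8-vector, u_fs = 8-vector) where cfac is
# the active energy prefactor mu_a * overlap * (n_AMp + n_AM) / 2.
element_system <- function(X, u, a0_fun, tp, active = NULL, elem = NA,
                           want_K = TRUE) {
  q <- gauss_hex8()
  kin <- vector("list", 8)
  V0 <- 0
  Jbar_num <- 0
  a0s <- vector("list", 8)
  for (g in 1:8) {
    xg <- drop(q$N[g, ] %*% X)
    a0s[[g]] <- a0_fun(xg)
    kin[[g]] <- kinematics_at_gp(X, u, g, a0s[[g]], elem = elem)
    dV <- kin[[g]]$detJ0 * q$w[g]
    V0 <- V0 + dV
    Jbar_num <- Jbar_num + kin[[g]]$J * dV
  }
  Theta <- Jbar_num / V0              # element dilatation
  # volumetric potential kappa/4 (J^2 - 1 - 2 ln J): zero at J = 1,
  # unbounded compression barrier; element pressure (condensed)
  pbar <- 0.5 * tp$kappa * (Theta - 1 / Theta)
  f <- numeric(24)
  K <- if (want_K) matrix(0, 24, 24) else NULL
  gvec <- numeric(24)                 # d(V0*Theta)/du for the rank-one term
  for (g in 1:8) {
    k <- kin[[g]]
    dV <- k$detJ0 * q$w[g]
    ps4 <- 0; ps44 <- 0
    if (!is.null(active) && active$cfac[g] != 0) {
      ad <- active_pair(k$I4_bar, active$u_fs[g], active$cfac[g])
      ps4 <- ad[1]; ps44 <- ad[2]
    }
    ts <- total_stress(k$C, a0s[[g]], tp, pbar, ps4, ps44)
    B <- bmat_tl(k$F, k$gradN)
    Sv <- t2v(ts$S)
    f <- f + drop(crossprod(B, Sv)) * dV
    jciv <- k$J * t2v(solve(k$C))
    gvec <- gvec + drop(crossprod(B, jciv)) * dV
    if (want_K) {
      K <- K + crossprod(B, ts$CC %*% B) * dV
      # geometric (initial stress) stiffness
      GS <- k$gradN %*% ts$S %*% t(k$gradN)   # 8 x 8
      for (i in 1:3) {
        idx <- seq(i, 24, by = 3)
        K[idx, idx] <- K[idx, idx] + GS * dV
      }
    }
  }
  dp <- 0.5 * tp$kappa * (1 + 1 / Theta^2)   # dp/dTheta
  if (want_K) K <- K + (dp / V0) * tcrossprod(gvec)
  list(f = f, K = K, pbar = pbar, Theta = Theta, V0 = V0, kin = kin,
       a0 = a0s)
}

# Assemble global residual and sparse tangent.
# bc: list(dofs = integer, vals = numeric) prescribed displacement dofs.
#' Assemble the global residual and tangent
#'
#' Standard Galerkin assembly of the Q1/P0 hexahedral mesh with
#' 2x2x2 Gauss quadrature; element pressure is condensed.
#'
#' @param mesh a `ring_mesh`.
#' @param u N x 3 nodal displacement matrix.
#' @param tp a [tissue_params()].
#' @param active `NULL` (passive) or a list per element of
#'   `list(cfac, u_fs)` (8-vectors per Gauss point) carrying the
#'   active energy prefactor and the filament sliding.
#' @param want_K assemble the tangent (default TRUE).
#' @param engine `"cpp"` (compiled kernel, default) or `"R"`
#'   (reference implementation).
#' @return list with `f` (3N residual/internal force vector), `K`
#'   (sparse dgCMatrix or NULL), `pbar`, `Theta` per element, and
#'   `lam_gp` (E x 8 matrix of fibre stretches).
#' @export
assemble <- function(mesh, u, tp, active = NULL, want_K = TRUE,
                     engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  ne <- nrow(mesh$elems)
  nn <- nrow(mesh$nodes)
  gpc <- mesh_gp_cache(mesh)
  f <- numeric(3 * nn)
  pbar <- numeric(ne)
  Theta <- numeric(ne)
  lam_gp <- matrix(0, ne, 8)
  ijx <- if (want_K) vector("list", ne) else NULL
  zero8 <- numeric(8)
  for (e in seq_len(ne)) {
    conn <- mesh$elems[e, ]
    ue <- u[conn, , drop = FALSE]
    ae <- if (is.null(active)) NULL else active[[e]]
    if (engine == "cpp") {
      ce <- gpc[[e]]
      es <- .element_system_cpp(mesh$nodes[conn, ], ue, ce$gradN0, ce$detJ0,
                                ce$a0, tp$kappa, tp$mu_p, tp$c_p1, tp$c_p2,
                                if (is.null(ae)) zero8 else ae$cfac,
                                if (is.null(ae)) zero8 else ae$u_fs,
                                want_K)
      lam_e <- es$lam
    } else {
      es <- element_system(mesh$nodes[conn, ], ue, mesh_fibre_fun(mesh), tp,
                           active = ae, elem = e, want_K = want_K)
      lam_e <- vapply(es$kin, function(k) k$lam, 0)
    }
    # dofs for node a are (3a-2, 3a-1, 3a); local order follows nodes
    dofs <- integer(24)
    for (a in 1:8) dofs[(3 * a - 2):(3 * a)] <- (3 * conn[a] - 2):(3 * conn[a])
    f[dofs] <- f[dofs] + es$f
    pbar[e] <- es$pbar
    Theta[e] <- es$Theta
    lam_gp[e, ] <- lam_e
    if (want_K) {
      ijx[[e]] <- list(i = rep(dofs, times = 24),
                       j = rep(dofs, each = 24),
                       x = as.vector(es$K))
    }
  }
  K <- NULL
  if (want_K) {
    K <- Matrix::sparseMatrix(
      i = unlist(lapply(ijx, `[[`, "i")),
      j = unlist(lapply(ijx, `[[`, "j")),
      x = unlist(lapply(ijx, `[[`, "x")),
      dims = c(3 * nn, 3 * nn))
  }
  list(f = f, K = K, pbar = pbar, Theta = Theta, lam_gp = lam_gp)
}

#' Newton-Raphson solve of the quasi-static equilibrium
#'
#' Iterates on the free displacement dofs until the residual norm
#' drops below `rtol` times its initial value (plus an absolute
#' floor), with optional backtracking line search; prescribed dofs are
#' set before the first iteration.
#'
#' @param mesh a `ring_mesh`.
#' @param u0 initial N x 3 displacement guess.
#' @param bc list with `dofs` (global dof indices) and `vals`
#'   (prescribed values, mm).
#' @param tp a [tissue_params()].
#' @param active as in [assemble()].
#' @param rtol,atol convergence tolerances on the residual norm.
#' @param maxit maximum Newton iterations.
#' @return Object of class `fe_solution`: `u`, `pbar`, `Theta`,
#'   `lam_gp`, `f_int`, `converged`, `residual_norm`, `iterations`,
#'   `history`.
#' @export
newton_solve <- function(mesh, u0, bc, tp, active = NULL, rtol = 1e-8,
                         atol = 1e-10, maxit = 40L,
                         engine = c("cpp", "R"), abs_floor = 0) {
  engine <- match.arg(engine)
  nn <- nrow(mesh$nodes)
  uv <- as.vector(t(u0))          # dof-ordered (x1,y1,z1,x2,...)
  free <- setdiff(seq_len(3 * nn), bc$dofs)
  hist <- numeric(0)
  conv <- FALSE
  asm <- NULL
  r0 <- NA_real_
  lev_mu <- 0
  n_damp <- 0L
  for (it in seq_len(maxit)) {
    u <- matrix(uv, nn, 3, byrow = TRUE)
    asm <- assemble(mesh, u, tp, active = active, want_K = TRUE,
                    engine = engine)
    # remaining prescribed-displacement increment is driven through the
    # tangent (incremental displacement control): never assemble a state
    # with a raw boundary jump
    dp <- bc$vals - uv[bc$dofs]
    dpn <- sqrt(sum(dp^2))
    r <- asm$f[free]
    rn <- sqrt(sum(r^2))
    hist <- c(hist, rn)
    if (it == 1L) r0 <- max(rn, atol)
    fscale <- max(1e-3, sqrt(sum(asm$f^2)))
    if (dpn < 1e-14 && rn <= max(atol, rtol * r0, abs_floor)) {
      conv <- TRUE; break
    }
    # stall tolerance: the smooth tension ramp keeps the residual C1 but
    # strong curvature can leave slow linear convergence at residuals far
    # below the force scale
    if (dpn < 1e-14 && it >= 6L && rn <= 1e-3 * fscale &&
        rn > 0.7 * hist[it - 2L]) { conv <- TRUE; break }
    Kff <- asm$K[free, free, drop = FALSE]
    rhs <- -r
    if (dpn > 0) {
      rhs <- rhs - as.numeric(asm$K[free, bc$dofs, drop = FALSE] %*% dp)
    }
    # Levenberg-style damping: the tangent of a slack bending-dominated
    # state can be indefinite (near-buckling); shift by mu * diag scale
    # until the step is productive
    dscale <- Matrix::Diagonal(x = pmax(abs(Matrix::diag(Kff)), 1e-8))
    solve_damped <- function(mu) {
      tryCatch(as.numeric(Matrix::solve(Kff + mu * dscale, rhs)),
               error = function(e) NULL)
    }
    du <- if (lev_mu > 0) solve_damped(lev_mu) else tryCatch(
      as.numeric(Matrix::solve(Kff, rhs)),
      error = function(e) stop("singular constrained system: check boundary ",
                               "conditions (", conditionMessage(e), ")"))
    if (is.null(du)) du <- rep(0, length(rhs))
    # backtracking line search on the residual norm (the prescribed
    # increment is scaled together with the free-dof step)
    step <- 1
    ok_step <- FALSE
    for (ls in 1:10) {
      uv_try <- uv
      uv_try[free] <- uv[free] + step * du
      uv_try[bc$dofs] <- uv[bc$dofs] + step * dp
      u_try <- matrix(uv_try, nn, 3, byrow = TRUE)
      rn_try <- tryCatch({
        a_try <- assemble(mesh, u_try, tp, active = active, want_K = FALSE,
                          engine = engine)
        sqrt(sum(a_try$f[free]^2))
      }, error = function(e) Inf)
      if (is.finite(rn_try) &&
          ((step == 1 && dpn > 0) ||   # accept while BC still incomplete
           rn_try < rn || rn_try < max(atol, rtol * r0))) {
        ok_step <- TRUE
        break
      }
      step <- step / 2
    }
    if (!ok_step || (step < 1 && dpn == 0)) {
      # unproductive direction: raise damping and retry the iteration
      lev_mu <- max(lev_mu * 10, 1e-4)
      n_damp <- n_damp + 1L
      if (!ok_step) {
        if (n_damp > 12L) break
        next
      }
    } else if (step == 1) {
      lev_mu <- lev_mu / 4
      if (lev_mu < 1e-8) lev_mu <- 0
    }
    uv[free] <- uv[free] + step * du
    uv[bc$dofs] <- uv[bc$dofs] + step * dp
  }
  if (!conv) {
    u <- matrix(uv, nn, 3, byrow = TRUE)
    asm <- assemble(mesh, u, tp, active = active, want_K = FALSE,
                    engine = engine)
    rn <- sqrt(sum(asm$f[free]^2))
    if (max(abs(bc$vals - uv[bc$dofs])) < 1e-14 &&
        rn <= max(atol, rtol * r0, abs_floor)) conv <- TRUE
    hist <- c(hist, rn)
  }
  structure(list(u = matrix(uv, nn, 3, byrow = TRUE), pbar = asm$pbar,
                 Theta = asm$Theta, lam_gp = asm$lam_gp, f_int = asm$f,
                 converged = conv, residual_norm = hist[length(hist)],
                 iterations = length(hist) - 1L, history = hist),
            class = "fe_solution")
}

# Dirichlet set for the symmetry-reduced (or full) ring with hook
# displacement d along x.
ring_bcs <- function(mesh, d) {
  ns <- mesh$node_sets
  dofs <- integer(0); vals <- numeric(0)
  add <- function(nodes, comp, val) {
    dofs <<- c(dofs, 3 * (nodes - 1L) + comp)
    vals <<- c(vals, rep(val, length(nodes)))
  }
  if (mesh$span == "eighth") {
    add(ns$hook_contact, 1L, d)
    add(ns$hook_contact, 2L, 0)   # no-slip hook: patch translates rigidly
    add(ns$sym_x, 1L, 0)
    add(ns$sym_y, 2L, 0)
    add(ns$sym_z, 3L, 0)
  } else if (mesh$span == "strip") {
    # axial constraints on both faces; lateral contraction left free,
    # rigid-body modes pinned at two corner nodes
    add(ns$left, 1L, 0)
    add(ns$right, 1L, d)
    nd <- mesh$nodes
    origin <- which(rowSums(abs(nd)) < 1e-12)[1]
    ymax <- max(nd[, 2])
    pin2 <- which(abs(nd[, 1]) < 1e-12 & abs(nd[, 2] - ymax) < 1e-12 &
                    abs(nd[, 3]) < 1e-12)[1]
    add(origin, 2L, 0); add(origin, 3L, 0)
    add(pin2, 3L, 0)
  } else {
    add(ns$hook_contact, 1L, d)
    add(ns$hook_contact, 2L, 0)
    add(ns$hook_left, 1L, -d)
    add(ns$hook_left, 2L, 0)
    add(ns$sym_y, 2L, 0)
    add(ns$sym_z, 3L, 0)
  }
  keep <- !duplicated(dofs)
  list(dofs = dofs[keep], vals = vals[keep])
}

#' Hook reaction force
#'
#' Sums the x-components of the internal force vector over the
#' hook-contact node set and scales by the mirror-symmetry factor of
#' the model span, giving the force a physical hook would read (mN;
#' kPa times mm^2).
#'
#' @param sol an `fe_solution`.
#' @param mesh the `ring_mesh` it was computed on.
#' @return force (mN).
#' @export
hook_force <- function(sol, mesh) {
  hooks <- mesh$node_sets$hook_contact
  if (length(hooks) == 0) stop("empty hook contact set")
  rx <- sum(sol$f_int[3 * (hooks - 1L) + 1L])
  fac <- switch(mesh$span, eighth = 4, full = 2, 1)
  fac * rx
}

# Solve the ring at hook displacement d.  The initial guess may come
# from a continuation predictor; on failure the displacement increment
# is substepped (prescribed jumps larger than an element edge invert
# elements if applied in one go).
solve_at_displacement <- function(mesh, d, tp, u0 = NULL, active = NULL,
                                  d_from = 0, depth = 0L) {
  if (is.null(u0)) u0 <- matrix(0, nrow(mesh$nodes), 3)
  sol <- tryCatch(newton_solve(mesh, u0, ring_bcs(mesh, d), tp,
                               active = active, maxit = 80L,
                               abs_floor = 2e-4),
                  error = function(e) e)
  ok <- !inherits(sol, "error") && sol$converged
  if (!ok) {
    if (depth >= 8L) stop("load step failed after substepping at d = ", d)
    dm <- (d_from + d) / 2
    mid <- solve_at_displacement(mesh, dm, tp, u0, active = active,
                                 d_from = d_from, depth = depth + 1L)
    sol <- solve_at_displacement(mesh, d, tp, mid$u, active = active,
                                 d_from = dm, depth = depth + 1L)
  }
  sol
}

# March the passive ring from (d_from, sol_from) to d with a secant
# predictor on the displacement field and adaptive step size.
march_to <- function(mesh, d, tp, sol_from = NULL, d_from = 0,
                     step0 = NULL, active = NULL) {
  r0 <- mesh_dscale(mesh)
  hmin <- 0.004 * r0
  h <- if (is.null(step0)) 0.05 * r0 else step0
  u_prev <- if (is.null(sol_from)) matrix(0, nrow(mesh$nodes), 3) else sol_from$u
  d_prev <- d_from
  u_pp <- NULL; d_pp <- NULL
  sol <- sol_from
  dir <- if (d >= d_from) 1 else -1
  while (dir * (d - d_prev) > 1e-12) {
    h <- min(h, abs(d - d_prev))
    d_try <- d_prev + dir * h
    guess <- if (!is.null(u_pp) && d_prev > d_pp) {
      u_prev + (d_try - d_prev) / (d_prev - d_pp) * (u_prev - u_pp)
    } else u_prev
    sol_try <- tryCatch(newton_solve(mesh, guess, ring_bcs(mesh, d_try), tp,
                                     active = active, maxit = 80L,
                                     abs_floor = 2e-4),
                        error = function(e) e)
    if (!inherits(sol_try, "error") && sol_try$converged) {
      u_pp <- u_prev; d_pp <- d_prev
      u_prev <- sol_try$u; d_prev <- d_try
      sol <- sol_try
      if (sol_try$iterations <= 6L) h <- h * 1.5
    } else {
      h <- h / 2
      if (h < hmin) stop("continuation stalled at d = ", signif(d_prev, 5))
    }
  }
  sol
}

#' Displacement-controlled loading phase to a target preload
#'
#' Finds the hook displacement at which the passive ring carries the
#' target hook force (the resting tension of the myograph protocol),
#' by bracketing and regula-falsi iteration on the scalar
#' force-displacement relation; each force evaluation is a converged
#' Newton solve reached by predictor continuation from the nearest
#' known state.
#'
#' @param mesh a `ring_mesh`.
#' @param tp a [tissue_params()].
#' @param target_force target hook force (mN), >= 0.
#' @param tol_rel relative force tolerance (default 0.005).
#' @param d0 initial displacement probe (mm); default 40% of the
#'   inner radius.
#' @param maxit maximum force evaluations.
#' @return list with `sol` (`fe_solution`), `d` (hook displacement,
#'   mm), `force` (mN), `iterations`.
#' @export
loading_phase <- function(mesh, tp, target_force = 1.0, tol_rel = 0.005,
                          d0 = NULL, maxit = 60L) {
  if (target_force == 0) {
    sol <- solve_at_displacement(mesh, 0, tp)
    return(list(sol = sol, d = 0, force = 0, iterations = 0L))
  }
  if (target_force < 0) stop("target_force must be >= 0")
  r0 <- mesh_dscale(mesh)
  if (is.null(d0)) d0 <- 0.4 * r0
  step0 <- 0.05 * r0
  d_lo <- 0; f_lo <- 0
  d_cur <- d0
  sol <- march_to(mesh, d_cur, tp, step0 = step0)
  f_cur <- hook_force(sol, mesh)
  it <- 1L
  while (f_cur < target_force) {
    if (it >= maxit) stop("loading phase: target force not bracketed within ",
                          maxit, " steps (last F = ", signif(f_cur, 5), " mN)")
    d_lo <- d_cur; f_lo <- f_cur
    d_next <- d_cur + 0.2 * r0
    sol <- march_to(mesh, d_next, tp, sol_from = sol, d_from = d_cur,
                    step0 = step0)
    d_cur <- d_next
    f_cur <- hook_force(sol, mesh)
    it <- it + 1L
  }
  d_hi <- d_cur; f_hi <- f_cur
  while (abs(f_cur - target_force) > tol_rel * target_force) {
    if (it >= maxit) stop("loading phase: target force not reached within ",
                          maxit, " iterations (last F = ", signif(f_cur, 5),
                          " mN)")
    d_new <- d_lo + (target_force - f_lo) * (d_hi - d_lo) /
      max(f_hi - f_lo, .Machine$double.eps)
    d_new <- min(max(d_new, d_lo + 0.02 * (d_hi - d_lo)),
                 d_hi - 0.02 * (d_hi - d_lo))
    sol <- march_to(mesh, d_new, tp, sol_from = sol, d_from = d_cur,
                    step0 = step0)
    f_cur <- hook_force(sol, mesh)
    d_cur <- d_new
    if (f_cur < target_force) { d_lo <- d_new; f_lo <- f_cur }
    else { d_hi <- d_new; f_hi <- f_cur }
    it <- it + 1L
  }
  list(sol = sol, d = d_cur, force = f_cur, iterations = it)
}

# Per-element Gauss-point cache of reference shape gradients, weighted
# reference Jacobians and fibre directions.  Built lazily and stored in
# an environment attached to the mesh.
mesh_gp_cache <- function(mesh) {
  if (!is.null(mesh$gp)) return(mesh$gp)
  q <- gauss_hex8()
  ne <- nrow(mesh$elems)
  ffun <- mesh_fibre_fun(mesh)
  cache <- vector("list", ne)
  for (e in seq_len(ne)) {
    X <- mesh$nodes[mesh$elems[e, ], ]
    gradN0 <- array(0, c(8, 3, 8))
    detJ0 <- numeric(8)
    a0 <- matrix(0, 8, 3)
    for (g in 1:8) {
      dN <- q$dN[[g]]
      Jm <- t(dN) %*% X
      dJ <- det(Jm)
      if (dJ <= 0) stop("degenerate reference element ", e)
      gradN0[, , g] <- dN %*% t(solve(Jm))
      detJ0[g] <- dJ * q$w[g]
      a0[g, ] <- ffun(drop(q$N[g, ] %*% X))
    }
    cache[[e]] <- list(gradN0 = gradN0, detJ0 = detJ0, a0 = a0)
  }
  cache
}
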