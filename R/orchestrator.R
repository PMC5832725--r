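#' Assemble a multiscale simulation configuration
#'
#' Collects geometry, discretization, parameter blocks, protocol and
#' numerical settings for [run_simulation()].  The two time scales are
#' the cellular step `dt_cell` (ionic dynamics solved adaptively
#' inside it; cross-bridge and contractile-unit updates by forward
#' Euler on it) and the solid step `dt_solid` (quasi-static continuum
#' solves), with `dt_solid` an integer multiple of `dt_cell`.
#'
#' @param geometry a [ring_geometry()].
#' @param resolution mesh resolution triple.
#' @param mesh optional prebuilt mesh (overrides geometry/resolution).
#' @param cell,cb,cu,tissue parameter objects ([cell_params()],
#'   [cb_params()], [cu_params()], [tissue_params()]).
#' @param protocol `NULL`, a protocol name, or a [make_protocol()]
#'   schedule.
#' @param protocol_options list passed to [make_protocol()] when
#'   `protocol` is a name.
#' @param phi_A_mean,phi_A_sd population distribution of the NSCC
#'   influx (uM/s); the mean defaults to the protocol's baseline.
#' @param coupling gap-junction diffusivities: scalar applied to both
#'   `alpha_C` and `alpha_V` (1/s), or `NULL` to keep the values in
#'   `cell`.
#' @param dt_cell,dt_solid cellular and solid time steps (s).
#' @param t_end protocol duration after the intervention onset (s);
#'   0 runs the loading phase only.
#' @param preroll stationarity pre-roll before the intervention (s).
#' @param preload resting hook tension target (mN).
#' @param mechanics logical; FALSE runs the cellular/cross-bridge
#'   levels only (e.g. unloaded-ring coupling studies).
#' @param seed integer seed for the population randomization.
#' @param record_cells indices of cells whose state series are kept.
#' @param record_every recording cadence (s); default `dt_solid`.
#' @param rtol,atol adaptive integrator tolerances.
#' @param out_dir optional output directory for VTK snapshots.
#' @param vtk_every snapshot cadence (s); 0 disables.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = ring_geometry(),
                              resolution = c(2L, 24L, 5L),
                              mesh = NULL,
                              cell = cell_params(),
                              cb = cb_params(),
                              cu = cu_params(),
                              tissue = tissue_params(),
                              protocol = NULL,
                              protocol_options = list(),
                              phi_A_mean = NULL,
                              phi_A_sd = 0.1,
                              coupling = NULL,
                              dt_cell = 0.001,
                              dt_solid = 0.1,
                              t_end = 600,
                              preroll = 200,
                              preload = 1.0,
                              mechanics = TRUE,
                              seed = 1L,
                              record_cells = NULL,
                              record_every = NULL,
                              rtol = 1e-7, atol = 1e-9,
                              out_dir = NULL, vtk_every = 0) {
  if (is.character(protocol)) {
    protocol <- do.call(make_protocol, c(list(name = protocol),
                                         protocol_options))
  }
  if (dt_solid < dt_cell) stop("dt_solid must be >= dt_cell")
  stride <- dt_solid / dt_cell
  if (abs(stride - round(stride)) > 1e-9) {
    stop("dt_solid must be an integer multiple of dt_cell")
  }
  if (t_end < 0) stop("t_end must be >= 0")
  if (is.null(phi_A_mean)) {
    phi_A_mean <- if (!is.null(protocol)) protocol$phi_A_mean else 0.6
  }
  if (!is.null(coupling)) {
    cell$alpha_C <- coupling
    cell$alpha_V <- coupling
  }
  cfg <- list(geometry = geometry, resolution = resolution, mesh = mesh,
              cell = cell, cb = cb, cu = cu, tissue = tissue,
              protocol = protocol, phi_A_mean = phi_A_mean,
              phi_A_sd = phi_A_sd, dt_cell = dt_cell, dt_solid = dt_solid,
              t_end = t_end, preroll = preroll, preload = preload,
              mechanics = mechanics, seed = as.integer(seed),
              record_cells = record_cells, record_every = record_every,
              rtol = rtol, atol = atol, out_dir = out_dir,
              vtk_every = vtk_every)
  class(cfg) <- "simulation_config"
  cfg
}

#' Run the block-segregated multiscale simulation
#'
#' Executes, in order: (i) the passive displacement-controlled loading
#' phase to the resting preload; (ii) a stationarity pre-roll of the
#' cellular and cross-bridge dynamics (with the contractile units and
#' continuum advancing isometrically at the held hook displacement);
#' (iii) the pharmacological protocol.  Within every solid step the
#' cellular network advances on the `dt_cell` grid with frozen
#' neighbour coupling, the cross-bridge fractions by forward Euler,
#' the chemical filament sliding by forward Euler against the stretch
#' of the previous converged continuum state (lagged, feed-forward
#' coupling: no feedback from mechanics to the cells), and the
#' continuum by a Newton solve at the held hook displacement.
#'
#' @param cfg a [simulation_config()].
#' @return Object of class `vasomech_sim` with fields
#'   \describe{
#'     \item{times}{recording grid (s), protocol time (0 = onset).}
#'     \item{force}{hook force series (mN), or NULL without mechanics.}
#'     \item{force_norm}{force normalized by its value at onset.}
#'     \item{cells}{recorded cell indices.}
#'     \item{chi, zeta, eta}{recorded ionic state series.}
#'     \item{n_Mp, n_AMp, n_AM, n_att}{recorded cross-bridge series.}
#'     \item{preload}{loading-phase summary (d, force).}
#'     \item{manifest}{seed, parameter digests, package version.}
#'   }
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  mesh <- cfg$mesh
  if (is.null(mesh)) {
    mesh <- build_ring_mesh(cfg$geometry, cfg$resolution)
  }
  ne <- nrow(mesh$elems)
  phi_A0 <- randomize_population(ne, mean = cfg$phi_A_mean,
                                 sd = cfg$phi_A_sd, seed = cfg$seed)
  cell_p <- cfg$cell
  cell_p$Phi_A <- phi_A0
  cb_p <- cfg$cb
  net <- cell_network(ne, cell_p, adjacency = mesh$adjacency)
  S_cb <- matrix(c(0.5, 0, 0), ne, 3, byrow = TRUE)  # detached start
  record_cells <- cfg$record_cells
  if (is.null(record_cells)) record_cells <- seq_len(min(3L, ne))
  record_every <- if (is.null(cfg$record_every)) cfg$dt_solid else cfg$record_every
  rec_stride <- max(1L, as.integer(round(record_every / cfg$dt_cell)))
  stride <- as.integer(round(cfg$dt_solid / cfg$dt_cell))

  # (i) loading phase
  pre <- NULL
  sol <- NULL
  lam_prev <- NULL
  u_fs_c <- NULL
  d_hold <- NA_real_
  if (cfg$mechanics) {
    pre <- loading_phase(mesh, cfg$tissue, target_force = cfg$preload)
    sol <- pre$sol
    d_hold <- pre$d
    lam_prev <- sol$lam_gp
    u_fs_c <- matrix(0, ne, 8)
  }

  n_steps <- as.integer(round((cfg$preroll + cfg$t_end) / cfg$dt_cell))
  t0 <- -cfg$preroll
  nrec <- floor(n_steps / rec_stride) + 1L
  times <- numeric(nrec)
  nr <- length(record_cells)
  chi <- matrix(NA_real_, nrec, nr); zeta <- matrix(NA_real_, nrec, nr)
  eta <- matrix(NA_real_, nrec, nr)
  nMp <- matrix(NA_real_, nrec, nr); nAMp <- matrix(NA_real_, nrec, nr)
  nAM <- matrix(NA_real_, nrec, nr)
  n_solid <- floor(n_steps / stride)
  times_F <- numeric(0); force <- numeric(0)
  if (cfg$mechanics) {
    if (n_solid == 0L) {
      # loading phase only: the series is the preload reading
      times_F <- t0
      force <- pre$force
    } else {
      times_F <- t0 + cfg$dt_solid * seq_len(n_solid)
      force <- rep(NA_real_, n_solid)
    }
  }
  rec <- function(k, t) {
    i <- k / rec_stride + 1L
    times[i] <<- t
    chi[i, ] <<- net$states[record_cells, 1L]
    zeta[i, ] <<- net$states[record_cells, 2L]
    eta[i, ] <<- net$states[record_cells, 3L]
    nMp[i, ] <<- S_cb[record_cells, 1L]
    nAMp[i, ] <<- S_cb[record_cells, 2L]
    nAM[i, ] <<- S_cb[record_cells, 3L]
  }
  rec(0L, t0)
  h <- NULL
  isolid <- 0L
  for (k in seq_len(n_steps)) {
    t <- t0 + (k - 1L) * cfg$dt_cell
    if (!is.null(cfg$protocol)) {
      up <- apply_protocol(cfg$protocol, net$params, cb_p, t, phi_A0)
      net$params <- up$cell_p
      cb_p <- up$cb_p
    }
    net <- network_step(net, t, cfg$dt_cell, rtol = cfg$rtol,
                        atol = cfg$atol, h0 = h)
    h <- attr(net, "h")
    S_cb <- step_cb(S_cb, net$states[, 1L], cfg$dt_cell, cb_p)
    if (k %% rec_stride == 0L) rec(k, t + cfg$dt_cell)
    if (cfg$mechanics && k %% stride == 0L) {
      isolid <- isolid + 1L
      # contractile units: forward Euler on the chemical sliding with
      # the lagged stretch, then active energy coefficients per GP
      n_AMp_e <- S_cb[mesh$cell_of_element, 2L]
      n_AM_e <- S_cb[mesh$cell_of_element, 3L]
      active <- vector("list", ne)
      for (e in seq_len(ne)) {
        u_fs_c[e, ] <- evolve_ufs_c(u_fs_c[e, ], lam_prev[e, ],
                                    n_AMp_e[e], n_AM_e[e],
                                    cfg$dt_solid, cfg$cu)
        cfac <- 0.5 * cfg$cu$mu_a * overlap(u_fs_c[e, ], cfg$cu) *
          (n_AMp_e[e] + n_AM_e[e])
        active[[e]] <- list(cfac = cfac, u_fs = u_fs_c[e, ])
      }
      sol <- newton_solve(mesh, sol$u, ring_bcs(mesh, d_hold), cfg$tissue,
                          active = active, maxit = 60L, abs_floor = 2e-4)
      if (!sol$converged) {
        stop("continuum solve failed at t = ", signif(t, 6),
             " (residual ", signif(sol$residual_norm, 3), ")")
      }
      lam_prev <- sol$lam_gp
      force[isolid] <- hook_force(sol, mesh)
      if (!is.null(cfg$out_dir) && cfg$vtk_every > 0 &&
          isolid %% max(1L, round(cfg$vtk_every / cfg$dt_solid)) == 0L) {
        P_a_e <- vapply(seq_len(ne), function(e)
          mean(filament_stress(lam_prev[e, ], u_fs_c[e, ],
                               n_AMp_e[e], n_AM_e[e], cfg$cu)), 0)
        write_vtk(mesh,
                  file.path(cfg$out_dir,
                            sprintf("state_%06d.vtk", isolid)),
                  point_data = list(displacement = sol$u),
                  cell_data = list(J = sol$Theta,
                                   chi = net$states[mesh$cell_of_element, 1L],
                                   u_fs = rowMeans(u_fs_c),
                                   P_a = P_a_e,
                                   n_att = n_AMp_e + n_AM_e))
      }
    }
  }
  out <- list(times = times, cells = record_cells,
              chi = chi, zeta = zeta, eta = eta,
              n_Mp = nMp, n_AMp = nAMp, n_AM = nAM, n_att = nAMp + nAM,
              force = if (cfg$mechanics) force else NULL,
              times_force = if (cfg$mechanics) times_F else NULL,
              preload = if (cfg$mechanics) {
                list(d = pre$d, force = pre$force)
              } else NULL,
              config = cfg,
              manifest = list(seed = cfg$seed,
                              n_cells = ne,
                              package = as.character(utils::packageVersion("vasomech"))))
  if (cfg$mechanics && cfg$t_end > 0) {
    # no normalization when the onset force is not positive (e.g. an
    # unloaded strip before active tone develops)
    out$force_norm <- tryCatch(
      normalized_force(list(times = times_F, force = force),
                       t_intervention = 0),
      error = function(e) NULL)
  }
  class(out) <- "vasomech_sim"
  out
}

#' Normalize a force series by its value at the intervention onset
#'
#' @param series list with `times` and `force`.
#' @param t_intervention onset time (s); the reference `F0` is the
#'   first sample at or after it.
#' @return list with `times`, `ratio` (F/F0) and `F0`.
#' @export
normalized_force <- function(series, t_intervention = 0) {
  i0 <- which(series$times >= t_intervention - 1e-12)[1]
  if (is.na(i0)) stop("no samples at or after the intervention onset")
  F0 <- series$force[i0]
  if (!is.finite(F0) || F0 <= 0) stop("F0 must be > 0 for normalization")
  list(times = series$times, ratio = series$force / F0, F0 = F0)
}

#' @export
print.vasomech_sim <- function(x, ...) {
  cfg <- x$config
  cat("Multiscale arterial ring simulation\n")
  cat(sprintf("  cells/elements: %d   seed: %d\n",
              x$manifest$n_cells, x$manifest$seed))
  if (!is.null(cfg$protocol)) {
    cat(sprintf("  protocol: %s\n", cfg$protocol$name))
  }
  cat(sprintf("  time: preroll %g s + protocol %g s (dt_cell %g s, dt_solid %g s)\n",
              cfg$preroll, cfg$t_end, cfg$dt_cell, cfg$dt_solid))
  if (!is.null(x$force)) {
    cat(sprintf("  preload: %.4f mN at hook displacement %.4f mm\n",
                x$preload$force, x$preload$d))
    cat(sprintf("  final hook force: %.4f mN\n",
                x$force[length(x$force)]))
  }
  invisible(x)
}

#' @export
summary.vasomech_sim <- function(object, ...) {
  x <- object
  post <- x$times >= 0
  out <- list(
    n_cells = x$manifest$n_cells,
    chi_range = range(x$chi[post, , drop = FALSE]),
    zeta_range = range(x$zeta[post, , drop = FALSE]),
    n_att_final = x$n_att[nrow(x$n_att), ],
    force_final = if (!is.null(x$force)) x$force[length(x$force)] else NA,
    F0 = if (!is.null(x$force_norm)) x$force_norm$F0 else NA)
  class(out) <- "summary.vasomech_sim"
  out
}

#' @export
print.summary.vasomech_sim <- function(x, ...) {
  cat(sprintf("cells: %d\n", x$n_cells))
  cat(sprintf("chi range (post-onset): [%.4f, %.4f] uM\n",
              x$chi_range[1], x$chi_range[2]))
  cat(sprintf("zeta range (post-onset): [%.4f, %.4f] uM\n",
              x$zeta_range[1], x$zeta_range[2]))
  if (is.finite(x$force_final)) {
    cat(sprintf("final hook force: %.4f mN (F0 = %.4f mN)\n",
                x$force_final, x$F0))
  }
  invisible(x)
}

#' @export
plot.vasomech_sim <- function(x, which = c("force", "calcium"), ...) {
  which <- match.arg(which)
  if (which == "force" && !is.null(x$force)) {
    plot(x$times_force, x$force, type = "l", xlab = "time (s)",
         ylab = "hook force (mN)", ...)
    abline(v = 0, lty = 3)
  } else {
    matplot(x$times, x$chi, type = "l", lty = 1, xlab = "time (s)",
            ylab = expression(chi ~ (mu * M)), ...)
    abline(v = 0, lty = 3)
  }
  invisible(x)
}

#' Long-format per-cell records of a simulation
#'
#' @param x a `vasomech_sim`.
#' @return data.frame with the documented CSV schema
#'   (t, cell_id, chi, zeta, eta, n_M, n_Mp, n_AMp, n_AM, n_att).
#' @export
sim_records <- function(x) {
  nr <- length(x$cells)
  nt <- length(x$times)
  data.frame(
    t = rep(x$times, nr),
    cell_id = rep(x$cells, each = nt),
    chi = as.vector(x$chi), zeta = as.vector(x$zeta),
    eta = as.vector(x$eta),
    n_M = as.vector(1 - x$n_Mp - x$n_AMp - x$n_AM),
    n_Mp = as.vector(x$n_Mp), n_AMp = as.vector(x$n_AMp),
    n_AM = as.vector(x$n_AM), n_att = as.vector(x$n_att))
}
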