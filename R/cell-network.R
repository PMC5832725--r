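#' Construct a network of coupled smooth muscle cells
#'
#' A cell network holds the per-cell states, the (possibly per-cell)
#' parameter set and a symmetric face-sharing adjacency list through
#' which Ca2+ and voltage are exchanged.
#'
#' @param n_cells number of cells.
#' @param params [cell_params()]; the `Phi_A` field may be a vector of
#'   length `n_cells` (heterogeneous population).
#' @param adjacency list of integer neighbour vectors (symmetric, no
#'   self-loops); `NULL` means an uncoupled population.
#' @param states optional n x 3 matrix (columns chi, zeta, eta);
#'   defaults to the reference initial conditions chi = 0.1 uM,
#'   zeta = 0.2 uM, eta = -0.02 V for every cell.
#' @return Object of class `cell_network`.
#' @export
cell_network <- function(n_cells, params = cell_params(), adjacency = NULL,
                         states = NULL) {
  stopifnot(n_cells >= 1)
  if (is.null(adjacency)) adjacency <- rep(list(integer(0)), n_cells)
  validate_adjacency(adjacency, n_cells)
  if (is.null(states)) {
    s0 <- cell_state()
    states <- matrix(rep(as.numeric(s0), each = n_cells), nrow = n_cells,
                     dimnames = list(NULL, c("chi", "zeta", "eta")))
  } else {
    states <- as.matrix(states)
    stopifnot(nrow(states) == n_cells, ncol(states) == 3)
    colnames(states) <- c("chi", "zeta", "eta")
  }
  if (!(length(params$Phi_A) %in% c(1L, n_cells))) {
    stop("Phi_A must be scalar or length n_cells")
  }
  structure(list(n_cells = n_cells, states = states, params = params,
                 adjacency = adjacency),
            class = "cell_network")
}

validate_adjacency <- function(adj, n) {
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (any(nb == i)) stop("self-loop in adjacency at cell ", i)
    if (any(nb < 1L | nb > n)) stop("dangling neighbour index at cell ", i)
    for (j in nb) {
      if (!(i %in% adj[[j]])) stop("adjacency not symmetric: ", i, " -> ", j)
    }
  }
  invisible(adj)
}

state_list <- function(Y) {
  list(chi = Y[, 1L], zeta = Y[, 2L], eta = Y[, 3L])
}

rhs_matrix <- function(Y, p, J_Ca, J_V) {
  # trial stages of the embedded scheme may probe slightly negative
  # concentrations; the acceptance-time guard lives in network_step()
  d <- cell_rhs(state_list(Y), p, J_Ca = J_Ca, J_V = J_V, check = FALSE)
  cbind(d$dchi, d$dzeta, d$deta)
}

# Cash-Karp embedded Runge-Kutta 4(5) tableau
.ck_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(3 / 10, -9 / 10, 6 / 5),
  c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
  c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096)
)
.ck_b5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
.ck_b4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)

# Adaptive embedded explicit RK (Cash-Karp 4/5) with PI step control,
# vectorized over all cells; coupling currents are held frozen by the
# caller for the duration of the span.
rk45_span <- function(Y, p, J_Ca, J_V, t0, t1, rtol, atol, h0 = NULL) {
  span <- t1 - t0
  if (span <= 0) return(list(Y = Y, h = h0))
  h <- if (is.null(h0) || !is.finite(h0) || h0 <= 0) span else min(h0, span)
  t <- t0
  err_prev <- 1
  n_reject <- 0L
  while (t < t1 - 1e-14 * span) {
    h <- min(h, t1 - t)
    k1 <- rhs_matrix(Y, p, J_Ca, J_V)
    k2 <- rhs_matrix(Y + h * .ck_a[[1]][1] * k1, p, J_Ca, J_V)
    k3 <- rhs_matrix(Y + h * (.ck_a[[2]][1] * k1 + .ck_a[[2]][2] * k2),
                     p, J_Ca, J_V)
    k4 <- rhs_matrix(Y + h * (.ck_a[[3]][1] * k1 + .ck_a[[3]][2] * k2 +
                                .ck_a[[3]][3] * k3), p, J_Ca, J_V)
    k5 <- rhs_matrix(Y + h * (.ck_a[[4]][1] * k1 + .ck_a[[4]][2] * k2 +
                                .ck_a[[4]][3] * k3 + .ck_a[[4]][4] * k4),
                     p, J_Ca, J_V)
    k6 <- rhs_matrix(Y + h * (.ck_a[[5]][1] * k1 + .ck_a[[5]][2] * k2 +
                                .ck_a[[5]][3] * k3 + .ck_a[[5]][4] * k4 +
                                .ck_a[[5]][5] * k5), p, J_Ca, J_V)
    Y5 <- Y + h * (.ck_b5[1] * k1 + .ck_b5[3] * k3 + .ck_b5[4] * k4 +
                     .ck_b5[6] * k6)
    Y4 <- Y + h * (.ck_b4[1] * k1 + .ck_b4[3] * k3 + .ck_b4[4] * k4 +
                     .ck_b4[5] * k5 + .ck_b4[6] * k6)
    sc <- atol + rtol * pmax(abs(Y), abs(Y5))
    err <- max(abs(Y5 - Y4) / sc)
    if (!is.finite(err)) err <- 2
    if (err <= 1) {
      t <- t + h
      Y <- Y5
      # PI controller (orders 4/5)
      fac <- 0.9 * err^(-0.7 / 5) * err_prev^(0.4 / 5)
      err_prev <- max(err, 1e-10)
      h <- h * min(5, max(0.2, fac))
      n_reject <- 0L
    } else {
      h <- h * max(0.1, 0.9 * err^(-0.2))
      n_reject <- n_reject + 1L
    }
    if (h < 1e-12 * max(span, abs(t1)) || n_reject > 50L) {
      stop("step-size underflow (stiffness) at t = ", signif(t, 6),
           "; state range chi [", signif(min(Y[, 1]), 4), ", ",
           signif(max(Y[, 1]), 4), "]")
    }
  }
  list(Y = Y, h = h)
}

#' Advance the cell network by one cellular time step
#'
#' Coupling currents are evaluated from the states at the beginning of
#' the step and held frozen while the ionic ODEs of every cell are
#' advanced over `dt` with the adaptive embedded Runge-Kutta scheme
#' (segregated cellular update).
#'
#' @param net a [cell_network()].
#' @param t current time (s).
#' @param dt cellular step (s).
#' @param rtol,atol integrator tolerances.
#' @param h0 initial inner step suggestion (internal reuse).
#' @return Updated `cell_network` with attribute `h` (last inner step).
#' @export
network_step <- function(net, t, dt, rtol = 1e-7, atol = 1e-9, h0 = NULL) {
  Y <- net$states
  p <- net$params
  J_Ca <- coupling_current(Y[, 1L], net$adjacency, p$alpha_C)
  J_V <- coupling_current(Y[, 3L], net$adjacency, p$alpha_V)
  res <- rk45_span(Y, p, J_Ca, J_V, t, t + dt, rtol, atol, h0)
  if (min(res$Y[, 1:2]) < -1e-9) {
    stop("negative concentration produced at t = ", signif(t + dt, 6),
         " (min = ", signif(min(res$Y[, 1:2]), 4), ")")
  }
  net$states <- res$Y
  attr(net, "h") <- res$h
  net
}

#' Integrate a cell network over a time span
#'
#' States are advanced on the uniform `dt_cell` grid; inside each grid
#' step the ionic system is integrated adaptively with neighbour states
#' frozen at the step start.  The result is reported on the grid.
#'
#' @param net a [cell_network()].
#' @param t_span length-2 numeric `c(t0, t1)` (s).
#' @param dt_cell cellular reporting/coupling step (s).
#' @param rtol,atol integrator tolerances.
#' @param modulate optional `function(params, t)` applied at the start
#'   of every grid step (parameter ramps).
#' @param record_cells integer indices of cells whose trajectories are
#'   stored (default: all).
#' @return Object of class `network_trajectory`: list with `times` and
#'   matrices `chi`, `zeta`, `eta` (time x recorded cell), the indices
#'   `cells`, and the final `net`.
#' @export
integrate_network <- function(net, t_span, dt_cell, rtol = 1e-7, atol = 1e-9,
                              modulate = NULL, record_cells = NULL) {
  stopifnot(dt_cell > 0, length(t_span) == 2, t_span[2] >= t_span[1])
  if (is.null(record_cells)) record_cells <- seq_len(net$n_cells)
  n_steps <- max(1L, as.integer(round((t_span[2] - t_span[1]) / dt_cell)))
  times <- t_span[1] + dt_cell * (0:n_steps)
  nr <- length(record_cells)
  chi <- matrix(NA_real_, n_steps + 1L, nr)
  zeta <- matrix(NA_real_, n_steps + 1L, nr)
  eta <- matrix(NA_real_, n_steps + 1L, nr)
  chi[1L, ] <- net$states[record_cells, 1L]
  zeta[1L, ] <- net$states[record_cells, 2L]
  eta[1L, ] <- net$states[record_cells, 3L]
  h <- NULL
  for (k in seq_len(n_steps)) {
    t <- times[k]
    if (!is.null(modulate)) net$params <- modulate(net$params, t)
    net <- network_step(net, t, dt_cell, rtol = rtol, atol = atol, h0 = h)
    h <- attr(net, "h")
    chi[k + 1L, ] <- net$states[record_cells, 1L]
    zeta[k + 1L, ] <- net$states[record_cells, 2L]
    eta[k + 1L, ] <- net$states[record_cells, 3L]
  }
  structure(list(times = times, chi = chi, zeta = zeta, eta = eta,
                 cells = record_cells, net = net),
            class = "network_trajectory")
}
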