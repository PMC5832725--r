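test_that("flux laws match an independent transcription over random states", {
  p <- cell_params()
  set.seed(11)
  for (k in 1:25) {
    chi <- runif(1, 0, 2); zeta <- runif(1, 0, 4)
    eta <- runif(1, -0.12, 0.08)
    pk <- cell_params(Phi_A = runif(1, 0.2, 4),
                      A_S = sample(c(0, 0.1), 1),
                      C_Ry = runif(1, 300, 1250))
    got <- flux_vector(list(chi = chi, zeta = zeta, eta = eta), pk)
    want <- oracle_fluxes(chi, zeta, eta, pk)
    for (nm in names(want)) {
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-14, label = nm)
    }
  }
})

test_that("tabulated anchor values and zero limits hold", {
  p <- cell_params()
  s <- list(chi = 0.1, zeta = 0.2, eta = -0.02)
  # constant NSCC influx equals its tabulated default
  expect_identical(extracellular_influx(s, p)$Phi_A, 0.6)
  # store-operated channel off at the default amplitude
  expect_identical(extracellular_influx(s, p)$Phi_S, 0)
  # SERCA at its half-point carries half the maximal rate
  expect_equal(store_exchange(list(chi = 4.4, zeta = 1), p)$Phi_B, 200)
  # zero-substrate limits
  z <- store_exchange(list(chi = 0, zeta = 0), p)
  expect_identical(unname(c(z$Phi_B, z$Phi_C, z$Phi_L)), c(0, 0, 0))
  expect_identical(membrane_efflux(list(chi = 0, eta = -0.02), p)$Phi_D, 0)
  # negative concentrations rejected
  expect_error(store_exchange(list(chi = -0.1, zeta = 1), p), "negative")
  expect_error(extracellular_influx(list(chi = NaN, zeta = 1, eta = 0), p),
               "non-finite")
})

test_that("voltage-gated fluxes vanish at their reversal potentials", {
  p <- cell_params()
  at <- function(eta) list(chi = 0.4, zeta = 1.1, eta = eta)
  expect_equal(extracellular_influx(at(p$z_Ca1), p)$Phi_V, 0)
  expect_equal(extracellular_influx(at(p$z_NCX), p)$Phi_N, 0)
  expect_equal(membrane_efflux(at(p$z_Cl), p)$Phi_Cl, 0)
  expect_equal(membrane_efflux(at(p$z_K), p)$Phi_K, 0)
})

test_that("coupling currents are antisymmetric and conservative", {
  # two-cell chain: equal and opposite
  J <- coupling_current(c(0.1, 0.3), list(2L, 1L), alpha = 1.0)
  expect_equal(J, c(0.2, -0.2))
  # identical cells: zero everywhere
  expect_equal(coupling_current(rep(0.7, 5),
                                list(2L, c(1L, 3L), c(2L, 4L), c(3L, 5L), 4L),
                                1.0),
               rep(0, 5))
  # alpha = 0 switches coupling off
  expect_equal(coupling_current(c(0.1, 9), list(2L, 1L), 0), c(0, 0))
  # random graph: exact global conservation
  set.seed(7)
  n <- 20
  adj <- rep(list(integer(0)), n)
  for (k in 1:30) {
    ij <- sample(n, 2)
    if (!(ij[2] %in% adj[[ij[1]]])) {
      adj[[ij[1]]] <- c(adj[[ij[1]]], ij[2])
      adj[[ij[2]]] <- c(adj[[ij[2]]], ij[1])
    }
  }
  v <- runif(n)
  expect_equal(sum(coupling_current(v, adj, 1.3)), 0, tolerance = 1e-14)
  # dangling index is a configuration error
  expect_error(coupling_current(c(1, 2), list(5L, 1L), 1), "dangling")
})

test_that("cell_rhs has the documented structure", {
  p <- cell_params()
  s <- list(chi = 0.3, zeta = 1.2, eta = -0.03)
  d <- cell_rhs(s, p)
  fl <- flux_vector(s, p)
  # store balance involves only SERCA, CICR and leak
  expect_equal(d$dzeta, fl$Phi_B - fl$Phi_C - fl$Phi_L)
  # all rates/conductances zero is an equilibrium of the whole system
  p0 <- cell_params(Phi_A = 0, L_SR = 0, A_S = 0, E_Ca = 0, E_NCX = 0,
                    B_SR = 0, C_Ry = 0, D_EX = 0, E_Cl = 0, E_K = 0)
  d0 <- cell_rhs(s, p0)
  expect_equal(unname(unlist(d0)), c(0, 0, 0))
  # matches the independent transcription including coupling
  d2 <- cell_rhs(s, p, J_Ca = 0.05, J_V = -0.2)
  want <- oracle_rhs(c(0.3, 1.2, -0.03), p, 0.05, -0.2)
  expect_equal(unname(c(d2$dchi, d2$dzeta, d2$deta)), want, tolerance = 1e-14)
})

test_that("adaptive network integration matches a reference integrator", {
  skip_if_not_installed("deSolve")
  p <- cell_params(Phi_A = 0.8)
  net <- cell_network(1, p)
  tr <- integrate_network(net, c(0, 100), dt_cell = 0.05)
  ref <- deSolve::lsoda(
    y = c(0.1, 0.2, -0.02), times = tr$times,
    func = function(t, y, parms) list(oracle_rhs(y, p)),
    rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tr$chi[, 1] - ref[, 2])), 1e-4)
})

test_that("adaptive integrator agrees with fixed-step RK4", {
  p <- cell_params(Phi_A = 0.8)
  net <- cell_network(1, p)
  tr <- integrate_network(net, c(0, 10), dt_cell = 0.1)
  rk <- oracle_rk4(c(0.1, 0.2, -0.02), p, 10, 1e-4)
  idx <- round(seq(1, nrow(rk), length.out = length(tr$times)))
  expect_lt(max(abs(tr$chi[, 1] - rk[idx, 1])), 1e-4)
})

test_that("states stay constant under a zero right-hand side", {
  p0 <- cell_params(Phi_A = 0, L_SR = 0, A_S = 0, E_Ca = 0, E_NCX = 0,
                    B_SR = 0, C_Ry = 0, D_EX = 0, E_Cl = 0, E_K = 0)
  net <- cell_network(3, p0)
  tr <- integrate_network(net, c(0, 5), dt_cell = 0.5)
  expect_equal(tr$chi[nrow(tr$chi), ], rep(0.1, 3))
  expect_equal(tr$zeta[nrow(tr$zeta), ], rep(0.2, 3))
  expect_equal(tr$eta[nrow(tr$eta), ], rep(-0.02, 3))
})

test_that("a single cell at baseline influx oscillates and stays positive", {
  net <- cell_network(1, cell_params(Phi_A = 0.8))
  tr <- integrate_network(net, c(0, 1000), dt_cell = 0.1)
  late <- tr$times > 500
  # sustained periodic oscillation of chi
  amp <- diff(range(tr$chi[late, 1]))
  expect_gt(amp, 0.2)
  pk <- peak_times(tr$times[late], tr$chi[late, 1])
  expect_gte(length(pk), 4)
  periods <- diff(pk)
  expect_lt(stats::sd(periods) / mean(periods), 0.05)
  # non-negativity over the whole 1000 s run
  expect_gte(min(tr$chi), 0)
  expect_gte(min(tr$zeta), 0)
  # membrane potential stays physiological
  expect_true(all(abs(tr$eta) < 0.2))
})

test_that("coupling synchronizes a heterogeneous chain without killing it", {
  phi <- c(0.7, 0.8, 0.9)
  run <- function(alpha) {
    p <- cell_params(Phi_A = phi, alpha_C = alpha, alpha_V = alpha)
    adj <- list(2L, c(1L, 3L), 2L)
    integrate_network(cell_network(3, p, adj), c(0, 300), dt_cell = 0.05)
  }
  tr0 <- run(0)
  tr1 <- run(1.0)
  half <- function(tr) tr$times > 150
  pks <- function(tr) lapply(1:3, function(i)
    peak_times(tr$times[half(tr)], tr$chi[half(tr), i]))
  t_eval <- seq(200, 290, by = 1)
  r0 <- order_parameter(t_eval, pks(tr0))
  r1 <- order_parameter(t_eval, pks(tr1))
  expect_gt(r1, r0)
  # amplitudes are not significantly affected by coupling
  a0 <- osc_amplitude(tr0$times, tr0$chi[, 2])
  a1 <- osc_amplitude(tr1$times, tr1$chi[, 2])
  expect_lt(abs(a1 - a0) / a0, 0.2)
})

test_that("network validation catches malformed adjacency", {
  expect_error(cell_network(2, adjacency = list(c(1L), integer(0))),
               "self-loop")
  expect_error(cell_network(2, adjacency = list(2L, integer(0))),
               "symmetric")
  expect_error(cell_network(2, adjacency = list(3L, integer(0))),
               "dangling")
})
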