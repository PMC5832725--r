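# small strip configuration used by several blocks
strip_cfg <- function(...) {
  make_fixture("strip", n = 4, phi_A_mean = 0.8, phi_A_sd = 0.05,
               dt_cell = 0.05, dt_solid = 0.5, t_end = 20, preroll = 10,
               record_cells = 1:4, ...)
}

test_that("a zero-duration protocol returns the loading-phase preload", {
  cfg <- simulation_config(resolution = c(1, 8, 1), t_end = 0, preroll = 0,
                           preload = 0.5, dt_cell = 0.05, dt_solid = 0.5)
  sim <- run_simulation(cfg)
  expect_equal(length(sim$force), 1)
  expect_equal(sim$force, sim$preload$force)
  expect_lt(abs(sim$force - 0.5) / 0.5, 0.005)
})

test_that("with phosphorylation off the force relaxes to the passive preload", {
  # the initially phosphorylated detached pool attaches transiently even
  # at tau1 = 0; once it drains into free myosin the active stress is
  # exactly zero and the hook force returns to the passive value
  cfg <- simulation_config(resolution = c(1, 8, 1), preload = 0.4,
                           cb = cb_params(theta = 0),  # phosphorylation off
                           dt_cell = 0.05, dt_solid = 0.5,
                           t_end = 10, preroll = 30, phi_A_sd = 0.05)
  sim <- run_simulation(cfg)
  late <- sim$times_force > 0
  expect_lt(max(abs(sim$force[late] - sim$preload$force)), 1e-4)
  expect_lt(max(sim$n_att[nrow(sim$n_att), ]), 1e-6)
})

test_that("the cellular level is independent of the mechanics (feed-forward)", {
  cfg_on <- strip_cfg(seed = 7)
  cfg_off <- strip_cfg(seed = 7, mechanics = FALSE)
  s1 <- run_simulation(cfg_on)
  s2 <- run_simulation(cfg_off)
  expect_identical(s1$chi, s2$chi)
  expect_identical(s1$n_AMp, s2$n_AMp)
  expect_null(s2$force)
})

test_that("identical configuration and seed reproduce identical output", {
  s1 <- run_simulation(strip_cfg(seed = 5))
  s2 <- run_simulation(strip_cfg(seed = 5))
  expect_identical(s1$force, s2$force)
  expect_identical(s1$chi, s2$chi)
  s3 <- run_simulation(strip_cfg(seed = 6))
  expect_false(identical(s3$chi, s1$chi))
})

test_that("refining the solid step changes the force trace by little", {
  base <- make_fixture("strip", n = 4, phi_A_mean = 0.8, phi_A_sd = 0.05,
                       dt_cell = 0.05, dt_solid = 0.05, t_end = 30,
                       preroll = 20, seed = 2)
  coarse <- make_fixture("strip", n = 4, phi_A_mean = 0.8, phi_A_sd = 0.05,
                         dt_cell = 0.05, dt_solid = 0.5, t_end = 30,
                         preroll = 20, seed = 2)
  s_f <- run_simulation(base)
  s_c <- run_simulation(coarse)
  # compare on the coarse grid
  idx <- match(round(s_c$times_force, 9), round(s_f$times_force, 9))
  keep <- !is.na(idx) & s_c$times_force > -15
  rms <- sqrt(mean((s_c$force[keep] - s_f$force[idx[keep]])^2))
  expect_lt(rms / max(abs(s_f$force)), 0.02)
})

test_that("force normalization behaves as a ratio to the onset value", {
  s <- list(times = 0:10, force = rep(2.5, 11))
  expect_equal(normalized_force(s)$ratio, rep(1, 11))
  s2 <- list(times = -5:5, force = c(rep(1, 6), rep(2, 5)))
  nf <- normalized_force(s2, t_intervention = 0)
  expect_equal(nf$F0, 1)
  expect_equal(nf$ratio[length(nf$ratio)], 2)
  # commutes with uniform rescaling
  s3 <- list(times = -5:5, force = 7 * s2$force)
  expect_equal(normalized_force(s3, 0)$ratio, nf$ratio)
  expect_error(normalized_force(list(times = 0:2, force = c(0, 1, 2)), 0),
               "F0")
})

test_that("simulation objects print, summarize and export records", {
  sim <- run_simulation(strip_cfg(seed = 1))
  expect_output(print(sim), "Multiscale")
  expect_output(print(summary(sim)), "final hook force")
  rec <- sim_records(sim)
  expect_true(all(c("t", "cell_id", "chi", "n_AM", "n_att") %in% names(rec)))
  expect_equal(nrow(rec), length(sim$times) * length(sim$cells))
  # conservation columns close exactly
  expect_equal(max(abs(rec$n_M + rec$n_Mp + rec$n_AMp + rec$n_AM - 1)), 0)
})

test_that("the CLI dispatches, validates and is deterministic", {
  expect_equal(cli(character(0)), 1L, ignore_attr = TRUE)
  expect_equal(suppressMessages(cli(c("run", "--config", "missing.yaml"))), 1L)
  expect_equal(suppressMessages(cli(c("frobnicate"))), 1L)
  td <- tempfile(); dir.create(td)
  f1 <- file.path(td, "a.csv"); f2 <- file.path(td, "b.csv")
  suppressMessages(cli(c("single-cell", "--t-end", "5", "--dt", "0.05",
                         "--seed", "1", "--out", f1)))
  suppressMessages(cli(c("single-cell", "--t-end", "5", "--dt", "0.05",
                         "--seed", "1", "--out", f2)))
  expect_identical(readLines(f1), readLines(f2))
  # mesh subcommand writes a readable MSH
  fm <- file.path(td, "ring.msh")
  suppressMessages(cli(c("mesh", "--resolution", "1,4,1", "--out", fm)))
  expect_equal(nrow(read_msh(fm)$elems), 4)
})

test_that("the run subcommand consumes a YAML config and writes outputs", {
  td <- tempfile(); dir.create(td)
  cfg <- simulation_config(mesh = build_strip_mesh(nx = 2), preload = 0,
                           phi_A_mean = 0.8, phi_A_sd = 0.05,
                           dt_cell = 0.05, dt_solid = 0.5,
                           t_end = 2, preroll = 1, seed = 9)
  fcfg <- file.path(td, "cfg.yaml")
  write_config(config_to_list(cfg), fcfg)
  # the YAML config describes a ring; run it cellular-only for speed
  raw <- read_config(fcfg)
  raw$mechanics <- FALSE
  raw$resolution <- c(1, 4, 1)
  write_config(raw, fcfg)
  out <- file.path(td, "out")
  st <- suppressMessages(cli(c("run", "--config", fcfg, "--seed", "9",
                               "--out", out)))
  expect_equal(st, 0L, ignore_attr = TRUE)
  expect_true(file.exists(file.path(out, "cells.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 9L)
})

test_that("periodic VTK snapshots carry the Gauss-point fields", {
  td <- tempfile(); dir.create(td)
  cfg <- make_fixture("strip", n = 2, phi_A_mean = 0.8, phi_A_sd = 0,
                      dt_cell = 0.05, dt_solid = 0.5, t_end = 2, preroll = 0,
                      out_dir = td, vtk_every = 1)
  run_simulation(cfg)
  vtks <- list.files(td, pattern = "state_.*vtk")
  expect_gte(length(vtks), 2)
  lines <- readLines(file.path(td, vtks[1]))
  for (fld in c("u_fs", "P_a", "n_att", "chi")) {
    expect_true(any(grepl(paste("SCALARS", fld), lines)), label = fld)
  }
})
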