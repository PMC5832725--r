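#' Randomize the NSCC influx across a cell population
#'
#' Cellular variability (size, uptake and extrusion rates) is emulated
#' by drawing each cell's constant Ca2+ influx `Phi_A` from a normal
#' distribution; negative draws are redrawn.  Seeded and reproducible.
#'
#' @param n_cells population size (>= 1).
#' @param mean distribution mean (uM/s).
#' @param sd standard deviation (uM/s), default 0.1.
#' @param seed integer RNG seed.
#' @return numeric vector of per-cell `Phi_A` values.
#' @export
randomize_population <- function(n_cells, mean = 0.6, sd = 0.1, seed = 1L) {
  stopifnot(n_cells >= 1, sd >= 0)
  if (sd == 0) {
    if (mean < 0) stop("Phi_A mean must be >= 0")
    return(rep(mean, n_cells))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- stats::rnorm(n_cells, mean, sd)
  for (k in 1:100) {
    bad <- x <= 0
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  if (any(x <= 0)) stop("could not draw a positive population")
  x
}

#' Piecewise-linear parameter ramp
#'
#' @param ramp list with `t_start` (s), `duration` (s), `from`, `to`
#'   (`from`/`to` may be vectors, e.g. per-cell values).
#' @param t time (s).
#' @return the interpolated value: `from` before `t_start`, linear
#'   during the ramp, `to` afterwards.
#' @export
ramp_value <- function(ramp, t) {
  stopifnot(ramp$duration >= 0)
  if (t <= ramp$t_start) return(ramp$from)
  if (ramp$duration == 0 || t >= ramp$t_start + ramp$duration) return(ramp$to)
  w <- (t - ramp$t_start) / ramp$duration
  (1 - w) * ramp$from + w * ramp$to
}

#' Build a pharmacological intervention schedule
#'
#' Encodes the three reference drug interventions as linear parameter
#' ramps plus static overrides, applied to an already randomized cell
#' population:
#' \describe{
#'   \item{phenylephrine}{each cell's `Phi_A` (baseline population
#'     mean 0.6 uM/s) is scaled by a factor 7 over the dilution time
#'     `dt_dil` (50 or 100 s), so the population mean rises from 0.6
#'     to 4.2 uM/s; theta = 1.}
#'   \item{cpa}{SERCA inhibition: `B_SR` ramps down; variant `"text"`
#'     400 -> 350 uM/s over 2000 s, variant `"table"` 400 -> 200 uM/s
#'     over 1000 s (both published values are shipped; `"text"` is the
#'     default).  Baseline `Phi_A` mean 0.8 uM/s; `theta` must be
#'     supplied explicitly (the tabulated value is ambiguous;
#'     candidates 30.0 and 0.0).}
#'   \item{ryanodine}{CICR block: `C_Ry` ramps 1250 -> 312.5 uM/s over
#'     2000 s starting at t = 100 s, with store-operated entry enabled
#'     (`A_S` = 0.1 1/s) and `theta` = 0.5; baseline `Phi_A` mean
#'     0.8 uM/s.}
#' }
#'
#' @param name one of `"phenylephrine"`, `"cpa"`, `"ryanodine"`.
#' @param dt_dil phenylephrine dilution time (s), 50 or 100.
#' @param variant CPA variant, `"text"` (default) or `"table"`.
#' @param theta CPA enhancement coefficient (required for `"cpa"`).
#' @param t_start intervention start time (s) relative to protocol
#'   time zero; the ryanodine ramp adds its own 100 s offset.
#' @return Object of class `protocol_schedule`: list with `name`,
#'   `phi_A_mean` (baseline population mean), `ramps` (named list of
#'   ramps keyed by parameter path), `overrides` (static parameter
#'   overrides), `scale_Phi_A` (multiplicative per-cell ramp or NULL).
#' @export
make_protocol <- function(name = c("phenylephrine", "cpa", "ryanodine"),
                          dt_dil = 50, variant = c("text", "table"),
                          theta = NULL, t_start = 0) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop("unknown protocol; valid: ",
                                            "phenylephrine, cpa, ryanodine"))
  variant <- match.arg(variant)
  out <- switch(name,
    phenylephrine = {
      if (!dt_dil %in% c(50, 100)) {
        stop("phenylephrine dilution time must be 50 or 100 s")
      }
      list(name = name, phi_A_mean = 0.6,
           scale_Phi_A = list(t_start = t_start, duration = dt_dil,
                              from = 1, to = 7),
           ramps = list(), overrides = list(theta = 1.0))
    },
    cpa = {
      if (is.null(theta)) {
        stop("cpa protocol requires an explicit theta ",
             "(documented candidates: 30.0, 0.0)")
      }
      ramp <- if (variant == "text") {
        list(t_start = t_start, duration = 2000, from = 400, to = 350)
      } else {
        list(t_start = t_start, duration = 1000, from = 400, to = 200)
      }
      list(name = name, phi_A_mean = 0.8, scale_Phi_A = NULL,
           ramps = list(B_SR = ramp),
           overrides = list(theta = theta))
    },
    ryanodine = {
      list(name = name, phi_A_mean = 0.8, scale_Phi_A = NULL,
           ramps = list(C_Ry = list(t_start = t_start + 100, duration = 2000,
                                    from = 1250, to = 312.5)),
           overrides = list(A_S = 0.1, theta = 0.5))
    })
  out$variant <- if (name == "cpa") variant else NULL
  class(out) <- "protocol_schedule"
  out
}

#' Apply a protocol to the model parameters at time t
#'
#' Returns updated cell parameters (and the CB `theta` override)
#' without touching any parameter outside the protocol's declared
#' paths.  The phenylephrine scaling is multiplicative per cell, so
#' the population coefficient of variation is preserved.
#'
#' @param proto a [make_protocol()] schedule.
#' @param cell_p a [cell_params()] whose `Phi_A` holds the randomized
#'   per-cell baseline.
#' @param cb_p a [cb_params()].
#' @param t protocol time (s); the intervention ramps start at their
#'   `t_start`.
#' @param phi_A_baseline per-cell baseline `Phi_A` vector (uM/s).
#' @return list with updated `cell_p` and `cb_p`.
#' @export
apply_protocol <- function(proto, cell_p, cb_p, t, phi_A_baseline) {
  if (!is.null(proto$scale_Phi_A)) {
    cell_p$Phi_A <- phi_A_baseline * ramp_value(proto$scale_Phi_A, t)
  } else {
    cell_p$Phi_A <- phi_A_baseline
  }
  for (nm in names(proto$ramps)) {
    cell_p[[nm]] <- ramp_value(proto$ramps[[nm]], t)
  }
  for (nm in names(proto$overrides)) {
    if (nm == "theta") cb_p$theta <- proto$overrides$theta
    else cell_p[[nm]] <- proto$overrides[[nm]]
  }
  list(cell_p = cell_p, cb_p = cb_p)
}
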