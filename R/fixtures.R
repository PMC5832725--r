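#' Structured hexahedral mesh of a uniaxial strip
#'
#' A bar along x with fibres aligned axially, clamped at the left face
#' and displacement-loaded at the right face; used for closed-form
#' verification of the continuum and contractile-unit coupling.
#'
#' @param length,width,height bar dimensions (mm).
#' @param nx,ny,nz element counts.
#' @return a `ring_mesh`-compatible object with `span = "strip"` and
#'   node sets `left`, `right` (`hook_contact` aliases `right`).
#' @export
build_strip_mesh <- function(length = 1, width = 0.2, height = 0.2,
                             nx = 1L, ny = 1L, nz = 1L) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  xs <- seq(0, length, length.out = nx + 1L)
  ys <- seq(0, width, length.out = ny + 1L)
  zs <- seq(0, height, length.out = nz + 1L)
  nid <- function(i, j, k) {
    (k - 1L) * ((nx + 1L) * (ny + 1L)) + (j - 1L) * (nx + 1L) + i
  }
  nodes <- matrix(0, (nx + 1L) * (ny + 1L) * (nz + 1L), 3)
  for (k in seq_len(nz + 1L)) for (j in seq_len(ny + 1L)) {
    for (i in seq_len(nx + 1L)) nodes[nid(i, j, k), ] <- c(xs[i], ys[j], zs[k])
  }
  elems <- matrix(0L, nx * ny * nz, 8)
  e <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    e <- e + 1L
    elems[e, ] <- c(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k),
                    nid(i, j + 1L, k), nid(i, j, k + 1L),
                    nid(i + 1L, j, k + 1L), nid(i + 1L, j + 1L, k + 1L),
                    nid(i, j + 1L, k + 1L))
  }
  left <- which(abs(nodes[, 1]) < 1e-12)
  right <- which(abs(nodes[, 1] - length) < 1e-12)
  mesh <- structure(list(nodes = nodes, elems = elems,
                         node_sets = list(left = left, right = right,
                                          hook_contact = right),
                         cell_of_element = seq_len(nrow(elems)),
                         geom = NULL, resolution = c(nx, ny, nz),
                         span = "strip", length = length,
                         fibre = function(x) c(1, 0, 0)),
                    class = "ring_mesh")
  mesh$adjacency <- cell_graph_from_mesh(mesh)
  mesh$gp <- mesh_gp_cache(mesh)
  mesh
}

#' Build small deterministic test systems
#'
#' Ready-to-run configurations for the standard verification fixtures:
#' \describe{
#'   \item{single_cell}{one uncoupled cell, cellular levels only.}
#'   \item{cell_chain}{`n` cells on a path graph, cellular levels
#'     only.}
#'   \item{two_cell_coupled}{a two-cell chain.}
#'   \item{strip}{uniaxial `nx`-element bar with clamped ends
#'     (isometric at reference length; mechanics on).}
#'   \item{coarse_ring}{the (2, 24, 5) one-eighth ring with
#'     mechanics.}
#' }
#'
#' @param kind fixture name.
#' @param n cells in a chain / elements along the strip.
#' @param resolution ring resolution for `coarse_ring`.
#' @param seed RNG seed.
#' @param ... overrides forwarded to [simulation_config()].
#' @return a [simulation_config()] (with the mesh attached for the
#'   mechanical fixtures).
#' @export
make_fixture <- function(kind = c("single_cell", "cell_chain",
                                  "two_cell_coupled", "strip",
                                  "coarse_ring"),
                         n = 3L, resolution = c(2L, 24L, 5L),
                         seed = 1L, ...) {
  kind <- match.arg(kind)
  chain_adj <- function(n) {
    adj <- rep(list(integer(0)), n)
    for (i in seq_len(n - 1L)) {
      adj[[i]] <- c(adj[[i]], i + 1L)
      adj[[i + 1L]] <- c(adj[[i + 1L]], i)
    }
    adj
  }
  chain_mesh <- function(n) {
    m <- build_strip_mesh(length = 0.05 * n, width = 0.05, height = 0.05,
                          nx = n)
    m
  }
  switch(kind,
    single_cell = simulation_config(mesh = chain_mesh(1L), mechanics = FALSE,
                                    phi_A_sd = 0, seed = seed, ...),
    cell_chain = simulation_config(mesh = chain_mesh(n), mechanics = FALSE,
                                   seed = seed, ...),
    two_cell_coupled = simulation_config(mesh = chain_mesh(2L),
                                         mechanics = FALSE, seed = seed, ...),
    strip = simulation_config(mesh = build_strip_mesh(nx = n),
                              preload = 0, seed = seed, ...),
    coarse_ring = simulation_config(resolution = resolution, seed = seed,
                                    ...))
}
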