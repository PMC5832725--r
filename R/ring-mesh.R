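#' Arterial ring geometry
#'
#' Nominal myograph geometry: a thin-walled ring held on two steel
#' hooks and loaded along x.
#'
#' @param inner_diameter,outer_diameter lumen and outer diameter (mm).
#' @param axial_width ring width along the vessel axis z (mm).
#' @param hook_diameter hook wire diameter (mm).
#' @return Object of class `ring_geometry`.
#' @export
ring_geometry <- function(inner_diameter = 0.7, outer_diameter = 0.8,
                          axial_width = 2.0, hook_diameter = 0.25) {
  if (!(0 < inner_diameter && inner_diameter < outer_diameter)) {
    stop("need 0 < inner_diameter < outer_diameter")
  }
  if (axial_width <= 0) stop("axial_width must be > 0")
  structure(list(inner_diameter = inner_diameter,
                 outer_diameter = outer_diameter,
                 axial_width = axial_width,
                 hook_diameter = hook_diameter),
            class = "ring_geometry")
}

#' Structured hexahedral mesh of the arterial ring
#'
#' Builds a structured mesh of the ring (by default the one-eighth
#' symmetry model: a quarter annulus in the loading quadrant times the
#' half axial width, exploiting the x, y and z mirror symmetries of
#' two-hook loading along x).  Node sets tag the symmetry planes and
#' the hook contact strip (inner-surface nodes within the arc
#' subtended by the hook radius).  Each element doubles as one smooth
#' muscle cell; the face-sharing element adjacency is the cell
#' communication graph.
#'
#' @param geom a [ring_geometry()].
#' @param resolution integer triple `(n_radial, n_circum, n_axial)`;
#'   `n_circum` counts elements over the quarter arc (eighth model) or
#'   the full circle (`span = "full"`).
#' @param span `"eighth"` (default) or `"full"` (complete annulus over
#'   the half width, used to validate the symmetry reduction).
#' @return Object of class `ring_mesh`: list with `nodes` (N x 3, mm),
#'   `elems` (E x 8, 1-based hexahedron connectivity), `node_sets`
#'   (`hook_contact`, `sym_x`, `sym_y`, `sym_z`, and for the full model
#'   `hook_left`), `adjacency`, `cell_of_element`, `geom`,
#'   `resolution`, `span`.
#' @export
build_ring_mesh <- function(geom = ring_geometry(),
                            resolution = c(2L, 24L, 5L),
                            span = c("eighth", "full")) {
  span <- match.arg(span)
  res <- as.integer(resolution)
  if (length(res) != 3 || any(res < 1) || res[2] < 4) {
    stop("resolution must be (n_radial >= 1, n_circum >= 4, n_axial >= 1)")
  }
  n_r <- res[1]; n_c <- res[2]; n_a <- res[3]
  r0 <- geom$inner_diameter / 2
  r1 <- geom$outer_diameter / 2
  w2 <- geom$axial_width / 2
  full <- span == "full"
  theta_max <- if (full) 2 * pi else pi / 2
  n_ct <- if (full) n_c else n_c + 1L   # circumferential node count
  rs <- seq(r0, r1, length.out = n_r + 1L)
  ths <- seq(0, theta_max, length.out = n_c + 1L)
  zs <- seq(0, w2, length.out = n_a + 1L)

  nid <- function(ir, ic, ia) {
    # wrap the circumferential index on the full ring
    icw <- if (full) ((ic - 1L) %% n_c) + 1L else ic
    (ia - 1L) * ((n_r + 1L) * n_ct) + (icw - 1L) * (n_r + 1L) + ir
  }
  nodes <- matrix(0, (n_r + 1L) * n_ct * (n_a + 1L), 3)
  for (ia in seq_len(n_a + 1L)) {
    for (ic in seq_len(n_ct)) {
      for (ir in seq_len(n_r + 1L)) {
        th <- ths[ic]
        nodes[nid(ir, ic, ia), ] <- c(rs[ir] * cos(th), rs[ir] * sin(th),
                                      zs[ia])
      }
    }
  }
  elems <- matrix(0L, n_r * n_c * n_a, 8)
  e <- 0L
  for (ia in seq_len(n_a)) {
    for (ic in seq_len(n_c)) {
      for (ir in seq_len(n_r)) {
        e <- e + 1L
        elems[e, ] <- c(nid(ir, ic, ia), nid(ir + 1L, ic, ia),
                        nid(ir + 1L, ic + 1L, ia), nid(ir, ic + 1L, ia),
                        nid(ir, ic, ia + 1L), nid(ir + 1L, ic, ia + 1L),
                        nid(ir + 1L, ic + 1L, ia + 1L),
                        nid(ir, ic + 1L, ia + 1L))
      }
    }
  }

  hook_arc <- asin(min(1, (geom$hook_diameter / 2) / r0))
  th_of <- atan2(nodes[, 2], nodes[, 1])
  on_inner <- abs(sqrt(nodes[, 1]^2 + nodes[, 2]^2) - r0) < 1e-9
  tol_th <- 1e-9
  node_sets <- list()
  if (full) {
    node_sets$hook_contact <- which(on_inner &
      (abs(th_of) <= hook_arc + tol_th))
    node_sets$hook_left <- which(on_inner &
      (abs(abs(th_of) - pi) <= hook_arc + tol_th))
    node_sets$sym_y <- which(abs(nodes[, 2]) < 1e-9)
    node_sets$sym_z <- which(abs(nodes[, 3]) < 1e-9)
  } else {
    node_sets$hook_contact <- which(on_inner & th_of <= hook_arc + tol_th)
    node_sets$sym_x <- which(abs(nodes[, 1]) < 1e-9)  # theta = pi/2 plane
    node_sets$sym_y <- which(abs(nodes[, 2]) < 1e-9)  # theta = 0 plane
    node_sets$sym_z <- which(abs(nodes[, 3]) < 1e-9)
  }

  mesh <- structure(list(nodes = nodes, elems = elems,
                         node_sets = node_sets,
                         cell_of_element = seq_len(nrow(elems)),
                         geom = geom, resolution = res, span = span),
                    class = "ring_mesh")
  mesh$adjacency <- cell_graph_from_mesh(mesh)
  mesh$gp <- mesh_gp_cache(mesh)
  mesh
}

#' Face-sharing element adjacency graph
#'
#' Brute-force face matching: every hexahedron face is keyed by its
#' sorted node quadruple; elements sharing a face are neighbours.
#' Interior cells of a structured grid have six neighbours.
#'
#' @param mesh a `ring_mesh` (or any list with an `elems` matrix).
#' @return list of integer neighbour vectors, symmetric and
#'   self-loop-free.
#' @export
cell_graph_from_mesh <- function(mesh) {
  el <- mesh$elems
  ne <- nrow(el)
  # local faces of the 8-node hexahedron
  faces <- list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                c(4, 3, 7, 8), c(2, 3, 7, 6), c(1, 4, 8, 5))
  keys <- character(6L * ne)
  owner <- integer(6L * ne)
  k <- 0L
  for (e in seq_len(ne)) {
    for (f in faces) {
      k <- k + 1L
      keys[k] <- paste(sort(el[e, f]), collapse = "-")
      owner[k] <- e
    }
  }
  adj <- rep(list(integer(0)), ne)
  sp <- split(owner, keys)
  for (own in sp) {
    if (length(own) == 2L) {
      adj[[own[1]]] <- c(adj[[own[1]]], own[2])
      adj[[own[2]]] <- c(adj[[own[2]]], own[1])
    }
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Total reference volume of a hexahedral mesh
#'
#' 2x2x2 Gauss quadrature of `det J` over every element.
#'
#' @param mesh a `ring_mesh`.
#' @return volume (mm^3).
#' @export
mesh_volume <- function(mesh) {
  gp <- gauss_hex8()
  vol <- 0
  for (e in seq_len(nrow(mesh$elems))) {
    X <- mesh$nodes[mesh$elems[e, ], ]
    for (g in seq_len(8)) {
      dN <- gp$dN[[g]]
      Jm <- t(dN) %*% X
      vol <- vol + det(Jm) * gp$w[g]
    }
  }
  vol
}
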