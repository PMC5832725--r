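#' Write a hexahedral mesh with fields to legacy VTK
#'
#' ASCII legacy unstructured-grid format readable by ParaView/VTK.
#'
#' @param mesh a `ring_mesh`.
#' @param path output file.
#' @param point_data named list of per-node vectors or N x 3 matrices.
#' @param cell_data named list of per-element vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); e <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con)
  wl("# vtk DataFile Version 3.0")
  wl("vasomech unstructured grid")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(apply(format(mesh$nodes, digits = 17, trim = TRUE), 1, paste,
           collapse = " "))
  wl(sprintf("CELLS %d %d", e, 9 * e))
  wl(apply(cbind(8L, mesh$elems - 1L), 1, paste, collapse = " "))
  wl(sprintf("CELL_TYPES %d", e))
  wl(as.character(rep(12L, e)))
  if (length(point_data)) {
    wl(sprintf("POINT_DATA %d", n))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        wl(sprintf("VECTORS %s double", nm))
        wl(apply(format(v, digits = 17, trim = TRUE), 1, paste,
                 collapse = " "))
      } else {
        wl(sprintf("SCALARS %s double 1", nm))
        wl("LOOKUP_TABLE default")
        wl(format(v, digits = 17, trim = TRUE))
      }
    }
  }
  if (length(cell_data)) {
    wl(sprintf("CELL_DATA %d", e))
    for (nm in names(cell_data)) {
      wl(sprintf("SCALARS %s double 1", nm))
      wl("LOOKUP_TABLE default")
      wl(format(cell_data[[nm]], digits = 17, trim = TRUE))
    }
  }
  invisible(path)
}

#' Write a hexahedral mesh in Gmsh MSH 2.2 ASCII format
#'
#' @param mesh a `ring_mesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con)
  wl("$MeshFormat"); wl("2.2 0 8"); wl("$EndMeshFormat")
  wl("$Nodes"); wl(as.character(nrow(mesh$nodes)))
  wl(paste(seq_len(nrow(mesh$nodes)),
           apply(format(mesh$nodes, digits = 17, trim = TRUE), 1, paste,
                 collapse = " ")))
  wl("$EndNodes")
  wl("$Elements"); wl(as.character(nrow(mesh$elems)))
  # type 5 = 8-node hexahedron; two tags (physical, elementary) = 1 1
  wl(paste(seq_len(nrow(mesh$elems)), "5 2 1 1",
           apply(mesh$elems, 1, paste, collapse = " ")))
  wl("$EndElements")
  invisible(path)
}

#' Read a hexahedral mesh from a Gmsh MSH file (v2.2 or v4.1 ASCII)
#'
#' Only 8-node hexahedra are retained; other element types (points,
#' lines, surface quads) are skipped.  Node tags may be sparse; they
#' are remapped to a dense 1-based index.  The returned mesh carries
#' the face-sharing adjacency but no symmetry/hook node sets (those
#' are defined by the structured generator).
#'
#' @param path MSH file.
#' @return a `ring_mesh`-compatible list.
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) {
      stop("malformed MSH file: missing $", name, " section")
    }
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(trimws(sect("MeshFormat")[1]), "\\s+")[[1]]
  ver <- as.numeric(fmt[1])
  if (is.na(ver)) stop("malformed MSH file: bad $MeshFormat at line ",
                       match("$MeshFormat", lines) + 1L)
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  if (ver < 4) {
    nl <- sect("Nodes")
    n <- as.integer(nl[1])
    rec <- t(vapply(nl[1 + seq_len(n)], nums, numeric(4), USE.NAMES = FALSE))
    tags <- as.integer(rec[, 1]); coords <- rec[, 2:4, drop = FALSE]
    el <- sect("Elements")
    ne_all <- as.integer(el[1])
    elems <- list()
    for (k in seq_len(ne_all)) {
      v <- nums(el[1 + k])
      if (length(v) < 2) stop("malformed MSH element at line ", k)
      if (v[2] == 5) {  # hexahedron
        ntags <- v[3]
        elems[[length(elems) + 1L]] <- as.integer(v[(4 + ntags):(11 + ntags)])
      }
    }
  } else {
    nl <- sect("Nodes")
    hdr <- nums(nl[1])
    nblocks <- hdr[1]
    tags <- integer(0); coords <- NULL
    i <- 2L
    for (b in seq_len(nblocks)) {
      bh <- nums(nl[i]); nb <- as.integer(bh[4])
      btags <- as.integer(vapply(nl[i + seq_len(nb)], nums, numeric(1),
                                 USE.NAMES = FALSE))
      bc <- t(vapply(nl[i + nb + seq_len(nb)], nums, numeric(3),
                     USE.NAMES = FALSE))
      tags <- c(tags, btags); coords <- rbind(coords, bc)
      i <- i + 2L * nb + 1L
    }
    el <- sect("Elements")
    hdr <- nums(el[1])
    nblocks <- hdr[1]
    elems <- list()
    i <- 2L
    for (b in seq_len(nblocks)) {
      bh <- nums(el[i]); etype <- bh[3]; nb <- as.integer(bh[4])
      for (k in seq_len(nb)) {
        v <- nums(el[i + k])
        if (etype == 5) elems[[length(elems) + 1L]] <- as.integer(v[-1])
      }
      i <- i + nb + 1L
    }
  }
  if (!length(elems)) stop("no hexahedral elements in ", path)
  remap <- integer(max(tags)); remap[tags] <- seq_along(tags)
  E <- do.call(rbind, lapply(elems, function(v) remap[v]))
  mesh <- structure(list(nodes = coords, elems = E, node_sets = list(),
                         cell_of_element = seq_len(nrow(E)),
                         geom = NULL, resolution = NULL, span = "imported"),
                    class = "ring_mesh")
  mesh$adjacency <- cell_graph_from_mesh(mesh)
  mesh$gp <- mesh_gp_cache(mesh)
  mesh
}

#' Write per-cell time series to CSV
#'
#' Long-format records with the documented column schema
#' `t, cell_id, chi, zeta, eta` and, when cross-bridge states are
#' present, `n_M, n_Mp, n_AMp, n_AM` plus the local force proxy
#' `n_att = n_AMp + n_AM`.
#'
#' @param records a data.frame with (at least) those columns.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(records, path) {
  need <- c("t", "cell_id", "chi", "zeta", "eta")
  if (!all(need %in% names(records))) {
    stop("records must contain columns: ", paste(need, collapse = ", "))
  }
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a simulation configuration (YAML)
#'
#' The configuration is a nested list mirroring
#' [simulation_config()]; parameter blocks round-trip through the
#' file.
#'
#' @param path YAML file.
#' @return For `read_config`, the configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
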