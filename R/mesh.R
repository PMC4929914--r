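#' Triangle-mesh container
#'
#' Lightweight container for triangulated surfaces used throughout the
#' package.  `nodes` is either an `n x 3` matrix (single frame) or an
#' `n x 3 x n_t` array (time-resolved); `triangles` is an integer `m x 3`
#' matrix of 1-based node indices whose winding defines the surface normal
#' (right-hand rule).  Connectivity is constant over time; only node
#' positions (and velocities) move.
#'
#' @param nodes node coordinates, m.
#' @param triangles integer `m x 3` index matrix.
#' @param times optional sample instants (s) for time-resolved meshes.
#' @param node_velocities optional array matching `nodes`, m/s.
#' @param side label, e.g. `"left"`, `"right"`, `"body"`.
#' @return An object of class `wing_mesh`.
#' @export
wing_mesh <- function(nodes, triangles, times = NULL, node_velocities = NULL,
                      side = "left") {
  triangles <- matrix(as.integer(triangles), ncol = 3)
  n_nodes <- if (length(dim(nodes)) == 3) dim(nodes)[1] else nrow(nodes)
  if (any(triangles < 1L) || any(triangles > n_nodes))
    stop("wing_mesh: triangle indices out of range", call. = FALSE)
  structure(list(nodes = nodes, triangles = triangles, times = times,
                 node_velocities = node_velocities, side = side),
            class = "wing_mesh")
}

#' @export
print.wing_mesh <- function(x, ...) {
  nt <- if (length(dim(x$nodes)) == 3) dim(x$nodes)[3] else 1L
  cat(sprintf("<wing_mesh '%s'> %d nodes, %d triangles, %d frame(s)\n",
              x$side, if (nt > 1) dim(x$nodes)[1] else nrow(x$nodes),
              nrow(x$triangles), nt))
  invisible(x)
}

# node matrix of frame it
mesh_frame_nodes <- function(mesh, it = 1L) {
  if (length(dim(mesh$nodes)) == 3) mesh$nodes[, , it] else mesh$nodes
}

#' Per-triangle areas and total surface area
#'
#' Each triangle area is half the norm of the cross product of two edge
#' vectors; `mesh_area` sums them.
#'
#' @param mesh a [wing_mesh()].
#' @param it frame index for time-resolved meshes.
#' @return `triangle_areas`: numeric vector (m^2); `mesh_area`: scalar.
#' @export
triangle_areas <- function(mesh, it = 1L) {
  nd <- mesh_frame_nodes(mesh, it)
  tr <- mesh$triangles
  a <- nd[tr[, 2], ] - nd[tr[, 1], ]
  b <- nd[tr[, 3], ] - nd[tr[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname triangle_areas
#' @export
mesh_area <- function(mesh, it = 1L) sum(triangle_areas(mesh, it))

# per-triangle unit normals and centroids for frame it
triangle_normals <- function(mesh, it = 1L) {
  nd <- mesh_frame_nodes(mesh, it)
  tr <- mesh$triangles
  a <- nd[tr[, 2], ] - nd[tr[, 1], ]
  b <- nd[tr[, 3], ] - nd[tr[, 1], ]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

triangle_centroids <- function(mesh, it = 1L) {
  nd <- mesh_frame_nodes(mesh, it)
  tr <- mesh$triangles
  (nd[tr[, 1], ] + nd[tr[, 2], ] + nd[tr[, 3], ]) / 3
}

#' Watertightness check and enclosed volume
#'
#' A closed surface has every edge shared by exactly two triangles with
#' opposite orientation.  The enclosed volume uses the divergence theorem
#' (sum of signed tetrahedron volumes); it is positive for outward-oriented
#' normals.
#'
#' @param mesh a [wing_mesh()].
#' @param it frame index.
#' @return `is_watertight`: logical; `mesh_volume`: signed volume (m^3).
#' @export
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  tab <- table(key)
  all(tab == 2L)
}

#' @rdname is_watertight
#' @export
mesh_volume <- function(mesh, it = 1L) {
  nd <- mesh_frame_nodes(mesh, it)
  tr <- mesh$triangles
  a <- nd[tr[, 1], ]; b <- nd[tr[, 2], ]; c_ <- nd[tr[, 3], ]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# ordered boundary loop(s) of an open mesh: edges used by exactly one
# triangle, chained into node-index cycles.  Returns a list of integer
# vectors (usually one loop for a wing membrane).
boundary_loops <- function(mesh) {
  tr <- mesh$triangles
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  once <- names(which(table(key) == 1L))
  bed <- ed[key %in% once, , drop = FALSE]
  if (nrow(bed) == 0L) return(list())
  nxt <- split(bed[, 2], bed[, 1])
  loops <- list()
  used <- character(0)
  for (s in as.character(bed[, 1])) {
    if (s %in% used) next
    loop <- as.integer(s)
    cur <- s
    repeat {
      used <- c(used, cur)
      cand <- nxt[[cur]]
      cand <- cand[!(as.character(cand) %in% used)]
      if (length(cand) == 0L) break
      cur <- as.character(cand[1])
      loop <- c(loop, as.integer(cur))
    }
    if (length(loop) > 2L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Write / read meshes as OBJ or PLY
#'
#' Plain-text Wavefront OBJ and ASCII PLY, one frame per file.
#'
#' @param mesh a [wing_mesh()].
#' @param path file path.
#' @param it frame index to write.
#' @return Readers return a single-frame [wing_mesh()]; writers return
#'   `path` invisibly.
#' @export
write_obj <- function(mesh, path, it = 1L) {
  nd <- mesh_frame_nodes(mesh, it)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.10g %.10g %.10g", nd[, 1], nd[, 2], nd[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L)
    stop("read_obj: no vertices or faces in `", path, "`", call. = FALSE)
  nd <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[2:4])))
  tr <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
    as.integer(sub("/.*", "", p[2:4]))))
  wing_mesh(nd, tr)
}

#' @rdname write_obj
#' @export
write_ply <- function(mesh, path, it = 1L) {
  nd <- mesh_frame_nodes(mesh, it)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(nd)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.10g %.10g %.10g", nd[, 1], nd[, 2], nd[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  hdr_end <- which(lines == "end_header")
  if (length(hdr_end) != 1L) stop("read_ply: missing end_header", call. = FALSE)
  nd <- do.call(rbind, lapply(strsplit(lines[hdr_end + seq_len(nv)], "\\s+"),
                              function(p) as.numeric(p[1:3])))
  tr <- do.call(rbind, lapply(strsplit(lines[hdr_end + nv + seq_len(nf)], "\\s+"),
                              function(p) as.integer(p[2:4]) + 1L))
  wing_mesh(nd, tr)
}
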