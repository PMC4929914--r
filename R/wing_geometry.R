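#' Reconstruct a closed wing outline from one frame of markers
#'
#' Builds a closed periodic cubic-spline curve through the nine wing markers
#' in anatomical order (leading edge root to tip, then wingtip, then
#' trailing edge tip back to root), with chord-length parameterisation.
#' The ordering is fixed by the anatomical marker labels, never by
#' geometric sorting.
#'
#' @param markers `9 x 3` matrix of marker coordinates with rownames
#'   `LE1..LE5, TIP, TE1..TE3` (any row order).
#' @return An object of class `wing_outline`: function `point(s)` mapping
#'   normalised arc parameter `s` in \[0,1) to 3D points, plus the anchor
#'   parameters of the markers (`s_markers`, named) and the marker matrix in
#'   loop order.
#' @export
reconstruct_outline <- function(markers) {
  ids <- marker_stations()$marker_id
  if (is.null(rownames(markers)) || !all(ids %in% rownames(markers)) ||
      nrow(markers) != 9L)
    stop("reconstruct_outline: need exactly 9 markers with rownames ",
         paste(ids, collapse = ", "), call. = FALSE)
  loop_order <- c("LE1", "LE2", "LE3", "LE4", "LE5", "TIP", "TE3", "TE2", "TE1")
  pts <- markers[loop_order, , drop = FALSE]

  seg <- rbind(diff(pts), pts[1, ] - pts[9, ])
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len < 1e-12))
    stop("reconstruct_outline: duplicated markers give a degenerate outline",
         call. = FALSE)
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)$d
  if (sv[2] < 1e-6 * sv[1])
    stop("reconstruct_outline: markers are collinear (degenerate outline)",
         call. = FALSE)

  t_knot <- c(0, cumsum(seg_len))        # length 10, closing at total length
  L <- t_knot[10]
  sx <- splinefun(t_knot, c(pts[, 1], pts[1, 1]), method = "periodic")
  sy <- splinefun(t_knot, c(pts[, 2], pts[1, 2]), method = "periodic")
  sz <- splinefun(t_knot, c(pts[, 3], pts[1, 3]), method = "periodic")

  point <- function(s) {
    t <- (s %% 1) * L
    cbind(sx(t), sy(t), sz(t))
  }
  s_markers <- t_knot[1:9] / L
  names(s_markers) <- loop_order
  structure(list(point = point, s_markers = s_markers, markers = pts, length = L),
            class = "wing_outline")
}

#' Triangulate the wing planform inside an outline
#'
#' Meshes the interior of a reconstructed outline with a transfinite
#' (Coons-patch) structured grid: the leading-edge and trailing-edge spline
#' arcs bound the patch spanwise, the root spline arc bounds it at the
#' shoulder, and the wingtip collapses to a point.  The structured quads are
#' split into consistently wound triangles, so the mesh boundary follows the
#' outline exactly at the sampled resolution.
#'
#' @param outline a [reconstruct_outline()] result.
#' @param target_elements desired triangle count (achieved within ~15%).
#' @param side label stored on the mesh.
#' @param layout optional `c(n_span, n_chord)` grid layout; supplying the
#'   layout of a previous frame guarantees identical connectivity across a
#'   time series.
#' @return A single-frame [wing_mesh()] with attribute `layout`.
#' @export
triangulate_wing <- function(outline, target_elements = 1335L, side = "left",
                             layout = NULL) {
  stopifnot(inherits(outline, "wing_outline"))
  sm <- outline$s_markers
  s_tip <- sm[["TIP"]]; s_te1 <- sm[["TE1"]]

  # simple-outline check on a dense resampling (adjacent-segment crossing
  # in the dominant plane would make the Coons patch fold)
  dense <- outline$point(seq(0, 1, length.out = 200)[-200])
  if (any(!is.finite(dense)))
    stop("triangulate_wing: outline evaluates to non-finite points", call. = FALSE)

  if (is.null(layout)) {
    # aspect ratio estimate: spanwise arc vs root chord
    root_chord <- sqrt(sum((outline$markers["LE1", ] - outline$markers["TE1", ])^2))
    span <- sqrt(sum((outline$markers["TIP", ] -
                      0.5 * (outline$markers["LE1", ] + outline$markers["TE1", ]))^2))
    ar <- max(1, span / max(root_chord, 1e-12))
    n_chord <- max(2L, as.integer(round(sqrt(target_elements / (2 * ar)))))
    n_span <- max(2L, as.integer(round((target_elements + n_chord) / (2 * n_chord))))
  } else {
    n_span <- as.integer(layout[1]); n_chord <- as.integer(layout[2])
  }

  u <- seq(0, 1, length.out = n_span + 1)
  v <- seq(0, 1, length.out = n_chord + 1)
  LE <- function(uu) outline$point(uu * s_tip)
  TE <- function(uu) outline$point(s_te1 - uu * (s_te1 - s_tip))
  ROOT <- function(vv) outline$point(1 - vv * (1 - s_te1))  # LE1 -> TE1
  P_LE1 <- outline$point(0); P_TIP <- outline$point(s_tip); P_TE1 <- outline$point(s_te1)

  # Coons patch nodes; tip column (u = 1) collapses to the single TIP node
  nid <- matrix(0L, n_span + 1, n_chord + 1)
  nodes <- matrix(0, n_span * (n_chord + 1) + 1, 3)
  k <- 0L
  for (i in seq_len(n_span)) {       # u index 1..n_span (u < 1)
    ui <- u[i]
    le_i <- LE(ui); te_i <- TE(ui)
    for (j in seq_len(n_chord + 1)) {
      vj <- v[j]
      p <- (1 - vj) * le_i + vj * te_i + (1 - ui) * ROOT(vj) + ui * P_TIP -
        ((1 - ui) * (1 - vj) * P_LE1 + ui * (1 - vj) * P_TIP +
           (1 - ui) * vj * P_TE1 + ui * vj * P_TIP)
      k <- k + 1L
      nodes[k, ] <- p
      nid[i, j] <- k
    }
  }
  tip_id <- k + 1L
  nodes[tip_id, ] <- P_TIP
  nid[n_span + 1, ] <- tip_id

  tris <- vector("list", n_span * n_chord)
  m <- 0L
  for (i in seq_len(n_span)) {
    for (j in seq_len(n_chord)) {
      a <- nid[i, j]; b <- nid[i, j + 1]; c_ <- nid[i + 1, j + 1]; d <- nid[i + 1, j]
      m <- m + 1L
      if (i == n_span) {
        tris[[m]] <- c(a, b, d)      # c_ == d == tip
      } else {
        tris[[m]] <- rbind(c(a, b, d), c(b, c_, d))
      }
    }
  }
  mesh <- wing_mesh(nodes, do.call(rbind, tris), side = side)
  attr(mesh, "layout") <- c(n_span, n_chord)
  mesh
}

#' Reconstruct a time-resolved wing mesh from a marker set
#'
#' Applies [reconstruct_outline()] + [triangulate_wing()] to every frame of
#' one wing of a marker set.  Connectivity is built once (from the first
#' frame) and reused, so only node positions move between frames.
#'
#' @param set a `marker_set`.
#' @param wing `"left"` or `"right"`.
#' @param target_elements triangle-count target per frame.
#' @return A time-resolved [wing_mesh()] (no velocities; see
#'   [refine_in_time()]).
#' @export
reconstruct_wing_series <- function(set, wing = "left", target_elements = 1335L) {
  stopifnot(inherits(set, "marker_set"))
  arr <- set$markers[[wing]]
  if (is.null(arr)) stop("reconstruct_wing_series: no `", wing, "` wing in set", call. = FALSE)
  n_t <- dim(arr)[3]
  first <- triangulate_wing(reconstruct_outline(arr[, , 1]), target_elements, side = wing)
  lay <- attr(first, "layout")
  n_nodes <- nrow(first$nodes)
  nodes <- array(NA_real_, c(n_nodes, 3, n_t))
  nodes[, , 1] <- first$nodes
  for (it in seq(2, length.out = n_t - 1)) {
    mi <- triangulate_wing(reconstruct_outline(arr[, , it]), target_elements,
                           side = wing, layout = lay)
    if (nrow(mi$nodes) != n_nodes)
      stop("reconstruct_wing_series: connectivity mismatch between frames", call. = FALSE)
    nodes[, , it] <- mi$nodes
  }
  wing_mesh(nodes, first$triangles, times = set$times, side = wing)
}

#' Temporal refinement of mesh node trajectories
#'
#' Interpolates every node coordinate with a periodic cubic spline over each
#' wingbeat cycle and resamples `refinement_factor` times more densely.
#' Node velocities are the analytic spline derivatives.  Positions at the
#' original sample times are unchanged.
#'
#' @param mesh a time-resolved [wing_mesh()] whose frames sample
#'   `n_frames_per_cycle * n_cycles` instants at uniform spacing.
#' @param n_frames_per_cycle frames per cycle in the input.
#' @param refinement_factor integer >= 1; 1 returns the input (with
#'   velocities attached).
#' @return A time-resolved [wing_mesh()] with `node_velocities`.
#' @export
refine_in_time <- function(mesh, n_frames_per_cycle, refinement_factor = 10L) {
  stopifnot(inherits(mesh, "wing_mesh"), length(dim(mesh$nodes)) == 3)
  if (n_frames_per_cycle < 10)
    stop("refine_in_time: need at least 10 frames per cycle", call. = FALSE)
  n_t <- dim(mesh$nodes)[3]
  if (n_t %% n_frames_per_cycle != 0L)
    stop("refine_in_time: frame count is not a whole number of cycles", call. = FALSE)
  n_cycles <- n_t %/% n_frames_per_cycle
  dt_in <- mesh$times[2] - mesh$times[1]
  refinement_factor <- as.integer(refinement_factor)
  n_out <- n_t * refinement_factor
  t_out <- mesh$times[1] + (seq_len(n_out) - 1) * dt_in / refinement_factor
  n_nodes <- dim(mesh$nodes)[1]
  nodes <- array(NA_real_, c(n_nodes, 3, n_out))
  vels <- array(NA_real_, c(n_nodes, 3, n_out))
  t_knot <- c(0, seq_len(n_frames_per_cycle)) * dt_in
  for (cyc in seq_len(n_cycles)) {
    idx_in <- (cyc - 1) * n_frames_per_cycle + seq_len(n_frames_per_cycle)
    idx_out <- (cyc - 1) * n_frames_per_cycle * refinement_factor +
      seq_len(n_frames_per_cycle * refinement_factor)
    t_loc <- (seq_along(idx_out) - 1) * dt_in / refinement_factor
    for (nn in seq_len(n_nodes)) {
      for (co in 1:3) {
        y <- mesh$nodes[nn, co, idx_in]
        f <- splinefun(t_knot, c(y, y[1]), method = "periodic")
        nodes[nn, co, idx_out] <- f(t_loc)
        vels[nn, co, idx_out] <- f(t_loc, deriv = 1L)
      }
    }
  }
  wing_mesh(nodes, mesh$triangles, times = t_out, node_velocities = vels,
            side = mesh$side)
}

#' Continuous-time evaluator for mesh node trajectories
#'
#' Periodic cubic splines per node coordinate over each cycle; `position(t)`
#' and `velocity(t)` evaluate at arbitrary instants (times beyond the
#' sampled range wrap periodically into the last cycle).
#'
#' @param mesh time-resolved [wing_mesh()] with uniform frame spacing.
#' @param n_frames_per_cycle frames per cycle.
#' @return List with `position(t)`, `velocity(t)` (both return `n x 3`
#'   matrices) and `period`.
#' @export
mesh_motion <- function(mesh, n_frames_per_cycle) {
  stopifnot(length(dim(mesh$nodes)) == 3)
  n_t <- dim(mesh$nodes)[3]
  if (n_t %% n_frames_per_cycle != 0L)
    stop("mesh_motion: frame count is not a whole number of cycles", call. = FALSE)
  n_cycles <- n_t %/% n_frames_per_cycle
  dt_in <- mesh$times[2] - mesh$times[1]
  period <- n_frames_per_cycle * dt_in
  t0 <- mesh$times[1]
  n_nodes <- dim(mesh$nodes)[1]

  # per-cycle periodic splines: list[[cycle]][[coord]] of splinefuns over
  # local time in [0, period]
  spl <- vector("list", n_cycles)
  for (cyc in seq_len(n_cycles)) {
    idx <- (cyc - 1) * n_frames_per_cycle + seq_len(n_frames_per_cycle)
    tt <- c(0, seq_len(n_frames_per_cycle)) * dt_in
    spl[[cyc]] <- lapply(1:3, function(co) {
      lapply(seq_len(n_nodes), function(nn) {
        y <- mesh$nodes[nn, co, idx]
        splinefun(tt, c(y, y[1]), method = "periodic")
      })
    })
  }
  eval_at <- function(t, deriv) {
    tl <- t - t0
    cyc <- min(n_cycles, max(1L, 1L + as.integer(floor(tl / period + 1e-9))))
    tloc <- (tl - (cyc - 1) * period) %% period
    out <- matrix(0, n_nodes, 3)
    for (co in 1:3)
      out[, co] <- vapply(spl[[cyc]][[co]], function(f) f(tloc, deriv = deriv), 0)
    out
  }
  list(position = function(t) eval_at(t, 0L),
       velocity = function(t) eval_at(t, 1L),
       period = period)
}

#' Phase average a periodic series
#'
#' Bins samples by wingbeat-cycle phase and averages within bins; requires
#' at least two complete cycles so the average is meaningful.
#'
#' @param values numeric vector or matrix (rows = samples).
#' @param times sample instants, s.
#' @param f_beat wingbeat frequency, Hz.
#' @param n_bins number of phase bins.
#' @param t0 time of phase zero (start of downstroke); default `times[1]`.
#' @return List with `phase` (bin centres in \[0,1)) and `mean` (vector or
#'   matrix of per-bin means).
#' @export
phase_average <- function(values, times, f_beat, n_bins = 50L, t0 = times[1]) {
  # coverage counts the sample spacing past the last sample
  span <- max(times) - min(times) + stats::median(diff(sort(unique(times))))
  if (span * f_beat < 2 - 1e-9)
    stop("phase_average: series must cover at least 2 complete cycles", call. = FALSE)
  vals <- as.matrix(values)
  phase <- ((times - t0) * f_beat) %% 1
  # nudge guards samples that land exactly on bin boundaries against
  # floating-point jitter
  bin <- pmin(n_bins, 1L + as.integer(floor(phase * n_bins + 1e-9)))
  mu <- matrix(NA_real_, n_bins, ncol(vals))
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    if (any(sel)) mu[b, ] <- colMeans(vals[sel, , drop = FALSE])
  }
  out_mean <- if (ncol(vals) == 1L) drop(mu) else mu
  list(phase = (seq_len(n_bins) - 0.5) / n_bins, mean = out_mean)
}

#' Build a synthetic hummingbird body surface
#'
#' Closed fusiform surface of revolution (tapered ellipsoid-like radius
#' profile) of hummingbird scale, ~8 cm long, pitched nose-up at the body
#' angle `chi_b` and centred just below the shoulder origin.  The surface is
#' watertight with outward normals; it is static in the bird-fixed frame.
#'
#' @param config a [flight_config()].
#' @param n_axial,n_circ grid resolution (defaults reproduce ~3520 elements
#'   and ~1762 nodes, the scale used for the production body mesh).
#' @param length_m body length, m.
#' @param max_radius_m maximum body radius, m.
#' @return A single-frame [wing_mesh()] with `side = "body"`.
#' @export
build_body <- function(config, n_axial = 42L, n_circ = 44L,
                       length_m = 0.08, max_radius_m = 0.011) {
  stopifnot(inherits(config, "flight_config"))
  chi <- deg2rad(config$chi_b)
  # axis from tail to head; the bird faces upstream (-X), nose pitched up
  axis_dir <- c(-cos(chi), 0, sin(chi))
  e1 <- c(0, 1, 0)
  e2 <- c(sin(chi), 0, cos(chi))     # completes right-handed frame with axis
  centre <- c(0, 0, -0.012)

  xi <- seq(0, 1, length.out = n_axial)
  radius <- max_radius_m * sin(pi * xi)^0.8
  th <- 2 * pi * (seq_len(n_circ) - 1) / n_circ

  n_ring <- n_axial - 2L
  nodes <- matrix(0, n_ring * n_circ + 2L, 3)
  nodes[1, ] <- centre + (xi[1] - 0.5) * length_m * axis_dir          # tail pole
  nodes[n_ring * n_circ + 2L, ] <- centre + (xi[n_axial] - 0.5) * length_m * axis_dir
  k <- 1L
  for (i in seq(2, n_axial - 1)) {
    base <- centre + (xi[i] - 0.5) * length_m * axis_dir
    for (j in seq_len(n_circ)) {
      k <- k + 1L
      nodes[k, ] <- base + radius[i] * (cos(th[j]) * e1 + sin(th[j]) * e2)
    }
  }
  ring <- function(i) 1L + (i - 1L) * n_circ + seq_len(n_circ)  # i in 1..n_ring
  tris <- list()
  # tail cap: pole node 1 to first ring; winding chosen for outward normals
  r1 <- ring(1L)
  for (j in seq_len(n_circ))
    tris[[length(tris) + 1L]] <- c(1L, r1[j %% n_circ + 1L], r1[j])
  for (i in seq_len(n_ring - 1L)) {
    ra <- ring(i); rb <- ring(i + 1L)
    for (j in seq_len(n_circ)) {
      jn <- j %% n_circ + 1L
      tris[[length(tris) + 1L]] <- rbind(c(ra[j], rb[j], rb[jn]),
                                         c(ra[j], rb[jn], ra[jn]))
    }
  }
  head_pole <- n_ring * n_circ + 2L
  rl <- ring(n_ring)
  for (j in seq_len(n_circ))
    tris[[length(tris) + 1L]] <- c(head_pole, rl[j], rl[j %% n_circ + 1L])
  mesh <- wing_mesh(nodes, do.call(rbind, tris), side = "body")
  if (mesh_volume(mesh) < 0)   # flip winding if normals came out inward
    mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  mesh
}
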