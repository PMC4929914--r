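#' Chord section of a wing at a spanwise station
#'
#' A chord section holds the leading- and trailing-edge points where the
#' wing boundary crosses the plane of constant spanwise coordinate
#' `r_hat * R` (measured along the instantaneous shoulder-to-tip axis),
#' plus the translational velocity of the leading-edge point in the
#' bird-fixed frame.
#'
#' @param r_hat dimensionless spanwise station r/R in \[0,1\].
#' @param le_point,te_point 3D coordinates, m.
#' @param le_velocity 3D leading-edge velocity (bird-fixed frame), m/s.
#' @return Object of class `chord_section`.
#' @export
chord_section <- function(r_hat, le_point, te_point, le_velocity = c(0, 0, 0)) {
  if (r_hat < 0 || r_hat > 1)
    stop("chord_section: r_hat must lie in [0, 1]", call. = FALSE)
  if (sqrt(sum((te_point - le_point)^2)) <= 0)
    stop("chord_section: zero-length chord", call. = FALSE)
  structure(list(r_hat = r_hat, le_point = as.numeric(le_point),
                 te_point = as.numeric(te_point),
                 le_velocity = as.numeric(le_velocity)),
            class = "chord_section")
}

#' Extract a chord section from a wing mesh
#'
#' Slices the ordered boundary loop of the wing membrane with the
#' parasagittal plane passing through the point at spanwise station
#' `r_hat * R` on the instantaneous shoulder-to-tip axis.  Chord sections
#' in this analysis are parasagittal throughout (the chord angle itself is
#' defined in the parasagittal projection): a plane perpendicular to the
#' shoulder-to-tip axis would connect slightly different anatomical
#' stations on the two edges whenever the chord is not perpendicular to
#' the axis, and tilt the measured chord.  The leading edge is the
#' upstream (smaller X) crossing.  Velocities are interpolated along the
#' crossed boundary edges when the mesh carries `node_velocities`.
#'
#' @param mesh a [wing_mesh()] (single- or multi-frame).
#' @param r_hat spanwise station in \[0,1\].
#' @param it frame index.
#' @param shoulder shoulder coordinate; defaults to the package's left/right
#'   shoulder positions `(0, +-0.006, 0)` m based on `mesh$side`.
#' @return A [chord_section()].
#' @export
extract_chord <- function(mesh, r_hat, it = 1L, shoulder = NULL) {
  if (r_hat < 0 || r_hat > 1)
    stop("extract_chord: station r_hat = ", r_hat, " lies outside the wing", call. = FALSE)
  if (is.null(shoulder))
    shoulder <- c(0, if (identical(mesh$side, "right")) -0.006 else 0.006, 0)
  nd <- mesh_frame_nodes(mesh, it)
  vel <- if (!is.null(mesh$node_velocities)) {
    if (length(dim(mesh$node_velocities)) == 3) mesh$node_velocities[, , it]
    else mesh$node_velocities
  } else matrix(0, nrow(nd), 3)

  loops <- boundary_loops(mesh)
  if (length(loops) == 0L)
    stop("extract_chord: mesh has no boundary (closed surface?)", call. = FALSE)
  loop <- loops[[which.max(lengths(loops))]]

  d <- sweep(nd, 2, shoulder)
  tip_id <- which.max(rowSums(d^2))

  # parasagittal station coordinate: lateral (y) offset from the shoulder,
  # signed towards the wingtip
  side_sign <- if (d[tip_id, 2] < 0) -1 else 1
  s <- side_sign * d[, 2]
  s_target <- r_hat * s[tip_id]

  ids <- c(loop, loop[1])
  crossings <- list()
  for (k in seq_len(length(ids) - 1L)) {
    a <- ids[k]; b <- ids[k + 1L]
    sa <- s[a] - s_target; sb <- s[b] - s_target
    if ((sa <= 0 && sb > 0) || (sa > 0 && sb <= 0)) {
      w <- sa / (sa - sb)
      crossings[[length(crossings) + 1L]] <- list(
        point = (1 - w) * nd[a, ] + w * nd[b, ],
        vel = (1 - w) * vel[a, ] + w * vel[b, ])
    }
  }
  if (length(crossings) < 2L)
    stop("extract_chord: station r_hat = ", r_hat,
         " does not cross the wing boundary twice", call. = FALSE)
  xs <- vapply(crossings, function(cr) cr$point[1], 0)
  le <- crossings[[which.min(xs)]]
  te <- crossings[[which.max(xs)]]
  chord_section(r_hat, le$point, te$point, le$vel)
}

#' Chord angle
#'
#' Instantaneous signed angle between the LE-to-TE chord vector, projected
#' to the parasagittal (X-Z) plane, and the flight direction.  Positive when
#' the leading edge is pitched up relative to the trailing edge, so a
#' leading edge tilting downward gives a negative chord angle.
#'
#' @param section a [chord_section()].
#' @param config a [flight_config()] (fixes the flight direction, +X).
#' @return Angle in degrees in (-180, 180\].
#' @export
chord_angle <- function(section, config) {
  ch <- section$te_point - section$le_point
  if (sqrt(ch[1]^2 + ch[3]^2) < 1e-12)
    stop("chord_angle: chord has zero length in the X-Z projection", call. = FALSE)
  rad2deg(atan2(-ch[3], ch[1]))
}

#' Effective angle of attack
#'
#' Angle between the chord and the relative flow direction combining the
#' freestream with the translational velocity of the chord at the leading
#' edge: the relative flow is `U e_x - v_LE`, and alpha is the signed angle
#' from the relative-flow direction to the chord direction (X-Z projection),
#' positive when the flow impinges on the ventral surface.  With a
#' motionless wing, alpha equals the chord angle psi.
#'
#' @inheritParams chord_angle
#' @return Angle in degrees in (-180, 180\].
#' @export
effective_aoa <- function(section, config) {
  v_rel <- c(config$U, 0, 0) - section$le_velocity
  if (sqrt(v_rel[1]^2 + v_rel[3]^2) < 1e-9 * config$U)
    stop("effective_aoa: relative flow speed vanishes; angle of attack undefined",
         call. = FALSE)
  psi <- chord_angle(section, config)
  flow_ang <- rad2deg(atan2(-v_rel[3], v_rel[1]))
  wrap_angle(psi - flow_ang)
}

# wrap degrees into (-180, 180]
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

# unwrap a degree series to be continuous (no 360-degree jumps)
unwrap_angle <- function(a) {
  d <- diff(a)
  jump <- cumsum(c(0, round(d / 360))) * 360
  a - jump
}

#' Kinematic descriptor series for a wing
#'
#' Computes, per time sample of a (temporally refined) wing mesh: chord
#' angles `psi_p`, `psi_d` and effective angles of attack `alpha_p`,
#' `alpha_d` at the proximal (r/R = 0.15) and distal (r/R = 0.9) stations,
#' the spanwise twist `psi_d - psi_p`, the wingtip speed in the bird-fixed
#' frame, the instantaneous mesh area, and the wingtip elevation angle in
#' the stroke plane (used to segment down- and upstroke).
#'
#' @param mesh a time-resolved [wing_mesh()] with `node_velocities`.
#' @param config a [flight_config()].
#' @param r_p,r_d proximal and distal stations.
#' @return A data frame of class `kinematics_series` with one row per time
#'   sample.
#' @export
kinematics_series <- function(mesh, config, r_p = 0.15, r_d = 0.9) {
  stopifnot(inherits(mesh, "wing_mesh"), length(dim(mesh$nodes)) == 3,
            !is.null(mesh$node_velocities))
  n_t <- dim(mesh$nodes)[3]
  shoulder <- c(0, if (identical(mesh$side, "right")) -0.006 else 0.006, 0)
  basis <- stroke_plane_basis(config$beta)
  e_y <- c(0, if (identical(mesh$side, "right")) -1 else 1, 0)

  psi_p <- psi_d <- alpha_p <- alpha_d <- tip_speed <- area <- tip_elev <-
    numeric(n_t)
  for (it in seq_len(n_t)) {
    sp <- extract_chord(mesh, r_p, it, shoulder)
    sd_ <- extract_chord(mesh, r_d, it, shoulder)
    psi_p[it] <- chord_angle(sp, config)
    psi_d[it] <- chord_angle(sd_, config)
    alpha_p[it] <- effective_aoa(sp, config)
    alpha_d[it] <- effective_aoa(sd_, config)
    nd <- mesh$nodes[, , it]
    d <- sweep(nd, 2, shoulder)
    tip_id <- which.max(rowSums(d^2))
    tip_speed[it] <- sqrt(sum(mesh$node_velocities[tip_id, , it]^2))
    area[it] <- mesh_area(mesh, it)
    tip_elev[it] <- rad2deg(atan2(sum(d[tip_id, ] * basis$e_d), sum(d[tip_id, ] * e_y)))
  }
  psi_p <- wrap_angle(unwrap_angle(psi_p)); psi_d <- wrap_angle(unwrap_angle(psi_d))
  alpha_p <- wrap_angle(unwrap_angle(alpha_p)); alpha_d <- wrap_angle(unwrap_angle(alpha_d))
  out <- data.frame(time_s = mesh$times, psi_p = psi_p, psi_d = psi_d,
                    alpha_p = alpha_p, alpha_d = alpha_d,
                    twist = psi_d - psi_p, tip_speed = tip_speed,
                    area = area, tip_elev = tip_elev)
  class(out) <- c("kinematics_series", "data.frame")
  out
}

#' Segment a series into down- and upstroke by tip elevation
#'
#' Cycle boundaries are placed at the maxima of the phase-averaged wingtip
#' elevation in the stroke plane (start of downstroke); the downstroke runs
#' from that maximum to the elevation minimum, the upstroke is the rest.
#'
#' @param series a [kinematics_series()].
#' @param config a [flight_config()].
#' @param n_bins phase bins used to locate the extrema.
#' @return Factor with levels `down`, `up`, one per row of `series`.
#' @export
stroke_segmentation <- function(series, config, n_bins = 50L) {
  t <- series$time_s
  n_cyc <- (max(t) - min(t)) * config$f_beat
  phase <- ((t - t[1]) * config$f_beat) %% 1
  if (n_cyc >= 2 - 1e-9) {
    pa <- phase_average(series$tip_elev, t, config$f_beat, n_bins = n_bins)
    ph_max <- pa$phase[which.max(pa$mean)]
    ph_min <- pa$phase[which.min(pa$mean)]
  } else {
    ph_max <- phase[which.max(series$tip_elev)]
    ph_min <- phase[which.min(series$tip_elev)]
  }
  rel <- (phase - ph_max) %% 1
  rel_min <- (ph_min - ph_max) %% 1
  factor(ifelse(rel < rel_min, "down", "up"), levels = c("down", "up"))
}

#' Cycle summaries of the kinematics
#'
#' Mean wingtip speed `U_tip` (bird-fixed frame), advance ratio
#' `J = U / U_tip`, stroke-conditional mean areas `S_down` / `S_up` and
#' cycle-mean area `S_mean`.
#'
#' @param series a [kinematics_series()] covering >= 1 full cycle.
#' @param config a [flight_config()].
#' @return Named list `U_tip`, `J`, `S_down`, `S_up`, `S_mean`.
#' @export
cycle_summaries <- function(series, config) {
  if (nrow(series) == 0L) stop("cycle_summaries: empty series", call. = FALSE)
  U_tip <- mean(series$tip_speed)
  stroke <- stroke_segmentation(series, config)
  list(U_tip = U_tip,
       J = config$U / U_tip,
       S_down = mean(series$area[stroke == "down"]),
       S_up = mean(series$area[stroke == "up"]),
       S_mean = mean(series$area))
}
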