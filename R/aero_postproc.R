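#' Integrate surface tractions into forces
#'
#' Net force on a surface is the area-weighted sum of per-triangle
#' tractions; thrust is the upstream force `F_T = -F_X`.
#'
#' @param traction `m x 3` matrix of tractions, Pa.
#' @param areas per-triangle areas, m^2 (same length `m`).
#' @return Named vector `F_X, F_Y, F_Z, F_T` (N).
#' @export
integrate_forces <- function(traction, areas) {
  traction <- as.matrix(traction)
  if (nrow(traction) != length(areas))
    stop("integrate_forces: traction rows and triangle areas differ in length",
         call. = FALSE)
  f <- colSums(traction * areas)
  c(F_X = f[1], F_Y = f[2], F_Z = f[3], F_T = -f[1])
}

#' Normalise forces into lift/thrust coefficients
#'
#' `C_Z = F_Z / (0.5 rho U^2 S)` and `C_T = F_T / (0.5 rho U^2 S)`, with
#' `S` the fixed reference single-wing area.  Body lift and drag are
#' normalised in the same manner.
#'
#' @param F force, N (vectorised).
#' @param config a [flight_config()].
#' @return Dimensionless coefficient(s).
#' @export
force_coefficient <- function(F, config) {
  F / (0.5 * config$rho * config$U^2 * config$S_ref)
}

#' Aerodynamic power coefficient of a wing
#'
#' `C_P = (sum over the surface of f . u dA) / (0.5 rho U^3 S)`, where `f`
#' is the fluid traction on the wing and `u` the velocity of the surface
#' point in the body-fixed frame (freestream excluded).
#'
#' @param stress `m x 3` per-triangle stress exerted by the wing on the
#'   fluid, Pa (minus the fluid traction on the wing), so `C_P` is positive
#'   when the wing drives the flow.
#' @param velocities `m x 3` per-triangle surface velocities in the
#'   bird-fixed frame, m/s.
#' @param areas per-triangle areas, m^2.
#' @param config a [flight_config()].
#' @return Scalar power coefficient.
#' @export
power_coefficient <- function(stress, velocities, areas, config) {
  stress <- as.matrix(stress); velocities <- as.matrix(velocities)
  if (nrow(stress) != nrow(velocities) || nrow(stress) != length(areas))
    stop("power_coefficient: stress, velocity and area lengths differ",
         call. = FALSE)
  num <- sum(rowSums(stress * velocities) * areas)
  num / (0.5 * config$rho * config$U^3 * config$S_ref)
}

#' Force/power coefficient series container
#'
#' Tidy per-time-sample table of coefficients per surface with phase and
#' stroke labels, as produced by the flow pipeline.
#'
#' @param df data frame with columns `time_s`, `phase`, `stroke` and
#'   coefficient columns (`C_Z`, `C_T`, `C_P`, `C_Z_b`, `C_D_b`, ...).
#' @return The data frame with class `force_series`.
#' @export
force_series <- function(df) {
  stopifnot(all(c("time_s", "phase", "stroke") %in% names(df)))
  class(df) <- c("force_series", "data.frame")
  df
}

#' Stroke-resolved averages of a coefficient series
#'
#' Computes downstroke, upstroke and whole-cycle time-weighted means of
#' every coefficient column, plus down-/upstroke ratios.
#'
#' @param series a [force_series()] (or data frame with `stroke` labels).
#' @param cols coefficient columns to average; default all numeric columns
#'   except time/phase.
#' @return Data frame with rows `whole_cycle`, `downstroke`, `upstroke`,
#'   `down_up_ratio` and one column per coefficient.
#' @export
stroke_averages <- function(series, cols = NULL) {
  if (is.null(series$stroke)) stop("stroke_averages: missing stroke labels", call. = FALSE)
  if (is.null(cols))
    cols <- setdiff(names(series)[vapply(series, is.numeric, TRUE)],
                    c("time_s", "phase"))
  down <- series$stroke == "down"
  out <- rbind(
    whole_cycle = colMeans(series[, cols, drop = FALSE]),
    downstroke = colMeans(series[down, cols, drop = FALSE]),
    upstroke = colMeans(series[!down, cols, drop = FALSE]))
  out <- as.data.frame(rbind(out, down_up_ratio = out["downstroke", ] / out["upstroke", ]))
  out
}

#' Derived flight-performance summary
#'
#' Turns whole-cycle force and power coefficients into the derived
#' performance quantities:
#' \itemize{
#'   \item aerodynamic power `P = 0.5 C_P rho U^3 (2S)` (both wings), W;
#'   \item body-mass-specific power `P / M`, W/kg;
#'   \item weight support `0.5 (2 C_Z + C_Z_b) rho U^2 S / (M g)`;
#'   \item thrust-to-body-drag ratio `2 C_T / C_D_b`;
#'   \item `body_share`: the body's fraction of total vertical force,
#'     `C_Z_b / (2 C_Z + C_Z_b)`;
#'   \item `body_weight_frac`: body lift as a fraction of body weight,
#'     `0.5 C_Z_b rho U^2 S / (M g)`.
#' }
#' `body_share` and `body_weight_frac` are deliberately both reported: the
#' former expresses the body contribution relative to the total vertical
#' aerodynamic force, the latter relative to the actual weight.
#'
#' @param C_Z,C_T,C_P,C_Z_b,C_D_b whole-cycle mean coefficients (per wing
#'   for `C_Z`, `C_T`, `C_P`; body for the `_b` pair).
#' @param config a [flight_config()].
#' @return Named list of class `derived_performance`.
#' @export
performance_summary <- function(C_Z, C_T, C_P, C_Z_b, C_D_b, config) {
  if (config$M <= 0 || config$U <= 0)
    stop("performance_summary: mass and speed must be positive", call. = FALSE)
  q <- 0.5 * config$rho * config$U^2 * config$S_ref
  P <- 0.5 * C_P * config$rho * config$U^3 * (2 * config$S_ref)
  F_total <- q * (2 * C_Z + C_Z_b)
  structure(list(
    P = P,
    P_massspec = P / config$M,
    F_total = F_total,
    weight_support_frac = F_total / (config$M * config$g),
    thrust_to_body_drag = if (C_D_b != 0) 2 * C_T / C_D_b else 0,
    body_share = if ((2 * C_Z + C_Z_b) != 0) C_Z_b / (2 * C_Z + C_Z_b) else 0,
    body_weight_frac = q * C_Z_b / (config$M * config$g)),
    class = "derived_performance")
}

#' @export
print.derived_performance <- function(x, ...) {
  cat("<derived_performance>\n")
  cat(sprintf("  aerodynamic power        P = %.4g mW (%.3g W/kg body mass)\n",
              x$P * 1e3, x$P_massspec))
  cat(sprintf("  weight support           %.1f%% of body weight\n",
              100 * x$weight_support_frac))
  cat(sprintf("  thrust / body drag       %.1f%%\n", 100 * x$thrust_to_body_drag))
  cat(sprintf("  body share of lift       %.1f%% (%.1f%% of weight)\n",
              100 * x$body_share, 100 * x$body_weight_frac))
  invisible(x)
}

#' Reference force coefficients for the calliope hummingbird at 8.3 m/s
#'
#' Stroke-resolved force and power coefficients of the production-scale
#' simulation of calliope-hummingbird fast forward flight (chord Reynolds
#' number 3000): per-wing vertical-force, thrust and power coefficients and
#' body lift/drag coefficients, for the whole cycle and each half-stroke.
#' These serve as printed reference inputs for the worked-example
#' post-processing (the desk-scale solver in this package runs the same
#' physics at reduced resolution and Reynolds number and is not expected to
#' reproduce them).
#'
#' @return Data frame with rows `whole_cycle`, `downstroke`, `upstroke` and
#'   columns `C_Z`, `C_T`, `C_P`, `C_Z_b`, `C_D_b`.
#' @export
calliope_reference_coefficients <- function() {
  data.frame(
    C_Z = c(0.466, 1.006, -0.074),
    C_T = c(0.115, 0.157, 0.073),
    C_P = c(0.266, 0.394, 0.137),
    C_Z_b = c(0.266, 0.342, 0.189),
    C_D_b = c(0.151, 0.157, 0.146),
    row.names = c("whole_cycle", "downstroke", "upstroke"))
}

#' Reference grid-convergence force coefficients
#'
#' Cycle-averaged coefficients of the production baseline grid and the
#' refined verification grid, with the per-column percent difference
#' relative to the refined grid.  The maximum difference across all forces
#' is below 5%, the criterion under which the baseline resolution was
#' deemed converged.
#'
#' @return List: `table` (rows `baseline`, `fine_mesh`), `percent_diff`
#'   (named vector), `max_percent_diff`.
#' @export
grid_convergence_reference <- function() {
  tab <- data.frame(
    C_Z = c(0.374, 0.381), C_T = c(0.112, 0.117),
    C_Z_b = c(0.239, 0.238), C_D_b = c(0.151, 0.150),
    row.names = c("baseline", "fine_mesh"))
  pd <- 100 * abs(tab["fine_mesh", ] - tab["baseline", ]) / abs(tab["fine_mesh", ])
  pd <- unlist(pd)
  list(table = tab, percent_diff = pd, max_percent_diff = max(pd))
}
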