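#' Generate synthetic wing-marker trajectories
#'
#' Emulates the output of high-speed-video marker tracking: nine markers per
#' wing (five on the leading edge, one at the wingtip, three on the trailing
#' edge) swept through the stroke-plane program, pitched by the twist
#' profile, with stroke-plane deviation and area modulation applied.  Left
#' and right wings are mirror images through the sagittal (X-Z) plane.
#' Optional isotropic Gaussian noise models tracking error; with
#' `noise_sd = 0` the generator is fully deterministic and the seed is
#' ignored.
#'
#' @param config a [flight_config()].
#' @param program a [kinematic_program()].
#' @param seed integer seed fixing the noise stream.
#' @return A `marker_set`: list with `times` (s), `markers` (named list
#'   `left`/`right` of arrays `9 x 3 x n_t`, marker ids as rownames),
#'   `config` and `program`.
#' @examples
#' cfg <- default_calliope_config()
#' prog <- default_kinematic_program(cfg, noise_sd = 0)
#' ms <- generate_markers(cfg, prog, seed = 1)
#' dim(ms$markers$left)
#' @export
generate_markers <- function(config, program, seed = 1L) {
  stopifnot(inherits(config, "flight_config"), inherits(program, "kinematic_program"))
  n_t <- program$n_frames_per_cycle * program$n_cycles
  times <- (seq_len(n_t) - 1) / (program$n_frames_per_cycle * config$f_beat)
  phases <- (seq_len(n_t) - 1) / program$n_frames_per_cycle
  st <- marker_stations()

  mk <- function(side) {
    arr <- array(NA_real_, c(9, 3, n_t),
                 dimnames = list(st$marker_id, c("x", "y", "z"), NULL))
    for (it in seq_len(n_t))
      arr[, , it] <- wing_boundary_points(st$t_deg, phases[it],
                                          config, program, side = side)
    arr
  }
  left <- mk(1); right <- mk(-1)

  if (program$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    left <- left + array(rnorm(length(left), 0, program$noise_sd), dim(left))
    right <- right + array(rnorm(length(right), 0, program$noise_sd), dim(right))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  structure(list(times = times, markers = list(left = left, right = right),
                 config = config, program = program),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d frames (%.4g s), 9 markers x 2 wings\n",
              length(x$times), max(x$times) - min(x$times)))
  invisible(x)
}

#' Convert a marker set to a tidy data frame
#'
#' One row per (time, wing, marker): columns `time_s`, `wing`, `marker_id`,
#' `x_m`, `y_m`, `z_m`.
#'
#' @param x a `marker_set`.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.marker_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- list()
  for (w in c("left", "right")) {
    arr <- x$markers[[w]]
    for (it in seq_along(x$times)) {
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = x$times[it], wing = w, marker_id = rownames(arr),
        x_m = arr[, 1, it], y_m = arr[, 2, it], z_m = arr[, 3, it],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$time_s, out$wing, match(out$marker_id, marker_stations()$marker_id)), ,
      drop = FALSE]
}

#' Write / read marker trajectories as delimited text
#'
#' The on-disk layout is a CSV with columns `time_s`, `wing`, `marker_id`
#' (`LE1`..`LE5`, `TIP`, `TE1`..`TE3`), `x_m`, `y_m`, `z_m`, written at full
#' double precision so a round trip is lossless to well below 1e-12 m.
#'
#' @param set a `marker_set`.
#' @param path file path.
#' @return `read_markers` returns a `marker_set` (without config/program
#'   metadata); `write_markers` returns `path` invisibly.
#' @export
write_markers <- function(set, path) {
  stopifnot(inherits(set, "marker_set"))
  df <- as.data.frame(set)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,wing,marker_id,x_m,y_m,z_m", con)
  writeLines(sprintf("%.17g,%s,%s,%.17g,%.17g,%.17g",
                     df$time_s, df$wing, df$marker_id, df$x_m, df$y_m, df$z_m), con)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  lines <- readLines(path)
  if (length(lines) <= 1L)
    stop("read_markers: `", path, "` contains no marker rows (empty set)", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  want <- c("time_s", "wing", "marker_id", "x_m", "y_m", "z_m")
  if (!identical(header, want))
    stop("read_markers: unexpected header on line 1; expected ",
         paste(want, collapse = ","), call. = FALSE)
  ids <- marker_stations()$marker_id
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    stop("read_markers: malformed row on line ", which(nf != 6L)[1] + 1L,
         " (expected 6 comma-separated fields)", call. = FALSE)
  m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
  time_s <- as.numeric(m[, 1]); xyz <- matrix(as.numeric(m[, 4:6]), ncol = 3)
  if (anyNA(time_s) || anyNA(xyz))
    stop("read_markers: non-numeric coordinate on line ",
         which(is.na(time_s) | rowSums(is.na(xyz)) > 0)[1] + 1L, call. = FALSE)
  wing <- m[, 2]; marker_id <- m[, 3]
  if (!all(marker_id %in% ids))
    stop("read_markers: unknown marker id on line ",
         which(!marker_id %in% ids)[1] + 1L, call. = FALSE)

  times <- sort(unique(time_s))
  arrs <- list()
  for (w in c("left", "right")) {
    sel <- wing == w
    if (!any(sel)) next
    arr <- array(NA_real_, c(9, 3, length(times)), dimnames = list(ids, c("x", "y", "z"), NULL))
    it_of <- match(time_s[sel], times)
    id_of <- match(marker_id[sel], ids)
    arr[cbind(rep(id_of, 3), rep(1:3, each = sum(sel)), rep(it_of, 3))] <- xyz[sel, ]
    if (anyNA(arr)) {
      bad_t <- which(apply(arr, 3, anyNA))[1]
      n_seen <- sum(!is.na(arr[, 1, bad_t]))
      stop("read_markers: frame at t = ", signif(times[bad_t], 8), " s has ",
           n_seen, " markers for wing `", w, "` (expected 9)", call. = FALSE)
    }
    arrs[[w]] <- arr
  }
  if (length(arrs) == 0L) stop("read_markers: no wing data found", call. = FALSE)
  structure(list(times = times, markers = arrs, config = NULL, program = NULL),
            class = "marker_set")
}
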