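#' Swirling strength of velocity-gradient tensors
#'
#' The swirling strength lambda_ci is the maximum imaginary part of the
#' eigenvalues of the local velocity-gradient tensor: zero wherever the
#' spectrum is real (pure strain), positive in locally rotating flow.  The
#' eigenvalues come from the closed-form solution of the characteristic
#' cubic (deterministic and fast over millions of cells); tensors with a
#' real spectrum return exactly 0.
#'
#' @param tensors a single 3x3 matrix, or an `n x 9` matrix of tensor
#'   components in column-major order (a11, a21, a31, a12, ...), s^-1.
#' @return Numeric vector of lambda_ci values (s^-1), one per tensor.
#' @examples
#' swirling_strength(matrix(c(0, 2, 0, -2, 0, 0, 0, 0, 0), 3, 3))  # 2
#' swirling_strength(diag(c(1, -1, 0)))                            # 0
#' @export
swirling_strength <- function(tensors) {
  if (is.matrix(tensors) && nrow(tensors) == 3 && ncol(tensors) == 3)
    tensors <- matrix(as.vector(tensors), 1, 9)
  tensors <- as.matrix(tensors)
  if (ncol(tensors) != 9)
    stop("swirling_strength: expected a 3x3 tensor or an n x 9 matrix", call. = FALSE)
  if (any(!is.finite(tensors)))
    stop("swirling_strength: non-finite tensor entries", call. = FALSE)
  a11 <- tensors[, 1]; a21 <- tensors[, 2]; a31 <- tensors[, 3]
  a12 <- tensors[, 4]; a22 <- tensors[, 5]; a32 <- tensors[, 6]
  a13 <- tensors[, 7]; a23 <- tensors[, 8]; a33 <- tensors[, 9]

  i1 <- a11 + a22 + a33
  i2 <- a11 * a22 - a12 * a21 + a11 * a33 - a13 * a31 + a22 * a33 - a23 * a32
  i3 <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)

  # depressed cubic t^3 + p t + q, lambda = t + i1/3
  p <- i2 - i1^2 / 3
  q <- -2 * i1^3 / 27 + i1 * i2 / 3 - i3
  disc <- (q / 2)^2 + (p / 3)^3
  out <- numeric(length(p))
  pos <- disc > 0                      # one real root, one complex pair
  if (any(pos)) {
    sq <- sqrt(disc[pos])
    cbrt <- function(x) sign(x) * abs(x)^(1 / 3)
    A <- cbrt(-q[pos] / 2 + sq)
    B <- cbrt(-q[pos] / 2 - sq)
    out[pos] <- sqrt(3) / 2 * abs(A - B)
  }
  out
}

# nonuniform central first derivative of a 3D array along one axis
# (one-sided at non-periodic ends)
deriv_center <- function(arr, coords, axis, periodic = FALSE, period = NULL) {
  d <- dim(arr)
  n <- d[axis]
  idx <- function(i) {
    ii <- rep(list(quote(expr = )), 3)
    ii[[axis]] <- i
    do.call(`[`, c(list(arr), ii, list(drop = FALSE)))
  }
  sh <- function(off) {   # shifted array with clamped or wrapped ends
    i <- seq_len(n) + off
    if (periodic) i <- ((i - 1) %% n) + 1 else i <- pmin(pmax(i, 1L), n)
    idx(i)
  }
  x0 <- coords
  if (periodic) {
    if (is.null(period)) period <- (coords[n] - coords[1]) * n / (n - 1)
    xm <- c(coords[n] - period, coords[-n])
    xp <- c(coords[-1], coords[1] + period)
  } else {
    xm <- coords[pmax(seq_len(n) - 1L, 1L)]
    xp <- coords[pmin(seq_len(n) + 1L, n)]
  }
  hm <- x0 - xm; hp <- xp - x0
  # one-sided at the ends: fall back to simple difference
  hm[hm == 0] <- hp[hm == 0]
  hp[hp == 0] <- hm[hp == 0]
  wshape <- c(1, 1, 1); wshape[axis] <- n
  Hm <- array(rep(hm, each = prod(d[seq_len(axis - 1)])), d)
  Hp <- array(rep(hp, each = prod(d[seq_len(axis - 1)])), d)
  (Hm^2 * sh(1) - Hp^2 * sh(-1) + (Hp^2 - Hm^2) * arr) / (Hm * Hp * (Hm + Hp))
}

#' Velocity-gradient tensor field
#'
#' Cell-centred velocity gradients by second-order central differences on
#' the non-uniform grid (one-sided at boundaries).
#'
#' @param state a [flow_state()].
#' @param grid a [build_grid()].
#' @return List with `grad` (`n_cells x 9` matrix, column-major tensor
#'   components du_i/dx_j) and `dims`.
#' @export
velocity_gradient <- function(state, grid) {
  cv <- cpp_center_velocity(state$u, state$v, state$w, grid_cpp(grid))
  comps <- list(array(cv$u, grid$dims), array(cv$v, grid$dims),
                array(cv$w, grid$dims))
  coords <- list(grid$xc, grid$yc, grid$zc)
  faces <- list(grid$xf, grid$yf, grid$zf)
  per <- vapply(1:3, function(d) grid$bc_code[2 * d - 1] == 3L, TRUE)
  spans <- vapply(faces, function(f) f[length(f)] - f[1], 0)
  g <- matrix(0, prod(grid$dims), 9)
  for (i in 1:3)
    for (j in 1:3)
      g[, i + 3 * (j - 1)] <- as.vector(
        deriv_center(comps[[i]], coords[[j]], j, per[j], spans[j]))
  list(grad = g, dims = grid$dims)
}

#' Swirling-strength field
#'
#' Per-cell swirling strength of the velocity-gradient tensor; cells inside
#' solid bodies are masked to `NA`.
#'
#' @param state a [flow_state()].
#' @param grid a [build_grid()].
#' @param classification optional [classify_cells()] result for masking.
#' @return 3D array of lambda_ci (s^-1).
#' @export
swirl_field <- function(state, grid, classification = NULL) {
  vg <- velocity_gradient(state, grid)
  lam <- array(swirling_strength(vg$grad), grid$dims)
  if (!is.null(classification)) lam[classification$center == 1L] <- NA_real_
  lam
}

#' Extract a planar pressure slice
#'
#' Interpolates cell-centre pressure onto an axis-aligned plane (linear
#' interpolation between the two adjacent centre slabs, exact for linear
#' fields).  Solid cells are masked to `NA` when a classification is given.
#'
#' @param state a [flow_state()].
#' @param grid a [build_grid()].
#' @param axis `"x"`, `"y"` or `"z"` (plane normal).
#' @param value coordinate of the plane, m.
#' @param classification optional [classify_cells()] result.
#' @return List: `coord1`, `coord2` (in-plane centre coordinates) and `p`
#'   (matrix), plus the axis labels.
#' @export
pressure_slice <- function(state, grid, axis = "y", value = 0,
                           classification = NULL) {
  d <- match(axis, c("x", "y", "z"))
  if (is.na(d)) stop("pressure_slice: axis must be x, y or z", call. = FALSE)
  faces <- list(grid$xf, grid$yf, grid$zf)[[d]]
  if (value < faces[1] || value > faces[length(faces)])
    stop("pressure_slice: plane lies outside the domain", call. = FALSE)
  cc <- list(grid$xc, grid$yc, grid$zc)[[d]]
  n <- length(cc)
  i0 <- findInterval(value, cc)
  i0 <- min(max(i0, 1L), n - 1L)
  wt <- (value - cc[i0]) / (cc[i0 + 1] - cc[i0])
  wt <- min(max(wt, 0), 1)
  take <- function(arr, i) {
    ii <- rep(list(quote(expr = )), 3); ii[[d]] <- i
    do.call(`[`, c(list(arr), ii, list(drop = TRUE)))
  }
  p <- array(state$p, grid$dims)
  sl <- (1 - wt) * take(p, i0) + wt * take(p, i0 + 1L)
  if (!is.null(classification)) {
    solid <- (1 - wt) * take(classification$center == 1L, i0) +
      wt * take(classification$center == 1L, i0 + 1L)
    sl[solid > 0] <- NA_real_
  }
  oth <- setdiff(1:3, d)
  coords <- list(grid$xc, grid$yc, grid$zc)
  list(axis = axis, value = value,
       coord1 = coords[[oth[1]]], coord2 = coords[[oth[2]]],
       labels = c("x", "y", "z")[oth], p = sl)
}

#' Export fields on the structured grid as a legacy VTK file
#'
#' ASCII rectilinear-grid VTK with point data at the cell centres: any
#' number of scalar fields plus an optional velocity vector field.
#' Suitable for ParaView/VisIt iso-surface and slice rendering.
#'
#' @param path output file.
#' @param grid a [build_grid()].
#' @param scalars named list of 3D arrays (`grid$dims`).
#' @param velocity optional list with components `u`, `v`, `w` at centres
#'   (as from `cpp_center_velocity`) or NULL.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(path, grid, scalars = list(), velocity = NULL) {
  d <- grid$dims
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "flapwing flow field", "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("X_COORDINATES %d double", d[1]),
               paste(sprintf("%.9g", grid$xc), collapse = " "),
               sprintf("Y_COORDINATES %d double", d[2]),
               paste(sprintf("%.9g", grid$yc), collapse = " "),
               sprintf("Z_COORDINATES %d double", d[3]),
               paste(sprintf("%.9g", grid$zc), collapse = " "),
               sprintf("POINT_DATA %d", prod(d))), con)
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    vals <- as.vector(scalars[[nm]])
    vals[!is.finite(vals)] <- 0
    writeLines(paste(sprintf("%.7g", vals), collapse = " "), con)
  }
  if (!is.null(velocity)) {
    writeLines("VECTORS velocity double", con)
    m <- cbind(as.vector(velocity$u), as.vector(velocity$v), as.vector(velocity$w))
    writeLines(sprintf("%.7g %.7g %.7g", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
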