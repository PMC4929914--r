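#' Build a non-uniform structured Cartesian grid
#'
#' Single-block grid with a uniform fine region around the wings and
#' geometrically stretched outer regions, per axis.  The stretching ratio
#' between adjacent cells never exceeds `stretch` (capped at 1.1).
#'
#' @param domain 2-column matrix or list of per-axis `c(lo, hi)` extents, m.
#' @param fine_block per-axis `c(lo, hi)` bounds of the uniform region.
#' @param h_fine fine-region spacing, m (scalar or per-axis).
#' @param stretch maximum adjacent-cell expansion ratio (<= 1.1).
#' @param bc named character vector of boundary conditions for faces
#'   `xlo, xhi, ylo, yhi, zlo, zhi`; each of `"inflow"`, `"outflow"`,
#'   `"slip"`, `"periodic"` (periodic must pair up per axis).
#' @param Uin inflow speed, m/s.
#' @return Object of class `flow_grid` with face coordinates `xf, yf, zf`,
#'   centre coordinates, `dims`, boundary codes and `h_fine`.
#' @export
build_grid <- function(domain, fine_block = domain, h_fine,
                       stretch = 1.05,
                       bc = c(xlo = "inflow", xhi = "outflow", ylo = "slip",
                              yhi = "slip", zlo = "slip", zhi = "slip"),
                       Uin = 0) {
  if (stretch > 1.1 + 1e-12)
    stop("build_grid: stretch ratio > 1.1 requested", call. = FALSE)
  if (is.matrix(domain)) domain <- lapply(1:3, function(d) domain[d, ])
  if (is.matrix(fine_block)) fine_block <- lapply(1:3, function(d) fine_block[d, ])
  h_fine <- rep_len(h_fine, 3)
  bc_opts <- c("inflow", "outflow", "slip", "periodic")
  face_names <- c("xlo", "xhi", "ylo", "yhi", "zlo", "zhi")
  bc <- bc[face_names]
  if (anyNA(bc) || !all(bc %in% bc_opts))
    stop("build_grid: bc must name all of ", paste(face_names, collapse = ", "),
         " with values in ", paste(bc_opts, collapse = "/"), call. = FALSE)

  # spacings of one stretched outer region of length L starting from h
  stretched <- function(L, h, r_max) {
    if (L <= 1e-12) return(numeric(0))
    if (L <= 1.5 * h) return(rep(L / ceiling(L / h), ceiling(L / h)))
    ssum <- function(r, m) if (abs(r - 1) < 1e-12) m * h else h * r * (r^m - 1) / (r - 1)
    m <- 1L
    while (ssum(r_max, m) < L && m < 100000L) m <- m + 1L
    if (m * h >= L * (1 - 1e-9)) return(rep(L / m, m))   # no expansion needed
    r <- stats::uniroot(function(r) ssum(r, m) - L,
                        lower = 1 + 1e-9, upper = r_max, tol = 1e-13)$root
    h * r^seq_len(m)
  }

  axes <- lapply(1:3, function(d) {
    a <- domain[[d]][1]; b <- domain[[d]][2]
    f1 <- max(a, fine_block[[d]][1]); f2 <- min(b, fine_block[[d]][2])
    if (f2 <= f1) stop("build_grid: fine block must lie inside the domain", call. = FALSE)
    h <- h_fine[d]
    n_f <- max(2L, as.integer(round((f2 - f1) / h)))
    h_act <- (f2 - f1) / n_f
    left <- stretched(f1 - a, h_act, stretch)    # sizes moving outward
    right <- stretched(b - f2, h_act, stretch)
    # coarsening away from the fine block must stay within the stretch
    # ratio (cells may only ever be finer than that bound allows)
    exp_ok <- function(s) length(s) < 2 ||
      all(s[-1] / s[-length(s)] <= stretch + 1e-9)
    if (!exp_ok(left) || !exp_ok(right) ||
        (length(left) && left[1] > h_act * (stretch + 1e-9)) ||
        (length(right) && right[1] > h_act * (stretch + 1e-9)))
      stop("build_grid: internal error, stretching ratio exceeded ", stretch,
           call. = FALSE)
    faces <- a + cumsum(c(0, rev(left), rep(h_act, n_f), right))
    faces[length(faces)] <- b
    faces
  })

  for (d in 1:3) {
    per <- bc[2 * d - 1] == "periodic" | bc[2 * d] == "periodic"
    if (per && (bc[2 * d - 1] != "periodic" || bc[2 * d] != "periodic"))
      stop("build_grid: periodic boundaries must pair up per axis", call. = FALSE)
  }
  bc_code <- match(unname(bc), bc_opts) - 1L

  structure(list(
    xf = axes[[1]], yf = axes[[2]], zf = axes[[3]],
    xc = (axes[[1]][-1] + axes[[1]][-length(axes[[1]])]) / 2,
    yc = (axes[[2]][-1] + axes[[2]][-length(axes[[2]])]) / 2,
    zc = (axes[[3]][-1] + axes[[3]][-length(axes[[3]])]) / 2,
    dims = vapply(axes, function(f) length(f) - 1L, 1L),
    bc = bc, bc_code = bc_code, Uin = Uin,
    h_fine = h_fine,
    cache = new.env(parent = emptyenv())), class = "flow_grid")
}

#' @export
print.flow_grid <- function(x, ...) {
  cat(sprintf("<flow_grid> %d x %d x %d cells (%.3g total), h_fine = %s m\n",
              x$dims[1], x$dims[2], x$dims[3], prod(x$dims),
              paste(signif(x$h_fine, 3), collapse = "/")))
  cat("  bc:", paste(names(x$bc), x$bc, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# compact list passed to the C++ kernels
grid_cpp <- function(grid) {
  list(xf = grid$xf, yf = grid$yf, zf = grid$zf,
       bc_code = grid$bc_code, Uin = grid$Uin)
}

# staggered array dims for component comp (1=u, 2=v, 3=w)
stag_dims <- function(grid, comp) {
  d <- grid$dims
  if (grid$bc_code[2 * comp - 1] != 3L) d[comp] <- d[comp] + 1L
  d
}
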