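#' Discretized magnetization grid
#'
#' A magnetization vector field on a regular 3D cell grid: the parent
#' structure over which the bead moves.  Cells are cell-centred: cell
#' `(i, j, k)` (1-based) has its centre at
#' `origin + ((i,j,k) - 1) * cell_size`.  Cells outside the structure carry
#' zero magnetization.
#'
#' @param M numeric array of dimension `c(nx, ny, nz, 3)`, magnetization in
#'   A/m.
#' @param cell_size numeric 3-vector `(dx, dy, dz)` in metres, all > 0.
#' @param origin numeric 3-vector, position of the centre of cell
#'   `(1, 1, 1)` in metres.
#' @param Ms saturation magnetization in A/m; every cell must satisfy
#'   `|M| <= Ms * (1 + 1e-6)`.
#' @param periodic logical 2-vector: is the structure periodic along x / y
#'   (period = grid extent `n * cell_size`)?
#' @param direction optional unit 3-vector: set when every magnetized cell
#'   points along the same direction (enables the shared-tensor fast path in
#'   [potential_sequence()]).
#' @return an object of class `mag_grid`.
#' @seealso [synth_state()], [read_ovf()], [downsample()], [rotate_state()]
#' @export
mag_grid <- function(M, cell_size, origin = c(0, 0, 0), Ms,
                     periodic = c(FALSE, FALSE), direction = NULL) {
  if (!is.array(M) || length(dim(M)) != 4 || dim(M)[4] != 3)
    stop("'M' must be an array [nx, ny, nz, 3]")
  stopifnot(length(cell_size) == 3, length(origin) == 3, length(periodic) == 2)
  if (any(cell_size <= 0)) stop("'cell_size' must be strictly positive")
  if (any(dim(M)[1:3] < 1)) stop("grid must have >= 1 cell per axis")
  if (!is.numeric(Ms) || Ms < 0) stop("'Ms' must be a non-negative number")
  nrm2 <- M[, , , 1]^2 + M[, , , 2]^2 + M[, , , 3]^2
  if (any(nrm2 > (Ms * (1 + 1e-6))^2))
    stop("|M| exceeds Ms * (1 + 1e-6) in at least one cell")
  structure(list(M = M, n = dim(M)[1:3], cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), Ms = Ms,
                 periodic = as.logical(periodic), direction = direction),
            class = "mag_grid")
}

#' @export
print.mag_grid <- function(x, ...) {
  cat(sprintf("<mag_grid> %d x %d x %d cells, cell %.3g x %.3g x %.3g um, Ms = %.4g A/m\n",
              x$n[1], x$n[2], x$n[3],
              x$cell_size[1] * 1e6, x$cell_size[2] * 1e6, x$cell_size[3] * 1e6,
              x$Ms))
  if (any(x$periodic))
    cat(sprintf("  periodic: x=%s y=%s\n", x$periodic[1], x$periodic[2]))
  invisible(x)
}

# physical extent along x, y, z [m]
grid_extent <- function(grid) grid$n * grid$cell_size

# coordinates of cell centres along one axis
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$n[axis]) - 1) * grid$cell_size[axis]
}

# matrix of magnetized cell centres and their M vectors
grid_cells <- function(grid, drop_zero = TRUE) {
  n <- grid$n
  Mmat <- matrix(grid$M, nrow = prod(n), ncol = 3)
  xs <- grid_axis(grid, 1); ys <- grid_axis(grid, 2); zs <- grid_axis(grid, 3)
  pos <- cbind(rep(xs, times = n[2] * n[3]),
               rep(rep(ys, each = n[1]), times = n[3]),
               rep(zs, each = n[1] * n[2]))
  if (drop_zero) {
    keep <- rowSums(Mmat^2) > 0
    pos <- pos[keep, , drop = FALSE]
    Mmat <- Mmat[keep, , drop = FALSE]
  }
  list(pos = pos, M = Mmat, dV = prod(grid$cell_size))
}

#' Total magnetic moment of a grid
#'
#' Sum of `M * cell volume` over all cells, in A m^2.
#'
#' @param grid a [mag_grid()].
#' @return numeric 3-vector.
#' @export
total_moment <- function(grid) {
  dV <- prod(grid$cell_size)
  c(sum(grid$M[, , , 1]), sum(grid$M[, , , 2]), sum(grid$M[, , , 3])) * dV
}

#' Downsample a magnetization grid in the xy-plane
#'
#' Averages the magnetization over `factor x factor` blocks of neighbouring
#' cells in the xy-plane, the standard way to cut potential-map runtime while
#' conserving the total magnetic moment exactly.  When `factor` does not
#' divide the cell counts, the grid is padded at the high-index edge with
#' zero-magnetization (vacuum) cells before averaging.
#'
#' @param grid a [mag_grid()].
#' @param factor positive integer block size.
#' @return a coarser [mag_grid()] with `cell_size` scaled by `factor` in x
#'   and y.
#' @export
downsample <- function(grid, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor))
    stop("'factor' must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)
  n <- grid$n
  nx2 <- ceiling(n[1] / factor) * factor
  ny2 <- ceiling(n[2] / factor) * factor
  M <- grid$M
  if (nx2 != n[1] || ny2 != n[2]) {
    Mp <- array(0, dim = c(nx2, ny2, n[3], 3))
    Mp[seq_len(n[1]), seq_len(n[2]), , ] <- M
    M <- Mp
  }
  cx <- nx2 %/% factor
  cy <- ny2 %/% factor
  # average factor x factor xy blocks: reshape so block indices are separate
  dim(M) <- c(factor, cx, factor, cy, n[3], 3)
  Mc <- apply(M, c(2, 4, 5, 6), mean)
  # padded vacuum cells count toward the mean, so sum(M) dV is conserved
  new_cell <- grid$cell_size * c(factor, factor, 1)
  new_origin <- grid$origin + c((factor - 1) / 2 * grid$cell_size[1],
                                (factor - 1) / 2 * grid$cell_size[2], 0)
  mag_grid(Mc, new_cell, new_origin, grid$Ms, grid$periodic,
           direction = grid$direction)
}

#' Rotate a magnetization state about the grid centre
#'
#' Rotates both the cell positions (nearest-neighbour resampling, so `|M|`
#' is preserved exactly) and the in-plane vector components by `angle`.
#' Intended for circularly symmetric footprints (discs), where the
#' magnetization state under a rotated field is the rotated state; only
#' `nx == ny` is checked.
#'
#' @param grid a [mag_grid()] with `nx == ny`.
#' @param angle rotation angle in degrees, counterclockwise.
#' @return the rotated [mag_grid()].
#' @export
rotate_state <- function(grid, angle) {
  n <- grid$n
  if (n[1] != n[2])
    stop("rotate_state() requires a square grid (nx == ny)")
  # cospi/sinpi are exact at multiples of 90 degrees
  ct <- cospi(angle / 180); st <- sinpi(angle / 180)
  # grid centre in index units (0-based)
  c0 <- (n[1] - 1) / 2
  idx <- seq_len(n[1]) - 1
  X <- outer(idx - c0, rep(1, n[2]))        # target x offsets
  Y <- outer(rep(1, n[1]), idx - c0)        # target y offsets
  # source position = inverse rotation of target position
  sx <- round(ct * X + st * Y + c0) + 1
  sy <- round(-st * X + ct * Y + c0) + 1
  ok <- sx >= 1 & sx <= n[1] & sy >= 1 & sy <= n[2]
  sx[!ok] <- 1L; sy[!ok] <- 1L
  src <- cbind(as.vector(sx), as.vector(sy))
  Mout <- array(0, dim = dim(grid$M))
  for (k in seq_len(n[3])) {
    mx <- grid$M[, , k, 1][src]
    my <- grid$M[, , k, 2][src]
    mz <- grid$M[, , k, 3][src]
    mx[!ok] <- 0; my[!ok] <- 0; mz[!ok] <- 0
    Mout[, , k, 1] <- matrix(ct * mx - st * my, n[1], n[2])
    Mout[, , k, 2] <- matrix(st * mx + ct * my, n[1], n[2])
    Mout[, , k, 3] <- matrix(mz, n[1], n[2])
  }
  dir <- grid$direction
  if (!is.null(dir))
    dir <- c(ct * dir[1] - st * dir[2], st * dir[1] + ct * dir[2], dir[3])
  mag_grid(Mout, grid$cell_size, grid$origin, grid$Ms, grid$periodic,
           direction = dir)
}
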