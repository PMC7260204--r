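#' Potential-map grid specification
#'
#' Defines where the bead's potential energy is sampled: an in-plane node
#' grid spanning `xlim` x `ylim` plus a list of height layers.  The z
#' coordinate convention follows the bead: z = 0 is the bead-centre rest
#' height, one bead radius above the film surface, and layers may start at
#' -r_mb/2 for fitting below ground level.
#'
#' Non-periodic axes carry `nx` nodes spanning `xlim` inclusively
#' (vertex-centred).  Periodic axes carry `nx` nodes at spacing `L/nx`
#' starting at `xlim[1]` (no duplicated seam node); the parent structure is
#' replicated `images` times on each side before summation.
#'
#' @param xlim,ylim numeric 2-vectors, in-plane extent in metres.
#' @param nx,ny node counts (>= 3; local polynomial fitting needs 3).
#' @param z_layers strictly increasing vector of heights in metres.
#' @param periodic logical 2-vector, per in-plane axis.
#' @param images integer 2-vector: periodic image count per side per axis.
#' @return an object of class `potential_grid_spec` with node coordinate
#'   vectors `x`, `y`, `z_layers`.
#' @export
potential_grid_spec <- function(xlim, ylim, nx, ny, z_layers,
                                periodic = c(FALSE, FALSE),
                                images = c(3, 3)) {
  stopifnot(length(xlim) == 2, length(ylim) == 2, length(periodic) == 2,
            length(images) == 2)
  if (nx < 3 || ny < 3) stop("'nx' and 'ny' must be >= 3")
  z_layers <- as.numeric(z_layers)
  if (length(z_layers) < 1 || is.unsorted(z_layers, strictly = TRUE))
    stop("'z_layers' must be strictly increasing")
  Lx <- diff(xlim); Ly <- diff(ylim)
  if (Lx <= 0 || Ly <= 0) stop("'xlim'/'ylim' must have positive extent")
  x <- if (periodic[1]) xlim[1] + (seq_len(nx) - 1) * Lx / nx
       else seq(xlim[1], xlim[2], length.out = nx)
  y <- if (periodic[2]) ylim[1] + (seq_len(ny) - 1) * Ly / ny
       else seq(ylim[1], ylim[2], length.out = ny)
  structure(list(xlim = xlim, ylim = ylim, nx = as.integer(nx),
                 ny = as.integer(ny), x = x, y = y, z_layers = z_layers,
                 nz = length(z_layers), period = c(Lx, Ly),
                 periodic = as.logical(periodic), images = as.integer(images)),
            class = "potential_grid_spec")
}

#' @export
print.potential_grid_spec <- function(x, ...) {
  cat(sprintf("<potential_grid_spec> %d x %d nodes, %d z layer(s), periodic x=%s y=%s\n",
              x$nx, x$ny, x$nz, x$periodic[1], x$periodic[2]))
  invisible(x)
}

# image shift matrix (k x 3) for the periodic replication of the parent
image_shifts <- function(spec) {
  ix <- if (spec$periodic[1]) -spec$images[1]:spec$images[1] else 0L
  iy <- if (spec$periodic[2]) -spec$images[2]:spec$images[2] else 0L
  sh <- expand.grid(x = ix * spec$period[1], y = iy * spec$period[2])
  cbind(sh$x, sh$y, 0)
}

# node positions (n x 3) in the physical frame of the parent grid:
# bead-centre z = grid z + r_mb
spec_nodes <- function(spec, r_mb) {
  nn <- spec$nx * spec$ny * spec$nz
  cbind(rep(spec$x, times = spec$ny * spec$nz),
        rep(rep(spec$y, each = spec$nx), times = spec$nz),
        rep(spec$z_layers + r_mb, each = spec$nx * spec$ny))
}

#' Potential energy slab for a single field state
#'
#' Evaluates the bead's magnetic potential energy on the node grid via the
#' magnetostatic reciprocity theorem: instead of computing the parent
#' structure's stray field everywhere, the parent magnetization is
#' integrated against the bead's dipole stray field,
#' `U(s) = -2 mu0 sum_cells M_p . H_mb(r_cell - s) dV`.
#' The position-independent `M_p . H_ext` term is dropped (it cannot
#' contribute to forces), as is the integration constant.  For periodic
#' axes the parent cells are replicated `images` times per side.
#'
#' @param grid parent [mag_grid()].
#' @param bead a [bead_spec()]; sets both the dipole moment and the rest
#'   height r_mb relating grid z to physical height.
#' @param H_ext external field 3-vector in A/m.
#' @param spec a [potential_grid_spec()].
#' @return numeric array `[nx, ny, nz]` of energies in joules.
#' @export
compute_potential <- function(grid, bead, H_ext, spec) {
  m <- bead_moment(bead, H_ext)
  cells <- grid_cells(grid)
  U <- array(0, dim = c(spec$nx, spec$ny, spec$nz))
  if (nrow(cells$pos) == 0 || all(m == 0)) return(U)
  nodes <- spec_nodes(spec, bead$r_mb)
  Vf <- cpp_dipole_vector_sum(nodes, cells$pos, cells$M, cells$dV,
                              image_shifts(spec))
  U[] <- -2 * MU0 * as.vector(Vf %*% m)
  U
}

# per-node dipole tensor map G (n x 6, packed xx xy xz yy yz zz):
# U = -2 mu0 * Ms * m^T G d for a mask uniformly magnetized along d
potential_tensor <- function(grid, bead, spec) {
  cells <- grid_cells(grid)
  nodes <- spec_nodes(spec, bead$r_mb)
  cpp_dipole_tensor_sum(nodes, cells$pos, cells$dV, image_shifts(spec))
}

quad_form_cols <- function(G, a, b) {
  # rows of G are packed symmetric tensors; returns a^T G b per row
  G[, 1] * a[1] * b[1] + G[, 4] * a[2] * b[2] + G[, 6] * a[3] * b[3] +
    G[, 2] * (a[1] * b[2] + a[2] * b[1]) +
    G[, 3] * (a[1] * b[3] + a[3] * b[1]) +
    G[, 5] * (a[2] * b[3] + a[3] * b[2])
}

#' Potential map over a field sequence
#'
#' Stacks one potential slab per field state into a `potential_map`.  Three
#' evaluation routes produce identical results (to rounding) and are chosen
#' automatically:
#' \describe{
#'   \item{`per_state`}{one [compute_potential()] per state, each with its
#'     own magnetization grid (a list in `grids`, or a circularly symmetric
#'     grid rotated per angle via [rotate_state()] when
#'     `rotate_symmetric = TRUE`).}
#'   \item{`fixed_pattern`}{the parent magnetization is the same for every
#'     state (exchange-biased stripes): the dipole vector sum is computed
#'     once and re-contracted with each state's bead moment.}
#'   \item{`tensor`}{every state is the same mask saturated along the
#'     in-plane field direction (synthetic rotating/switching states): a
#'     per-node dipole tensor is computed once and contracted with each
#'     state's direction pair.}
#' }
#'
#' @param grids a [mag_grid()] or list of them (one per field state).
#' @param bead a [bead_spec()].
#' @param field a [field_sequence()].
#' @param spec a [potential_grid_spec()].
#' @param method `"auto"`, `"per_state"`, `"fixed_pattern"` or `"tensor"`.
#' @param rotate_symmetric if `TRUE` (and a single grid is given with a
#'   rotating field), per-angle states are obtained by [rotate_state()].
#' @return an object of class `potential_map`: list with `U` (array
#'   `[nx, ny, nz, n_states]`), `spec`, `field`, `times`, `omega`.
#' @export
potential_sequence <- function(grids, bead, field, spec,
                               method = c("auto", "per_state",
                                          "fixed_pattern", "tensor"),
                               rotate_symmetric = FALSE) {
  method <- match.arg(method)
  multi <- is.list(grids) && !inherits(grids, "mag_grid")
  if (multi) {
    if (length(grids) != field$n_states)
      stop(sprintf("got %d magnetization states for %d field states",
                   length(grids), field$n_states))
    if (method %in% c("auto", "per_state")) method <- "per_state"
    else stop("method '", method, "' needs a single grid")
  } else if (method == "auto") {
    inplane <- all(vapply(field$H, function(h) h[3] == 0, logical(1)))
    method <- if (!is.null(grids$direction) && inplane) "tensor"
              else "fixed_pattern"
  }

  nst <- field$n_states
  U <- array(0, dim = c(spec$nx, spec$ny, spec$nz, nst))
  if (method == "per_state") {
    if (multi) {
      for (j in seq_len(nst))
        U[, , , j] <- compute_potential(grids[[j]], bead, field$H[[j]], spec)
    } else if (rotate_symmetric) {
      if (field$mode != "rotating")
        stop("rotate_symmetric needs a rotating field")
      for (j in seq_len(nst)) {
        gj <- rotate_state(grids, field$angles[j] - field$angles[1])
        U[, , , j] <- compute_potential(gj, bead, field$H[[j]], spec)
      }
    } else {
      for (j in seq_len(nst))
        U[, , , j] <- compute_potential(grids, bead, field$H[[j]], spec)
    }
  } else if (method == "fixed_pattern") {
    cells <- grid_cells(grids)
    nodes <- spec_nodes(spec, bead$r_mb)
    Vf <- cpp_dipole_vector_sum(nodes, cells$pos, cells$M, cells$dV,
                                image_shifts(spec))
    for (j in seq_len(nst)) {
      m <- bead_moment(bead, field$H[[j]])
      U[, , , j] <- -2 * MU0 * as.vector(Vf %*% m)
    }
  } else {  # tensor
    if (is.null(grids$direction))
      stop("tensor route needs a uniform-direction grid (synth_state)")
    G <- potential_tensor(grids, bead, spec)
    chiV <- bead$chi * bead_volume(bead)
    for (j in seq_len(nst)) {
      H <- field$H[[j]]
      Hn <- sqrt(sum(H^2))
      if (Hn == 0) next
      d <- H / Hn  # saturated parent follows the field direction
      m <- chiV * H
      U[, , , j] <- -2 * MU0 * grids$Ms * quad_form_cols(G, m, d)
    }
  }
  structure(list(U = U, spec = spec, field = field, times = field$times,
                 omega = field$omega, n_states = nst, method = method,
                 bead = bead),
            class = "potential_map")
}

#' Assemble a potential map from raw values
#'
#' Wraps a user-supplied energy array (e.g. an analytic test landscape) in
#' the same container [potential_sequence()] produces, so it can be fitted
#' and simulated.
#'
#' @param U array `[nx, ny, nz, n_states]` (a 3D array is treated as one
#'   state) of energies in joules.
#' @param spec a [potential_grid_spec()].
#' @param times sample times (s), length = number of states.
#' @param omega fundamental angular frequency (rad/s); for a single static
#'   state any positive value works.
#' @return a `potential_map`.
#' @export
potential_map <- function(U, spec, times = 0, omega = 2 * pi) {
  if (length(dim(U)) == 3) dim(U) <- c(dim(U), 1)
  stopifnot(length(dim(U)) == 4,
            all(dim(U)[1:3] == c(spec$nx, spec$ny, spec$nz)),
            dim(U)[4] == length(times))
  structure(list(U = U, spec = spec, field = NULL, times = times,
                 omega = omega, n_states = dim(U)[4], method = "direct",
                 bead = NULL),
            class = "potential_map")
}

#' @export
print.potential_map <- function(x, ...) {
  cat(sprintf("<potential_map> %d x %d x %d nodes, %d state(s) [%s]\n",
              x$spec$nx, x$spec$ny, x$spec$nz, x$n_states, x$method))
  invisible(x)
}

#' Repeat potential states into a square-wave time sequence
#'
#' Discrete switching sequences are emulated by concatenating each state's
#' slab `copies` times before the Fourier fit, e.g. 100 copies of the 30
#' degree potential followed by 100 copies of the 150 degree potential for
#' a two-state switch.  Sample times become uniform over one field period.
#'
#' @param map a `potential_map`.
#' @param copies copies per state (>= 1).
#' @return a `potential_map` with `n_states * copies` samples.
#' @export
concat_states <- function(map, copies) {
  if (!is.numeric(copies) || length(copies) != 1 || copies < 1 ||
      copies != round(copies))
    stop("'copies' must be a positive integer")
  copies <- as.integer(copies)
  idx <- rep(seq_len(map$n_states), each = copies)
  U <- map$U[, , , idx, drop = FALSE]
  n <- length(idx)
  period <- 2 * pi / map$omega
  out <- map
  out$U <- U
  out$n_states <- n
  out$times <- (seq_len(n) - 1) * period / n
  out
}
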