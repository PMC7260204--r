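#' Fourier basis row
#'
#' `(1, cos(w t), ..., cos(N w t), sin(w t), ..., sin(N w t))`.
#'
#' @param t time(s) in seconds (vectorized).
#' @param N Fourier order.
#' @param omega fundamental angular frequency (rad/s).
#' @return a length `2N+1` vector, or an `length(t) x (2N+1)` matrix.
#' @export
fourier_basis <- function(t, N, omega) {
  k <- seq_len(N)
  if (length(t) == 1) {
    c(1, cos(k * omega * t), if (N > 0) sin(k * omega * t))
  } else {
    wt <- outer(t, k * omega)
    cbind(1, cos(wt), if (N > 0) sin(wt))
  }
}

#' Fit the time dependence of a potential map with a Fourier series
#'
#' Least-squares Fourier coefficients up to order `N` per grid node, from
#' the sampled field states.  On a uniform sample grid this equals the
#' discrete Fourier transform; design columns whose sampled norm vanishes
#' (the sine at the Nyquist harmonic when `2N` equals the sample count) are
#' dropped and their coefficients set to zero.
#'
#' @param map a `potential_map` (see [potential_sequence()]).
#' @param N Fourier order; needs at least `2N` time samples.
#' @return a `time_fit`: list with `coef` (array `[nx, ny, nz, 2N+1]`,
#'   order `a0, a1..aN, b1..bN`), `N`, `omega`, `spec`.
#' @export
fit_time <- function(map, N) {
  stopifnot(inherits(map, "potential_map"), N >= 0)
  n <- length(map$times)
  X <- fourier_basis(map$times, N, map$omega)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  keep <- sqrt(colSums(X^2)) > 1e-9 * sqrt(n)
  if (sum(keep) > n)
    stop(sprintf(
      "rank error: %d Fourier coefficients but only %d time samples",
      sum(keep), n))
  sp <- map$spec
  nn <- sp$nx * sp$ny * sp$nz
  Um <- matrix(map$U, nrow = nn, ncol = n)   # nodes x samples
  qrX <- qr(X[, keep, drop = FALSE])
  if (qrX$rank < sum(keep))
    stop("rank error: Fourier design matrix is rank deficient at these sample times")
  cf <- qr.coef(qrX, t(Um))                  # kept x nodes
  coef <- matrix(0, 2 * N + 1, nn)
  coef[keep, ] <- cf
  coef <- array(t(coef), dim = c(sp$nx, sp$ny, sp$nz, 2 * N + 1))
  structure(list(coef = coef, N = N, omega = map$omega, spec = sp),
            class = "time_fit")
}

# polynomial basis exponents: 1, x, y, z, xy, xz, yz, xyz, x^2, y^2, z^2
poly_terms_3d <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1),
  c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))

poly_design <- function(pts, terms) {
  # pts: n x 3 local coordinates; terms: nterms x 3 exponents
  X <- matrix(1, nrow(pts), nrow(terms))
  for (j in seq_len(nrow(terms)))
    for (ax in 1:3)
      if (terms[j, ax] > 0) X[, j] <- X[, j] * pts[, ax]^terms[j, ax]
  X
}

poly_row_and_grad <- function(xi, terms) {
  # value row p(xi) and Jacobian rows dp/dxi (nterms x 3), local units
  p <- numeric(nrow(terms))
  g <- matrix(0, nrow(terms), 3)
  for (j in seq_len(nrow(terms))) {
    e <- terms[j, ]
    p[j] <- prod(xi^e)
    for (ax in 1:3) {
      if (e[ax] > 0) {
        ee <- e
        ee[ax] <- ee[ax] - 1
        g[j, ax] <- e[ax] * prod(xi^ee)
      }
    }
  }
  list(p = p, grad = g)
}

#' Fit the spatial dependence with per-submatrix polynomials
#'
#' Every grid node is the centre of a `sub x sub x sub` submatrix (3 or 5
#' nodes per axis) over which each Fourier-coefficient map is fitted by
#' least squares with the 11-term polynomial basis
#' `(1, x, y, z, xy, xz, yz, xyz, x^2, y^2, z^2)` in node-centred local
#' coordinates scaled by the grid step.  Windows wrap on periodic axes
#' (overlapping submatrices across the seam) and shift inwards at
#' non-periodic borders.  With fewer than 3 z layers the z-dependent terms
#' are dropped and the landscape is quasi-2D.
#'
#' Submatrix coefficient matrices are computed lazily on first evaluation
#' near a node and cached, together with the per-submatrix maximum fit
#' residual.
#'
#' @param tfit a `time_fit` from [fit_time()].
#' @param sub submatrix size per axis, 3 or 5.
#' @return a `fitted_potential`, evaluable with [eval_U()] and
#'   [eval_force()].
#' @export
fit_space <- function(tfit, sub = 3) {
  stopifnot(inherits(tfit, "time_fit"))
  if (!sub %in% c(3, 5)) stop("'sub' must be 3 or 5")
  sp <- tfit$spec
  if (sp$nx < sub || sp$ny < sub)
    stop(sprintf("grid too small for %d^3 submatrices", sub))
  use_z <- sp$nz >= 3
  terms <- if (use_z) poly_terms_3d else
    poly_terms_3d[poly_terms_3d[, 3] == 0, , drop = FALSE]
  dx <- if (sp$periodic[1]) sp$period[1] / sp$nx else diff(sp$x[1:2])
  dy <- if (sp$periodic[2]) sp$period[2] / sp$ny else diff(sp$y[1:2])
  dz <- if (sp$nz > 1) mean(diff(sp$z_layers)) else 1
  structure(list(coef = tfit$coef, N = tfit$N, omega = tfit$omega, spec = sp,
                 sub = as.integer(sub), use_z = use_z, terms = terms,
                 scale = c(dx, dy, dz), cache = new.env(parent = emptyenv())),
            class = "fitted_potential")
}

#' @export
print.fitted_potential <- function(x, ...) {
  cat(sprintf("<fitted_potential> N = %d, %d x %d x %d nodes, %d^3 submatrices, %s\n",
              x$N, x$spec$nx, x$spec$ny, x$spec$nz, x$sub,
              if (x$use_z) "3D" else "quasi-2D"))
  invisible(x)
}

# window index vector around node i (1-based), length sub, on an axis with
# n nodes; periodic axes wrap, others shift the window inside the grid
window_idx <- function(i, n, sub, periodic) {
  h <- (sub - 1L) %/% 2L
  idx <- (i - h):(i + h)
  if (periodic) return(((idx - 1L) %% n) + 1L)
  if (n < sub) return(seq_len(n))
  idx + max(0L, 1L - idx[1]) - max(0L, idx[sub] - n)
}

# local (scaled) coordinates of window nodes relative to node i
window_local <- function(idx, i, coords, period, periodic, scale) {
  d <- coords[idx] - coords[i]
  if (periodic) d <- (d + period / 2) %% period - period / 2
  d / scale
}

# fit (and cache) the submatrix centred on node (i, j, k):
# returns list(C = nterms x (2N+1) coefficients, resid, node indices)
node_coef <- function(fit, i, j, k) {
  key <- paste(i, j, k, sep = ",")
  hit <- fit$cache[[key]]
  if (!is.null(hit)) return(hit)
  sp <- fit$spec
  sub <- fit$sub
  ix <- window_idx(i, sp$nx, sub, sp$periodic[1])
  iy <- window_idx(j, sp$ny, sub, sp$periodic[2])
  iz <- if (fit$use_z) window_idx(k, sp$nz, min(sub, sp$nz), FALSE) else k
  lx <- window_local(ix, i, sp$x, sp$period[1], sp$periodic[1], fit$scale[1])
  ly <- window_local(iy, j, sp$y, sp$period[2], sp$periodic[2], fit$scale[2])
  lz <- if (fit$use_z)
    (sp$z_layers[iz] - sp$z_layers[k]) / fit$scale[3] else 0
  pts <- as.matrix(expand.grid(x = lx, y = ly, z = lz))
  X <- poly_design(pts, fit$terms)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop(sprintf("fit error: degenerate submatrix at node (%d, %d, %d)",
                 i, j, k))
  nmaps <- dim(fit$coef)[4]
  Uw <- fit$coef[ix, iy, iz, , drop = FALSE]
  Umat <- matrix(Uw, nrow = nrow(pts), ncol = nmaps)
  C <- qr.coef(qrX, Umat)
  resid <- max(abs(X %*% C - Umat))
  out <- list(C = C, resid = resid, idx = c(i, j, k))
  fit$cache[[key]] <- out
  out
}

# wrap a coordinate into [x0, x0 + L)
wrap_coord <- function(v, x0, L) ((v - x0) %% L) + x0

# nearest node indices for a position; 'prev' (indices) adds hysteresis so
# the active submatrix only changes when the trajectory truly crosses a
# node boundary
nearest_node <- function(fit, s, prev = NULL) {
  sp <- fit$spec
  near_ax <- function(v, coords, n, periodic, period, prev_i) {
    if (periodic) {
      step <- period / n
      i <- (round((v - coords[1]) / step) %% n) + 1
    } else {
      step <- coords[2] - coords[1]
      i <- round((v - coords[1]) / step) + 1
      i <- min(max(i, 1), n)
    }
    if (!is.null(prev_i)) {
      d <- v - coords[prev_i]
      if (periodic) d <- (d + period / 2) %% period - period / 2
      if (abs(d) <= step / 2 * (1 + 1e-9)) i <- prev_i
    }
    as.integer(i)
  }
  i <- near_ax(s[1], sp$x, sp$nx, sp$periodic[1], sp$period[1], prev[1])
  j <- near_ax(s[2], sp$y, sp$ny, sp$periodic[2], sp$period[2], prev[2])
  k <- if (sp$nz == 1) 1L else which.min(abs(sp$z_layers - s[3]))
  if (!is.null(prev) && sp$nz > 1) {
    zd <- abs(s[3] - sp$z_layers[prev[3]])
    if (zd <= abs(s[3] - sp$z_layers[k]) * (1 + 1e-9)) k <- prev[3]
  }
  c(i, j, k)
}

# local scaled displacement from node (with periodic wrapping);
# checks the domain on non-periodic axes unless extrapolation is granted
local_xi <- function(fit, s, node, grace = 0) {
  sp <- fit$spec
  xi <- numeric(3)
  ax_coords <- list(sp$x, sp$y, sp$z_layers)
  for (ax in 1:3) {
    v <- s[ax]
    coords <- ax_coords[[ax]]
    periodic <- ax <= 2 && sp$periodic[ax]
    if (periodic) {
      d <- v - coords[node[ax]]
      d <- (d + sp$period[ax] / 2) %% sp$period[ax] - sp$period[ax] / 2
    } else {
      lo <- coords[1]; hi <- coords[length(coords)]
      span <- if (length(coords) > 1) fit$scale[ax] else Inf
      if (v < lo - grace * span || v > hi + grace * span)
        stop(sprintf(
          "domain error: position %.4g um outside the fitted extent on axis %d",
          v * 1e6, ax))
      d <- v - coords[node[ax]]
    }
    xi[ax] <- d / fit$scale[ax]
  }
  if (!fit$use_z) xi[3] <- 0
  xi
}

#' Evaluate the fitted potential
#'
#' `U(t, s)` from the submatrix whose centre is the nearest grid node to
#' `s`: `U = F1(t)' A p(s) + F2(t)' B p(s)` with the Fourier rows `F1, F2`
#' and the node's polynomial coefficient matrices.  Positions wrap on
#' periodic axes; on non-periodic axes positions outside the fitted extent
#' raise a domain error.
#'
#' @param fit a `fitted_potential` from [fit_space()].
#' @param t time in seconds (any real; the fit is time-periodic).
#' @param s position 3-vector in metres (grid z convention).
#' @return energy in joules ([eval_U]) or force 3-vector in newtons
#'   ([eval_force], the analytic negative gradient of the local polynomial).
#' @export
eval_U <- function(fit, t, s) {
  node <- nearest_node(fit, s)
  nc <- node_coef(fit, node[1], node[2], node[3])
  xi <- local_xi(fit, s, node)
  f <- fourier_basis(t, fit$N, fit$omega)
  pg <- poly_row_and_grad(xi, fit$terms)
  as.numeric(pg$p %*% (nc$C %*% f))
}

#' @rdname eval_U
#' @export
eval_force <- function(fit, t, s) {
  node <- nearest_node(fit, s)
  nc <- node_coef(fit, node[1], node[2], node[3])
  xi <- local_xi(fit, s, node)
  f <- fourier_basis(t, fit$N, fit$omega)
  q <- as.vector(nc$C %*% f)
  pg <- poly_row_and_grad(xi, fit$terms)
  F3 <- -as.vector(crossprod(pg$grad, q)) / fit$scale
  if (!fit$use_z) F3[3] <- 0
  F3
}
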