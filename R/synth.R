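#' Shape specifications for synthetic magnetization states
#'
#' Constructors for the supported parent-structure footprints.  Each returns
#' a `shape_spec` with an `inside(x, y)` predicate (vectorized, metres,
#' coordinates relative to the shape frame), an analytic area, and a frame
#' convention: `"centred"` shapes sit at the origin of a grid centred on
#' them; `"cell"` shapes tile the unit cell `[0, Lx) x [0, Ly)`.
#'
#' The oval is two circular arcs of different radii (blunt "base" and
#' sharper "tip") joined by their common external tangents — a synthetic,
#' parametric outline emulating asymmetric track elements whose two
#' curvatures create an asymmetric potential along the track.
#'
#' @param radius disc radius (m).
#' @param side triangle side length (m); triangles are equilateral.
#' @param orientation rotation of the triangle in degrees (0 = pointing +y).
#' @param Lx,Ly unit-cell dimensions (m).
#' @param width stripe width (m); each stripe occupies `[0, width)` of every
#'   period along y.
#' @param period stripe repeat distance along y (m).
#' @param length,height oval bounding-box dimensions (m).
#' @param tip_radius,base_radius oval arc radii (m), `tip_radius <
#'   base_radius <= height/2`; base at -x, tip at +x.
#' @return a `shape_spec` object.
#' @name shapes
NULL

new_shape <- function(kind, inside, area, frame = "centred", bbox = NULL,
                      params = list()) {
  structure(list(kind = kind, inside = inside, area = area, frame = frame,
                 bbox = bbox, params = params),
            class = "shape_spec")
}

#' @rdname shapes
#' @export
geom_disc <- function(radius) {
  stopifnot(radius > 0)
  new_shape("disc",
            function(x, y) x^2 + y^2 <= radius^2,
            area = pi * radius^2,
            bbox = c(2 * radius, 2 * radius),
            params = list(radius = radius))
}

# equilateral triangle, centroid at origin, pointing +y, rotated by
# 'orientation' degrees
triangle_inside <- function(side, orientation) {
  h_top <- side / sqrt(3)        # centroid to vertex
  h_bot <- side / (2 * sqrt(3))  # centroid to edge midpoint
  th <- -orientation * pi / 180
  function(x, y) {
    xr <- cos(th) * x - sin(th) * y
    yr <- sin(th) * x + cos(th) * y
    (yr >= -h_bot) &
      (yr <= h_top - sqrt(3) * xr) &
      (yr <= h_top + sqrt(3) * xr)
  }
}

#' @rdname shapes
#' @export
geom_triangle <- function(side, orientation = 0) {
  stopifnot(side > 0)
  new_shape("triangle", triangle_inside(side, orientation),
            area = sqrt(3) / 4 * side^2,
            bbox = c(side, side),
            params = list(side = side, orientation = orientation))
}

#' @rdname shapes
#' @export
geom_triangle_lattice <- function(side, Lx, Ly) {
  stopifnot(side > 0, Lx > 0, Ly > 0)
  tri <- triangle_inside(side, 0)
  inside <- function(x, y) {
    # full triangle at the cell centre + triangles at the four corners
    # (their quarters falling inside the cell), i.e. a centred rectangular
    # (hexagonal-like) lattice
    res <- tri(x - Lx / 2, y - Ly / 2)
    for (cx in c(0, Lx)) for (cy in c(0, Ly))
      res <- res | tri(x - cx, y - cy)
    res
  }
  new_shape("triangle_lattice", inside,
            area = 2 * sqrt(3) / 4 * side^2,  # per unit cell: 1 centre + 4 quarters
            frame = "cell", bbox = c(Lx, Ly),
            params = list(side = side, Lx = Lx, Ly = Ly))
}

#' @rdname shapes
#' @export
geom_stripe <- function(width, period) {
  stopifnot(width > 0, period >= width)
  new_shape("stripe",
            function(x, y) (y %% period) < width,
            area = NA_real_,  # infinite stripe; per-period fill = width/period
            frame = "cell", bbox = c(NA_real_, period),
            params = list(width = width, period = period))
}

#' @rdname shapes
#' @export
geom_oval <- function(length, height, tip_radius, base_radius = height / 2) {
  stopifnot(length > 0, height > 0, tip_radius > 0,
            tip_radius < base_radius, base_radius <= height / 2 + 1e-15,
            length > base_radius + tip_radius)
  rb <- base_radius; rt <- tip_radius
  xb <- -length / 2 + rb   # base-arc centre
  xt <- length / 2 - rt    # tip-arc centre
  d <- xt - xb
  sina <- (rb - rt) / d
  if (sina >= 1) stop("oval arcs admit no common external tangent")
  cosa <- sqrt(1 - sina^2)
  # tangency points (upper tangent)
  x1 <- xb + rb * sina; y1 <- rb * cosa
  x2 <- xt + rt * sina; y2 <- rt * cosa
  slope <- (y2 - y1) / (x2 - x1)
  inside <- function(x, y) {
    ((x - xb)^2 + y^2 <= rb^2) |
      ((x - xt)^2 + y^2 <= rt^2) |
      (x >= x1 & x <= x2 & abs(y) <= y1 + slope * (x - x1))
  }
  alpha <- asin(sina)
  area <- rb^2 * (pi + 2 * alpha) / 2 + rt^2 * (pi - 2 * alpha) / 2 +
    (x2 - x1) * (y1 + y2)
  new_shape("oval", inside, area = area, bbox = c(length, height),
            params = list(length = length, height = height,
                          tip_radius = rt, base_radius = rb))
}

#' Generate a synthetic saturated magnetization state
#'
#' Builds a [mag_grid()] with `M = Ms * direction` inside the shape mask and
#' zero outside: a stand-in for the near-saturated micromagnetic states of
#' soft-magnetic elements under a strong (here 20 mT scale) applied field.
#' Internal flux-closure detail of relaxed states (onion flanks, edge
#' curling, exchange-bias inhomogeneities) is deliberately not modelled.
#'
#' @param geometry a `shape_spec` from [geom_disc()], [geom_triangle()],
#'   [geom_triangle_lattice()], [geom_stripe()] or [geom_oval()].
#' @param direction unit 3-vector, the magnetization direction.
#' @param Ms saturation magnetization in A/m (e.g. `Js / mu0`).
#' @param n_cells integer 3-vector `(nx, ny, nz)`.
#' @param cell_size numeric 3-vector `(dx, dy, dz)` in metres.  For
#'   cell-frame shapes (lattice, stripe) the grid extent `n * cell` must
#'   equal the shape's unit cell along tiled axes.
#' @param thickness film thickness in metres; defaults to `nz * dz`.  The
#'   film top sits at z = 0 (the bead rolls on it), cells below.
#' @param periodic optional logical 2-vector overriding the default
#'   periodicity (cell-frame shapes default to periodic, centred shapes to
#'   isolated; an oval used as a track element wants `c(TRUE, FALSE)`).
#' @return a [mag_grid()] with the `direction` attribute set (all magnetized
#'   cells share one direction), `periodic` set for cell-frame shapes.
#' @examples
#' st <- synth_state(geom_disc(15e-6), c(1, 0, 0), Ms = 1 / MU0,
#'                   n_cells = c(64, 64, 1), cell_size = rep(32e-6 / 64, 2),
#'                   thickness = 30e-9)
#' @export
synth_state <- function(geometry, direction, Ms, n_cells, cell_size,
                        thickness = NULL, periodic = NULL) {
  if (!inherits(geometry, "shape_spec")) stop("'geometry' must be a shape_spec")
  direction <- as.numeric(direction)
  if (length(direction) != 3 || abs(sqrt(sum(direction^2)) - 1) > 1e-8)
    stop("'direction' must be a unit 3-vector")
  n_cells <- as.integer(n_cells)
  if (length(cell_size) == 2) {
    if (is.null(thickness)) stop("give 'thickness' when cell_size has no z entry")
    cell_size <- c(cell_size, thickness / max(n_cells[3], 1))
  }
  stopifnot(length(n_cells) == 3, length(cell_size) == 3)
  if (is.null(thickness)) thickness <- n_cells[3] * cell_size[3]

  ext <- n_cells * cell_size
  default_periodic <- c(FALSE, FALSE)
  if (geometry$frame == "cell") {
    origin_xy <- cell_size[1:2] / 2
    default_periodic <- c(TRUE, TRUE)
    if (geometry$kind == "stripe") {
      if (abs(ext[2] %% geometry$params$period) > 1e-12 * ext[2] &&
          abs(ext[2] %% geometry$params$period - geometry$params$period) >
            1e-12 * ext[2])
        stop("stripe grid y-extent must be a whole number of stripe periods")
    } else {
      if (!is.na(geometry$bbox[1]) && abs(ext[1] - geometry$bbox[1]) > 1e-12)
        stop("lattice grid x-extent must equal the unit cell Lx")
      if (!is.na(geometry$bbox[2]) && abs(ext[2] - geometry$bbox[2]) > 1e-12)
        stop("lattice grid y-extent must equal the unit cell Ly")
    }
  } else {
    if (any(geometry$bbox > ext[1:2] * (1 + 1e-9)))
      stop(sprintf("shape (%.3g x %.3g um) exceeds grid extent (%.3g x %.3g um)",
                   geometry$bbox[1] * 1e6, geometry$bbox[2] * 1e6,
                   ext[1] * 1e6, ext[2] * 1e6))
    origin_xy <- -ext[1:2] / 2 + cell_size[1:2] / 2
  }
  if (is.null(periodic)) periodic <- default_periodic
  # film occupies physical z in [-thickness, 0]
  origin <- c(origin_xy, -thickness + cell_size[3] / 2)

  xs <- origin[1] + (seq_len(n_cells[1]) - 1) * cell_size[1]
  ys <- origin[2] + (seq_len(n_cells[2]) - 1) * cell_size[2]
  mask <- outer(xs, ys, geometry$inside)
  M <- array(0, dim = c(n_cells, 3))
  for (k in seq_len(n_cells[3]))
    for (cc in 1:3)
      M[, , k, cc] <- mask * (Ms * direction[cc])
  mag_grid(M, cell_size, origin, Ms, periodic = periodic,
           direction = direction)
}
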