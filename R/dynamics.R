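#' Dynamic viscosity of water
#'
#' Vogel-type correlation `eta(T) = A * 10^(B / (T_K - C))` with
#' `A = 2.414e-5 Pa s`, `B = 247.8 K`, `C = 140 K`; reproduces handbook
#' values within about 1% over 0-100 degrees C (1.002e-3 Pa s at 20 C).
#'
#' @param temperature water temperature in degrees Celsius (0-100).
#' @return dynamic viscosity in Pa s.
#' @export
viscosity_water <- function(temperature) {
  if (any(temperature < 0 | temperature > 100))
    stop("viscosity_water() is defined for 0-100 degrees C")
  2.414e-5 * 10^(247.8 / (temperature + 273.15 - 140))
}

#' Stokes drag coefficient
#'
#' `Gamma_hd = 6 pi eta r_mb` (kg/s), the linear hydrodynamic damping of a
#' sphere in unbounded fluid.
#'
#' @param bead a [bead_spec()].
#' @param env an [environment_spec()].
#' @return drag coefficient in kg/s.
#' @export
drag_gamma <- function(bead, env) 6 * pi * env$eta * bead$r_mb

#' Wall correction factors for Stokes drag
#'
#' Linear near-wall corrections for a sphere of radius `r_mb` whose centre
#' sits `r_mb + z` above a plane wall: in-plane
#' `1 + 9 r / (16 (r + z))`, out-of-plane `1 + 9 r / (8 (r + z))`.
#' At contact (z = 0) these are 1.5625 and 2.125.
#'
#' @param r_mb bead radius (m).
#' @param z height above ground level (m), `z >= -r_mb/2`.
#' @return numeric 3-vector `(fx, fy, fz)` of dimensionless factors.
#' @export
wall_drag_factors <- function(r_mb, z) {
  fxy <- 1 + 9 * r_mb / (16 * (r_mb + z))
  c(fxy, fxy, 1 + 9 * r_mb / (8 * (r_mb + z)))
}

#' Effective inertial mass of the bead
#'
#' Added-mass corrected inertia
#' `m_eff = (4 pi / 3) r^3 (rho_mb + rho_water / 2)` (kg).
#'
#' @param bead a [bead_spec()].
#' @param env an [environment_spec()].
#' @return effective mass in kg.
#' @export
effective_mass <- function(bead, env) {
  bead_volume(bead) * (bead$rho_mb + env$rho_water / 2)
}

#' Dry friction force at ground contact
#'
#' Coulomb-type kinetic friction proportional to the magnetic force pressing
#' the bead onto the substrate: `F_f = -Fc * max(0, -F_mz) * v / |v|`,
#' active only at z = 0 and only while moving.  When the net magnetic
#' z-force points upward the bead is about to lift and friction vanishes;
#' there is no static-friction model (`F_f = 0` at rest).
#'
#' @param bead a [bead_spec()].
#' @param F_m magnetic force 3-vector (N).
#' @param v velocity 3-vector (m/s).
#' @param z height above ground level (m).
#' @return friction force 3-vector (N).
#' @export
friction_force <- function(bead, F_m, v, z) {
  if (z != 0 || bead$Fc == 0) return(c(0, 0, 0))
  speed <- sqrt(sum(v^2))
  if (speed == 0) return(c(0, 0, 0))
  -bead$Fc * max(0, -F_m[3]) * v / speed
}

# buoyancy-corrected weight [N], z component (negative = downward)
gravity_force_z <- function(bead, env) {
  -(bead$rho_mb - env$rho_water) * bead_volume(bead) * env$g
}

#' Integrate the bead's equation of motion
#'
#' Solves `m_eff s'' = -Gamma_hd diag(wall factors) s' + F_m + F_f (+ F_G)`
#' over `t_span`, in macro-steps of at most `max_dt` seconds.  At the start
#' of each step the force state is frozen: the active submatrix is
#' re-centred on the nearest grid node along the trajectory, and the
#' out-of-plane force from the previous evaluation decides the regime —
#' at ground level with no net upward force the in-plane 2D equation is
#' solved (z frozen, friction active); otherwise the 3D equation with
#' buoyant gravity.  A step ending below the surface is clamped to z = 0
#' with the vertical velocity zeroed.  Periodic axes accumulate unwrapped
#' coordinates.  Within each macro-step a stiff variable-order solver
#' (`deSolve::ode`, lsoda) integrates the frozen-regime equations.
#'
#' @param fit a `fitted_potential` from [fit_space()].
#' @param bead a [bead_spec()].
#' @param env an [environment_spec()].
#' @param s0 initial position 3-vector (m), grid z convention.
#' @param t_span total simulated time (s), or `c(t0, t1)`.
#' @param max_dt maximum solver macro-step (s), default 7e-4.
#' @param v0 initial velocity 3-vector (m/s).
#' @param sample_every keep every k-th macro step in the output (>= 1).
#' @param rtol,atol solver tolerances passed to `deSolve::ode`.
#' @return an object of class `bead_trajectory`: a data frame with columns
#'   `t, x, y, z, x_unwrapped, y_unwrapped, vx, vy, vz, regime` and an
#'   `events` attribute (data frame: time, event, detail) recording floor
#'   contacts, boundary wraps and submatrix hops.
#' @export
simulate_bead <- function(fit, bead, env, s0, t_span, max_dt = 7e-4,
                          v0 = c(0, 0, 0), sample_every = 1,
                          rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(fit, "fitted_potential"), length(s0) == 3)
  if (length(t_span) == 1) t_span <- c(0, t_span)
  if (max_dt <= 0) stop("'max_dt' must be > 0")
  sp <- fit$spec
  gamma <- drag_gamma(bead, env)
  meff <- effective_mass(bead, env)
  Fg <- gravity_force_z(bead, env)
  r_mb <- bead$r_mb
  Fc <- bead$Fc
  use_z <- fit$use_z

  nstep <- ceiling(diff(t_span) / max_dt)
  tgrid <- seq(t_span[1], t_span[2], length.out = nstep + 1)

  # unwrapped position; wrapping happens only inside force evaluation
  pos <- as.numeric(s0)
  vel <- as.numeric(v0)
  node <- NULL
  events <- list()
  ev <- function(t, what, detail = "") {
    events[[length(events) + 1L]] <<- data.frame(time = t, event = what,
                                                 detail = detail)
  }

  wrap_pos <- function(p) {
    w <- p
    if (sp$periodic[1]) w[1] <- wrap_coord(p[1], sp$xlim[1], sp$period[1])
    if (sp$periodic[2]) w[2] <- wrap_coord(p[2], sp$ylim[1], sp$period[2])
    w
  }

  # frozen-submatrix force evaluation (1 grid step of extrapolation grace,
  # so transient excursions past the node hull do not abort the step)
  force_at <- function(nc, t, s) {
    xi <- local_xi(fit, wrap_pos(s), nc$idx, grace = 1)
    f <- fourier_basis(t, fit$N, fit$omega)
    q <- as.vector(nc$C %*% f)
    pg <- poly_row_and_grad(xi, fit$terms)
    Fm <- -as.vector(crossprod(pg$grad, q)) / fit$scale
    if (!use_z) Fm[3] <- 0
    Fm
  }

  nkeep <- nstep %/% sample_every + 1L
  out <- matrix(NA_real_, nkeep, 10)
  krow <- 1L
  record <- function(t, p, v, regime) {
    w <- wrap_pos(p)
    out[krow, ] <<- c(t, w[1], w[2], p[3], p[1], p[2], v, regime)
    krow <<- krow + 1L
  }
  record(tgrid[1], pos, vel, NA_real_)

  prev_cell <- floor((pos[1:2] - c(sp$xlim[1], sp$ylim[1])) / sp$period)

  for (i in seq_len(nstep)) {
    t0 <- tgrid[i]; t1 <- tgrid[i + 1]
    wpos <- wrap_pos(pos)
    new_node <- nearest_node(fit, wpos, node)
    if (!is.null(node) && any(new_node != node))
      ev(t0, "hop", paste(new_node, collapse = ","))
    node <- new_node
    nc <- node_coef(fit, node[1], node[2], node[3])

    Fm0 <- force_at(nc, t0, pos)
    regime2d <- (pos[3] <= 0) && (Fm0[3] + Fg <= 0)

    if (regime2d) {
      pos[3] <- 0
      vel[3] <- 0
      z_node_plane <- pos[3]
      rhs <- function(t, y, parms) {
        s <- c(y[1], y[2], z_node_plane)
        v <- c(y[3], y[4], 0)
        Fm <- force_at(nc, t, s)
        fxy <- 1 + 9 * r_mb / (16 * r_mb)
        Ff <- c(0, 0)
        sp2 <- sqrt(v[1]^2 + v[2]^2)
        # mollified Coulomb direction v/(|v| + eps): keeps the right-hand
        # side Lipschitz when the bead stalls (eps = 1 nm/s, far below any
        # transport speed, so the friction magnitude is unaffected in motion)
        if (Fc > 0 && sp2 > 0)
          Ff <- -Fc * max(0, -Fm[3]) * v[1:2] / (sp2 + 1e-9)
        a <- (Fm[1:2] + Ff - gamma * fxy * v[1:2]) / meff
        list(c(v[1], v[2], a[1], a[2]))
      }
      sol <- deSolve::ode(y = c(pos[1], pos[2], vel[1], vel[2]),
                          times = c(t0, t1), func = rhs, parms = NULL,
                          method = "lsoda", rtol = rtol, atol = atol,
                          maxsteps = 20000)
      fin <- sol[nrow(sol), -1]
      pos <- c(fin[1], fin[2], 0)
      vel <- c(fin[3], fin[4], 0)
    } else {
      rhs <- function(t, y, parms) {
        s <- y[1:3]
        v <- y[4:6]
        Fm <- force_at(nc, t, s)
        fac <- wall_drag_factors(r_mb, max(s[3], -r_mb / 2))
        a <- (Fm + c(0, 0, Fg) - gamma * fac * v) / meff
        list(c(v, a))
      }
      sol <- deSolve::ode(y = c(pos, vel), times = c(t0, t1), func = rhs,
                          parms = NULL, method = "lsoda",
                          rtol = rtol, atol = atol, maxsteps = 20000)
      fin <- sol[nrow(sol), -1]
      pos <- fin[1:3]
      vel <- fin[4:6]
      if (pos[3] < 0) {
        pos[3] <- 0
        vel[3] <- 0
        ev(t1, "floor", "z clamped to ground level")
      }
    }

    cell <- floor((pos[1:2] - c(sp$xlim[1], sp$ylim[1])) / sp$period)
    if (any(cell != prev_cell & sp$periodic))
      ev(t1, "wrap", paste(cell - prev_cell, collapse = ","))
    prev_cell <- cell

    if (i %% sample_every == 0)
      record(t1, pos, vel, if (regime2d) 2 else 3)
  }

  out <- out[seq_len(krow - 1L), , drop = FALSE]
  traj <- data.frame(t = out[, 1], x = out[, 2], y = out[, 3], z = out[, 4],
                     x_unwrapped = out[, 5], y_unwrapped = out[, 6],
                     vx = out[, 7], vy = out[, 8], vz = out[, 9],
                     regime = out[, 10])
  attr(traj, "events") <- if (length(events)) do.call(rbind, events)
    else data.frame(time = numeric(0), event = character(0),
                    detail = character(0))
  class(traj) <- c("bead_trajectory", "data.frame")
  traj
}

#' @export
print.bead_trajectory <- function(x, ...) {
  cat(sprintf("<bead_trajectory> %d samples, t = [%.4g, %.4g] s, max z = %.3g um\n",
              nrow(x), min(x$t), max(x$t), max(x$z) * 1e6))
  invisible(x)
}
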