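#' Scenario presets
#'
#' Configuration builders for the four reference systems:
#' \describe{
#'   \item{disc}{an 8 um bead circling a 15 um-radius, 30 nm permalloy disc
#'     in a 20 mT field rotating at 0.9 Hz; shows looping and lifting above
#'     the critical frequency.}
#'   \item{triangles}{an 8 um bead stepping +y across a hexagonal lattice of
#'     15 um, 50 nm permalloy triangles under a 20 mT field switching
#'     between 30 and 150 degrees at 1 Hz (periodic boundaries).}
#'   \item{stripes}{a 2.8 um bead dragged across 10 um-wide exchange-biased
#'     permalloy stripes by a four-state field sequence
#'     (mu0 Hy 0/5 mT, mu0 Hz -2.5/+2.5 mT) at 3 Hz.}
#'   \item{ovals}{an 8 um bead transported unidirectionally along a periodic
#'     track of asymmetric FeCoSiB oval elements by a 20 mT field rotating
#'     clockwise at 1 Hz, resting between elements each turn.}
#' }
#'
#' The default ("full") profile follows the published simulation settings;
#' `coarse = TRUE` scales grid resolutions down for desk-scale runs
#' (potential grids at most 64 nodes per axis, parent grids at most 256
#' cells per axis, at most 9 z layers) while keeping every physical
#' parameter unchanged.
#'
#' @param name one of `"disc"`, `"triangles"`, `"stripes"`, `"ovals"`.
#' @param overrides named list merged over the defaults (nested lists merge
#'   recursively), e.g. `list(field = list(frequency = 2))`.
#' @param coarse use the desk-scale resolution profile.
#' @return a `scenario_config` list with elements `name`, `bead`, `env`
#'   (argument lists for [bead_spec()] / [environment_spec()]), `structure`,
#'   `parent` (synthetic-state resolution), `field`, `potential`, `fit`,
#'   `sim` and `metrics`.
#' @export
build_scenario <- function(name = c("disc", "triangles", "stripes", "ovals"),
                           overrides = list(), coarse = FALSE) {
  name <- match.arg(name)
  r8 <- 4e-6                       # 8 um diameter bead
  base <- list(
    name = name,
    bead = list(radius = r8, chi = 0.0256, density = 1050, friction = 0.03),
    env = list(temperature = 22),
    fit = list(N = 30, sub = 3),
    sim = list(max_dt = 7e-4)
  )
  cfg <- switch(
    name,
    disc = modifyList(base, list(
      structure = list(shape = "disc", radius = 15e-6, thickness = 30e-9,
                       Js = 1.0),
      parent = list(n = if (coarse) c(128, 128, 1) else c(170, 170, 3),
                    extent = 30.6e-6),
      field = list(mode = "rotating", amplitude = 20e-3, frequency = 0.9,
                   n_states = if (coarse) 72 else 120, sense = 1,
                   start_angle = 0),
      potential = list(xlim = c(-30e-6, 30e-6), ylim = c(-30e-6, 30e-6),
                       nx = if (coarse) 64 else 200,
                       ny = if (coarse) 64 else 200,
                       z_layers = if (coarse) c(-0.2e-6, seq(0, 8e-6, length.out = 8))
                                  else c(-0.2e-6, seq(0, 8e-6, length.out = 41)),
                       periodic = c(FALSE, FALSE), images = c(0, 0)),
      fit = list(N = 30, sub = 3),
      sim = list(max_dt = 7e-4, n_periods = 6, start = c(15e-6, 0, 0)),
      metrics = list(centre = c(0, 0), structure_radius = 15e-6)
    )),
    triangles = modifyList(base, list(
      structure = list(shape = "triangle_lattice", side = 15e-6,
                       Lx = 2048 * 17.8e-9, Ly = 1024 * 20.5e-9,
                       thickness = 50e-9, Js = 1.0),
      parent = list(n = if (coarse) c(192, 96, 1) else c(512, 256, 1)),
      field = list(mode = "switching", frequency = 1, angles = c(30, 150),
                   amplitude = 20e-3),
      potential = list(xlim = c(0, 2048 * 17.8e-9), ylim = c(0, 1024 * 20.5e-9),
                       nx = if (coarse) 64 else 100,
                       ny = if (coarse) 64 else 100,
                       z_layers = if (coarse) seq(-2e-6, 12e-6, length.out = 8)
                                  else seq(-2e-6, 12e-6, length.out = 22),
                       periodic = c(TRUE, TRUE), images = c(1, 1)),
      fit = list(N = 100, sub = 3, copies = 100),
      sim = list(max_dt = 7e-4, n_periods = 4,
                 start = c(2048 * 17.8e-9 / 2,
                           1024 * 20.5e-9 / 2 + 15e-6 / sqrt(3), 0)),
      metrics = list()
    )),
    stripes = modifyList(base, list(
      bead = list(radius = 1.4e-6, chi = 0.0256, density = 1050,
                  friction = 0.03),
      structure = list(shape = "stripe", width = 10e-6, period = 12.5e-6,
                       thickness = 20e-9, Js = 1.0,
                       bias_direction = c(0, -1, 0)),
      parent = list(n = c(2, 256, 1), cell_x = 50e-9),
      field = list(mode = "switching", frequency = 3,
                   states = list(c(0, 0, -2.5e-3), c(0, 5e-3, -2.5e-3),
                                 c(0, 5e-3, 2.5e-3), c(0, 0, 2.5e-3))),
      potential = list(xlim = c(0, 100e-9), ylim = c(0, 12.5e-6),
                       nx = 4, ny = if (coarse) 64 else 100,
                       z_layers = if (coarse) seq(-0.7e-6, 4.2e-6, length.out = 8)
                                  else seq(-0.7e-6, 4.2e-6, length.out = 16),
                       periodic = c(TRUE, TRUE), images = c(300, 1)),
      fit = list(N = 50, sub = 3, copies = 50),
      sim = list(max_dt = 7e-4, n_periods = 2, start = c(50e-9, 0, 0)),
      metrics = list()
    )),
    ovals = modifyList(base, list(
      structure = list(shape = "oval", length = 26e-6, height = 21e-6,
                       tip_radius = 5e-6, base_radius = 10.5e-6,
                       thickness = 50e-9, Js = 1.5, pitch = 30e-6),
      parent = list(n = if (coarse) c(144, 96, 1) else c(256, 176, 1),
                    extent_y = 22e-6),
      field = list(mode = "rotating", amplitude = 20e-3, frequency = 1,
                   n_states = 180, sense = -1, start_angle = 0),
      potential = list(xlim = c(-15e-6, 15e-6), ylim = c(-13e-6, 13e-6),
                       nx = if (coarse) 64 else 125,
                       ny = if (coarse) 48 else 125,
                       z_layers = seq(-2e-6, 8e-6, length.out = 6),
                       periodic = c(TRUE, FALSE), images = c(1, 0)),
      fit = list(N = 30, sub = 3),
      sim = list(max_dt = 7e-4, n_periods = if (coarse) 3 else 7,
                 start = c(-15e-6, 0, 0)),
      metrics = list(speed_floor = 1e-6, min_rest = 0.02)
    ))
  )
  cfg$coarse <- coarse
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s%s: bead r = %g um, f = %g Hz\n",
              x$name, if (isTRUE(x$coarse)) " (coarse)" else "",
              x$bead$radius * 1e6, x$field$frequency))
  invisible(x)
}

# build the field_sequence of a scenario config
scenario_field <- function(cfg) {
  f <- cfg$field
  if (f$mode == "rotating") {
    field_sequence("rotating", amplitude = f$amplitude,
                   frequency = f$frequency, n_states = f$n_states,
                   start_angle = f$start_angle, sense = f$sense)
  } else {
    states <- f$states
    if (is.null(states)) {
      th <- f$angles * pi / 180
      states <- lapply(th, function(a) f$amplitude * c(cos(a), sin(a), 0))
    }
    field_sequence("switching", frequency = f$frequency, states = states)
  }
}

# build the synthetic parent magnetization grid of a scenario config
scenario_grid <- function(cfg, field) {
  st <- cfg$structure
  Ms <- st$Js / MU0
  H1 <- field$H[[1]]
  d1 <- if (sqrt(sum(H1^2)) > 0) H1 / sqrt(sum(H1^2)) else c(1, 0, 0)
  switch(
    cfg$name,
    disc = {
      n <- cfg$parent$n
      cell_xy <- cfg$parent$extent / n[1]
      synth_state(geom_disc(st$radius), d1, Ms, n,
                  c(cell_xy, cell_xy, st$thickness / n[3]))
    },
    triangles = {
      n <- cfg$parent$n
      synth_state(geom_triangle_lattice(st$side, st$Lx, st$Ly), d1, Ms, n,
                  c(st$Lx / n[1], st$Ly / n[2], st$thickness / n[3]))
    },
    stripes = {
      n <- cfg$parent$n
      synth_state(geom_stripe(st$width, st$period), st$bias_direction, Ms, n,
                  c(cfg$parent$cell_x, st$period / n[2], st$thickness / n[3]))
    },
    ovals = {
      n <- cfg$parent$n
      synth_state(geom_oval(st$length, st$height, st$tip_radius,
                            st$base_radius),
                  d1, Ms, n,
                  c(st$pitch / n[1], cfg$parent$extent_y / n[2],
                    st$thickness / n[3]),
                  periodic = c(TRUE, FALSE))
    })
}

#' Run a scenario end to end
#'
#' Executes the full pipeline for a [build_scenario()] configuration:
#' synthetic magnetization state, potential map over the field sequence,
#' Fourier + polynomial fit, trajectory integration and scenario metrics.
#'
#' @param cfg a `scenario_config`.
#' @param verbose print stage timings to stderr.
#' @return a list with `config`, `field`, `grid`, `map`, `fit`,
#'   `trajectory` and `metrics`.
#' @export
run_scenario <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  stage <- function(what, expr) {
    t0 <- proc.time()[3]
    res <- force(expr)
    if (verbose)
      message(sprintf("[beadscape] %-12s %6.1f s", what, proc.time()[3] - t0))
    res
  }
  bead <- do.call(bead_spec, cfg$bead)
  env <- do.call(environment_spec, cfg$env)
  field <- scenario_field(cfg)
  grid <- stage("parent", scenario_grid(cfg, field))
  pspec <- do.call(potential_grid_spec, cfg$potential)
  map <- stage("potential", potential_sequence(grid, bead, field, pspec))
  if (field$mode == "switching")
    map <- concat_states(map, cfg$fit$copies)
  fit <- stage("fit", fit_space(fit_time(map, cfg$fit$N), cfg$fit$sub))
  t_end <- cfg$sim$n_periods / cfg$field$frequency
  traj <- stage("simulate",
                simulate_bead(fit, bead, env, cfg$sim$start, t_end,
                              max_dt = cfg$sim$max_dt))
  metrics <- stage("metrics", scenario_metrics(cfg, field, bead, traj))
  list(config = cfg, field = field, grid = grid, map = map, fit = fit,
       trajectory = traj, metrics = metrics)
}

# scenario-specific trajectory metrics
scenario_metrics <- function(cfg, field, bead, traj) {
  period <- 1 / cfg$field$frequency
  out <- list(max_z = max(traj$z),
              displacement = displacement_per_period(traj, period))
  if (cfg$name == "disc") {
    out$phase_lag <- phase_lag(traj, field, cfg$metrics$centre)
    out$looping <- detect_looping(traj, cfg$metrics$centre,
                                  cfg$metrics$structure_radius, bead$r_mb)
  }
  if (cfg$name == "ovals") {
    out$rests <- detect_rests(traj, cfg$metrics$speed_floor,
                              cfg$metrics$min_rest)
  }
  out
}
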