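# Independent oracles: plain-R implementations of the physics, written from
# the defining formulas with explicit loops, deliberately not sharing code
# with the package internals.

mu0 <- 4e-7 * pi

# field of a point dipole m at displacement r (single vectors)
oracle_dipole_field <- function(m, r) {
  rn <- sqrt(sum(r^2))
  (3 * r * sum(m * r) / rn^2 - m) / (4 * pi * rn^3)
}

# brute-force reciprocity-theorem potential: naive loop over every node,
# every parent cell and every periodic image shift
oracle_potential <- function(grid, bead, H_ext, spec) {
  m <- bead$chi * H_ext * (4 / 3) * pi * bead$r_mb^3
  dV <- prod(grid$cell_size)
  shifts_x <- if (spec$periodic[1]) (-spec$images[1]:spec$images[1]) * spec$period[1] else 0
  shifts_y <- if (spec$periodic[2]) (-spec$images[2]:spec$images[2]) * spec$period[2] else 0
  U <- array(0, dim = c(spec$nx, spec$ny, spec$nz))
  n <- grid$n
  for (ix in seq_len(spec$nx)) for (iy in seq_len(spec$ny)) for (iz in seq_len(spec$nz)) {
    s <- c(spec$x[ix], spec$y[iy], spec$z_layers[iz] + bead$r_mb)
    acc <- 0
    for (sx in shifts_x) for (sy in shifts_y) {
      for (ci in seq_len(n[1])) for (cj in seq_len(n[2])) for (ck in seq_len(n[3])) {
        Mp <- grid$M[ci, cj, ck, ]
        if (all(Mp == 0)) next
        cpos <- grid$origin + (c(ci, cj, ck) - 1) * grid$cell_size + c(sx, sy, 0)
        acc <- acc + sum(Mp * oracle_dipole_field(m, cpos - s))
      }
    }
    U[ix, iy, iz] <- -2 * mu0 * acc * dV
  }
  U
}

# two-dipole interaction energy (closed form) times the reciprocity factor 2
oracle_two_dipole_U <- function(m1, m2, r) {
  rn <- sqrt(sum(r^2))
  -2 * mu0 / (4 * pi * rn^3) * (3 * sum(m1 * r) * sum(m2 * r) / rn^2 - sum(m1 * m2))
}

# truncated Fourier partial sum of a sampled periodic signal: coefficients
# by explicit rectangle-rule sums (the DFT route), reconstruction by direct
# summation -- an independent path to the least-squares fit on uniform grids
oracle_fourier_partial_sum <- function(u, times, omega, N, t_eval) {
  n <- length(u)
  a0 <- mean(u)
  val <- rep(a0, length(t_eval))
  for (k in seq_len(N)) {
    ck <- cos(k * omega * times)
    sk <- sin(k * omega * times)
    ak <- sum(u * ck) / sum(ck^2)
    bk <- if (sum(sk^2) > 1e-12 * n) sum(u * sk) / sum(sk^2) else 0
    val <- val + ak * cos(k * omega * t_eval) + bk * sin(k * omega * t_eval)
  }
  val
}

# random magnetization grid with |M| <= Ms
random_grid <- function(n, cell = c(1e-7, 1e-7, 5e-8), origin = NULL,
                        Ms = 4e5, seed = 1, periodic = c(FALSE, FALSE)) {
  set.seed(seed)
  M <- array(stats::runif(prod(n) * 3, -1, 1), dim = c(n, 3))
  nrm <- sqrt(M[, , , 1]^2 + M[, , , 2]^2 + M[, , , 3]^2)
  for (cc in 1:3) M[, , , cc] <- M[, , , cc] / pmax(nrm, 1e-12) * Ms * 0.9
  if (is.null(origin)) origin <- -(n - 1) / 2 * cell
  mag_grid(M, cell, origin, Ms, periodic = periodic)
}

# analytic quadratic landscape wrapped as a potential_map (static)
quadratic_map <- function(kx = 2, ky = 3, kz = -1, kxy = 1,
                          nx = 9, ny = 9, nz = 5, L = 8e-6) {
  spec <- potential_grid_spec(c(-L, L), c(-L, L), nx, ny,
                              seq(-L / 4, L / 4, length.out = nz))
  U <- array(0, dim = c(nx, ny, nz))
  for (iz in seq_len(nz)) {
    z <- spec$z_layers[iz]
    U[, , iz] <- outer(spec$x, spec$y, function(x, y)
      kx * x^2 + ky * y^2 + kz * z^2 + kxy * x * y)
  }
  list(map = potential_map(U, spec),
       U_fun = function(s) kx * s[1]^2 + ky * s[2]^2 + kz * s[3]^2 + kxy * s[1] * s[2],
       F_fun = function(s) -c(2 * kx * s[1] + kxy * s[2],
                              2 * ky * s[2] + kxy * s[1],
                              2 * kz * s[3]),
       spec = spec)
}
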