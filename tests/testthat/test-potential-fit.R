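# Fourier (time) + local polynomial (space) fitting and evaluation

test_that("a constant-in-time map fits to a pure DC coefficient", {
  qm <- quadratic_map()
  U <- qm$map$U
  map <- potential_map(array(rep(as.vector(U), 5), c(dim(U)[1:3], 5)),
                       qm$spec, times = (0:4) / 5, omega = 2 * pi)
  tf <- fit_time(map, 2)
  expect_equal(tf$coef[, , , 1], U[, , , 1], tolerance = 1e-12)
  a0 <- max(abs(tf$coef[, , , 1]))
  expect_lt(max(abs(tf$coef[, , , 2:5])), 1e-12 * a0)
})

test_that("cos(wt) sampled at 180 states fits with a1 = 1 at order 30", {
  qm <- quadratic_map(nx = 5, ny = 5, nz = 3)
  U <- qm$map$U[, , , 1]
  times <- (0:179) / 180
  arr <- array(rep(as.vector(U), 180), c(dim(U), 180)) *
    rep(cos(2 * pi * times), each = length(U))
  map <- potential_map(arr, qm$spec, times = times, omega = 2 * pi)
  tf <- fit_time(map, 30)
  expect_equal(tf$coef[, , , 2], U, tolerance = 1e-10)        # a1
  others <- tf$coef[, , , -2]
  expect_lt(max(abs(others)), 1e-10 * max(abs(U)))
})

test_that("square-wave concatenation fit matches the partial-sum oracle", {
  # 2 states x 100 copies, order 30 (oversampled: LS equals the DFT route)
  n <- 200
  times <- (0:(n - 1)) / n
  u <- ifelse(times < 0.5, 1, -1)          # square wave, per node scaled
  qm <- quadratic_map(nx = 5, ny = 5, nz = 3)
  U <- qm$map$U[, , , 1]
  arr <- array(rep(as.vector(U), n), c(dim(U), n)) * rep(u, each = length(U))
  map <- potential_map(arr, qm$spec, times = times, omega = 2 * pi)
  for (N in c(30, 100)) {
    tf <- fit_time(map, N)
    node <- c(3, 3, 2)
    recon <- sapply(times, function(t)
      sum(tf$coef[node[1], node[2], node[3], ] * fourier_basis(t, N, 2 * pi)))
    oracle <- oracle_fourier_partial_sum(u * U[node[1], node[2], node[3]],
                                         times, 2 * pi, N, times)
    expect_equal(recon, oracle, tolerance = 1e-9)
    # the truncation (Gibbs) residual is the same along both routes
    expect_equal(max(abs(recon - u * U[node[1], node[2], node[3]])),
                 max(abs(oracle - u * U[node[1], node[2], node[3]])),
                 tolerance = 1e-9)
  }
})

test_that("too few samples for the requested order is a rank error", {
  qm <- quadratic_map(nx = 5, ny = 5, nz = 3)
  U <- qm$map$U[, , , 1]
  times <- (0:9) / 10
  arr <- array(rep(as.vector(U), 10), c(dim(U), 10))
  map <- potential_map(arr, qm$spec, times = times, omega = 2 * pi)
  expect_error(fit_time(map, 8), "rank error")
  expect_silent(tf <- fit_time(map, 5))   # 2N = n: Nyquist sine dropped
})

test_that("a map in the polynomial basis span is recovered exactly", {
  qm <- quadratic_map(kx = 2, ky = 3, kz = -1, kxy = 1)
  fit <- fit_space(fit_time(qm$map, 0), 3)
  set.seed(42)
  for (q in 1:20) {
    s <- c(runif(1, -6e-6, 6e-6), runif(1, -6e-6, 6e-6), runif(1, -1.5e-6, 1.5e-6))
    expect_equal(eval_U(fit, 0, s), qm$U_fun(s),
                 tolerance = 1e-10)
    expect_equal(eval_force(fit, 0, s), qm$F_fun(s), tolerance = 1e-10)
  }
  # stored residual of a visited submatrix is at numerical zero
  key <- ls(fit$cache)[1]
  expect_lt(fit$cache[[key]]$resid, 1e-12 * diff(range(qm$map$U)))
})

test_that("constant maps fit with only the constant coefficient", {
  spec <- potential_grid_spec(c(0, 4e-6), c(0, 4e-6), 5, 5, c(0, 1e-6, 2e-6))
  map <- potential_map(array(7.5e-18, c(5, 5, 3, 1)), spec)
  fit <- fit_space(fit_time(map, 0), 3)
  nc <- beadscape:::node_coef(fit, 3, 3, 2)
  expect_equal(nc$C[1, 1], 7.5e-18)
  expect_lt(max(abs(nc$C[-1, 1])), 1e-12 * 7.5e-18)
  expect_equal(eval_force(fit, 0, c(2e-6, 2e-6, 1e-6)), c(0, 0, 0),
               tolerance = 1e-27)
})

test_that("out-of-span maps leave a residual that shrinks on refinement", {
  mk <- function(nx) {
    spec <- potential_grid_spec(c(-4e-6, 4e-6), c(-4e-6, 4e-6), nx, nx,
                                c(-1e-6, 0, 1e-6))
    U <- array(0, c(nx, nx, 3))
    for (iz in 1:3) U[, , iz] <- outer(spec$x, spec$y, function(x, y) (x / 1e-6)^3)
    fit <- fit_space(fit_time(potential_map(U, spec), 0), 3)
    ic <- (nx + 1) %/% 2
    beadscape:::node_coef(fit, ic, ic, 2)$resid
  }
  r_coarse <- mk(9)
  r_fine <- mk(17)
  expect_gt(r_coarse, 0)
  expect_lt(r_fine, r_coarse)
})

test_that("eval_force matches central finite differences at random points", {
  qm <- quadratic_map(kx = 1.5, ky = -2, kz = 0.7, kxy = 0.3)
  # add a cubic component so the landscape is not exactly in span
  spec <- qm$spec
  U <- qm$map$U
  for (iz in seq_len(spec$nz))
    U[, , iz, 1] <- U[, , iz, 1] +
      outer(spec$x, spec$y, function(x, y) 5e11 * x^3 + 2e11 * x * y^2)
  fit <- fit_space(fit_time(potential_map(U, spec), 0), 3)
  set.seed(7)
  h <- diff(spec$x[1:2]) / 100
  nbad <- 0
  ok_pts <- 0
  while (ok_pts < 100) {
    s <- c(runif(1, -5e-6, 5e-6), runif(1, -5e-6, 5e-6), runif(1, -1e-6, 1e-6))
    # keep points whose +-h stencil stays inside one submatrix (the fit is
    # piecewise polynomial; finite differences across a hop are meaningless)
    nodes <- apply(rbind(s, s + c(h, 0, 0), s - c(h, 0, 0), s + c(0, h, 0),
                         s - c(0, h, 0), s + c(0, 0, h), s - c(0, 0, h)), 1,
                   function(p) paste(beadscape:::nearest_node(fit, p),
                                     collapse = ","))
    if (length(unique(nodes)) > 1) next
    ok_pts <- ok_pts + 1
    Fa <- eval_force(fit, 0, s)
    fd <- sapply(1:3, function(ax) {
      e <- c(0, 0, 0); e[ax] <- h
      -(eval_U(fit, 0, s + e) - eval_U(fit, 0, s - e)) / (2 * h)
    })
    if (max(abs(fd - Fa)) > 1e-6 * max(abs(Fa), 1e-30)) nbad <- nbad + 1
  }
  expect_equal(nbad, 0)
})

test_that("periodic axes wrap exactly and seams are consistent", {
  nx <- 8
  spec <- potential_grid_spec(c(0, 8e-6), c(0, 8e-6), nx, nx, c(0, 1e-6, 2e-6),
                              periodic = c(TRUE, TRUE))
  # periodic band-limited landscape: sin(2 pi x / L) * cos(2 pi y / L)
  L <- 8e-6
  U <- array(0, c(nx, nx, 3))
  for (iz in 1:3)
    U[, , iz] <- outer(spec$x, spec$y, function(x, y)
      1e-18 * sin(2 * pi * x / L) * cos(2 * pi * y / L)) * iz
  fit <- fit_space(fit_time(potential_map(U, spec), 0), 3)
  for (delta in c(0.3e-6, 1.7e-6)) {
    # wrap-consistent up to one ulp of the coordinate arithmetic
    expect_equal(eval_U(fit, 0, c(L + delta, 2e-6, 1e-6)),
                 eval_U(fit, 0, c(delta, 2e-6, 1e-6)), tolerance = 1e-12)
    expect_equal(eval_U(fit, 0, c(2e-6, -delta, 1e-6)),
                 eval_U(fit, 0, c(2e-6, L - delta, 1e-6)), tolerance = 1e-12)
  }
  # adjacent submatrices agree at their shared boundary within 2x residual
  r1 <- beadscape:::node_coef(fit, 2, 3, 2)
  r2 <- beadscape:::node_coef(fit, 3, 3, 2)
  mid <- c((spec$x[2] + spec$x[3]) / 2, spec$y[3], 1e-6)
  u_from <- function(nc) {
    xi <- beadscape:::local_xi(fit, mid, nc$idx)
    pg <- beadscape:::poly_row_and_grad(xi, fit$terms)
    sum(pg$p * (nc$C %*% fourier_basis(0, fit$N, fit$omega)))
  }
  expect_lt(abs(u_from(r1) - u_from(r2)),
            2 * max(r1$resid, r2$resid) + 1e-30)
})

test_that("positions outside a non-periodic extent raise a domain error", {
  qm <- quadratic_map()
  fit <- fit_space(fit_time(qm$map, 0), 3)
  expect_error(eval_U(fit, 0, c(9e-6, 0, 0)), "domain error")
})

test_that("band-limited time x space signals are reproduced to 1e-9", {
  # U(t, s) = (a + b x^2)(1 + cos wt + 0.5 sin 2wt), N = 3
  nx <- 7
  spec <- potential_grid_spec(c(-3e-6, 3e-6), c(-3e-6, 3e-6), nx, nx,
                              c(-1e-6, 0, 1e-6))
  n <- 16
  times <- (0:(n - 1)) / n
  g_t <- 1 + cos(2 * pi * times) + 0.5 * sin(4 * pi * times)
  Us <- outer(spec$x, spec$y, function(x, y) 1e-18 + 3e-7 * x^2)
  arr <- array(0, c(nx, nx, 3, n))
  for (j in seq_len(n)) for (iz in 1:3) arr[, , iz, j] <- Us * g_t[j]
  fit <- fit_space(fit_time(potential_map(arr, spec, times = times), 3), 3)
  set.seed(11)
  for (q in 1:10) {
    s <- c(runif(1, -2.5e-6, 2.5e-6), runif(1, -2.5e-6, 2.5e-6), 0)
    t <- runif(1)
    truth <- (1e-18 + 3e-7 * s[1]^2) *
      (1 + cos(2 * pi * t) + 0.5 * sin(4 * pi * t))
    expect_equal(eval_U(fit, t, s), truth, tolerance = 1e-9)
  }
})
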