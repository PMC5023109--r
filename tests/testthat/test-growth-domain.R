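test_that("ellipse meshes have the right area, orientation and markers", {
  m <- make_ellipse_mesh(20, 20, n_rings = 12)
  expect_lt(abs(m$area - pi * 400) / (pi * 400), 0.01)
  expect_true(all(m$areas > 0))
  expect_true(all(m$quality > 0.3))
  expect_equal(m$L_AP, 40)
  # refinement strictly reduces the polygonal area error
  errs <- vapply(c(6, 12, 24), function(nr)
    abs(make_ellipse_mesh(20, 20, n_rings = nr)$area - pi * 400), numeric(1))
  expect_true(all(diff(errs) < 0))
  # posterior margin markers exist and stay within the posterior 20%
  me <- make_ellipse_mesh(50, 35, n_rings = 8)
  pm <- posterior_margin_edges(me, 0.2)
  expect_gt(nrow(pm), 0)
  xm <- (me$nodes[pm[, 1], 1] + me$nodes[pm[, 2], 1]) / 2 - me$x_pole
  expect_true(all(xm <= 0.2 * me$L_AP))
  expect_error(make_ellipse_mesh(-1, 2, n_rings = 4), "positive")
})

test_that("growth source is gated by the progenitor field and decays with PL", {
  p <- eye_disc_parameters()
  Pi <- c(0, 1, 1)
  expect_equal(growth_source(Pi, 0, p), c(0, p$k0, p$k0))
  # half-decay length of the growth rate: ln2 / delta_PL
  PL_half <- log(2) / p$delta_PL
  expect_equal(growth_source(1, PL_half, p), p$k0 / 2)
  expect_error(growth_source(Pi, -1, p), "PL")
})

test_that("mesh motion: rigid translation, dilation consistency, inversion", {
  m <- make_ellipse_mesh(20, 15, n_rings = 6)
  n <- nrow(m$nodes)
  # zero velocity: unchanged
  m0 <- advance_domain(m, matrix(0, n, 2), 100)
  expect_equal(m0$nodes, m$nodes)
  # uniform velocity: rigid translation, area unchanged
  mt <- advance_domain(m, cbind(rep(1e-3, n), rep(-2e-3, n)), 100)
  expect_equal(mt$area, m$area, tolerance = 1e-12)
  expect_equal(mt$L_AP, m$L_AP, tolerance = 1e-12)
  # uniform source via its dilation field u = S x / 2:
  # one step changes area by S dt + O(dt^2)
  S <- 1e-4; dt <- 50
  md <- advance_domain(m, 0.5 * S * m$nodes, dt)
  expect_equal(md$area / m$area, 1 + S * dt, tolerance = (S * dt)^2)
  # an inverting motion (x-reflection) signals the dedicated condition
  u_bad <- cbind(-m$nodes[, 1] / 5, 0 * m$nodes[, 2])
  expect_error(advance_domain(m, u_bad, 10), class = "eyedisc_inversion")
  expect_error(advance_domain(m, matrix(0, n, 2), -1), "dt")
})

test_that("Stokes velocity solves the prescribed-divergence problem", {
  p <- eye_disc_parameters()
  # uniform source on a disc: radial flow with boundary speed S R / 2
  R <- 20; S <- 1e-4
  m <- make_ellipse_mesh(R, R, n_rings = 10)
  v <- solve_velocity(m, rep(S, nrow(m$nodes)), p)
  expect_lt(v$div_residual, 1e-6)
  bn <- m$boundary
  ur <- rowSums(v$u[bn, ] * m$nodes[bn, ]) / sqrt(rowSums(m$nodes[bn, ]^2))
  expect_equal(mean(ur), S * R / 2, tolerance = 0.02)
  # zero source: no flow
  v0 <- solve_velocity(m, rep(0, nrow(m$nodes)), p)
  expect_lt(max(abs(v0$u)), 1e-12)
  # uniform source on an ellipse: isotropic dilation, centroid ratio 1
  me <- make_ellipse_mesh(50, 35, n_rings = 10)
  ve <- solve_velocity(me, rep(S, nrow(me$nodes)), p)
  g <- velocity_gradient_at(me, ve$u, c(0, 0), 10)
  expect_equal(unname(g[2] / g[1]), 1, tolerance = 0.05)
})

test_that("boundary speed of a radial parabolic source converges with refinement", {
  # S(r) = S0 (1 - r^2/R^2): by mass conservation the radial flow is
  # u_r = S0 (r/2 - r^3/(4 R^2)), so the boundary speed is S0 R / 4
  p <- eye_disc_parameters()
  R <- 20; S0 <- 1e-4
  err <- vapply(c(6, 12), function(nr) {
    m <- make_ellipse_mesh(R, R, n_rings = nr)
    r2 <- rowSums(m$nodes^2)
    v <- solve_velocity(m, S0 * (1 - r2 / R^2), p)
    bn <- m$boundary
    ur <- rowSums(v$u[bn, ] * m$nodes[bn, ]) / sqrt(rowSums(m$nodes[bn, ]^2))
    abs(mean(ur) - S0 * R / 4)
  }, numeric(1))
  expect_lt(err[2], err[1] / 1.8)   # at least ~first order in edge length
})

test_that("remeshing preserves the domain and transfers fields faithfully", {
  m <- make_ellipse_mesh(50, 35, n_rings = 8)
  lin <- 0.3 + 0.01 * m$nodes[, 1] - 0.02 * m$nodes[, 2]
  rf <- remesh_domain(m, list(f = lin))
  # boundary-preserving: area changes below 0.1%
  expect_lt(abs(rf$mesh$area - m$area) / m$area, 1e-3)
  # linear interpolation reproduces affine fields exactly
  lin_new <- 0.3 + 0.01 * rf$mesh$nodes[, 1] - 0.02 * rf$mesh$nodes[, 2]
  expect_equal(rf$fields$f, lin_new, tolerance = 1e-9)
  # constant fields are transferred exactly
  rc <- remesh_domain(m, list(g = rep(2.5, nrow(m$nodes))))
  expect_equal(rc$fields$g, rep(2.5, nrow(rc$mesh$nodes)))
  # total mass of a smooth field is conserved within 1%
  sc_old <- eyedisc:::assemble_scalar(m)
  f <- exp(-((m$nodes[, 1] - 10)^2 + m$nodes[, 2]^2) / 400)
  rf2 <- remesh_domain(m, list(f = f), target_edge = 4)
  sc_new <- eyedisc:::assemble_scalar(rf2$mesh)
  mass_old <- sum(as.numeric(sc_old$M %*% f))
  mass_new <- sum(as.numeric(sc_new$M %*% rf2$fields$f))
  expect_lt(abs(mass_new - mass_old) / mass_old, 0.01)
})

test_that("area growth tracks the source integral on a growth-only run", {
  # no reactions: S = k0 uniformly, so the area follows A' = k0 A.
  # theta_Hth is set far below the Hth level so that growth dilution
  # (conservative transport on the expanding domain) cannot reclassify
  # progenitors during the run.
  p <- eye_disc_parameters(a = 30, b = 22, n_rings = 8, k0 = 3e-5,
                           theta_Hth = 1e-3)
  r <- simulate_eye_disc(p, t_end = 12, output_every = 2, reactions = FALSE,
                         influx = FALSE)
  expect_equal(r$area_total / r$area_total[1],
               exp(p$k0 * r$time * 3600), tolerance = 0.02)
  # growth is isotropic while the source is uniform
  a_ok <- r$anisotropy[is.finite(r$anisotropy)]
  expect_true(all(abs(a_ok - 1) < 0.05))
})

test_that("snapshots round-trip through the CSV and VTK writers", {
  m <- make_ellipse_mesh(10, 8, n_rings = 3)
  snap <- list(nodes = m$nodes, tri = m$tri,
               fields = list(Hh = seq_len(nrow(m$nodes)) / 10))
  fc <- tempfile(fileext = ".csv")
  write_snapshot(snap, fc, "csv")
  back <- read.csv(fc)
  expect_equal(back$Hh, snap$fields$Hh)
  expect_equal(back$x, m$nodes[, 1])
  fv <- tempfile(fileext = ".vtk")
  write_snapshot(snap, fv, "vtk")
  lines <- readLines(fv)
  expect_true(any(grepl(sprintf("^POINTS %d float", nrow(m$nodes)), lines)))
  expect_true(any(grepl("^SCALARS Hh float 1", lines)))
})
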