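small_params <- function(...) {
  eye_disc_parameters(a = 25, b = 18, n_rings = 6, ...)
}

test_that("a single step conserves mass exactly without reactions or flux", {
  p <- small_params()
  mesh <- make_ellipse_mesh(p$a, p$b, n_rings = p$n_rings)
  st <- initial_state(p, mesh)
  # seed a smooth non-uniform field in every species
  f <- exp(-((mesh$nodes[, 1] - 5)^2 + mesh$nodes[, 2]^2) / 100)
  for (s in names(st$c)) st$c[[s]] <- 0.5 + 0.2 * f
  sc <- eyedisc:::assemble_scalar(mesh)
  mass0 <- vapply(st$c, function(cc) sum(as.numeric(sc$M %*% cc)), numeric(1))
  out <- step_eye_disc(st, mesh, 250, p, growth = FALSE, reactions = FALSE,
                       influx = FALSE)
  sc1 <- eyedisc:::assemble_scalar(out$mesh)
  mass1 <- vapply(out$state$c, function(cc) sum(as.numeric(sc1$M %*% cc)), numeric(1))
  expect_equal(unname(mass1 / mass0), rep(1, 5), tolerance = 1e-10)
  expect_error(step_eye_disc(st, mesh, 1e4, p), "maximum step")
})

test_that("mass also stays conserved per step while the domain grows", {
  p <- small_params()
  mesh <- make_ellipse_mesh(p$a, p$b, n_rings = p$n_rings)
  st <- initial_state(p, mesh)
  f <- exp(-((mesh$nodes[, 1] - 5)^2 + mesh$nodes[, 2]^2) / 100)
  for (s in names(st$c)) st$c[[s]] <- 0.5 + 0.2 * f
  sc <- eyedisc:::assemble_scalar(mesh)
  mass0 <- sum(as.numeric(sc$M %*% st$c$Hh))
  cur <- list(state = st, mesh = mesh)
  for (k in 1:5)
    cur <- step_eye_disc(cur$state, cur$mesh, 250, p, growth = TRUE,
                         reactions = FALSE, influx = FALSE)
  sc1 <- eyedisc:::assemble_scalar(cur$mesh)
  mass1 <- sum(as.numeric(sc1$M %*% cur$state$c$Hh))
  expect_gt(cur$mesh$area, mesh$area)      # the disc actually grew
  expect_equal(mass1 / mass0, 1, tolerance = 1e-8)
})

test_that("a decaying species follows the closed-form exponential in total mass", {
  p <- small_params()
  mesh <- make_ellipse_mesh(p$a, p$b, n_rings = p$n_rings)
  st <- initial_state(p, mesh)
  # Dpp decays at delta_Dpp with no source while the disc is all
  # progenitor (its production requires a furrow band)
  st$c$Dpp <- rep(0.4, nrow(mesh$nodes))
  sc <- eyedisc:::assemble_scalar(mesh)
  mass0 <- sum(as.numeric(sc$M %*% st$c$Dpp))
  dt <- 250; nstep <- 40
  cur <- list(state = st, mesh = mesh)
  for (k in seq_len(nstep))
    cur <- step_eye_disc(cur$state, cur$mesh, dt, p, growth = FALSE, influx = FALSE)
  mass1 <- sum(as.numeric(sc$M %*% cur$state$c$Dpp))
  expect_equal(mass1 / mass0, exp(-p$delta_Dpp * dt * nstep), tolerance = 1e-3)
})

test_that("furrow tracking reads the Hth threshold crossing on the midline", {
  p <- small_params()
  mesh <- make_ellipse_mesh(p$a, p$b, n_rings = p$n_rings)
  st <- initial_state(p, mesh)
  expect_equal(track_mf(st, mesh, p), 0)                   # all progenitors
  st$c$Hth <- rep(0, nrow(mesh$nodes))
  expect_equal(track_mf(st, mesh, p), mesh$L_AP)           # fully converted
  # a linear Hth ramp crossing theta mid-domain is located by interpolation
  xr <- mesh$nodes[, 1] - mesh$x_pole
  st$c$Hth <- pmin(1, pmax(0, (xr - 10) / 10))             # crosses 0.5 at x = 15
  pl <- track_mf(st, mesh, p)
  expect_equal(pl, 15, tolerance = 2.5)                    # within one bin
})

test_that("perturbation objects rescale parameters from their activation time", {
  p <- eye_disc_parameters()
  pe <- perturbation("p_Hh", "scale", 0.5, time = 20)
  expect_equal(apply_perturbation(p, pe, 10), p$p_Hh)
  expect_equal(apply_perturbation(p, pe, 25), 0.5 * p$p_Hh)
  ps <- perturbation("eta", "set", 0)
  expect_equal(apply_perturbation(p, ps, 5), 0)
  expect_error(perturbation("bogus", "scale", 2), "unknown parameter")
  expect_error(perturbation("theta_Hh", "scale", 2,
                            region = list(center_ap = 0.5, center_dv = 0, radius = 5)),
               "clone regions")
})

test_that("runs are deterministic and scale factor one is a no-op", {
  p <- small_params()
  r1 <- simulate_eye_disc(p, t_end = 3, output_every = 1)
  r2 <- simulate_eye_disc(p, t_end = 3, output_every = 1)
  expect_identical(r1$PL, r2$PL)
  expect_identical(r1$area_total, r2$area_total)
  r3 <- simulate_eye_disc(p, t_end = 3, output_every = 1,
                          perturbations = perturbation("p_Hh", "scale", 1))
  expect_equal(r3$PL, r1$PL, tolerance = 1e-12)
})

test_that("area compartments always sum to the total", {
  p <- small_params()
  r <- simulate_eye_disc(p, t_end = 6, output_every = 1)
  expect_equal(r$area_anterior + r$area_mf + r$area_posterior,
               r$area_total, tolerance = 1e-6)
  expect_equal(r$area_anterior[1], r$area_total[1])   # all progenitor at t = 0
  expect_true(all(r$PL >= 0 & r$PL <= r$L_AP + 1e-9))
  expect_true(all(diff(r$PL) > -1.0))   # irreversible up to bin noise
})

test_that("zero Hh influx precludes furrow initiation entirely", {
  p <- small_params(eta = 1e-12)
  r <- simulate_eye_disc(p, t_end = 8, output_every = 2)
  expect_true(all(r$PL == 0))
  expect_true(is.na(r$events$mf_initiation))
  expect_equal(r$area_anterior, r$area_total, tolerance = 1e-9)
})

test_that("2D engine front speed agrees with the 1D finite-difference oracle", {
  # static domain (growth off) so the two transport formulations face
  # the same problem; the oracle integrates the same reaction terms with
  # an independent discretisation
  p <- eye_disc_parameters(a = 50, b = 35, n_rings = 17)
  r <- simulate_eye_disc(p, t_end = 24, output_every = 1, growth = FALSE)
  sel <- r$time >= 8 & r$PL > 0 & r$PL < 0.93 * r$L_AP
  v2 <- fit_mf_kinetics(r$time[sel], r$PL[sel])$speed
  o <- oracle_1d_front(p, L = 100, n = 400, t_end = 24, output_every = 1)
  sel1 <- o$time >= 8 & o$front > 0 & o$front < 93
  v1 <- fit_mf_kinetics(o$time[sel1], o$front[sel1])$speed
  expect_lt(abs(v2 - v1) / v1, 0.10)
})
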