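test_that("furrow kinetics fit recovers slope and nonlinearity", {
  tt <- seq(0, 20, by = 0.5)
  k <- fit_mf_kinetics(tt, 3.4 * tt)
  expect_equal(k$speed, 3.4)
  expect_equal(k$nonlinearity, 0, tolerance = 1e-10)
  k0 <- fit_mf_kinetics(tt, rep(7, length(tt)))
  expect_equal(k0$speed, 0)
  # 3-point quadratic, by closed-form least squares: y = t^2 on {0,1,2}
  # gives slope 2, intercept -1/3, residuals (1/3, -2/3, 1/3), RMSE sqrt(2)/3
  kq <- fit_mf_kinetics(c(0, 1, 2), c(0, 1, 4))
  expect_equal(kq$speed, 2)
  expect_equal(kq$intercept, -1 / 3)
  expect_equal(kq$nonlinearity, sqrt(2) / 3)
  expect_error(fit_mf_kinetics(c(0, 1), c(0, 1)), "fewer than 3")
  # window restriction applies before fitting
  kw <- fit_mf_kinetics(tt, ifelse(tt < 10, 0, 5 * (tt - 10)), window = c(10, 20))
  expect_equal(kw$speed, 5)
})

test_that("area series reproduces the recorded compartment bookkeeping", {
  p <- eye_disc_parameters(a = 25, b = 18, n_rings = 6)
  r <- simulate_eye_disc(p, t_end = 4, output_every = 1)
  a <- area_series(r)
  expect_named(a, c("time_h", "total", "anterior", "mf", "posterior"))
  expect_equal(a$anterior + a$mf + a$posterior, a$total, tolerance = 1e-6)
  expect_equal(a$anterior[1], a$total[1])
})

test_that("AP profiles flatten uniform fields and recentre on the furrow", {
  p <- eye_disc_parameters(a = 30, b = 20, n_rings = 8)
  mesh <- make_ellipse_mesh(p$a, p$b, n_rings = p$n_rings)
  snap <- list(nodes = mesh$nodes, tri = mesh$tri, x_pole = mesh$x_pole,
               L_AP = mesh$L_AP, PL = 12,
               fields = list(Hh = rep(0.7, nrow(mesh$nodes)),
                             Dpp = exp(-(mesh$nodes[, 1] - mesh$x_pole) / 15)))
  pr <- profile_along_ap(snap, p, species = c("Hh", "Dpp"))
  expect_true(all(abs(pr$Hh - 0.7) < 1e-12))
  # furrow-relative axis: position 0 sits at the tracked furrow
  expect_lt(min(abs(pr$position_um)), 3)
  # translated fronts overlay in furrow-relative coordinates
  snap2 <- snap
  snap2$PL <- 25
  snap2$fields$Dpp <- exp(-(mesh$nodes[, 1] - mesh$x_pole - 13) / 15)
  pr2 <- profile_along_ap(snap2, p, species = "Dpp")
  xq <- seq(0, 15, by = 1)
  v1 <- approx(pr$position_um, pr$Dpp, xq)$y
  v2 <- approx(pr2$position_um, pr2$Dpp, xq)$y
  expect_lt(max(abs(v1 - v2) / max(v1)), 0.05)
})

test_that("scaling analysis distinguishes scaling from fixed-length gradients", {
  # build two synthetic snapshot families on a static mesh:
  # (i) gradients whose length scales with the anterior length overlay after
  # normalisation; (ii) fixed-length gradients widen as the domain shrinks
  p <- eye_disc_parameters(a = 60, b = 25, n_rings = 10)
  mesh <- make_ellipse_mesh(p$a, p$b, n_rings = p$n_rings)
  mk <- function(PL, lambda) {
    x <- mesh$nodes[, 1] - mesh$x_pole
    f <- exp(-pmax(x - PL, 0) / lambda)
    list(time = PL, nodes = mesh$nodes, tri = mesh$tri, x_pole = mesh$x_pole,
         L_AP = mesh$L_AP, PL = PL,
         fields = list(Dpp = f, pMad = f))
  }
  L <- mesh$L_AP
  # scaling family: lambda = 0.2 * anterior length
  r_sc <- structure(list(snapshots = list(mk(10, 0.2 * (L - 10)),
                                          mk(60, 0.2 * (L - 60))),
                         params = p), class = "eye_disc_sim")
  sc <- scaling_test(r_sc, times = c(10, 60))
  expect_equal(sc$summary$lambda_Dpp / (0.2 * sc$summary$anterior_um),
               c(1, 1), tolerance = 0.15)
  d <- merge(sc$profiles[[1]], sc$profiles[[2]], by = NULL)
  # normalised profiles overlay: compare on a common xi grid
  xi <- seq(0.05, 0.9, by = 0.05)
  p1 <- approx(sc$profiles[[1]]$xi, sc$profiles[[1]]$Dpp, xi)$y
  p2 <- approx(sc$profiles[[2]]$xi, sc$profiles[[2]]$Dpp, xi)$y
  expect_lt(sqrt(mean((p1 - p2)^2)), 0.05)

  # fixed-length family: same lambda, shrinking anterior -> normalised widening
  r_fx <- structure(list(snapshots = list(mk(10, 12), mk(60, 12)),
                         params = p), class = "eye_disc_sim")
  fx <- scaling_test(r_fx, times = c(10, 60))
  expect_equal(fx$summary$lambda_Dpp, c(12, 12), tolerance = 0.15)
  q1 <- approx(fx$profiles[[1]]$xi, fx$profiles[[1]]$Dpp, xi)$y
  q2 <- approx(fx$profiles[[2]]$xi, fx$profiles[[2]]$Dpp, xi)$y
  expect_true(all(q2 >= q1 - 1e-9))            # shorter anterior looks wider
  expect_gt(sqrt(mean((q1 - q2)^2)), 0.05)     # and clearly deviates
})

test_that("calibration with no free parameters returns the base configuration", {
  targets <- gen_target_profiles(sigma = 0)
  p <- eye_disc_parameters()
  cal <- calibrate(targets["Hth"], free = character(), params = p,
                   L = 150, n = 150, t_end = 12, profile_time = 10)
  expect_identical(cal$params, p)
  expect_true(is.finite(cal$value))
  expect_true(cal$converged)
})

test_that("calibration recovers a perturbed threshold from model-generated targets", {
  # self-consistency: targets simulated at the true theta_Hth, fit started
  # from a 30% misspecified value, must come back within 10%
  p_true <- eye_disc_parameters()
  o <- oracle_1d_front(p_true, L = 150, n = 150, t_end = 12, output_every = 2)
  k <- which.min(abs(o$time - 10))
  tg <- list(Hth = data.frame(position_um = o$x - o$front[k],
                              intensity = o$fields$Hth[k, ]))
  p_start <- eye_disc_parameters(theta_Hth = 0.65)
  cal <- calibrate(tg, free = "theta_Hth", params = p_start,
                   L = 150, n = 150, t_end = 12, profile_time = 10, maxit = 40)
  expect_lt(abs(cal$params$theta_Hth - p_true$theta_Hth) / p_true$theta_Hth, 0.1)
  # optimiser contract: the fitted residual never exceeds the starting one
  base <- calibrate(tg, free = character(), params = p_start,
                    L = 150, n = 150, t_end = 12, profile_time = 10)
  expect_lte(cal$value, base$value + 1e-12)
})

test_that("wild-type furrow-relative profiles have the measured shapes", {
  r <- wildtype_run()
  sn <- r$snapshots[[1]]                      # 20 h, mid-development
  pr <- profile_along_ap(sn, r$params, species = c("pMad", "Hth", "Eya"))
  # pMad peaks at/near the furrow
  expect_lt(abs(pr$position_um[which.max(pr$pMad)]), 15)
  # Hth is depleted at the furrow and recovers anteriorly
  at_mf <- pr$Hth[which.min(abs(pr$position_um))]
  expect_gt(mean(tail(pr$Hth, 5)), 1.5 * at_mf)
  # Eya marks the differentiated posterior and is absent far anterior
  expect_gt(mean(head(pr$Eya, 5)), 10 * mean(tail(pr$Eya, 5)) + 0.1)
})
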