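# Synthetic-data generators. Everything the estimation and analysis
# code consumes can be produced here with known ground truth: bleach-
# chase intensity pairs, confocal FRAP recovery from a finite-difference
# diffusion oracle, expression-profile targets, and a fine-grid 1D
# solution of the signalling network that is independent of the 2D
# finite-element engine.

#' Generate a bleach-chase intensity series
#'
#' Produces paired mean intensities of an unbleached and a bleached
#' region whose difference decays as d0 * exp(-delta_true * t), the
#' closed-form behaviour of a protein pool after partial photobleaching
#' under linear turnover. Noise is applied to each intensity
#' independently: multiplicative log-normal by default (detector
#' physics) or additive Gaussian.
#'
#' @param delta_true true degradation rate (s^-1).
#' @param d0 initial bleached/unbleached intensity difference.
#' @param baseline unbleached steady-state intensity.
#' @param sigma noise level (relative for `"lognormal"`, absolute for
#'   `"gaussian"`); 0 for a noiseless series.
#' @param n_points number of frames.
#' @param duration total imaging time (s). The default matches a
#'   120-minute movie with one frame every 5 minutes.
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @param noise noise model.
#' @return object of class `bleach_chase_series`: data frame with
#'   `time_s`, `unbleached`, `bleached`; ground truth in
#'   `attr(, "truth")`.
#' @export
gen_bleach_chase <- function(delta_true, d0 = 0.5, baseline = 1,
                             sigma = 0.02, n_points = 25,
                             duration = 120 * 60, seed = 1,
                             noise = c("lognormal", "gaussian")) {
  stopifnot(delta_true > 0, sigma >= 0, n_points >= 2)
  noise <- match.arg(noise)
  tt <- seq(0, duration, length.out = n_points)
  u <- rep(baseline, n_points)
  b <- baseline - d0 * exp(-delta_true * tt)
  if (sigma > 0) {
    set.seed(seed)
    if (noise == "lognormal") {
      s <- sqrt(log(1 + sigma^2))
      u <- u * exp(stats::rnorm(n_points, -s^2 / 2, s))
      b <- b * exp(stats::rnorm(n_points, -s^2 / 2, s))
    } else {
      u <- u + stats::rnorm(n_points, 0, sigma)
      b <- b + stats::rnorm(n_points, 0, sigma)
    }
  }
  structure(data.frame(time_s = tt, unbleached = u, bleached = b),
            class = c("bleach_chase_series", "data.frame"),
            truth = list(delta = delta_true, d0 = d0, baseline = baseline,
                         sigma = sigma, noise = noise, seed = seed))
}

#' Generate a confocal FRAP recovery experiment from a diffusion oracle
#'
#' Initialises a Gaussian bleach spot
#' \eqn{c(r, 0) = 1 - K\exp(-2r^2/r_e^2)} (the spot-spread convention
#' under which the half-width at 0.86 of the bleach depth equals the
#' effective radius) and evolves pure 2D diffusion with reflecting far
#' boundaries by explicit finite differences — a numerical route wholly
#' independent of the estimators it is used to test. Records the mean
#' intensity over the nominal ROI over time and the initial postbleach
#' profile along a line through the spot centre.
#'
#' @param D_true diffusion coefficient (um^2 s^-1); 0 gives no recovery.
#' @param r_n nominal (ROI) radius (um).
#' @param K bleach depth in (0, 1].
#' @param r_e effective (spread) radius of the bleach spot (um).
#' @param L side length of the square domain (um); keep >= 6 r_e so the
#'   far field stays at the prebleach level.
#' @param dx grid spacing (um); must resolve the spot.
#' @param duration recorded recovery time (s).
#' @param frame_every frame interval (s).
#' @param sigma multiplicative noise level on recorded intensities.
#' @param seed RNG seed (used only when `sigma > 0`).
#' @return object of class `frap_recovery_series`: list with `time_s`,
#'   `F` (ROI mean intensity), `profile` (data frame `position_um`,
#'   `intensity` at t = 0), and `r_n`; ground truth in `attr(, "truth")`.
#' @export
gen_frap_recovery <- function(D_true, r_n = 5, K = 0.6, r_e = 6,
                              L = 60, dx = 1, duration = 3600,
                              frame_every = 120, sigma = 0, seed = 1) {
  stopifnot(D_true >= 0, r_n > 0, K > 0, K <= 1, r_e > 0)
  if (r_n / dx < 5) stop("gen_frap_recovery: grid too coarse for the ROI")
  g <- seq(-L / 2, L / 2, by = dx)
  n <- length(g)
  xx <- matrix(g, n, n); yy <- t(xx)
  r2 <- xx^2 + yy^2
  conc <- 1 - K * exp(-2 * r2 / r_e^2)
  roi <- r2 <= r_n^2
  mid <- which.min(abs(g))
  profile <- data.frame(position_um = g, intensity = conc[, mid])
  times <- seq(0, duration, by = frame_every)
  Fv <- numeric(length(times))
  Fv[1] <- mean(conc[roi])
  if (D_true > 0) {
    dt_sub <- 0.2 * dx^2 / D_true
    k <- 1L
    t_now <- 0
    for (k in seq_along(times)[-1]) {
      n_sub <- ceiling((times[k] - t_now) / dt_sub)
      dts <- (times[k] - t_now) / n_sub
      lam <- D_true * dts / dx^2
      for (s in seq_len(n_sub)) {
        up <- conc[c(1, seq_len(n - 1)), ]; dn <- conc[c(seq_len(n)[-1], n), ]
        lf <- conc[, c(1, seq_len(n - 1))]; rt <- conc[, c(seq_len(n)[-1], n)]
        conc <- conc + lam * (up + dn + lf + rt - 4 * conc)
      }
      t_now <- times[k]
      Fv[k] <- mean(conc[roi])
    }
  } else {
    Fv[] <- Fv[1]
  }
  if (sigma > 0) {
    set.seed(seed)
    s <- sqrt(log(1 + sigma^2))
    Fv <- Fv * exp(stats::rnorm(length(Fv), -s^2 / 2, s))
    profile$intensity <- profile$intensity *
      exp(stats::rnorm(nrow(profile), -s^2 / 2, s))
  }
  structure(list(time_s = times, F = Fv, profile = profile, r_n = r_n),
            class = "frap_recovery_series",
            truth = list(D = D_true, K = K, r_e = r_e, sigma = sigma))
}

#' Generate expression-profile targets on a furrow-relative axis
#'
#' Smooth parametric profiles with the qualitative shapes of the
#' measured furrow-relative gradients: pMad peaks at the furrow and
#' decays anteriorly; Hth is low posteriorly and rises sigmoidally into
#' the anterior; Eya is high posteriorly and falls across the furrow.
#' Positions are furrow-relative (x = 0 at the furrow, positive
#' anterior).
#'
#' @param x positions (um), furrow-relative.
#' @param pmad,hth,eya named lists of shape parameters: amplitude `A`,
#'   length scale `lambda` (pMad decay), midpoint `x0` and steepness `s`
#'   (sigmoids).
#' @param sigma multiplicative noise level.
#' @param seed RNG seed.
#' @return named list of data frames (`position_um`, `intensity`).
#' @export
gen_target_profiles <- function(x = seq(-40, 60, by = 1),
                                pmad = list(A = 1, lambda = 15, post = 5),
                                hth = list(A = 1, x0 = 10, s = 4),
                                eya = list(A = 1, x0 = 5, s = 4),
                                sigma = 0, seed = 1) {
  prof <- list(
    pMad = pmad$A * ifelse(x >= 0, exp(-x / pmad$lambda), exp(x / pmad$post)),
    Hth  = hth$A / (1 + exp(-(x - hth$x0) / hth$s)),
    Eya  = eya$A / (1 + exp((x - eya$x0) / eya$s)))
  if (sigma > 0) {
    set.seed(seed)
    s <- sqrt(log(1 + sigma^2))
    prof <- lapply(prof, function(v) v * exp(stats::rnorm(length(v), -s^2 / 2, s)))
  }
  lapply(prof, function(v) data.frame(position_um = x, intensity = v))
}

#' Fine-grid 1D front oracle for the signalling network
#'
#' Solves the five-species reaction-diffusion system on a static 1D
#' anterior-posterior interval (no growth, no advection) by the method
#' of lines on a fine finite-difference grid, with the Hh margin influx
#' applied at x = 0. This is an independent numerical route to the
#' travelling differentiation front: the system is irreversibly bistable
#' and Hh/Dpp diffusion turns the threshold cascade into a wave whose
#' speed can be compared against the 2D finite-element engine.
#'
#' @param params an [eye_disc_parameters()] object (shared with the 2D
#'   engine so cross-checks cannot drift apart).
#' @param L interval length (um).
#' @param n grid points.
#' @param t_end simulated time (h).
#' @param output_every output interval (h).
#' @return list with `x` (grid, um), `time` (h), `front` (um; threshold
#'   crossing of the Hth field, the 1D analogue of the posterior
#'   length), and `fields`, a list of species matrices (time x space).
#' @export
oracle_1d_front <- function(params, L = 300, n = 400, t_end = 60,
                            output_every = 1) {
  h <- L / (n - 1)
  x <- seq(0, L, length.out = n)
  front_width <- params$D_Hh / params$delta_Hh    # ~ lambda^2
  if (sqrt(front_width) < 4 * h)
    warning("oracle_1d_front: front width is under-resolved (< 4 grid cells)")
  p <- params
  idx <- function(s) ((s - 1) * n + 1):(s * n)   # Hh, Dpp, pMad, Eya, Hth
  Dg <- c(p$D_Hh, p$D_Dpp, p$D_intra, p$D_intra, p$D_intra)
  dl <- c(p$delta_Hh, p$delta_Dpp, p$delta_pMad, p$delta_Eya, p$delta_Hth)
  rhs <- function(t, y, parms) {
    m <- matrix(y, n, 5)
    mc <- pmax(m, 0)       # the integrator may probe tiny negative values
    ind <- classify_cells(mc[, 5], mc[, 1], p, smooth = TRUE)
    sig_Dpp  <- hill_activation(mc[, 2], p$K_Dpp, p$n_Dpp)
    sig_pMad <- hill_activation(mc[, 3], p$K_pMad, p$n_pMad)
    sig_Hh   <- hill_activation(mc[, 1], p$K_Hh, p$n_Hh)
    R <- cbind(p$p_Hh * ind$Phi,
               p$p_Dpp * mc[, 1] * ind$Theta,
               p$p_pMad * sig_Dpp,
               p$p_Eya * (sig_pMad + sig_Hh),
               p$p_Hth * (1 - sig_pMad) * (1 - sig_Hh)) -
         sweep(m, 2, dl, `*`)
    lap <- (m[c(1, seq_len(n - 1)), ] - 2 * m + m[c(seq_len(n)[-1], n), ]) / h^2
    dy <- sweep(lap, 2, Dg, `*`) + R
    q <- hh_boundary_flux(0, t, L, p)
    dy[1, 1] <- dy[1, 1] + 2 * q / h
    list(as.numeric(dy))
  }
  y0 <- c(rep(0, 4 * n), rep(p$p_Hth / p$delta_Hth, n))
  times <- seq(0, t_end * 3600, by = output_every * 3600)
  sol <- deSolve::ode.1D(y = y0, times = times, func = rhs, parms = NULL,
                         nspec = 5, dimens = n, method = "lsoda")
  fields <- lapply(1:5, function(s) sol[, 1 + idx(s), drop = FALSE])
  names(fields) <- species_names
  front <- vapply(seq_along(times), function(k) {
    cH <- fields$Hth[k, ]
    below <- which(cH <= p$theta_Hth)
    if (!length(below)) return(0)
    i <- max(below)
    if (i == n) return(L)
    x[i] + (p$theta_Hth - cH[i]) / (cH[i + 1] - cH[i]) * h
  }, numeric(1))
  list(x = x, time = times / 3600, front = front, fields = fields)
}
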