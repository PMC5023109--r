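# Derived quantities of a simulation: furrow kinetics, area bookkeeping,
# anterior-posterior profiles, gradient-scaling analysis, parameter
# sensitivity, and calibration of free parameters against target
# profiles.

#' Furrow kinetics: speed and nonlinearity of the posterior length
#'
#' Ordinary least-squares line through the posterior-length series; the
#' slope is the furrow speed and the root-mean-square error of the
#' residuals quantifies how nonlinear the movement is.
#'
#' @param times times (h).
#' @param PL posterior lengths (um); use post-initiation samples.
#' @param window optional `c(t_min, t_max)` fit window (h).
#' @return object of class `mf_kinetics`: list with `speed` (um/h),
#'   `intercept` (um), `nonlinearity` (RMSE, um), `window` and `n`.
#' @export
fit_mf_kinetics <- function(times, PL, window = NULL) {
  stopifnot(length(times) == length(PL))
  keep <- is.finite(times) & is.finite(PL)
  if (!is.null(window)) keep <- keep & times >= window[1] & times <= window[2]
  t <- times[keep]; y <- PL[keep]
  if (length(t) < 3) stop("fit_mf_kinetics: fewer than 3 points in the fit window")
  fit <- stats::lm(y ~ t)
  structure(list(speed = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 nonlinearity = sqrt(mean(stats::resid(fit)^2)),
                 window = range(t), n = length(t)),
            class = "mf_kinetics")
}

#' @export
print.mf_kinetics <- function(x, ...) {
  cat(sprintf("furrow kinetics: speed %.3g um/h, RMSE %.3g um (n = %d, window %.1f-%.1f h)\n",
              x$speed, x$nonlinearity, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Area bookkeeping of a simulation
#'
#' @param result an `eye_disc_sim` from [simulate_eye_disc()].
#' @return data frame with `time_h` and total, anterior (progenitor),
#'   furrow, and posterior (differentiated) areas (um^2). The three
#'   compartments sum to the total by the indicator partition of unity.
#' @export
area_series <- function(result) {
  stopifnot(inherits(result, "eye_disc_sim"))
  data.frame(time_h = result$time,
             total = result$area_total,
             anterior = result$area_anterior,
             mf = result$area_mf,
             posterior = result$area_posterior)
}

#' Band-averaged anterior-posterior concentration profiles
#'
#' Averages nodal fields over a band around the DV midline and bins
#' them along the AP axis, optionally re-centring positions on the
#' tracked furrow so profiles from different times can be overlaid.
#'
#' @param snapshot one element of `result$snapshots` (see
#'   [simulate_eye_disc()]), or a list with `nodes`, `fields`, `x_pole`,
#'   `L_AP` and `PL`.
#' @param params an [eye_disc_parameters()] object.
#' @param species character vector of species to extract.
#' @param band band half-width (um); default two element layers.
#' @param bin bin width (um); default one element layer.
#' @param relative_to_mf if `TRUE`, positions are x - x_MF (negative =
#'   posterior to the furrow).
#' @return data frame with `position_um` and one column per species.
#' @export
profile_along_ap <- function(snapshot, params, species = c("Hh", "Dpp", "pMad", "Eya", "Hth"),
                             band = NULL, bin = NULL, relative_to_mf = TRUE) {
  nodes <- snapshot$nodes
  h <- sqrt(2 * stats::median(tri_signed_areas(nodes, snapshot$tri)))
  if (is.null(band)) band <- 2 * h
  if (is.null(bin)) bin <- h
  sel <- abs(nodes[, 2]) <= band
  if (!any(sel)) stop("profile_along_ap: empty DV band")
  x <- nodes[sel, 1] - snapshot$x_pole
  bi <- findInterval(x, seq(0, snapshot$L_AP + bin, by = bin))
  out <- data.frame(position_um = as.numeric(tapply(x, bi, mean)))
  for (s in species)
    out[[s]] <- as.numeric(tapply(snapshot$fields[[s]][sel], bi, mean))
  out <- out[order(out$position_um), , drop = FALSE]
  if (relative_to_mf) out$position_um <- out$position_um - snapshot$PL
  rownames(out) <- NULL
  out
}

# decay length of an anterior gradient. The log-linear least-squares
# fit on the 10-90% amplitude segment estimates a single-exponential
# length; when the domain length L is supplied, a reflected-boundary
# profile A cosh((L - x)/lambda) is fitted instead (zero flux at the
# anterior pole flattens the tail into a cosh, which would otherwise
# inflate the apparent length once L is only a few lambda). The two
# coincide for L >> lambda.
fit_decay_length <- function(position, value, L = NULL, lo = 0.02, hi = 0.9) {
  ok <- is.finite(value) & value > 0
  position <- position[ok]; value <- value[ok]
  if (length(value) < 3) return(list(lambda = NA_real_, warn = TRUE))
  vmax <- max(value); vmin <- min(value)
  seg <- value <= vmax * hi & value >= pmax(vmin, vmax * lo)
  if (sum(seg) < 3) seg <- rep(TRUE, length(value))
  fit <- stats::lm(log(value[seg]) ~ position[seg])
  sl <- stats::coef(fit)[[2]]
  lam0 <- if (sl < 0) -1 / sl else NA_real_
  if (is.null(L) || !is.finite(lam0))
    return(list(lambda = lam0, warn = sl >= 0))
  xs <- position[seg]; vs <- value[seg]
  # log-space residuals: fluorescence-like data carry multiplicative
  # error, and equal relative weighting keeps the tail informative
  cfit <- tryCatch(
    minpack.lm::nlsLM(log(vs) ~ log(A) + log(cosh((L - xs) / lam)),
                      start = list(A = vmax / cosh(L / lam0), lam = lam0),
                      lower = c(1e-12, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(cfit)) return(list(lambda = lam0, warn = TRUE))
  list(lambda = unname(stats::coef(cfit)["lam"]), warn = FALSE)
}

#' Gradient-scaling analysis of the anterior Dpp and pMad profiles
#'
#' Extracts the anterior (furrow-to-anterior-pole) Dpp and pMad
#' profiles at the requested times, rescales position to [0, 1] by the
#' anterior length, and fits a single-exponential decay length per
#' time. A gradient that scales with the anterior length would show a
#' decay length proportional to it; a constant decay length instead
#' makes the normalised profile widen as the anterior shrinks.
#'
#' @param result an `eye_disc_sim` run with snapshots at (or near) the
#'   requested times.
#' @param times times to analyse (h).
#' @param params parameters used for the run (defaults to
#'   `result$params`).
#' @return object of class `scaling_report`: data frame `summary` with
#'   per-time anterior length, per-species decay length lambda (um) and
#'   amplitude, plus `profiles`, a list of per-time data frames with
#'   normalised position `xi` in [0, 1] and normalised Dpp/pMad values.
#' @export
scaling_test <- function(result, times = c(20, 40, 60), params = result$params) {
  stopifnot(inherits(result, "eye_disc_sim"), length(result$snapshots) > 0)
  snap_times <- vapply(result$snapshots, `[[`, numeric(1), "time")
  rows <- NULL; profs <- list()
  for (tt in times) {
    k <- which.min(abs(snap_times - tt))
    sn <- result$snapshots[[k]]
    L_ant <- sn$L_AP - sn$PL
    if (L_ant <= 0) stop(sprintf("scaling_test: anterior region empty at t = %g h", tt))
    pr <- profile_along_ap(sn, params, species = c("Dpp", "pMad"),
                           relative_to_mf = TRUE)
    ant <- pr[pr$position_um >= 0 & pr$position_um <= L_ant, , drop = FALSE]
    if (nrow(ant) < 3) stop(sprintf("scaling_test: too few anterior bins at t = %g h", tt))
    fD <- fit_decay_length(ant$position_um, ant$Dpp, L = L_ant)
    fM <- fit_decay_length(ant$position_um, ant$pMad, L = L_ant)
    rows <- rbind(rows, data.frame(
      time_h = snap_times[k], anterior_um = L_ant,
      lambda_Dpp = fD$lambda, lambda_pMad = fM$lambda,
      amp_Dpp = max(ant$Dpp), amp_pMad = max(ant$pMad),
      fit_warning = fD$warn || fM$warn))
    profs[[as.character(tt)]] <- data.frame(
      xi = ant$position_um / L_ant,
      Dpp = ant$Dpp / max(ant$Dpp),
      pMad = ant$pMad / max(ant$pMad))
  }
  structure(list(summary = rows, profiles = profs), class = "scaling_report")
}

#' @export
print.scaling_report <- function(x, ...) {
  cat("anterior gradient scaling report\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Parameter sensitivity sweep
#'
#' Re-runs the simulation with each named parameter increased and
#' decreased by a fixed fraction (1% by default) and records the furrow
#' speed, nonlinearity and final total area, both absolute and relative
#' to the unperturbed run. "Final area" is read at growth termination,
#' the first time the relative area growth rate falls below 1%/h (the
#' last sample if the run never terminates).
#'
#' @param params base parameters.
#' @param parameters character vector of parameter names to perturb.
#' @param fraction perturbation fraction.
#' @param t_end,fit_from run length and speed-fit start (h).
#' @param ... further arguments passed to [simulate_eye_disc()].
#' @return data frame of class `sensitivity_sweep`, one row per
#'   (parameter, direction) plus a `wildtype` reference row with ratio
#'   1 by construction; failed runs carry `NA` and a note.
#' @export
sensitivity_sweep <- function(params,
                              parameters = c("p_Hh", "delta_Hh", "theta_Hh",
                                             "p_Hth", "delta_Hth", "theta_Hth",
                                             "p_Dpp", "delta_Dpp",
                                             "p_pMad", "delta_pMad"),
                              fraction = 0.01, t_end = 45, fit_from = 12, ...) {
  run_one <- function(p) {
    r <- simulate_eye_disc(p, t_end = t_end, ...)
    sel <- r$time >= fit_from & r$PL > 0 & r$PL < 0.93 * r$L_AP
    kin <- fit_mf_kinetics(r$time[sel], r$PL[sel])
    gr <- c(NA, diff(r$area_total) / diff(r$time)) / r$area_total
    term <- which(r$time > fit_from & gr < 0.01)
    list(speed = kin$speed, nonlinearity = kin$nonlinearity,
         final_area = r$area_total[if (length(term)) term[1] else length(r$area_total)])
  }
  wt <- run_one(params)
  rows <- data.frame(parameter = "wildtype", direction = 0,
                     speed = wt$speed, nonlinearity = wt$nonlinearity,
                     final_area = wt$final_area,
                     speed_ratio = 1, nonlinearity_ratio = 1, area_ratio = 1,
                     note = "")
  for (pn in parameters) for (dir in c(-1, 1)) {
    p2 <- params
    p2[[pn]] <- params[[pn]] * (1 + dir * fraction)
    res <- tryCatch(run_one(validate_parameters(p2)), error = function(e) e)
    if (inherits(res, "error")) {
      rows <- rbind(rows, data.frame(parameter = pn, direction = dir,
                                     speed = NA, nonlinearity = NA, final_area = NA,
                                     speed_ratio = NA, nonlinearity_ratio = NA,
                                     area_ratio = NA, note = conditionMessage(res)))
    } else {
      rows <- rbind(rows, data.frame(parameter = pn, direction = dir,
                                     speed = res$speed, nonlinearity = res$nonlinearity,
                                     final_area = res$final_area,
                                     speed_ratio = res$speed / wt$speed,
                                     nonlinearity_ratio = res$nonlinearity / wt$nonlinearity,
                                     area_ratio = res$final_area / wt$final_area,
                                     note = ""))
    }
  }
  class(rows) <- c("sensitivity_sweep", "data.frame")
  rows
}

#' Calibrate free parameters against target expression profiles
#'
#' Adjusts a subset of parameters so that the model's furrow-relative
#' concentration profiles match target profiles (each normalised to
#' unit maximum, since concentration units are arbitrary), optionally
#' with a penalty holding the furrow speed at a target value. Profiles
#' are computed with the fast 1D front solver ([oracle_1d_front()]),
#' which shares its reaction terms with the 2D engine.
#'
#' @param targets named list of data frames (`position_um`,
#'   `intensity`), furrow-relative, e.g. from [gen_target_profiles()];
#'   names must be species names.
#' @param free character vector of parameter names to fit (possibly
#'   empty, in which case the base residual is just evaluated).
#' @param params base parameters; fitted values start here.
#' @param profile_time time (h) at which simulated profiles are taken.
#' @param speed_target,speed_weight optional furrow-speed penalty
#'   `speed_weight * (speed/speed_target - 1)^2`.
#' @param L,n,t_end 1D solver settings (um, grid points, h).
#' @param maxit optimiser iteration budget (Nelder-Mead on log scale).
#' @return object of class `calibration`: list with `params` (fitted),
#'   `value` (final loss), `residuals` (per-species), `speed`,
#'   `converged`, and the optimiser trace length.
#' @export
calibrate <- function(targets, free = character(), params = eye_disc_parameters(),
                      profile_time = 25, speed_target = NULL, speed_weight = 1,
                      L = 250, n = 300, t_end = 30, maxit = 60) {
  stopifnot(all(names(targets) %in% species_names))
  loss_parts <- function(p) {
    o <- oracle_1d_front(p, L = L, n = n, t_end = t_end, output_every = 1)
    k <- which.min(abs(o$time - profile_time))
    front <- o$front[k]
    res <- numeric(0)
    for (s in names(targets)) {
      tg <- targets[[s]]
      sim <- o$fields[[s]][k, ]
      simv <- stats::approx(o$x - front, sim / max(sim, .Machine$double.eps),
                            xout = tg$position_um, rule = 2)$y
      tv <- tg$intensity / max(tg$intensity)
      res[s] <- mean((simv - tv)^2)
    }
    sp <- NA_real_
    if (!is.null(speed_target)) {
      late <- o$time >= t_end / 2
      sp <- unname(stats::coef(stats::lm(o$front[late] ~ o$time[late]))[2])
    }
    list(res = res, speed = sp)
  }
  build <- function(logv) {
    p2 <- params
    for (i in seq_along(free)) p2[[free[i]]] <- exp(logv[i])
    validate_parameters(p2)
  }
  objective <- function(logv) {
    p2 <- tryCatch(build(logv), error = function(e) NULL)
    if (is.null(p2)) return(1e6)
    lp <- tryCatch(loss_parts(p2), error = function(e) NULL)
    if (is.null(lp)) return(1e6)
    val <- sum(lp$res)
    if (!is.null(speed_target) && is.finite(lp$speed))
      val <- val + speed_weight * (lp$speed / speed_target - 1)^2
    val
  }
  if (length(free)) {
    start <- log(vapply(free, function(nm) params[[nm]], numeric(1)))
    base_val <- objective(start)
    opt <- stats::optim(start, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    # optimiser contract: never worse than the starting configuration
    if (opt$value <= base_val) {
      fitted <- build(opt$par); value <- opt$value; conv <- opt$convergence == 0
    } else {
      fitted <- params; value <- base_val; conv <- FALSE
    }
  } else {
    fitted <- params; value <- objective(numeric(0)); conv <- TRUE
  }
  lp <- loss_parts(fitted)
  structure(list(params = fitted, value = value, residuals = lp$res,
                 speed = lp$speed, converged = conv,
                 free = free), class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration over {%s}: loss %.4g%s\n",
              paste(x$free, collapse = ", "), x$value,
              if (x$converged) "" else " (not converged; best-so-far reported)"))
  for (s in names(x$residuals))
    cat(sprintf("  %-5s residual %.4g\n", s, x$residuals[s]))
  if (is.finite(x$speed)) cat(sprintf("  front speed %.3g um/h\n", x$speed))
  invisible(x)
}
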