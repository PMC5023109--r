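`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# Time integration of the coupled transport-reaction-growth system on
# the deforming mesh.
#
# Each step is operator-split: (i) classify cells, (ii) compute the
# growth source and solve the Stokes velocity, (iii) move the mesh with
# the tissue (Lagrangian ALE), (iv) update all species implicitly in
# diffusion with exact exponential decay and explicit production.
# Because mesh nodes travel with the material, the advection term
# div(u c) reduces to the dilution implied by the change of the mass
# matrix: M_new c_new = M_old c_old + ... conserves total mass exactly
# when reactions and boundary flux vanish.

#' Posterior length: track the morphogenetic furrow
#'
#' PL is the distance from the posterior pole to the anterior-most
#' non-progenitor tissue in a band around the DV midline. The Hth field
#' is bin-averaged along x inside the band (half-width of two element
#' layers by default: a pointwise maximum would be mesh-noise sensitive)
#' and the threshold crossing c_Hth = theta_Hth is located by linear
#' interpolation, giving a PL that varies continuously under parameter
#' changes.
#'
#' @param state a classified `field_state`.
#' @param mesh the current `growing_mesh`.
#' @param params an [eye_disc_parameters()] object.
#' @param y0 DV position of the band centre (um; 0 = midline).
#' @param band band half-width (um); default two typical element layers.
#' @return posterior length (um); 0 before furrow initiation, `L_AP`
#'   when the whole band has left the progenitor state.
#' @export
track_mf <- function(state, mesh, params, y0 = 0, band = NULL) {
  h <- sqrt(2 * stats::median(mesh$areas))
  if (is.null(band)) band <- 2 * h
  sel <- abs(mesh$nodes[, 2] - y0) <= band
  if (!any(sel)) stop("track_mf: empty DV band")
  x <- mesh$nodes[sel, 1] - mesh$x_pole
  cH <- state$c$Hth[sel]
  # bin-average along x
  br <- seq(0, mesh$L_AP + h, by = h)
  bi <- findInterval(x, br, rightmost.closed = TRUE)
  xb <- tapply(x, bi, mean)
  cb <- tapply(cH, bi, mean)
  o <- order(xb)
  xb <- as.numeric(xb[o]); cb <- as.numeric(cb[o])
  th <- params$theta_Hth
  below <- which(cb <= th)
  if (!length(below)) return(0)
  i <- max(below)
  if (i == length(cb)) return(mesh$L_AP)
  j <- i + 1L
  xs <- xb[i] + (th - cb[i]) / (cb[j] - cb[i]) * (xb[j] - xb[i])
  max(0, min(xs, mesh$L_AP))
}

#' Define a parameter perturbation (mutant or clone)
#'
#' Whole-disc perturbations rescale or set a named global parameter from
#' an activation time onwards; clone perturbations apply only inside a
#' circular tissue region that is selected at activation time and then
#' advected passively with the flow (only production and degradation
#' rates may vary clonally).
#'
#' @param param parameter name from [eye_disc_parameters()].
#' @param mode `"scale"` (multiply by `value`) or `"set"`.
#' @param value scale factor or replacement value.
#' @param time activation time (h); 0 applies from the start.
#' @param region `NULL` for whole-disc, or
#'   `list(center_ap =, center_dv =, radius =)`: AP centre as a fraction
#'   of the AP length from the posterior pole, DV centre in um, radius
#'   in um.
#' @return object of class `perturbation`.
#' @examples
#' perturbation("p_Hh", "scale", 0.5)                      # hypomorph
#' perturbation("p_Hth", "scale", 4, time = 20,
#'              region = list(center_ap = 0.6, center_dv = 0, radius = 12))
#' @export
perturbation <- function(param, mode = c("scale", "set"), value,
                         time = 0, region = NULL) {
  mode <- match.arg(mode)
  known <- names(eye_disc_parameters())
  if (!param %in% known) stop("perturbation: unknown parameter '", param, "'")
  if (!is.null(region)) {
    if (!grepl("^(p|delta)_", param))
      stop("perturbation: clone regions support production/degradation rates only")
    stopifnot(all(c("center_ap", "center_dv", "radius") %in% names(region)))
  }
  structure(list(param = param, mode = mode, value = value,
                 time = time, region = region), class = "perturbation")
}

#' Effective value of a (whole-disc) perturbed parameter
#'
#' @param params base parameters.
#' @param pert a [perturbation()] (whole-disc mode).
#' @param t current time (h).
#' @return the parameter value in force at time `t`.
#' @export
apply_perturbation <- function(params, pert, t) {
  base <- params[[pert$param]]
  if (t < pert$time) return(base)
  if (pert$mode == "scale") base * pert$value else pert$value
}

# assemble the scalar-parameter set and nodal rate multipliers in force
# at time t_h (hours)
effective_parameters <- function(params, perts, t_h, clone_fields) {
  eff <- params
  prod_mult <- list(); delta_mult <- list()
  for (i in seq_along(perts)) {
    pe <- perts[[i]]
    if (t_h < pe$time) next
    if (is.null(pe$region)) {
      eff[[pe$param]] <- apply_perturbation(params, pe, t_h)
    } else {
      cf <- clone_fields[[i]]
      if (is.null(cf)) next
      fac <- if (pe$mode == "scale") pe$value else pe$value / max(params[[pe$param]], .Machine$double.eps)
      mult <- 1 + (fac - 1) * cf
      if (grepl("^p_", pe$param)) {
        s <- sub("^p_", "", pe$param)
        prod_mult[[s]] <- if (is.null(prod_mult[[s]])) mult else prod_mult[[s]] * mult
      } else {
        s <- sub("^delta_", "", pe$param)
        delta_mult[[s]] <- if (is.null(delta_mult[[s]])) mult else delta_mult[[s]] * mult
      }
    }
  }
  list(params = eff, prod_mult = prod_mult, delta_mult = delta_mult)
}

# one operator-split step; cache carries the scalar matrices of the
# current mesh and the last velocity solution
engine_step <- function(state, mesh, params, dt, opts, cache) {
  n <- nrow(mesh$nodes)
  ind_s <- classify_cells(state$c$Hth, state$c$Hh, params, smooth = TRUE)
  if (is.null(cache$sc)) cache$sc <- assemble_scalar(mesh)

  PL <- track_mf(state, mesh, params)
  if (opts$growth) {
    S <- growth_source(ind_s$Pi, PL, params)
    if (is.null(cache$vel) || cache$step %% opts$vel_every == 0L)
      cache$vel <- solve_velocity(mesh, S, params)
    u <- cache$vel$u
  } else {
    u <- matrix(0, n, 2)
  }

  M_old <- cache$sc$M
  mesh_new <- if (opts$growth) advance_domain(mesh, u, dt) else mesh
  sc_new <- if (opts$growth) assemble_scalar(mesh_new) else cache$sc

  t_new <- state$t + dt
  cc <- state$c
  if (opts$reactions) {
    p <- params
    sig_Dpp  <- hill_activation(cc$Dpp,  p$K_Dpp,  p$n_Dpp)
    sig_pMad <- hill_activation(cc$pMad, p$K_pMad, p$n_pMad)
    sig_Hh   <- hill_activation(cc$Hh,   p$K_Hh,   p$n_Hh)
    prod <- list(
      Hh   = p$p_Hh * ind_s$Phi,
      Dpp  = p$p_Dpp * cc$Hh * ind_s$Theta,
      pMad = p$p_pMad * sig_Dpp,
      Eya  = p$p_Eya * (sig_pMad + sig_Hh),
      Hth  = p$p_Hth * (1 - sig_pMad) * (1 - sig_Hh))
    for (s in names(opts$prod_mult)) prod[[s]] <- prod[[s]] * opts$prod_mult[[s]]
    deltas <- list(Hh = p$delta_Hh, Dpp = p$delta_Dpp, pMad = p$delta_pMad,
                   Eya = p$delta_Eya, Hth = p$delta_Hth)
    for (s in names(opts$delta_mult)) deltas[[s]] <- deltas[[s]] * opts$delta_mult[[s]]
  } else {
    prod <- lapply(cc, function(z) numeric(n))
    deltas <- list(Hh = 0, Dpp = 0, pMad = 0, Eya = 0, Hth = 0)
  }
  Dcoef <- list(Hh = params$D_Hh, Dpp = params$D_Dpp, pMad = params$D_intra,
                Eya = params$D_intra, Hth = params$D_intra)

  # Hh margin influx (natural boundary condition), evaluated at midstep
  flux <- numeric(n)
  if (opts$influx && params$eta > 0) {
    tau_mid <- hh_boundary_flux(0, state$t + dt / 2, mesh_new$L_AP, params) / params$eta
    if (tau_mid > 0) {
      edges <- posterior_margin_edges(mesh_new, params$margin_fraction)
      flux <- boundary_flux_load(mesh_new, edges, params$eta * tau_mid)
    }
  }

  rhs <- matrix(0, n, 5)
  colnames(rhs) <- species_names
  for (s in species_names) {
    d <- deltas[[s]]
    if (all(d == 0)) { f <- 1; dte <- dt } else {
      f <- exp(-d * dt); dte <- (1 - f) / d
    }
    rhs[, s] <- as.numeric(M_old %*% (cc[[s]] * f)) +
                as.numeric(sc_new$M %*% (prod[[s]] * dte))
    if (s == "Hh") rhs[, s] <- rhs[, s] + flux * (if (length(dte) > 1) mean(dte) else dte)
  }
  # one factorisation per distinct diffusion coefficient (the three
  # intracellular species share D_intra and hence the system matrix)
  for (Dv in unique(unlist(Dcoef))) {
    grp <- species_names[vapply(species_names, function(s) Dcoef[[s]] == Dv, logical(1))]
    A <- sc_new$M + (dt * Dv) * sc_new$K
    sol <- Matrix::solve(A, rhs[, grp, drop = FALSE])
    for (j in seq_along(grp)) cc[[grp[j]]] <- pmax(0, as.numeric(sol[, j]))
  }

  state$c <- cc
  state$t <- t_new
  state$ind <- classify_cells(cc$Hth, cc$Hh, params, smooth = FALSE)
  cache$sc <- sc_new
  cache$step <- cache$step + 1L
  list(state = state, mesh = mesh_new, cache = cache)
}

#' Advance the model by a single time step
#'
#' One operator-split step of the coupled system (classification, growth
#' velocity, ALE mesh motion, implicit diffusion with exact decay and
#' explicit production). Mainly useful for testing and for custom
#' drivers; [simulate_eye_disc()] wraps this in a full run.
#'
#' @param state a `field_state`.
#' @param mesh a `growing_mesh`.
#' @param dt time step (s); must not exceed `params$dt`.
#' @param params an [eye_disc_parameters()] object.
#' @param growth,reactions,influx logical switches for the growth
#'   (velocity + mesh motion), reaction, and Hh-margin-influx terms.
#' @return list with the updated `state` and `mesh`.
#' @export
step_eye_disc <- function(state, mesh, dt, params,
                          growth = TRUE, reactions = TRUE, influx = TRUE) {
  if (dt > params$dt + 1e-9)
    stop("step_eye_disc: dt exceeds the configured maximum step params$dt")
  opts <- list(growth = growth, reactions = reactions, influx = influx,
               vel_every = 1L, prod_mult = list(), delta_mult = list())
  res <- engine_step(state, mesh, params, dt, opts,
                     cache = list(step = 0L, sc = NULL, vel = NULL))
  list(state = res$state, mesh = res$mesh)
}

#' Simulate eye disc development
#'
#' Runs the full coupled patterning-growth model from the pre-furrow
#' initial state to `t_end`, tracking the furrow, the area bookkeeping
#' and any requested field snapshots. The run is deterministic: no
#' randomness enters the model.
#'
#' @param params an [eye_disc_parameters()] object.
#' @param t_end end of the simulation (h).
#' @param output_every output sampling interval (h).
#' @param snapshot_times times (h) at which full field snapshots are
#'   stored (nearest step).
#' @param perturbations list of [perturbation()] objects.
#' @param growth,reactions,influx model-term switches (see
#'   [step_eye_disc()]); disabling growth yields a static domain,
#'   disabling reactions a growth-only run.
#' @param vel_every recompute the Stokes velocity every this many steps;
#'   the growth source changes on the scale of hours, so refreshing the
#'   flow every few time steps (default 6, i.e. 25 simulated minutes)
#'   leaves the trajectory essentially unchanged at a fraction of the
#'   cost. Set to 1 for a velocity solve in every step.
#' @param remesh `"auto"` (regenerate when the minimum element quality
#'   falls below `params$remesh_quality`), `"schedule"` (every
#'   `remesh_every` hours; useful when comparing runs that must share
#'   their discretisation history), or `"off"`.
#' @param remesh_every remesh interval (h) for `remesh = "schedule"`.
#' @return object of class `eye_disc_sim`: list with vectors `time`
#'   (h), `PL` (um), `L_AP`, `area_total`, `area_anterior`, `area_mf`,
#'   `area_posterior` (um^2), `anisotropy` (centroid dv/dy / du/dx
#'   ratio), an `events` list (furrow initiation, remesh times, growth
#'   termination), optional
#'   `snapshots`, and the `params` used.
#' @export
simulate_eye_disc <- function(params = eye_disc_parameters(),
                              t_end = 75, output_every = 1,
                              snapshot_times = NULL,
                              perturbations = list(),
                              growth = TRUE, reactions = TRUE, influx = TRUE,
                              vel_every = 6L,
                              remesh = c("auto", "schedule", "off"),
                              remesh_every = 10, keep_resolution = TRUE,
                              remesh_target_edge = NULL) {
  remesh <- match.arg(remesh)
  if (inherits(perturbations, "perturbation")) perturbations <- list(perturbations)
  mesh <- make_ellipse_mesh(params$a, params$b, n_rings = params$n_rings)
  target_edge <- if (!is.null(remesh_target_edge)) remesh_target_edge
    else if (keep_resolution) ((params$a + params$b) / 2) / params$n_rings
    else NULL
  state <- initial_state(params, mesh)
  dt <- params$dt
  n_steps <- ceiling(t_end * 3600 / dt)
  cache <- list(step = 0L, sc = NULL, vel = NULL)
  clone_fields <- vector("list", length(perturbations))

  out_every_steps <- max(1L, round(output_every * 3600 / dt))
  n_out <- floor(n_steps / out_every_steps) + 1L
  rec <- list(time = numeric(n_out), PL = numeric(n_out), L_AP = numeric(n_out),
              area_total = numeric(n_out), area_anterior = numeric(n_out),
              area_mf = numeric(n_out), area_posterior = numeric(n_out),
              anisotropy = rep(NA_real_, n_out))
  snaps <- list()
  events <- list(mf_initiation = NA_real_, remesh = numeric(0))
  snap_steps <- if (length(snapshot_times)) pmax(1L, round(snapshot_times * 3600 / dt)) else integer(0)
  last_remesh_t <- 0
  k_out <- 0L

  record <- function(k, state, mesh, cache) {
    sc <- cache$sc
    ones <- function(f) sum(as.numeric(sc$M %*% f))
    rec$time[k] <<- state$t / 3600
    rec$PL[k] <<- track_mf(state, mesh, params)
    rec$L_AP[k] <<- mesh$L_AP
    rec$area_total[k] <<- mesh$area
    rec$area_anterior[k] <<- ones(state$ind$Pi)
    rec$area_mf[k] <<- ones(state$ind$Theta)
    rec$area_posterior[k] <<- ones(state$ind$Phi)
    if (!is.null(cache$vel)) {
      ctr <- c(sum((mesh$nodes[mesh$tri[, 1], 1] + mesh$nodes[mesh$tri[, 2], 1] +
                    mesh$nodes[mesh$tri[, 3], 1]) / 3 * mesh$areas) / mesh$area,
               sum((mesh$nodes[mesh$tri[, 1], 2] + mesh$nodes[mesh$tri[, 2], 2] +
                    mesh$nodes[mesh$tri[, 3], 2]) / 3 * mesh$areas) / mesh$area)
      gr <- velocity_gradient_at(mesh, cache$vel$u, ctr, 0.15 * mesh$L_AP)
      rec$anisotropy[k] <<- gr[2] / gr[1]
    }
  }

  if (is.null(cache$sc)) cache$sc <- assemble_scalar(mesh)
  k_out <- 1L
  record(1L, state, mesh, cache)

  for (istep in seq_len(n_steps)) {
    t_h <- state$t / 3600
    # activate clone regions whose time has come
    for (i in seq_along(perturbations)) {
      pe <- perturbations[[i]]
      if (!is.null(pe$region) && is.null(clone_fields[[i]]) && t_h >= pe$time) {
        cx <- mesh$x_pole + pe$region$center_ap * mesh$L_AP
        cy <- pe$region$center_dv
        d2 <- (mesh$nodes[, 1] - cx)^2 + (mesh$nodes[, 2] - cy)^2
        clone_fields[[i]] <- as.numeric(d2 <= pe$region$radius^2)
      }
    }
    effp <- effective_parameters(params, perturbations, t_h, clone_fields)
    opts <- list(growth = growth, reactions = reactions, influx = influx,
                 vel_every = as.integer(vel_every),
                 prod_mult = effp$prod_mult, delta_mult = effp$delta_mult)
    res <- tryCatch(engine_step(state, mesh, effp$params, dt, opts, cache),
                    eyedisc_inversion = function(e) NULL)
    if (is.null(res)) {      # element inversion: remesh and retry the step
      live <- !vapply(clone_fields, is.null, TRUE)
      fl <- c(state$c, stats::setNames(clone_fields[live],
                                       sprintf(".clone%d", which(live))))
      rf <- remesh_domain(mesh, fl, target_edge = target_edge)
      mesh <- rf$mesh
      state$c <- rf$fields[species_names]
      for (i in which(live))
        clone_fields[[i]] <- as.numeric(rf$fields[[paste0(".clone", i)]] >= 0.5)
      state$ind <- classify_cells(state$c$Hth, state$c$Hh, params)
      cache <- list(step = cache$step, sc = assemble_scalar(mesh), vel = NULL)
      events$remesh <- c(events$remesh, t_h)
      last_remesh_t <- state$t
      res <- engine_step(state, mesh, effp$params, dt, opts, cache)
    }
    state <- res$state; mesh <- res$mesh; cache <- res$cache

    if (is.na(events$mf_initiation) && any(state$ind$Theta + state$ind$Phi > 0))
      events$mf_initiation <- state$t / 3600

    grown <- !is.null(target_edge) &&
      stats::median(mesh$areas) > 1.4 * 0.433 * target_edge^2
    do_remesh <- switch(remesh,
      auto = (min(mesh$quality) < params$remesh_quality || grown) &&
             (state$t - last_remesh_t) >= 20 * dt,
      schedule = (state$t - last_remesh_t) >= remesh_every * 3600 - 1e-6,
      off = FALSE)
    if (do_remesh) {
      fl <- state$c
      live <- !vapply(clone_fields, is.null, TRUE)
      fl <- c(fl, stats::setNames(clone_fields[live],
                                  sprintf(".clone%d", which(live))))
      rf <- remesh_domain(mesh, fl, target_edge = target_edge)
      last_remesh_t <- state$t
      if (!isTRUE(rf$skipped)) {
        mesh <- rf$mesh
        state$c <- rf$fields[species_names]
        for (i in which(live))
          clone_fields[[i]] <- as.numeric(rf$fields[[paste0(".clone", i)]] >= 0.5)
        state$ind <- classify_cells(state$c$Hth, state$c$Hh, params)
        cache$sc <- assemble_scalar(mesh)
        cache$vel <- NULL
        events$remesh <- c(events$remesh, state$t / 3600)
      }
    }

    if (istep %% out_every_steps == 0L) {
      k_out <- k_out + 1L
      record(k_out, state, mesh, cache)
    }
    si <- which(snap_steps == istep)
    if (length(si)) {
      for (j in si)
        snaps[[length(snaps) + 1L]] <- list(
          time = state$t / 3600, nodes = mesh$nodes, tri = mesh$tri,
          x_pole = mesh$x_pole, L_AP = mesh$L_AP,
          fields = state$c, ind = state$ind,
          PL = track_mf(state, mesh, params))
    }
  }

  rec <- lapply(rec, function(v) v[seq_len(k_out)])
  # growth termination: first output time with relative area growth < 1%/h
  gr <- c(NA, diff(rec$area_total) / diff(rec$time)) / rec$area_total
  term <- which(rec$time > (events$mf_initiation %||% 0) & gr < 0.01)
  events$termination <- if (length(term)) rec$time[term[1]] else NA_real_
  structure(c(rec, list(events = events, snapshots = snaps, params = params,
                        final_state = state, final_mesh = mesh)),
            class = "eye_disc_sim")
}

#' @export
print.eye_disc_sim <- function(x, ...) {
  cat(sprintf("eye_disc_sim: %d output times over %.1f h\n",
              length(x$time), max(x$time)))
  cat(sprintf("  furrow initiation: %s h; final PL %.1f um of L_AP %.1f um\n",
              format(x$events$mf_initiation, digits = 3),
              x$PL[length(x$PL)], x$L_AP[length(x$L_AP)]))
  cat(sprintf("  area %.0f -> %.0f um^2; %d remesh event(s)\n",
              x$area_total[1], x$area_total[length(x$area_total)],
              length(x$events$remesh)))
  invisible(x)
}
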