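species_names <- c("Hh", "Dpp", "pMad", "Eya", "Hth")

#' Regulatory reaction rates of the five-species network
#'
#' Evaluates, nodewise, the production minus degradation terms of the
#' signalling network:
#' \deqn{R_{Hh} = p_{Hh}\Phi - \delta_{Hh} c_{Hh}}
#' \deqn{R_{Dpp} = p_{Dpp} c_{Hh} \Theta - \delta_{Dpp} c_{Dpp}}
#' \deqn{R_{pMad} = p_{pMad}\sigma_{Dpp} - \delta_{pMad} c_{pMad}}
#' \deqn{R_{Eya} = p_{Eya}(\sigma_{pMad} + \sigma_{Hh}) - \delta_{Eya} c_{Eya}}
#' \deqn{R_{Hth} = p_{Hth}\bar\sigma_{pMad}\bar\sigma_{Hh} - \delta_{Hth} c_{Hth}}
#' where sigma are Hill activation terms ([hill_activation()]) and
#' sigma-bar their complements: Hh is made by differentiated cells, Dpp
#' by furrow cells in proportion to local Hh, pMad tracks Dpp signalling,
#' Eya responds to either pMad or Hh, and Hth production requires the
#' absence of both repressive inputs.
#'
#' @param state a `field_state` (see [initial_state()]); its indicator
#'   fields must be consistent with its concentrations (re-run
#'   [classify_cells()] after changing concentrations).
#' @param params an [eye_disc_parameters()] object.
#' @return named list of per-species nodal rate vectors.
#' @export
reaction_rates <- function(state, params) {
  cc <- state$c
  for (s in species_names)
    if (any(cc[[s]] < 0)) stop("reaction_rates: negative ", s, " concentration")
  p <- params
  sig_Dpp  <- hill_activation(cc$Dpp,  p$K_Dpp,  p$n_Dpp)
  sig_pMad <- hill_activation(cc$pMad, p$K_pMad, p$n_pMad)
  sig_Hh   <- hill_activation(cc$Hh,   p$K_Hh,   p$n_Hh)
  list(
    Hh   = p$p_Hh * state$ind$Phi - p$delta_Hh * cc$Hh,
    Dpp  = p$p_Dpp * cc$Hh * state$ind$Theta - p$delta_Dpp * cc$Dpp,
    pMad = p$p_pMad * sig_Dpp - p$delta_pMad * cc$pMad,
    Eya  = p$p_Eya * (sig_pMad + sig_Hh) - p$delta_Eya * cc$Eya,
    Hth  = p$p_Hth * (1 - sig_pMad) * (1 - sig_Hh) - p$delta_Hth * cc$Hth
  )
}

#' Initial model state on a mesh
#'
#' Before furrow initiation the whole primordium expresses Homothorax at
#' its steady state p_Hth/delta_Hth while all signalling species are
#' absent, so every node classifies as progenitor.
#'
#' @param params an [eye_disc_parameters()] object.
#' @param mesh a [make_ellipse_mesh()] mesh.
#' @param smooth use smoothed indicator fields (PDE use) or sharp ones.
#' @return object of class `field_state`: list with `c` (named list of
#'   the five nodal concentration vectors), `ind` (indicator fields
#'   `Pi`, `Theta`, `Phi`) and simulated time `t` (s).
#' @export
initial_state <- function(params, mesh, smooth = FALSE) {
  css <- params$p_Hth / params$delta_Hth
  if (css <= params$theta_Hth)
    stop("configuration rejected: Hth steady state p_Hth/delta_Hth does not ",
         "exceed theta_Hth, so no progenitor state exists at t = 0")
  n <- nrow(mesh$nodes)
  zero <- numeric(n)
  cc <- list(Hh = zero, Dpp = zero, pMad = zero, Eya = zero,
             Hth = rep(css, n))
  ind <- classify_cells(cc$Hth, cc$Hh, params, smooth = smooth)
  structure(list(c = cc, ind = ind, t = 0), class = "field_state")
}

#' Hedgehog influx through the posterior margin
#'
#' Flux density of the Hh boundary condition
#' \eqn{D_{Hh}\nabla c_{Hh}\cdot n = \eta\,\Lambda(x)\,\tau(t)}:
#' the spatial gate \eqn{\Lambda} is 1 on the posterior-most
#' `margin_fraction` (default 20%) of the current AP length and 0
#' elsewhere. The temporal gate \eqn{\tau} is 1 until `t_on`, then
#' declines linearly with slope `1/tau_ramp`, and is cut to 0 at
#' `t_off` (with the default 1 h ramp and 0.5 h shutdown window the
#' influx drops from half strength straight to zero at `t_off`); it
#' mimics the vanishing margin-to-disc Hh gradient once the disc fills
#' with Hh made by differentiated cells.
#'
#' @param x AP coordinate(s), um, measured from the posterior pole
#'   (x = 0) towards anterior.
#' @param t time (s), scalar.
#' @param L_AP current total AP length (um).
#' @param params an [eye_disc_parameters()] object.
#' @return influx density (concentration um s^-1), vectorised over `x`.
#' @export
hh_boundary_flux <- function(x, t, L_AP, params) {
  if (!is.finite(t) || t < 0) stop("hh_boundary_flux: t must be >= 0")
  if (!is.finite(L_AP) || L_AP <= 0) stop("hh_boundary_flux: L_AP must be > 0")
  lam <- as.numeric(x <= params$margin_fraction * L_AP)
  tau <- if (t < params$t_on) 1
         else if (t > params$t_off) 0
         else max(0, 1 - (t - params$t_on) / params$tau_ramp)
  params$eta * lam * tau
}
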