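#' Wild-type model parameters for the eye disc simulation
#'
#' Builds the full parameter set of the model: production and degradation
#' rates, diffusion coefficients, Hill parameters, cell-transition
#' thresholds, the Hedgehog margin-influx settings, the growth law, fluid
#' constants, domain geometry and the main numerics settings.
#'
#' Units are seconds and micrometres throughout; concentrations are in
#' arbitrary units, normalised so that the Homothorax progenitor steady
#' state p_Hth/delta_Hth equals 1 (thresholds are then fractions of the
#' maximal Hth level). Measured rates ship as defaults: the Hth
#' degradation rate (bleach-chase FRAP, 6.97e-5 s^-1), the Hh diffusion
#' coefficient (confocal FRAP, 0.033 um^2 s^-1) with the decay rate
#' implied by the 7 um Hh gradient length, the effective Dpp transport
#' parameters from the wing disc (D = 0.1 um^2 s^-1, delta = 2.5e-4
#' s^-1), a small intracellular diffusion coefficient (2.5e-4 um^2 s^-1)
#' for the nuclear species, and the exponential growth-decay constant
#' delta_PL = 0.0107 um^-1. All species share one production rate.
#' Quantities that are not fixed by measurements (Hill constants and
#' coefficients, thresholds, influx amplitude, initial growth rate,
#' initial semi-axes) default to the values obtained by calibrating the
#' model against furrow speed (3.4 um/h) and the qualitative expression
#' profile shapes; see the package vignette.
#'
#' @param ... named overrides for any parameter listed below.
#' @return object of class `eye_disc_parameters`: a validated named list.
#' @section Parameters:
#' \describe{
#'   \item{p_Hh, p_Dpp, p_pMad, p_Eya, p_Hth}{production rates. All equal
#'     by default; p_Hth = delta_Hth so the progenitor Hth level is 1.}
#'   \item{delta_Hh, delta_Dpp, delta_pMad, delta_Eya, delta_Hth}{linear
#'     degradation rates (s^-1).}
#'   \item{D_Hh, D_Dpp, D_intra}{diffusion coefficients (um^2 s^-1);
#'     `D_intra` applies to pMad, Eya and Hth.}
#'   \item{K_Hh, K_Dpp, K_pMad; n_Hh, n_Dpp, n_pMad}{Hill constants and
#'     coefficients, shared per ligand across its regulatory targets.}
#'   \item{theta_Hth, theta_Hh}{cell-transition thresholds.}
#'   \item{eta, margin_fraction, t_on, t_off, tau_ramp}{Hh boundary
#'     influx amplitude (conc um s^-1), relative AP extent of the
#'     producing margin, the start and hard stop (s) of the influx
#'     shutdown, and the ramp timescale (s) of its linear decline.}
#'   \item{k0, delta_PL}{initial area growth rate (s^-1) and its
#'     exponential decay constant with posterior length (um^-1).}
#'   \item{mu, rho}{dynamic viscosity and density of the tissue fluid
#'     (arbitrary; they only rescale pressure in the quasi-static limit).}
#'   \item{a, b}{initial ellipse semi-axes (um), AP and DV.}
#'   \item{eps_Hth, eps_Hh}{smoothing widths of the regularised Heaviside
#'     used in the PDE right-hand sides (concentration; default 1% of
#'     the corresponding threshold).}
#'   \item{dt, remesh_quality, n_rings}{maximum time step (s), minimum
#'     element quality triggering a remesh, and mesh resolution (number
#'     of concentric node rings; the element count is 6 n_rings^2).}
#' }
#' @examples
#' p <- eye_disc_parameters()
#' p$delta_Hth                       # measured Hth turnover
#' mut <- eye_disc_parameters(p_Hh = 0.5 * p$p_Hh)
#' @export
eye_disc_parameters <- function(...) {
  p_all <- 6.97e-5   # shared production rate = delta_Hth => Hth steady state 1
  def <- list(
    p_Hh = p_all, p_Dpp = p_all, p_pMad = p_all, p_Eya = p_all, p_Hth = p_all,
    delta_Hh = 6.7e-4, delta_Dpp = 2.5e-4, delta_pMad = 5e-4,
    delta_Eya = 1e-4, delta_Hth = 6.97e-5,
    D_Hh = 0.033, D_Dpp = 0.1, D_intra = 2.5e-4,
    K_Hh = 0.005, K_Dpp = 1e-3, K_pMad = 0.05,
    n_Hh = 4, n_Dpp = 4, n_pMad = 4,
    theta_Hth = 0.5, theta_Hh = 0.0415,
    eta = 2e-4, margin_fraction = 0.2,
    t_on = 10 * 3600, t_off = 10.5 * 3600, tau_ramp = 3600,
    k0 = 5.2e-5, delta_PL = 0.0107,
    mu = 1, rho = 1,
    a = 50, b = 35,
    eps_Hth = NA_real_, eps_Hh = NA_real_,
    dt = 250, remesh_quality = 0.3, n_rings = 12
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(def))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    def[names(over)] <- over
  }
  if (is.na(def$eps_Hth)) def$eps_Hth <- 0.01 * def$theta_Hth
  if (is.na(def$eps_Hh))  def$eps_Hh  <- 0.01 * def$theta_Hh
  validate_parameters(def)
}

validate_parameters <- function(p) {
  pos <- c("p_Hh", "p_Dpp", "p_pMad", "p_Eya", "p_Hth",
           "delta_Hh", "delta_Dpp", "delta_pMad", "delta_Eya", "delta_Hth",
           "D_Hh", "D_Dpp", "D_intra", "K_Hh", "K_Dpp", "K_pMad",
           "theta_Hth", "theta_Hh", "mu", "rho", "a", "b",
           "eps_Hth", "eps_Hh", "dt", "k0", "delta_PL")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single finite positive number")
  }
  for (nm in c("n_Hh", "n_Dpp", "n_pMad"))
    if (p[[nm]] < 1) stop("Hill coefficient '", nm, "' must be >= 1")
  if (!(p$margin_fraction > 0 && p$margin_fraction < 1))
    stop("margin_fraction must lie in (0, 1)")
  if (!(p$t_on < p$t_off)) stop("t_on must be earlier than t_off")
  if (p$tau_ramp <= 0) stop("tau_ramp must be > 0")
  if (p$eta < 0) stop("eta must be >= 0")
  if (p$p_Hth / p$delta_Hth <= p$theta_Hth)
    stop("p_Hth/delta_Hth must exceed theta_Hth: otherwise no progenitor ",
         "state exists at t = 0")
  if (!(p$remesh_quality > 0 && p$remesh_quality < 1))
    stop("remesh_quality must lie in (0, 1)")
  if (p$n_rings < 2 || p$n_rings != round(p$n_rings))
    stop("n_rings must be an integer >= 2")
  structure(p, class = "eye_disc_parameters")
}

#' @export
print.eye_disc_parameters <- function(x, ...) {
  cat("Eye disc model parameters (units: s, um; concentrations arbitrary)\n")
  cat(sprintf("  Hth steady state p_Hth/delta_Hth = %.3g, thresholds: theta_Hth = %.3g, theta_Hh = %.3g\n",
              x$p_Hth / x$delta_Hth, x$theta_Hth, x$theta_Hh))
  cat(sprintf("  D (um^2/s): Hh %.3g, Dpp %.3g, intracellular %.3g\n",
              x$D_Hh, x$D_Dpp, x$D_intra))
  cat(sprintf("  growth: k0 = %.3g s^-1, delta_PL = %.4g um^-1; ellipse %g x %g um\n",
              x$k0, x$delta_PL, x$a, x$b))
  invisible(x)
}

#' Read / write a parameter configuration file
#'
#' Flat key/value YAML; every field of [eye_disc_parameters()] is
#' addressable, unknown keys are rejected.
#'
#' @param path file path.
#' @return for `read_parameters`, a validated `eye_disc_parameters`
#'   object; `write_parameters` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!length(vals)) return(eye_disc_parameters())
  do.call(eye_disc_parameters, vals)
}

#' @rdname read_parameters
#' @param params an `eye_disc_parameters` object to serialise.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "eye_disc_parameters"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
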