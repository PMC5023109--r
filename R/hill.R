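#' Hill activation function
#'
#' Fraction of half-maximal activity at concentration `c` for a Hill
#' response with constant `K` (concentration of half-maximal activity)
#' and coefficient `n` (steepness).
#'
#' @param c concentration (>= 0); vectorised.
#' @param K Hill constant (> 0), same units as `c`.
#' @param n Hill coefficient (> 0, dimensionless).
#' @return values of c^n / (c^n + K^n), in [0, 1].
#' @examples
#' hill_activation(1, 1, 2)      # 0.5 at c = K
#' hill_activation(3, 1, 2)      # 9/10
#' @seealso [hill_inhibition()]
#' @export
hill_activation <- function(c, K, n) {
  if (any(!is.finite(c)) || any(c < 0))
    stop("hill_activation: concentrations must be finite and >= 0")
  if (!is.numeric(K) || any(K <= 0)) stop("hill_activation: K must be > 0")
  if (!is.numeric(n) || any(n <= 0)) stop("hill_activation: n must be > 0")
  # work on the ratio to avoid overflow for large c^n
  r <- (c / K)^n
  r / (1 + r)
}

#' Hill inhibition function
#'
#' Complement of [hill_activation()]: 1 - c^n/(c^n + K^n). Used for
#' repressive regulatory inputs.
#'
#' @inheritParams hill_activation
#' @return values in [0, 1]; 1 at c = 0, 0.5 at c = K.
#' @export
hill_inhibition <- function(c, K, n) {
  1 - hill_activation(c, K, n)
}

#' Sharp Heaviside step H(x): 0 for x <= 0, 1 for x > 0.
#' @noRd
heaviside_sharp <- function(x) as.numeric(x > 0)

#' Smoothed Heaviside step of width eps (tanh profile), used inside PDE
#' right-hand sides where a discontinuous source would destabilise the
#' implicit solver. Converges to the sharp step as eps -> 0.
#' @noRd
heaviside_smooth <- function(x, eps) 0.5 * (1 + tanh(x / eps))

#' Classify tissue into progenitor / furrow / differentiated cells
#'
#' Applies the threshold rules of the model: cells with Homothorax above
#' `theta_Hth` are proliferating progenitors (Pi); cells below it are in
#' the morphogenetic furrow (Theta) until Hedgehog exceeds `theta_Hh`,
#' after which they count as differentiated (Phi):
#' \deqn{\Pi = H(c_{Hth}-\theta_{Hth}),\quad
#'       \Theta = (1-H(c_{Hth}-\theta_{Hth}))(1-H(c_{Hh}-\theta_{Hh})),\quad
#'       \Phi = (1-H(c_{Hth}-\theta_{Hth}))H(c_{Hh}-\theta_{Hh})}
#' With the sharp Heaviside the three indicators form an exact partition
#' of unity at every node; the smoothed variant (width `eps_Hth`,
#' `eps_Hh` from `params`) preserves the partition to within the
#' smoothing tolerance and is what the PDE right-hand sides consume.
#'
#' @param c_Hth,c_Hh nodal concentration vectors of equal length.
#' @param params a [eye_disc_parameters()] object.
#' @param smooth logical; sharp step (default, for reporting) or smoothed.
#' @return list with numeric vectors `Pi`, `Theta`, `Phi`.
#' @export
classify_cells <- function(c_Hth, c_Hh, params, smooth = FALSE) {
  if (length(c_Hth) != length(c_Hh))
    stop("classify_cells: c_Hth and c_Hh live on different meshes (lengths differ)")
  if (smooth) {
    H_th <- heaviside_smooth(c_Hth - params$theta_Hth, params$eps_Hth)
    H_hh <- heaviside_smooth(c_Hh - params$theta_Hh, params$eps_Hh)
  } else {
    H_th <- heaviside_sharp(c_Hth - params$theta_Hth)
    H_hh <- heaviside_sharp(c_Hh - params$theta_Hh)
  }
  list(Pi = H_th, Theta = (1 - H_th) * (1 - H_hh), Phi = (1 - H_th) * H_hh)
}
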