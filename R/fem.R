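# Linear (P1) finite-element machinery on the triangulated domain:
# scalar mass/stiffness assembly for the transport equations and a
# stabilised P1-P1 Stokes solve for the tissue velocity.

# per-element shape-function gradients; returns list of areas and the
# 3 x 2 gradient components per element (vectorised over elements)
element_gradients <- function(mesh) {
  nd <- mesh$nodes; tr <- mesh$tri
  x <- cbind(nd[tr[, 1], 1], nd[tr[, 2], 1], nd[tr[, 3], 1])
  y <- cbind(nd[tr[, 1], 2], nd[tr[, 2], 2], nd[tr[, 3], 2])
  A <- mesh$areas
  gx <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / (2 * A)
  gy <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / (2 * A)
  list(A = A, gx = gx, gy = gy)
}

# consistent mass matrix and Laplace stiffness matrix
assemble_scalar <- function(mesh, geom = element_gradients(mesh)) {
  tr <- mesh$tri; A <- geom$A
  ii <- jj <- mm <- kk <- vector("list", 9)
  q <- 0
  for (i in 1:3) for (j in 1:3) {
    q <- q + 1
    ii[[q]] <- tr[, i]; jj[[q]] <- tr[, j]
    mm[[q]] <- A / 12 * (1 + (i == j))
    kk[[q]] <- A * (geom$gx[, i] * geom$gx[, j] + geom$gy[, i] * geom$gy[, j])
  }
  n <- nrow(mesh$nodes)
  i <- unlist(ii); j <- unlist(jj)
  M <- Matrix::sparseMatrix(i = i, j = j, x = unlist(mm), dims = c(n, n))
  K <- Matrix::sparseMatrix(i = i, j = j, x = unlist(kk), dims = c(n, n))
  list(M = M, K = K)
}

# nodal load vector for an influx density q (constant per edge) through
# the given boundary edges
boundary_flux_load <- function(mesh, edges, q_edge) {
  n <- nrow(mesh$nodes)
  load <- numeric(n)
  if (!nrow(edges)) return(load)
  len <- sqrt(rowSums((mesh$nodes[edges[, 2], , drop = FALSE] -
                       mesh$nodes[edges[, 1], , drop = FALSE])^2))
  w <- q_edge * len / 2
  load[edges[, 1]] <- load[edges[, 1]] + w
  load[edges[, 2]] <- load[edges[, 2]] + w
  load
}

# outward boundary flux of a nodal vector field (discrete divergence
# theorem companion of solve_velocity)
boundary_outflux <- function(mesh, u) {
  be <- mesh$boundary_edges
  dx <- mesh$nodes[be[, 2], 1] - mesh$nodes[be[, 1], 1]
  dy <- mesh$nodes[be[, 2], 2] - mesh$nodes[be[, 1], 2]
  um <- (u[be[, 1], , drop = FALSE] + u[be[, 2], , drop = FALSE]) / 2
  sum(um[, 1] * dy - um[, 2] * dx)   # outward normal of a CCW loop
}

#' Tissue velocity from the proliferation source
#'
#' Solves the quasi-static Stokes problem for an incompressible
#' Newtonian fluid with a prescribed volumetric source,
#' \deqn{0 = -\nabla p + \mu(\nabla^2 u + \tfrac13\nabla(\nabla\cdot u)),
#'       \qquad \nabla\cdot u = S,}
#' with zero-traction (free) boundary everywhere, which leaves normal
#' motion of the boundary unconstrained. Inertial terms are dropped: at
#' tissue scales and um/h velocities the Reynolds number is negligible,
#' so the flow is fully determined by the instantaneous source. The
#' rigid-body nullspace (two translations and one rotation) is removed
#' with Lagrange multipliers pinning the domain's mean motion, and the
#' equal-order P1-P1 discretisation is stabilised with a
#' Brezzi-Pitkaranta pressure-Laplacian term.
#'
#' @param mesh a `growing_mesh`.
#' @param S nodal source vector (s^-1), e.g. from [growth_source()].
#' @param params an [eye_disc_parameters()] object (`mu` is used).
#' @param alpha stabilisation coefficient.
#' @return object of class `velocity_solution`: list with nodal velocity
#'   matrix `u` (n x 2, um/s), nodal pressure `p`, and `div_residual`,
#'   the relative mismatch between the boundary outflux of `u` and the
#'   integral of `S` (divergence-theorem diagnostic).
#' @export
solve_velocity <- function(mesh, S, params, alpha = 0.05) {
  n <- nrow(mesh$nodes)
  if (length(S) != n) stop("solve_velocity: S must be nodal (length n)")
  geom <- element_gradients(mesh)
  sc <- assemble_scalar(mesh, geom)
  mu <- params$mu
  tr <- mesh$tri; A <- geom$A
  g <- list(geom$gx, geom$gy)     # g[[alpha]][, i]

  ti <- tj <- tx <- list(); q <- 0
  add <- function(I, J, X) { q <<- q + 1; ti[[q]] <<- I; tj[[q]] <<- J; tx[[q]] <<- X }

  # viscous block A[(j,beta),(i,alpha)] and pressure coupling B
  for (i in 1:3) for (j in 1:3) {
    gij <- geom$gx[, i] * geom$gx[, j] + geom$gy[, i] * geom$gy[, j]
    for (al in 1:2) for (be in 1:2) {
      val <- mu * A * ((al == be) * gij +
                       g[[be]][, i] * g[[al]][, j] -
                       (2 / 3) * g[[al]][, i] * g[[be]][, j])
      add((be - 1L) * n + tr[, j], (al - 1L) * n + tr[, i], val)
    }
  }
  for (j in 1:3) for (l in 1:3) for (be in 1:2) {
    val <- A / 3 * g[[be]][, j]
    add((be - 1L) * n + tr[, j], 2L * n + tr[, l], -val)  # momentum: -B p
    add(2L * n + tr[, l], (be - 1L) * n + tr[, j], -val)  # -continuity row
  }
  # stabilisation -C on the (negated) continuity rows
  h2 <- A                          # element area ~ h^2
  for (l in 1:3) for (k in 1:3) {
    glk <- geom$gx[, l] * geom$gx[, k] + geom$gy[, l] * geom$gy[, k]
    add(2L * n + tr[, l], 2L * n + tr[, k], -alpha * h2 / mu * A * glk)
  }
  # remove the rigid-body nullspace (2 translations + 1 rotation) by
  # pinning point DOFs: both components at the node nearest the domain
  # centroid, and u_y at the boundary node furthest along x from it.
  # The zero-traction problem with a compatible source exerts no net
  # force or torque, so the pin reactions vanish and the pinned solution
  # is an exact member of the solution family (it fixes which rigid
  # motion is reported, nothing else).
  ctr <- colMeans(mesh$nodes)
  pin_c <- which.min((mesh$nodes[, 1] - ctr[1])^2 + (mesh$nodes[, 2] - ctr[2])^2)
  pin_r <- mesh$boundary[which.max(abs(mesh$nodes[mesh$boundary, 1] - ctr[1]))]
  pinned <- c(pin_c, n + pin_c, n + pin_r)
  N <- 3L * n
  Amat <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                               dims = c(N, N))
  rhs <- c(numeric(2 * n), -as.numeric(sc$M %*% S))
  keep <- !(seq_len(N) %in% pinned)
  sol <- numeric(N)
  sol[keep] <- as.numeric(Matrix::solve(Amat[keep, keep], rhs[keep]))
  u <- cbind(sol[seq_len(n)], sol[n + seq_len(n)])
  p <- sol[2 * n + seq_len(n)]
  src <- sum(as.numeric(sc$M %*% S))
  flx <- boundary_outflux(mesh, u)
  res <- abs(flx - src) / max(abs(src), .Machine$double.eps)
  structure(list(u = u, p = p, div_residual = res), class = "velocity_solution")
}

# area-weighted mean velocity-gradient components over elements whose
# centroid lies within `radius` of a point; returns c(du/dx, dv/dy)
velocity_gradient_at <- function(mesh, u, point, radius) {
  geom <- element_gradients(mesh)
  tc <- (mesh$nodes[mesh$tri[, 1], , drop = FALSE] +
         mesh$nodes[mesh$tri[, 2], , drop = FALSE] +
         mesh$nodes[mesh$tri[, 3], , drop = FALSE]) / 3
  sel <- (tc[, 1] - point[1])^2 + (tc[, 2] - point[2])^2 <= radius^2
  if (!any(sel)) sel[which.min((tc[, 1] - point[1])^2 + (tc[, 2] - point[2])^2)] <- TRUE
  ux <- cbind(u[mesh$tri[, 1], 1], u[mesh$tri[, 2], 1], u[mesh$tri[, 3], 1])
  uy <- cbind(u[mesh$tri[, 1], 2], u[mesh$tri[, 2], 2], u[mesh$tri[, 3], 2])
  dudx <- rowSums(geom$gx * ux)
  dvdy <- rowSums(geom$gy * uy)
  w <- mesh$areas[sel]
  c(dudx = sum(dudx[sel] * w) / sum(w), dvdy = sum(dvdy[sel] * w) / sum(w))
}
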