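# Triangulated, deforming elliptical domain.
#
# The mesh is built from a structured disc template: concentric rings
# j = 0..m with 6j nodes on ring j (plus the centre node), stitched into
# 6 m^2 positively oriented triangles, then scaled by the semi-axes.
# Because the simulation moves nodes with the tissue velocity
# (Lagrangian ALE), the same connectivity persists until a remesh is
# triggered by element-quality decay.

#' Triangulate an ellipse
#'
#' @param a,b semi-axes (um): `a` along the AP (x) axis, `b` along DV (y).
#' @param target_edge_length requested typical edge length (um); ignored
#'   when `n_rings` is given.
#' @param n_rings number of concentric node rings; the mesh has
#'   `6*n_rings^2` triangles.
#' @return object of class `growing_mesh`: list with `nodes` (n x 2
#'   coordinate matrix, um), `tri` (m x 3 integer connectivity, counter-
#'   clockwise), `boundary` (ordered boundary node indices), cached
#'   element `areas` and `quality` scores in (0, 1], and cached `L_AP`
#'   (um) and `area` (um^2).
#' @export
make_ellipse_mesh <- function(a, b, target_edge_length = NULL, n_rings = NULL) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("make_ellipse_mesh: semi-axes must be positive")
  if (is.null(n_rings)) {
    if (is.null(target_edge_length) || target_edge_length <= 0)
      stop("make_ellipse_mesh: give a positive target_edge_length or n_rings")
    n_rings <- max(2L, round(((a + b) / 2) / target_edge_length))
  }
  m <- as.integer(n_rings)
  tmpl <- disc_template(m)
  nodes <- cbind(a * tmpl$nodes[, 1], b * tmpl$nodes[, 2])
  build_mesh(nodes, tmpl$tri)
}

# unit-disc template: node ring radii j/m, 6j nodes per ring
disc_template <- function(m) {
  nodes <- matrix(0, nrow = 1 + 3 * m * (m + 1), ncol = 2)
  ring_idx <- vector("list", m + 1)
  ring_idx[[1]] <- 1L
  ang <- vector("list", m + 1)
  ang[[1]] <- 0
  pos <- 2L
  for (j in seq_len(m)) {
    nj <- 6L * j
    th <- 2 * pi * (seq_len(nj) - 1) / nj
    idx <- pos:(pos + nj - 1L)
    nodes[idx, ] <- (j / m) * cbind(cos(th), sin(th))
    ring_idx[[j + 1]] <- idx
    ang[[j + 1]] <- th
    pos <- pos + nj
  }
  tri <- NULL
  for (j in seq_len(m))
    tri <- rbind(tri, stitch_rings(ring_idx[[j]], ang[[j]],
                                   ring_idx[[j + 1]], ang[[j + 1]]))
  list(nodes = nodes, tri = tri, ring_idx = ring_idx)
}

# triangulate the band between an inner ring (possibly a single node)
# and an outer ring, merging by angle
stitch_rings <- function(inner, ath_in, outer, ath_out) {
  n2 <- length(outer)
  if (length(inner) == 1L) {     # fan around the centre
    k <- seq_len(n2)
    return(cbind(rep(inner, n2), outer[k], outer[ifelse(k == n2, 1L, k + 1L)]))
  }
  n1 <- length(inner)
  tri <- matrix(0L, nrow = n1 + n2, ncol = 3)
  i <- 1L; k <- 1L; r <- 0L
  repeat {
    adv_inner <- if (i > n1) FALSE
      else if (k > n2) TRUE
      else {
        a_next <- if (i < n1) ath_in[i + 1L] else 2 * pi
        b_next <- if (k < n2) ath_out[k + 1L] else 2 * pi
        a_next < b_next
      }
    ii <- inner[if (i > n1) 1L else i]
    kk <- outer[if (k > n2) 1L else k]
    if (adv_inner) {
      i2 <- inner[if (i + 1L > n1) 1L else i + 1L]
      r <- r + 1L; tri[r, ] <- c(ii, kk, i2)
      i <- i + 1L
    } else {
      k2 <- outer[if (k + 1L > n2) 1L else k + 1L]
      r <- r + 1L; tri[r, ] <- c(ii, kk, k2)
      k <- k + 1L
    }
    if (i > n1 && k > n2) break
  }
  tri[seq_len(r), , drop = FALSE]
}

# signed areas (positive for counter-clockwise triangles)
tri_signed_areas <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

# inradius/circumradius quality, scaled so an equilateral triangle = 1
tri_quality <- function(nodes, tri, areas = NULL) {
  if (is.null(areas)) areas <- tri_signed_areas(nodes, tri)
  e <- function(i, j) sqrt(rowSums((nodes[tri[, i], , drop = FALSE] -
                                    nodes[tri[, j], , drop = FALSE])^2))
  la <- e(1, 2); lb <- e(2, 3); lc <- e(3, 1)
  16 * areas^2 / ((la + lb + lc) * la * lb * lc)
}

# directed boundary edges (interior on the left), ordered head-to-tail
boundary_edges_of <- function(tri) {
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key  <- paste(ed[, 1], ed[, 2])
  rkey <- paste(ed[, 2], ed[, 1])
  b <- ed[!(key %in% rkey), , drop = FALSE]
  # order into a closed loop
  ord <- integer(nrow(b))
  nxt <- match(b[, 1], b[, 2])   # edge whose head is this edge's tail
  cur <- 1L
  for (i in seq_len(nrow(b))) {
    ord[i] <- cur
    cur <- which(b[, 1] == b[cur, 2])[1]
  }
  b[ord, , drop = FALSE]
}

build_mesh <- function(nodes, tri) {
  areas <- tri_signed_areas(nodes, tri)
  flip <- areas < 0
  if (any(flip)) {               # enforce counter-clockwise orientation
    tri[flip, ] <- tri[flip, c(1, 3, 2)]
    areas[flip] <- -areas[flip]
  }
  if (any(areas <= 0)) stop("build_mesh: degenerate (zero-area) element")
  be <- boundary_edges_of(tri)
  mesh <- list(nodes = nodes, tri = tri,
               boundary_edges = be, boundary = be[, 1],
               areas = areas, quality = tri_quality(nodes, tri, areas))
  mesh$area <- sum(areas)
  bx <- nodes[mesh$boundary, 1]
  mesh$x_pole <- min(bx)
  mesh$L_AP <- max(bx) - min(bx)
  class(mesh) <- "growing_mesh"
  mesh
}

# refresh cached geometry after node motion (connectivity unchanged)
refresh_mesh <- function(mesh, nodes) {
  areas <- tri_signed_areas(nodes, mesh$tri)
  if (any(areas <= 0)) {
    cond <- structure(class = c("eyedisc_inversion", "error", "condition"),
                      list(message = sprintf(
                        "mesh motion inverted %d element(s); reduce dt or remesh",
                        sum(areas <= 0)), call = NULL))
    stop(cond)
  }
  mesh$nodes <- nodes
  mesh$areas <- areas
  mesh$quality <- tri_quality(nodes, mesh$tri, areas)
  mesh$area <- sum(areas)
  bx <- nodes[mesh$boundary, 1]
  mesh$x_pole <- min(bx)
  mesh$L_AP <- max(bx) - min(bx)
  mesh
}

#' @export
print.growing_mesh <- function(x, ...) {
  cat(sprintf("growing_mesh: %d nodes, %d triangles, area %.1f um^2, L_AP %.1f um, min quality %.2f\n",
              nrow(x$nodes), nrow(x$tri), x$area, x$L_AP, min(x$quality)))
  invisible(x)
}

#' Posterior-margin boundary edges
#'
#' Boundary edges whose midpoint lies within the posterior
#' `margin_fraction` of the current AP extent; this is the part of the
#' margin through which Hh flows into the disc.
#'
#' @param mesh a `growing_mesh`.
#' @param margin_fraction relative AP extent of the producing margin.
#' @return integer matrix of directed boundary edges (rows of node pairs).
#' @export
posterior_margin_edges <- function(mesh, margin_fraction = 0.2) {
  be <- mesh$boundary_edges
  xm <- (mesh$nodes[be[, 1], 1] + mesh$nodes[be[, 2], 1]) / 2 - mesh$x_pole
  be[xm <= margin_fraction * mesh$L_AP, , drop = FALSE]
}

#' Move the mesh with the tissue velocity (explicit ALE step)
#'
#' @param mesh a `growing_mesh`.
#' @param u nodal velocity matrix (n x 2, um/s).
#' @param dt time step (s, > 0).
#' @return the deformed mesh with refreshed geometry caches. Signals an
#'   error of class `eyedisc_inversion` if any element inverts.
#' @export
advance_domain <- function(mesh, u, dt) {
  if (!is.finite(dt) || dt <= 0) stop("advance_domain: dt must be > 0")
  u <- as.matrix(u)
  if (nrow(u) != nrow(mesh$nodes) || ncol(u) != 2)
    stop("advance_domain: u must be an n x 2 nodal velocity matrix")
  refresh_mesh(mesh, mesh$nodes + dt * u)
}

#' Growth source field
#'
#' Local relative area growth rate S = Pi * k0 * exp(-delta_PL * PL):
#' uniform over the progenitor region, zero elsewhere, and decaying
#' exponentially as the furrow advances (PL, the posterior length, is a
#' surrogate of developmental time).
#'
#' @param Pi_field nodal progenitor indicator (in [0, 1]).
#' @param PL current posterior length (um, >= 0).
#' @param params an [eye_disc_parameters()] object.
#' @return nodal source vector (s^-1).
#' @export
growth_source <- function(Pi_field, PL, params) {
  if (!is.finite(PL) || PL < 0) stop("growth_source: PL must be >= 0")
  Pi_field * params$k0 * exp(-params$delta_PL * PL)
}

# ---- remeshing ------------------------------------------------------------

#' Regenerate the mesh on the current boundary and transfer fields
#'
#' Builds a fresh structured triangulation of the current boundary
#' polygon: new boundary nodes are sampled uniformly by arc length and
#' lie on the old polygon (the area change is a second-order corner
#' effect), interior rings are scaled copies of the boundary shape, and
#' nodal fields transfer by linear interpolation on the old mesh. If the
#' new triangulation would be worse than the current one (pathological
#' boundary shapes), the old mesh is kept and `skipped = TRUE` is
#' returned.
#'
#' @param mesh a `growing_mesh` whose interior elements have degraded.
#' @param fields named list of nodal vectors to carry over (may be empty).
#' @param target_edge desired boundary node spacing (um); by default the
#'   current boundary node count is kept, so the mesh coarsens as the
#'   domain grows. Passing the initial edge length instead keeps the
#'   spatial resolution constant as the tissue expands.
#' @return list with the new `mesh` and interpolated `fields`.
#' @export
remesh_domain <- function(mesh, fields = list(), target_edge = NULL) {
  bnd <- mesh$boundary                      # ordered closed loop
  nb <- length(bnd)
  poly <- mesh$nodes[bnd, , drop = FALSE]
  # area centroid of the boundary polygon
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A2 <- sum(cr)
  ctr <- c(sum((x + xn) * cr), sum((y + yn) * cr)) / (3 * A2)
  if (A2 < 0) { poly <- poly[rev(seq_len(nb)), , drop = FALSE] }  # force CCW
  # arc-length parameterisation of the boundary
  seg <- sqrt(rowSums((poly[c(2:nb, 1), , drop = FALSE] - poly)^2))
  s_cum <- c(0, cumsum(seg))
  P <- s_cum[nb + 1]
  m <- if (is.null(target_edge)) max(2L, round(nb / 6))
       else max(2L, round(P / (6 * target_edge)))
  sample_bnd <- function(svals) {
    svals <- svals %% P
    i <- findInterval(svals, s_cum, rightmost.closed = TRUE)
    i[i > nb] <- nb
    w <- (svals - s_cum[i]) / pmax(seg[i], .Machine$double.eps)
    nxt <- ifelse(i == nb, 1L, i + 1L)
    poly[i, , drop = FALSE] * (1 - w) + poly[nxt, , drop = FALSE] * w
  }
  nodes <- matrix(0, nrow = 1 + 3 * m * (m + 1), ncol = 2)
  nodes[1, ] <- ctr
  ring_idx <- vector("list", m + 1); ring_idx[[1]] <- 1L
  ang <- vector("list", m + 1); ang[[1]] <- 0
  pos <- 2L
  for (j in seq_len(m)) {
    nj <- 6L * j
    pts <- sample_bnd(P * (seq_len(nj) - 1) / nj)
    f <- j / m
    pts <- sweep(sweep(pts, 2, ctr) * f, 2, ctr, `+`)
    th <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
    o <- order(th)                         # ascending angle for stitching
    nodes[pos:(pos + nj - 1L), ] <- pts[o, , drop = FALSE]
    ring_idx[[j + 1]] <- pos:(pos + nj - 1L)
    ang[[j + 1]] <- th[o]
    pos <- pos + nj
  }
  tri <- NULL
  for (j in seq_len(m))
    tri <- rbind(tri, stitch_rings(ring_idx[[j]], ang[[j]],
                                   ring_idx[[j + 1]], ang[[j + 1]]))
  new_mesh <- build_mesh(nodes, tri)
  if (min(new_mesh$quality) <= min(mesh$quality))   # failsafe: keep the old mesh
    return(list(mesh = mesh, fields = fields, skipped = TRUE))
  out_fields <- interpolate_fields(mesh, new_mesh$nodes, fields)
  list(mesh = new_mesh, fields = out_fields)
}

#' Interpolate nodal fields onto query points
#'
#' Linear (barycentric) interpolation on the source mesh; points that
#' fall marginally outside (boundary round-off) take the value at the
#' nearest source node.
#'
#' @param mesh source `growing_mesh`.
#' @param pts query point matrix (k x 2).
#' @param fields named list of nodal vectors on `mesh`.
#' @return named list of vectors of length `nrow(pts)`.
#' @export
interpolate_fields <- function(mesh, pts, fields) {
  if (!length(fields)) return(list())
  loc <- locate_points(mesh, pts)
  lapply(fields, function(f) {
    v <- numeric(nrow(pts))
    inside <- loc$tri > 0L
    tr <- mesh$tri[loc$tri[inside], , drop = FALSE]
    v[inside] <- rowSums(loc$bary[inside, , drop = FALSE] *
                           cbind(f[tr[, 1]], f[tr[, 2]], f[tr[, 3]]))
    if (any(!inside)) v[!inside] <- f[loc$nearest[!inside]]
    v
  })
}

# barycentric point location: for each point test the triangles whose
# centroids are nearest (domains here are star-shaped and quasi-uniform,
# so a modest candidate list suffices)
locate_points <- function(mesh, pts, n_cand = 30L, tol = 1e-9) {
  tc <- (mesh$nodes[mesh$tri[, 1], , drop = FALSE] +
         mesh$nodes[mesh$tri[, 2], , drop = FALSE] +
         mesh$nodes[mesh$tri[, 3], , drop = FALSE]) / 3
  k <- nrow(pts)
  tri_hit <- integer(k); bary <- matrix(0, k, 3)
  x1 <- mesh$nodes[mesh$tri[, 1], 1]; y1 <- mesh$nodes[mesh$tri[, 1], 2]
  x2 <- mesh$nodes[mesh$tri[, 2], 1]; y2 <- mesh$nodes[mesh$tri[, 2], 2]
  x3 <- mesh$nodes[mesh$tri[, 3], 1]; y3 <- mesh$nodes[mesh$tri[, 3], 2]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  for (q in seq_len(k)) {
    d2 <- (tc[, 1] - pts[q, 1])^2 + (tc[, 2] - pts[q, 2])^2
    cand <- order(d2)[seq_len(min(n_cand, length(d2)))]
    for (tr in cand) {
      l1 <- ((y2[tr] - y3[tr]) * (pts[q, 1] - x3[tr]) +
             (x3[tr] - x2[tr]) * (pts[q, 2] - y3[tr])) / det[tr]
      l2 <- ((y3[tr] - y1[tr]) * (pts[q, 1] - x3[tr]) +
             (x1[tr] - x3[tr]) * (pts[q, 2] - y3[tr])) / det[tr]
      l3 <- 1 - l1 - l2
      if (l1 >= -tol && l2 >= -tol && l3 >= -tol) {
        tri_hit[q] <- tr
        bary[q, ] <- pmax(c(l1, l2, l3), 0)
        break
      }
    }
  }
  d2n <- NULL
  nearest <- integer(k)
  if (any(tri_hit == 0L)) {
    for (q in which(tri_hit == 0L)) {
      d2n <- (mesh$nodes[, 1] - pts[q, 1])^2 + (mesh$nodes[, 2] - pts[q, 2])^2
      nearest[q] <- which.min(d2n)
    }
  }
  list(tri = tri_hit, bary = bary, nearest = nearest)
}
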