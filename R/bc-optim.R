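#' Optimisation sub-region and angular-deviation objective
#'
#' The boundary-condition fit is evaluated on a sub-region of the muscle
#' that excludes the elements a reference tractography field is least
#' trustworthy in: a surface layer of stated thickness and the distal
#' portion of the muscle.
#'
#' @name bc-objective
NULL

# exact minimum distance from points (n x 3) to one triangle (3 x 3),
# vectorised over points (Eberly's region decomposition)
point_triangle_distance <- function(p, tri) {
  b <- tri[1, ]
  e0 <- tri[2, ] - b
  e1 <- tri[3, ] - b
  a <- sum(e0 * e0); bb <- sum(e0 * e1); c_ <- sum(e1 * e1)
  dv <- sweep(p, 2, b)            # b - p, sign handled below
  d <- -(dv %*% e0); e <- -(dv %*% e1)
  f <- rowSums(dv^2)
  det <- a * c_ - bb * bb
  s <- bb * e - c_ * d
  t <- bb * d - a * e
  s_ <- numeric(nrow(p)); t_ <- numeric(nrow(p))
  clamp01 <- function(x) pmin(1, pmax(0, x))
  inside <- s + t <= det & s >= 0 & t >= 0
  s_[inside] <- s[inside] / det
  t_[inside] <- t[inside] / det
  out <- which(!inside)
  if (length(out)) {
    # fall back: minimise over the three edges (exact for exterior regions)
    for (edge in list(list(o = c(0, 0), d = c(1, 0)),
                      list(o = c(0, 0), d = c(0, 1)),
                      list(o = c(1, 0), d = c(-1, 1)))) {
      # parametrise (s,t) = o + u * d, u in [0,1]; minimise quadratic
      o <- edge$o; dd <- edge$d
      # Q(s,t) = a s^2 + 2b s t + c t^2 + 2 d s + 2 e t + f
      qa <- a * dd[1]^2 + 2 * bb * dd[1] * dd[2] + c_ * dd[2]^2
      qb <- a * o[1] * dd[1] + bb * (o[1] * dd[2] + o[2] * dd[1]) +
        c_ * o[2] * dd[2] + d[out] * dd[1] + e[out] * dd[2]
      u <- clamp01(-qb / qa)
      su <- o[1] + u * dd[1]; tu <- o[2] + u * dd[2]
      qv <- a * su^2 + 2 * bb * su * tu + c_ * tu^2 +
        2 * d[out] * su + 2 * e[out] * tu + f[out]
      if (edge$o[1] == 0 && edge$d[1] == 1) { best <- qv; bs <- su; bt <- tu }
      else { imp <- qv < best; best[imp] <- qv[imp]
             bs[imp] <- su[imp]; bt[imp] <- tu[imp] }
    }
    s_[out] <- bs; t_[out] <- bt
  }
  q <- a * s_^2 + 2 * bb * s_ * t_ + c_ * t_^2 + 2 * d * s_ + 2 * e * t_ + f
  sqrt(pmax(0, q))
}

# minimum distance from points to a triangulated surface (node triples)
points_surface_distance <- function(points, nodes, faces) {
  dmin <- rep(Inf, nrow(points))
  for (r in seq_len(nrow(faces))) {
    tri <- nodes[faces[r, ], , drop = FALSE]
    # cheap prune: centre + circumradius bound
    ctr <- colMeans(tri)
    rad <- sqrt(max(rowSums(sweep(tri, 2, ctr)^2)))
    lb <- sqrt(rowSums(sweep(points, 2, ctr)^2)) - rad
    cand <- which(lb < dmin)
    if (length(cand))
      dmin[cand] <- pmin(dmin[cand],
                         point_triangle_distance(points[cand, , drop = FALSE],
                                                 tri))
  }
  dmin
}

#' Build the optimisation sub-region of muscle elements
#'
#' Starts from all muscle-region elements and excludes those whose
#' centroid lies within \code{surface_offset_mm} of the muscle's exterior
#' surface (exact point-to-triangle distances) or distal of the stated
#' axial fraction of the mesh extent.
#'
#' @param mesh a tagged \code{tet_mesh}.
#' @param surface_offset_mm surface-layer thickness to exclude (mm).
#' @param distal_cut_fraction fraction of the axial extent, measured from
#'   the distal end, to exclude (0 = keep everything).
#' @return logical vector over elements (the sub-region mask) with
#'   attribute \code{"excluded_fraction"}, the share of muscle elements
#'   removed.
#' @export
make_subregion <- function(mesh, surface_offset_mm = 3.0,
                           distal_cut_fraction = 0.1) {
  muscle <- mesh$region == "muscle"
  mask <- muscle
  ctr <- tet_centroids(mesh)
  zc <- drop(ctr %*% mesh$e2)
  zall <- drop(mesh$nodes %*% mesh$e2)
  zcut <- max(zall) - distal_cut_fraction * (max(zall) - min(zall))
  mask <- mask & zc <= zcut
  if (surface_offset_mm > 0) {
    surf <- mesh$face_sets$muscle_surface
    if (is.null(surf) || nrow(surf) == 0L)
      stop("make_subregion: muscle_surface face set required")
    sel <- which(mask)
    d <- points_surface_distance(ctr[sel, , drop = FALSE], mesh$nodes, surf)
    mask[sel[d < surface_offset_mm]] <- FALSE
  }
  if (!any(mask))
    stop("make_subregion: sub-region is empty (offset or cut too large)")
  attr(mask, "excluded_fraction") <- 1 - sum(mask) / sum(muscle)
  mask
}

#' Cosine distance between paired vectors
#'
#' \code{1 - a . b / (|a| |b|)}, in [0, 2].
#'
#' @param a,b vectors (length 3) or n x 3 matrices of paired rows.
#' @return scalar or vector of cosine distances.
#' @export
cosine_distance <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na < 1e-300) || any(nb < 1e-300))
    stop("cosine_distance: zero vector")
  y <- pmin(pmax(1 - rowSums(a * b) / (na * nb), 0), 2)
  if (length(y) == 1L) y[[1]] else y
}

#' Mean angular deviation between two element fibre fields
#'
#' Arithmetic mean of per-element cosine distances over the masked
#' elements. Elements flagged invalid in either field are excluded (their
#' count is attached as attribute \code{"n_excluded"}, with a warning).
#' The per-element deviation angles \code{acos(1 - y)} in degrees are
#' attached as attribute \code{"angles_deg"}.
#'
#' @param field_a,field_b E x 3 fibre fields on the same mesh.
#' @param mask logical element mask (default: all elements).
#' @return mean cosine distance (scalar).
#' @export
mean_deviation <- function(field_a, field_b,
                           mask = rep(TRUE, nrow(field_a))) {
  stopifnot(nrow(field_a) == nrow(field_b))
  if (!any(mask)) stop("mean_deviation: empty mask")
  ok <- mask
  for (f in list(field_a, field_b)) {
    v <- attr(f, "valid")
    if (!is.null(v)) ok <- ok & v
  }
  nex <- sum(mask) - sum(ok)
  if (nex > 0)
    warning("mean_deviation: ", nex, " invalid elements excluded")
  y <- cosine_distance(field_a[ok, , drop = FALSE],
                       field_b[ok, , drop = FALSE])
  structure(mean(y), n_excluded = nex,
            angles_deg = acos(pmin(1, pmax(-1, 1 - y))) * 180 / pi)
}

#' Design space for the boundary-condition parameters
#'
#' Box bounds and start point for (T1, alpha1, alpha2), with the linear
#' feasibility constraint \code{alpha2 - alpha1 >= 0} (fibre flux must
#' incline towards the aponeurosis, not away from it). The defaults span
#' T1 in [-200, -1] and both exponents in [0, 20], starting from
#' (-100, 5, 10).
#'
#' @param t1_range,alpha1_range,alpha2_range length-2 bounds.
#' @param start start point inside the box.
#' @param n_designs number of space-filling design points.
#' @param seed integer seed for design sampling.
#' @return object of class \code{design_space}.
#' @export
design_space <- function(t1_range = c(-200, -1), alpha1_range = c(0, 20),
                         alpha2_range = c(0, 20),
                         start = c(-100, 5, 10), n_designs = 200,
                         seed = 1L) {
  lower <- c(t1_range[1], alpha1_range[1], alpha2_range[1])
  upper <- c(t1_range[2], alpha1_range[2], alpha2_range[2])
  stopifnot(all(lower < upper), length(start) == 3,
            all(start >= lower & start <= upper), n_designs >= 4)
  if (max(lower[2], lower[3]) > min(upper[2], upper[3]))
    stop("design_space: constraint alpha2 >= alpha1 infeasible in box")
  structure(list(lower = lower, upper = upper, start = start,
                 names = c("T1", "alpha1", "alpha2"),
                 n_designs = as.integer(n_designs),
                 seed = as.integer(seed)),
            class = "design_space")
}

#' Space-filling design points
#'
#' Maximin-optimised Latin hypercube over the full box (the feasibility
#' constraint only restricts the optimiser, not the design, so the
#' metamodel is informed on both sides of the constraint). Deterministic
#' for a fixed seed.
#'
#' @param space a \code{design_space}.
#' @return \code{n_designs} x 3 matrix with named columns.
#' @export
sample_designs <- function(space) {
  set.seed(space$seed)
  u <- lhs::maximinLHS(space$n_designs, 3L)
  s <- sweep(sweep(u, 2, space$upper - space$lower, "*"), 2, space$lower,
             "+")
  colnames(s) <- space$names
  s
}
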