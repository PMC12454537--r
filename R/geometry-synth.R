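#' Synthetic bipennate muscle geometry
#'
#' The generator replaces a subject-specific MRI/CAD chain with a
#' parameterised phantom whose ground truth is known exactly: a fusiform
#' solid (smooth radius profile, flat tendon end faces) containing a thin
#' planar mid-sheet -- the anterior aponeurosis -- that starts part-way
#' along the muscle and reaches its distal end, attached to the anterior
#' surface and free elsewhere. The world frame puts the principal muscle
#' axis \code{e2} on +z (z = 0 proximal), the sheet normal on x, and
#' anterior on +y.
#'
#' @param total_length_mm overall muscle-tendon length (z extent).
#' @param tendon_proximal_mm,tendon_distal_mm lengths of the tendon
#'   regions at the two ends.
#' @param max_radius_mm belly radius.
#' @param end_radius_mm radius of the flat tendon end faces.
#' @param apo_thickness_mm nominal sheet thickness at the belly.
#' @param apo_start_fraction start of the sheet as a fraction of the
#'   muscle (non-tendon) span; the sheet always reaches the distal end.
#' @param apo_posterior_fraction posterior edge of the sheet in the
#'   normalised cross-section (-1 posterior surface, +1 anterior surface);
#'   the sheet spans from there to the anterior surface, where it attaches.
#' @param apo_bc_band_fraction fraction of the sheet's width, centred on
#'   its central axis, whose interface faces form the
#'   \code{aponeurosis_surface} boundary set (temperature boundary
#'   conditions act on a strip along the central axis of the sheet, not
#'   on its whole interface).
#' @param pennation_deg fibre pennation angle from the principal axis.
#' @param element_size_mm target edge length of the structured grid.
#' @param seed integer seed recorded with the spec (the mesh itself is
#'   deterministic; the seed governs streamline synthesis).
#' @return object of class \code{bipennate_spec}.
#' @export
bipennate_spec <- function(total_length_mm = 150, tendon_proximal_mm = 15,
                           tendon_distal_mm = 15, max_radius_mm = 15,
                           end_radius_mm = 6, apo_thickness_mm = 2,
                           apo_start_fraction = 0.4,
                           apo_posterior_fraction = -0.6,
                           apo_bc_band_fraction = 0.5,
                           pennation_deg = 15, element_size_mm = 5,
                           seed = 1L) {
  sp <- list(total_length_mm = total_length_mm,
             tendon_proximal_mm = tendon_proximal_mm,
             tendon_distal_mm = tendon_distal_mm,
             max_radius_mm = max_radius_mm,
             end_radius_mm = end_radius_mm,
             apo_thickness_mm = apo_thickness_mm,
             apo_start_fraction = apo_start_fraction,
             apo_posterior_fraction = apo_posterior_fraction,
             apo_bc_band_fraction = apo_bc_band_fraction,
             pennation_deg = pennation_deg,
             element_size_mm = element_size_mm,
             seed = as.integer(seed))
  with(sp, {
    stopifnot(total_length_mm > 0, max_radius_mm > 0, end_radius_mm > 0,
              tendon_proximal_mm > 0, tendon_distal_mm > 0,
              tendon_proximal_mm + tendon_distal_mm < total_length_mm,
              apo_thickness_mm > 0, pennation_deg > 0, pennation_deg < 90,
              apo_start_fraction > 0, apo_start_fraction < 1,
              apo_posterior_fraction > -1, apo_posterior_fraction < 1,
              apo_bc_band_fraction > 0, apo_bc_band_fraction <= 1)
  })
  if (sp$apo_thickness_mm >= 2 * sp$element_size_mm)
    stop("bipennate_spec: element size too large to resolve the sheet ",
         "(apo_thickness_mm must be below twice the element size)")
  class(sp) <- "bipennate_spec"
  sp
}

#' @export
print.bipennate_spec <- function(x, ...) {
  cat(sprintf(paste0("Bipennate spec: L=%g mm (tendons %g/%g), r=%g mm, ",
                     "sheet %g mm from %.0f%%, pennation %g deg, h=%g mm\n"),
              x$total_length_mm, x$tendon_proximal_mm, x$tendon_distal_mm,
              x$max_radius_mm, x$apo_thickness_mm,
              100 * x$apo_start_fraction, x$pennation_deg,
              x$element_size_mm))
  invisible(x)
}

# fusiform radius profile: end_radius at both ends, max_radius at the belly
radius_profile <- function(spec, z) {
  t <- pmin(pmax(z / spec$total_length_mm, 0), 1)
  spec$end_radius_mm +
    (spec$max_radius_mm - spec$end_radius_mm) * sin(pi * t)^0.8
}

# z where the sheet starts
apo_start_z <- function(spec) {
  spec$tendon_proximal_mm + spec$apo_start_fraction *
    (spec$total_length_mm - spec$tendon_proximal_mm - spec$tendon_distal_mm)
}

# square -> disk elliptical mapping of normalised cross-section coords
square_to_disk <- function(xh, yh) {
  cbind(xh * sqrt(1 - yh^2 / 2), yh * sqrt(1 - xh^2 / 2))
}

#' Generate a tagged bipennate tetrahedral mesh
#'
#' A structured hexahedral grid on the normalised cross-section square
#' times the axis is mapped to a fusiform solid of revolution (elliptical
#' square-to-disk map, smooth radius profile) and split into six
#' tetrahedra per hexahedron with a consistent diagonal so the mesh is
#' conforming. A dedicated thin column of elements at the mid-plane
#' carries the aponeurosis region; its nominal thickness is
#' \code{apo_thickness_mm} at the belly and scales with the local radius.
#' Regions and the four face sets (\code{inlet}, \code{outlet},
#' \code{muscle_surface}, \code{aponeurosis_surface}) are tagged
#' geometrically. The construction is deterministic for a fixed spec.
#'
#' @param spec a \code{bipennate_spec}.
#' @return a \code{tet_mesh}.
#' @export
make_bipennate_mesh <- function(spec) {
  stopifnot(inherits(spec, "bipennate_spec"))
  L <- spec$total_length_mm
  h <- spec$element_size_mm
  xt <- spec$apo_thickness_mm / (2 * spec$max_radius_mm)  # sheet half-width
  # x-grid: m graded columns per side plus the thin sheet column
  m <- max(2L, ceiling((1 - xt) * spec$max_radius_mm / h))
  xh <- c(seq(-1, -xt, length.out = m + 1L), seq(xt, 1, length.out = m + 1L))
  ny <- max(3L, ceiling(2 * spec$max_radius_mm / h))
  yh <- seq(-1, 1, length.out = ny + 1L)
  # z-grid with exact breaks at the tendon junctions and the sheet start
  zb <- sort(unique(c(0, spec$tendon_proximal_mm, apo_start_z(spec),
                      L - spec$tendon_distal_mm, L)))
  zs <- unlist(lapply(seq_len(length(zb) - 1L), function(i) {
    n <- max(1L, round((zb[i + 1L] - zb[i]) / h))
    seq(zb[i], zb[i + 1L], length.out = n + 1L)[-1L]
  }))
  zh <- c(0, zs)
  nx <- length(xh); nyn <- length(yh); nz <- length(zh)
  gid <- function(i, j, k) i + nx * ((j - 1L) + nyn * (k - 1L))
  # nodes
  gxy <- expand.grid(x = xh, y = yh)
  uv <- square_to_disk(gxy$x, gxy$y)
  nodes <- matrix(0, nx * nyn * nz, 3)
  for (k in seq_len(nz)) {
    r <- radius_profile(spec, zh[k])
    rows <- (k - 1L) * nx * nyn + seq_len(nx * nyn)
    nodes[rows, 1] <- r * uv[, 1]
    nodes[rows, 2] <- r * uv[, 2]
    nodes[rows, 3] <- zh[k]
  }
  # hexes -> 6 tets (Kuhn split along the main diagonal)
  hex <- expand.grid(i = seq_len(nx - 1L), j = seq_len(nyn - 1L),
                     k = seq_len(nz - 1L))
  v000 <- gid(hex$i, hex$j, hex$k)
  v100 <- gid(hex$i + 1L, hex$j, hex$k)
  v010 <- gid(hex$i, hex$j + 1L, hex$k)
  v110 <- gid(hex$i + 1L, hex$j + 1L, hex$k)
  v001 <- gid(hex$i, hex$j, hex$k + 1L)
  v101 <- gid(hex$i + 1L, hex$j, hex$k + 1L)
  v011 <- gid(hex$i, hex$j + 1L, hex$k + 1L)
  v111 <- gid(hex$i + 1L, hex$j + 1L, hex$k + 1L)
  splits <- list(cbind(v000, v100, v110, v111),
                 cbind(v000, v110, v010, v111),
                 cbind(v000, v010, v011, v111),
                 cbind(v000, v011, v001, v111),
                 cbind(v000, v001, v101, v111),
                 cbind(v000, v101, v100, v111))
  elems <- do.call(rbind, splits)
  # fix inverted tets (mapping preserves orientation, but be safe)
  v <- tet_volumes_raw(nodes, elems)
  if (any(v < 0)) elems[v < 0, c(3, 4)] <- elems[v < 0, c(4, 3)]
  if (any(tet_volumes_raw(nodes, elems) <= 0))
    stop("make_bipennate_mesh: degenerate elements; decrease element size")
  # region tagging from parameter-space centroids
  par_x <- rep(c(xh[-nx] + diff(xh) / 2), times = (nyn - 1L) * (nz - 1L))
  par_y <- rep(rep(yh[-nyn] + diff(yh) / 2, each = nx - 1L),
               times = nz - 1L)
  par_z <- rep(zh[-nz] + diff(zh) / 2, each = (nx - 1L) * (nyn - 1L))
  hex_region <- rep("muscle", nrow(hex))
  hex_region[par_z < spec$tendon_proximal_mm] <- "tendon_proximal"
  hex_region[par_z > L - spec$tendon_distal_mm] <- "tendon_distal"
  sheet <- abs(par_x) < xt + 1e-12 & par_z >= apo_start_z(spec) &
    par_z <= L - spec$tendon_distal_mm &
    par_y >= spec$apo_posterior_fraction
  hex_region[sheet & hex_region == "muscle"] <- "aponeurosis"
  region <- rep(hex_region, 6L)
  mesh <- tet_mesh(nodes, elems, region, e2 = c(0, 0, 1))
  # face sets
  bf <- boundary_faces(mesh)
  fz <- cbind(nodes[bf$faces[, 1], 3], nodes[bf$faces[, 2], 3],
              nodes[bf$faces[, 3], 3])
  tol <- 1e-9 * L
  inlet <- apply(abs(fz) < tol, 1, all)
  outlet <- apply(abs(fz - L) < tol, 1, all)
  msurf <- mesh$region[bf$owner] == "muscle" & !inlet & !outlet
  apo_faces <- interface_faces(mesh, "aponeurosis", "muscle")
  # temperature BCs act on a strip along the sheet's central axis, not
  # on the whole interface: keep faces near the middle of the sheet's
  # width (in the normalised cross-section)
  fy <- (nodes[apo_faces[, 1], 2] + nodes[apo_faces[, 2], 2] +
           nodes[apo_faces[, 3], 2]) / 3
  fz <- (nodes[apo_faces[, 1], 3] + nodes[apo_faces[, 2], 3] +
           nodes[apo_faces[, 3], 3]) / 3
  yh_face <- fy / radius_profile(spec, fz)
  yh_mid <- (spec$apo_posterior_fraction + 1) / 2
  half_band <- spec$apo_bc_band_fraction *
    (1 - spec$apo_posterior_fraction) / 2
  strip <- abs(yh_face - yh_mid) <= half_band
  mesh$face_sets <- list(
    inlet = bf$faces[inlet, , drop = FALSE],
    outlet = bf$faces[outlet, , drop = FALSE],
    muscle_surface = bf$faces[msurf, , drop = FALSE],
    aponeurosis_surface = apo_faces[strip, , drop = FALSE])
  mesh$spec <- spec
  mesh
}

#' Analytic bipennate fibre field (ground truth)
#'
#' In the muscle the fibre direction is tilted by the pennation angle from
#' the principal axis towards the mid-sheet plane, mirror-symmetric across
#' it; inside the tendons and the sheet the direction is the principal
#' axis itself. Points on the mid-plane get the principal axis.
#'
#' @param points n x 3 matrix of world coordinates inside the solid.
#' @param spec a \code{bipennate_spec}.
#' @return n x 3 matrix of unit vectors.
#' @export
analytic_bipennate_field <- function(points, spec) {
  p <- matrix(as.numeric(points), ncol = 3)
  r <- radius_profile(spec, p[, 3])
  inside <- p[, 3] >= -1e-9 & p[, 3] <= spec$total_length_mm + 1e-9 &
    p[, 1]^2 + p[, 2]^2 <= (r * (1 + 1e-9))^2
  if (!all(inside))
    stop("analytic_bipennate_field: point(s) outside the muscle volume")
  L <- spec$total_length_mm
  th <- spec$pennation_deg * pi / 180
  axial <- p[, 3] < spec$tendon_proximal_mm |
    p[, 3] > L - spec$tendon_distal_mm |
    (abs(p[, 1]) <= spec$apo_thickness_mm / 2 &
       p[, 3] >= apo_start_z(spec) &
       p[, 2] >= spec$apo_posterior_fraction * r)
  vx <- ifelse(axial, 0, -sign(p[, 1]) * sin(th))
  vz <- ifelse(axial, 1, cos(th))
  v <- unname(cbind(vx, 0, vz))
  v / sqrt(rowSums(v^2))
}

#' Map a fibre field onto mesh elements
#'
#' Evaluates the analytic bipennate field at element centroids, using the
#' mesh region tags (tendon and aponeurosis elements are axial).
#'
#' @param mesh a \code{tet_mesh} from \code{\link{make_bipennate_mesh}}.
#' @param spec optional \code{bipennate_spec}; defaults to the one stored
#'   in the mesh. Supply a modified spec (e.g. different pennation) to
#'   build steeper or flatter fields on the same mesh.
#' @return an element fibre field, see \code{\link{element_fibre_field}}.
#' @export
element_field_analytic <- function(mesh, spec = mesh$spec) {
  stopifnot(!is.null(spec))
  ctr <- tet_centroids(mesh)
  th <- spec$pennation_deg * pi / 180
  axial <- mesh$region != "muscle"
  vx <- ifelse(axial, 0, -sign(ctr[, 1]) * sin(th))
  vz <- ifelse(axial, 1, cos(th))
  v <- unname(cbind(vx, 0, vz))
  v <- v / sqrt(rowSums(v^2))
  element_fibre_field(v, source = "analytic", e2 = mesh$e2)
}

#' Synthesise streamlines through the bipennate field
#'
#' Streamlines mimic deterministic tractography of the phantom: seed
#' points are drawn uniformly inside the muscle volume and a track is
#' integrated from each seed in both directions of the analytic fibre
#' field by explicit stepping, with per-step angular noise (rotation by a
#' zero-mean Gaussian angle about a random axis perpendicular to the
#' travel direction) modelling tractography dispersion. Tracks terminate
#' at the muscle boundary; on the sheet side they do not stop dead on
#' first contact but -- as tracks following the locally axial diffusion
#' direction inside an aponeurosis do -- run on for a random arc length
#' (uniform between 2 mm and \code{apo_run_mm}) before terminating.
#' Fibres therefore both converge on (density) and terminate in
#' (divergence) the sheet voxels. Reproducible for a fixed seed.
#'
#' @param spec a \code{bipennate_spec}.
#' @param n number of streamlines (>= 1).
#' @param step_mm integration step.
#' @param noise_deg angular noise scale in degrees.
#' @param apo_run_mm maximum in-sheet run length before termination.
#' @param seed integer seed; defaults to the spec's.
#' @return a \code{streamline_set}.
#' @export
synth_streamlines <- function(spec, n = 2000, step_mm = 0.5, noise_deg = 0,
                              apo_run_mm = 10, seed = spec$seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  L <- spec$total_length_mm
  z0 <- spec$tendon_proximal_mm
  z1 <- L - spec$tendon_distal_mm
  # uniform seeds inside the muscle volume by rejection sampling
  seeds <- matrix(0, 0, 3)
  while (nrow(seeds) < n) {
    m <- 2L * (n - nrow(seeds)) + 16L
    cand <- cbind(runif(m, -spec$max_radius_mm, spec$max_radius_mm),
                  runif(m, -spec$max_radius_mm, spec$max_radius_mm),
                  runif(m, z0 + 1e-6, z1 - 1e-6))
    keep <- cand[, 1]^2 + cand[, 2]^2 <
      (0.98 * radius_profile(spec, cand[, 3]))^2
    seeds <- rbind(seeds, cand[keep, , drop = FALSE])
  }
  seeds <- seeds[seq_len(n), , drop = FALSE]
  run_budget <- runif(n, min(2, apo_run_mm), apo_run_mm)
  fwd <- march_streamlines(spec, seeds, +1, step_mm, noise_deg,
                           run_budget)
  bwd <- march_streamlines(spec, seeds, -1, step_mm, noise_deg,
                           rep(Inf, n))
  lines <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- bwd$len[i]
    back <- if (nb > 1L)
      cbind(bwd$pts[i, nb:2, 1L], bwd$pts[i, nb:2, 2L],
            bwd$pts[i, nb:2, 3L]) else NULL
    fore <- cbind(fwd$pts[i, seq_len(fwd$len[i]), 1L],
                  fwd$pts[i, seq_len(fwd$len[i]), 2L],
                  fwd$pts[i, seq_len(fwd$len[i]), 3L])
    lines[[i]] <- rbind(back, fore)
  }
  keep <- vapply(lines, nrow, integer(1)) >= 2L
  streamline_set(lines[keep])
}

# vectorised explicit marcher used by synth_streamlines; dirsign +-1
march_streamlines <- function(spec, seeds, dirsign, step_mm, noise_deg,
                              run_budget) {
  n <- nrow(seeds)
  L <- spec$total_length_mm
  z0 <- spec$tendon_proximal_mm
  z1 <- L - spec$tendon_distal_mm
  za <- apo_start_z(spec)
  half_t <- spec$apo_thickness_mm / 2
  noise_rad <- noise_deg * pi / 180
  max_steps <- ceiling(2.5 * L / step_mm)
  pts <- array(NA_real_, c(n, max_steps + 1L, 3L))
  pts[, 1L, ] <- seeds
  len <- rep(1L, n)
  cur <- seeds
  active <- rep(TRUE, n)
  sheet_run <- numeric(n)
  for (s in seq_len(max_steps)) {
    if (!any(active)) break
    ia <- which(active)
    d <- dirsign * analytic_bipennate_field(cur[ia, , drop = FALSE],
                                            spec)
    if (noise_rad > 0) {
      xi <- matrix(stats::rnorm(3 * length(ia)), ncol = 3)
      ax <- xi - rowSums(xi * d) * d
      axn <- sqrt(rowSums(ax^2))
      ok <- axn > 1e-12
      ax[ok, ] <- ax[ok, ] / axn[ok]
      ang <- stats::rnorm(length(ia), 0, noise_rad)
      dn <- d * cos(ang) + cross3(ax, d) * sin(ang)
      dn[!ok, ] <- d[!ok, , drop = FALSE]
      d <- dn / sqrt(rowSums(dn^2))
    }
    q <- cur[ia, , drop = FALSE] + step_mm * d
    in_sheet <- abs(q[, 1]) <= half_t & q[, 3] >= za &
      q[, 2] >= spec$apo_posterior_fraction * radius_profile(spec, q[, 3])
    outside <- q[, 3] <= z0 | q[, 3] >= z1 |
      q[, 1]^2 + q[, 2]^2 >= radius_profile(spec, q[, 3])^2
    adv <- !outside
    iadv <- ia[adv]
    if (length(iadv)) {
      cur[iadv, ] <- q[adv, , drop = FALSE]
      len[iadv] <- len[iadv] + 1L
      pts[cbind(iadv, len[iadv], 1L)] <- q[adv, 1]
      pts[cbind(iadv, len[iadv], 2L)] <- q[adv, 2]
      pts[cbind(iadv, len[iadv], 3L)] <- q[adv, 3]
      sheet_run[ia[adv & in_sheet]] <-
        sheet_run[ia[adv & in_sheet]] + step_mm
    }
    done <- sheet_run[ia] >= run_budget[ia]
    active[ia[outside | done]] <- FALSE
  }
  list(pts = pts, len = len)
}
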