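#' Per-voxel fields derived from a streamline set
#'
#' \code{tract_voxel_fields()} converts a streamline set into the three
#' co-registered per-voxel maps on which aponeurosis detection rests:
#' the fibre count (density map) \code{K}, the averaged fibre orientation
#' and the discrete divergence \code{D}. See the individual functions for
#' the definitions.
#'
#' @name tract-fields
NULL

# Sample table shared by count/orientation: resample all streamlines and
# keep, per sample, the stream id, sample order, voxel id and whether it
# falls inside the voxel-centred sphere.
streamline_samples <- function(set, grid, sphere_diameter_mm = 2.625,
                               resample_mm = 0.5) {
  if (sphere_diameter_mm > min(grid$spacing) + 1e-12)
    stop("sphere diameter must not exceed the smallest voxel spacing")
  rs <- resample_streamlines(set, resample_mm)
  np <- vapply(rs, nrow, integer(1))
  pts <- do.call(rbind, unclass(rs))
  stream <- rep.int(seq_along(rs), np)
  ord <- sequence(np)
  # local unit tangent per sample: segment tangent, repeated for last point
  tang <- do.call(rbind, lapply(rs, function(p) {
    t <- segment_tangents(p)
    rbind(t, t[nrow(t), , drop = FALSE])
  }))
  ci <- world_to_index(grid, pts)
  ijk <- floor(ci)
  ok <- in_grid(grid, ijk)
  centre <- index_to_world(grid, ijk + 0.5)
  d2 <- rowSums((pts - centre)^2)
  insphere <- ok & d2 <= (sphere_diameter_mm / 2)^2
  list(points = pts, stream = stream, order = ord, tangent = tang,
       voxel = ifelse(ok, flat_voxel_id(grid, ijk), NA_integer_),
       insphere = insphere)
}

#' Fibre density map: distinct streamlines per voxel-centred sphere
#'
#' For every voxel a sphere of the stated diameter is centred at the voxel
#' centre (the sphere must fit inside the voxel). \code{K(V)} counts the
#' number of distinct streamlines with at least one resampled point inside
#' that sphere; repeated visits by the same streamline count once.
#'
#' @param set a \code{streamline_set}.
#' @param grid a \code{voxel_grid}.
#' @param sphere_diameter_mm sphere diameter, default 2.625 mm; must not
#'   exceed the smallest voxel spacing.
#' @param resample_mm arc-length resampling step before the sphere test.
#' @return integer array of dimension \code{grid$shape}.
#' @export
voxel_fibre_count <- function(set, grid, sphere_diameter_mm = 2.625,
                              resample_mm = 0.5) {
  s <- streamline_samples(set, grid, sphere_diameter_mm, resample_mm)
  K <- array(0L, grid$shape)
  sel <- s$insphere
  if (any(sel)) {
    pair <- unique(cbind(s$voxel[sel], s$stream[sel]))
    tab <- table(pair[, 1])
    K[as.integer(names(tab))] <- as.integer(tab)
  }
  K
}

#' Averaged fibre orientation per voxel
#'
#' Each streamline contributes, per voxel, one unit vector: the normalised
#' chord from its first to its last resampled point inside the voxel's
#' sphere (falling back to the local tangent when only one sample lies
#' inside). The voxel orientation is the plain arithmetic mean of these
#' unit vectors, sign-flipped as a whole so that its component along the
#' principal axis \code{e2} is non-negative. The mean is deliberately not
#' re-normalised, so its magnitude (at most 1) reflects local coherence.
#' Voxels with no fibres get the zero vector.
#'
#' @inheritParams voxel_fibre_count
#' @return numeric array of dimension \code{c(grid$shape, 3)}.
#' @export
voxel_mean_orientation <- function(set, grid, sphere_diameter_mm = 2.625,
                                   resample_mm = 0.5) {
  s <- streamline_samples(set, grid, sphere_diameter_mm, resample_mm)
  A <- array(0, c(grid$shape, 3L))
  sel <- which(s$insphere)
  if (length(sel) == 0L) return(A)
  vox <- s$voxel[sel]; str <- s$stream[sel]; ord <- s$order[sel]
  grp <- paste(vox, str, sep = ":")
  o <- order(grp, ord)
  grp <- grp[o]; sel <- sel[o]
  first <- sel[!duplicated(grp)]
  last <- sel[rev(!duplicated(rev(grp)))]
  chord <- s$points[last, , drop = FALSE] - s$points[first, , drop = FALSE]
  nrm <- sqrt(rowSums(chord^2))
  single <- nrm < 1e-12
  if (any(single))
    chord[single, ] <- s$tangent[first[single], , drop = FALSE]
  a0 <- chord / sqrt(rowSums(chord^2))
  gv <- s$voxel[first]
  sx <- rowsum(a0, gv)
  k <- drop(rowsum(rep(1, nrow(a0)), gv))
  vid <- as.integer(rownames(sx))
  h <- ifelse(sx %*% grid$e2 >= 0, 1, -1)
  mean_a <- drop(h) * sx / k
  n <- prod(grid$shape)
  for (c_ in 1:3) {
    comp <- array(0, grid$shape)
    comp[vid] <- mean_a[, c_]
    A[(c_ - 1L) * n + seq_len(n)] <- comp
  }
  A
}

#' Discrete divergence of the streamline field
#'
#' Mode \code{"endpoint"} (the aponeurosis-detector default) counts, per
#' voxel, oriented streamlines entering (+1) minus leaving (-1). For any
#' polyline this net count equals [endpoint inside] - [start point inside],
#' so pass-through fibres contribute 0 and fibres terminating inside a
#' voxel contribute +1. Before counting, each streamline is oriented so
#' that its end-to-end chord has a non-negative component along \code{e2}
#' (disable with \code{orient = FALSE}); sinks such as an aponeurosis then
#' accumulate large positive values. Mode \code{"fd"} instead takes the
#' central-difference divergence of the averaged orientation field with the
#' voxel spacing, masked (zero) wherever a required neighbour has no fibres.
#'
#' @inheritParams voxel_fibre_count
#' @param mode \code{"endpoint"} or \code{"fd"}.
#' @param orient orient streamlines along \code{e2} before endpoint
#'   counting.
#' @param orientation optional precomputed orientation array for
#'   \code{mode = "fd"}.
#' @param count optional precomputed fibre count array for masking in
#'   \code{mode = "fd"}.
#' @return numeric array of dimension \code{grid$shape}.
#' @export
discrete_divergence <- function(set, grid, mode = c("endpoint", "fd"),
                                orient = TRUE, orientation = NULL,
                                count = NULL, sphere_diameter_mm = 2.625,
                                resample_mm = 0.5) {
  mode <- match.arg(mode)
  if (mode == "endpoint") {
    D <- array(0, grid$shape)
    starts <- t(vapply(set, function(p) p[1, ], numeric(3)))
    ends <- t(vapply(set, function(p) p[nrow(p), ], numeric(3)))
    if (orient) {
      flip <- drop((ends - starts) %*% grid$e2) < 0
      tmp <- starts[flip, , drop = FALSE]
      starts[flip, ] <- ends[flip, , drop = FALSE]
      ends[flip, ] <- tmp
    }
    for (sgn in c(1, -1)) {
      pts <- if (sgn > 0) ends else starts
      ijk <- floor(world_to_index(grid, pts))
      ok <- in_grid(grid, ijk)
      if (any(ok)) {
        tab <- table(flat_voxel_id(grid, ijk[ok, , drop = FALSE]))
        idx <- as.integer(names(tab))
        D[idx] <- D[idx] + sgn * as.integer(tab)
      }
    }
    return(D)
  }
  # finite-difference mode
  if (is.null(orientation))
    orientation <- voxel_mean_orientation(set, grid, sphere_diameter_mm,
                                          resample_mm)
  if (is.null(count))
    count <- voxel_fibre_count(set, grid, sphere_diameter_mm, resample_mm)
  valid <- count > 0
  sh <- grid$shape
  D <- array(0, sh)
  shift <- function(a, axis, by) {
    idx <- lapply(sh, seq_len)
    idx[[axis]] <- pmin(pmax(idx[[axis]] + by, 1L), sh[axis])
    a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  okall <- array(TRUE, sh)
  for (axis in 1:3) {
    comp <- array(orientation[, , , axis], sh)
    fwd <- shift(comp, axis, 1L); bwd <- shift(comp, axis, -1L)
    vf <- shift(valid, axis, 1L); vb <- shift(valid, axis, -1L)
    D <- D + (fwd - bwd) / (2 * grid$spacing[axis])
    okall <- okall & vf & vb
  }
  D[!(okall & valid)] <- 0
  D
}

#' Compute the full voxel field set from streamlines
#'
#' @inheritParams discrete_divergence
#' @param divergence_mode mode passed to \code{\link{discrete_divergence}}.
#' @return object of class \code{voxel_fields} with components
#'   \code{grid}, \code{count}, \code{orientation}, \code{divergence} and
#'   logical \code{valid} (voxels with at least one fibre).
#' @export
tract_voxel_fields <- function(set, grid, sphere_diameter_mm = 2.625,
                               resample_mm = 0.5,
                               divergence_mode = "endpoint") {
  K <- voxel_fibre_count(set, grid, sphere_diameter_mm, resample_mm)
  A <- voxel_mean_orientation(set, grid, sphere_diameter_mm, resample_mm)
  D <- discrete_divergence(set, grid, mode = divergence_mode,
                           orientation = A, count = K,
                           sphere_diameter_mm = sphere_diameter_mm,
                           resample_mm = resample_mm)
  structure(list(grid = grid, count = K, orientation = A, divergence = D,
                 valid = K > 0L),
            class = "voxel_fields")
}

#' @export
print.voxel_fields <- function(x, ...) {
  cat("Voxel field set on", paste(x$grid$shape, collapse = " x "),
      "grid;", sum(x$valid), "voxels with fibres; max K =",
      max(x$count), "; max D =", max(x$divergence), "\n")
  invisible(x)
}

#' Write voxel maps as NIfTI-1 and a CSV summary
#'
#' @param fields a \code{voxel_fields} object.
#' @param prefix output path prefix; writes \code{<prefix>_count.nii.gz},
#'   \code{<prefix>_divergence.nii.gz} and \code{<prefix>_summary.csv}
#'   (voxel index triplets, K, D for voxels with fibres).
#' @return invisibly, the paths written.
#' @export
write_voxel_fields <- function(fields, prefix) {
  g <- fields$grid
  paths <- c(count = paste0(prefix, "_count.nii.gz"),
             divergence = paste0(prefix, "_divergence.nii.gz"),
             summary = paste0(prefix, "_summary.csv"))
  # NIfTI sform expects index->world for 0-based voxel corners
  for (nm in c("count", "divergence")) {
    img <- RNifti::asNifti(fields[[nm]] * 1.0)
    img <- RNifti::`sform<-`(img, structure(g$affine, code = 2L))
    RNifti::writeNifti(img, paths[[nm]])
  }
  idx <- which(fields$valid, arr.ind = TRUE) - 1L
  utils::write.csv(data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                              K = fields$count[fields$valid],
                              D = fields$divergence[fields$valid]),
                   paths[["summary"]], row.names = FALSE)
  invisible(paths)
}
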