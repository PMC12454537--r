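#' Regular voxel grid with world coordinates
#'
#' A voxel grid ties a 3-D array shape to world (scanner) coordinates in mm
#' through an affine transform, and carries the muscle's principal axis
#' \code{e2} used to orient fibre vectors consistently. Voxel membership is
#' half-open in index space: a world point belongs to voxel \code{(i,j,k)}
#' (0-based) iff its continuous index lies in \code{[i, i+1)} etc. The voxel
#' centre sits at continuous index \code{(i+0.5, j+0.5, k+0.5)}.
#'
#' The default spacing 2.625 x 2.625 x 6.25 mm matches a typical thigh DTI
#' acquisition (in-plane resolution times slice thickness).
#'
#' @param shape integer length-3, number of voxels per axis.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin world coordinates of the corner of voxel (0,0,0). Ignored
#'   when \code{affine} is supplied.
#' @param affine optional 4x4 matrix mapping homogeneous 0-based continuous
#'   indices to world mm; must be invertible.
#' @param e2 unit vector of the principal muscle axis in world coordinates.
#' @return An object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(shape, spacing = c(2.625, 2.625, 6.25),
                       origin = c(0, 0, 0), affine = NULL,
                       e2 = c(0, 0, 1)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(affine)) {
    stopifnot(length(spacing) == 3L, all(spacing > 0))
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- origin
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("voxel_grid: affine must be invertible")
  e2 <- as.numeric(e2)
  n2 <- sqrt(sum(e2^2))
  if (n2 < 1e-12) stop("voxel_grid: e2 must be non-zero")
  structure(list(shape = shape,
                 spacing = c(sqrt(colSums(affine[1:3, 1:3]^2))),
                 affine = affine, inv_affine = solve(affine),
                 e2 = e2 / n2),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("Voxel grid:", paste(x$shape, collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 5), collapse = " x "),
      "mm\n")
  invisible(x)
}

#' Convert world coordinates to continuous 0-based voxel indices
#' @param grid a \code{voxel_grid}.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of continuous indices.
#' @export
world_to_index <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  h <- cbind(xyz, 1) %*% t(grid$inv_affine)
  h[, 1:3, drop = FALSE]
}

#' Convert continuous 0-based voxel indices to world coordinates
#' @inheritParams world_to_index
#' @param ijk n x 3 matrix of continuous indices.
#' @export
index_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

#' World coordinates of all voxel centres
#' @inheritParams world_to_index
#' @return \code{prod(shape)} x 3 matrix ordered with the first index
#'   varying fastest (R array order).
#' @export
voxel_centres <- function(grid) {
  g <- expand.grid(i = seq_len(grid$shape[1]) - 1L,
                   j = seq_len(grid$shape[2]) - 1L,
                   k = seq_len(grid$shape[3]) - 1L)
  index_to_world(grid, as.matrix(g) + 0.5)
}

#' Build a voxel grid covering a bounding box
#'
#' Axes listed in \code{centre_on} are shifted so that the stated world
#' coordinate falls exactly on a voxel centre, which keeps thin mid-plane
#' structures from straddling two voxel columns.
#'
#' @param lo,hi world corners of the box to cover (mm).
#' @param spacing voxel spacing (mm).
#' @param centre_on numeric length-3 with NA for axes left free.
#' @param e2 principal axis passed to \code{\link{voxel_grid}}.
#' @param pad number of extra voxels added on every side.
#' @export
voxel_grid_cover <- function(lo, hi, spacing = c(2.625, 2.625, 6.25),
                             centre_on = c(NA, NA, NA), e2 = c(0, 0, 1),
                             pad = 1L) {
  origin <- numeric(3); shape <- integer(3)
  for (a in 1:3) {
    if (is.na(centre_on[a])) {
      origin[a] <- lo[a] - pad * spacing[a]
    } else {
      # voxel centre at centre_on[a]: origin = centre_on - (m + 0.5) * d
      m <- ceiling((centre_on[a] - lo[a]) / spacing[a] - 0.5) + pad
      origin[a] <- centre_on[a] - (m + 0.5) * spacing[a]
    }
    shape[a] <- ceiling((hi[a] - origin[a]) / spacing[a]) + pad
  }
  voxel_grid(shape, spacing, origin, e2 = e2)
}

# flat 1-based voxel id from integer 0-based ijk triplets (matrix)
flat_voxel_id <- function(grid, ijk) {
  1L + ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3])
}

in_grid <- function(grid, ijk) {
  ijk[, 1] >= 0 & ijk[, 1] < grid$shape[1] &
    ijk[, 2] >= 0 & ijk[, 2] < grid$shape[2] &
    ijk[, 3] >= 0 & ijk[, 3] < grid$shape[3]
}
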