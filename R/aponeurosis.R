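#' Aponeurosis segmentation from divergence and density maps
#'
#' In a bipennate muscle the fibres of both halves insert into a central
#' aponeurosis sheet, which therefore acts as a sink of the oriented fibre
#' field and accumulates both a high discrete divergence and a high fibre
#' density. The detector thresholds the two maps jointly inside a region of
#' interest, removes small islands by connected-component filtering and
#' keeps the largest remaining component.
#'
#' @name aponeurosis
NULL

#' Threshold candidate aponeurosis voxels
#'
#' \code{mask = roi & (D > div_threshold) & (K > density_threshold)}; the
#' inequalities are strict ("exceed"). The default thresholds (3.0 for the
#' divergence, 600 for the density) correspond to a full-resolution
#' acquisition with on the order of 1e5 tracks; both scale with track count
#' and must be adapted to smaller streamline sets (see
#' \code{\link{detect_aponeurosis}}).
#'
#' @param D divergence array.
#' @param K fibre count array.
#' @param roi logical array, region of interest (e.g. excluding posterior
#'   voxels); \code{NULL} means the whole grid.
#' @param div_threshold,density_threshold strict lower thresholds.
#' @return logical array.
#' @export
threshold_candidates <- function(D, K, roi = NULL, div_threshold = 3.0,
                                 density_threshold = 600) {
  if (is.null(roi)) roi <- array(TRUE, dim(D))
  if (!all(dim(D) == dim(K)) || !all(dim(D) == dim(roi)))
    stop("threshold_candidates: D, K and roi must share one grid")
  roi & (D > div_threshold) & (K > density_threshold)
}

# 26- or 6-connected neighbour offsets
connectivity_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity != 26) stop("connectivity must be 6 or 26")
  g
}

#' Label connected components and remove small islands
#'
#' Components are found on the voxel adjacency graph (26-connectivity by
#' default, i.e. sharing a vertex, edge or face; 6-connectivity optional).
#' Components with fewer than \code{min_island_voxels} voxels are removed;
#' the survivors are labelled 1, 2, ... by decreasing size (ties broken by
#' the smallest flat voxel index contained).
#'
#' @param mask logical array.
#' @param min_island_voxels smallest surviving component size (strict
#'   "less than" removal).
#' @param connectivity 26 or 6.
#' @return integer array of labels (0 = background) with attribute
#'   \code{"sizes"}, the voxel counts of the ranked components.
#' @export
connected_filter <- function(mask, min_island_voxels = 10,
                             connectivity = 26) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  idx <- which(mask)
  if (length(idx) == 0L) {
    attr(lab, "sizes") <- integer(0)
    return(lab)
  }
  ai <- which(mask, arr.ind = TRUE)
  off <- connectivity_offsets(connectivity)
  pos <- integer(prod(dims)); pos[idx] <- seq_along(idx)
  edges <- NULL
  from <- NULL; to <- NULL
  for (r in seq_len(nrow(off))) {
    nb <- sweep(ai, 2, off[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nbid <- rep(0L, length(idx))
    nbid[ok] <- pos[(nb[ok, 3] - 1L) * dims[1] * dims[2] +
                      (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]]
    sel <- nbid > 0L
    from <- c(from, which(sel)); to <- c(to, nbid[sel])
  }
  if (length(from) == 0L) {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  } else {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  }
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_island_voxels)
  if (length(keep) == 0L) {
    attr(lab, "sizes") <- integer(0)
    return(lab)
  }
  # rank by size desc, tie-break: smallest flat voxel index in component
  minidx <- vapply(keep, function(cid) min(idx[comp$membership == cid]),
                   numeric(1))
  o <- order(-comp$csize[keep], minidx)
  keep <- keep[o]
  for (r in seq_along(keep))
    lab[idx[comp$membership == keep[r]]] <- r
  attr(lab, "sizes") <- as.integer(comp$csize[keep])
  lab
}

#' Extract the largest labelled component as a mask
#'
#' @param labelled integer label array from \code{\link{connected_filter}}
#'   (label 1 is the largest component).
#' @return logical array.
#' @export
largest_component <- function(labelled) {
  if (all(labelled == 0L))
    stop("largest_component: no components survive filtering; detection failed")
  labelled == 1L
}

#' Dice similarity coefficient of two voxel masks
#'
#' \code{2 |A & B| / (|A| + |B|)}. Two empty masks give 1 by the limit
#' convention; empty vs non-empty gives 0.
#'
#' @param a,b logical arrays on the same grid.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("dice: masks must share one grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1.0)
  2 * sum(a & b) / (na + nb)
}

#' Half-space region of interest
#'
#' Keeps voxels whose centre coordinate along \code{axis} is at least (or
#' at most) the stated fraction of the grid extent on that axis; used to
#' exclude e.g. the posterior voxels before aponeurosis detection.
#'
#' @param grid a \code{voxel_grid}.
#' @param axis axis index 1..3 (world axis of the grid's affine).
#' @param fraction cut position as a fraction of the extent.
#' @param keep \code{"above"} or \code{"below"}.
#' @return logical array.
#' @export
half_space_roi <- function(grid, axis, fraction, keep = c("above", "below")) {
  keep <- match.arg(keep)
  ctr <- voxel_centres(grid)[, axis]
  cut <- min(ctr) + fraction * (max(ctr) - min(ctr))
  sel <- if (keep == "above") ctr >= cut else ctr <= cut
  array(sel, grid$shape)
}

#' Detect the aponeurosis from voxel fields
#'
#' Runs the full detection chain: joint thresholding inside the RoI,
#' island removal, and extraction of the largest connected component.
#' Thresholds may be given as absolute values or, for the density map, as
#' \code{density_quantile}, the quantile of K over fibre-carrying RoI
#' voxels (useful when the track count differs from the full-scale
#' acquisition the absolute default 600 was calibrated for).
#'
#' @param fields a \code{voxel_fields} object.
#' @param roi logical array or \code{NULL}.
#' @param div_threshold strict divergence threshold.
#' @param density_threshold strict density threshold, or \code{NULL} to use
#'   \code{density_quantile}.
#' @param density_quantile quantile of K over valid RoI voxels used when
#'   \code{density_threshold} is \code{NULL}.
#' @param min_island_voxels,connectivity passed to
#'   \code{\link{connected_filter}}.
#' @param reference optional reference mask; when given, the Dice
#'   coefficient against the detected mask is reported.
#' @return object of class \code{apo_detection}: list with \code{mask},
#'   \code{labels}, \code{component_sizes}, thresholds used and optional
#'   \code{dice}.
#' @export
detect_aponeurosis <- function(fields, roi = NULL, div_threshold = 3.0,
                               density_threshold = NULL,
                               density_quantile = 0.75,
                               min_island_voxels = 10, connectivity = 26,
                               reference = NULL) {
  stopifnot(inherits(fields, "voxel_fields"))
  if (is.null(density_threshold)) {
    sel <- fields$valid
    if (!is.null(roi)) sel <- sel & roi
    density_threshold <- as.numeric(
      stats::quantile(fields$count[sel], density_quantile))
  }
  cand <- threshold_candidates(fields$divergence, fields$count, roi,
                               div_threshold, density_threshold)
  lab <- connected_filter(cand, min_island_voxels, connectivity)
  mask <- largest_component(lab)
  out <- list(mask = mask, labels = lab,
              component_sizes = attr(lab, "sizes"),
              div_threshold = div_threshold,
              density_threshold = density_threshold,
              min_island_voxels = min_island_voxels,
              connectivity = connectivity, grid = fields$grid)
  if (!is.null(reference)) out$dice <- dice(mask, reference)
  class(out) <- "apo_detection"
  out
}

#' @export
print.apo_detection <- function(x, ...) {
  cat("Aponeurosis detection:", sum(x$mask), "voxels in largest component",
      sprintf("(D > %.3g, K > %.3g, %d components kept)\n",
              x$div_threshold, x$density_threshold,
              length(x$component_sizes)))
  if (!is.null(x$dice))
    cat("Dice vs reference mask:", sprintf("%.4f\n", x$dice))
  invisible(x)
}

#' Write a detection report as JSON and the mask as NIfTI
#'
#' @param det an \code{apo_detection} object.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_detection_report <- function(det, prefix) {
  paths <- c(mask = paste0(prefix, "_mask.nii.gz"),
             report = paste0(prefix, "_report.json"))
  img <- RNifti::asNifti(array(as.integer(det$mask), dim(det$mask)))
  img <- RNifti::`sform<-`(img, structure(det$grid$affine, code = 2L))
  RNifti::writeNifti(img, paths[["mask"]])
  rep <- list(voxels = sum(det$mask),
              component_sizes = det$component_sizes,
              div_threshold = det$div_threshold,
              density_threshold = det$density_threshold,
              min_island_voxels = det$min_island_voxels,
              connectivity = det$connectivity)
  if (!is.null(det$dice)) rep$dice <- det$dice
  jsonlite::write_json(rep, paths[["report"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
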