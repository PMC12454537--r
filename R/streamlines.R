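#' Streamline sets
#'
#' A streamline set is an ordered list of polylines in world coordinates
#' (mm), the product of fibre tractography. Each streamline is an n x 3
#' matrix with n >= 2 and no repeated consecutive points.
#'
#' @param lines list of n_i x 3 numeric matrices (world mm).
#' @return object of class \code{streamline_set}.
#' @export
streamline_set <- function(lines) {
  stopifnot(is.list(lines))
  lines <- lapply(lines, function(p) {
    p <- matrix(as.numeric(p), ncol = 3)
    if (nrow(p) < 2L) stop("streamline_set: each streamline needs >= 2 points")
    seg <- diff(p)
    if (any(rowSums(seg^2) == 0))
      stop("streamline_set: consecutive points must be distinct")
    dimnames(p) <- NULL
    p
  })
  structure(lines, class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  np <- vapply(x, nrow, integer(1))
  cat("Streamline set:", length(x), "streamlines,",
      sum(np), "points\n")
  invisible(x)
}

#' @export
`[.streamline_set` <- function(x, i) {
  structure(unclass(x)[i], class = "streamline_set")
}

#' Arc lengths of streamlines
#' @param set a \code{streamline_set}.
#' @return numeric vector of polyline arc lengths in mm.
#' @export
streamline_lengths <- function(set) {
  vapply(set, function(p) sum(sqrt(rowSums(diff(p)^2))), numeric(1))
}

# unit tangents of the segments of one polyline ((n-1) x 3)
segment_tangents <- function(p) {
  seg <- diff(p)
  seg / sqrt(rowSums(seg^2))
}

#' Maximum per-step turning angle of each streamline
#' @param set a \code{streamline_set}.
#' @return numeric vector, degrees; 0 for two-point streamlines.
#' @export
streamline_max_turn <- function(set) {
  vapply(set, function(p) {
    t <- segment_tangents(p)
    if (nrow(t) < 2L) return(0)
    d <- rowSums(t[-nrow(t), , drop = FALSE] * t[-1, , drop = FALSE])
    max(acos(pmin(1, pmax(-1, d)))) * 180 / pi
  }, numeric(1))
}

#' Resample streamlines at a fixed arc-length step
#'
#' Samples are taken every \code{step_mm} along the polyline (linear
#' interpolation), always keeping the first and last point. A 0.5 mm step
#' guarantees that no voxel-centred sphere of the default 2.625 mm diameter
#' can be skipped between consecutive samples.
#'
#' @param set a \code{streamline_set}.
#' @param step_mm arc-length sampling step in mm.
#' @return a \code{streamline_set} of resampled polylines.
#' @export
resample_streamlines <- function(set, step_mm = 0.5) {
  stopifnot(step_mm > 0)
  out <- lapply(set, function(p) {
    seglen <- sqrt(rowSums(diff(p)^2))
    s <- c(0, cumsum(seglen))
    total <- s[length(s)]
    ss <- seq(0, total, by = step_mm)
    if (total - ss[length(ss)] > 1e-9 * step_mm) ss <- c(ss, total)
    # arc lengths can repeat at machine precision; drop such samples
    ss <- ss[c(TRUE, diff(ss) > 1e-9 * step_mm)]
    if (length(ss) < 2L) ss <- c(0, total)
    cbind(approx(s, p[, 1], xout = ss)$y,
          approx(s, p[, 2], xout = ss)$y,
          approx(s, p[, 3], xout = ss)$y)
  })
  streamline_set(out)
}

#' Fractional anisotropy from diffusion-tensor eigenvalues
#'
#' FA is computed as \code{prefactor * sqrt((L1-L2)^2 + (L2-L3)^2 +
#' (L3-L1)^2) / sqrt(L1^2 + L2^2 + L3^2)}. The default prefactor 1/2 follows
#' the tracking-parameter convention used with muscle tractography here; the
#' textbook normalisation \code{sqrt(1/2)} (giving FA in [0,1]) is available
#' through \code{prefactor = sqrt(0.5)}. FA is invariant to a common scaling
#' of the eigenvalues.
#'
#' @param eigenvalues length-3 vector or n x 3 matrix of non-negative
#'   diffusion-tensor eigenvalues.
#' @param prefactor scalar multiplier, default 1/2.
#' @return FA value(s).
#' @export
compute_fa <- function(eigenvalues, prefactor = 0.5) {
  ev <- matrix(as.numeric(eigenvalues), ncol = 3)
  ssq <- rowSums(ev^2)
  if (any(ssq == 0))
    stop("compute_fa: FA undefined for all-zero eigenvalues")
  num <- sqrt((ev[, 1] - ev[, 2])^2 + (ev[, 2] - ev[, 3])^2 +
                (ev[, 3] - ev[, 1])^2)
  fa <- prefactor * num / sqrt(ssq)
  if (length(fa) == 1L) fa[[1]] else fa
}

#' Filter streamlines by length, turning angle and fractional anisotropy
#'
#' Keeps streamlines whose arc length lies within \code{length_range_mm},
#' whose per-step turning angle never exceeds \code{max_turn_deg}, and --
#' when per-point FA samples are supplied -- whose FA stays within
#' \code{fa_range}. Defaults follow standard muscle-tractography practice:
#' FA in [0.1, 0.5], turning angle at most 10 degrees, length 15--200 mm.
#' Streamline order is preserved; an empty input yields an empty output.
#'
#' @param set a \code{streamline_set}.
#' @param fa_values optional list of per-point FA vectors, parallel to
#'   \code{set}.
#' @param fa_range length-2 inclusive FA range.
#' @param max_turn_deg maximum allowed per-step turning angle (degrees).
#' @param length_range_mm length-2 inclusive arc-length range (mm).
#' @return the filtered \code{streamline_set}.
#' @export
filter_streamlines <- function(set, fa_values = NULL,
                               fa_range = c(0.1, 0.5),
                               max_turn_deg = 10,
                               length_range_mm = c(15, 200)) {
  if (length(set) == 0L) return(set)
  len <- streamline_lengths(set)
  keep <- len >= length_range_mm[1] & len <= length_range_mm[2]
  keep <- keep & streamline_max_turn(set) <= max_turn_deg
  if (!is.null(fa_values)) {
    stopifnot(length(fa_values) == length(set))
    ok <- vapply(fa_values, function(v)
      all(v >= fa_range[1] & v <= fa_range[2]), logical(1))
    keep <- keep & ok
  }
  set[keep]
}
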