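#' Comparing two element fibre fields
#'
#' Fibre orientations have no intrinsic sign, so both fields are first
#' aligned to the principal muscle axis. The relative fibre inclination
#' condenses the difference between two fields into a signed per-element
#' angle: positive where the first (reference) field is steeper -- more
#' aligned with the principal axis -- than the second, negative where it
#' is flatter.
#'
#' @name fibre-metrics
NULL

#' Align fibre vectors to the principal axis
#'
#' Sign-flips every vector whose component along \code{e2} is negative;
#' vectors exactly orthogonal to \code{e2} keep their sign. Idempotent.
#'
#' @param field n x 3 matrix of unit vectors (or an
#'   \code{element_fibre_field}).
#' @param e2 principal axis.
#' @return the aligned field (same class as the input).
#' @export
align_to_axis <- function(field, e2 = attr(field, "e2")) {
  if (is.null(e2)) stop("align_to_axis: e2 required")
  flip <- drop(field %*% e2) < 0
  field[flip, ] <- -field[flip, , drop = FALSE]
  field
}

#' Relative fibre inclination between two aligned fields
#'
#' Per element, \code{90 - acos(((a - b)/|a - b|) . e2)} in degrees,
#' where \code{a} is the first (reference) field and \code{b} the second.
#' The sign encodes which field is steeper with respect to the principal
#' axis: positive means \code{a} is steeper. Where the two vectors are
#' (numerically) identical the difference direction is undefined; those
#' elements get 0 and are flagged in the logical attribute
#' \code{"degenerate"} so summaries can exclude them.
#'
#' @param a_ref,b n x 3 matrices of unit vectors, both aligned to
#'   \code{e2} (see \code{\link{align_to_axis}}).
#' @param e2 principal axis.
#' @param eps threshold on \code{|a - b|} below which an element is
#'   treated as degenerate.
#' @return numeric vector of signed angles in degrees, in [-90, 90].
#' @export
relative_inclination <- function(a_ref, b, e2 = attr(a_ref, "e2"),
                                 eps = 1e-9) {
  if (is.null(e2)) stop("relative_inclination: e2 required")
  a_ref <- matrix(as.numeric(a_ref), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d <- a_ref - b
  nrm <- sqrt(rowSums(d^2))
  deg <- nrm < eps
  nrm[deg] <- 1
  ct <- pmin(1, pmax(-1, (d %*% e2) / nrm))
  alpha <- 90 - acos(ct) * 180 / pi
  alpha[deg] <- 0
  structure(drop(alpha), degenerate = deg)
}

#' Relative inclination in a deformed configuration
#'
#' Pushes both fibre fields forward with the per-element deformation
#' gradient (\code{F a}), re-normalises, re-aligns to the principal axis
#' and applies \code{\link{relative_inclination}}. Uniform scalings of
#' \code{F} cancel.
#'
#' @param a_ref,b n x 3 matrices of unit vectors.
#' @param F_el deformation gradients: 3 x 3 matrix (applied to all
#'   elements) or n x 3 x 3 array (\code{det F > 0} required).
#' @param e2 principal axis.
#' @param eps degeneracy threshold, see
#'   \code{\link{relative_inclination}}.
#' @return numeric vector of signed angles in degrees.
#' @export
deformed_inclination <- function(a_ref, b, F_el,
                                 e2 = attr(a_ref, "e2"), eps = 1e-9) {
  push <- function(v) {
    v <- matrix(as.numeric(v), ncol = 3)
    if (is.matrix(F_el)) {
      if (det(F_el) <= 0) stop("deformed_inclination: det F must be > 0")
      w <- v %*% t(F_el)
    } else {
      stopifnot(length(dim(F_el)) == 3L, dim(F_el)[1] == nrow(v))
      w <- cbind(
        F_el[, 1, 1] * v[, 1] + F_el[, 1, 2] * v[, 2] + F_el[, 1, 3] * v[, 3],
        F_el[, 2, 1] * v[, 1] + F_el[, 2, 2] * v[, 2] + F_el[, 2, 3] * v[, 3],
        F_el[, 3, 1] * v[, 1] + F_el[, 3, 2] * v[, 2] + F_el[, 3, 3] * v[, 3])
    }
    w <- w / sqrt(rowSums(w^2))
    align_to_axis(w, e2)
  }
  relative_inclination(push(a_ref), push(b), e2 = e2, eps = eps)
}

#' Histogram counts of angular values
#'
#' Half-open bins \code{[lo, hi)}, with the last bin closed so the
#' maximum value is counted.
#'
#' @param values finite numeric vector.
#' @param bin_edges increasing vector of bin edges.
#' @param normalise divide counts by the number of values.
#' @return data frame with \code{lower}, \code{upper}, \code{count}.
#' @export
angle_histogram <- function(values, bin_edges, normalise = FALSE) {
  stopifnot(all(is.finite(values)), !is.unsorted(bin_edges),
            length(bin_edges) >= 2)
  nb <- length(bin_edges) - 1L
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  counts <- tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
  out <- data.frame(lower = bin_edges[-length(bin_edges)],
                    upper = bin_edges[-1],
                    count = if (normalise) counts / length(values)
                    else counts)
  out
}
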