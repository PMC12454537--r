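#' Element fibre fields
#'
#' One 3-vector per tetrahedron, unit on valid elements and aligned so the
#' component along the principal axis \code{e2} is non-negative.
#'
#' @param vectors E x 3 matrix.
#' @param source provenance tag: \code{"thermal"}, \code{"analytic"} or
#'   \code{"dti_mapped"}.
#' @param valid logical vector of length E.
#' @param e2 principal axis used for alignment.
#' @return object of class \code{element_fibre_field} (an E x 3 matrix
#'   with attributes \code{source}, \code{valid}, \code{e2}).
#' @export
element_fibre_field <- function(vectors, source = "analytic",
                                valid = rep(TRUE, nrow(vectors)),
                                e2 = c(0, 0, 1)) {
  v <- matrix(as.numeric(vectors), ncol = 3)
  structure(v, source = source, valid = valid, e2 = e2,
            class = "element_fibre_field")
}

#' @export
print.element_fibre_field <- function(x, ...) {
  cat("Element fibre field (", attr(x, "source"), "): ", nrow(x),
      " elements, ", sum(attr(x, "valid")), " valid\n", sep = "")
  invisible(x)
}

#' Power-law Dirichlet boundary-condition parameters
#'
#' The thermal fibre generator drives steady-state heat conduction with
#' fixed temperatures \code{T0} at the proximal tendon end face (inlet)
#' and \code{T1} at the distal one (outlet), plus power-law ramps
#' \code{T0 * n^alpha1} on the muscle surface and \code{T0 * n^alpha2} on
#' the aponeurosis surface, where \code{n} is the normalised axial
#' coordinate of each boundary set (1 at its proximal end by default, so
#' the ramps meet \code{T0} on the proximal side). Temperatures are
#' dimensionless: only flux directions are used. \code{0^0} is taken as 1
#' so that \code{alpha = 0} yields a constant ramp.
#'
#' @param T1 outlet temperature (\code{!= T0}); negative values simply
#'   steepen the axial gradient.
#' @param alpha1,alpha2 ramp exponents (>= 0) for the muscle and
#'   aponeurosis surfaces.
#' @param T0 inlet temperature, default 1.
#' @param proximal_high if \code{TRUE} (default) the ramp coordinate is 1
#'   at the proximal end of each face set.
#' @return object of class \code{thermal_bc_params}.
#' @export
thermal_bc_params <- function(T1, alpha1, alpha2, T0 = 1,
                              proximal_high = TRUE) {
  stopifnot(T0 != T1, alpha1 >= 0, alpha2 >= 0)
  structure(list(T0 = T0, T1 = T1, alpha1 = alpha1, alpha2 = alpha2,
                 proximal_high = proximal_high),
            class = "thermal_bc_params")
}

#' @export
print.thermal_bc_params <- function(x, ...) {
  cat(sprintf("Thermal BCs: T0=%g, T1=%g, alpha1=%g, alpha2=%g\n",
              x$T0, x$T1, x$alpha1, x$alpha2))
  invisible(x)
}

ramp_values <- function(z, T0, alpha, proximal_high) {
  zmin <- min(z); zmax <- max(z)
  if (zmax - zmin < 1e-12)
    stop("build_dirichlet_values: degenerate axial range on a ramped ",
         "face set")
  n <- if (proximal_high) (zmax - z) / (zmax - zmin)
  else (z - zmin) / (zmax - zmin)
  T0 * n^alpha                      # 0^0 == 1 in R, as intended
}

#' Nodal Dirichlet values from the boundary-condition parameters
#'
#' Inlet nodes take \code{T0}, outlet nodes \code{T1}; muscle-surface and
#' aponeurosis-surface nodes take the power-law ramps evaluated on each
#' set's own axial range. A node in several sets takes the value of the
#' highest-precedence set: inlet > outlet > aponeurosis > muscle.
#'
#' @param mesh a \code{tet_mesh} with all four face sets.
#' @param params a \code{thermal_bc_params}.
#' @return list with integer \code{nodes} and numeric \code{values}.
#' @export
build_dirichlet_values <- function(mesh, params) {
  need <- c("inlet", "outlet", "aponeurosis_surface", "muscle_surface")
  if (!all(need %in% names(mesh$face_sets)))
    stop("build_dirichlet_values: face sets missing: ",
         paste(setdiff(need, names(mesh$face_sets)), collapse = ", "))
  zc <- drop(mesh$nodes %*% mesh$e2)
  val <- rep(NA_real_, nrow(mesh$nodes))
  assign_set <- function(val, nodes, values) {
    fresh <- is.na(val[nodes])
    val[nodes[fresh]] <- values[fresh]
    val
  }
  n_in <- face_set_nodes(mesh, "inlet")
  val <- assign_set(val, n_in, rep(params$T0, length(n_in)))
  n_out <- face_set_nodes(mesh, "outlet")
  val <- assign_set(val, n_out, rep(params$T1, length(n_out)))
  n_apo <- face_set_nodes(mesh, "aponeurosis_surface")
  val <- assign_set(val, n_apo, ramp_values(zc[n_apo], params$T0,
                                            params$alpha2,
                                            params$proximal_high))
  n_mus <- face_set_nodes(mesh, "muscle_surface")
  val <- assign_set(val, n_mus, ramp_values(zc[n_mus], params$T0,
                                            params$alpha1,
                                            params$proximal_high))
  nodes <- which(!is.na(val))
  list(nodes = nodes, values = val[nodes])
}

# E x 3 slice of the gradient array without dimension dropping
grad_slice <- function(g, a) matrix(g[, a, ], ncol = 3)

# assemble the sparse Laplace stiffness matrix (unit conductivity)
assemble_laplacian <- function(mesh, sg = shape_gradients(mesh)) {
  el <- mesh$elems
  ii <- jj <- xx <- vector("list", 16L)
  t <- 0L
  for (a in 1:4) for (b in 1:4) {
    t <- t + 1L
    ii[[t]] <- el[, a]; jj[[t]] <- el[, b]
    xx[[t]] <- sg$volume * rowSums(grad_slice(sg$grad, a) *
                                     grad_slice(sg$grad, b))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2L))
}

#' Solve steady-state heat conduction on a tet mesh
#'
#' Galerkin linear-tetrahedron discretisation of the Laplace equation with
#' the supplied Dirichlet constraints, solved with a sparse direct
#' (Cholesky) factorisation -- ample for the mesh sizes this package
#' targets. The reduced system is symmetric positive definite; the
#' relative residual is checked against 1e-10.
#'
#' @param mesh a \code{tet_mesh}.
#' @param dirichlet list with \code{nodes} and \code{values} (from
#'   \code{\link{build_dirichlet_values}}).
#' @return numeric vector of nodal temperatures.
#' @export
solve_steady_heat <- function(mesh, dirichlet) {
  if (length(dirichlet$nodes) == 0L)
    stop("solve_steady_heat: at least one constrained node is required")
  N <- nrow(mesh$nodes)
  K <- assemble_laplacian(mesh)
  Tval <- numeric(N)
  fixed <- dirichlet$nodes
  Tval[fixed] <- dirichlet$values
  free <- setdiff(seq_len(N), fixed)
  if (length(free)) {
    Kff <- K[free, free, drop = FALSE]
    rhs <- -K[free, fixed, drop = FALSE] %*% dirichlet$values
    Tf <- Matrix::solve(Kff, rhs)
    Tval[free] <- as.numeric(Tf)
    res <- sqrt(sum((Kff %*% Tf - rhs)^2))
    scl <- max(sqrt(sum(rhs^2)), 1e-300)
    if (res / scl > 1e-8)
      warning("solve_steady_heat: relative residual ", res / scl)
  }
  Tval
}

#' Element heat-flux fibre directions
#'
#' Per element the heat flux is \code{q = -kappa * grad T} (constant on a
#' linear tetrahedron). Fibre vectors are the unit flux directions,
#' sign-flipped so their component along \code{e2} is non-negative; the
#' conductivity only scales the magnitude and cancels. Elements with flux
#' magnitude below \code{1e-12} times the mean are flagged invalid.
#'
#' @param mesh a \code{tet_mesh}.
#' @param temperature nodal temperature vector.
#' @param kappa thermal conductivity (scale-irrelevant), default 1.
#' @return an \code{element_fibre_field} with source \code{"thermal"}.
#' @export
element_flux_fibres <- function(mesh, temperature, kappa = 1) {
  sg <- shape_gradients(mesh)
  el <- mesh$elems
  g <- sg$grad
  q <- -kappa * (temperature[el[, 1]] * grad_slice(g, 1) +
                   temperature[el[, 2]] * grad_slice(g, 2) +
                   temperature[el[, 3]] * grad_slice(g, 3) +
                   temperature[el[, 4]] * grad_slice(g, 4))
  nrm <- sqrt(rowSums(q^2))
  valid <- nrm > 1e-12 * mean(nrm)
  v <- q
  v[valid, ] <- q[valid, , drop = FALSE] / nrm[valid]
  v[!valid, ] <- 0
  flip <- drop(v %*% mesh$e2) < 0
  v[flip, ] <- -v[flip, , drop = FALSE]
  element_fibre_field(v, source = "thermal", valid = valid, e2 = mesh$e2)
}

#' Thermal fibre field for given boundary-condition parameters
#'
#' Convenience wrapper: builds the Dirichlet values, solves the steady
#' heat equation and converts element fluxes to unit fibre vectors. The
#' nodal temperature field is attached as attribute
#' \code{"temperature"}.
#'
#' @param mesh a \code{tet_mesh}.
#' @param params a \code{thermal_bc_params}.
#' @return an \code{element_fibre_field}.
#' @export
thermal_fibre_field <- function(mesh, params) {
  bc <- build_dirichlet_values(mesh, params)
  Tval <- solve_steady_heat(mesh, bc)
  f <- element_flux_fibres(mesh, Tval)
  attr(f, "temperature") <- Tval
  f
}
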