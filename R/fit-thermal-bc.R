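#' Reusable steady-heat solver for one mesh
#'
#' Precomputes everything that does not depend on the boundary-condition
#' parameters -- the stiffness matrix, the constrained node set and its
#' sparse Cholesky factorisation -- so that many parameter sets can be
#' evaluated cheaply (one triangular solve each), as required by the
#' design-of-experiments loop.
#'
#' @param mesh a tagged \code{tet_mesh}.
#' @return function \code{(params)} mapping a \code{thermal_bc_params} (or
#'   a length-3 vector \code{c(T1, alpha1, alpha2)}) to an
#'   \code{element_fibre_field}.
#' @export
thermal_solver <- function(mesh) {
  sg <- shape_gradients(mesh)
  K <- assemble_laplacian(mesh, sg)
  probe <- build_dirichlet_values(mesh, thermal_bc_params(-1, 1, 1))
  fixed <- probe$nodes
  N <- nrow(mesh$nodes)
  free <- setdiff(seq_len(N), fixed)
  Kff <- K[free, free, drop = FALSE]
  Kfc <- K[free, fixed, drop = FALSE]
  Ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)
  el <- mesh$elems
  g1 <- grad_slice(sg$grad, 1); g2 <- grad_slice(sg$grad, 2)
  g3 <- grad_slice(sg$grad, 3); g4 <- grad_slice(sg$grad, 4)
  e2 <- mesh$e2
  function(params) {
    if (!inherits(params, "thermal_bc_params"))
      params <- thermal_bc_params(params[1], params[2], params[3])
    bc <- build_dirichlet_values(mesh, params)
    Tval <- numeric(N)
    Tval[bc$nodes] <- bc$values
    if (length(free)) {
      rhs <- -Kfc %*% bc$values
      Tval[free] <- as.numeric(Matrix::solve(Ch, rhs))
    }
    q <- -(Tval[el[, 1]] * g1 + Tval[el[, 2]] * g2 +
             Tval[el[, 3]] * g3 + Tval[el[, 4]] * g4)
    nrm <- sqrt(rowSums(q^2))
    valid <- nrm > 1e-12 * mean(nrm)
    q[valid, ] <- q[valid, , drop = FALSE] / nrm[valid]
    q[!valid, ] <- 0
    flip <- drop(q %*% e2) < 0
    q[flip, ] <- -q[flip, , drop = FALSE]
    f <- element_fibre_field(q, source = "thermal", valid = valid, e2 = e2)
    attr(f, "temperature") <- Tval
    f
  }
}

#' Fit thermal boundary-condition parameters to a reference fibre field
#'
#' The central estimator of the package. Given a tagged tetrahedral mesh
#' and a reference element fibre field (e.g. mapped from tractography, or
#' a synthetic ground truth), it identifies the power-law Dirichlet
#' boundary-condition parameters (T1, alpha1, alpha2) whose steady-state
#' heat-flux directions best match the reference, in the sense of the
#' mean per-element cosine distance over a trusted sub-region of the
#' muscle. The procedure follows the metamodel-based design: a
#' maximin Latin-hypercube design over the parameter box, one thermal
#' solve per design point, a radial-basis-function metamodel of the mean
#' deviation, seeded simulated annealing on the metamodel under the
#' constraint \code{alpha2 >= alpha1}, and a final constrained direct
#' search on the true (simulator) objective.
#'
#' @param mesh a tagged \code{tet_mesh}.
#' @param reference an \code{element_fibre_field} on the same mesh.
#' @param space a \code{design_space}; its \code{n_designs} and
#'   \code{seed} drive the design stage.
#' @param subregion logical element mask, or \code{NULL} to build one
#'   with \code{\link{make_subregion}}.
#' @param surface_offset_mm,distal_cut_fraction passed to
#'   \code{\link{make_subregion}} when \code{subregion} is \code{NULL}.
#' @param kernel RBF kernel for the metamodel.
#' @param n_holdout number of fresh design points used to estimate the
#'   metamodel's out-of-sample R^2 (0 disables).
#' @param polish \code{"direct"} (default): final local search on the
#'   simulator objective; \code{"metamodel"}: on the metamodel;
#'   \code{"none"}.
#' @param sensitivity_mc Monte-Carlo size for the variance-based
#'   sensitivity of the metamodel (0 disables).
#' @return object of class \code{thermal_bc_fit}; see
#'   \code{\link{summary.thermal_bc_fit}}.
#' @seealso \code{\link{thermal_fibre_field}}, \code{\link{anneal_bc}}
#' @export
fit_thermal_bc <- function(mesh, reference, space = design_space(),
                           subregion = NULL, surface_offset_mm = 3.0,
                           distal_cut_fraction = 0.1,
                           kernel = "multiquadric", n_holdout = 20L,
                           polish = c("direct", "metamodel", "none"),
                           sensitivity_mc = 4096L) {
  polish <- match.arg(polish)
  stopifnot(inherits(mesh, "tet_mesh"),
            nrow(reference) == nrow(mesh$elems))
  if (is.null(subregion))
    subregion <- make_subregion(mesh, surface_offset_mm,
                                distal_cut_fraction)
  solver <- thermal_solver(mesh)
  direct <- function(s)
    as.numeric(suppressWarnings(
      mean_deviation(solver(s), reference, subregion)))
  designs <- sample_designs(space)
  responses <- apply(designs, 1, direct)
  # the exponents act as powers of the normalised axial coordinate, so
  # the response varies fastest near zero; a square-root stretch of the
  # exponent axes equalises the metamodel's resolution there
  warp <- function(s) cbind(s[, 1], sqrt(s[, 2]), sqrt(s[, 3]))
  wlo <- c(space$lower[1], sqrt(space$lower[2]), sqrt(space$lower[3]))
  whi <- c(space$upper[1], sqrt(space$upper[2]), sqrt(space$upper[3]))
  mm <- fit_metamodel(warp(designs), responses, kernel = kernel,
                      width = 0.45, lower = wlo, upper = whi)
  predict_objective <- function(s)
    predict(mm, warp(matrix(as.numeric(s), ncol = 3)))
  surrogate <- function(s) predict_objective(matrix(s, 1))
  opt <- anneal_bc(surrogate, space, seed = space$seed + 1L,
                   polish_objective = NULL)
  # multi-start local polish: the annealed optimum plus the best feasible
  # design points, each refined on the chosen objective
  feas <- designs[, 3] - designs[, 2] >= 0
  cand <- order(ifelse(feas, responses, Inf))[1:3]
  starts <- rbind(opt$par, designs[cand, , drop = FALSE])
  pobj <- switch(polish, direct = direct, metamodel = surrogate,
                 none = NULL)
  par <- opt$par; value <- direct(par)
  if (!is.null(pobj)) {
    for (r in seq_len(nrow(starts))) {
      po <- polish_constrained(starts[r, ], pobj, space)
      v <- direct(po)
      if (v < value) { par <- po; value <- v }
    }
  } else {
    for (r in seq_len(nrow(starts))) {
      v <- direct(starts[r, ])
      if (v < value) { par <- starts[r, ]; value <- v }
    }
  }
  names(par) <- space$names
  holdout <- NULL; r2_holdout <- NA_real_
  if (n_holdout > 0) {
    set.seed(space$seed + 2L)
    h <- matrix(stats::runif(3 * n_holdout), ncol = 3)
    h <- sweep(sweep(h, 2, space$upper - space$lower, "*"), 2,
               space$lower, "+")
    colnames(h) <- space$names
    sim <- apply(h, 1, direct)
    pred <- predict_objective(h)
    r2_holdout <- r2_score(pred, sim)
    holdout <- list(designs = h, simulated = sim, predicted = pred)
  }
  sens <- if (sensitivity_mc > 0)
    sensitivity(predict_objective, space, n_mc = sensitivity_mc,
                seed = space$seed + 3L)
  else NULL
  field_opt <- solver(par)
  md <- mean_deviation(field_opt, reference, subregion)
  structure(list(coefficients = par, value = value,
                 mean_angle_deg = mean(attr(md, "angles_deg")),
                 designs = designs, responses = responses,
                 metamodel = mm,
                 predict_objective = predict_objective,
                 r2_holdout = r2_holdout,
                 holdout = holdout, sensitivity = sens,
                 subregion = subregion, reference = reference,
                 field = field_opt, mesh = mesh, space = space,
                 polish = polish, n_evaluations = opt$n_evaluations),
            class = "thermal_bc_fit")
}

#' @export
print.thermal_bc_fit <- function(x, ...) {
  cat("Thermal boundary-condition fit\n")
  cat("  coefficients:",
      paste(sprintf("%s = %.4f", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  mean cosine deviation over sub-region: %.5f (mean angle %.2f deg)\n",
              x$value, x$mean_angle_deg))
  invisible(x)
}

#' @export
coef.thermal_bc_fit <- function(object, ...) object$coefficients

#' Summary of a thermal boundary-condition fit
#' @param object a \code{thermal_bc_fit}.
#' @param ... unused.
#' @return object of class \code{summary.thermal_bc_fit}.
#' @export
summary.thermal_bc_fit <- function(object, ...) {
  ang <- attr(mean_deviation(object$field, object$reference,
                             object$subregion), "angles_deg")
  structure(list(coefficients = object$coefficients,
                 value = object$value,
                 angle_summary = summary(ang),
                 angle_sd = stats::sd(ang),
                 r2_holdout = object$r2_holdout,
                 sensitivity = object$sensitivity,
                 n_designs = nrow(object$designs),
                 n_subregion = sum(object$subregion),
                 excluded_fraction = attr(object$subregion,
                                          "excluded_fraction"),
                 n_evaluations = object$n_evaluations),
            class = "summary.thermal_bc_fit")
}

#' @export
print.summary.thermal_bc_fit <- function(x, ...) {
  cat("Thermal boundary-condition fit\n")
  cat("  coefficients:",
      paste(sprintf("%s = %.4f", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  mean cosine deviation: %.5f\n", x$value))
  cat("  angular deviation (deg):\n")
  print(x$angle_summary)
  cat(sprintf("  sd of angular deviation: %.2f deg\n", x$angle_sd))
  if (!is.na(x$r2_holdout))
    cat(sprintf("  metamodel hold-out R^2: %.4f\n", x$r2_holdout))
  if (!is.null(x$sensitivity))
    cat("  sensitivity (%):",
        paste(sprintf("%s = %.1f", names(x$sensitivity), x$sensitivity),
              collapse = ", "), "\n")
  cat(sprintf("  %d design points, %d sub-region elements (%.0f%% of muscle excluded)\n",
              x$n_designs, x$n_subregion, 100 * x$excluded_fraction))
  invisible(x)
}

#' Predict the fibre field at given boundary-condition parameters
#'
#' @param object a \code{thermal_bc_fit}.
#' @param params length-3 vector (T1, alpha1, alpha2) or a
#'   \code{thermal_bc_params}; default the fitted coefficients.
#' @param what \code{"field"} for the element fibre field, or
#'   \code{"objective"} for the metamodel's prediction of the mean
#'   deviation at \code{params}.
#' @param ... unused.
#' @export
predict.thermal_bc_fit <- function(object, params = coef(object),
                                   what = c("field", "objective"), ...) {
  what <- match.arg(what)
  if (what == "objective")
    return(object$predict_objective(matrix(as.numeric(params),
                                           ncol = 3)))
  solver <- thermal_solver(object$mesh)
  solver(params)
}

#' @export
fitted.thermal_bc_fit <- function(object, ...) object$field

#' Per-element residual cosine distances of the fit
#'
#' @param object a \code{thermal_bc_fit}.
#' @param ... unused.
#' @return numeric vector over the sub-region elements (attribute
#'   \code{"elements"} holds their indices).
#' @export
residuals.thermal_bc_fit <- function(object, ...) {
  ok <- object$subregion & attr(object$field, "valid") &
    attr(object$reference, "valid")
  y <- cosine_distance(object$field[ok, , drop = FALSE],
                       object$reference[ok, , drop = FALSE])
  structure(y, elements = which(ok))
}

#' Plot a thermal boundary-condition fit
#'
#' Left: histogram of per-element angular deviations over the sub-region
#' at the optimum. Right: metamodel response surface over
#' (alpha1, alpha2) at the fitted T1, with the infeasible half
#' (alpha2 < alpha1) shaded and the optimum marked.
#'
#' @param x a \code{thermal_bc_fit}.
#' @param which subset of \code{c("histogram", "surface")}.
#' @param ... unused.
#' @export
plot.thermal_bc_fit <- function(x, which = c("histogram", "surface"),
                                ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  if ("histogram" %in% which) {
    y <- residuals(x)
    ang <- acos(pmin(1, pmax(-1, 1 - y))) * 180 / pi
    graphics::hist(ang, breaks = 30, main = "Angular deviation",
                   xlab = "degrees", col = "grey80")
  }
  if ("surface" %in% which) {
    a1 <- seq(x$space$lower[2], x$space$upper[2], length.out = 60)
    a2 <- seq(x$space$lower[3], x$space$upper[3], length.out = 60)
    g <- as.matrix(expand.grid(T1 = x$coefficients[1], alpha1 = a1,
                               alpha2 = a2))
    z <- matrix(x$predict_objective(g), length(a1), length(a2))
    graphics::contour(a1, a2, z, xlab = "alpha1", ylab = "alpha2",
                      main = "Metamodel response")
    graphics::polygon(c(x$space$lower[2], x$space$upper[2],
                        x$space$upper[2]),
                      c(x$space$lower[3], x$space$lower[3],
                        x$space$upper[3]),
                      col = grDevices::adjustcolor("steelblue", 0.2),
                      border = NA)
    graphics::points(x$coefficients[2], x$coefficients[3], pch = 15,
                     col = "purple")
  }
  invisible(x)
}
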