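#' Quasi-static finite-element mechanics of the MTA complex
#'
#' Total-Lagrangian equilibrium on linear tetrahedra with the
#' transversely isotropic active/passive constitutive model, solved by
#' incremental loading and full Newton iterations (element tangents by
#' numerical differentiation of the internal force, line search, adaptive
#' step halving on divergence). Linear tetrahedra are accepted -- as in
#' the reference workflow -- with the usual caveat that they are stiff
#' under near-incompressibility; the finite bulk modulus keeps the
#' response usable.
#'
#' @name mechanics
NULL

m9 <- function(i, j) i + 3L * (j - 1L)

# det of E x 9 column-major 3x3 matrices
det3_9 <- function(F9) {
  F9[, 1] * (F9[, 5] * F9[, 9] - F9[, 8] * F9[, 6]) -
    F9[, 4] * (F9[, 2] * F9[, 9] - F9[, 8] * F9[, 3]) +
    F9[, 7] * (F9[, 2] * F9[, 6] - F9[, 5] * F9[, 3])
}

# vectorised total PK2 stress for E x 9 deformation gradients
pk2_elements <- function(F9, a0, mp, alpha = 0, lambda_shift = 0) {
  E <- nrow(F9)
  C9 <- matrix(0, E, 9L)
  for (i in 1:3) for (j in i:3) {
    v <- F9[, m9(1L, i)] * F9[, m9(1L, j)] +
      F9[, m9(2L, i)] * F9[, m9(2L, j)] +
      F9[, m9(3L, i)] * F9[, m9(3L, j)]
    C9[, m9(i, j)] <- v
    C9[, m9(j, i)] <- v
  }
  J <- det3_9(F9)
  if (any(J <= 0)) stop("pk2_elements: inverted element (det F <= 0)")
  I3 <- J^2
  I1 <- C9[, 1] + C9[, 5] + C9[, 9]
  trC2 <- rowSums(C9[, c(1, 5, 9)]^2) +
    2 * (C9[, m9(1, 2)]^2 + C9[, m9(1, 3)]^2 + C9[, m9(2, 3)]^2)
  I2 <- 0.5 * (I1^2 - trC2)
  # inverse of symmetric C via adjugate
  Ci9 <- matrix(0, E, 9L)
  Ci9[, m9(1, 1)] <- C9[, 5] * C9[, 9] - C9[, m9(2, 3)]^2
  Ci9[, m9(2, 2)] <- C9[, 1] * C9[, 9] - C9[, m9(1, 3)]^2
  Ci9[, m9(3, 3)] <- C9[, 1] * C9[, 5] - C9[, m9(1, 2)]^2
  Ci9[, m9(1, 2)] <- C9[, m9(1, 3)] * C9[, m9(2, 3)] -
    C9[, m9(1, 2)] * C9[, 9]
  Ci9[, m9(1, 3)] <- C9[, m9(1, 2)] * C9[, m9(2, 3)] -
    C9[, m9(1, 3)] * C9[, 5]
  Ci9[, m9(2, 3)] <- C9[, m9(1, 2)] * C9[, m9(1, 3)] -
    C9[, 1] * C9[, m9(2, 3)]
  Ci9[, m9(2, 1)] <- Ci9[, m9(1, 2)]
  Ci9[, m9(3, 1)] <- Ci9[, m9(1, 3)]
  Ci9[, m9(3, 2)] <- Ci9[, m9(2, 3)]
  Ci9 <- Ci9 / I3
  B1 <- 2 * mp$C1 * I3^(-1 / 3) + 2 * mp$C2 * I3^(-2 / 3) * I1
  B2 <- -2 * mp$C2 * I3^(-2 / 3)
  B3 <- -(2 / 3) * mp$C1 * I3^(-1 / 3) * I1 -
    (4 / 3) * mp$C2 * I3^(-2 / 3) * I2
  vol <- mp$k * (J - 1) * J
  I4 <- a0[, 1]^2 * C9[, 1] + a0[, 2]^2 * C9[, 5] + a0[, 3]^2 * C9[, 9] +
    2 * (a0[, 1] * a0[, 2] * C9[, m9(1, 2)] +
           a0[, 1] * a0[, 3] * C9[, m9(1, 3)] +
           a0[, 2] * a0[, 3] * C9[, m9(2, 3)])
  lam <- pmax(sqrt(pmax(I4, 1e-12)) + lambda_shift, 1e-6)
  coef_p <- ifelse(lam >= 1, mp$C3 * (lam^mp$C4 - 1) / lam^2, 0)
  asc <- lam <= mp$lambda_opt
  w <- ifelse(asc, mp$delta_w_asc, mp$delta_w_dsc)
  nu <- ifelse(asc, mp$nu_asc, mp$nu_dsc)
  coef_a <- if (alpha > 0)
    alpha * mp$activation_scale * mp$sigma_max / lam^2 *
    exp(-abs((lam / mp$lambda_opt - 1) / w)^nu) else 0
  fib <- coef_p + coef_a
  S9 <- B2 * C9 + B3 * Ci9 + vol * Ci9
  S9[, c(1, 5, 9)] <- S9[, c(1, 5, 9)] + B1
  for (i in 1:3) for (j in 1:3)
    S9[, m9(i, j)] <- S9[, m9(i, j)] + fib * a0[, i] * a0[, j]
  attr(S9, "lambda_s") <- lam
  S9
}

# per-element material parameter vectors from region tags
material_vectors <- function(region, materials) {
  tend <- region %in% c("tendon_proximal", "tendon_distal", "aponeurosis")
  pick <- function(f) ifelse(tend, materials$tendon_aponeurosis[[f]],
                             materials$muscle[[f]])
  list(C1 = pick("C1"), C2 = pick("C2"), k = pick("k"), C3 = pick("C3"),
       C4 = pick("C4"), sigma_max = pick("sigma_max"),
       delta_w_asc = pick("delta_w_asc"),
       delta_w_dsc = pick("delta_w_dsc"), nu_asc = pick("nu_asc"),
       nu_dsc = pick("nu_dsc"), lambda_opt = pick("lambda_opt"),
       activation_scale = pick("activation_scale"))
}

# deformation gradients (E x 9) from element nodal displacements (E x 12,
# columns x1 y1 z1 x2 ... z4)
def_grad_from_ue <- function(ue, g) {
  E <- nrow(ue)
  F9 <- matrix(0, E, 9L)
  F9[, c(1, 5, 9)] <- 1
  for (a in 1:4) {
    ga <- g[[a]]
    for (i in 1:3) {
      ua <- ue[, (a - 1L) * 3L + i]
      for (j in 1:3)
        F9[, m9(i, j)] <- F9[, m9(i, j)] + ua * ga[, j]
    }
  }
  F9
}

# element internal forces (E x 12) for displacements ue
element_forces <- function(ue, g, vol, a0, mp, alpha, lambda_shift) {
  F9 <- def_grad_from_ue(ue, g)
  S9 <- pk2_elements(F9, a0, mp, alpha, lambda_shift)
  # P = F S
  P9 <- matrix(0, nrow(F9), 9L)
  for (i in 1:3) for (j in 1:3)
    P9[, m9(i, j)] <- F9[, m9(i, 1)] * S9[, m9(1, j)] +
      F9[, m9(i, 2)] * S9[, m9(2, j)] + F9[, m9(i, 3)] * S9[, m9(3, j)]
  f <- matrix(0, nrow(F9), 12L)
  for (a in 1:4) {
    ga <- g[[a]]
    for (i in 1:3)
      f[, (a - 1L) * 3L + i] <- vol *
        (P9[, m9(i, 1)] * ga[, 1] + P9[, m9(i, 2)] * ga[, 2] +
           P9[, m9(i, 3)] * ga[, 3])
  }
  attr(f, "lambda_s") <- attr(S9, "lambda_s")
  f
}

# persistent per-mesh FE precomputation
fem_setup <- function(mesh, field, materials) {
  sg <- shape_gradients(mesh)
  g <- lapply(1:4, function(a) grad_slice(sg$grad, a))
  el <- mesh$elems
  dofs <- matrix(0L, nrow(el), 12L)
  for (a in 1:4) for (i in 1:3)
    dofs[, (a - 1L) * 3L + i] <- 3L * (el[, a] - 1L) + i
  list(g = g, vol = sg$volume, dofs = dofs,
       a0 = matrix(as.numeric(field), ncol = 3),
       mp = material_vectors(mesh$region, materials),
       # the applied initial fibre stretch is a muscle-tissue load; the
       # tendons and aponeurosis carry no activation pre-stretch
       shift_scale = as.numeric(mesh$region == "muscle"),
       n_dof = 3L * nrow(mesh$nodes), elems = el)
}

assemble_internal <- function(fe, u) {
  ue <- matrix(u[fe$dofs], ncol = 12L)
  f <- element_forces(ue, fe$g, fe$vol, fe$a0, fe$mp,
                      attr(u, "alpha") %||% 0,
                      (attr(u, "lambda_shift") %||% 0) * fe$shift_scale)
  fint <- numeric(fe$n_dof)
  acc <- rowsum(as.vector(f), as.vector(fe$dofs))
  fint[as.integer(rownames(acc))] <- acc
  attr(fint, "lambda_s") <- attr(f, "lambda_s")
  fint
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assemble the FD tangent stiffness (sparse), given current u
assemble_tangent <- function(fe, u, alpha, lambda_shift, h) {
  ue <- matrix(u[fe$dofs], ncol = 12L)
  E <- nrow(ue)
  ii <- jj <- xx <- vector("list", 12L)
  for (d in 1:12) {
    up <- ue; um <- ue
    up[, d] <- up[, d] + h
    um[, d] <- um[, d] - h
    fd <- (element_forces(up, fe$g, fe$vol, fe$a0, fe$mp, alpha,
                          lambda_shift * fe$shift_scale) -
             element_forces(um, fe$g, fe$vol, fe$a0, fe$mp, alpha,
                            lambda_shift * fe$shift_scale)) / (2 * h)
    ii[[d]] <- as.vector(fe$dofs)
    jj[[d]] <- rep(fe$dofs[, d], 12L)
    xx[[d]] <- as.vector(fd)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(fe$n_dof, fe$n_dof))
}

# Newton solve at fixed load: fixed dofs carry prescribed values in u0.
# The tangent turns indefinite or singular on the descending limb of the
# active force-length relation (negative fibre stiffness), where the
# quasi-static path can pass limit points. The iteration is therefore a
# pseudo-transient Levenberg-damped Newton: (K + mu*D) du = -r with D
# the diagonal magnitude of K. Steps are accepted even when the residual
# rises moderately (the pseudo-dynamic ride over a fold), and mu follows
# switched evolution relaxation -- it shrinks with the residual ratio
# after good steps and grows on rejected or inverting steps.
fem_newton <- function(fe, u0, fixed, f_ext, alpha = 0, lambda_shift = 0,
                       tol = 1e-8, max_iter = 200L, h_char = 1e-6) {
  u <- u0
  free <- setdiff(seq_len(fe$n_dof), fixed)
  attr(u, "alpha") <- alpha; attr(u, "lambda_shift") <- lambda_shift
  fint <- assemble_internal(fe, u)
  r <- fint - f_ext
  rn <- sqrt(sum(r[free]^2))
  scale_ref <- max(sqrt(sum(f_ext[free]^2)), sqrt(sum(fint^2)), 1e-10)
  best <- list(u = u, rn = rn, fint = fint)
  mu <- 0
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (rn <= tol * scale_ref)
      return(list(u = u, converged = TRUE, iterations = it - 1L,
                  fint = fint, residual = rn / scale_ref))
    K <- assemble_tangent(fe, u, alpha, lambda_shift, h_char)
    Kff <- K[free, free, drop = FALSE]
    dscale <- mean(abs(Matrix::diag(Kff)))
    accepted <- FALSE
    for (sub in 1:15) {
      Kmu <- if (mu > 0) Kff + mu * dscale *
        Matrix::Diagonal(length(free)) else Kff
      du <- try(-as.numeric(Matrix::solve(Kmu, r[free])), silent = TRUE)
      if (!inherits(du, "try-error")) {
        ut <- u
        ut[free] <- u[free] + du
        attr(ut, "alpha") <- alpha
        attr(ut, "lambda_shift") <- lambda_shift
        ft <- tryCatch(assemble_internal(fe, ut), error = function(e) NULL)
        if (!is.null(ft)) {
          rt <- sqrt(sum((ft - f_ext)[free]^2))
          # accept decreases always; with damping active, also accept a
          # moderate rise (pseudo-transient move past a fold)
          if (rt < rn || (mu > 0 && rt < 3 * rn)) {
            ratio <- rt / rn
            u <- ut; r <- ft - f_ext; rn <- rt; fint <- ft
            if (rn < best$rn) best <- list(u = u, rn = rn, fint = fint)
            mu <- if (ratio < 1) max(mu * ratio, 0) else mu
            if (mu > 0 && mu < 1e-10) mu <- 0
            accepted <- TRUE
            break
          }
        }
      }
      mu <- max(mu * 8, 1e-6)
    }
    if (!accepted) break
  }
  u <- best$u; fint <- best$fint
  attr(u, "alpha") <- alpha; attr(u, "lambda_shift") <- lambda_shift
  list(u = u, converged = best$rn <= tol * scale_ref, iterations = it,
       fint = fint, residual = best$rn / scale_ref)
}

#' Load-case definition for the quasi-static solver
#'
#' \code{"passive_stretch"}: proximal tendon end fixed, nodal forces
#' summing to \code{f2_max} (N) along the principal axis applied to the
#' distal tendon end face and ramped linearly over \code{n_steps}.
#' \code{"isometric"}: both tendon ends fixed; first the applied initial
#' fibre stretch \code{lambda_ini_app} is equilibrated as an internal
#' load (ramped over \code{n_steps_prestretch}), then the activation
#' level is ramped from 0 to 1 over \code{n_steps}.
#'
#' @param kind \code{"passive_stretch"} or \code{"isometric"}.
#' @param f2_max total applied force (N) for passive stretch.
#' @param lambda_ini_app applied initial fibre stretch for the isometric
#'   case (1.10, 1.25, 1.35 are typical study levels).
#' @param n_steps load steps of the main ramp.
#' @param n_steps_prestretch steps of the pre-stretch ramp.
#' @return object of class \code{load_case}.
#' @export
load_case <- function(kind = c("passive_stretch", "isometric"),
                      f2_max = 5, lambda_ini_app = 1.25, n_steps = 10L,
                      n_steps_prestretch = 5L) {
  kind <- match.arg(kind)
  stopifnot(n_steps >= 1L, n_steps_prestretch >= 1L)
  structure(list(kind = kind, f2_max = f2_max,
                 lambda_ini_app = lambda_ini_app,
                 n_steps = as.integer(n_steps),
                 n_steps_prestretch = as.integer(n_steps_prestretch)),
            class = "load_case")
}

#' Solve a quasi-static load case
#'
#' @param mesh a tagged \code{tet_mesh}.
#' @param field an \code{element_fibre_field} (unit reference fibre
#'   directions).
#' @param materials named list from \code{\link{default_materials}}.
#' @param case a \code{\link{load_case}}.
#' @param tol relative residual tolerance of the Newton solver.
#' @param max_iter Newton iterations per step (a diverged step is retried
#'   once with halved increments).
#' @return object of class \code{muscle_sim}: list of per-step states
#'   (displacements \code{u} as N x 3, per-element \code{lambda_s},
#'   \code{alpha}, applied force, proximal reaction along the axis) plus
#'   the summary \code{table}.
#' @export
solve_quasistatic <- function(mesh, field, materials = default_materials(),
                              case = load_case(), tol = 1e-8,
                              max_iter = 30L) {
  stopifnot(inherits(mesh, "tet_mesh"), nrow(field) == nrow(mesh$elems))
  fe <- fem_setup(mesh, field, materials)
  e2 <- mesh$e2
  n_in <- face_set_nodes(mesh, "inlet")
  n_out <- face_set_nodes(mesh, "outlet")
  dof_in <- as.vector(outer(1:3, 3L * (n_in - 1L), "+"))
  dof_out <- as.vector(outer(1:3, 3L * (n_out - 1L), "+"))
  u <- numeric(fe$n_dof)
  states <- list()
  axis_dof <- function(nodes) 3L * (nodes - 1L) + which.max(abs(e2))
  run_steps <- function(u, fixed, targets,
                        prev0 = list(f_ext = numeric(fe$n_dof),
                                     alpha = 0, shift = 0)) {
    # targets: list of (f_ext, alpha, shift) endpoints per step; a failed
    # step is bisected recursively (adaptive halving)
    prev <- prev0
    advance <- function(u, from, to, depth) {
      sol <- fem_newton(fe, u, fixed, to$f_ext, to$alpha, to$shift,
                        tol = tol, max_iter = max_iter)
      if (sol$converged) return(sol)
      if (depth >= 5L)
        stop("solve_quasistatic: Newton did not converge (residual ",
             signif(sol$residual, 3), ") at alpha=", to$alpha,
             ", shift=", to$shift)
      mid <- list(f_ext = (from$f_ext + to$f_ext) / 2,
                  alpha = (from$alpha + to$alpha) / 2,
                  shift = (from$shift + to$shift) / 2)
      sol_mid <- advance(u, from, mid, depth + 1L)
      advance(sol_mid$u, mid, to, depth + 1L)
    }
    for (tg in targets) {
      sol <- advance(u, prev, tg, 0L)
      u <- sol$u
      prev <- tg
      lam <- attr(sol$fint, "lambda_s")
      reaction <- -sum(sol$fint[dof_in] *
                         rep(e2, times = length(n_in)))
      states[[length(states) + 1L]] <<-
        list(u = matrix(u, ncol = 3L, byrow = TRUE),
             lambda_s = lam, alpha = tg$alpha, shift = tg$shift,
             applied = tg$applied,
             reaction_proximal = reaction,
             mean_outlet_disp = mean(matrix(u, ncol = 3L,
                                            byrow = TRUE)[n_out, ] %*% e2),
             iterations = sol$iterations)
      u
    }
    u
  }
  zero_f <- numeric(fe$n_dof)
  if (case$kind == "passive_stretch") {
    fixed <- dof_in
    targets <- lapply(seq_len(case$n_steps), function(s) {
      fr <- s / case$n_steps
      f <- zero_f
      per_node <- fr * case$f2_max / length(n_out)
      for (i in 1:3)
        f[3L * (n_out - 1L) + i] <- per_node * e2[i]
      list(f_ext = f, alpha = 0, shift = 0, applied = fr * case$f2_max)
    })
    u <- run_steps(u, fixed, targets)
  } else {
    fixed <- c(dof_in, dof_out)
    shift_max <- case$lambda_ini_app - 1
    t1 <- lapply(seq_len(case$n_steps_prestretch), function(s)
      list(f_ext = zero_f, alpha = 0,
           shift = s / case$n_steps_prestretch * shift_max,
           applied = 0))
    u <- run_steps(u, fixed, t1)
    t2 <- lapply(seq_len(case$n_steps), function(s)
      list(f_ext = zero_f, alpha = s / case$n_steps, shift = shift_max,
           applied = 0))
    u <- run_steps(u, fixed, t2,
                   prev0 = list(f_ext = zero_f, alpha = 0,
                                shift = shift_max))
  }
  tab <- data.frame(
    step = seq_along(states),
    applied_force = vapply(states, `[[`, numeric(1), "applied"),
    alpha = vapply(states, `[[`, numeric(1), "alpha"),
    mean_outlet_disp = vapply(states, `[[`, numeric(1),
                              "mean_outlet_disp"),
    reaction_proximal = vapply(states, `[[`, numeric(1),
                               "reaction_proximal"))
  structure(list(states = states, table = tab, case = case,
                 mesh = mesh, e2 = e2),
            class = "muscle_sim")
}

#' @export
print.muscle_sim <- function(x, ...) {
  cat("Quasi-static simulation (", x$case$kind, "), ",
      length(x$states), " steps\n", sep = "")
  print(utils::tail(x$table, 3L))
  invisible(x)
}

#' Passive stretch load case (force-displacement)
#'
#' Fixes the proximal tendon end, ramps nodal forces summing to
#' \code{f2_max} Newton along the principal axis on the distal end face,
#' and records the mean axial displacement of the distal face per step.
#'
#' @inheritParams solve_quasistatic
#' @param f2_max peak applied force (N).
#' @param n_steps load steps.
#' @return a \code{muscle_sim}; its \code{table} holds the
#'   force-displacement curve.
#' @export
run_load_case_1 <- function(mesh, field, materials = default_materials(),
                            f2_max = 5, n_steps = 10L, tol = 1e-8) {
  solve_quasistatic(mesh, field, materials,
                    load_case("passive_stretch", f2_max = f2_max,
                              n_steps = n_steps), tol = tol)
}

#' Isometric contraction load case (reaction vs activation)
#'
#' Both tendon ends fixed; an applied initial fibre stretch is
#' equilibrated as an internal load, then activation ramps from 0 to 1
#' while the proximal reaction force is recorded.
#'
#' @inheritParams solve_quasistatic
#' @param lambda_ini_app applied initial fibre stretch.
#' @param n_steps activation steps.
#' @param n_steps_prestretch pre-stretch ramp steps.
#' @return a \code{muscle_sim}; rows of its \code{table} with
#'   \code{alpha > 0} (and the last pre-stretch row at \code{alpha = 0})
#'   form the reaction-activation curve.
#' @export
run_load_case_2 <- function(mesh, field, materials = default_materials(),
                            lambda_ini_app = 1.25, n_steps = 10L,
                            n_steps_prestretch = 5L, tol = 1e-8) {
  solve_quasistatic(mesh, field, materials,
                    load_case("isometric",
                              lambda_ini_app = lambda_ini_app,
                              n_steps = n_steps,
                              n_steps_prestretch = n_steps_prestretch),
                    tol = tol)
}

#' Per-element deformation gradients for a displacement field
#'
#' @param mesh a \code{tet_mesh}.
#' @param u N x 3 nodal displacement matrix.
#' @return E x 3 x 3 array of deformation gradients.
#' @export
deformation_gradients <- function(mesh, u) {
  sg <- shape_gradients(mesh)
  g <- lapply(1:4, function(a) grad_slice(sg$grad, a))
  el <- mesh$elems
  ue <- matrix(0, nrow(el), 12L)
  for (a in 1:4) for (i in 1:3)
    ue[, (a - 1L) * 3L + i] <- u[el[, a], i]
  F9 <- def_grad_from_ue(ue, g)
  array(F9, c(nrow(el), 3L, 3L))
}
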