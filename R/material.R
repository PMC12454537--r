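#' Material parameters of the soft-tissue model
#'
#' Transversely isotropic, quasi-compressible hyperelastic model: a
#' Mooney-Rivlin matrix with a volumetric penalty, a passive fibre stress
#' active above unit fibre stretch, and an active fibre stress with an
#' exponential force-length relation around the optimal stretch.
#' Defaults are the calibrated soft-tissue constants: muscle
#' C1 = 2e-3, C2 = 2e-4 MPa, bulk k = 7.2 MPa, fibre-passive C3 = 5e-3
#' MPa, C4 = 6, sigma_max = 0.3 MPa, Delta-W 0.15/0.16, nu 2/6,
#' Lambda_opt = 1.3; tendon/aponeurosis C1 = 2e-2, C2 = 2e-3 MPa,
#' C3 = 0.5 MPa, C4 = 25 and no active response.
#'
#' The printed parameter table assigns gamma = 0 to muscle and gamma = 1
#' to tendon, which read literally would disable activation exactly in
#' the contractile tissue; it is kept as \code{gamma_printed} for
#' traceability while \code{activation_scale} (1 for muscle, 0 for
#' tendon/aponeurosis) is what multiplies the active stress.
#'
#' @param region \code{"muscle"} or \code{"tendon_aponeurosis"}.
#' @param C1,C2 Mooney-Rivlin constants (MPa).
#' @param k bulk modulus of the volumetric penalty (MPa).
#' @param C3,C4 passive fibre constants (MPa, -).
#' @param sigma_max peak active stress at optimal stretch (MPa).
#' @param delta_w_asc,delta_w_dsc,nu_asc,nu_dsc force-length shape
#'   constants of the ascending/descending branches.
#' @param lambda_opt optimal fibre stretch.
#' @param activation_scale multiplier of the active stress (1 muscle, 0
#'   tendon/aponeurosis).
#' @param gamma_printed the parameter-table gamma, kept for reference.
#' @return object of class \code{material_params}.
#' @export
material_params <- function(region = c("muscle", "tendon_aponeurosis"),
                            C1 = NULL, C2 = NULL, k = 7.2, C3 = NULL,
                            C4 = NULL, sigma_max = 0.3,
                            delta_w_asc = 0.15, delta_w_dsc = 0.16,
                            nu_asc = 2, nu_dsc = 6, lambda_opt = 1.3,
                            activation_scale = NULL,
                            gamma_printed = NULL) {
  region <- match.arg(region)
  if (region == "muscle") {
    if (is.null(C1)) C1 <- 2e-3
    if (is.null(C2)) C2 <- 2e-4
    if (is.null(C3)) C3 <- 5e-3
    if (is.null(C4)) C4 <- 6
    if (is.null(activation_scale)) activation_scale <- 1
    if (is.null(gamma_printed)) gamma_printed <- 0
  } else {
    if (is.null(C1)) C1 <- 2e-2
    if (is.null(C2)) C2 <- 2e-3
    if (is.null(C3)) C3 <- 0.5
    if (is.null(C4)) C4 <- 25
    if (is.null(activation_scale)) activation_scale <- 0
    if (is.null(gamma_printed)) gamma_printed <- 1
  }
  stopifnot(k > 0, C1 >= 0, C2 >= 0, C3 >= 0, C4 >= 0, lambda_opt > 1)
  structure(list(region = region, C1 = C1, C2 = C2, k = k, C3 = C3,
                 C4 = C4, sigma_max = sigma_max,
                 delta_w_asc = delta_w_asc, delta_w_dsc = delta_w_dsc,
                 nu_asc = nu_asc, nu_dsc = nu_dsc,
                 lambda_opt = lambda_opt,
                 activation_scale = activation_scale,
                 gamma_printed = gamma_printed),
            class = "material_params")
}

#' Default material set for the muscle-tendon-aponeurosis complex
#' @return named list with \code{muscle} and \code{tendon_aponeurosis}
#'   \code{\link{material_params}}.
#' @export
default_materials <- function() {
  list(muscle = material_params("muscle"),
       tendon_aponeurosis = material_params("tendon_aponeurosis"))
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf(paste0("Material (%s): C1=%g C2=%g k=%g C3=%g C4=%g MPa/-; ",
                     "active: sigma_max=%g, L_opt=%g, scale=%g\n"),
              x$region, x$C1, x$C2, x$k, x$C3, x$C4, x$sigma_max,
              x$lambda_opt, x$activation_scale))
  invisible(x)
}

#' Isotropic second Piola-Kirchhoff stress
#'
#' \code{S_iso = B1 I + B2 C + B3 C^-1 + k (det F - 1) sqrt(I3) C^-1} with
#' \code{B1 = 2 C1 I3^(-1/3) + 2 C2 I3^(-2/3) I1},
#' \code{B2 = -2 C2 I3^(-2/3)} and
#' \code{B3 = -(2/3) C1 I3^(-1/3) I1 - (4/3) C2 I3^(-2/3) I2}. Vanishes
#' identically in the reference configuration.
#'
#' @param F 3 x 3 deformation gradient with positive determinant.
#' @param mat a \code{material_params}.
#' @return 3 x 3 symmetric stress tensor (MPa).
#' @export
s_iso <- function(F, mat) {
  J <- det(F)
  if (J <= 0) stop("s_iso: det F must be positive (inverted element)")
  C <- t(F) %*% F
  Ci <- solve(C)
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(C * C))
  I3 <- J^2
  B1 <- 2 * mat$C1 * I3^(-1 / 3) + 2 * mat$C2 * I3^(-2 / 3) * I1
  B2 <- -2 * mat$C2 * I3^(-2 / 3)
  B3 <- -(2 / 3) * mat$C1 * I3^(-1 / 3) * I1 -
    (4 / 3) * mat$C2 * I3^(-2 / 3) * I2
  B1 * diag(3) + B2 * C + B3 * Ci + mat$k * (J - 1) * sqrt(I3) * Ci
}

#' Passive fibre stress
#'
#' \code{(C3 / Lambda_s^2) (Lambda_s^C4 - 1) M} for fibre stretch at or
#' above 1, zero in compression; \code{M = a0 (x) a0}.
#'
#' @param lambda_s fibre stretch.
#' @param mat a \code{material_params}.
#' @param M structural tensor (3 x 3), or \code{NULL} to return the
#'   scalar coefficient.
#' @return 3 x 3 tensor (or scalar coefficient).
#' @export
s_passive <- function(lambda_s, mat, M = NULL) {
  stopifnot(lambda_s > 0)
  coef <- if (lambda_s >= 1)
    mat$C3 * (lambda_s^mat$C4 - 1) / lambda_s^2 else 0
  if (is.null(M)) coef else coef * M
}

#' Active fibre stress
#'
#' \code{alpha * scale * (sigma_max / Lambda_s^2) *
#' exp(-|(Lambda_s/Lambda_opt - 1)/DW|^nu) M}, with the ascending
#' constants for stretches at or below the optimum and the descending
#' ones beyond it.
#'
#' @param lambda_s fibre stretch.
#' @param mat a \code{material_params}.
#' @param M structural tensor or \code{NULL} for the scalar coefficient.
#' @param alpha activation level in [0, 1].
#' @return 3 x 3 tensor (or scalar coefficient).
#' @export
s_active <- function(lambda_s, mat, M = NULL, alpha = 1) {
  stopifnot(alpha >= 0, alpha <= 1, lambda_s > 0)
  asc <- lambda_s <= mat$lambda_opt
  w <- if (asc) mat$delta_w_asc else mat$delta_w_dsc
  nu <- if (asc) mat$nu_asc else mat$nu_dsc
  coef <- alpha * mat$activation_scale * mat$sigma_max / lambda_s^2 *
    exp(-abs((lambda_s / mat$lambda_opt - 1) / w)^nu)
  if (is.null(M)) coef else coef * M
}

#' Total second Piola-Kirchhoff stress
#'
#' Sum of the isotropic matrix stress and the passive and active fibre
#' stresses. The fibre stretch entering the fibre laws is
#' \code{Lambda_s = sqrt(I4) + lambda_shift} with \code{I4 = a0 . C a0};
#' \code{lambda_shift} realises an applied initial fibre pre-stretch as
#' an internal load (\code{lambda_shift = Lambda_ini_app - 1} makes the
#' fibre laws see the pre-stretch at zero deformation), and is 0 for a
#' plain passive analysis.
#'
#' @param F 3 x 3 deformation gradient.
#' @param a0 reference fibre direction (unit 3-vector).
#' @param mat a \code{material_params}.
#' @param alpha activation level in [0, 1].
#' @param lambda_shift additive shift of the fibre stretch.
#' @return 3 x 3 symmetric stress tensor (MPa).
#' @export
total_pk2 <- function(F, a0, mat, alpha = 0, lambda_shift = 0) {
  C <- t(F) %*% F
  I4 <- drop(a0 %*% C %*% a0)
  lambda_s <- sqrt(I4) + lambda_shift
  M <- outer(a0, a0)
  s_iso(F, mat) + s_passive(lambda_s, mat, M) +
    s_active(lambda_s, mat, M, alpha)
}
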