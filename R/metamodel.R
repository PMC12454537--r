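#' Radial-basis-function metamodel
#'
#' Interpolates (or ridge-smooths) a scalar response over the design space
#' with an RBF expansion plus a linear polynomial tail, after scaling the
#' inputs to the unit box. With zero regularisation the model interpolates
#' the training responses exactly.
#'
#' @param designs n x d matrix of design points.
#' @param responses numeric vector of length n.
#' @param kernel \code{"multiquadric"} (default, well-conditioned),
#'   \code{"gaussian"} or \code{"thinplate"}.
#' @param width kernel width in unit-box units. The default 0.6 balances
#'   smoothing against conditioning for space-filling designs of around
#'   100--200 points in three dimensions (chosen by a calibration study
#'   on synthetic thermal-objective responses).
#' @param ridge regularisation added to the kernel diagonal, default 0.
#' @param lower,upper optional box bounds used for input scaling; default
#'   the ranges of \code{designs}.
#' @return object of class \code{rbf_metamodel}.
#' @export
fit_metamodel <- function(designs, responses,
                          kernel = c("multiquadric", "gaussian",
                                     "thinplate"),
                          width = NULL, ridge = 0,
                          lower = NULL, upper = NULL) {
  kernel <- match.arg(kernel)
  s <- as.matrix(designs)
  y <- as.numeric(responses)
  n <- nrow(s); d <- ncol(s)
  stopifnot(length(y) == n, n >= d + 1)
  if (is.null(lower)) lower <- apply(s, 2, min)
  if (is.null(upper)) upper <- apply(s, 2, max)
  scl <- pmax(upper - lower, 1e-300)
  u <- sweep(sweep(s, 2, lower), 2, scl, "/")
  dist <- as.matrix(stats::dist(u))
  dup <- which(dist < 1e-12 & upper.tri(dist), arr.ind = TRUE)
  if (nrow(dup) && any(abs(y[dup[, 1]] - y[dup[, 2]]) > 1e-12))
    stop("fit_metamodel: duplicate design points with differing responses")
  if (is.null(width)) width <- 0.6
  P <- cbind(1, u)
  rhs <- c(y, rep(0, d + 1))
  A <- rbind(cbind(rbf_kernel(dist, kernel, width) + diag(ridge, n), P),
             cbind(t(P), matrix(0, d + 1, d + 1)))
  w <- solve(A, rhs)
  structure(list(u = u, lower = lower, upper = upper, scl = scl,
                 kernel = kernel, width = width, ridge = ridge,
                 weights = w[seq_len(n)], poly = w[-seq_len(n)],
                 responses = y),
            class = "rbf_metamodel")
}

rbf_kernel <- function(r, kernel, width) {
  switch(kernel,
         multiquadric = sqrt(r^2 + width^2),
         gaussian = exp(-(r / width)^2),
         thinplate = ifelse(r > 0, r^2 * log(r), 0))
}

#' Predict from an RBF metamodel
#' @param object an \code{rbf_metamodel}.
#' @param newdata m x d matrix of design points.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.rbf_metamodel <- function(object, newdata, ...) {
  x <- matrix(as.numeric(newdata), ncol = length(object$lower))
  ux <- sweep(sweep(x, 2, object$lower), 2, object$scl, "/")
  # m x n distance matrix
  r <- sqrt(pmax(outer(rowSums(ux^2), rowSums(object$u^2), "+") -
                   2 * ux %*% t(object$u), 0))
  drop(rbf_kernel(r, object$kernel, object$width) %*% object$weights +
         cbind(1, ux) %*% object$poly)
}

#' @export
print.rbf_metamodel <- function(x, ...) {
  cat("RBF metamodel:", length(x$responses), "design points,",
      x$kernel, "kernel, width", signif(x$width, 4), "\n")
  invisible(x)
}

#' Coefficient of determination
#'
#' \code{1 - SS_res / SS_tot} between model predictions and simulated
#' (reference) values.
#'
#' @param predicted,simulated numeric vectors of equal length >= 2.
#' @return scalar, at most 1.
#' @export
r2_score <- function(predicted, simulated) {
  stopifnot(length(predicted) == length(simulated),
            length(simulated) >= 2)
  1 - sum((simulated - predicted)^2) /
    sum((simulated - mean(simulated))^2)
}

#' First-order variance-based sensitivity of the metamodel
#'
#' Saltelli-style pick-freeze Monte-Carlo estimate of the first-order
#' Sobol' indices of each input parameter, expressed as percentages (they
#' sum to at most 100 up to Monte-Carlo error for near-additive
#' responses).
#'
#' @param model a fitted \code{rbf_metamodel} (or any function taking an
#'   m x d matrix).
#' @param space a \code{design_space} providing the box.
#' @param n_mc Monte-Carlo base sample size.
#' @param seed integer seed.
#' @return named numeric vector of percentage influences.
#' @export
sensitivity <- function(model, space, n_mc = 4096, seed = 1L) {
  f <- if (inherits(model, "rbf_metamodel"))
    function(x) predict(model, x) else model
  set.seed(seed)
  d <- length(space$lower)
  scale_u <- function(u)
    sweep(sweep(u, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  A <- scale_u(matrix(stats::runif(n_mc * d), ncol = d))
  B <- scale_u(matrix(stats::runif(n_mc * d), ncol = d))
  yA <- f(A); yB <- f(B)
  vy <- stats::var(c(yA, yB))
  s1 <- numeric(d)
  for (i in seq_len(d)) {
    ABi <- A; ABi[, i] <- B[, i]
    yABi <- f(ABi)
    s1[i] <- mean(yB * (yABi - yA)) / vy    # Saltelli (2010) estimator
  }
  s1 <- pmax(0, s1)
  names(s1) <- space$names
  100 * s1
}
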