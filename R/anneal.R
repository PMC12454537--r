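#' Constrained simulated annealing over the design space
#'
#' Seeded geometric-cooling simulated annealing with adaptive step
#' scaling, followed by a local polish with a constrained direct search
#' (\code{stats::constrOptim}, Nelder-Mead). Proposals are projected onto
#' the feasible set: the box bounds and the linear constraint
#' \code{alpha2 - alpha1 >= 0}.
#'
#' @param objective function taking a length-3 parameter vector
#'   (T1, alpha1, alpha2) and returning a scalar to minimise.
#' @param space a \code{design_space}.
#' @param seed integer seed.
#' @param n_restarts number of annealing restarts (best result kept).
#' @param n_iter iterations per restart.
#' @param cooling geometric cooling factor per adaptation batch.
#' @param batch iterations per adaptation batch (step size is rescaled
#'   towards a 40\% acceptance rate after each batch).
#' @param polish_objective optional objective for the final local polish
#'   (e.g. the direct simulator when annealing ran on a metamodel);
#'   default the annealing objective. \code{NULL} disables polishing.
#' @return list with \code{par}, \code{value} (of the polish objective
#'   when used, else the annealing objective), \code{anneal_value},
#'   \code{n_evaluations}.
#' @export
anneal_bc <- function(objective, space, seed = 1L, n_restarts = 5L,
                      n_iter = 400L, cooling = 0.95, batch = 40L,
                      polish_objective = objective) {
  lower <- space$lower; upper <- space$upper
  project <- function(s) {
    s <- pmin(upper, pmax(lower, s))
    if (s[3] < s[2]) {                       # alpha2 >= alpha1
      m <- (s[2] + s[3]) / 2
      s[2] <- max(lower[2], min(upper[2], m))
      s[3] <- max(lower[3], min(upper[3], m))
      if (s[3] < s[2]) s[3] <- s[2]
    }
    s
  }
  set.seed(seed)
  nev <- 0L
  fwrap <- function(s) { nev <<- nev + 1L; objective(s) }
  best_par <- project(space$start)
  best_val <- fwrap(best_par)
  range_ <- upper - lower
  for (r in seq_len(n_restarts)) {
    cur <- if (r == 1L) best_par else
      project(lower + stats::runif(3) * range_)
    cur_val <- fwrap(cur)
    if (cur_val < best_val) { best_val <- cur_val; best_par <- cur }
    temp <- max(abs(cur_val), 0.1)
    step <- 0.25
    acc <- 0L
    for (it in seq_len(n_iter)) {
      cand <- project(cur + stats::rnorm(3) * step * range_)
      cand_val <- fwrap(cand)
      if (cand_val < cur_val ||
            stats::runif(1) < exp((cur_val - cand_val) / temp)) {
        cur <- cand; cur_val <- cand_val; acc <- acc + 1L
        if (cur_val < best_val) { best_val <- cur_val; best_par <- cur }
      }
      if (it %% batch == 0L) {
        rate <- acc / batch
        step <- max(1e-3, min(1, step * ifelse(rate > 0.4, 1.2, 0.8)))
        temp <- temp * cooling
        acc <- 0L
      }
    }
  }
  out <- list(par = best_par, value = best_val, anneal_value = best_val,
              n_evaluations = nev)
  if (!is.null(polish_objective)) {
    po <- polish_constrained(best_par, polish_objective, space)
    pval <- polish_objective(po)
    bval <- polish_objective(best_par)
    if (pval <= bval) {
      out$par <- po
      out$value <- pval
    } else out$value <- bval
  }
  out
}

#' Constrained local polish over the design space
#'
#' Nelder-Mead direct search under the box bounds and the linear
#' constraint \code{alpha2 - alpha1 >= 0} (via \code{stats::constrOptim}),
#' started strictly inside the feasible region.
#'
#' @param start length-3 start point (moved strictly inside the feasible
#'   region if needed).
#' @param objective scalar objective over (T1, alpha1, alpha2).
#' @param space a \code{design_space}.
#' @return the polished parameter vector (the start if the search fails).
#' @export
polish_constrained <- function(start, objective, space) {
  lower <- space$lower; upper <- space$upper
  ui <- rbind(diag(3), -diag(3), c(0, -1, 1))
  ci <- c(lower, -upper, 0)
  eps <- 1e-6 * (upper - lower)
  s <- pmin(upper - eps, pmax(lower + eps, start))
  if (s[3] - s[2] <= 0) {
    mid <- (s[2] + s[3]) / 2
    s[2] <- mid - eps[2]; s[3] <- mid + eps[3]
    s <- pmin(upper - eps, pmax(lower + eps, s))
    if (s[3] <= s[2]) s[3] <- s[2] + eps[3]
  }
  po <- try(stats::constrOptim(s, objective, grad = NULL, ui = ui,
                               ci = ci,
                               control = list(maxit = 200,
                                              reltol = 1e-10)),
            silent = TRUE)
  if (inherits(po, "try-error")) return(s)
  p <- pmin(upper, pmax(lower, po$par))
  if (p[3] < p[2]) p[3] <- p[2]
  p
}
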