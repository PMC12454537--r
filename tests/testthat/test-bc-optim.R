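test_that("sub-region exclusions match a brute-force distance oracle", {
  mesh <- test_mesh()
  mask0 <- make_subregion(mesh, surface_offset_mm = 0,
                          distal_cut_fraction = 0)
  expect_equal(sum(mask0), sum(mesh$region == "muscle"))
  expect_error(make_subregion(mesh, surface_offset_mm = 50), "empty")
  mask <- make_subregion(mesh, 3, 0.1)
  expect_gt(attr(mask, "excluded_fraction"), 0)
  # brute-force point-triangle oracle on the excluded-by-offset elements
  ctr <- tet_centroids(mesh)
  zc <- drop(ctr %*% mesh$e2)
  zall <- drop(mesh$nodes %*% mesh$e2)
  zcut <- max(zall) - 0.1 * (max(zall) - min(zall))
  excl_off <- which(mesh$region == "muscle" & !mask & zc <= zcut)
  tri_dist <- function(p, tri) {
    # dense sampling of the triangle as an independent oracle
    w <- expand.grid(a = seq(0, 1, by = 0.05), b = seq(0, 1, by = 0.05))
    w <- w[w$a + w$b <= 1, ]
    pts <- cbind(1 - w$a - w$b, w$a, w$b) %*% tri
    min(sqrt(rowSums(sweep(pts, 2, p)^2)))
  }
  surf <- mesh$face_sets$muscle_surface
  set.seed(51)
  for (e in sample(excl_off, 8)) {
    d <- min(vapply(seq_len(nrow(surf)), function(r)
      tri_dist(ctr[e, ], mesh$nodes[surf[r, ], ]), numeric(1)))
    expect_lt(d, 3 + 0.08)              # sampling resolution slack
  }
})

test_that("cosine distance follows its arithmetic definition", {
  expect_equal(cosine_distance(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(cosine_distance(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(cosine_distance(c(1, 0, 0), c(-1, 0, 0)), 2)
  expect_equal(cosine_distance(c(1, 0, 0), c(1, 1, 0) / sqrt(2)),
               1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 0, 0), c(1, 1, 0) / sqrt(2)),
               0.29289, tolerance = 1e-4)
  expect_error(cosine_distance(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("mean deviation averages cosine distances with angle companion", {
  set.seed(52)
  a <- matrix(rnorm(60), ncol = 3)
  a <- a / sqrt(rowSums(a^2))
  expect_equal(as.numeric(mean_deviation(a, a)), 0)
  # rotate every vector by 45 degrees about a perpendicular axis
  rot45 <- t(vapply(seq_len(nrow(a)), function(i) {
    v <- a[i, ]
    perp <- c(-v[2], v[1], 0)
    if (sum(perp^2) < 1e-9) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    v * cos(pi / 4) + myoarch:::cross3(matrix(perp, 1),
                                       matrix(v, 1))[1, ] * sin(pi / 4)
  }, numeric(3)))
  md <- mean_deviation(a, rot45)
  expect_equal(as.numeric(md), 1 - cos(pi / 4), tolerance = 1e-9)
  expect_equal(mean(attr(md, "angles_deg")), 45, tolerance = 1e-9)
  # orthogonal pairs give 1
  b <- t(vapply(seq_len(nrow(a)), function(i) {
    v <- a[i, ]; p <- c(-v[2], v[1], 0)
    if (sum(p^2) < 1e-9) p <- c(0, 1, 0)
    p / sqrt(sum(p^2))
  }, numeric(3)))
  expect_equal(as.numeric(mean_deviation(a, b)), 1, tolerance = 1e-9)
  expect_error(mean_deviation(a, b, mask = rep(FALSE, nrow(a))), "empty")
})

test_that("mean deviation is invariant to aligned sign flips", {
  set.seed(53)
  e2 <- c(0, 0, 1)
  a <- matrix(rnorm(60), ncol = 3); a <- a / sqrt(rowSums(a^2))
  b <- a + 0.2 * matrix(rnorm(60), ncol = 3)
  b <- b / sqrt(rowSums(b^2))
  a <- align_to_axis(a, e2); b <- align_to_axis(b, e2)
  flip <- rep(c(1, -1), length.out = nrow(b))
  b_flipped <- align_to_axis(b * flip, e2)
  expect_equal(as.numeric(mean_deviation(a, b)),
               as.numeric(mean_deviation(a, b_flipped)), tolerance = 1e-12)
})

test_that("design sampling is stratified, deterministic and maximin", {
  space <- design_space(n_designs = 200, seed = 7)
  s <- sample_designs(space)
  expect_equal(dim(s), c(200L, 3L))
  for (d in 1:3) {
    u <- (s[, d] - space$lower[d]) / (space$upper[d] - space$lower[d])
    expect_true(all(u >= 0 & u <= 1))
    # Latin hypercube: one point per 1/200 stratum
    expect_equal(sort(unique(floor(u * 200))), 0:199)
  }
  expect_identical(sample_designs(space), s)
  # maximin improves the worst pairwise distance over a plain random LHS
  set.seed(space$seed)
  plain <- lhs::randomLHS(200, 3)
  mind <- function(u) min(dist(u))
  u_s <- sweep(sweep(s, 2, space$lower), 2,
               space$upper - space$lower, "/")
  expect_gte(mind(u_s), mind(plain))
})

test_that("design space validates bounds, start and constraint", {
  expect_error(design_space(start = c(0, 5, 10)))     # start outside T1 box
  expect_error(design_space(alpha1_range = c(5, 4)))
  sp <- design_space()
  expect_equal(sp$lower, c(-200, 0, 0))
  expect_equal(sp$upper, c(-1, 20, 20))
  expect_equal(sp$start, c(-100, 5, 10))
  expect_equal(sp$n_designs, 200L)
})

test_that("the RBF metamodel interpolates and generalises a quadratic", {
  set.seed(61)
  X <- sweep(sweep(lhs::randomLHS(50, 3), 2, c(199, 20, 20), "*"),
             2, c(-200, 0, 0), "+")
  f <- function(s) 1e-4 * s[, 1]^2 / 200 + 0.01 * (s[, 2] - 7)^2 +
    0.02 * (s[, 3] - 12)^2 + 0.5
  y <- f(X)
  mm <- fit_metamodel(X, y, width = 2, lower = c(-200, 0, 0),
                      upper = c(-1, 20, 20))
  expect_lt(max(abs(predict(mm, X) - y)), 1e-8)
  set.seed(62)
  H <- sweep(sweep(matrix(runif(60), ncol = 3), 2, c(199, 20, 20), "*"),
             2, c(-200, 0, 0), "+")
  rmse <- sqrt(mean((predict(mm, H) - f(H))^2))
  expect_lt(rmse, 1e-2 * diff(range(y)))
  # constant responses give a constant predictor
  mc <- fit_metamodel(X, rep(2.5, 50), width = 2,
                      lower = c(-200, 0, 0), upper = c(-1, 20, 20))
  expect_equal(predict(mc, H), rep(2.5, 20), tolerance = 1e-8)
  # duplicate designs with differing responses are rejected
  Xd <- rbind(X, X[1, ]); yd <- c(y, y[1] + 1)
  expect_error(fit_metamodel(Xd, yd, width = 2, lower = c(-200, 0, 0),
                             upper = c(-1, 20, 20)), "duplicate")
})

test_that("the coefficient of determination follows its definition", {
  expect_equal(r2_score(c(1, 2, 3), c(1, 2, 3)), 1.0)
  y <- c(1, 2, 3, 4)
  expect_equal(r2_score(rep(mean(y), 4), y), 0.0)
  expect_equal(r2_score(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_error(r2_score(1, 1))
})

test_that("variance-based sensitivity identifies active inputs", {
  space <- design_space(seed = 3)
  only_a1 <- function(s) (s[, 2] - 10)^2
  s1 <- sensitivity(only_a1, space, n_mc = 4096, seed = 3)
  expect_gt(s1["alpha1"], 90)
  expect_lt(s1["T1"] + s1["alpha2"], 10)
  symm <- function(s) (s[, 2] - 10)^2 + (s[, 3] - 10)^2
  s2 <- sensitivity(symm, space, n_mc = 8192, seed = 3)
  expect_equal(unname(s2["alpha1"]), unname(s2["alpha2"]),
               tolerance = 0.15)
  expect_lte(sum(s2), 110)
})

test_that("annealing recovers a convex optimum under the constraint", {
  space <- design_space(seed = 11)
  target <- c(-60, 4, 9)
  quad <- function(s) sum(((s - target) / (space$upper - space$lower))^2)
  opt <- anneal_bc(quad, space, seed = 11)
  expect_lt(max(abs(opt$par - target) / (space$upper - space$lower)),
            1e-2)
  expect_lte(quad(opt$par), quad(space$start))
  # minimum outside the feasible half-space: the constraint becomes active
  bad <- c(-60, 15, 3)
  quad2 <- function(s) sum(((s - bad) / (space$upper - space$lower))^2)
  opt2 <- anneal_bc(quad2, space, seed = 11)
  expect_gte(opt2$par[3] - opt2$par[2], -1e-9)
  # repeatability budget across seeds
  opt3 <- anneal_bc(quad, space, seed = 12)
  expect_lt(abs(opt3$value - opt$value), 1e-3)
})

test_that("the fitting object exposes the usual modelling interface", {
  mesh <- fixture("mesh10", function()
    make_bipennate_mesh(test_spec(element_size_mm = 10)))
  solver <- thermal_solver(mesh)
  truth <- c(-30, 2.5, 3.5)
  ref <- solver(truth)
  space <- design_space(n_designs = 40, seed = 2)
  fit <- fit_thermal_bc(mesh, ref, space, n_holdout = 5L,
                        sensitivity_mc = 512L)
  expect_s3_class(fit, "thermal_bc_fit")
  expect_named(coef(fit), c("T1", "alpha1", "alpha2"))
  expect_lt(fit$value, 0.05)
  expect_output(print(fit), "coefficients")
  expect_output(print(summary(fit)), "hold-out")
  f <- predict(fit)
  expect_s3_class(f, "element_fibre_field")
  expect_equal(nrow(f), nrow(mesh$elems))
  r <- residuals(fit)
  expect_equal(length(r), sum(fit$subregion))
  expect_true(all(r >= 0))
  expect_equal(as.numeric(mean_deviation(fitted(fit), ref,
                                         fit$subregion)),
               fit$value, tolerance = 1e-9)
  obj <- predict(fit, params = truth, what = "objective")
  expect_true(is.finite(obj))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
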