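test_that("power-law ramps follow the normalised axial coordinate", {
  mesh <- box_mesh()
  # proximal_high = FALSE makes the ramp coordinate grow with z, so the
  # values can be checked against plain arithmetic on node positions
  p <- thermal_bc_params(T1 = -2, alpha1 = 2, alpha2 = 3,
                         proximal_high = FALSE)
  bc <- build_dirichlet_values(mesh, p)
  val <- rep(NA_real_, nrow(mesh$nodes))
  val[bc$nodes] <- bc$values
  n_in <- face_set_nodes(mesh, "inlet")
  n_out <- face_set_nodes(mesh, "outlet")
  expect_true(all(val[n_in] == 1))
  expect_true(all(val[n_out] == -2))
  mset <- face_set_nodes(mesh, "muscle_surface")
  zset <- mesh$nodes[mset, 3]          # the ramp spans the full set
  msurf <- setdiff(mset, c(n_in, n_out,
                           face_set_nodes(mesh, "aponeurosis_surface")))
  z <- mesh$nodes[msurf, 3]
  nz <- (z - min(zset)) / (max(zset) - min(zset))
  expect_equal(val[msurf], nz^2, tolerance = 1e-12)
  # mid-ramp with alpha = 2 gives 0.25
  mid <- msurf[which(abs(nz - 0.5) < 1e-9)]
  expect_true(length(mid) > 0)
  expect_equal(val[mid], rep(0.25, length(mid)))
})

test_that("alpha = 0 gives a constant ramp (0^0 convention)", {
  mesh <- box_mesh()
  p <- thermal_bc_params(T1 = -2, alpha1 = 0, alpha2 = 0)
  bc <- build_dirichlet_values(mesh, p)
  val <- rep(NA_real_, nrow(mesh$nodes))
  val[bc$nodes] <- bc$values
  msurf <- setdiff(face_set_nodes(mesh, "muscle_surface"),
                   face_set_nodes(mesh, "outlet"))
  msurf <- setdiff(msurf, face_set_nodes(mesh, "inlet"))
  msurf <- setdiff(msurf, face_set_nodes(mesh, "aponeurosis_surface"))
  expect_true(all(val[msurf] == 1))
})

test_that("shared nodes take the highest-precedence face set", {
  mesh <- box_mesh()
  p <- thermal_bc_params(T1 = -5, alpha1 = 1, alpha2 = 1)
  bc <- build_dirichlet_values(mesh, p)
  val <- rep(NA_real_, nrow(mesh$nodes))
  val[bc$nodes] <- bc$values
  # corner nodes shared between inlet and lateral surfaces keep T0
  shared <- intersect(face_set_nodes(mesh, "inlet"),
                      face_set_nodes(mesh, "muscle_surface"))
  expect_true(length(shared) > 0)
  expect_true(all(val[shared] == 1))
  shared_out <- intersect(face_set_nodes(mesh, "outlet"),
                          face_set_nodes(mesh, "aponeurosis_surface"))
  expect_true(length(shared_out) > 0)
  expect_true(all(val[shared_out] == -5))
})

test_that("degenerate axial range on a ramped set errors", {
  mesh <- box_mesh()
  flat <- mesh
  # point the aponeurosis set at a flat end face: its axial range is zero
  flat$face_sets$aponeurosis_surface <- mesh$face_sets$inlet
  expect_error(build_dirichlet_values(flat, thermal_bc_params(-1, 1, 1)),
               "degenerate")
  # a missing face set is reported as such
  nofs <- mesh
  nofs$face_sets$outlet <- NULL
  expect_error(build_dirichlet_values(nofs, thermal_bc_params(-1, 1, 1)),
               "missing")
})

test_that("the Laplace solve reproduces the linear closed form on a box", {
  mesh <- box_mesh(n = c(3, 3, 8), L = c(1, 1, 2))
  nodes_bot <- face_set_nodes(mesh, "inlet")
  nodes_top <- face_set_nodes(mesh, "outlet")
  bc <- list(nodes = c(nodes_bot, nodes_top),
             values = c(rep(0, length(nodes_bot)),
                        rep(1, length(nodes_top))))
  Tv <- solve_steady_heat(mesh, bc)
  expect_lt(max(abs(Tv - mesh$nodes[, 3] / 2)), 1e-9)
  # discrete maximum principle
  expect_true(all(Tv >= -1e-12 & Tv <= 1 + 1e-12))
  # constant constraints give a constant field
  bc_c <- list(nodes = bc$nodes, values = rep(0.7, length(bc$nodes)))
  expect_equal(solve_steady_heat(mesh, bc_c),
               rep(0.7, nrow(mesh$nodes)), tolerance = 1e-12)
  expect_error(solve_steady_heat(mesh, list(nodes = integer(0),
                                            values = numeric(0))),
               "constrained")
})

test_that("flux fibres are unit, axis-aligned and conductivity-invariant", {
  mesh <- box_mesh(n = c(3, 3, 6), L = c(1, 1, 2))
  Tv <- -mesh$nodes[, 3]                # uniform gradient along -z
  f1 <- element_flux_fibres(mesh, Tv)
  expect_true(all(abs(f1[, 3] - 1) < 1e-12))
  f2 <- element_flux_fibres(mesh, Tv, kappa = 2)
  expect_equal(unclass(f1)[, ], unclass(f2)[, ])
  # flipped gradient still aligns with +e2
  f3 <- element_flux_fibres(mesh, -Tv)
  expect_true(all(abs(f3[, 3] - 1) < 1e-12))
  # constant temperature: all elements masked invalid
  f0 <- element_flux_fibres(mesh, rep(1, nrow(mesh$nodes)))
  expect_true(all(!attr(f0, "valid")))
})

test_that("discrete flux is conserved at free nodes", {
  mesh <- test_mesh()
  f <- thermal_fibre_field(mesh, thermal_bc_params(-30, 2.5, 3))
  Tv <- attr(f, "temperature")
  K <- myoarch:::assemble_laplacian(mesh)
  res <- as.numeric(K %*% Tv)
  fixed <- build_dirichlet_values(mesh, thermal_bc_params(-30, 2.5, 3))$nodes
  free <- setdiff(seq_len(nrow(mesh$nodes)), fixed)
  expect_lt(max(abs(res[free])), 1e-8 * max(abs(res)))
})

test_that("end-only boundary conditions give a fusiform field; ramps feather it", {
  mesh <- test_mesh()
  # fusiform: only inlet/outlet constrained
  bc <- build_dirichlet_values(mesh, thermal_bc_params(-30, 1, 1))
  n_in <- face_set_nodes(mesh, "inlet")
  n_out <- face_set_nodes(mesh, "outlet")
  ends_only <- list(nodes = c(n_in, n_out),
                    values = c(rep(1, length(n_in)),
                               rep(-30, length(n_out))))
  Tv <- solve_steady_heat(mesh, ends_only)
  fus <- element_flux_fibres(mesh, Tv)
  feather <- thermal_fibre_field(mesh, thermal_bc_params(-30, 2.5, 3))
  ang <- function(f) mean(acos(pmin(1, abs(f %*% mesh$e2))) * 180 / pi)
  expect_lt(ang(fus), 10)
  expect_gt(ang(feather), ang(fus))
})

test_that("fibres adjacent to the sheet point towards it when alpha2 > alpha1", {
  mesh <- test_mesh()
  f <- thermal_fibre_field(mesh, thermal_bc_params(-30, 1, 6))
  ctr <- tet_centroids(mesh)
  za <- myoarch:::apo_start_z(mesh$spec)
  near <- which(mesh$region == "muscle" &
                  abs(ctr[, 1]) > mesh$spec$apo_thickness_mm / 2 &
                  abs(ctr[, 1]) < 6 & ctr[, 3] > za + 10 &
                  ctr[, 3] < 120 & abs(ctr[, 2]) < 6)
  # component along the local sheet-normal direction towards the plane
  toward <- -sign(ctr[near, 1]) * f[near, 1]
  expect_gt(mean(toward > 0), 0.9)
})
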