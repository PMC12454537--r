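test_that("the reference configuration is stress-free", {
  for (mat in default_materials()) {
    expect_lt(max(abs(s_iso(diag(3), mat))), 1e-12)
    expect_lt(max(abs(total_pk2(diag(3), c(0, 0, 1), mat))), 1e-12)
  }
})

test_that("passive fibre stress follows its piecewise law", {
  mat <- material_params("muscle")
  M <- diag(c(0, 0, 1))
  expect_equal(s_passive(1, mat, M), 0 * M)
  expect_equal(s_passive(0.9, mat, M), 0 * M)
  # direct arithmetic oracle at 10% stretch
  oracle <- 5e-3 * (1.1^6 - 1) / 1.1^2
  expect_equal(s_passive(1.1, mat, M)[3, 3], oracle, tolerance = 1e-12)
  expect_equal(oracle, 3.189e-3, tolerance = 1e-3)
  # tendon stiffens much faster
  matT <- material_params("tendon_aponeurosis")
  expect_gt(s_passive(1.1, matT)[1], 100 * s_passive(1.1, mat)[1])
})

test_that("active fibre stress peaks at the optimal stretch", {
  mat <- material_params("muscle")
  M <- diag(c(0, 0, 1))
  expect_equal(s_active(1.2, mat, M, alpha = 0), 0 * M)
  peak <- s_active(1.3, mat, M, alpha = 1)[3, 3]
  expect_equal(peak, 0.3 / 1.3^2, tolerance = 1e-12)
  expect_equal(peak, 0.17751, tolerance = 1e-4)
  # decays monotonically away from the optimum on both branches
  lam_asc <- seq(1.3, 0.9, by = -0.05)
  v_asc <- vapply(lam_asc, function(l)
    l^2 * s_active(l, mat, NULL, 1), numeric(1))
  expect_true(all(diff(v_asc) <= 1e-12))
  lam_dsc <- seq(1.3, 1.8, by = 0.05)
  v_dsc <- vapply(lam_dsc, function(l)
    l^2 * s_active(l, mat, NULL, 1), numeric(1))
  expect_true(all(diff(v_dsc) <= 1e-12))
  # tendon and aponeurosis receive no activation
  matT <- material_params("tendon_aponeurosis")
  expect_equal(s_active(1.3, matT, M, 1), 0 * M)
})

test_that("total PK2 is symmetric and orthogonal fibres add nothing", {
  mat <- material_params("muscle")
  set.seed(81)
  for (i in 1:10) {
    F <- diag(3) + 0.1 * matrix(rnorm(9), 3)
    if (det(F) <= 0) next
    S <- total_pk2(F, c(0, 0, 1), mat, alpha = 0.5)
    expect_lt(max(abs(S - t(S))), 1e-12)
  }
  # fibre orthogonal to a uniaxial stretch: I4 = 1, fibre stress silent
  F <- diag(c(1, 1, 1.2))
  S_perp <- total_pk2(F, c(1, 0, 0), mat)
  S_iso_only <- s_iso(F, mat)
  expect_equal(S_perp, S_iso_only, tolerance = 1e-12)
  expect_gt(max(abs(S_iso_only)), 0)
  expect_error(s_iso(diag(c(-1, 1, 1)), mat), "det F")
})

test_that("stresses agree with the energy gradient on random states", {
  mat <- material_params("muscle")
  set.seed(82)
  for (i in 1:25) {
    F <- diag(3) + 0.15 * matrix(rnorm(9), 3)
    if (det(F) < 0.3) next
    a0 <- rnorm(3); a0 <- a0 / sqrt(sum(a0^2))
    lam <- sqrt(drop(a0 %*% (t(F) %*% F) %*% a0))
    if (abs(lam - 1) < 0.02) next       # keep clear of the kink
    P_fd <- pk1_fd_oracle(F, a0, mat)
    P <- F %*% total_pk2(F, a0, mat)
    expect_lt(max(abs(P - P_fd)) / max(abs(P_fd)), 1e-6)
  }
})

test_that("vectorised element stress matches the single-element API", {
  mat <- default_materials()
  set.seed(83)
  F9 <- matrix(0, 6, 9)
  a0 <- matrix(rnorm(18), ncol = 3)
  a0 <- a0 / sqrt(rowSums(a0^2))
  ref <- matrix(0, 6, 9)
  region <- c("muscle", "muscle", "tendon_proximal", "aponeurosis",
              "muscle", "tendon_distal")
  mp <- myoarch:::material_vectors(region, mat)
  for (e in 1:6) {
    F <- diag(3) + 0.12 * matrix(rnorm(9), 3)
    while (det(F) < 0.5) F <- diag(3) + 0.12 * matrix(rnorm(9), 3)
    F9[e, ] <- as.vector(F)
    m <- if (region[e] == "muscle") mat$muscle else mat$tendon_aponeurosis
    shift <- if (region[e] == "muscle") 0.1 else 0
    ref[e, ] <- as.vector(total_pk2(F, a0[e, ], m, alpha = 0.6,
                                    lambda_shift = shift))
  }
  S9 <- myoarch:::pk2_elements(F9, a0, mp, alpha = 0.6,
                               lambda_shift = 0.1 *
                                 as.numeric(region == "muscle"))
  expect_equal(S9[, ], ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero load produces zero displacement", {
  mesh <- unit_cube_mesh()
  field <- element_fibre_field(matrix(rep(c(0, 0, 1), 6), ncol = 3,
                                      byrow = TRUE))
  sim <- run_load_case_1(mesh, field, f2_max = 0, n_steps = 1)
  expect_lt(max(abs(sim$states[[1]]$u)), 1e-10)
})

test_that("single-element uniaxial response matches the 1D closed form", {
  mesh <- unit_cube_mesh()
  field <- element_fibre_field(matrix(rep(c(0, 0, 1), 6), ncol = 3,
                                      byrow = TRUE))
  mats <- default_materials()
  fe <- myoarch:::fem_setup(mesh, field, mats)
  lz <- 1.15
  cf <- uniaxial_oracle(lz, mats$muscle)
  nodes <- mesh$nodes
  fixed <- integer(0); u0 <- numeric(fe$n_dof)
  for (nidx in seq_len(nrow(nodes))) {
    if (nodes[nidx, 1] == 0) fixed <- c(fixed, 3L * (nidx - 1L) + 1L)
    if (nodes[nidx, 2] == 0) fixed <- c(fixed, 3L * (nidx - 1L) + 2L)
    if (nodes[nidx, 3] == 0) fixed <- c(fixed, 3L * (nidx - 1L) + 3L)
    if (nodes[nidx, 3] == 1) {
      fixed <- c(fixed, 3L * (nidx - 1L) + 3L)
      u0[3L * (nidx - 1L) + 3L] <- lz - 1
    }
  }
  sol <- myoarch:::fem_newton(fe, u0, fixed, numeric(fe$n_dof))
  expect_true(sol$converged)
  top <- which(nodes[, 3] == 1)
  reaction <- sum(sol$fint[3L * (top - 1L) + 3L])
  expect_lt(abs(reaction - cf$nominal_stress) / abs(cf$nominal_stress),
            1e-6)
  # the lateral contraction matches too
  um <- matrix(sol$u, ncol = 3, byrow = TRUE)
  corner <- which(nodes[, 1] == 1 & nodes[, 2] == 1 & nodes[, 3] == 0)
  expect_equal(um[corner, 1], cf$lt - 1, tolerance = 1e-6)
})

test_that("passive stretch is monotone with balanced reactions", {
  mesh <- fixture("mesh12", function()
    make_bipennate_mesh(test_spec(element_size_mm = 12)))
  field <- element_field_analytic(mesh)
  sim <- run_load_case_1(mesh, field, n_steps = 5)
  expect_true(all(diff(sim$table$mean_outlet_disp) > 0))
  # reaction at the fixed proximal end equals the applied force
  expect_equal(sim$table$reaction_proximal,
               sim$table$applied_force, tolerance = 1e-6)
  lam <- sim$states[[5]]$lambda_s
  expect_true(all(lam > 0.8 & lam < 1.6))
})

test_that("isometric activation raises the proximal reaction", {
  mesh <- fixture("mesh12", function()
    make_bipennate_mesh(test_spec(element_size_mm = 12)))
  field <- element_field_analytic(mesh)
  sim <- run_load_case_2(mesh, field, n_steps = 5,
                         n_steps_prestretch = 5)
  tab <- sim$table
  act <- tab[tab$alpha > 0 | seq_len(nrow(tab)) == 5, ]
  expect_true(all(diff(act$reaction_proximal) > -1e-8))
  r0 <- tab$reaction_proximal[5]       # end of pre-stretch, alpha = 0
  r1 <- tab$reaction_proximal[nrow(tab)]
  expect_gt(r0, 0)
  expect_gt(r1, r0)
})
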