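test_that("generated mesh has all regions, face sets and positive volumes", {
  mesh <- test_mesh()
  expect_setequal(unique(mesh$region),
                  c("muscle", "tendon_proximal", "tendon_distal",
                    "aponeurosis"))
  for (fs in c("inlet", "outlet", "muscle_surface", "aponeurosis_surface"))
    expect_gt(nrow(mesh$face_sets[[fs]]), 0)
  expect_gt(min(tet_volumes(mesh)), 0)
  q <- mesh_quality(mesh)
  expect_gt(q$min_volume, 0)
  # inlet/outlet are flat end faces
  zi <- mesh$nodes[unique(as.integer(mesh$face_sets$inlet)), 3]
  zo <- mesh$nodes[unique(as.integer(mesh$face_sets$outlet)), 3]
  expect_true(all(abs(zi) < 1e-9))
  expect_true(all(abs(zo - mesh$spec$total_length_mm) < 1e-9))
})

test_that("mesh generation is deterministic and refines as expected", {
  m1 <- make_bipennate_mesh(test_spec())
  m2 <- make_bipennate_mesh(test_spec())
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)
  expect_identical(m1$region, m2$region)
  fine <- make_bipennate_mesh(test_spec(element_size_mm = 4))
  ratio <- nrow(fine$elems) / nrow(m1$elems)
  expect_gte(ratio, 4)
  expect_lte(ratio, 16)
})

test_that("sheet resolution guard fires for oversized elements", {
  expect_error(bipennate_spec(apo_thickness_mm = 20, element_size_mm = 5),
               "element size")
})

test_that("analytic field is pennate, mirror-symmetric and axial on the plane", {
  spec <- test_spec()
  th <- spec$pennation_deg * pi / 180
  mid <- matrix(c(0, 0, 75), 1)
  expect_equal(drop(analytic_bipennate_field(mid, spec)), c(0, 0, 1))
  lat <- matrix(c(8, 0, 50), 1)
  v <- drop(analytic_bipennate_field(lat, spec))
  expect_equal(v[3], cos(th), tolerance = 1e-12)
  expect_equal(cos(th), 0.9659, tolerance = 1e-4)
  mirror <- drop(analytic_bipennate_field(matrix(c(-8, 0, 50), 1), spec))
  expect_equal(mirror, v * c(-1, 1, 1))
  # tendon points are axial
  expect_equal(drop(analytic_bipennate_field(matrix(c(2, 0, 5), 1), spec)),
               c(0, 0, 1))
  expect_error(analytic_bipennate_field(matrix(c(40, 0, 50), 1), spec),
               "outside")
})

test_that("element field mapping follows region tags and pennation", {
  mesh <- test_mesh()
  f <- element_field_analytic(mesh)
  expect_equal(rowSums(f^2), rep(1, nrow(f)), tolerance = 1e-12)
  axial <- mesh$region != "muscle"
  expect_true(all(abs(f[axial, 3] - 1) < 1e-12))
  th <- mesh$spec$pennation_deg * pi / 180
  expect_true(all(abs(f[!axial, 3] - cos(th)) < 1e-9))
  # a steeper spec gives a field closer to the axis on the same mesh
  steep <- element_field_analytic(mesh, test_spec(pennation_deg = 5))
  expect_gt(mean(steep[, 3]), mean(f[, 3]))
})

test_that("noise-free streamlines terminate on the sheet or boundary", {
  spec <- test_spec()
  sl <- synth_streamlines(spec, n = 120, noise_deg = 0, seed = 9)
  L <- spec$total_length_mm
  za <- myoarch:::apo_start_z(spec)
  ends <- t(vapply(unclass(sl), function(p) p[nrow(p), ], numeric(3)))
  on_sheet <- abs(ends[, 1]) <= spec$apo_thickness_mm / 2 + 0.6 &
    ends[, 3] >= za - 0.6
  rr <- myoarch:::radius_profile(spec, ends[, 3])
  on_boundary <- ends[, 3] <= spec$tendon_proximal_mm + 0.6 |
    ends[, 3] >= L - spec$tendon_distal_mm - 0.6 |
    sqrt(ends[, 1]^2 + ends[, 2]^2) >= rr - 0.6
  expect_true(all(on_sheet | on_boundary))
  # without noise no step turns more than the pennation angle allows
  turn <- streamline_max_turn(sl)
  expect_true(all(turn <= 2 * spec$pennation_deg + 1e-6))
})

test_that("mid-plane seeds run straight and seeds are reproducible", {
  spec <- test_spec()
  s1 <- synth_streamlines(spec, n = 60, noise_deg = 2, seed = 4)
  s2 <- synth_streamlines(spec, n = 60, noise_deg = 2, seed = 4)
  expect_identical(unclass(s1), unclass(s2))
  s3 <- synth_streamlines(spec, n = 60, noise_deg = 2, seed = 5)
  expect_false(identical(unclass(s1), unclass(s3)))
  # a noise-free line from the mid-plane below the sheet oscillates about
  # the plane: its lateral excursion stays within one integration step
  sl <- synth_streamlines(spec, n = 200, noise_deg = 0, seed = 6)
  starts <- t(vapply(unclass(sl), function(p) p[1, ], numeric(3)))
  midplane <- which(abs(starts[, 1]) < 0.2)
  for (i in utils::head(midplane, 3)) {
    p <- sl[[i]]
    expect_true(all(abs(p[, 1]) <= abs(p[1, 1]) + 0.5 + 1e-9))
  }
})
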