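# a small grid whose central voxel column is centred on x = 0
small_grid <- function() voxel_grid(c(5, 5, 5), origin = -0.5 * c(2.625, 2.625, 6.25) * 5)

test_that("fibre count is identity-based and sphere-limited", {
  g <- small_grid()
  centre <- index_to_world(g, matrix(c(2.5, 2.5, 2.5), 1))  # centre voxel
  through <- straight_line(centre - c(0, 0, 10), centre + c(0, 0, 10), n = 5)
  K <- voxel_fibre_count(streamline_set(list(through)), g)
  ijk <- floor(world_to_index(g, centre))
  expect_equal(K[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1], 1L)
  # passing 2.0 mm from the centre: outside the 1.3125 mm radius sphere
  offset <- straight_line(centre + c(2.0, 0, -10) - c(0, 0, centre[3] - centre[3]),
                          centre + c(2.0, 0, 10), n = 5)
  K2 <- voxel_fibre_count(streamline_set(list(offset)), g)
  expect_equal(K2[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1], 0L)
  # a streamline entering the sphere twice still counts once
  loop <- rbind(centre + c(0, 0, -8), centre, centre + c(0, 4, 0),
                centre + c(0.2, 0, 0), centre + c(0, 0, 8))
  K3 <- voxel_fibre_count(streamline_set(list(loop)), g)
  expect_equal(K3[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1], 1L)
})

test_that("sphere diameter above the smallest spacing is rejected", {
  g <- small_grid()
  s <- streamline_set(list(straight_line(c(0, 0, -5), c(0, 0, 5))))
  expect_error(voxel_fibre_count(s, g, sphere_diameter_mm = 3),
               "spacing")
})

test_that("mean orientation averages unit chords with axis alignment", {
  g <- small_grid()
  centre <- drop(index_to_world(g, matrix(c(2.5, 2.5, 2.5), 1)))
  ijk <- floor(world_to_index(g, matrix(centre, 1))) + 1
  mk <- function(dir) straight_line(centre - 10 * dir, centre + 10 * dir,
                                    n = 9)
  # two fibres along +y: mean is (0,1,0)
  A <- voxel_mean_orientation(streamline_set(list(mk(c(0, 1, 0)),
                                                  mk(c(0, 1, 0)))),
                              voxel_grid(g$shape, affine = g$affine,
                                         e2 = c(0, 1, 0)))
  expect_equal(A[ijk[1], ijk[2], ijk[3], ], c(0, 1, 0), tolerance = 1e-9)
  # three fibres travelling along -y: h flips the mean to +y
  g2 <- voxel_grid(g$shape, affine = g$affine, e2 = c(0, 1, 0))
  lines <- lapply(1:3, function(i)
    straight_line(centre + 10 * c(0, 1, 0), centre - 10 * c(0, 1, 0),
                  n = 9))
  A2 <- voxel_mean_orientation(streamline_set(lines), g2)
  expect_equal(A2[ijk[1], ijk[2], ijk[3], ], c(0, 1, 0), tolerance = 1e-9)
  # orthogonal pair: mean (0.5, 0.5, 0) is not re-normalised
  g3 <- voxel_grid(g$shape, affine = g$affine, e2 = c(1, 0, 0))
  A3 <- voxel_mean_orientation(streamline_set(list(mk(c(1, 0, 0)),
                                                   mk(c(0, 1, 0)))), g3)
  v <- A3[ijk[1], ijk[2], ijk[3], ]
  expect_equal(v, c(0.5, 0.5, 0), tolerance = 1e-9)
  expect_equal(sqrt(sum(v^2)), sqrt(0.5), tolerance = 1e-9)
})

test_that("endpoint divergence counts sinks and respects the sum rule", {
  g <- small_grid()
  centre <- drop(index_to_world(g, matrix(c(2.5, 2.5, 2.5), 1)))
  ijk <- floor(world_to_index(g, matrix(centre, 1))) + 1
  # pass-through contributes zero
  through <- straight_line(centre - c(0, 0, 12), centre + c(0, 0, 12),
                           n = 9)
  D0 <- discrete_divergence(streamline_set(list(through)), g)
  expect_equal(D0[ijk[1], ijk[2], ijk[3]], 0)
  # three oriented streamlines terminating inside: +3
  enders <- lapply(list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0)), function(d)
    straight_line(centre + 10 * d - c(0, 0, 10), centre, n = 9))
  D3 <- discrete_divergence(streamline_set(enders), g)
  expect_equal(D3[ijk[1], ijk[2], ijk[3]], 3)
  # global sum rule: ends inside minus starts inside, exactly
  set.seed(31)
  lines <- lapply(1:40, function(i) matrix(rnorm(9, sd = 6), ncol = 3))
  lines <- lines[vapply(lines, function(p)
    all(rowSums(diff(p)^2) > 0), logical(1))]
  set <- streamline_set(lines)
  D <- discrete_divergence(set, g, orient = FALSE)
  starts <- t(vapply(set, function(p) p[1, ], numeric(3)))
  ends <- t(vapply(set, function(p) p[nrow(p), ], numeric(3)))
  inside <- function(p) sum(in_grid(g, floor(world_to_index(g, p))))
  expect_equal(sum(D), inside(ends) - inside(starts))
})

test_that("reversal symmetries hold", {
  g <- small_grid()
  set.seed(32)
  lines <- lapply(1:15, function(i) {
    p <- matrix(cumsum(rnorm(12, sd = 2)), ncol = 3)
    p
  })
  set <- streamline_set(lines)
  rev_set <- streamline_set(lapply(lines, function(p) p[nrow(p):1, ]))
  # K is invariant under point-order reversal
  expect_equal(voxel_fibre_count(set, g), voxel_fibre_count(rev_set, g))
  # with orientation disabled, endpoint divergence flips sign
  expect_equal(discrete_divergence(set, g, orient = FALSE),
               -discrete_divergence(rev_set, g, orient = FALSE))
  # with the alignment rule it is reversal-invariant
  expect_equal(discrete_divergence(set, g), discrete_divergence(rev_set, g))
})

test_that("finite-difference divergence of a uniform field is zero", {
  g <- voxel_grid(c(6, 6, 6), spacing = c(2, 2, 2),
                  origin = c(-6, -6, -6))
  lines <- lapply(seq(-5, 5, by = 1.5), function(x)
    lapply(seq(-5, 5, by = 1.5), function(y)
      straight_line(c(x, y, -7), c(x, y, 7), n = 10)))
  set <- streamline_set(unlist(lines, recursive = FALSE))
  D <- discrete_divergence(set, g, mode = "fd",
                           sphere_diameter_mm = 1.9)
  interior <- D[3:4, 3:4, 3:4]
  expect_true(all(abs(interior) < 1e-9))
  expect_error(discrete_divergence(set, g, mode = "nope"))
})

test_that("orientation magnitude and alignment invariants hold on synthetic tracks", {
  spec <- test_spec()
  sl <- synth_streamlines(spec, n = 150, noise_deg = 4, seed = 5)
  pts <- do.call(rbind, unclass(sl))
  g <- voxel_grid_cover(apply(pts, 2, min), apply(pts, 2, max),
                        centre_on = c(0, NA, NA))
  vf <- tract_voxel_fields(sl, g)
  a_e2 <- apply(vf$orientation, c(1, 2, 3), function(v) sum(v * g$e2))
  norms <- sqrt(apply(vf$orientation^2, c(1, 2, 3), sum))
  expect_true(all(a_e2[vf$valid] >= -1e-12))
  expect_true(all(norms <= 1 + 1e-9))
  expect_true(all(vf$orientation[!vf$valid] == 0))
  expect_true(all(vf$count[!vf$valid] == 0L))
})
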