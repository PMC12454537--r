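# Shared fixtures, built lazily and cached for the duration of a test file.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small bipennate mesh shared by thermal/mechanics tests
test_spec <- function(element_size_mm = 8, ...)
  bipennate_spec(element_size_mm = element_size_mm, ...)

test_mesh <- function() fixture("mesh8", function()
  make_bipennate_mesh(test_spec()))

# unit cube split into 6 tets, inlet z=0 / outlet z=1, muscle region
unit_cube_mesh <- function(region = "muscle") {
  nodes <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  v <- function(i, j, k) 1L + i + 2L * j + 4L * k
  elems <- rbind(
    c(v(0, 0, 0), v(1, 0, 0), v(1, 1, 0), v(1, 1, 1)),
    c(v(0, 0, 0), v(1, 1, 0), v(0, 1, 0), v(1, 1, 1)),
    c(v(0, 0, 0), v(0, 1, 0), v(0, 1, 1), v(1, 1, 1)),
    c(v(0, 0, 0), v(0, 1, 1), v(0, 0, 1), v(1, 1, 1)),
    c(v(0, 0, 0), v(0, 0, 1), v(1, 0, 1), v(1, 1, 1)),
    c(v(0, 0, 0), v(1, 0, 1), v(1, 0, 0), v(1, 1, 1)))
  vol <- myoarch:::tet_volumes_raw(nodes, elems)
  elems[vol < 0, c(3, 4)] <- elems[vol < 0, c(4, 3)]
  tet_mesh(nodes, elems, rep(region, 6L),
           face_sets = list(
             inlet = rbind(c(v(0, 0, 0), v(1, 0, 0), v(1, 1, 0)),
                           c(v(0, 0, 0), v(1, 1, 0), v(0, 1, 0))),
             outlet = rbind(c(v(0, 0, 1), v(1, 0, 1), v(1, 1, 1)),
                            c(v(0, 0, 1), v(1, 1, 1), v(0, 1, 1)))),
           e2 = c(0, 0, 1))
}

# structured box mesh nx x ny x nz over [0,Lx]x[0,Ly]x[0,Lz] with
# inlet/outlet at z = 0 / z = Lz and the lateral boundary split into
# muscle_surface (x faces) and aponeurosis_surface (y faces) so that all
# four face sets exist for Dirichlet tests
box_mesh <- function(n = c(3, 3, 6), L = c(1, 1, 2)) {
  nx <- n[1] + 1L; ny <- n[2] + 1L; nz <- n[3] + 1L
  g <- expand.grid(x = seq(0, L[1], length.out = nx),
                   y = seq(0, L[2], length.out = ny),
                   z = seq(0, L[3], length.out = nz))
  nodes <- as.matrix(g)
  gid <- function(i, j, k) i + nx * ((j - 1L) + ny * (k - 1L))
  hex <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L),
                     k = seq_len(nz - 1L))
  vv <- function(di, dj, dk) gid(hex$i + di, hex$j + dj, hex$k + dk)
  elems <- rbind(cbind(vv(0,0,0), vv(1,0,0), vv(1,1,0), vv(1,1,1)),
                 cbind(vv(0,0,0), vv(1,1,0), vv(0,1,0), vv(1,1,1)),
                 cbind(vv(0,0,0), vv(0,1,0), vv(0,1,1), vv(1,1,1)),
                 cbind(vv(0,0,0), vv(0,1,1), vv(0,0,1), vv(1,1,1)),
                 cbind(vv(0,0,0), vv(0,0,1), vv(1,0,1), vv(1,1,1)),
                 cbind(vv(0,0,0), vv(1,0,1), vv(1,0,0), vv(1,1,1)))
  vol <- myoarch:::tet_volumes_raw(nodes, elems)
  elems[vol < 0, c(3, 4)] <- elems[vol < 0, c(4, 3)]
  mesh <- tet_mesh(nodes, elems, rep("muscle", nrow(elems)),
                   e2 = c(0, 0, 1))
  bf <- boundary_faces(mesh)
  fc <- (nodes[bf$faces[, 1], ] + nodes[bf$faces[, 2], ] +
           nodes[bf$faces[, 3], ]) / 3
  tol <- 1e-9
  inlet <- abs(fc[, 3]) < tol
  outlet <- abs(fc[, 3] - L[3]) < tol
  xface <- abs(fc[, 1]) < tol | abs(fc[, 1] - L[1]) < tol
  yface <- (abs(fc[, 2]) < tol | abs(fc[, 2] - L[2]) < tol) & !xface
  mesh$face_sets <- list(
    inlet = bf$faces[inlet, , drop = FALSE],
    outlet = bf$faces[outlet, , drop = FALSE],
    muscle_surface = bf$faces[xface & !inlet & !outlet, , drop = FALSE],
    aponeurosis_surface = bf$faces[yface & !inlet & !outlet, ,
                                   drop = FALSE])
  mesh
}

# straight streamline along a direction
straight_line <- function(from, to, n = 2) {
  t <- seq(0, 1, length.out = n)
  cbind(from[1] + t * (to[1] - from[1]),
        from[2] + t * (to[2] - from[2]),
        from[3] + t * (to[3] - from[3]))
}

# independent scalar strain-energy oracle for the passive constitutive
# model (matrix + volumetric + passive fibre), used to check stresses by
# central differences; deliberately written from the energy, not from
# the stress formulas under test
energy_oracle <- function(F, a0, mat, lambda_shift = 0) {
  C <- t(F) %*% F
  J <- det(F)
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(C * C))
  W_iso <- mat$C1 * (I1 * J^(-2 / 3) - 3) + mat$C2 * (I2 * J^(-4 / 3) - 3)
  W_vol <- mat$k / 2 * (J - 1)^2
  lam <- sqrt(drop(a0 %*% C %*% a0)) + lambda_shift
  W_fib <- if (lam >= 1)
    mat$C3 * (lam^mat$C4 / mat$C4 - log(lam)) -
      mat$C3 * (1 / mat$C4)                       # zero at lam = 1
  else 0
  W_iso + W_vol + W_fib
}

# first Piola-Kirchhoff stress of the oracle energy by central differences
pk1_fd_oracle <- function(F, a0, mat, lambda_shift = 0, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fm <- F
    Fp[i, j] <- Fp[i, j] + h
    Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (energy_oracle(Fp, a0, mat, lambda_shift) -
                  energy_oracle(Fm, a0, mat, lambda_shift)) / (2 * h)
  }
  P
}

# closed-form uniaxial stress response along the fibre axis (z): finds
# the lateral stretch giving zero transverse stress, returns the nominal
# axial stress; independent 1D oracle for the FE solver
uniaxial_oracle <- function(lz, mat, alpha = 0, lambda_shift = 0) {
  f <- function(lt) {
    S <- total_pk2(diag(c(lt, lt, lz)), c(0, 0, 1), mat, alpha,
                   lambda_shift)
    S[1, 1]
  }
  lt <- stats::uniroot(f, c(0.3, 2), tol = 1e-14)$root
  S <- total_pk2(diag(c(lt, lt, lz)), c(0, 0, 1), mat, alpha,
                 lambda_shift)
  list(lt = lt, nominal_stress = lz * S[3, 3])
}
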