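#' Tagged tetrahedral meshes
#'
#' A \code{tet_mesh} couples nodes and linear tetrahedra with per-element
#' region labels (\code{muscle}, \code{tendon_proximal},
#' \code{tendon_distal}, \code{aponeurosis}) and named face sets
#' (\code{inlet}, \code{outlet}, \code{muscle_surface},
#' \code{aponeurosis_surface}) used as Dirichlet boundaries by the thermal
#' fibre solver and as kinematic boundaries by the mechanics solver.
#'
#' @param nodes N x 3 matrix of node coordinates (mm).
#' @param elems E x 4 integer matrix of node indices (1-based), positively
#'   oriented.
#' @param region character vector of length E.
#' @param face_sets named list of F x 3 node-index matrices.
#' @param e2 principal muscle axis (unit vector).
#' @return object of class \code{tet_mesh}.
#' @export
tet_mesh <- function(nodes, elems, region, face_sets = list(),
                     e2 = c(0, 0, 1)) {
  nodes <- matrix(as.numeric(nodes), ncol = 3)
  elems <- matrix(as.integer(elems), ncol = 4)
  stopifnot(length(region) == nrow(elems))
  v <- tet_volumes_raw(nodes, elems)
  if (any(v <= 0)) stop("tet_mesh: all element volumes must be positive")
  structure(list(nodes = nodes, elems = elems,
                 region = as.character(region),
                 face_sets = face_sets, e2 = e2 / sqrt(sum(e2^2))),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("Tetrahedral mesh:", nrow(x$nodes), "nodes,", nrow(x$elems),
      "elements\n")
  cat("  regions:", paste(sprintf("%s=%d", names(table(x$region)),
                                  table(x$region)), collapse = ", "), "\n")
  if (length(x$face_sets))
    cat("  face sets:", paste(sprintf("%s=%d", names(x$face_sets),
                                      vapply(x$face_sets, nrow, integer(1))),
                              collapse = ", "), "\n")
  invisible(x)
}

tet_volumes_raw <- function(nodes, elems) {
  a <- nodes[elems[, 2], ] - nodes[elems[, 1], ]
  b <- nodes[elems[, 3], ] - nodes[elems[, 1], ]
  c_ <- nodes[elems[, 4], ] - nodes[elems[, 1], ]
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
     a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
     a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Element volumes of a tet mesh
#' @param mesh a \code{tet_mesh}.
#' @return numeric vector of volumes (mm^3).
#' @export
tet_volumes <- function(mesh) tet_volumes_raw(mesh$nodes, mesh$elems)

#' Element centroids
#' @param mesh a \code{tet_mesh}.
#' @return E x 3 matrix.
#' @export
tet_centroids <- function(mesh) {
  (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
     mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Shape-function gradients of linear tetrahedra
#'
#' Gradients of the four barycentric shape functions are constant per
#' element.
#'
#' @param mesh a \code{tet_mesh}.
#' @return list with \code{grad}, an E x 4 x 3 array (\code{grad[e, a, ]}
#'   is the gradient of shape function a on element e), and \code{volume}.
#' @export
shape_gradients <- function(mesh) {
  n <- mesh$nodes; el <- mesh$elems
  a <- n[el[, 2], , drop = FALSE] - n[el[, 1], , drop = FALSE]
  b <- n[el[, 3], , drop = FALSE] - n[el[, 1], , drop = FALSE]
  c_ <- n[el[, 4], , drop = FALSE] - n[el[, 1], , drop = FALSE]
  bxc <- cross3(b, c_); cxa <- cross3(c_, a); axb <- cross3(a, b)
  det <- rowSums(a * bxc)                      # 6 V
  E <- nrow(el)
  g <- array(0, c(E, 4L, 3L))
  g[, 2L, ] <- bxc / det
  g[, 3L, ] <- cxa / det
  g[, 4L, ] <- axb / det
  g[, 1L, ] <- -(g[, 2L, ] + g[, 3L, ] + g[, 4L, ])
  list(grad = g, volume = det / 6)
}

# all 4 faces of every element as sorted node triples
element_faces <- function(elems) {
  E <- nrow(elems)
  f <- rbind(elems[, c(1, 2, 3)], elems[, c(1, 2, 4)],
             elems[, c(1, 3, 4)], elems[, c(2, 3, 4)])
  owner <- rep.int(seq_len(E), 4L)
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  list(faces = f, sorted = cbind(lo, mid, hi), owner = owner,
       key = paste(lo, mid, hi))
}

#' Boundary faces of a tet mesh
#' @param mesh a \code{tet_mesh}.
#' @return list with \code{faces} (F x 3 node triples) and \code{owner}
#'   (element index of the owning tet).
#' @export
boundary_faces <- function(mesh) {
  ef <- element_faces(mesh$elems)
  cnt <- table(ef$key)
  bd <- cnt[ef$key] == 1L
  list(faces = ef$faces[bd, , drop = FALSE], owner = ef$owner[bd])
}

# interface faces between two region labels; returns F x 3 node triples
interface_faces <- function(mesh, region_a, region_b) {
  ef <- element_faces(mesh$elems)
  o <- order(ef$key)
  key <- ef$key[o]; owner <- ef$owner[o]; faces <- ef$faces[o, , drop = FALSE]
  dup <- which(key[-1] == key[-length(key)])
  r1 <- mesh$region[owner[dup]]; r2 <- mesh$region[owner[dup + 1L]]
  sel <- (r1 %in% region_a & r2 %in% region_b) |
    (r1 %in% region_b & r2 %in% region_a)
  faces[dup[sel], , drop = FALSE]
}

#' Basic element quality metrics
#' @param mesh a \code{tet_mesh}.
#' @return list with \code{min_volume}, \code{max_edge_ratio} (longest over
#'   shortest edge, worst element).
#' @export
mesh_quality <- function(mesh) {
  v <- tet_volumes(mesh)
  el <- mesh$elems; n <- mesh$nodes
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  elen <- sapply(seq_len(nrow(pairs)), function(p)
    sqrt(rowSums((n[el[, pairs[p, 1]], ] - n[el[, pairs[p, 2]], ])^2)))
  list(min_volume = min(v),
       max_edge_ratio = max(apply(elen, 1, max) / apply(elen, 1, min)))
}

#' Nearest-point pairing between two point sets
#'
#' For every row of \code{query} returns the index of the nearest row of
#' \code{ref} (Euclidean). Uniform spatial bucketing with vectorised
#' neighbourhood joins keeps large element-centroid pairings (e.g.
#' between mesh refinement levels) fast; a brute-force safety pass makes
#' the result exact.
#'
#' @param query,ref n x 3 and m x 3 coordinate matrices.
#' @return integer vector of length n with indices into \code{ref}.
#' @export
nearest_point_pairs <- function(query, ref) {
  query <- matrix(as.numeric(query), ncol = 3)
  ref <- matrix(as.numeric(ref), ncol = 3)
  n <- nrow(query); m <- nrow(ref)
  lo <- pmin(apply(ref, 2, min), apply(query, 2, min))
  hi <- pmax(apply(ref, 2, max), apply(query, 2, max))
  span <- pmax(hi - lo, 1e-9)
  cell <- max((prod(span) / m)^(1 / 3) * 1.3, max(span) * 1e-6)
  dims <- pmax(ceiling(span / cell) + 2L, 1L)
  keyof <- function(ijk)
    ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
  qi <- floor(sweep(query, 2, lo) / cell)
  ri <- floor(sweep(ref, 2, lo) / cell)
  rkey <- keyof(ri)
  ord <- order(rkey)
  rk_s <- rkey[ord]
  ukey <- rk_s[!duplicated(rk_s)]
  starts <- which(!duplicated(rk_s))
  counts <- diff(c(starts, m + 1L))
  qkey <- keyof(qi)
  Q <- list(); Rm <- list(); t <- 0L
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- keyof(cbind(qi[, 1] + dx, qi[, 2] + dy, qi[, 3] + dz))
    b <- match(k, ukey)
    sel <- which(!is.na(b))
    if (!length(sel)) next
    sz <- counts[b[sel]]
    t <- t + 1L
    Q[[t]] <- rep(sel, sz)
    Rm[[t]] <- ord[sequence(sz) + rep(starts[b[sel]] - 1L, sz)]
  }
  Q <- unlist(Q); Rm <- unlist(Rm)
  nn <- integer(n)
  dmin <- rep(Inf, n)
  if (length(Q)) {
    d2 <- (query[Q, 1] - ref[Rm, 1])^2 + (query[Q, 2] - ref[Rm, 2])^2 +
      (query[Q, 3] - ref[Rm, 3])^2
    o <- order(Q, d2)
    first <- !duplicated(Q[o])
    nn[Q[o][first]] <- Rm[o][first]
    dmin[Q[o][first]] <- sqrt(d2[o][first])
  }
  # exactness: the 3x3x3 block only guarantees the nearest point within
  # the query point distance to the block boundary
  qin <- sweep(query, 2, lo) - qi * cell
  margin <- pmin(qin[, 1], qin[, 2], qin[, 3],
                 cell - qin[, 1], cell - qin[, 2], cell - qin[, 3]) +
    cell
  redo <- which(dmin > margin)
  for (chunk in split(redo, ceiling(seq_along(redo) / 64))) {
    d2 <- outer(rowSums(query[chunk, , drop = FALSE]^2), rowSums(ref^2),
                "+") - 2 * query[chunk, , drop = FALSE] %*% t(ref)
    nn[chunk] <- max.col(-d2, ties.method = "first")
  }
  nn
}

#' Nodes belonging to a face set
#' @param mesh a \code{tet_mesh}.
#' @param set face-set name.
#' @return sorted unique node indices.
#' @export
face_set_nodes <- function(mesh, set) {
  fs <- mesh$face_sets[[set]]
  if (is.null(fs)) stop("face set not present: ", set)
  sort(unique(as.integer(fs)))
}
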