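# Triangular meshes on the sphere: convex-hull triangulation of a sparse
# direction set, iterated face subdivision to a dense grid, and VBAP gain
# solving over mesh faces.

new_tri_mesh <- function(vertices, faces) {
  m <- list(vertices = vertices, faces = faces)
  class(m) <- "tri_mesh"
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("tri_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces,", nrow(mesh_edges(x)), "edges\n")
  invisible(x)
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a `tri_mesh`.
#' @return a 2-column integer matrix, one row per edge.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Mesh vertices as spherical directions
#'
#' @param mesh a `tri_mesh`.
#' @return a `dir_sph` object, one row per vertex.
#' @export
mesh_directions <- function(mesh) cart_to_sph(mesh$vertices)

# Directed edges of the faces listed in `rows`.
directed_edges <- function(faces) {
  rbind(faces[, c(1, 2), drop = FALSE],
        faces[, c(2, 3), drop = FALSE],
        faces[, c(3, 1), drop = FALSE])
}

#' Triangulate a direction set by its convex hull
#'
#' Builds the closed triangular mesh over the unit vectors of the given
#' directions (incremental convex hull). Faces are oriented outward and the
#' closed mesh satisfies Euler's formula V - E + F = 2.
#'
#' @param directions a `dir_sph` object with at least 4 non-coplanar
#'   directions, no duplicates.
#' @return a `tri_mesh`.
#' @examples
#' m <- triangulate(cart_to_sph(rbind(c(1, 0, 0), c(0, 1, 0),
#'                                    c(0, 0, 1), c(-1, -1, -1))))
#' nrow(m$faces)  # 4
#' @export
triangulate <- function(directions) {
  v <- sph_to_cart(directions)
  n <- nrow(v)
  if (n < 4) stop("triangulation needs at least 4 directions")
  dots <- tcrossprod(v)
  diag(dots) <- -1
  if (any(dots > 1 - 1e-12)) stop("duplicate directions in triangulation input")

  # initial tetrahedron: spread-out non-coplanar quadruple
  i1 <- 1L
  d1 <- dots[i1, ]
  d1[i1] <- 2          # exclude the point itself from the farthest search
  i2 <- which.min(d1)
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  ab <- v[i2, ] - v[i1, ]
  area2 <- vapply(seq_len(n), function(i)
    sum(cr(ab, v[i, ] - v[i1, ])^2), numeric(1))
  i3 <- which.max(area2)
  nrm <- cr(ab, v[i3, ] - v[i1, ])
  vol <- abs(as.vector((v - matrix(v[i1, ], n, 3, byrow = TRUE)) %*% nrm))
  i4 <- which.max(vol)
  if (vol[i4] < 1e-10) stop("directions are coplanar; cannot triangulate")

  tet <- c(i1, i2, i3, i4)
  centroid <- colMeans(v[tet, ])
  faces <- rbind(tet[c(1, 2, 3)], tet[c(1, 2, 4)],
                 tet[c(1, 3, 4)], tet[c(2, 3, 4)])
  # orient each face outward w.r.t. the tetrahedron centroid
  for (fi in seq_len(4)) {
    f <- faces[fi, ]
    nr <- cr(v[f[2], ] - v[f[1], ], v[f[3], ] - v[f[1], ])
    if (sum(nr * (v[f[1], ] - centroid)) < 0) faces[fi, ] <- f[c(1, 3, 2)]
  }

  eps <- 1e-10
  for (p in setdiff(seq_len(n), tet)) {
    # visibility of each current face from point p
    a <- faces[, 1]
    nrs <- t(vapply(seq_len(nrow(faces)), function(fi) {
      f <- faces[fi, ]
      cr(v[f[2], ] - v[f[1], ], v[f[3], ] - v[f[1], ])
    }, numeric(3)))
    vis <- rowSums(nrs * (matrix(v[p, ], nrow(faces), 3, byrow = TRUE) -
                            v[a, , drop = FALSE])) > eps
    if (!any(vis)) next  # inside current hull
    de <- directed_edges(faces[vis, , drop = FALSE])
    key <- paste(de[, 1], de[, 2])
    rkey <- paste(de[, 2], de[, 1])
    horizon <- de[!(key %in% rkey), , drop = FALSE]
    faces <- rbind(faces[!vis, , drop = FALSE],
                   cbind(horizon, p))
  }

  m <- new_tri_mesh(v, unname(faces))
  e <- nrow(mesh_edges(m))
  if (nrow(m$vertices) - e + nrow(m$faces) != 2)
    stop("triangulation produced a non-closed mesh")
  m
}

#' Icosahedron mesh
#'
#' The regular icosahedron on the unit sphere (12 vertices, 20 faces,
#' 30 edges); the usual seed mesh for subdivision grids.
#'
#' @return a `tri_mesh`.
#' @export
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  triangulate(cart_to_sph(v))
}

#' Subdivide a mesh toward a dense spherical grid
#'
#' Each face is split into four by its edge midpoints projected back to the
#' unit sphere; midpoints are shared (deduplicated) across adjacent faces,
#' so one iteration maps V -> V + E vertices and F -> 4F faces.
#'
#' @param mesh a closed `tri_mesh`.
#' @param iterations number of subdivision passes (0 returns the mesh
#'   unchanged). Three passes turn a sparse measurement grid into the dense
#'   rendering grid.
#' @return a `tri_mesh`.
#' @examples
#' nrow(subdivide(icosahedron(), 1)$vertices)  # 42
#' @export
subdivide <- function(mesh, iterations = 3) {
  stopifnot(iterations >= 0)
  v <- mesh$vertices
  f <- mesh$faces
  for (it in seq_len(iterations)) {
    e <- mesh_edges(new_tri_mesh(v, f))
    mid <- v[e[, 1], , drop = FALSE] + v[e[, 2], , drop = FALSE]
    mid <- mid / sqrt(rowSums(mid^2))
    midx <- matrix(0L, nrow(v), nrow(v))
    midx[cbind(e[, 1], e[, 2])] <- nrow(v) + seq_len(nrow(e))
    midx[cbind(e[, 2], e[, 1])] <- nrow(v) + seq_len(nrow(e))
    v <- rbind(v, mid)
    newf <- matrix(0L, 4 * nrow(f), 3)
    for (fi in seq_len(nrow(f))) {
      a <- f[fi, 1]; b <- f[fi, 2]; cc <- f[fi, 3]
      ab <- midx[a, b]; bc <- midx[b, cc]; ca <- midx[cc, a]
      newf[4 * fi - 3, ] <- c(a, ab, ca)
      newf[4 * fi - 2, ] <- c(b, bc, ab)
      newf[4 * fi - 1, ] <- c(cc, ca, bc)
      newf[4 * fi, ]     <- c(ab, bc, ca)
    }
    f <- newf
  }
  new_tri_mesh(v, f)
}

# Stacked inverse vertex matrices, one 3x3 block per face, for fast VBAP
# gain evaluation: gains for all faces at once are solvers %*% p.
vbap_face_solvers <- function(mesh) {
  fmat <- matrix(0, 3 * nrow(mesh$faces), 3)
  for (fi in seq_len(nrow(mesh$faces))) {
    L <- t(mesh$vertices[mesh$faces[fi, ], ])   # vertex vectors as columns
    fmat[(3 * fi - 2):(3 * fi), ] <- solve(L)
  }
  fmat
}

#' VBAP gains for a target direction
#'
#' Finds the mesh face whose three vertices surround the target (the unique
#' face for which solving L g = p gives all-nonnegative gains) and returns
#' the gains normalised to unit Euclidean norm, so the amplitude-panned
#' image points at the target: L g is proportional to the target vector.
#'
#' If no face yields nonnegative gains within tolerance (a numerical corner
#' case), the face minimising the worst negative gain is used with negative
#' gains clamped to zero, with a warning.
#'
#' @param mesh a `tri_mesh`.
#' @param target a single `dir_sph` direction on the sphere.
#' @param solvers optional precomputed [vbap_face_solvers()] output (for
#'   repeated calls on one mesh).
#' @return a list with `face` (face index), `vertices` (3 vertex indices),
#'   and `gains` (3 nonnegative gains, unit Euclidean norm).
#' @export
vbap_gains <- function(mesh, target, solvers = NULL) {
  if (is.null(solvers)) solvers <- vbap_face_solvers(mesh)
  p <- drop(sph_to_cart(target)[1, ])
  G <- matrix(solvers %*% p, nrow = 3)           # 3 x F
  worst <- pmin(G[1, ], G[2, ], G[3, ])
  fi <- which.max(worst)
  g <- G[, fi]
  if (worst[fi] < -1e-9) {
    warning("target outside all mesh faces; clamping negative VBAP gain")
    g <- pmax(g, 0)
  } else {
    g <- pmax(g, 0)
  }
  g <- g / sqrt(sum(g^2))
  list(face = fi, vertices = mesh$faces[fi, ], gains = g)
}

#' Sparse loudspeaker gain vector for a free-field target
#'
#' VBAP over a loudspeaker layout, returned as a full gain vector over all
#' loudspeakers with (at most) three nonzero entries. This is the free-field
#' playback representation: the condition is characterised by its amplitude
#' gains, not rendered audio.
#'
#' @param layout a `tri_mesh` whose vertices are the loudspeaker directions.
#' @param target a single `dir_sph` direction.
#' @param solvers optional precomputed [vbap_face_solvers()] output.
#' @return numeric gain vector of length `nrow(layout$vertices)`, unit
#'   Euclidean norm.
#' @export
vbap_speaker_gains <- function(layout, target, solvers = NULL) {
  g <- vbap_gains(layout, target, solvers)
  out <- numeric(nrow(layout$vertices))
  out[g$vertices] <- g$gains
  out
}
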