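## Mesh geometry utilities: mirroring, signed surface distance, volume.

#' Signed volume of a closed mesh
#'
#' Divergence-theorem volume: sum of signed tetrahedron volumes spanned by
#' the faces and the origin. Positive for outward-oriented (counter-clockwise
#' seen from outside) closed surfaces.
#'
#' @param mesh a [TriangleMesh-class].
#' @return volume in mm^3 (signed).
#' @export
meshVolume <- function(mesh) {
  V <- mesh@vertices
  F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c3 <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Is a mesh watertight?
#'
#' A mesh is treated as closed when every undirected edge is shared by
#' exactly two faces with opposite orientation, which is the precondition
#' for a well-defined inside/outside in [signedGeometricError()].
#'
#' @param mesh a [TriangleMesh-class].
#' @return logical.
#' @export
isWatertight <- function(mesh) {
  F <- mesh@faces
  if (nrow(F) == 0) return(FALSE)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  directed <- paste(e[, 1], e[, 2])
  if (anyDuplicated(directed)) return(FALSE)
  undirected <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(undirected) == 2L)
}

#' Mirror a mesh through a plane
#'
#' Reflects the vertices through the plane through the origin with the given
#' unit normal and reverses the face winding so outward normals (and signed
#' volume) are preserved.
#'
#' @param mesh a [TriangleMesh-class].
#' @param planeNormal unit normal of the mirror plane.
#' @return the mirrored [TriangleMesh-class].
#' @export
mirrorMesh <- function(mesh, planeNormal = c(0, 0, 1)) {
  n <- checkUnitNormal(planeNormal)
  H <- diag(3) - 2 * tcrossprod(n)
  mesh@vertices <- mesh@vertices %*% H   # H symmetric
  mesh@faces <- mesh@faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

checkUnitNormal <- function(n) {
  if (length(n) != 3 || abs(sqrt(sum(n^2)) - 1) > 1e-9)
    stop("plane normal must be a unit 3-vector")
  as.numeric(n)
}

#' Mirror a limb model
#'
#' Mirrors every component (with face-winding reversal) and the skeleton
#' through a plane through the origin. Frame x and y axes are reflected and
#' z is recomputed as x cross y, which keeps every frame right-handed with z
#' perpendicular to the (mirrored) sagittal plane — the convention used to
#' turn right limbs into left-limb geometry.
#'
#' @param model a [LimbModel-class].
#' @param planeNormal unit normal of the mirror plane (plane through origin).
#' @return the mirrored [LimbModel-class].
#' @export
mirrorLimb <- function(model, planeNormal = c(0, 0, 1)) {
  n <- checkUnitNormal(planeNormal)
  H <- diag(3) - 2 * tcrossprod(n)
  model@components <- lapply(model@components, mirrorMesh,
                             planeNormal = n)
  skel <- model@skeleton
  for (b in skel@boneIds) {
    A <- skel@axes[[b]]
    x <- as.numeric(H %*% A[, 1])
    y <- as.numeric(H %*% A[, 2])
    skel@axes[[b]] <- cbind(x, y, crossProduct3(x, y))
    skel@origins[[b]] <- as.numeric(H %*% skel@origins[[b]])
  }
  model@skeleton <- skel
  model
}

#' Per-vertex area-weighted normals
#'
#' Unit vertex normals as the normalized sum of incident face (cross
#' product) normals; vertices without incident faces get a zero normal.
#'
#' @param mesh a [TriangleMesh-class].
#' @return n x 3 matrix of unit (or zero) normals.
#' @export
meshVertexNormals <- function(mesh) {
  V <- mesh@vertices
  F <- mesh@faces
  N <- matrix(0, nrow(V), 3)
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  for (f in seq_len(nrow(F))) for (k in 1:3)
    N[F[f, k], ] <- N[F[f, k], ] + fn[f, ]
  len <- sqrt(rowSums(N^2))
  ok <- len > 0
  N[ok, ] <- N[ok, ] / len[ok]
  N
}

#' Signed geometric error between a registered mesh and its target
#'
#' For every vertex of `registered`, the Euclidean distance to the closest
#' point on the `target` surface, signed negative when the vertex lies inside
#' the closed target and positive outside (generalized winding number test;
#' points exactly on the surface get distance 0). When the target is not
#' watertight the sign is undefined, so the unsigned distance is returned
#' with `unsignedFallback = TRUE` and a warning.
#'
#' @param registered a [TriangleMesh-class] (or n x 3 point matrix).
#' @param target a [TriangleMesh-class]; should be closed for signed output.
#' @return A list of class `"geometricError"`: `distance` (per-vertex signed
#'   mm), `mean`, `sd`, `meanUnsigned`, `unsignedFallback`.
#' @export
signedGeometricError <- function(registered, target) {
  pts <- if (is(registered, "TriangleMesh")) registered@vertices
         else as.matrix(registered)
  cp <- .meshClosestPoints(pts, target@vertices, target@faces)
  d <- cp$distance
  fallback <- !isWatertight(target)
  if (fallback) {
    warning("target mesh is not watertight; returning unsigned distances")
  } else {
    w <- .meshWindingNumber(pts, target@vertices, target@faces)
    inside <- abs(w) > 0.5 & d > 0
    d[inside] <- -d[inside]
  }
  structure(list(distance = d, mean = mean(d), sd = sd(d),
                 meanUnsigned = mean(abs(d)),
                 unsignedFallback = fallback),
            class = "geometricError")
}

#' @export
print.geometricError <- function(x, ...) {
  cat(sprintf(
    "geometric error over %d vertices: mean %+0.4f mm (sd %0.4f), mean unsigned %0.4f mm%s\n",
    length(x$distance), x$mean, x$sd, x$meanUnsigned,
    if (x$unsignedFallback) " [unsigned fallback: open target]" else ""))
  invisible(x)
}

#' Write a per-vertex distance table as CSV
#'
#' @param error a `"geometricError"` result.
#' @param path output CSV path (columns `vertex_index`, `signed_distance`).
#' @return `path`, invisibly.
#' @export
writeErrorCSV <- function(error, path) {
  df <- data.frame(vertex_index = seq_along(error$distance),
                   signed_distance = error$distance)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
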