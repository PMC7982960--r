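## Homogeneous 4x4 rigid / similarity transforms. Units: mm, radians.

crossProduct3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize zero vector")
  v / n
}

#' Build a homogeneous rigid (or similarity) transform
#'
#' @param rotation 3x3 rotation matrix (orthogonal, det +1).
#' @param translation numeric(3), mm.
#' @param scale optional uniform scale factor folded into the linear block.
#' @return 4x4 homogeneous matrix with last row (0,0,0,1).
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  T <- diag(4)
  T[1:3, 1:3] <- scale * rotation
  T[1:3, 4] <- translation
  T
}

#' Check the invariants of a rigid transform
#'
#' Verifies the last row is (0,0,0,1) and, unless `allowScale`, that the
#' linear block is orthogonal with positive determinant.
#'
#' @param T 4x4 matrix.
#' @param allowScale allow a uniform scale in the linear block.
#' @param tol orthogonality tolerance.
#' @return `TRUE` invisibly, or an error.
#' @export
validateTransform <- function(T, allowScale = FALSE, tol = 1e-9) {
  stopifnot(is.matrix(T), all(dim(T) == c(4, 4)))
  if (max(abs(T[4, ] - c(0, 0, 0, 1))) > tol)
    stop("last row of a homogeneous transform must be (0,0,0,1)")
  R <- T[1:3, 1:3]
  G <- crossprod(R)
  s2 <- mean(diag(G))
  if (!allowScale && abs(s2 - 1) > tol)
    stop("rotation block is not orthogonal (scale detected)")
  if (max(abs(G - s2 * diag(3))) > max(tol, 1e-9 * s2))
    stop("rotation block is not orthogonal")
  if (det(R) <= 0) stop("rotation block must have positive determinant")
  invisible(TRUE)
}

#' Elementary rotations
#'
#' 3x3 rotation matrices about the coordinate axes (right-hand rule).
#'
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotX3 <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rotX3
#' @export
rotY3 <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rotX3
#' @export
rotZ3 <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Homogeneous rotation about the z axis
#' @param theta angle in radians.
#' @return 4x4 homogeneous rotation matrix.
#' @export
rotZ4 <- function(theta) rigidTransform(rotZ3(theta))

#' Rotation about an arbitrary axis through a point
#'
#' Rodrigues rotation of angle `theta` about the line through `point` with
#' unit direction `axis`, as a homogeneous transform. The line is pointwise
#' fixed.
#'
#' @param axis unit numeric(3).
#' @param point numeric(3) on the axis, mm.
#' @param theta angle in radians.
#' @return 4x4 homogeneous matrix.
#' @export
axisAngleTransform <- function(axis, point, theta) {
  a <- normalize3(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  rigidTransform(R, point - R %*% point)
}

applyTransformPoints <- function(points, T) {
  out <- points %*% t(T[1:3, 1:3])
  out[, 1] <- out[, 1] + T[1, 4]
  out[, 2] <- out[, 2] + T[2, 4]
  out[, 3] <- out[, 3] + T[3, 4]
  out
}

#' Apply a homogeneous transform
#'
#' Maps every vertex through the homogeneous product. Faces (and for a
#' [LimbModel-class] the skeleton frames) are carried along; vertex order is
#' preserved.
#'
#' @param x a [TriangleMesh-class], [LimbModel-class], or an n x 3 point
#'   matrix.
#' @param transform 4x4 homogeneous matrix.
#' @return Object of the same class as `x`.
#' @export
setGeneric("applyTransform",
           function(x, transform) standardGeneric("applyTransform"))

#' @rdname applyTransform
setMethod("applyTransform", "matrix", function(x, transform) {
  applyTransformPoints(x, transform)
})

#' @rdname applyTransform
setMethod("applyTransform", "TriangleMesh", function(x, transform) {
  x@vertices <- applyTransformPoints(x@vertices, transform)
  x
})

#' @rdname applyTransform
setMethod("applyTransform", "LimbModel", function(x, transform) {
  x@components <- lapply(x@components, applyTransform, transform = transform)
  x@skeleton <- transformSkeleton(x@skeleton, transform)
  x
})

## Apply a transform to (a subset of) skeleton frames. Axes are rotated with
## the scale removed so frames stay orthonormal under similarity transforms.
transformSkeleton <- function(skel, T, bones = skel@boneIds) {
  R <- T[1:3, 1:3]
  s <- sqrt(mean(diag(crossprod(R))))
  Rn <- R / s
  for (b in bones) {
    skel@axes[[b]] <- Rn %*% skel@axes[[b]]
    skel@origins[[b]] <- as.numeric(applyTransformPoints(
      matrix(skel@origins[[b]], 1, 3), T))
  }
  skel
}
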