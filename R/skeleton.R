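## Kinematics of the articulated limb: bone frames, joint circle fitting,
## spherical joint angles, flexion transforms, whole-limb articulation.

#' Local-to-world transform of a bone frame
#'
#' Columns of the linear block are the frame's x, y, z axes; the translation
#' is the frame origin (the joint circle center c_b).
#'
#' @param skeleton a [Skeleton-class].
#' @param boneId bone identifier.
#' @return 4x4 homogeneous matrix.
#' @export
boneTransform <- function(skeleton, boneId) {
  rigidTransform(skeleton@axes[[boneId]], skeleton@origins[[boneId]])
}

boneOrder <- function(skeleton) {
  ids <- skeleton@boneIds
  ord <- character(0)
  left <- ids
  while (length(left)) {
    ready <- left[vapply(left, function(b) {
      p <- skeleton@parents[[b]]
      is.na(p) || p %in% ord
    }, logical(1))]
    ord <- c(ord, ready)
    left <- setdiff(left, ready)
  }
  ord
}

boneDescendants <- function(skeleton, boneId) {
  out <- boneId
  repeat {
    kids <- skeleton@boneIds[skeleton@parents %in% out &
                             !skeleton@boneIds %in% out]
    if (!length(kids)) break
    out <- c(out, kids)
  }
  out
}

#' Least-squares circle fit of a joint surface in its sagittal plane
#'
#' Projects the points into the plane through their centroid with the given
#' normal (the bone's sagittal plane has normal z_b) and fits a circle by the
#' algebraic (Kasa) least-squares method. The center is returned in 3D world
#' coordinates (it lies in the projection plane).
#'
#' @param points n x 3 matrix of joint-surface points (n >= 3).
#' @param planeNormal unit normal of the projection (sagittal) plane.
#' @return list with `center` (numeric(3)), `radius` (mm), `rmse` of the
#'   in-plane radial residuals.
#' @export
fitJointCircle <- function(points, planeNormal) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("circle fit needs at least 3 points")
  n <- checkUnitNormal(planeNormal)
  m <- colMeans(points)
  ## deterministic in-plane basis
  seed <- diag(3)[, which.min(abs(n))]
  e1 <- normalize3(seed - sum(seed * n) * n)
  e2 <- crossProduct3(n, e1)
  rel <- sweep(points, 2, m)
  u <- rel %*% e1
  v <- rel %*% e2
  A <- cbind(2 * u, 2 * v, 1)
  rhs <- u^2 + v^2
  qrA <- qr(A)
  if (qrA$rank < 3)
    stop("degenerate circle fit: projected points are collinear")
  sol <- qr.coef(qrA, rhs)
  r <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  center <- m + sol[1] * e1 + sol[2] * e2
  resid <- sqrt((u - sol[1])^2 + (v - sol[2])^2) - r
  list(center = as.numeric(center), radius = as.numeric(r),
       rmse = sqrt(mean(resid^2)))
}

#' Spherical joint angles between adjacent bone frames
#'
#' Decomposes the relative rotation from the parent frame to the bone frame
#' as R = Rz(alpha) Rx(beta) Ry(gamma) expressed in the parent frame:
#' `alpha` is the extension/flexion angle, measured inside the parent's
#' sagittal (x-y) plane about the parent z axis; `beta` is the
#' abduction/adduction elevation of the bone's y axis out of that plane;
#' `gamma` is the residual internal rotation about the bone's own y axis.
#' [frameFromAngles()] composes the inverse.
#'
#' @param bone 3x3 orthonormal axes matrix of the bone frame (columns x,y,z).
#' @param parent 3x3 orthonormal axes matrix of the parent frame.
#' @return named numeric(3): `alpha`, `beta`, `gamma` in radians.
#' @export
sphericalAngles <- function(bone, parent) {
  Q <- crossprod(parent, bone)     # t(parent) %*% bone
  u <- Q[, 2]                      # bone y axis in parent coordinates
  rxy <- sqrt(u[1]^2 + u[2]^2)
  if (rxy < 1e-9)
    stop(sprintf(
      "degenerate pose: bone y parallel to parent z (beta = %+0.6f rad)",
      sign(u[3]) * pi / 2))
  alpha <- atan2(-u[1], u[2])
  beta <- asin(max(-1, min(1, u[3])))
  M <- rotX3(-beta) %*% rotZ3(-alpha) %*% Q
  gamma <- atan2(M[1, 3], M[1, 1])
  c(alpha = alpha, beta = beta, gamma = gamma)
}

#' Compose a bone frame from spherical joint angles
#'
#' @param parent 3x3 orthonormal axes matrix of the parent frame.
#' @param alpha,beta,gamma angles in radians (see [sphericalAngles()]).
#' @return 3x3 axes matrix of the bone frame.
#' @export
frameFromAngles <- function(parent, alpha, beta, gamma) {
  parent %*% rotZ3(alpha) %*% rotX3(beta) %*% rotY3(gamma)
}

#' Flexion transform about a parent bone frame
#'
#' The world-coordinate rotation `T Rz(theta) T^-1` whose pointwise-fixed
#' line is the parent frame's local z axis through its origin.
#'
#' @param parentT 4x4 local-to-world transform of the parent frame.
#' @param theta flexion angle in radians.
#' @return 4x4 homogeneous matrix.
#' @export
flexionTransform <- function(parentT, theta) {
  parentT %*% rotZ4(theta) %*% solve(parentT)
}

#' Articulate a limb model
#'
#' Applies per-joint flexion angles down the kinematic chain: each component
#' is transformed by the composed flexion transforms of its bone and all
#' ancestors (the root bone stays fixed); skeleton frames are updated by the
#' same transforms, so components in the same rigid group receive the
#' identical transform.
#'
#' @param model a [LimbModel-class].
#' @param angles named numeric of flexion angles in radians; names must be
#'   joint names of the skeleton (e.g. `c(MCP = 0.2, PIP = -0.1, DIP = 0.1)`).
#' @return the articulated [LimbModel-class].
#' @export
articulate <- function(model, angles) {
  skel <- model@skeleton
  if (length(angles)) {
    if (is.null(names(angles)) ||
        !all(names(angles) %in% names(skel@jointMap)))
      stop(sprintf("unknown joint(s): %s; skeleton has %s",
                   paste(setdiff(names(angles), names(skel@jointMap)),
                         collapse = ", "),
                   paste(names(skel@jointMap), collapse = ", ")))
    if (any(!is.finite(angles))) stop("joint angles must be finite")
  }
  theta <- setNames(numeric(length(skel@boneIds)), skel@boneIds)
  for (j in names(angles)) theta[[skel@jointMap[[j]]]] <- angles[[j]]

  A <- list()
  for (b in boneOrder(skel)) {
    p <- skel@parents[[b]]
    if (is.na(p)) {
      A[[b]] <- diag(4)
    } else {
      A[[b]] <- A[[p]] %*% flexionTransform(boneTransform(skel, p),
                                            theta[[b]])
    }
  }
  comps <- model@components
  for (nm in names(comps)) {
    b <- skel@componentMap[[nm]]
    comps[[nm]] <- applyTransform(comps[[nm]], A[[b]])
  }
  newSkel <- skel
  for (b in skel@boneIds)
    newSkel <- transformSkeleton(newSkel, A[[b]], bones = b)
  model@components <- comps
  model@skeleton <- newSkel
  model
}
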