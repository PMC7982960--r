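## Scale and pose normalization of registered subjects: global scale from
## the third-metacarpal length, root alignment, then the optimal flexion
## angle per joint (single-axis least-squares Procrustes), proximal to
## distal. Only the extension/flexion degree of freedom is removed;
## abduction/adduction and internal rotation stay in the data as remnant
## posture.

#' Derive a subject's skeleton from its correspondence transforms
#'
#' Bone frame axes are the reference axes carried through each bone's
#' representative-component similarity transform (scale removed); frame
#' origins are re-estimated on the subject by least-squares circle fits of
#' the joint-surface vertex sets (transferred through the correspondence),
#' falling back to the transformed reference origin for bones without an
#' annotated joint surface.
#'
#' @param cs a [CorrespondenceSet-class].
#' @param i subject index.
#' @return A [Skeleton-class] posed in the subject's world coordinates.
#' @export
subjectSkeleton <- function(cs, i) {
  skel <- cs@reference@skeleton
  out <- skel
  for (b in skel@boneIds) {
    comp <- skel@boneComponent[[b]]
    T <- cs@transforms[[i]][[comp]]
    R <- T[1:3, 1:3]
    Rn <- R / sqrt(mean(diag(crossprod(R))))
    out@axes[[b]] <- Rn %*% skel@axes[[b]]
    js <- skel@jointSurface[[b]]
    if (!is.null(js)) {
      pts <- cs@subjects[[i]][[js$component]]@vertices[js$idx, , drop = FALSE]
      out@origins[[b]] <- fitJointCircle(pts, out@axes[[b]][, 3])$center
    } else {
      out@origins[[b]] <- as.numeric(applyTransformPoints(
        matrix(skel@origins[[b]], 1, 3), T))
    }
  }
  out
}

## Subject as a LimbModel in its world pose, on the reference topology.
subjectModel <- function(cs, i) {
  LimbModel(cs@subjects[[i]], subjectSkeleton(cs, i))
}

boneLength <- function(model, boneId) {
  skel <- model@skeleton
  comp <- skel@boneComponent[[boneId]]
  y <- skel@axes[[boneId]][, 2]
  proj <- model@components[[comp]]@vertices %*% y
  len <- max(proj) - min(proj)
  if (!is.finite(len) || len <= 0)
    stop(sprintf("non-positive length computed for bone %s", boneId))
  as.numeric(len)
}

## uniform scaling about an anchor point (default: the centroid of the
## root bone group, the same anchor the pose step aligns, so scaling and
## pose normalization commute and scaling never translates the limb)
scaleModel <- function(model, factor, center = NULL) {
  skel <- model@skeleton
  if (is.null(center)) {
    root <- skel@boneIds[is.na(skel@parents)]
    rootComps <- names(skel@componentMap)[skel@componentMap == root]
    rootComps <- intersect(rootComps, names(model@components))
    V <- do.call(rbind, lapply(model@components[rootComps],
                               function(m) m@vertices))
    center <- colMeans(V)
  }
  model@components <- lapply(model@components, function(m) {
    m@vertices <- sweep(sweep(m@vertices, 2, center) * factor, 2, center,
                        "+")
    m
  })
  for (b in skel@boneIds)
    skel@origins[[b]] <- center + factor * (skel@origins[[b]] - center)
  model@skeleton <- skel
  model
}

#' Scale-normalize a subject to the reference metacarpal length
#'
#' Multiplies all subject coordinates by
#' (reference root-bone length) / (subject root-bone length), where a bone's
#' length is the extent of its representative component's vertices projected
#' on the bone frame's y (elongation) axis. The factor is invariant to the
#' subject's world pose.
#'
#' @param model subject [LimbModel-class] (reference topology, world pose).
#' @param reference the reference [LimbModel-class].
#' @return list: `model` (scaled), `factor`.
#' @export
scaleNormalize <- function(model, reference) {
  root <- reference@skeleton@boneIds[is.na(reference@skeleton@parents)]
  factor <- boneLength(reference, root) / boneLength(model, root)
  list(model = scaleModel(model, factor), factor = factor)
}

#' Optimal single-axis flexion angle (least squares)
#'
#' Closed-form solution of
#' `argmin_theta || ref - Rz(theta) subj ||^2` over corresponding points
#' expressed in the parent bone's local frame:
#' `theta* = atan2(sum (subj x ref)·z, sum (ref·subj − ref_z subj_z))`.
#' The residual at `theta*` is a global minimum of the 1-D Procrustes
#' objective.
#'
#' @param refLocal,subjLocal n x 3 matrices of corresponding local
#'   coordinates.
#' @return `theta*` in radians.
#' @export
optimalFlexion <- function(refLocal, subjLocal) {
  a <- as.matrix(refLocal)
  b <- as.matrix(subjLocal)
  stopifnot(nrow(a) == nrow(b))
  S1 <- sum(b[, 1] * a[, 2] - b[, 2] * a[, 1])   # (b x a) . z
  S2 <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
  scale <- sum(a[, 1]^2 + a[, 2]^2) + sum(b[, 1]^2 + b[, 2]^2)
  if (abs(S1) + abs(S2) < 1e-12 * max(scale, 1))
    stop("undefined flexion angle: points lie on the rotation (z) axis")
  atan2(S1, S2)
}

#' Pose-normalize a scale-normalized subject
#'
#' Aligns the root (metacarpal) group rigidly to the reference using the
#' known correspondence, then walks the chain proximal to distal: for each
#' non-root bone the optimal flexion angle is solved in the parent bone's
#' local frame and removed by the corresponding world-frame flexion
#' transform applied to the bone and all its descendants. Abduction and
#' internal rotation are deliberately left untouched.
#'
#' @param model scale-normalized subject [LimbModel-class].
#' @param reference the reference [LimbModel-class].
#' @param scaleFactor the factor recorded by [scaleNormalize()] (stored in
#'   the result for audit).
#' @return A [NormalizedLimb-class].
#' @export
poseNormalize <- function(model, reference, scaleFactor = 1) {
  skelRef <- reference@skeleton
  root <- skelRef@boneIds[is.na(skelRef@parents)]
  rootComps <- names(skelRef@componentMap)[skelRef@componentMap == root]
  rootComps <- intersect(rootComps, names(model@components))
  X <- do.call(rbind, lapply(model@components[rootComps],
                             function(m) m@vertices))
  Y <- do.call(rbind, lapply(reference@components[rootComps],
                             function(m) m@vertices))
  ## rotation from a similarity fit (so a not-yet-normalized global scale
  ## cannot bias it), applied rigidly with centroid matching: the pose
  ## step must not alter scale
  sim <- umeyama(X, Y, allowScale = TRUE)
  Rr <- sim[1:3, 1:3] / sqrt(mean(diag(crossprod(sim[1:3, 1:3]))))
  model <- applyTransform(model, rigidTransform(
    Rr, colMeans(Y) - as.numeric(Rr %*% colMeans(X))))

  theta <- setNames(numeric(0), character(0))
  for (b in boneOrder(skelRef)) {
    p <- model@skeleton@parents[[b]]
    if (is.na(p)) next
    comps <- names(skelRef@componentMap)[skelRef@componentMap == b]
    comps <- intersect(comps, names(model@components))
    TpRef <- boneTransform(skelRef, p)
    TpSub <- boneTransform(model@skeleton, p)
    refLoc <- applyTransformPoints(
      do.call(rbind, lapply(reference@components[comps],
                            function(m) m@vertices)), solve(TpRef))
    subLoc <- applyTransformPoints(
      do.call(rbind, lapply(model@components[comps],
                            function(m) m@vertices)), solve(TpSub))
    th <- optimalFlexion(refLoc, subLoc)
    A <- flexionTransform(TpSub, th)
    moved <- boneDescendants(model@skeleton, b)
    movedComps <- names(skelRef@componentMap)[
      skelRef@componentMap %in% moved]
    movedComps <- intersect(movedComps, names(model@components))
    for (nm in movedComps)
      model@components[[nm]] <- applyTransform(model@components[[nm]], A)
    model@skeleton <- transformSkeleton(model@skeleton, A, bones = moved)
    joint <- names(skelRef@jointMap)[skelRef@jointMap == b]
    nm <- if (length(joint)) joint[1] else b
    theta[nm] <- th
  }
  new("NormalizedLimb", model = model, theta = theta,
      scale = as.numeric(scaleFactor))
}

#' Scale- and pose-normalize every subject of a correspondence set
#'
#' @param cs a [CorrespondenceSet-class].
#' @param reference reference model; defaults to the set's reference.
#' @return list of [NormalizedLimb-class], one per subject.
#' @export
normalizeSubjects <- function(cs, reference = cs@reference) {
  lapply(seq_along(cs@subjects), function(i) {
    sn <- scaleNormalize(subjectModel(cs, i), reference)
    poseNormalize(sn$model, reference, scaleFactor = sn$factor)
  })
}

#' Write a normalization audit manifest
#'
#' Records the scale factor and the per-joint flexion angles (radians)
#' removed from each subject.
#'
#' @param normalized list of [NormalizedLimb-class].
#' @param path output JSON path.
#' @param ids optional subject identifiers.
#' @return `path`, invisibly.
#' @export
writeNormalizationManifest <- function(normalized, path,
                                       ids = NULL) {
  if (is.null(ids)) ids <- sprintf("subject%02d", seq_along(normalized))
  rec <- lapply(seq_along(normalized), function(i)
    list(id = ids[i], scale = normalized[[i]]@scale,
         theta = as.list(normalized[[i]]@theta)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
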