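## Dense correspondence by elastic surface registration: similarity ICP
## pre-alignment, stiffness-annealed non-rigid ICP with per-vertex affine
## unknowns and a graph-based smoothness term, and the two-pass
## mean-reference refinement. Entirely deterministic: no randomness,
## nearest-point ties resolved by lowest face index.

#' Registration parameters
#'
#' @param stiffness decreasing stiffness annealing schedule (dimensionless
#'   weights of the smoothness term relative to the data term).
#' @param maxIterPerLevel inner iterations per stiffness level.
#' @param tol mean-vertex-movement convergence threshold (mm).
#' @param distanceCap matches farther than this (mm) get zero weight.
#' @param gamma weight of the translation entry in the per-vertex affine
#'   smoothness metric.
#' @param identityWeight weight of a weak prior pulling each vertex toward
#'   its pre-aligned position, selecting the minimal-displacement
#'   deformation among the surface-fitting ones (a smooth global affine
#'   slide along the target surface costs neither data nor smoothness
#'   energy, so without this prior the recovered correspondence could
#'   drift tangentially).
#' @param reverseWeight relative weight of the symmetric (target-to-source)
#'   data term that pins every target vertex to the deformed surface;
#'   without it the deformed mesh can fit the target one-sidedly while
#'   leaving parts of the target uncovered.
#' @param icpMaxIter,icpTol rigid pre-alignment ICP controls.
#' @param minTargetVertices targets smaller than this are refused as
#'   under-constrained unless `force`.
#' @param force allow very small targets.
#' @return A list of class `registrationParams`.
#' @export
registrationParams <- function(stiffness = c(50, 20, 8, 3, 1),
                               maxIterPerLevel = 10, tol = 1e-3,
                               distanceCap = Inf, gamma = 1,
                               identityWeight = 0.05, reverseWeight = 1,
                               icpMaxIter = 60, icpTol = 1e-8,
                               minTargetVertices = 100, force = FALSE) {
  structure(list(stiffness = stiffness, maxIterPerLevel = maxIterPerLevel,
                 tol = tol, distanceCap = distanceCap, gamma = gamma,
                 identityWeight = identityWeight,
                 reverseWeight = reverseWeight,
                 icpMaxIter = icpMaxIter, icpTol = icpTol,
                 minTargetVertices = minTargetVertices, force = force),
            class = "registrationParams")
}

## Closed-form similarity Procrustes (Umeyama): finds s, R, t minimizing
## sum ||y_i - (s R x_i + t)||^2 over given point pairs.
umeyama <- function(X, Y, allowScale = TRUE) {
  mx <- colMeans(X)
  my <- colMeans(Y)
  Xc <- sweep(X, 2, mx)
  Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / nrow(X)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  Dfix <- diag(c(1, 1, d))
  R <- sv$u %*% Dfix %*% t(sv$v)
  varX <- mean(rowSums(Xc^2))
  s <- if (allowScale) sum(sv$d * diag(Dfix)) / varX else 1
  t <- my - s * as.numeric(R %*% mx)
  rigidTransform(R, t, scale = s)
}

meshRMSToSurface <- function(points, target) {
  d <- .meshClosestPoints(points, target@vertices, target@faces)$distance
  sqrt(mean(d^2))
}

#' Rigid/similarity pre-alignment by ICP
#'
#' Aligns the reference mesh to the target with a similarity transform
#' (rotation, translation, uniform scale) minimizing point-to-surface
#' distance. Initialized by centroid and principal-axes alignment; all four
#' right-handed axis-flip hypotheses are tried and the lowest-residual
#' result kept.
#'
#' @param reference,target [TriangleMesh-class] objects.
#' @param params a [registrationParams()] list.
#' @param allowScale include a uniform scale.
#' @param init optional 4x4 transform added to the initialization
#'   hypotheses (e.g. a kinematically consistent neighbor alignment when
#'   registering a single, nearly symmetric component).
#' @param initOnly refine only from `init`, skipping the principal-axes
#'   hypotheses: for small components whose pose is dictated anatomically
#'   by a neighboring bone, a flipped pose can fit the surface as well as
#'   the true one, so the surface residual cannot arbitrate.
#' @return list: `transform` (4x4, scale folded into the linear block),
#'   `scale`, `rmse` (mm), `converged`.
#' @export
rigidPrealign <- function(reference, target, params = registrationParams(),
                          allowScale = TRUE, init = NULL,
                          initOnly = FALSE) {
  X <- reference@vertices
  Y <- target@vertices
  if (nrow(X) == 0 || nrow(Y) == 0) stop("empty mesh")
  if (initOnly && is.null(init)) stop("initOnly requires init")
  principalAxes <- function(P) {
    ev <- eigen(cov(P), symmetric = TRUE)$vectors
    if (det(ev) < 0) ev[, 3] <- -ev[, 3]
    ev
  }
  Ur <- principalAxes(X)
  Ut <- principalAxes(Y)
  mx <- colMeans(X)
  my <- colMeans(Y)
  s0 <- if (allowScale)
    sqrt(mean(rowSums(sweep(Y, 2, my)^2)) /
         mean(rowSums(sweep(X, 2, mx)^2))) else 1
  hypotheses <- list()
  if (!initOnly) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      Sflip <- diag(c(s1, s2, s1 * s2))
      R0 <- Ut %*% Sflip %*% t(Ur)
      hypotheses[[length(hypotheses) + 1L]] <-
        rigidTransform(R0, my - s0 * as.numeric(R0 %*% mx), scale = s0)
    }
  }
  if (!is.null(init)) hypotheses[[length(hypotheses) + 1L]] <- init
  results <- vector("list", length(hypotheses))
  for (hi in seq_along(hypotheses)) {
    T <- hypotheses[[hi]]
    prev <- Inf
    converged <- FALSE
    for (it in seq_len(params$icpMaxIter)) {
      cur <- applyTransformPoints(X, T)
      cp <- .meshClosestPoints(cur, Y, target@faces)
      Tnew <- umeyama(X, cp$closest, allowScale = allowScale)
      ## a collapsing correspondence (e.g. a thin component matched to a
      ## sliver of the target) drives the scale toward zero: reject
      if (!all(is.finite(Tnew)) ||
          sqrt(mean(diag(crossprod(Tnew[1:3, 1:3])))) < 1e-3) break
      T <- Tnew
      rmse <- sqrt(mean(cp$distance^2))
      if (abs(prev - rmse) < params$icpTol) { converged <- TRUE; break }
      prev <- rmse
    }
    rmse <- meshRMSToSurface(applyTransformPoints(X, T), target)
    if (!is.finite(rmse) ||
        sqrt(mean(diag(crossprod(T[1:3, 1:3])))) < 1e-3) next
    results[[hi]] <- list(transform = T,
                          scale = sqrt(mean(diag(crossprod(T[1:3, 1:3])))),
                          rmse = rmse, converged = converged)
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("rigid pre-alignment failed for all hypotheses")
  rmses <- vapply(results[ok], `[[`, numeric(1), "rmse")
  best <- results[ok][[which.min(rmses)]]
  ## for near-symmetric components a mirrored/flipped principal-axes pose
  ## can fit the surface almost as well as the true pose; when a
  ## globally-consistent initialization is supplied it wins unless an
  ## axis-flip hypothesis is clearly (20%) better
  if (!is.null(init) && !is.null(results[[length(hypotheses)]])) {
    fromInit <- results[[length(hypotheses)]]
    if (best$rmse > 0.8 * fromInit$rmse) best <- fromInit
  }
  best
}

## concatenate all components of a subject into one mesh
mergeComponents <- function(comps) {
  off <- 0L
  V <- NULL
  F <- NULL
  for (m in comps) {
    V <- rbind(V, m@vertices)
    F <- rbind(F, m@faces + off)
    off <- off + nrow(m@vertices)
  }
  TriangleMesh(V, F, name = "merged")
}

## barycentric coordinates of the closest points (rev$closest, lying on
## faces rev$face of the mesh with vertex positions cur) — vectorized
barycentricCoords <- function(Y, rev, cur, faces) {
  tri <- faces[rev$face, , drop = FALSE]
  a <- cur[tri[, 1], , drop = FALSE]
  v0 <- cur[tri[, 2], , drop = FALSE] - a
  v1 <- cur[tri[, 3], , drop = FALSE] - a
  v2 <- rev$closest - a
  d00 <- rowSums(v0 * v0)
  d01 <- rowSums(v0 * v1)
  d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0)
  d21 <- rowSums(v2 * v1)
  denom <- d00 * d11 - d01^2
  ok <- denom > 1e-12 * pmax(d00 * d11, 1e-300)
  v <- ifelse(ok, (d11 * d20 - d01 * d21) / denom, 0)
  w <- ifelse(ok, (d00 * d21 - d01 * d20) / denom, 0)
  v <- pmin(pmax(v, 0), 1)
  w <- pmin(pmax(w, 0), 1 - v)
  cbind(1 - v - w, v, w)
}

meshEdges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Elastic (non-rigid) registration of a reference mesh onto a target
#'
#' Stiffness-annealed non-rigid ICP: every reference vertex carries an
#' affine transform; each iteration matches the deformed vertices to their
#' closest points on the target surface and solves a sparse linear
#' least-squares problem balancing that data term against a graph smoothness
#' term penalizing differences between the affines of edge-adjacent
#' vertices. The stiffness weight is annealed from high to low so the
#' deformation proceeds from near-rigid to locally flexible. The output
#' keeps the reference topology (vertex count, order, and faces).
#'
#' @param reference a [TriangleMesh-class], already pre-aligned to the
#'   target.
#' @param target a [TriangleMesh-class].
#' @param params a [registrationParams()] list.
#' @return the deformed reference as a [TriangleMesh-class].
#' @export
elasticRegister <- function(reference, target,
                            params = registrationParams()) {
  V <- reference@vertices
  nV <- nrow(V)
  if (nrow(target@vertices) < params$minTargetVertices && !params$force)
    stop(sprintf(
      "target has %d vertices (< %d): under-constrained; set force=TRUE",
      nrow(target@vertices), params$minTargetVertices))
  edges <- meshEdges(reference@faces)
  nE <- nrow(edges)
  G <- Matrix::Diagonal(x = c(1, 1, 1, params$gamma))
  M <- Matrix::sparseMatrix(i = rep(seq_len(nE), 2),
                            j = c(edges[, 1], edges[, 2]),
                            x = rep(c(1, -1), each = nE),
                            dims = c(nE, nV))
  K <- Matrix::kronecker(M, G)            # 4E x 4V
  KtK <- Matrix::crossprod(K)
  ## D: nV x 4V, row i = [v_i 1] in vertex i's block
  D <- Matrix::sparseMatrix(
    i = rep(seq_len(nV), each = 4),
    j = as.vector(vapply(seq_len(nV), function(i) (4L * (i - 1L)) + 1:4,
                         integer(4))),
    x = as.vector(t(cbind(V, 1))),
    dims = c(nV, 4L * nV))
  DtD <- Matrix::crossprod(D)
  ## unknown X: 4V x 3; init per-vertex identity affine
  X <- matrix(0, 4L * nV, 3)
  X[seq(1, 4L * nV, by = 4L), 1] <- 1
  X[seq(2, 4L * nV, by = 4L), 2] <- 1
  X[seq(3, 4L * nV, by = 4L), 3] <- 1
  Yv <- target@vertices
  nT <- nrow(Yv)
  wRev <- params$reverseWeight * nV / nT
  cur <- V
  for (alpha in params$stiffness) {
    for (it in seq_len(params$maxIterPerLevel)) {
      cp <- .meshClosestPoints(cur, Yv, target@faces)
      w <- as.numeric(cp$distance <= params$distanceCap)
      W2 <- Matrix::Diagonal(x = w)
      lhs <- alpha^2 * KtK + Matrix::crossprod(D, W2 %*% D) +
        params$identityWeight * DtD
      rhs <- Matrix::crossprod(D, W2 %*% cp$closest) +
        params$identityWeight * Matrix::crossprod(D, V)
      if (wRev > 0) {
        ## symmetric term: each target vertex tied to its closest point on
        ## the deformed surface through the barycentric combination of the
        ## face's per-vertex affines
        rev <- .meshClosestPoints(Yv, cur, reference@faces)
        bc <- barycentricCoords(Yv, rev, cur, reference@faces)
        wr <- wRev * as.numeric(rev$distance <= params$distanceCap)
        tri <- reference@faces[rev$face, , drop = FALSE]
        ii <- rep(seq_len(nT), times = 12L)
        jj <- integer(0)
        xx <- numeric(0)
        for (m in 1:3) {
          cols <- 4L * (tri[, m] - 1L)
          jj <- c(jj, cols + 1L, cols + 2L, cols + 3L, cols + 4L)
          xx <- c(xx, bc[, m] * V[tri[, m], 1],
                  bc[, m] * V[tri[, m], 2],
                  bc[, m] * V[tri[, m], 3], bc[, m])
        }
        B <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                  dims = c(nT, 4L * nV))
        Wr <- Matrix::Diagonal(x = wr)
        lhs <- lhs + Matrix::crossprod(B, Wr %*% B)
        rhs <- rhs + Matrix::crossprod(B, Wr %*% Yv)
      }
      ## tiny Tikhonov term: thin, nearly collinear components leave some
      ## affine directions numerically unconstrained
      lhs <- lhs + Matrix::Diagonal(ncol(lhs),
                                    1e-9 * mean(Matrix::diag(lhs)))
      X <- as.matrix(Matrix::solve(lhs, rhs))
      newCur <- as.matrix(D %*% X)
      moved <- mean(sqrt(rowSums((newCur - cur)^2)))
      cur <- newCur
      if (moved < params$tol) break
    }
  }
  reference@vertices <- cur
  reference
}

#' Build dense correspondences for a population of limbs
#'
#' Two-pass scheme: pass 1 registers each reference component elastically
#' onto the corresponding component of every subject (after similarity
#' pre-alignment); pass 2 averages the pass-1 results vertex-wise in the
#' reference frame (pose and scale removed through the pre-alignment
#' transforms) to form a mean reference, and re-registers that mean onto
#' every subject, reducing bias toward the chosen reference. Registered
#' outputs stay in each subject's original world pose.
#'
#' @param reference a [LimbModel-class].
#' @param subjects list of [LimbModel-class] or named lists of
#'   [TriangleMesh-class] sharing the reference's component names.
#' @param params a [registrationParams()] list.
#' @param twoPass set `FALSE` to stop after pass 1.
#' @return A [CorrespondenceSet-class].
#' @export
buildCorrespondences <- function(reference, subjects,
                                 params = registrationParams(),
                                 twoPass = TRUE) {
  refComps <- reference@components
  getComps <- function(s) if (is(s, "LimbModel")) s@components else s
  ids <- names(subjects)
  if (is.null(ids)) ids <- sprintf("subject%02d", seq_along(subjects))
  keep <- vapply(subjects, function(s)
    all(names(refComps) %in% names(getComps(s))), logical(1))
  if (any(!keep))
    warning(sprintf("skipping subject(s) with missing components: %s",
                    paste(ids[!keep], collapse = ", ")))
  subjects <- subjects[keep]
  ids <- ids[keep]

  ## registration order follows the kinematic chain: each bone's large
  ## representative component is aligned first (its parent's transform as
  ## initialization hypothesis — adjacent bones differ only by a joint
  ## rotation), and then carries the small near-symmetric components of
  ## its rigid group (splint bones, sesamoids), whose own principal-axes
  ## alignment would be flip-ambiguous
  skel <- reference@skeleton
  compOrder <- character(0)
  for (b in boneOrder(skel)) {
    rep <- skel@boneComponent[[b]]
    others <- setdiff(names(skel@componentMap)[skel@componentMap == b],
                      rep)
    compOrder <- c(compOrder, rep, others)
  }
  compOrder <- intersect(compOrder, names(reference@components))

  registerAll <- function(refComps) {
    out <- lapply(seq_along(subjects), function(si) {
      comps <- getComps(subjects[[si]])
      reg <- list()
      trans <- list()
      for (nm in compOrder) {
        b <- skel@componentMap[[nm]]
        rep <- skel@boneComponent[[b]]
        init <- if (nm != rep) trans[[rep]]
                else {
                  p <- skel@parents[[b]]
                  if (!is.na(p)) trans[[skel@boneComponent[[p]]]] else NULL
                }
        pre <- rigidPrealign(refComps[[nm]], comps[[nm]], params,
                             init = init, initOnly = nm != rep)
        placed <- applyTransform(refComps[[nm]], pre$transform)
        reg[[nm]] <- elasticRegister(placed, comps[[nm]], params)
        trans[[nm]] <- pre$transform
      }
      list(reg = reg[names(refComps)], trans = trans[names(refComps)])
    })
    out
  }

  pass1 <- registerAll(refComps)
  if (twoPass) {
    meanComps <- refComps
    for (nm in names(refComps)) {
      acc <- 0
      for (r in pass1) {
        back <- applyTransform(r$reg[[nm]], solve(r$trans[[nm]]))
        acc <- acc + back@vertices
      }
      meanComps[[nm]]@vertices <- acc / length(pass1)
    }
    pass1 <- registerAll(meanComps)
  }
  new("CorrespondenceSet",
      reference = reference,
      subjects = lapply(pass1, `[[`, "reg"),
      transforms = lapply(pass1, `[[`, "trans"),
      subjectIds = ids)
}

#' Registration quality report
#'
#' Per-vertex signed error statistics of the registered (reference-topology)
#' meshes against the original subject surfaces, plus the global mean
#' unsigned error with its between-subject standard deviation.
#'
#' @param cs a [CorrespondenceSet-class].
#' @param originals list of the original subjects ([LimbModel-class] or
#'   named mesh lists), same order as the correspondence set.
#' @return list: `perVertex` (named list of data.frames with `mean`/`sd`
#'   columns per component), `globalMeanUnsigned`, `globalSD` (mm),
#'   `subjectMeans`.
#' @export
registrationReport <- function(cs, originals) {
  getComps <- function(s) if (is(s, "LimbModel")) s@components else s
  comps <- names(cs@reference@components)
  L <- length(cs@subjects)
  perComp <- list()
  subjAbs <- matrix(NA_real_, L, length(comps),
                    dimnames = list(NULL, comps))
  subjN <- vapply(cs@reference@components, nVertices, integer(1))
  for (ci in seq_along(comps)) {
    nm <- comps[ci]
    errs <- matrix(NA_real_, nVertices(cs@reference@components[[nm]]), L)
    for (i in seq_len(L)) {
      tgt <- getComps(originals[[i]])[[nm]]
      ge <- suppressWarnings(
        signedGeometricError(cs@subjects[[i]][[nm]], tgt))
      errs[, i] <- ge$distance
      subjAbs[i, ci] <- mean(abs(ge$distance))
    }
    perComp[[nm]] <- data.frame(
      mean = rowMeans(errs),
      sd = if (L > 1) apply(errs, 1, sd) else rep(0, nrow(errs)))
  }
  subjectMeans <- as.numeric(subjAbs %*% subjN / sum(subjN))
  list(perVertex = perComp,
       globalMeanUnsigned = mean(subjectMeans),
       globalSD = if (L > 1) sd(subjectMeans) else 0,
       subjectMeans = subjectMeans)
}
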