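## Anatomical biometrics computed automatically on the 3D models through a
## landmark schema living on the reference topology (landmarks transfer to
## every subject and every synthesized instance through the dense
## correspondence), plus the biometric <-> mode-weight linear regression,
## biometric-driven instance generation, the recomputation confidence
## interval, and the biometric correlation table.
##
## A landmark schema is a named list of `list(component =, idx =)` vertex
## index sets, with `attr(schema, "groundComponent")` naming the component
## whose lowest vertices define the ground plane.

landmarkPoints <- function(model, schema, name, biometric) {
  l <- schema[[name]]
  if (is.null(l))
    stop(sprintf("biometric %s: missing landmark '%s' in schema",
                 biometric, name))
  model@components[[l$component]]@vertices[l$idx, , drop = FALSE]
}

landmarkCentroid <- function(model, schema, name, biometric) {
  colMeans(landmarkPoints(model, schema, name, biometric))
}

## least-squares plane through the lowest 2% (at least 3) of the ground
## component's vertices, heights measured along the root bone's y axis
groundPlane <- function(model, schema) {
  comp <- attr(schema, "groundComponent")
  if (is.null(comp)) stop("schema lacks a groundComponent attribute")
  V <- model@components[[comp]]@vertices
  root <- model@skeleton@boneIds[is.na(model@skeleton@parents)]
  up <- model@skeleton@axes[[root]][, 2]
  h <- as.numeric(V %*% up)
  k <- max(3L, ceiling(0.02 * nrow(V)))
  pts <- V[order(h)[seq_len(k)], , drop = FALSE]
  ctr <- colMeans(pts)
  n <- fitPlaneNormal(pts)
  if (sum(n * up) < 0) n <- -n
  list(point = ctr, normal = n)
}

fitPlaneNormal <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  normalize3(sv$v[, 3])
}

fitLineDirection <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  normalize3(sv$v[, 1])
}

deg <- function(rad) 180 * rad / pi

## angle (degrees) between a line direction and a plane
lineToPlaneAngleDeg <- function(dir, planeNormal) {
  deg(asin(min(1, abs(sum(normalize3(dir) * normalize3(planeNormal))))))
}

planeToPlaneAngleDeg <- function(n1, n2) {
  deg(acos(min(1, abs(sum(normalize3(n1) * normalize3(n2))))))
}

pointToLineDistance <- function(p, linePoint, lineDir) {
  d <- normalize3(lineDir)
  r <- p - linePoint
  sqrt(max(0, sum(r^2) - sum(r * d)^2))
}

projectToPlane <- function(p, plane) {
  p - sum((p - plane$point) * plane$normal) * plane$normal
}

sagittalNormal <- function(model, boneId) model@skeleton@axes[[boneId]][, 3]

patchDepth <- function(pts) {
  n <- fitPlaneNormal(pts)
  r <- as.numeric(sweep(pts, 2, colMeans(pts)) %*% n)
  max(r) - min(r)
}

patchExtent <- function(pts, dir) {
  proj <- as.numeric(pts %*% normalize3(dir))
  max(proj) - min(proj)
}

#' Names of the built-in biometrics
#'
#' Hoof capsule: FL (frog length), FW (frog width), HA (heel angle), HW
#' (hoof width), SL (support length), TA (toe angle), TL (toe length), UR
#' (under-run = HA - TA), WT (wall thickness). Distal phalanx: CA (coffin
#' angle), PA (palmar angle), CD (capsule deviation = CA - TA), TS (toe to
#' heel support, percent of the support length ahead of the articulation
#' center). Proximal/middle phalanx: CR_P1/CR_P2 (distal joint curvature
#' radius), AD_P1/AD_P2 (articular surface depth), AW_P1/AW_P2 (articular
#' surface width), PL_P1/PL_P2 (phalanx length). Third metacarpal: CR
#' (distal joint curvature radius), MW (medio-lateral joint width), RW
#' (sagittal ridge width). Distal sesamoid: SA (sesamoid angle), SH
#' (sesamoid height). Lengths in mm, angles in degrees, TS in percent.
#'
#' @return character vector of biometric identifiers.
#' @export
biometricIds <- function() {
  c("FL", "FW", "HA", "HW", "SL", "TA", "TL", "UR", "WT",
    "CA", "PA", "CD", "TS",
    "CR_P1", "AD_P1", "AW_P1", "PL_P1",
    "CR_P2", "AD_P2", "AW_P2", "PL_P2",
    "CR", "MW", "RW", "SA", "SH")
}

phalanxBiometric <- function(model, schema, id, phal, bone) {
  kind <- sub("_P[12]$", "", id)
  switch(kind,
    CR = {
      pts <- landmarkPoints(model, schema,
                            paste0(tolower(phal), "_distal_joint"), id)
      fitJointCircle(pts, sagittalNormal(model, bone))$radius
    },
    AD = mean(c(
      patchDepth(landmarkPoints(model, schema,
                                paste0(tolower(phal), "_prox_medial"), id)),
      patchDepth(landmarkPoints(model, schema,
                                paste0(tolower(phal), "_prox_lateral"), id)))),
    AW = {
      x <- model@skeleton@axes[[bone]][, 1]
      mean(c(
        patchExtent(landmarkPoints(model, schema,
                                   paste0(tolower(phal), "_prox_medial"), id), x),
        patchExtent(landmarkPoints(model, schema,
                                   paste0(tolower(phal), "_prox_lateral"), id), x)))
    },
    PL = {
      V <- model@components[[phal]]@vertices
      z <- sagittalNormal(model, bone)
      Vp <- V - tcrossprod(as.numeric(V %*% z), z)
      patchExtent(Vp, fitLineDirection(Vp))
    },
    stop(sprintf("unknown biometric '%s'", id)))
}

#' Compute a biometric on a limb model
#'
#' Implements the standard linear and angular hoof/phalanx measures (see
#' [biometricIds()]) on a model in its neutral (reference) pose, using the
#' landmark schema. Measures against "the ground" use the least-squares
#' plane through the lowest 2% of the hoof capsule vertices; sagittal
#' planes are the bone frames' x-y planes.
#'
#' @param model a [LimbModel-class] in neutral pose.
#' @param schema landmark schema (see [generateReferenceLimb()]).
#' @param id biometric identifier from [biometricIds()].
#' @return scalar (mm, degrees, or percent).
#' @export
computeBiometric <- function(model, schema, id) {
  g <- function() groundPlane(model, schema)
  switch(id,
    FL = {
      apex <- landmarkCentroid(model, schema, "frog_apex", id)
      ph <- landmarkPoints(model, schema, "palmar_hoof_line", id)
      pointToLineDistance(apex, colMeans(ph), fitLineDirection(ph))
    },
    FW = sqrt(sum((landmarkCentroid(model, schema, "heel_buttress_medial", id) -
                   landmarkCentroid(model, schema, "heel_buttress_lateral", id))^2)),
    HA = lineToPlaneAngleDeg(
      fitLineDirection(landmarkPoints(model, schema, "heel_wall_line", id)),
      g()$normal),
    HW = {
      z <- sagittalNormal(model, model@skeleton@boneIds[
        length(model@skeleton@boneIds)])
      abs(sum((landmarkCentroid(model, schema, "lateral_wall", id) -
               landmarkCentroid(model, schema, "frog_apex", id)) * z))
    },
    SL = {
      gp <- g()
      toe <- projectToPlane(landmarkCentroid(model, schema, "toe", id), gp)
      ph <- projectToPlane(
        landmarkCentroid(model, schema, "palmar_hoof_line", id), gp)
      sqrt(sum((toe - ph)^2))
    },
    TA = lineToPlaneAngleDeg(
      fitLineDirection(landmarkPoints(model, schema, "dorsal_wall_line", id)),
      g()$normal),
    TL = sqrt(sum((landmarkCentroid(model, schema, "toe", id) -
                   landmarkCentroid(model, schema, "capsule_top", id))^2)),
    UR = computeBiometric(model, schema, "HA") -
         computeBiometric(model, schema, "TA"),
    WT = {
      outer <- landmarkPoints(model, schema, "wall_band_outer", id)
      inner <- landmarkPoints(model, schema, "inner_surface", id)
      ## distance from the outer wall band to the inner surface
      d <- vapply(seq_len(nrow(outer)), function(i)
        min(sqrt(rowSums(sweep(inner, 2, outer[i, ])^2))), numeric(1))
      mean(d)
    },
    CA = lineToPlaneAngleDeg(
      fitLineDirection(landmarkPoints(model, schema, "p3_dorsal_line", id)),
      g()$normal),
    PA = planeToPlaneAngleDeg(
      fitPlaneNormal(landmarkPoints(model, schema, "p3_palmar_surface", id)),
      g()$normal),
    CD = computeBiometric(model, schema, "CA") -
         computeBiometric(model, schema, "TA"),
    TS = {
      gp <- g()
      toe <- projectToPlane(landmarkCentroid(model, schema, "toe", id), gp)
      ph <- projectToPlane(
        landmarkCentroid(model, schema, "palmar_hoof_line", id), gp)
      sl <- sqrt(sum((toe - ph)^2))
      dir <- (ph - toe) / sl
      lastBone <- model@skeleton@boneIds[length(model@skeleton@boneIds)]
      c4 <- projectToPlane(model@skeleton@origins[[lastBone]], gp)
      tc <- sum((c4 - toe) * dir)
      100 * tc / sl
    },
    CR_P1 = , AD_P1 = , AW_P1 = , PL_P1 =
      phalanxBiometric(model, schema, id, "P1", "p1"),
    CR_P2 = , AD_P2 = , AW_P2 = , PL_P2 =
      phalanxBiometric(model, schema, id, "P2", "p2"),
    CR = {
      pts <- landmarkPoints(model, schema, "mc3_distal_joint", id)
      root <- model@skeleton@boneIds[is.na(model@skeleton@parents)]
      fitJointCircle(pts, sagittalNormal(model, root))$radius
    },
    MW = {
      root <- model@skeleton@boneIds[is.na(model@skeleton@parents)]
      patchExtent(landmarkPoints(model, schema, "mc3_distal_joint", id),
                  sagittalNormal(model, root))
    },
    RW = {
      root <- model@skeleton@boneIds[is.na(model@skeleton@parents)]
      patchExtent(landmarkPoints(model, schema, "mc3_sagittal_ridge", id),
                  sagittalNormal(model, root))
    },
    SA = {
      tip <- landmarkCentroid(model, schema, "p3_tip", id)
      dsCom <- landmarkCentroid(model, schema, "ds_all", id)
      lineToPlaneAngleDeg(dsCom - tip,
        fitPlaneNormal(landmarkPoints(model, schema, "p3_palmar_surface", id)))
    },
    SH = {
      lastBone <- model@skeleton@boneIds[length(model@skeleton@boneIds)]
      patchExtent(landmarkPoints(model, schema, "ds_all", id),
                  model@skeleton@axes[[lastBone]][, 2])
    },
    stop(sprintf("unknown biometric '%s'", id)))
}

## resolve a biometric spec: either an id string or a function(model) (or
## function(model, vector) for synthetic functionals of the shape vector)
biometricEvaluator <- function(biometric, schema) {
  if (is.function(biometric)) {
    if (length(formals(biometric)) >= 2)
      function(model, s) biometric(model, s)
    else
      function(model, s) biometric(model)
  } else {
    force(biometric)
    function(model, s) computeBiometric(model, schema, biometric)
  }
}

#' Regress mode weights on a biometric
#'
#' Samples `n` model instances from the SSM's multivariate normal
#' distribution, computes the biometric on each (at neutral pose), and fits
#' the multivariate linear regression `b(k) = alpha + beta k` by
#' independent per-mode least squares (equivalent to the stacked
#' multivariate form). The sample mean and sd of the biometric are stored
#' for the conventional `mu +/- 3 sigma` presets.
#'
#' @param ssm a [LimbSSM-class].
#' @param schema landmark schema.
#' @param biometric a biometric id (see [biometricIds()]) or a function of
#'   the reconstructed model (optionally `(model, shapeVector)`).
#' @param n number of simulated instances.
#' @param seed RNG seed.
#' @return list of class `biometricRegression`: `alpha`, `beta` (length-K
#'   vectors), `muK`, `sdK`, `n`.
#' @export
fitBiometricRegression <- function(ssm, schema, biometric, n = 1000,
                                   seed = 1) {
  stopifnot(n >= 10)
  ev <- biometricEvaluator(biometric, schema)
  sm <- sampleInstances(ssm, n, seed = seed)
  k <- vapply(seq_len(n), function(i) {
    model <- disassembleShapeVector(sm$vectors[, i], ssm@reference,
                                    ssm@mus, ssm@layout)
    ev(model, sm$vectors[, i])
  }, numeric(1))
  if (sd(k) < 1e-12)
    stop("degenerate regression: biometric has zero variance")
  kc <- k - mean(k)
  beta <- as.numeric(crossprod(sm$weights, kc) / sum(kc^2))
  alpha <- colMeans(sm$weights) - beta * mean(k)
  structure(list(alpha = alpha, beta = beta, muK = mean(k), sdK = sd(k),
                 n = n),
            class = "biometricRegression")
}

#' Mode weights for a target biometric value
#'
#' `b(k) = alpha + beta k`; instances for `k = muK +/- 3 sdK` are the
#' conventional presets for visualizing a biometric's effect.
#'
#' @param reg a [fitBiometricRegression()] result.
#' @param k target biometric value.
#' @return numeric weight vector.
#' @export
instanceFromBiometric <- function(reg, k) {
  reg$alpha + reg$beta * k
}

#' Recomputation confidence interval of a biometric regression
#'
#' For a grid of biometric values k spanning `muK +/- 3 sdK`, rebuilds the
#' model instance from `b(k)` and recomputes the biometric on it; the
#' signed differences (recomputed - requested) quantify the nonlinearity of
#' the biometric as a function of the mode weights. Grid points where the
#' reconstruction fails are excluded and reported.
#'
#' @param ssm a [LimbSSM-class].
#' @param schema landmark schema.
#' @param reg a [fitBiometricRegression()] result.
#' @param biometric same biometric the regression was fitted on.
#' @param grid number of grid points (>= 3).
#' @return list: `min`, `max` (signed bounds of recomputed - requested),
#'   `table` (data.frame k/kTilde/delta), `failed` (k values excluded).
#' @export
biometricCI <- function(ssm, schema, reg, biometric, grid = 25) {
  stopifnot(grid >= 3)
  ev <- biometricEvaluator(biometric, schema)
  ks <- seq(reg$muK - 3 * reg$sdK, reg$muK + 3 * reg$sdK,
            length.out = grid)
  delta <- rep(NA_real_, grid)
  ktilde <- rep(NA_real_, grid)
  failed <- numeric(0)
  for (i in seq_along(ks)) {
    res <- tryCatch({
      s <- synthesize(ssm, instanceFromBiometric(reg, ks[i]))
      model <- disassembleShapeVector(s, ssm@reference, ssm@mus,
                                      ssm@layout)
      ev(model, s)
    }, error = function(e) NA_real_)
    if (is.na(res)) {
      failed <- c(failed, ks[i])
    } else {
      ktilde[i] <- res
      delta[i] <- res - ks[i]
    }
  }
  if (length(failed))
    warning(sprintf("%d grid point(s) failed reconstruction and were excluded",
                    length(failed)))
  ok <- !is.na(delta)
  list(min = min(delta[ok]), max = max(delta[ok]),
       table = data.frame(k = ks[ok], kTilde = ktilde[ok],
                          delta = delta[ok]),
       failed = failed)
}

#' Pearson correlation table of biometrics
#'
#' Samples `n` instances and correlates all requested biometrics. Constant
#' biometrics get `NA` rows/columns.
#'
#' @param ssm a [LimbSSM-class].
#' @param schema landmark schema.
#' @param ids biometric identifiers (or named list of ids/functions).
#' @param n number of instances (>= 30).
#' @param seed RNG seed.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlationTable <- function(ssm, schema, ids = biometricIds(), n = 200,
                             seed = 1) {
  stopifnot(n >= 30)
  if (is.null(names(ids)))
    names(ids) <- if (is.character(ids)) ids
                  else sprintf("biometric%d", seq_along(ids))
  sm <- sampleInstances(ssm, n, seed = seed)
  K <- matrix(NA_real_, n, length(ids),
              dimnames = list(NULL, names(ids)))
  for (i in seq_len(n)) {
    model <- disassembleShapeVector(sm$vectors[, i], ssm@reference,
                                    ssm@mus, ssm@layout)
    for (j in seq_along(ids)) {
      ev <- biometricEvaluator(if (is.list(ids)) ids[[j]] else ids[[j]],
                               schema)
      K[i, j] <- ev(model, sm$vectors[, i])
    }
  }
  sds <- apply(K, 2, sd)
  C <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(names(ids), names(ids)))
  ok <- sds > 1e-12
  C[ok, ok] <- cor(K[, ok, drop = FALSE])
  diag(C)[ok] <- 1
  C
}
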