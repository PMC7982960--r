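## Synthetic articulated-limb generator: a procedurally built 10-component
## limb template (3 metacarpal bones, 2 proximal sesamoids, 3 phalanges,
## distal sesamoid, hoof capsule) carried by a 4-bone skeleton chain, with
## analytically known frames, joint-surface patches lying on analytic
## cylinders (so circle-fit truth is known), and a hoof capsule with a
## configurable dorsal-wall angle. The population generator layers low-rank
## smooth shape modes, per-subject global scale, per-joint flexion, optional
## abduction remnant and vertex noise, and an optional remeshing step that
## destroys vertex correspondence so the registration stage has real work
## to do. Everything is deterministic under the config seed.

## --- mesh builders -------------------------------------------------------

## incremental mesh builder: keeps vertex bookkeeping so landmark index sets
## can be recorded as parts are appended
mbNew <- function() list(V = NULL, F = NULL)
mbAdd <- function(mb, V, F) {
  off <- if (is.null(mb$V)) 0L else nrow(mb$V)
  mb$V <- rbind(mb$V, V)
  if (!is.null(F)) mb$F <- rbind(mb$F, F + off)
  list(mb = mb, idx = off + seq_len(nrow(V)))
}

gridFaces <- function(nRow, nCol, wrap = FALSE) {
  ## vertex (i,k) at index (i-1)*nCol + k; quads split into two triangles
  faces <- NULL
  kmax <- if (wrap) nCol else nCol - 1L
  for (i in seq_len(nRow - 1L)) for (k in seq_len(kmax)) {
    k2 <- if (k == nCol) 1L else k + 1L
    a <- (i - 1L) * nCol + k
    b <- (i - 1L) * nCol + k2
    c3 <- i * nCol + k2
    d <- i * nCol + k
    faces <- rbind(faces, c(a, c3, b), c(a, d, c3))
  }
  faces
}

## propagate a consistent face orientation over shared edges (BFS), then
## flip globally so the signed volume is positive (outward normals);
## requires a manifold surface (every edge on at most 2 faces)
orientFaces <- function(V, F) {
  nf <- nrow(F)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edgeFaces <- new.env(hash = TRUE)
  for (f in seq_len(nf)) {
    for (e in list(F[f, 1:2], F[f, 2:3], F[f, c(3, 1)])) {
      k <- key(e[1], e[2])
      edgeFaces[[k]] <- c(edgeFaces[[k]], f)
    }
  }
  visited <- logical(nf)
  hasEdgeDirected <- function(f, a, b) {
    fa <- F[f, ]
    (fa[1] == a && fa[2] == b) || (fa[2] == a && fa[3] == b) ||
      (fa[3] == a && fa[1] == b)
  }
  queue <- 1L
  visited[1] <- TRUE
  while (length(queue)) {
    f <- queue[1]
    queue <- queue[-1]
    for (e in list(F[f, 1:2], F[f, 2:3], F[f, c(3, 1)])) {
      nb <- setdiff(edgeFaces[[key(e[1], e[2])]], f)
      for (g in nb) {
        if (!visited[g]) {
          ## consistent orientation: the shared edge must run in opposite
          ## directions in the two faces
          if (hasEdgeDirected(g, e[1], e[2])) F[g, ] <- F[g, c(1, 3, 2)]
          visited[g] <- TRUE
          queue <- c(queue, g)
        }
      }
    }
  }
  m <- TriangleMesh(V, F)
  if (meshVolume(m) < 0) F <- F[, c(1, 3, 2)]
  F
}

## closed tube along +y with elliptical cross-section and cap fans; the
## cross-section carries a deterministic low-order asymmetry (and a taper
## along y) so the surface has no rotational or flip symmetry and dense
## correspondence to it is unambiguous
tubeMesh <- function(name, center = c(0, 0, 0), rx, rz, y0, y1,
                     nT = 12, nY = 7, texture = 0.04, texLambda = 18) {
  th <- 2 * pi * (seq_len(nT) - 1) / nT
  ys <- seq(y0, y1, length.out = nY)
  V <- do.call(rbind, lapply(ys, function(y) {
    f <- (1 + 0.12 * cos(th) + 0.07 * sin(th)) *
      (1 + 0.1 * (y - y0) / (y1 - y0))
    ## fine bump lattice: the surface texture that anchors dense
    ## correspondence, as muscle ridges and foramina do on real bone
    f <- f * (1 + texture * sin(2 * pi * y / texLambda) * cos(3 * th + 1) +
                texture * cos(2 * pi * y / (0.71 * texLambda) + 0.5) *
                  sin(2 * th))
    cbind(center[1] + rx * f * cos(th), center[2] + y,
          center[3] + rz * f * sin(th))
  }))
  F <- gridFaces(nY, nT, wrap = TRUE)
  nV <- nrow(V)
  V <- rbind(V, c(center[1], center[2] + y0, center[3]),
             c(center[1], center[2] + y1, center[3]))
  bot <- nV + 1L
  top <- nV + 2L
  for (k in seq_len(nT)) {
    k2 <- if (k == nT) 1L else k + 1L
    F <- rbind(F, c(bot, k, k2),
               c(top, (nY - 1L) * nT + k2, (nY - 1L) * nT + k))
  }
  m <- TriangleMesh(V, F, name = name)
  if (meshVolume(m) < 0) m@faces <- m@faces[, c(1, 3, 2)]
  m
}

## closed UV-sphere ellipsoid (y is the polar axis)
ellipsoidMesh <- function(name, center, radii, nU = 8, nV = 6) {
  phis <- pi * seq_len(nV - 1) / nV
  th <- 2 * pi * (seq_len(nU) - 1) / nU
  V <- rbind(center + c(0, radii[2], 0), center - c(0, radii[2], 0))
  for (phi in phis) {
    ## low-order asymmetry killing the three 180-degree flip symmetries,
    ## plus a fine bump lattice anchoring dense correspondence
    f <- 1 + 0.15 * sin(phi) * cos(th) + 0.1 * cos(phi) * cos(th) +
      0.05 * sin(3 * phi) * cos(2 * th + 1)
    V <- rbind(V, cbind(center[1] + radii[1] * f * sin(phi) * cos(th),
                        center[2] + radii[2] * f * cos(phi),
                        center[3] + radii[3] * f * sin(phi) * sin(th)))
  }
  ring <- function(i) 2L + (i - 1L) * nU + seq_len(nU)
  F <- NULL
  r1 <- ring(1)
  for (k in seq_len(nU)) {
    k2 <- if (k == nU) 1L else k + 1L
    F <- rbind(F, c(1L, r1[k], r1[k2]))
  }
  for (i in seq_len(nV - 2L)) {
    ra <- ring(i); rb <- ring(i + 1L)
    for (k in seq_len(nU)) {
      k2 <- if (k == nU) 1L else k + 1L
      F <- rbind(F, c(ra[k], rb[k], rb[k2]), c(ra[k], rb[k2], ra[k2]))
    }
  }
  rl <- ring(nV - 1L)
  for (k in seq_len(nU)) {
    k2 <- if (k == nU) 1L else k + 1L
    F <- rbind(F, c(2L, rl[k2], rl[k]))
  }
  m <- TriangleMesh(V, F, name = name)
  if (meshVolume(m) < 0) m@faces <- m@faces[, c(1, 3, 2)]
  m
}

## open grid patch on a cylinder of radius r about the z axis through
## `center`, opening toward -y (phi = 0), phi in [-arcHalf, arcHalf]
cylinderPatchVerts <- function(center, r, arcHalf, zHalf, nPhi = 7,
                               nZ = 5) {
  phis <- seq(-arcHalf, arcHalf, length.out = nPhi)
  zs <- seq(-zHalf, zHalf, length.out = nZ)
  V <- do.call(rbind, lapply(zs, function(z)
    cbind(center[1] + r * sin(phis), center[2] - r * cos(phis),
          center[3] + z)))
  list(V = V, F = gridFaces(nZ, nPhi, wrap = FALSE), nPhi = nPhi, nZ = nZ)
}

## hoof-capsule-like frustum: elliptical cross sections whose dorsal-most
## point recedes with height at the dorsal wall angle and whose palmar-most
## point advances at the heel/palmar wall angle (angles in radians)
frustumRow <- function(h, a0, p0, w0, dorsalAngle, palmarAngle, H, nT,
                       widthTaper = 0.15, texture = 0, texLambda = 18) {
  xmax <- a0 - h / tan(dorsalAngle)
  xmin <- -p0 + h / tan(palmarAngle)
  w <- w0 * (1 - widthTaper * h / H)
  th <- 2 * pi * (seq_len(nT) - 1) / nT
  ## texture windowed by sin(theta)^2: the dorsal and palmar mid-lines stay
  ## exactly on their configured wall slopes while the side walls carry
  ## the bump lattice that anchors registration
  f <- 1 + texture * sin(th)^2 *
    (sin(2 * pi * h / texLambda) * cos(3 * th + 1) +
     cos(2 * pi * h / (0.71 * texLambda) + 0.5) * sin(2 * th))
  cbind((xmax + xmin) / 2 + (xmax - xmin) / 2 * f * cos(th), h,
        w * f * sin(th))
}

## --- the reference limb --------------------------------------------------

#' Generate the synthetic reference limb
#'
#' Builds a 10-component limb template on a 4-bone skeleton chain
#' (metacarpus group MC2/MC3/MC4 -> P1 group with the proximal sesamoids ->
#' P2 -> P3 group with the distal sesamoid and the hoof capsule), with
#' analytically known bone frames (y along elongation, z the flexion axis),
#' joint-surface patches on analytic cylinders of known radius and center,
#' a hoof capsule with configurable dorsal (toe) and heel wall angles, and
#' a full landmark schema for the biometric module.
#'
#' @param detail resolution multiplier (>= 0.5); 1 gives roughly a thousand
#'   vertices over the whole limb.
#' @param toeAngle,heelAngle capsule dorsal/heel wall angles, degrees.
#' @param coffinAngle,palmarAngle P3 dorsal/palmar angles, degrees.
#' @param wallThickness capsule wall offset, mm.
#' @return list: `model` ([LimbModel-class]), `schema` (landmark schema,
#'   see [computeBiometric()]), `truth` (list of analytically known
#'   quantities: joint circle radii and centers, wall angles).
#' @export
generateReferenceLimb <- function(detail = 1, toeAngle = 52,
                                  heelAngle = 47, coffinAngle = 50,
                                  palmarAngle = 5, wallThickness = 9) {
  stopifnot(detail >= 0.4)
  sc <- function(n, lo = 4L) max(lo, as.integer(round(n * detail)))
  ta <- toeAngle * pi / 180
  ha <- heelAngle * pi / 180
  ca <- coffinAngle * pi / 180
  pa <- palmarAngle * pi / 180

  comps <- list()
  schema <- list()
  truth <- list(toeAngle = toeAngle, heelAngle = heelAngle,
                coffinAngle = coffinAngle, palmarAngle = palmarAngle,
                circles = list())
  jointSurface <- list()

  addPatchTo <- function(mesh, patch) {
    off <- nrow(mesh@vertices)
    mesh@vertices <- rbind(mesh@vertices, patch$V)
    F <- rbind(mesh@faces, patch$F + off)
    storage.mode(F) <- "integer"
    mesh@faces <- F
    list(mesh = mesh, idx = off + seq_len(nrow(patch$V)))
  }

  ## metacarpus group -----------------------------------------------------
  cMC <- c(0, 170, 0)
  mc3 <- tubeMesh("MC3", rx = 16, rz = 14, y0 = 170, y1 = 330,
                  nT = sc(16, 8), nY = sc(26, 8))
  p <- cylinderPatchVerts(cMC, r = 15, arcHalf = 1.0, zHalf = 9,
                          nPhi = sc(7, 5), nZ = sc(5, 4))
  res <- addPatchTo(mc3, p)
  mc3 <- res$mesh
  jointSurface$mc <- list(component = "MC3", idx = res$idx)
  truth$circles$mc <- list(center = cMC, radius = 15)
  ridge <- res$idx[abs(mc3@vertices[res$idx, 3]) < 5]
  schema$mc3_distal_joint <- list(component = "MC3", idx = res$idx)
  schema$mc3_sagittal_ridge <- list(component = "MC3", idx = ridge)
  comps$MC3 <- mc3
  comps$MC2 <- tubeMesh("MC2", center = c(-6, 0, -19), rx = 4.5, rz = 4.5,
                        y0 = 205, y1 = 320, nT = sc(8, 6), nY = sc(18, 6))
  comps$MC4 <- tubeMesh("MC4", center = c(-6, 0, 19), rx = 4.5, rz = 4.5,
                        y0 = 205, y1 = 320, nT = sc(8, 6), nY = sc(18, 6))

  ## P1 group -------------------------------------------------------------
  cP1 <- c(0, 96, 0)
  p1 <- tubeMesh("P1", rx = 13, rz = 12, y0 = 96, y1 = 168,
                 nT = sc(14, 7), nY = sc(12, 5))
  p <- cylinderPatchVerts(cP1, r = 11, arcHalf = 1.0, zHalf = 8,
                          nPhi = sc(6, 5), nZ = sc(4, 4))
  res <- addPatchTo(p1, p)
  p1 <- res$mesh
  jointSurface$p1 <- list(component = "P1", idx = res$idx)
  truth$circles$p1 <- list(center = cP1, radius = 11)
  schema$p1_distal_joint <- list(component = "P1", idx = res$idx)
  for (side in c("medial", "lateral")) {
    zs <- if (side == "medial") c(4, 9) else c(-9, -4)
    pp <- cylinderPatchVerts(c(0, 169, mean(zs)), r = 15.5, arcHalf = 0.9,
                             zHalf = diff(zs) / 2, nPhi = sc(5, 4),
                             nZ = sc(3, 3))
    res <- addPatchTo(p1, pp)
    p1 <- res$mesh
    schema[[paste0("p1_prox_", side)]] <- list(component = "P1",
                                               idx = res$idx)
  }
  comps$P1 <- p1
  comps$PS_med <- ellipsoidMesh("PS_med", c(-14, 172, 9), c(4.5, 6, 4),
                                nU = sc(10, 6), nV = sc(8, 5))
  comps$PS_lat <- ellipsoidMesh("PS_lat", c(-14, 172, -9), c(4.5, 6, 4),
                                nU = sc(10, 6), nV = sc(8, 5))

  ## P2 -------------------------------------------------------------------
  cP2 <- c(0, 50, 0)
  p2 <- tubeMesh("P2", rx = 12, rz = 11, y0 = 50, y1 = 96,
                 nT = sc(14, 7), nY = sc(8, 4))
  p <- cylinderPatchVerts(cP2, r = 10, arcHalf = 1.0, zHalf = 7,
                          nPhi = sc(6, 5), nZ = sc(4, 4))
  res <- addPatchTo(p2, p)
  p2 <- res$mesh
  jointSurface$p2 <- list(component = "P2", idx = res$idx)
  truth$circles$p2 <- list(center = cP2, radius = 10)
  schema$p2_distal_joint <- list(component = "P2", idx = res$idx)
  for (side in c("medial", "lateral")) {
    zs <- if (side == "medial") c(3, 7.5) else c(-7.5, -3)
    pp <- cylinderPatchVerts(c(0, 95, mean(zs)), r = 11.5, arcHalf = 0.9,
                             zHalf = diff(zs) / 2, nPhi = sc(5, 4),
                             nZ = sc(3, 3))
    res <- addPatchTo(p2, pp)
    p2 <- res$mesh
    schema[[paste0("p2_prox_", side)]] <- list(component = "P2",
                                               idx = res$idx)
  }
  comps$P2 <- p2

  ## P3 group -------------------------------------------------------------
  nTp3 <- sc(16, 8)
  nHp3 <- sc(7, 4)
  hs <- seq(0, 28, length.out = nHp3)
  V <- do.call(rbind, lapply(hs, function(h)
    frustumRow(h, a0 = 38, p0 = 28, w0 = 30, dorsalAngle = ca,
               palmarAngle = ha, H = 28, nT = nTp3, texture = 0.04,
               texLambda = 12)))
  V[, 2] <- V[, 2] + 9
  ## tilt the solar (bottom) row so the palmar plane makes the configured
  ## palmar angle with the ground
  baseRows <- seq_len(nTp3)
  V[baseRows, 2] <- V[baseRows, 2] + tan(pa) * V[baseRows, 1]
  F <- gridFaces(nHp3, nTp3, wrap = TRUE)
  nV0 <- nrow(V)
  V <- rbind(V, c(0, 9, 0), c(0, 9 + 28, 0))
  for (k in seq_len(nTp3)) {
    k2 <- if (k == nTp3) 1L else k + 1L
    F <- rbind(F, c(nV0 + 1L, k, k2),
               c(nV0 + 2L, (nHp3 - 1L) * nTp3 + k2, (nHp3 - 1L) * nTp3 + k))
  }
  p3 <- TriangleMesh(V, F, name = "P3")
  if (meshVolume(p3) < 0) p3@faces <- p3@faces[, c(1, 3, 2)]
  dorsalCol <- seq(1L, by = nTp3, length.out = nHp3)
  schema$p3_dorsal_line <- list(component = "P3", idx = dorsalCol)
  schema$p3_palmar_surface <- list(component = "P3",
                                   idx = c(baseRows, nV0 + 1L))
  schema$p3_tip <- list(component = "P3", idx = 1L)
  cP3 <- c(0, 46, 0)
  p <- cylinderPatchVerts(cP3, r = 9, arcHalf = 0.9, zHalf = 6,
                          nPhi = sc(6, 5), nZ = sc(4, 4))
  res <- addPatchTo(p3, p)
  p3 <- res$mesh
  jointSurface$p3 <- list(component = "P3", idx = res$idx)
  truth$circles$p3 <- list(center = cP3, radius = 9)
  comps$P3 <- p3
  comps$DS <- ellipsoidMesh("DS", c(-16, 46, 0), c(4, 8, 6),
                            nU = sc(10, 6), nV = sc(8, 5))
  schema$ds_all <- list(component = "DS",
                        idx = seq_len(nVertices(comps$DS)))

  ## hoof capsule ---------------------------------------------------------
  nT <- sc(24, 10)
  nH <- sc(9, 5)
  H <- 52
  tw <- wallThickness
  hOut <- seq(0, H, length.out = nH)
  outer <- do.call(rbind, lapply(hOut, function(h)
    frustumRow(h, a0 = 58, p0 = 42, w0 = 46, dorsalAngle = ta,
               palmarAngle = ha, H = H, nT = nT, texture = 0.04)))
  nHI <- max(4L, nH - 1L)
  hIn <- seq(2, H - 6, length.out = nHI)
  inner <- do.call(rbind, lapply(hIn, function(h)
    frustumRow(h, a0 = 58 - tw, p0 = 42 - tw, w0 = 46 - tw,
               dorsalAngle = ta, palmarAngle = ha, H = H, nT = nT,
               texture = 0.04)))
  V <- rbind(outer, inner)
  innerOff <- nrow(outer)
  F <- rbind(gridFaces(nH, nT, wrap = TRUE),
             gridFaces(nHI, nT, wrap = TRUE) + innerOff)
  ## top rim: outer top ring <-> inner top ring (coronet band)
  oTop <- (nH - 1L) * nT
  iTop <- innerOff + (nHI - 1L) * nT
  for (k in seq_len(nT)) {
    k2 <- if (k == nT) 1L else k + 1L
    F <- rbind(F, c(oTop + k, iTop + k2, iTop + k),
               c(oTop + k, oTop + k2, iTop + k2))
  }
  ## sole: fan closing the inner cavity at the frog apex, and a ground
  ## disk closing the outer bottom ring
  innerRow1 <- frustumRow(hIn[1], a0 = 58 - tw, p0 = 42 - tw, w0 = 46 - tw,
                          dorsalAngle = ta, palmarAngle = ha, H = H,
                          nT = nT)
  cxI <- (max(innerRow1[, 1]) + min(innerRow1[, 1])) / 2
  frogApex <- c(cxI + 0.3 * (max(innerRow1[, 1]) - cxI), hIn[1], 0)
  outerRow1 <- frustumRow(0, a0 = 58, p0 = 42, w0 = 46, dorsalAngle = ta,
                          palmarAngle = ha, H = H, nT = nT)
  groundCenter <- c((max(outerRow1[, 1]) + min(outerRow1[, 1])) / 2, 0, 0)
  V <- rbind(V, frogApex, groundCenter)
  apexIdx <- nrow(V) - 1L
  gcIdx <- nrow(V)
  for (k in seq_len(nT)) {
    k2 <- if (k == nT) 1L else k + 1L
    F <- rbind(F, c(apexIdx, innerOff + k2, innerOff + k),
               c(gcIdx, k, k2))
  }
  capsule <- TriangleMesh(V, orientFaces(V, F), name = "capsule")
  comps$capsule <- capsule
  th <- 2 * pi * (seq_len(nT) - 1) / nT
  colAt <- function(angle) which.min(pmin(abs(th - angle),
                                          2 * pi - abs(th - angle)))
  dorsalK <- colAt(0)
  heelK <- colAt(pi)
  latK <- colAt(pi / 2)
  outerCol <- function(k) seq(k, by = nT, length.out = nH)
  schema$dorsal_wall_line <- list(component = "capsule",
                                  idx = outerCol(dorsalK))
  schema$heel_wall_line <- list(component = "capsule",
                                idx = outerCol(heelK))
  schema$toe <- list(component = "capsule", idx = dorsalK)
  schema$capsule_top <- list(component = "capsule",
                             idx = (nH - 1L) * nT + dorsalK)
  schema$ground_ring <- list(component = "capsule", idx = seq_len(nT))
  schema$palmar_hoof_line <- list(component = "capsule",
                                  idx = which(cos(th) < -0.7))
  buttr <- function(sgn) {
    tgt <- pi - sgn * 0.45
    colAt(tgt)
  }
  schema$heel_buttress_medial <- list(component = "capsule",
                                      idx = buttr(-1))
  schema$heel_buttress_lateral <- list(component = "capsule",
                                       idx = buttr(1))
  schema$frog_apex <- list(component = "capsule", idx = apexIdx)
  midRows <- which(rep(hOut, each = nT) > 0.3 * H &
                   rep(hOut, each = nT) < 0.7 * H)
  schema$lateral_wall <- list(component = "capsule",
                              idx = intersect(midRows,
                                              which(sin(th)[((seq_len(nH * nT) - 1L) %% nT) + 1L] > 0.9)))
  schema$wall_band_outer <- list(component = "capsule", idx = midRows)
  schema$inner_surface <- list(component = "capsule",
                               idx = innerOff + seq_len(nHI * nT))
  attr(schema, "groundComponent") <- "capsule"

  ## skeleton -------------------------------------------------------------
  bones <- c("mc", "p1", "p2", "p3")
  skel <- Skeleton(
    boneIds = bones,
    parents = c(mc = NA_character_, p1 = "mc", p2 = "p1", p3 = "p2"),
    axes = setNames(rep(list(diag(3)), 4), bones),
    origins = list(mc = cMC, p1 = cP1, p2 = cP2, p3 = cP3),
    componentMap = c(MC2 = "mc", MC3 = "mc", MC4 = "mc",
                     P1 = "p1", PS_med = "p1", PS_lat = "p1",
                     P2 = "p2",
                     P3 = "p3", DS = "p3", capsule = "p3"),
    jointMap = c(MCP = "p1", PIP = "p2", DIP = "p3"),
    boneComponent = c(mc = "MC3", p1 = "P1", p2 = "P2", p3 = "P3"),
    jointSurface = jointSurface)

  list(model = LimbModel(comps, skel), schema = schema, truth = truth)
}

## --- population ----------------------------------------------------------

#' Synthetic population configuration
#'
#' Defaults define the study conditions the generator emulates: a few
#' smooth low-rank shape modes with millimetre-scale standard deviations,
#' per-joint flexion spread of an unloaded cadaver pose, global scale
#' spanning pony-to-horse around the reference, and an arbitrary world pose
#' per subject.
#'
#' @param nSubjects number of subjects.
#' @param nModes number of latent shape modes.
#' @param modeSd standard deviation (mm) per mode.
#' @param poseRange named half-ranges (radians) of the uniform per-joint
#'   flexion distribution.
#' @param scaleRange range of the uniform global scale factor.
#' @param noiseSd iid vertex noise, mm.
#' @param abductionSd sd (radians) of a small per-joint abduction remnant
#'   (rotation about the parent frame's x axis), also the mechanism that
#'   scatters the bone flexion axes in a cone for the spherical statistics.
#' @param worldPose give each subject a random rigid world pose.
#' @param remesh destroy vertex correspondence by resampling each subject
#'   surface, so correspondence must be re-established by registration.
#' @param seed integer; fixes all randomness.
#' @return list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nSubjects = 20, nModes = 3,
                            modeSd = c(1.5, 1.0, 0.7),
                            poseRange = c(MCP = 0.3, PIP = 0.3, DIP = 0.3),
                            scaleRange = c(0.9, 1.15), noiseSd = 0,
                            abductionSd = 0, worldPose = TRUE,
                            remesh = FALSE, seed = 1) {
  stopifnot(length(modeSd) == nModes, all(modeSd >= 0), noiseSd >= 0,
            all(is.finite(poseRange)))
  structure(list(nSubjects = nSubjects, nModes = nModes, modeSd = modeSd,
                 poseRange = poseRange, scaleRange = scaleRange,
                 noiseSd = noiseSd, abductionSd = abductionSd,
                 worldPose = worldPose, remesh = remesh, seed = seed),
            class = "syntheticConfig")
}

## smooth low-frequency displacement fields over the concatenated geometry,
## made orthogonal to every component's similarity-perturbation subspace
## (per-component translation, infinitesimal rotation, and scale moments)
## and zeroed on the joint-surface patches and the scale-reference
## (extreme metacarpal) vertices, then orthonormalized (QR). The
## constraints make shape strictly identifiable from pose and scale: a
## population built from such modes is inverted exactly by the
## normalization stage, so the latent subspace is recovered to numerical
## precision.
syntheticModes <- function(refModel, nModes) {
  comps <- refModel@components
  counts <- vapply(comps, nVertices, integer(1))
  offs <- c(0L, cumsum(counts))
  names(offs) <- c(names(comps), "end")
  nVert <- sum(counts)
  refGeom <- do.call(rbind, lapply(comps, function(m) m@vertices))

  ## vertices that must not move: joint-surface patches (articulation
  ## centers must stay analytic) and the root bone's extreme-y vertices
  ## (the scale reference length must stay exact)
  fixed <- integer(0)
  skel <- refModel@skeleton
  for (js in skel@jointSurface)
    fixed <- c(fixed, offs[[js$component]] + js$idx)
  root <- skel@boneIds[is.na(skel@parents)]
  rc <- skel@boneComponent[[root]]
  y <- comps[[rc]]@vertices %*% skel@axes[[root]][, 2]
  ext <- which(y > max(y) - 1e-9 | y < min(y) + 1e-9)
  fixed <- unique(c(fixed, offs[[rc]] + ext))
  fixedRows <- as.vector(vapply(fixed, function(p) 3L * (p - 1L) + 1:3,
                                integer(3)))

  ## per-component similarity moment constraints (7 columns each), with
  ## the fixed rows zeroed so projecting against them cannot reintroduce
  ## displacement there
  C <- matrix(0, 3L * nVert, 7L * length(comps))
  for (ci in seq_along(comps)) {
    rows <- as.vector(vapply((offs[ci] + 1L):offs[ci + 1L],
                             function(p) 3L * (p - 1L) + 1:3, integer(3)))
    Vc <- sweep(comps[[ci]]@vertices, 2, colMeans(comps[[ci]]@vertices))
    n <- nrow(Vc)
    block <- matrix(0, 3L * n, 7)
    block[seq(1, 3 * n, 3), 1] <- 1
    block[seq(2, 3 * n, 3), 2] <- 1
    block[seq(3, 3 * n, 3), 3] <- 1
    rot <- function(k) {
      e <- diag(3)[, k]
      as.vector(t(t(apply(Vc, 1, function(v) crossProduct3(e, v)))))
    }
    block[, 4] <- rot(1)
    block[, 5] <- rot(2)
    block[, 6] <- rot(3)
    block[, 7] <- as.vector(t(Vc))
    C[rows, 7L * (ci - 1L) + 1:7] <- block
  }
  C[fixedRows, ] <- 0
  Cq <- qr.Q(qr(C))

  ## modes displace along the vertex normals (surface offsets): shape
  ## variation of this kind is what dense surface registration can
  ## actually observe, whereas a tangential re-parameterization of the
  ## same surface is invisible to it
  normals <- do.call(rbind, lapply(comps, meshVertexNormals))
  M <- matrix(0, 3L * nVert, nModes)
  for (k in seq_len(nModes)) {
    amp <- numeric(nVert)
    for (w in 1:3) {
      wave <- normalize3(rnorm(3))
      lambda <- runif(1, 60, 150)
      phase <- runif(1, 0, 2 * pi)
      amp <- amp + as.numeric(sin(refGeom %*% wave * (2 * pi / lambda) +
                                  phase))
    }
    M[, k] <- as.vector(t(normals * amp))
  }
  M[fixedRows, ] <- 0
  M <- M - Cq %*% crossprod(Cq, M)
  qrd <- qr(M)
  Q <- qr.Q(qrd)
  sgn <- sign(diag(qr.R(qrd)))
  sgn[sgn == 0] <- 1
  Q %*% diag(sgn, nModes)
}

randomRotation <- function(maxAngle) {
  axisAngleTransform(normalize3(rnorm(3)), c(0, 0, 0),
                     runif(1, -maxAngle, maxAngle))
}

## 1-to-3 centroid face split plus vertex permutation: same surface, new
## topology, correspondence destroyed
remeshMesh <- function(mesh) {
  V <- mesh@vertices
  F <- mesh@faces
  cent <- (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
  V2 <- rbind(V, cent)
  cIdx <- nrow(V) + seq_len(nrow(F))
  F2 <- rbind(cbind(F[, 1], F[, 2], cIdx),
              cbind(F[, 2], F[, 3], cIdx),
              cbind(F[, 3], F[, 1], cIdx))
  perm <- sample(nrow(V2))
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  TriangleMesh(V2[perm, , drop = FALSE],
               matrix(inv[F2], ncol = 3), name = mesh@name)
}

#' Generate a synthetic population of articulated limbs
#'
#' Each subject is built as: reference geometry + low-rank smooth shape
#' deformation + optional vertex noise, uniformly scaled, optionally given
#' an abduction remnant, articulated with per-joint flexion angles, and
#' placed at a random world pose. All draws come from the config seed, so
#' identical configs give bit-identical populations.
#'
#' @param ref result of [generateReferenceLimb()] (or a [LimbModel-class]).
#' @param config a [syntheticConfig()].
#' @return list: `models` (list of [LimbModel-class]), `truth` (list with
#'   `weights` (subjects x modes), `scales`, `angles` (subjects x joints,
#'   radians), `modes` (orthonormal columns over the geometry block),
#'   `modeSd`, `config`).
#' @export
generatePopulation <- function(ref, config = syntheticConfig()) {
  refModel <- if (is(ref, "LimbModel")) ref else ref$model
  set.seed(config$seed)
  compNames <- names(refModel@components)
  counts <- vapply(refModel@components, nVertices, integer(1))
  refGeom <- do.call(rbind, lapply(refModel@components,
                                   function(m) m@vertices))
  modes <- if (config$nModes > 0)
    syntheticModes(refModel, config$nModes)
  else matrix(0, 3L * nrow(refGeom), 0)

  joints <- names(refModel@skeleton@jointMap)
  L <- config$nSubjects
  W <- matrix(rnorm(L * config$nModes), L, config$nModes)
  scales <- runif(L, config$scaleRange[1], config$scaleRange[2])
  angles <- matrix(0, L, length(joints), dimnames = list(NULL, joints))
  for (j in joints) {
    half <- if (j %in% names(config$poseRange)) config$poseRange[[j]]
            else 0
    angles[, j] <- runif(L, -half, half)
  }

  models <- vector("list", L)
  for (i in seq_len(L)) {
    geom <- refGeom
    if (config$nModes > 0) {
      ## modes have unit norm over the whole stacked geometry; rescale so
      ## modeSd is the per-vertex RMS displacement in mm
      amp <- W[i, ] * config$modeSd * sqrt(nrow(refGeom))
      geom <- geom + matrix(as.numeric(modes %*% amp), ncol = 3,
                            byrow = TRUE)
    }
    if (config$noiseSd > 0)
      geom <- geom + matrix(rnorm(length(geom), sd = config$noiseSd),
                            ncol = 3)
    model <- refModel
    off <- 0L
    for (nm in compNames) {
      n <- counts[[nm]]
      model@components[[nm]]@vertices <-
        geom[(off + 1L):(off + n), , drop = FALSE] * scales[i]
      off <- off + n
    }
    skel <- model@skeleton
    for (b in skel@boneIds)
      skel@origins[[b]] <- skel@origins[[b]] * scales[i]
    model@skeleton <- skel
    if (config$abductionSd > 0) {
      for (b in boneOrder(skel)) {
        p <- model@skeleton@parents[[b]]
        if (is.na(p)) next
        ang <- rnorm(1, sd = config$abductionSd)
        Tp <- boneTransform(model@skeleton, p)
        A <- axisAngleTransform(Tp[1:3, 1], Tp[1:3, 4], ang)
        moved <- boneDescendants(model@skeleton, b)
        for (nm in compNames[model@skeleton@componentMap[compNames]
                             %in% moved])
          model@components[[nm]] <- applyTransform(model@components[[nm]],
                                                   A)
        model@skeleton <- transformSkeleton(model@skeleton, A,
                                            bones = moved)
      }
    }
    model <- articulate(model, angles[i, ])
    if (config$worldPose) {
      Tw <- randomRotation(0.5)
      Tw[1:3, 4] <- runif(3, -50, 50)
      model <- applyTransform(model, Tw)
    }
    if (config$remesh)
      model@components <- lapply(model@components, remeshMesh)
    models[[i]] <- model
  }
  list(models = models,
       truth = list(weights = W, scales = scales, angles = angles,
                    modes = modes, modeSd = config$modeSd,
                    config = config))
}
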