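## Shared fixtures, all built in code.

refCache <- new.env(parent = emptyenv())

## the synthetic reference limb is expensive enough to build once per run
refFixture <- function(detail = 0.6) {
  key <- sprintf("d%.2f", detail)
  if (is.null(refCache[[key]]))
    refCache[[key]] <- generateReferenceLimb(detail = detail)
  refCache[[key]]
}

popCache <- new.env(parent = emptyenv())

## small exactly-invertible population (no remesh) shared across tests
popFixture <- function() {
  if (is.null(popCache$pop)) {
    ref <- refFixture()
    cfg <- syntheticConfig(nSubjects = 10, seed = 42)
    pop <- generatePopulation(ref, cfg)
    cs <- artiSSM:::directCorrespondences(ref$model, pop$models)
    norm <- normalizeSubjects(cs, ref$model)
    popCache$pop <- list(ref = ref, cfg = cfg, pop = pop, cs = cs,
                         norm = norm,
                         ssm = buildSSM(norm, reference = ref$model))
  }
  popCache$pop
}

## plain UV sphere (no asymmetry texture), outward-oriented and watertight
uvSphere <- function(radius = 1, center = c(0, 0, 0), nU = 24, nV = 16) {
  phis <- pi * seq_len(nV - 1) / nV
  th <- 2 * pi * (seq_len(nU) - 1) / nU
  V <- rbind(center + c(0, radius, 0), center - c(0, radius, 0))
  for (phi in phis)
    V <- rbind(V, cbind(center[1] + radius * sin(phi) * cos(th),
                        center[2] + radius * cos(phi),
                        center[3] + radius * sin(phi) * sin(th)))
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
  m <- TriangleMesh(V, F, name = "sphere")
  if (meshVolume(m) < 0) m@faces <- m@faces[, c(1, 3, 2)]
  m
}

tetraMesh <- function() {
  TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)),
               name = "tet")
}

## random right-handed orthonormal frame
randomFrame <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

## random rigid 4x4
randomRigid <- function(maxTrans = 50) {
  rigidTransform(randomFrame(), runif(3, -maxTrans, maxTrans))
}
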