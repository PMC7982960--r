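test_that("transforms act as homogeneous products and compose associatively", {
  m <- tetraMesh()
  expect_equal(applyTransform(m, diag(4))@vertices, m@vertices)
  t1 <- rigidTransform(diag(3), c(1, 2, 3))
  moved <- applyTransform(matrix(c(0, 0, 0), 1, 3), t1)
  expect_equal(as.numeric(moved), c(1, 2, 3))
  set.seed(7)
  for (i in 1:20) {
    ta <- randomRigid(); tb <- randomRigid()
    one <- applyTransform(applyTransform(m, ta), tb)
    two <- applyTransform(m, tb %*% ta)
    expect_lt(max(abs(one@vertices - two@vertices)), 1e-9)
  }
})

test_that("transform validation catches broken matrices", {
  T <- rigidTransform(rotZ3(0.3), c(1, 1, 1))
  expect_true(validateTransform(T))
  Tbad <- T; Tbad[4, 1] <- 0.1
  expect_error(validateTransform(Tbad), "last row")
  Tscale <- rigidTransform(diag(3), scale = 2)
  expect_error(validateTransform(Tscale), "scale")
  expect_true(validateTransform(Tscale, allowScale = TRUE))
})

test_that("mirroring is an involution and preserves signed volume", {
  s <- uvSphere(radius = 5, center = c(2, 1, 0))
  n <- c(1, 0, 0)
  m1 <- mirrorMesh(s, n)
  expect_equal(mirrorMesh(m1, n)@vertices, s@vertices, tolerance = 1e-12)
  expect_equal(as.numeric(mirrorMesh(
    TriangleMesh(rbind(c(1, 0, 0), diag(3) * 0.1 + 1), rbind(1:3, c(1, 2, 4))),
    n)@vertices[1, ]), c(-1, 0, 0))
  ## divergence-theorem volume oracle: winding flip keeps orientation
  expect_equal(meshVolume(m1), meshVolume(s), tolerance = 1e-9)
  expect_gt(meshVolume(m1), 0)
})

test_that("mirroring a limb keeps frames right-handed with z = x cross y", {
  ref <- refFixture()
  mir <- mirrorLimb(ref$model, c(0, 0, 1))
  for (b in mir@skeleton@boneIds) {
    A <- mir@skeleton@axes[[b]]
    expect_lt(max(abs(crossprod(A) - diag(3))), 1e-9)
    expect_equal(det(A), 1, tolerance = 1e-9)
  }
  expect_error(mirrorLimb(ref$model, c(0, 0, 2)), "unit")
  back <- mirrorLimb(mir, c(0, 0, 1))
  expect_lt(max(abs(back@components$P3@vertices -
                    ref$model@components$P3@vertices)), 1e-9)
})

test_that("signed distance is zero on itself and signed by containment", {
  s <- uvSphere(radius = 2)
  self <- signedGeometricError(s, s)
  expect_true(all(self$distance == 0))

  inner <- uvSphere(radius = 1)
  ge <- signedGeometricError(inner, s)
  ## analytic distance 1, minus mesh chord error of the coarse target
  chord <- 1 - cos(pi / 16)  # max sagitta of target facets (radius 2)
  expect_true(all(ge$distance < 0))
  expect_lt(max(abs(ge$distance + 1)), 2 * 2 * chord + 0.02)

  ge2 <- signedGeometricError(s, inner)
  expect_true(all(ge2$distance > 0))
  expect_lt(max(abs(ge2$distance - 1)), 2 * chord + 0.02)
})

test_that("uniform shrink/inflate of a closed target flips all signs", {
  s <- uvSphere(radius = 3, center = c(1, -2, 0.5), nU = 16, nV = 10)
  shrink <- s
  shrink@vertices <- sweep(sweep(s@vertices, 2, c(1, -2, 0.5)) * 0.99,
                           2, c(1, -2, 0.5), "+")
  expect_true(all(signedGeometricError(shrink, s)$distance < 0))
  inflate <- s
  inflate@vertices <- sweep(sweep(s@vertices, 2, c(1, -2, 0.5)) * 1.01,
                            2, c(1, -2, 0.5), "+")
  expect_true(all(signedGeometricError(inflate, s)$distance > 0))
})

test_that("open targets fall back to unsigned distances with a warning", {
  s <- uvSphere(radius = 2)
  open <- TriangleMesh(s@vertices, s@faces[-(1:5), ], name = "open")
  expect_warning(ge <- signedGeometricError(uvSphere(radius = 1), open),
                 "watertight")
  expect_true(ge$unsignedFallback)
  expect_true(all(ge$distance >= 0))
})

test_that("vertex normals of a sphere point radially outward", {
  s <- uvSphere(radius = 2, nU = 20, nV = 14)
  N <- meshVertexNormals(s)
  radial <- s@vertices / 2
  expect_gt(min(rowSums(N * radial)), 0.97)
})

test_that("error CSV emits one row per vertex", {
  s <- uvSphere(radius = 1, nU = 8, nV = 6)
  ge <- signedGeometricError(s, s)
  path <- tempfile(fileext = ".csv")
  writeErrorCSV(ge, path)
  df <- read.csv(path)
  expect_identical(names(df), c("vertex_index", "signed_distance"))
  expect_equal(nrow(df), nVertices(s))
})
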