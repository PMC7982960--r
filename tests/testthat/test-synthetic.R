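test_that("the reference limb has the expected articulated structure", {
  ref <- refFixture()
  expect_equal(length(ref$model@components), 10L)
  expect_equal(length(ref$model@skeleton@boneIds), 4L)
  expect_identical(names(ref$model@skeleton@jointMap),
                   c("MCP", "PIP", "DIP"))
  expect_true(validObject(ref$model))
})

test_that("joint-surface patches lie on their analytic cylinders", {
  ref <- refFixture()
  skel <- ref$model@skeleton
  for (b in skel@boneIds) {
    js <- skel@jointSurface[[b]]
    pts <- ref$model@components[[js$component]]@vertices[js$idx, ]
    fit <- fitJointCircle(pts, skel@axes[[b]][, 3])
    truth <- ref$truth$circles[[b]]
    expect_lt(abs(fit$radius - truth$radius) / truth$radius, 0.01)
    expect_lt(max(abs(fit$center - truth$center)), 0.05)
  }
})

test_that("the capsule encodes the configured wall angles", {
  custom <- generateReferenceLimb(detail = 0.5, toeAngle = 58,
                                  heelAngle = 40)
  expect_equal(computeBiometric(custom$model, custom$schema, "TA"), 58,
               tolerance = 0.5)
  expect_equal(computeBiometric(custom$model, custom$schema, "HA"), 40,
               tolerance = 0.5)
})

test_that("populations are bit-identical under a fixed config", {
  ref <- refFixture()
  cfg <- syntheticConfig(nSubjects = 3, seed = 77)
  a <- generatePopulation(ref, cfg)
  b <- generatePopulation(ref, cfg)
  expect_identical(a$truth$weights, b$truth$weights)
  expect_identical(a$models[[2]]@components$P3@vertices,
                   b$models[[2]]@components$P3@vertices)
})

test_that("latent modes are orthonormal and identifiable from pose", {
  ref <- refFixture()
  pop <- generatePopulation(ref, syntheticConfig(nSubjects = 2, seed = 5))
  M <- pop$truth$modes
  expect_lt(max(abs(crossprod(M) - diag(ncol(M)))), 1e-9)
  ## modes vanish on the joint-surface patches (articulation centers stay
  ## analytic)
  skel <- ref$model@skeleton
  counts <- vapply(ref$model@components, nVertices, integer(1))
  offs <- c(0, cumsum(counts)); names(offs) <- c(names(counts), "end")
  js <- skel@jointSurface$p1
  rows <- as.vector(sapply(offs[[js$component]] + js$idx,
                           function(p) 3 * (p - 1) + 1:3))
  expect_lt(max(abs(M[rows, ])), 1e-9)
})

test_that("a degenerate config reproduces the reference for all subjects", {
  ref <- refFixture()
  cfg <- syntheticConfig(nSubjects = 2, nModes = 0, modeSd = numeric(0),
                         poseRange = c(MCP = 0, PIP = 0, DIP = 0),
                         scaleRange = c(1, 1), worldPose = FALSE, seed = 1)
  pop <- generatePopulation(ref, cfg)
  for (i in 1:2)
    expect_equal(pop$models[[i]]@components$capsule@vertices,
                 ref$model@components$capsule@vertices, tolerance = 1e-12)
})

test_that("remeshing destroys vertex correspondence but keeps the surface", {
  ref <- refFixture()
  cfg <- syntheticConfig(nSubjects = 1, remesh = TRUE, seed = 9,
                         worldPose = FALSE)
  pop <- generatePopulation(ref, cfg)
  m <- pop$models[[1]]@components$P2
  expect_gt(nVertices(m), nVertices(ref$model@components$P2))
  expect_true(validObject(m))
})

test_that("axis perturbations scatter bone axes inside the cone", {
  ref <- refFixture()
  cfg <- syntheticConfig(nSubjects = 6, nModes = 0, modeSd = numeric(0),
                         poseRange = c(MCP = 0, PIP = 0, DIP = 0),
                         scaleRange = c(1, 1), worldPose = FALSE,
                         abductionSd = 0.05, seed = 31)
  pop <- generatePopulation(ref, cfg)
  angles <- sapply(pop$models, function(m)
    acos(min(1, sum(m@skeleton@axes[["p3"]][, 3] *
                    ref$model@skeleton@axes[["p3"]][, 3]))))
  expect_gt(max(angles), 0.01)
  expect_lt(max(angles), 0.05 * 3 * sqrt(3))
})
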