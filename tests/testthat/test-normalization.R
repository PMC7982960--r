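test_that("scale normalization inverts a known global scale exactly", {
  ref <- refFixture()
  sn <- scaleNormalize(ref$model, ref$model)
  expect_equal(sn$factor, 1)
  scaled <- artiSSM:::scaleModel(ref$model, 1.37)
  sn2 <- scaleNormalize(scaled, ref$model)
  expect_equal(sn2$factor, 1 / 1.37, tolerance = 1e-12)
  expect_lt(max(abs(sn2$model@components$MC3@vertices -
                    ref$model@components$MC3@vertices)), 1e-9)
})

test_that("the scale factor is invariant to the subject's world pose", {
  ref <- refFixture()
  scaled <- artiSSM:::scaleModel(ref$model, 1.2)
  set.seed(4)
  for (i in 1:5) {
    moved <- applyTransform(scaled, randomRigid())
    expect_equal(scaleNormalize(moved, ref$model)$factor, 1 / 1.2,
                 tolerance = 1e-9)
  }
})

test_that("the closed-form optimal flexion matches a grid search", {
  a <- matrix(rnorm(60), ncol = 3)
  expect_equal(optimalFlexion(a, a), 0)
  b <- a %*% t(rotZ3(-0.25))
  expect_equal(optimalFlexion(a, b), 0.25, tolerance = 1e-9)

  resid <- function(theta, a, b) sum((a - b %*% t(rotZ3(theta)))^2)
  set.seed(8)
  for (i in 1:100) {
    a <- matrix(rnorm(45, sd = 10), ncol = 3)
    b <- matrix(rnorm(45, sd = 10), ncol = 3)
    th <- optimalFlexion(a, b)
    grid <- seq(-pi + 1e-4, pi, by = 1e-4)
    gmin <- min(vapply(grid, resid, numeric(1), a = a, b = b))
    expect_lte(resid(th, a, b), gmin + 1e-9)
  }
  onAxis <- cbind(0, 0, 1:5)
  expect_error(optimalFlexion(onAxis, onAxis), "undefined")
})

test_that("pose normalization recovers injected flexion angles and scale", {
  ref <- refFixture()
  cfg <- syntheticConfig(nSubjects = 3, seed = 21)
  pop <- generatePopulation(ref, cfg)
  cs <- artiSSM:::directCorrespondences(ref$model, pop$models)
  norm <- normalizeSubjects(cs, ref$model)
  for (i in 1:3) {
    expect_equal(norm[[i]]@scale, 1 / pop$truth$scales[i],
                 tolerance = 1e-9)
    expect_lt(max(abs(norm[[i]]@theta[colnames(pop$truth$angles)] +
                      pop$truth$angles[i, ])), 1e-3)
  }
})

test_that("pose normalization is idempotent", {
  ref <- refFixture()
  sub <- articulate(ref$model, c(MCP = 0.2, PIP = -0.1, DIP = 0.3))
  n1 <- poseNormalize(sub, ref$model)
  expect_lt(max(abs(n1@model@components$capsule@vertices -
                    ref$model@components$capsule@vertices)), 1e-6)
  n2 <- poseNormalize(n1@model, ref$model)
  expect_lt(max(abs(n2@theta)), 1e-9)
  expect_lt(max(abs(n2@model@components$capsule@vertices -
                    n1@model@components$capsule@vertices)), 1e-6)
})

test_that("abduction remnant is preserved, not removed", {
  ref <- refFixture()
  skel <- ref$model@skeleton
  ## inject 0.05 rad abduction at the MCP (rotation about parent x axis)
  Tmc <- boneTransform(skel, "mc")
  A <- axisAngleTransform(Tmc[1:3, 1], Tmc[1:3, 4], 0.05)
  sub <- ref$model
  moved <- artiSSM:::boneDescendants(skel, "p1")
  for (nm in names(skel@componentMap)[skel@componentMap %in% moved])
    sub@components[[nm]] <- applyTransform(sub@components[[nm]], A)
  sub@skeleton <- artiSSM:::transformSkeleton(sub@skeleton, A, bones = moved)
  sub <- articulate(sub, c(MCP = 0.25))
  norm <- poseNormalize(sub, ref$model)
  ang <- sphericalAngles(norm@model@skeleton@axes[["p1"]],
                         norm@model@skeleton@axes[["mc"]])
  expect_equal(unname(ang["beta"]), 0.05, tolerance = 1e-3)
  expect_lt(abs(ang["alpha"]), 0.02)
})

test_that("scale and pose normalization commute", {
  ref <- refFixture()
  sub <- articulate(artiSSM:::scaleModel(ref$model, 1.25),
                    c(MCP = 0.15, PIP = 0.1, DIP = -0.2))
  a <- poseNormalize(scaleNormalize(sub, ref$model)$model, ref$model)
  sn <- scaleNormalize(poseNormalize(sub, ref$model)@model, ref$model)
  expect_lt(max(abs(a@model@components$P2@vertices -
                    sn$model@components$P2@vertices)), 1e-6)
})

test_that("normalization manifest records factor and angles", {
  ref <- refFixture()
  sub <- articulate(ref$model, c(MCP = 0.2))
  n <- poseNormalize(sub, ref$model, scaleFactor = 0.9)
  path <- tempfile(fileext = ".json")
  writeNormalizationManifest(list(n), path, ids = "s1")
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rec$scale, 0.9)
  expect_equal(rec$theta$MCP, -0.2, tolerance = 1e-6)
})
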