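test_that("sphere log/exp are mutually inverse and well conditioned", {
  mu <- c(0, 0, 1)
  expect_equal(sphereLog(mu, mu), c(0, 0, 0))
  t <- sphereLog(c(1, 0, 0), mu)
  expect_equal(sqrt(sum(t^2)), pi / 2, tolerance = 1e-12)
  expect_equal(t / sqrt(sum(t^2)), c(1, 0, 0), tolerance = 1e-12)
  set.seed(13)
  worst <- 0
  for (i in 1:1000) {
    v <- artiSSM:::normalize3(rnorm(3))
    m <- artiSSM:::normalize3(rnorm(3))
    if (sum(v * m) < -0.999) next
    worst <- max(worst, max(abs(sphereExp(sphereLog(v, m), m) - v)))
  }
  expect_lt(worst, 1e-12)
  expect_error(sphereLog(c(0, 0, -1), mu), "antipodal")
  expect_error(sphereLog(c(0, 0, 2), mu), "unit")
})

test_that("the intrinsic mean solves symmetry and simulation cases", {
  v <- artiSSM:::normalize3(c(1, 2, 3))
  expect_equal(as.numeric(intrinsicMean(rbind(v, v, v))), v,
               tolerance = 1e-12)
  a <- sphereExp(c(0.4, 0, 0), c(0, 0, 1))
  b <- sphereExp(c(-0.4, 0, 0), c(0, 0, 1))
  expect_equal(as.numeric(intrinsicMean(rbind(a, b))), c(0, 0, 1),
               tolerance = 1e-9)
  ## 500 draws in a 1-degree cone around a known axis
  set.seed(17)
  axis <- artiSSM:::normalize3(c(1, -1, 2))
  e1 <- artiSSM:::normalize3(artiSSM:::crossProduct3(axis, c(0, 0, 1)))
  e2 <- artiSSM:::crossProduct3(axis, e1)
  vs <- t(replicate(500, {
    t <- rnorm(2, sd = pi / 180)
    sphereExp(t[1] * e1 + t[2] * e2, axis)
  }))
  mu <- intrinsicMean(vs)
  err <- acos(min(1, sum(mu * axis)))
  expect_lt(err, (2 * pi / 180) / sqrt(500))
})

test_that("shape vectors assemble and disassemble losslessly", {
  ref <- refFixture()
  layout <- shapeLayout(ref$model)
  counts <- vapply(ref$model@components, nVertices, integer(1))
  expect_equal(layout$length, 3 * (sum(counts) + 2 * 4))
  mus <- lapply(ref$model@skeleton@axes, function(a) a[, 3])
  s <- assembleShapeVector(ref$model, mus, layout)
  expect_equal(length(s), layout$length)
  ## axis blocks at the intrinsic mean are exactly zero
  expect_true(all(s[(layout$geomLength + 1):(layout$geomLength + 12)] == 0))
  back <- disassembleShapeVector(s, ref$model, mus, layout)
  expect_lt(max(abs(back@components$P3@vertices -
                    ref$model@components$P3@vertices)), 1e-12)
  s2 <- assembleShapeVector(back, mus, layout)
  expect_lt(max(abs(s2 - s)), 1e-12)
  expect_error(disassembleShapeVector(s[-1], ref$model, mus, layout),
               "layout error")
})

test_that("Gram-matrix PCA matches a dense covariance eigensolver", {
  set.seed(23)
  X <- matrix(rnorm(50 * 10), 50, 10) + 5 * tcrossprod(rnorm(50), rnorm(10))
  p <- shapePCA(X)
  C <- cov(t(X))
  eg <- eigen(C, symmetric = TRUE)
  K <- 9
  expect_lt(max(abs(p$sigma^2 - eg$values[1:K]) /
                pmax(eg$values[1:K], 1e-12)), 1e-8)
  for (i in 1:K) {
    dot <- abs(sum(p$modes[, i] * eg$vectors[, i]))
    expect_gt(dot, 1 - 1e-8)
  }
  expect_lt(max(abs(crossprod(p$modes) - diag(K))), 1e-9)
})

test_that("degenerate populations yield zero variance and exact means", {
  s <- rnorm(30)
  X <- matrix(s, 30, 5)
  p <- shapePCA(X)
  expect_true(all(p$sigma == 0))
  expect_equal(p$mean, s)
  expect_lt(max(abs(crossprod(p$modes) - diag(4))), 1e-9)
})

test_that("a noise-free low-rank population has a clean spectrum", {
  fix <- popFixture()
  ssm <- fix$ssm
  expect_lt(ssm@sigma[4], 1e-8 * ssm@sigma[1])
  expect_true(all(diff(ssm@sigma) <= 1e-12))
})

test_that("synthesize and fit are mutually inverse on retained modes", {
  fix <- popFixture()
  ssm <- fix$ssm
  expect_equal(synthesize(ssm, numeric(0)), ssm@mean)
  s1 <- synthesize(ssm, c(1))
  expect_equal(sqrt(sum((s1 - ssm@mean)^2)), ssm@sigma[1],
               tolerance = 1e-9)
  b <- numeric(numModes(ssm)); b[3] <- 2
  sfit <- suppressWarnings(fitShape(ssm, synthesize(ssm, b)))
  ## identity on the numerically conditioned modes (weights of modes with
  ## sigma ~ 1e-8 sigma_1 divide float rounding by a near-zero sd)
  cond <- ssm@sigma > 1e-6 * ssm@sigma[1]
  expect_lt(max(abs(sfit[cond] - b[cond])), 1e-9)
  ## and exact as a reconstruction identity over all modes
  expect_lt(sqrt(mean((synthesize(ssm, sfit) - synthesize(ssm, b))^2)),
            1e-9)
  expect_equal(suppressWarnings(fitShape(ssm, ssm@mean)),
               numeric(numModes(ssm)))
  ## every training shape lies in the span of the modes
  for (l in c(1, 5, 10)) {
    bl <- suppressWarnings(fitShape(ssm, ssm@training[, l]))
    rec <- synthesize(ssm, bl)
    expect_lt(sqrt(mean((rec - ssm@training[, l])^2)), 1e-9)
  }
})

test_that("sampling is seeded and matches the prescribed distribution", {
  fix <- popFixture()
  ssm <- fix$ssm
  a <- sampleInstances(ssm, 5, seed = 99)
  b <- sampleInstances(ssm, 5, seed = 99)
  expect_identical(a$weights, b$weights)
  expect_identical(a$vectors, b$vectors)
  ## micro-model: mode-coefficient variance approaches sigma_i^2
  set.seed(31)
  Xs <- matrix(rnorm(40 * 8), 40, 8)
  micro <- buildSSM(Xs, reference = fix$ref$model,
                    mus = lapply(fix$ref$model@skeleton@axes,
                                 function(a) a[, 3]),
                    layout = list(components = c(x = 12L), bones = "mc",
                                  geomLength = 36L, length = 40L))
  sm <- sampleInstances(micro, 10000, seed = 7)
  for (i in 1:3) {
    coef <- crossprod(micro@modes[, i], sm$vectors - micro@mean)
    expect_lt(abs(var(as.numeric(coef)) / micro@sigma[i]^2 - 1), 0.05)
  }
})

test_that("posed reconstruction commutes with articulation", {
  fix <- popFixture()
  ssm <- fix$ssm
  mean0 <- reconstructPosed(ssm, numeric(0))
  expect_lt(max(abs(assembleShapeVector(mean0, ssm@mus, ssm@layout) -
                    ssm@mean)), 1e-9)
  ## continuity in the joint angles
  small <- reconstructPosed(ssm, numeric(0), c(MCP = 1e-8))
  expect_lt(max(abs(small@components$capsule@vertices -
                    mean0@components$capsule@vertices)), 1e-5)
  ## training subject: posed reconstruction equals articulated subject
  b <- suppressWarnings(fitShape(ssm, ssm@training[, 2]))
  ang <- c(MCP = 0.2, PIP = -0.15, DIP = 0.1)
  posed <- reconstructPosed(ssm, b, ang)
  direct <- articulate(disassembleShapeVector(ssm@training[, 2],
                                              ssm@reference, ssm@mus,
                                              ssm@layout), ang)
  expect_lt(max(abs(posed@components$capsule@vertices -
                    direct@components$capsule@vertices)), 1e-6)
})

test_that("SSM archives round trip through the plain-text format", {
  fix <- popFixture()
  dir <- file.path(tempdir(), "ssm-archive")
  writeSSM(fix$ssm, dir)
  back <- readSSM(dir)
  expect_equal(back@mean, fix$ssm@mean, tolerance = 1e-10)
  expect_equal(back@sigma, fix$ssm@sigma, tolerance = 1e-10)
  expect_lt(max(abs(back@modes - fix$ssm@modes)), 1e-10)
  expect_equal(back@layout, fix$ssm@layout)
  expect_equal(back@mus, fix$ssm@mus, tolerance = 1e-12)
  expect_identical(back@reference@skeleton@parents,
                   fix$ssm@reference@skeleton@parents)
})
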