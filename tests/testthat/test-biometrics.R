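test_that("biometrics hit their analytic construction values", {
  ref <- refFixture()
  m <- ref$model; s <- ref$schema
  expect_equal(computeBiometric(m, s, "TA"), ref$truth$toeAngle,
               tolerance = 0.5)
  expect_equal(computeBiometric(m, s, "HA"), ref$truth$heelAngle,
               tolerance = 0.5)
  expect_equal(computeBiometric(m, s, "UR"),
               computeBiometric(m, s, "HA") - computeBiometric(m, s, "TA"),
               tolerance = 1e-12)
  expect_equal(computeBiometric(m, s, "CD"),
               computeBiometric(m, s, "CA") - computeBiometric(m, s, "TA"),
               tolerance = 1e-12)
  expect_equal(computeBiometric(m, s, "CR"),
               ref$truth$circles$mc$radius, tolerance = 0.01)
  expect_equal(computeBiometric(m, s, "CR_P1"),
               ref$truth$circles$p1$radius, tolerance = 0.01)
  expect_equal(computeBiometric(m, s, "PA"), ref$truth$palmarAngle,
               tolerance = 0.5)
  ## every built-in biometric evaluates to a finite scalar
  for (id in biometricIds())
    expect_true(is.finite(computeBiometric(m, s, id)), info = id)
})

test_that("lengths scale linearly and angles are similarity invariant", {
  ref <- refFixture()
  m <- ref$model; s <- ref$schema
  lengths <- c("FL", "FW", "HW", "SL", "TL", "WT", "CR", "MW", "SH",
               "PL_P1", "CR_P2")
  angles <- c("HA", "TA", "CA", "PA", "SA")
  scaled <- artiSSM:::scaleModel(m, 2)
  moved <- applyTransform(m, rigidTransform(rotZ3(0.4) %*% rotX3(0.2),
                                            c(25, -10, 5)))
  for (id in lengths) {
    expect_equal(computeBiometric(scaled, s, id),
                 2 * computeBiometric(m, s, id), tolerance = 1e-6,
                 info = id)
  }
  for (id in angles) {
    expect_equal(computeBiometric(scaled, s, id),
                 computeBiometric(m, s, id), tolerance = 1e-6, info = id)
    expect_equal(computeBiometric(moved, s, id),
                 computeBiometric(m, s, id), tolerance = 1e-6, info = id)
  }
})

test_that("missing landmarks raise errors naming biometric and landmark", {
  ref <- refFixture()
  s <- ref$schema
  s$frog_apex <- NULL
  expect_error(computeBiometric(ref$model, s, "FL"),
               "FL.*frog_apex")
})

test_that("regression recovers an affine functional of the weights exactly", {
  fix <- popFixture()
  ssm <- fix$ssm
  w <- rnorm(length(ssm@mean), sd = 1 / sqrt(length(ssm@mean)))
  set.seed(2); w <- rnorm(length(ssm@mean)); w <- w / sqrt(sum(w^2))
  linear <- function(model, s) 10 + sum(w * (s - meanShape(ssm)))
  reg <- fitBiometricRegression(ssm, fix$ref$schema, linear, n = 200,
                                seed = 5)
  reg2 <- fitBiometricRegression(ssm, fix$ref$schema, linear, n = 200,
                                 seed = 5)
  expect_identical(reg$beta, reg2$beta)
  ## exact recomputation across the whole +-3 sigma range
  ci <- biometricCI(ssm, fix$ref$schema, reg, linear, grid = 11)
  expect_lt(max(abs(c(ci$min, ci$max))), 1e-6)
  ## b(k) presets are symmetric about the center
  b1 <- instanceFromBiometric(reg, reg$muK - 3 * reg$sdK)
  b2 <- instanceFromBiometric(reg, reg$muK + 3 * reg$sdK)
  b0 <- instanceFromBiometric(reg, reg$muK)
  expect_equal(b1 + b2, 2 * b0, tolerance = 1e-9)
})

test_that("a quadratic biometric yields a strictly wider interval", {
  fix <- popFixture()
  ssm <- fix$ssm
  u <- ssm@modes[, 1]
  linear <- function(model, s) sum(u * (s - meanShape(ssm)))
  quadratic <- function(model, s) {
    x <- sum(u * (s - meanShape(ssm)))
    x + 0.05 * x^2
  }
  regL <- fitBiometricRegression(ssm, fix$ref$schema, linear, n = 150,
                                 seed = 3)
  regQ <- fitBiometricRegression(ssm, fix$ref$schema, quadratic, n = 150,
                                 seed = 3)
  ciL <- biometricCI(ssm, fix$ref$schema, regL, linear, grid = 9)
  ciQ <- biometricCI(ssm, fix$ref$schema, regQ, quadratic, grid = 9)
  expect_gt(ciQ$max - ciQ$min, 10 * (ciL$max - ciL$min))
  ## the interval brackets zero when the grid passes through the center
  expect_lte(ciQ$min, 0)
  expect_gte(ciQ$max, 0)
})

test_that("the correlation table is symmetric with unit diagonal", {
  fix <- popFixture()
  ssm <- fix$ssm
  ids <- c("TA", "HA", "UR", "FW")
  C <- correlationTable(ssm, fix$ref$schema, ids, n = 40, seed = 9)
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 4))
  ## UR = HA - TA algebraically, so corr(UR, HA) = corr(HA - TA, HA)
  sm <- sampleInstances(ssm, 40, seed = 9)
  ks <- sapply(seq_len(40), function(i) {
    model <- disassembleShapeVector(sm$vectors[, i], ssm@reference,
                                    ssm@mus, ssm@layout)
    c(TA = computeBiometric(model, fix$ref$schema, "TA"),
      HA = computeBiometric(model, fix$ref$schema, "HA"))
  })
  expect_equal(C["UR", "HA"], cor(ks["HA", ] - ks["TA", ], ks["HA", ]),
               tolerance = 1e-9)
})

test_that("independent functionals decorrelate at the null rate", {
  fix <- popFixture()
  ssm <- fix$ssm
  u1 <- ssm@modes[, 1]; u2 <- ssm@modes[, 2]
  n <- 150
  C <- correlationTable(ssm, fix$ref$schema,
                        list(a = function(model, s) sum(u1 * s),
                             b = function(model, s) sum(u2 * s)),
                        n = n, seed = 12)
  expect_lt(abs(C["a", "b"]), 3 / sqrt(n))
})

test_that("constant biometrics are flagged, not correlated", {
  fix <- popFixture()
  C <- correlationTable(fix$ssm, fix$ref$schema,
                        list(const = function(model, s) 42,
                             ta = "TA"), n = 35, seed = 4)
  expect_true(is.na(C["const", "ta"]))
  expect_equal(C["ta", "ta"], 1)
})
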