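## micro-SSM over plain vectors: cheap, exactly controllable spectra
microSSM <- function(X) {
  ref <- refFixture()$model
  buildSSM(X, reference = ref,
           mus = lapply(ref@skeleton@axes, function(a) a[, 3]),
           layout = list(components = c(x = nrow(X) %/% 3L), bones = character(0),
                         geomLength = 3L * (nrow(X) %/% 3L),
                         length = nrow(X)))
}

test_that("compactness reports cumulative explained variance", {
  ## one dominant direction
  set.seed(1)
  u <- rnorm(30); u <- u / sqrt(sum(u^2))
  X <- tcrossprod(u, rnorm(8) * 5) + matrix(rnorm(240, sd = 1e-4), 30, 8)
  c1 <- compactness(microSSM(X))
  expect_gt(c1$value[1], 99.99)
  expect_true(all(diff(c1$value) >= -1e-12))
  expect_equal(c1$value[nrow(c1)], 100)

  ## exactly equal variances across 5 orthogonal modes
  Q <- qr.Q(qr(matrix(rnorm(30 * 5), 30, 5)))
  X2 <- cbind(Q, -Q)  # each mode appears with +-1 coefficient: equal variances
  c2 <- compactness(microSSM(X2))
  expect_equal(c2$value[1:5], 20 * (1:5), tolerance = 1e-8)

  zero <- matrix(1, 30, 4)
  expect_error(compactness(microSSM(zero)), "zero total variance")
})

test_that("specificity matches brute-force recomputation", {
  set.seed(6)
  X <- matrix(rnorm(30 * 5, sd = 2), 30, 5)
  ssm <- microSSM(X)
  sp <- specificity(ssm, nSamples = 20, seed = 3, modes = c(1, 2, 4))
  ## brute force with the same draws
  nVert <- ssm@layout$geomLength / 3
  for (mi in seq_along(sp$modes)) {
    m <- sp$modes[mi]
    sm <- sampleInstances(ssm, 20, seed = 3 + m, nModes = m)
    vals <- sapply(1:20, function(i) {
      min(sapply(1:5, function(l)
        sqrt(sum((sm$vectors[1:ssm@layout$geomLength, i] -
                  X[1:ssm@layout$geomLength, l])^2) / nVert)))
    })
    expect_equal(sp$value[mi], mean(vals), tolerance = 1e-12)
  }
  ## zero-variance model always reproduces the mean
  X0 <- matrix(rep(rnorm(30), 4), 30, 4)
  expect_equal(max(specificity(microSSM(X0), nSamples = 5, seed = 1)$value),
               0, tolerance = 1e-9)
  ## determinism
  expect_identical(specificity(ssm, nSamples = 10, seed = 8),
                   specificity(ssm, nSamples = 10, seed = 8))
})

test_that("generalizability matches brute force and bounds reconstruction", {
  set.seed(14)
  X <- matrix(rnorm(30 * 5, sd = 2), 30, 5)
  ssm <- microSSM(X)
  g <- generalizability(ssm, modes = 1:3)
  ## brute-force leave-one-out for one subject and mode count
  p <- shapePCA(X[, -2])
  coef <- as.numeric(crossprod(p$modes, X[, 2] - p$mean))
  rec <- p$mean + p$modes[, 1:2] %*% coef[1:2]
  nVert <- ssm@layout$geomLength / 3
  gl <- ssm@layout$geomLength
  expect_equal(g$traces[2, 2],
               sqrt(sum((X[1:gl, 2] - rec[1:gl])^2) / nVert),
               tolerance = 1e-12)
  ## discrepancy property: generalization is never below reconstruction
  expect_true(all(g$curve$generalization >=
                  g$curve$reconstruction - 1e-9))
  ## both error curves non-increasing in the mode count
  expect_true(all(diff(g$curve$generalization) <= 1e-9))
  expect_true(all(diff(g$curve$reconstruction) <= 1e-9))
})

test_that("identical populations have zero error everywhere", {
  X <- matrix(rep(rnorm(30), 5), 30, 5)
  g <- generalizability(microSSM(X), modes = 1:3)
  expect_lt(max(abs(g$curve$generalization)), 1e-9)
  expect_lt(max(abs(g$curve$reconstruction)), 1e-9)
})

test_that("reconstruction with all modes is exact on training data", {
  fix <- popFixture()
  g <- generalizability(fix$ssm, modes = c(1, 3, 9))
  expect_lt(g$curve$reconstruction[3], 1e-9)
})
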