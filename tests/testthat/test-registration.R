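params <- registrationParams(icpMaxIter = 30, force = TRUE)

test_that("rigid pre-alignment recovers known similarity motions", {
  ref <- refFixture()
  m <- ref$model@components$P2
  pre0 <- rigidPrealign(m, m, params)
  expect_lt(pre0$rmse, 1e-6)
  set.seed(9)
  T0 <- randomRigid()
  T0[1:3, 1:3] <- T0[1:3, 1:3] * 1.12
  tgt <- applyTransform(m, T0)
  pre <- rigidPrealign(m, tgt, params)
  expect_lt(max(abs(pre$transform - T0)), 1e-4)
  expect_equal(pre$scale, 1.12, tolerance = 1e-6)
  ## the multi-hypothesis search can only improve on any single
  ## initialization
  single <- rigidPrealign(m, tgt, params, init = diag(4), initOnly = TRUE)
  expect_lte(pre$rmse, single$rmse + 1e-12)
})

test_that("elastic registration is a fixed point on identical meshes", {
  m <- refFixture()$model@components$P2
  def <- elasticRegister(m, m, params)
  expect_lt(max(abs(def@vertices - m@vertices)), 1e-3)
  expect_identical(def@faces, m@faces)
})

test_that("elastic registration recovers a smooth radial bump", {
  m <- refFixture()$model@components$P2
  ctr <- colMeans(m@vertices)
  rel <- sweep(m@vertices, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  tgt <- m
  tgt@vertices <- m@vertices +
    rel / r * 2 * exp(-((m@vertices[, 2] - 70) / 12)^2)
  def <- elasticRegister(m, tgt, params)
  ge <- suppressWarnings(signedGeometricError(def, tgt))
  expect_lt(ge$meanUnsigned, 0.1)
  expect_equal(nVertices(def), nVertices(m))
})

test_that("surface error is non-increasing along the stiffness schedule", {
  m <- refFixture()$model@components$P2
  ctr <- colMeans(m@vertices)
  rel <- sweep(m@vertices, 2, ctr)
  tgt <- m
  tgt@vertices <- m@vertices +
    rel / sqrt(rowSums(rel^2)) * 2 * exp(-((m@vertices[, 2] - 70) / 12)^2)
  sched <- c(50, 20, 8, 3, 1)
  errs <- vapply(seq_along(sched), function(k) {
    p <- registrationParams(stiffness = sched[seq_len(k)],
                            icpMaxIter = 30, force = TRUE)
    d <- elasticRegister(m, tgt, p)
    suppressWarnings(signedGeometricError(d, tgt))$meanUnsigned
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
})

test_that("small targets are refused as under-constrained unless forced", {
  m <- refFixture()$model@components$P2
  small <- tetraMesh()
  expect_error(elasticRegister(m, small, registrationParams()),
               "under-constrained")
})

test_that("identical subjects make the two-pass mean a fixed point", {
  ref <- refFixture()
  comps <- ref$model@components[c("P2", "P3")]
  refSmall <- LimbModel(comps, ref$model@skeleton)
  subjects <- list(s1 = comps, s2 = comps, s3 = comps)
  cs <- buildCorrespondences(refSmall, subjects, params)
  expect_s4_class(cs, "CorrespondenceSet")
  for (i in 1:3) for (nm in names(comps)) {
    expect_equal(nVertices(cs@subjects[[i]][[nm]]), nVertices(comps[[nm]]))
    expect_identical(cs@subjects[[i]][[nm]]@faces, comps[[nm]]@faces)
    expect_lt(max(abs(cs@subjects[[i]][[nm]]@vertices -
                      comps[[nm]]@vertices)), 1e-2)
  }
})

test_that("subjects missing a component are skipped with a warning", {
  ref <- refFixture()
  comps <- ref$model@components[c("P2", "P3")]
  refSmall <- LimbModel(comps, ref$model@skeleton)
  subjects <- list(ok = comps, broken = comps["P2"])
  expect_warning(cs <- buildCorrespondences(refSmall, subjects, params,
                                            twoPass = FALSE),
                 "missing components")
  expect_equal(length(cs@subjects), 1L)
  expect_identical(cs@subjectIds, "ok")
})

test_that("registration report matches direct recomputation", {
  ref <- refFixture()
  comps <- ref$model@components[c("P3", "DS")]
  refSmall <- LimbModel(comps, ref$model@skeleton)
  cs <- new("CorrespondenceSet", reference = refSmall,
            subjects = list(comps, comps), transforms =
              list(list(P3 = diag(4), DS = diag(4)),
                   list(P3 = diag(4), DS = diag(4))),
            subjectIds = c("a", "b"))
  rep <- suppressWarnings(registrationReport(cs, list(comps, comps)))
  expect_equal(rep$globalMeanUnsigned, 0)
  expect_equal(rep$globalSD, 0)
  expect_true(all(rep$perVertex$P3$mean == 0))
  expect_true(all(rep$perVertex$P3$sd == 0))

  ## distorted subject: the global summary equals an independent
  ## recomputation from signedGeometricError
  sub2 <- comps
  sub2$P3@vertices <- sub2$P3@vertices + 0.5
  cs2 <- new("CorrespondenceSet", reference = refSmall,
             subjects = list(sub2), transforms =
               list(list(P3 = diag(4), DS = diag(4))),
             subjectIds = "a")
  rep2 <- suppressWarnings(registrationReport(cs2, list(comps)))
  ge <- suppressWarnings(signedGeometricError(sub2$P3, comps$P3))
  nP3 <- nVertices(comps$P3); nDS <- nVertices(comps$DS)
  expect_equal(rep2$globalMeanUnsigned,
               (mean(abs(ge$distance)) * nP3 + 0 * nDS) / (nP3 + nDS),
               tolerance = 1e-12)
})
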