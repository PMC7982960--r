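test_that("circle fitting recovers exact and noisy circles", {
  th <- 2 * pi * (0:7) / 8
  pts <- cbind(10 * cos(th), 10 * sin(th), 0)
  fit <- fitJointCircle(pts, c(0, 0, 1))
  expect_lt(max(abs(fit$center)), 1e-9)
  expect_equal(fit$radius, 10, tolerance = 1e-9)

  ## noisy case against an iterative geometric (Gauss-Newton via nls) fit
  set.seed(3)
  noisy <- pts + matrix(rnorm(24, sd = 0.01), ncol = 3)
  fitN <- fitJointCircle(noisy, c(0, 0, 1))
  expect_lt(abs(fitN$radius - 10), 0.01)
  geo <- suppressWarnings(
    nls(rep(0, 8) ~ sqrt((noisy[, 1] - cx)^2 + (noisy[, 2] - cy)^2) - r,
        start = list(cx = 0, cy = 0, r = 9),
        control = nls.control(warnOnly = TRUE)))
  expect_lt(abs(fitN$radius - coef(geo)[["r"]]), 5e-4)
})

test_that("three points give the closed-form circumcircle", {
  p <- rbind(c(3, 0, 2), c(0, 4, 2), c(-3, -1, 2))
  fit <- fitJointCircle(p, c(0, 0, 1))
  ## analytic circumcenter in 2D (z = 2 plane)
  ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
  cx <- p[3, 1]; cy <- p[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  expect_equal(fit$center, c(ux, uy, 2), tolerance = 1e-9)
  expect_equal(fit$radius, sqrt((ax - ux)^2 + (ay - uy)^2),
               tolerance = 1e-9)
})

test_that("collinear projections are a degenerate-fit error", {
  pts <- cbind(1:5, 2 * (1:5), 0)
  expect_error(fitJointCircle(pts, c(0, 0, 1)), "collinear")
})

test_that("spherical angles decompose and recompose adjacent frames", {
  P <- diag(3)
  expect_equal(unname(sphericalAngles(P, P)), c(0, 0, 0))
  B <- P %*% rotZ3(0.3)
  expect_equal(unname(sphericalAngles(B, P)), c(0.3, 0, 0),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:100) {
    parent <- randomFrame()
    abg <- c(runif(1, -1, 1), runif(1, -0.5, 0.5), runif(1, -1, 1))
    bone <- frameFromAngles(parent, abg[1], abg[2], abg[3])
    got <- sphericalAngles(bone, parent)
    expect_lt(max(abs(got - abg)), 1e-9)
  }
})

test_that("gimbal poses are reported as degenerate", {
  P <- diag(3)
  B <- P %*% rotX3(pi / 2)   # bone y maps onto parent z
  expect_error(sphericalAngles(B, P), "degenerate pose")
})

test_that("flexion transform is conjugation about the parent z axis", {
  expect_equal(flexionTransform(randomRigid(), 0), diag(4),
               tolerance = 1e-12)
  T <- flexionTransform(diag(4), pi / 2)
  expect_equal(as.numeric(applyTransform(matrix(c(1, 0, 0), 1, 3), T)),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    parentT <- randomRigid()
    theta <- runif(1, -pi, pi)
    A <- flexionTransform(parentT, theta)
    ## the parent's local z axis line is pointwise fixed
    for (t in c(-20, 0, 13)) {
      p <- parentT[1:3, 4] + t * parentT[1:3, 3]
      expect_lt(max(abs(applyTransform(matrix(p, 1, 3), A) - p)), 1e-9)
    }
  }
})

test_that("articulation is rigid per component and shares group transforms", {
  ref <- refFixture()
  model <- ref$model
  expect_equal(articulate(model, c(MCP = 0, PIP = 0, DIP = 0)),
               model, tolerance = 1e-12)
  ang <- c(MCP = 0.35, PIP = -0.2, DIP = 0.25)
  posed <- articulate(model, ang)
  set.seed(2)
  for (nm in c("P1", "capsule")) {
    V0 <- model@components[[nm]]@vertices
    V1 <- posed@components[[nm]]@vertices
    i <- sample(nrow(V0), 30)
    j <- sample(nrow(V0), 30)
    d0 <- sqrt(rowSums((V0[i, ] - V0[j, ])^2))
    d1 <- sqrt(rowSums((V1[i, ] - V1[j, ])^2))
    expect_lt(max(abs(d1 - d0) / pmax(d0, 1e-9)), 1e-9)
  }
  ## components in one rigid group: relative geometry preserved exactly
  rel0 <- model@components$PS_med@vertices[1, ] -
    model@components$P1@vertices[1, ]
  rel1 <- posed@components$PS_med@vertices[1, ] -
    posed@components$P1@vertices[1, ]
  expect_equal(sqrt(sum(rel1^2)), sqrt(sum(rel0^2)), tolerance = 1e-12)

  back <- articulate(posed, -ang)
  expect_lt(max(abs(back@components$capsule@vertices -
                    model@components$capsule@vertices)), 1e-6)
  expect_error(articulate(model, c(KNEE = 0.1)), "unknown joint")
})
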