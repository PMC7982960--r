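## Geometry of unit rotation-axis directions on S^2: logarithmic and
## exponential maps around a base point and the intrinsic (Karcher) mean.
## These carry the axis-orientation blocks of the composite shape vector
## into a Euclidean tangent space where PCA is valid (principal geodesic
## analysis).

checkUnit <- function(v, what = "vector") {
  if (abs(sqrt(sum(v^2)) - 1) > 1e-6)
    stop(sprintf("%s must be a unit 3-vector", what))
  as.numeric(v)
}

#' Logarithmic map on the unit sphere
#'
#' Maps a unit vector `v` to the tangent plane at `mu`: the result is
#' perpendicular to `mu` with magnitude equal to the geodesic angle between
#' `v` and `mu`. [sphereExp()] inverts it.
#'
#' @param v,mu unit 3-vectors.
#' @return tangent 3-vector (ambient coordinates, perpendicular to `mu`).
#' @export
sphereLog <- function(v, mu) {
  v <- checkUnit(v, "v")
  mu <- checkUnit(mu, "mu")
  d <- max(-1, min(1, sum(v * mu)))
  ## atan2 of the cross-product norm is well conditioned at both ends,
  ## unlike acos(d) near d = 1
  s <- sqrt(sum(crossProduct3(mu, v)^2))
  if (d < 0 && s < 1e-9)
    stop("logarithmic map undefined for antipodal points")
  theta <- atan2(s, d)
  if (theta < 1e-14) return(c(0, 0, 0))
  u <- v - d * mu
  theta * u / sqrt(sum(u^2))
}

#' Exponential map on the unit sphere
#'
#' @param t tangent 3-vector at `mu` (perpendicular to `mu`).
#' @param mu unit 3-vector.
#' @return unit 3-vector.
#' @export
sphereExp <- function(t, mu) {
  mu <- checkUnit(mu, "mu")
  theta <- sqrt(sum(t^2))
  if (theta < 1e-12) return(mu)
  as.numeric(cos(theta) * mu + sin(theta) * t / theta)
}

#' Intrinsic (Karcher) mean of unit vectors
#'
#' Iterated tangent-space averaging: `mu <- exp(mean of logs, mu)` until the
#' tangent step norm falls below `tol`. At convergence the mean of the
#' log-mapped data is (numerically) zero. Data should lie within an open
#' hemisphere; otherwise convergence is not guaranteed and the result
#' carries `attr(, "converged") = FALSE` with a warning.
#'
#' @param vs n x 3 matrix (or list) of unit vectors.
#' @param tol convergence threshold on the tangent step.
#' @param maxIter iteration cap.
#' @return unit numeric(3) with attribute `converged`.
#' @export
intrinsicMean <- function(vs, tol = 1e-12, maxIter = 100) {
  if (is.list(vs)) vs <- do.call(rbind, vs)
  vs <- as.matrix(vs)
  mu <- normalize3(colMeans(vs))
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    logs <- t(apply(vs, 1, sphereLog, mu = mu))
    step <- colMeans(logs)
    mu <- sphereExp(step, mu)
    if (sqrt(sum(step^2)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("intrinsic mean did not converge (non-hemispherical data?)")
  attr(mu, "converged") <- converged
  mu
}
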