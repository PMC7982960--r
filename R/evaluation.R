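## SSM quality metrics as functions of the number of modes: compactness,
## specificity, generalizability (leave-one-out), reconstruction error.
## All mm-valued metrics are RMS distances between corresponding vertices
## computed over the geometry block of the shape vector only (the axis and
## center entries are excluded, so the result is a surface distance in mm).

geomRMS <- function(a, b, layout) {
  g <- layout$geomLength
  nVert <- g / 3
  sqrt(sum((a[1:g] - b[1:g])^2) / nVert)
}

#' Compactness curve
#'
#' Cumulative percentage of total variance explained by the first m modes.
#'
#' @param ssm a [LimbSSM-class].
#' @return data.frame with columns `modes`, `value` (percent).
#' @export
compactness <- function(ssm) {
  v <- modeVariances(ssm)
  tot <- sum(v)
  if (tot <= 0) stop("compactness undefined: model has zero total variance")
  data.frame(modes = seq_along(v), value = 100 * cumsum(v) / tot)
}

#' Specificity curve
#'
#' For each mode count m: draw random instances using the first m modes and
#' measure, for each instance, the RMS corresponding-vertex distance to its
#' closest training shape; the curve is the mean over instances.
#'
#' @param ssm a [LimbSSM-class].
#' @param nSamples random instances per mode count.
#' @param seed RNG seed.
#' @param modes mode counts to evaluate (default 1..K).
#' @return data.frame with columns `modes`, `value` (mm).
#' @export
specificity <- function(ssm, nSamples = 200, seed = 1,
                        modes = seq_len(numModes(ssm))) {
  X <- ssm@training
  vals <- vapply(modes, function(m) {
    sm <- sampleInstances(ssm, nSamples, seed = seed + m, nModes = m)
    mean(vapply(seq_len(nSamples), function(i) {
      s <- sm$vectors[, i]
      min(vapply(seq_len(ncol(X)), function(l)
        geomRMS(s, X[, l], ssm@layout), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  data.frame(modes = modes, value = vals)
}

#' Generalizability and reconstruction-error curves
#'
#' Leave-one-out generalizability: for every training subject the model is
#' rebuilt on the remaining L-1 subjects, fitted to the held-out subject
#' with the first m modes, and the RMS corresponding-vertex error recorded;
#' the curve is the mean across subjects. The in-sample reconstruction
#' error (fitting each training subject with the full model truncated to m
#' modes) is returned alongside; the gap between the two curves is the cost
#' of generalizing to unseen subjects.
#'
#' @param ssm a [LimbSSM-class] built from at least 3 subjects.
#' @param modes mode counts to evaluate (default 1..L-1 of the LOO models).
#' @return list: `curve` (data.frame modes/generalization/reconstruction,
#'   mm), `traces` (subjects x modes matrix of per-subject LOO errors),
#'   `reconTraces`.
#' @export
generalizability <- function(ssm, modes = NULL) {
  X <- ssm@training
  L <- ncol(X)
  if (L < 3) stop("leave-one-out needs at least 3 subjects")
  if (is.null(modes)) modes <- seq_len(L - 2L)
  layout <- ssm@layout
  traces <- matrix(NA_real_, L, length(modes))
  reconTraces <- matrix(NA_real_, L, length(modes))
  for (l in seq_len(L)) {
    p <- shapePCA(X[, -l, drop = FALSE])
    held <- X[, l]
    dc <- held - p$mean
    live <- p$sigma > 1e-12 * max(p$sigma, .Machine$double.eps)
    coef <- as.numeric(crossprod(p$modes, dc))
    coef[!live] <- 0
    fullC <- as.numeric(crossprod(ssm@modes, held - ssm@mean))
    fullLive <- ssm@sigma > 1e-12 * max(ssm@sigma, .Machine$double.eps)
    fullC[!fullLive] <- 0
    for (mi in seq_along(modes)) {
      m <- min(modes[mi], length(coef))
      rec <- p$mean + p$modes[, seq_len(m), drop = FALSE] %*%
        coef[seq_len(m)]
      traces[l, mi] <- geomRMS(held, as.numeric(rec), layout)
      mf <- min(modes[mi], length(fullC))
      recf <- ssm@mean + ssm@modes[, seq_len(mf), drop = FALSE] %*%
        fullC[seq_len(mf)]
      reconTraces[l, mi] <- geomRMS(held, as.numeric(recf), layout)
    }
  }
  list(curve = data.frame(modes = modes,
                          generalization = colMeans(traces),
                          reconstruction = colMeans(reconTraces)),
       traces = traces, reconTraces = reconTraces)
}
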