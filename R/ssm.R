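## The statistical core: composite shape vectors (surface geometry plus
## skeleton rotation axes and centers), PCA through the small Gram matrix,
## sampling, fitting, and posed reconstruction.

#' Shape-vector layout of a reference model
#'
#' The composite shape vector concatenates, in this order: the x/y/z
#' coordinates of every vertex of every component (component order fixed by
#' the reference), then per skeleton bone the log-mapped flexion-axis
#' direction (3 numbers, tangent at that bone's intrinsic mean), then per
#' bone the axis center c_b (3 numbers). Its length is
#' 3 (sum_j N_j + 2 N_b).
#'
#' @param reference a [LimbModel-class].
#' @return list: `components` (named vertex counts), `bones`, `geomLength`,
#'   `length`.
#' @export
shapeLayout <- function(reference) {
  counts <- vapply(reference@components, nVertices, integer(1))
  bones <- reference@skeleton@boneIds
  geomLength <- 3L * sum(counts)
  list(components = counts, bones = bones, geomLength = geomLength,
       length = geomLength + 2L * 3L * length(bones))
}

## flexion-axis direction of a bone: its own frame z axis (the axis its
## child bone rotates about).
boneAxes <- function(model) {
  skel <- model@skeleton
  vapply(skel@boneIds, function(b) skel@axes[[b]][, 3], numeric(3))
}

#' Intrinsic mean axes over a set of normalized subjects
#'
#' @param normalized list of [NormalizedLimb-class].
#' @return named list of unit numeric(3), one per bone.
#' @export
intrinsicMeanAxes <- function(normalized) {
  bones <- normalized[[1]]@model@skeleton@boneIds
  out <- list()
  for (bi in seq_along(bones)) {
    axes <- t(vapply(normalized, function(n)
      boneAxes(n@model)[, bi], numeric(3)))
    out[[bones[bi]]] <- as.vector(intrinsicMean(axes))
  }
  out
}

#' Assemble a composite shape vector
#'
#' @param subject a [NormalizedLimb-class] (or [LimbModel-class]).
#' @param mus named list of per-bone intrinsic mean axes.
#' @param layout a [shapeLayout()]; defaults to the subject's own layout.
#' @return numeric shape vector.
#' @export
assembleShapeVector <- function(subject, mus, layout = NULL) {
  model <- if (is(subject, "NormalizedLimb")) subject@model else subject
  if (is.null(layout)) layout <- shapeLayout(model)
  counts <- vapply(model@components, nVertices, integer(1))
  if (!identical(unname(counts[names(layout$components)]),
                 unname(layout$components)))
    stop("layout error: component vertex counts do not match the manifest")
  geom <- unlist(lapply(names(layout$components), function(nm)
    as.vector(t(model@components[[nm]]@vertices))), use.names = FALSE)
  skel <- model@skeleton
  axes <- unlist(lapply(layout$bones, function(b)
    sphereLog(skel@axes[[b]][, 3], mus[[b]])), use.names = FALSE)
  centers <- unlist(lapply(layout$bones, function(b)
    skel@origins[[b]]), use.names = FALSE)
  c(geom, axes, centers)
}

#' Disassemble a shape vector into a posed limb model
#'
#' Inverts [assembleShapeVector()]: reads back the component geometry,
#' exp-maps the axis blocks to unit flexion axes, reads the centers, and
#' rebuilds full bone frames by completing each axis to a right-handed frame
#' (the reference frame's x axis is re-orthogonalized against the new z;
#' y = z cross x).
#'
#' @param s numeric shape vector.
#' @param reference the reference [LimbModel-class] (topology and frame
#'   completion).
#' @param mus named list of per-bone intrinsic mean axes.
#' @param layout a [shapeLayout()] of the reference.
#' @return A [LimbModel-class].
#' @export
disassembleShapeVector <- function(s, reference, mus,
                                   layout = shapeLayout(reference)) {
  if (length(s) != layout$length)
    stop(sprintf("layout error: shape vector length %d, manifest says %d",
                 length(s), layout$length))
  comps <- reference@components
  off <- 0L
  for (nm in names(layout$components)) {
    n <- layout$components[[nm]]
    comps[[nm]]@vertices <- matrix(s[(off + 1L):(off + 3L * n)],
                                   ncol = 3, byrow = TRUE)
    off <- off + 3L * n
  }
  skel <- reference@skeleton
  nb <- length(layout$bones)
  for (bi in seq_along(layout$bones)) {
    b <- layout$bones[bi]
    tang <- s[(off + 3L * (bi - 1L) + 1L):(off + 3L * bi)]
    z <- sphereExp(tang, mus[[b]])
    xRef <- skel@axes[[b]][, 1]
    x <- xRef - sum(xRef * z) * z
    nx <- sqrt(sum(x^2))
    if (nx < 1e-8)
      stop(sprintf("degenerate frame for bone %s: axis parallel to reference x", b))
    x <- x / nx
    skel@axes[[b]] <- cbind(x, crossProduct3(z, x), z)
  }
  off <- off + 3L * nb
  for (bi in seq_along(layout$bones)) {
    b <- layout$bones[bi]
    skel@origins[[b]] <- s[(off + 3L * (bi - 1L) + 1L):(off + 3L * bi)]
  }
  LimbModel(comps, skel)
}

#' Principal component modes of a set of shape vectors
#'
#' Mean-centers the columns of `X` (shapes as columns) and extracts at most
#' L-1 orthonormal modes with their standard deviations (sample covariance
#' divisor L-1). The decomposition runs as an economy singular value
#' decomposition of the centered 3F x L data matrix: in exact arithmetic
#' this is identical to the eigendecomposition of the small Gram matrix
#' `Xc' Xc` (the classical efficient route for tall shape matrices, which
#' the test suite uses as an oracle), but it avoids squaring the condition
#' number, so null modes come out at machine precision instead of at its
#' square root. Mode signs are fixed so the largest-magnitude entry of each
#' mode is positive.
#'
#' @param X numeric matrix, one shape vector per column.
#' @return list: `mean`, `modes` (orthonormal columns), `sigma`
#'   (descending standard deviations).
#' @export
shapePCA <- function(X) {
  X <- as.matrix(X)
  L <- ncol(X)
  if (L < 2) stop("need at least 2 shapes")
  m <- rowMeans(X)
  Xc <- X - m
  K <- L - 1L
  sv <- svd(Xc, nu = K, nv = 0)
  sigma <- sv$d[seq_len(K)] / sqrt(L - 1)
  modes <- sv$u
  for (i in seq_len(K)) {
    if (modes[which.max(abs(modes[, i])), i] < 0)
      modes[, i] <- -modes[, i]
  }
  list(mean = as.numeric(m), modes = modes, sigma = sigma)
}

#' Build the articulating statistical shape model
#'
#' Computes the per-bone intrinsic mean axes, assembles the composite shape
#' vector of every normalized subject, and extracts the PCA modes through
#' the Gram-matrix route.
#'
#' @param normalized list of [NormalizedLimb-class] (at least 2), or a
#'   numeric matrix of pre-assembled shape vectors (columns) if `layout`,
#'   `mus` and `reference` are given.
#' @param reference the reference [LimbModel-class]; defaults to deriving
#'   topology from the first subject.
#' @param mus optional named list of intrinsic mean axes (computed from the
#'   subjects when omitted).
#' @param layout optional [shapeLayout()].
#' @return A [LimbSSM-class].
#' @export
buildSSM <- function(normalized, reference = NULL, mus = NULL,
                     layout = NULL) {
  if (is.matrix(normalized)) {
    stopifnot(!is.null(reference), !is.null(mus))
    if (is.null(layout)) layout <- shapeLayout(reference)
    X <- normalized
  } else {
    if (length(normalized) < 2) stop("need at least 2 subjects")
    if (is.null(reference)) reference <- normalized[[1]]@model
    if (is.null(layout)) layout <- shapeLayout(reference)
    if (is.null(mus)) mus <- intrinsicMeanAxes(normalized)
    X <- vapply(normalized, assembleShapeVector, numeric(layout$length),
                mus = mus, layout = layout)
  }
  if (nrow(X) != layout$length)
    stop("layout error: inconsistent shape vector lengths")
  p <- shapePCA(X)
  new("LimbSSM", mean = p$mean, modes = p$modes, sigma = p$sigma,
      mus = mus, layout = layout, reference = reference, training = X)
}

#' Synthesize a shape vector from mode weights
#'
#' `s(b) = mean + E D b` with `D = diag(sigma)`: weight `b_i` counts in
#' units of mode standard deviations.
#'
#' @param ssm a [LimbSSM-class].
#' @param b numeric weight vector (zero-padded to the number of modes).
#' @return numeric shape vector.
#' @export
synthesize <- function(ssm, b) {
  K <- numModes(ssm)
  if (length(b) > K) stop("more weights than modes")
  b <- c(b, numeric(K - length(b)))
  as.numeric(ssm@mean + ssm@modes %*% (ssm@sigma * b))
}

#' Fit mode weights to a shape vector
#'
#' `b = D^-1 E^+ (s - mean)` over the non-degenerate modes (for orthonormal
#' `E` the pseudo-inverse is the transpose). Modes with a standard
#' deviation below `1e-12 sigma_1` are excluded (weight 0) with a warning
#' when explicitly requested.
#'
#' @param ssm a [LimbSSM-class].
#' @param s numeric shape vector.
#' @param nModes number of leading modes to use (default: all).
#' @return numeric weight vector of length [numModes()].
#' @export
fitShape <- function(ssm, s, nModes = numModes(ssm)) {
  K <- numModes(ssm)
  stopifnot(length(s) == length(ssm@mean), nModes <= K)
  live <- ssm@sigma > 1e-12 * max(ssm@sigma, .Machine$double.eps)
  if (nModes > sum(live))
    warning(sprintf(
      "%d requested mode(s) have zero variance and are excluded",
      nModes - sum(live)))
  use <- which(live)[which(live) <= nModes]
  b <- numeric(K)
  if (length(use))
    b[use] <- crossprod(ssm@modes[, use, drop = FALSE], s - ssm@mean) /
      ssm@sigma[use]
  b
}

#' Draw random model instances
#'
#' Mode weights are drawn i.i.d. standard normal (so mode i varies with
#' standard deviation sigma_i after synthesis), reproducibly under the
#' given seed.
#'
#' @param ssm a [LimbSSM-class].
#' @param n number of instances.
#' @param seed integer RNG seed.
#' @param nModes number of leading modes to sample (others held at 0).
#' @return list: `weights` (n x K matrix), `vectors` (3F x n matrix).
#' @export
sampleInstances <- function(ssm, n, seed = 1, nModes = numModes(ssm)) {
  stopifnot(n >= 1)
  K <- numModes(ssm)
  set.seed(seed)
  W <- matrix(0, n, K)
  if (nModes > 0)
    W[, seq_len(nModes)] <- matrix(rnorm(n * nModes), n, nModes)
  vecs <- vapply(seq_len(n), function(i) synthesize(ssm, W[i, ]),
                 numeric(length(ssm@mean)))
  list(weights = W, vectors = vecs)
}

#' Reconstruct a posed limb model from mode weights
#'
#' Synthesizes the shape vector, disassembles it into components and a
#' weight-dependent skeleton (axes exp-mapped, centers read back), and
#' articulates the result with the given joint angles. The articulation
#' uses the instance's own skeleton, not the mean's.
#'
#' @param ssm a [LimbSSM-class].
#' @param b numeric weight vector.
#' @param angles named joint angles in radians (see [articulate()]).
#' @return A [LimbModel-class].
#' @export
reconstructPosed <- function(ssm, b, angles = numeric(0)) {
  s <- synthesize(ssm, b)
  model <- disassembleShapeVector(s, ssm@reference, ssm@mus, ssm@layout)
  articulate(model, angles)
}

#' Serialize / load an SSM archive
#'
#' Plain-text directory archive: a JSON manifest (layout, intrinsic means,
#' sigma, reference faces) plus whitespace-delimited numeric tables for the
#' mean, modes, and training vectors, and PLY files for the reference
#' components.
#'
#' @param ssm a [LimbSSM-class].
#' @param dir archive directory (created if needed).
#' @return `dir` (for `writeSSM`), a [LimbSSM-class] (for `readSSM`).
#' @export
writeSSM <- function(ssm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- ssm@reference
  skel <- ref@skeleton
  manifest <- list(
    layout = list(components = as.list(ssm@layout$components),
                  bones = ssm@layout$bones),
    sigma = ssm@sigma,
    mus = ssm@mus,
    skeleton = list(
      boneIds = skel@boneIds,
      parents = as.list(setNames(
        ifelse(is.na(skel@parents), "NA", skel@parents),
        names(skel@parents))),
      axes = lapply(skel@axes, function(a) as.list(as.data.frame(a))),
      origins = skel@origins,
      componentMap = as.list(skel@componentMap),
      jointMap = as.list(skel@jointMap),
      boneComponent = as.list(skel@boneComponent),
      jointSurface = skel@jointSurface))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(ssm@mean, file.path(dir, "mean.txt"),
              row.names = FALSE, col.names = FALSE)
  write.table(ssm@modes, file.path(dir, "modes.txt"),
              row.names = FALSE, col.names = FALSE)
  write.table(ssm@training, file.path(dir, "training.txt"),
              row.names = FALSE, col.names = FALSE)
  compDir <- file.path(dir, "reference")
  dir.create(compDir, showWarnings = FALSE)
  for (nm in names(ref@components))
    writeMesh(ref@components[[nm]], file.path(compDir, paste0(nm, ".ply")))
  invisible(dir)
}

#' @rdname writeSSM
#' @export
readSSM <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  comps <- list()
  for (nm in names(man$layout$components))
    comps[[nm]] <- readMesh(file.path(dir, "reference", paste0(nm, ".ply")),
                            name = nm)
  sk <- man$skeleton
  parents <- unlist(sk$parents)
  parents <- setNames(as.character(parents), names(parents))
  parents[parents == "NA"] <- NA_character_
  js <- lapply(sk$jointSurface, function(x)
    list(component = x$component, idx = as.integer(x$idx)))
  skel <- Skeleton(
    boneIds = sk$boneIds,
    parents = parents[sk$boneIds],
    axes = lapply(sk$axes, function(a) matrix(unlist(a), 3, 3)),
    origins = lapply(sk$origins, as.numeric),
    componentMap = unlist(sk$componentMap),
    jointMap = if (length(sk$jointMap)) unlist(sk$jointMap)
               else character(0),
    boneComponent = if (length(sk$boneComponent)) unlist(sk$boneComponent)
                    else character(0),
    jointSurface = js)
  ref <- LimbModel(comps, skel)
  layout <- shapeLayout(ref)
  mus <- lapply(man$mus, as.numeric)
  modes <- as.matrix(read.table(file.path(dir, "modes.txt")))
  dimnames(modes) <- NULL
  training <- as.matrix(read.table(file.path(dir, "training.txt")))
  dimnames(training) <- NULL
  new("LimbSSM",
      mean = as.numeric(read.table(file.path(dir, "mean.txt"))[, 1]),
      modes = modes, sigma = as.numeric(man$sigma), mus = mus,
      layout = layout, reference = ref, training = training)
}
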