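#' TriangleMesh: an indexed triangle surface
#'
#' Container for one anatomical component surface. Vertex order is the
#' correspondence carrier throughout the package: no reader, writer or
#' operation is allowed to deduplicate or reorder vertices.
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#' @slot name component label (e.g. \code{"MC3"}, \code{"capsule"}).
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix", name = "character"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3), name = "")
)

setValidity("TriangleMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  if (ncol(v) != 3) return("vertices must have 3 columns")
  if (ncol(f) != 3) return("faces must have 3 columns")
  if (nrow(v) <= 3) return("mesh must have more than 3 vertices")
  if (nrow(f) > 0) {
    if (min(f) < 1 || max(f) > nrow(v))
      return("face indices out of range [1, n_vertices]")
    degen <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
    if (any(degen))
      return(sprintf("degenerate (repeated-index) triangle at face %d",
                     which(degen)[1]))
  }
  if (anyNA(v)) return("vertices contain NA")
  TRUE
})

#' Construct a TriangleMesh
#'
#' @param vertices numeric matrix (n x 3), mm.
#' @param faces integer matrix (f x 3), 1-based vertex indices.
#' @param name component label.
#' @return A [TriangleMesh-class] object.
#' @examples
#' m <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'                   rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)),
#'                   name = "tet")
#' nVertices(m)
#' @export
TriangleMesh <- function(vertices, faces, name = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  new("TriangleMesh", vertices = vertices, faces = faces, name = name)
}

#' Skeleton: articulated bone frames of a limb
#'
#' Kinematic description of the limb: one orthonormal right-handed reference
#' frame per skeleton bone (y along the bone's elongation axis, z
#' perpendicular to its sagittal plane), a parent map forming a chain with a
#' single root, the map from surface components to the bone that carries them
#' rigidly, joint names for the articulated degrees of freedom, and the
#' vertex sets of the joint surfaces used for circle fitting.
#'
#' @slot boneIds character vector of bone identifiers, proximal to distal.
#' @slot parents named character; parent bone of each bone, `NA` for the root.
#' @slot axes named list of 3x3 matrices; columns are the x, y, z unit axes.
#' @slot origins named list of numeric(3); frame origin c_b (joint circle
#'   center), mm.
#' @slot componentMap named character; component label -> bone id.
#' @slot jointMap named character; joint name (e.g. MCP) -> the bone that
#'   flexes at that joint (rotation happens about the parent bone's z axis
#'   through the parent origin).
#' @slot boneComponent named character; bone id -> representative component
#'   whose registration transform carries the bone frame.
#' @slot jointSurface named list; bone id -> list(component=, idx=) vertex
#'   index set of the distal articular surface on the reference topology.
#' @export
setClass("Skeleton",
  representation(boneIds = "character", parents = "character",
                 axes = "list", origins = "list",
                 componentMap = "character", jointMap = "character",
                 boneComponent = "character", jointSurface = "list")
)

setValidity("Skeleton", function(object) {
  ids <- object@boneIds
  if (!all(names(object@parents) == ids)) return("parents misnamed")
  roots <- ids[is.na(object@parents)]
  if (length(roots) != 1) return("skeleton must have exactly one root bone")
  for (b in ids) {
    p <- object@parents[[b]]
    seen <- character(0)
    while (!is.na(p)) {
      if (p %in% seen || !(p %in% ids)) return("parent map is not acyclic")
      seen <- c(seen, p)
      p <- object@parents[[p]]
    }
    A <- object@axes[[b]]
    if (is.null(A) || !is.matrix(A) || any(dim(A) != 3))
      return(sprintf("missing/invalid axes for bone %s", b))
    G <- crossprod(A)
    if (max(abs(G - diag(3))) > 1e-6)
      return(sprintf("axes of bone %s not orthonormal", b))
    z <- crossProduct3(A[, 1], A[, 2])
    if (max(abs(z - A[, 3])) > 1e-6)
      return(sprintf("frame of bone %s not right-handed (x cross y != z)", b))
    if (is.null(object@origins[[b]])) return("missing origin")
  }
  if (!all(object@componentMap %in% ids))
    return("componentMap refers to unknown bone")
  if (!all(object@jointMap %in% ids))
    return("jointMap refers to unknown bone")
  TRUE
})

#' Construct a Skeleton
#'
#' @param boneIds,parents,axes,origins,componentMap,jointMap,boneComponent,jointSurface
#'   see the slot documentation in [Skeleton-class].
#' @return A [Skeleton-class] object.
#' @export
Skeleton <- function(boneIds, parents, axes, origins, componentMap,
                     jointMap = character(0),
                     boneComponent = character(0),
                     jointSurface = list()) {
  new("Skeleton", boneIds = boneIds, parents = parents, axes = axes,
      origins = origins, componentMap = componentMap, jointMap = jointMap,
      boneComponent = boneComponent, jointSurface = jointSurface)
}

#' LimbModel: one subject's multi-component limb
#'
#' A set of component surfaces plus the articulated skeleton that moves them.
#'
#' @slot components named list of [TriangleMesh-class], one per component.
#' @slot skeleton a [Skeleton-class].
#' @export
setClass("LimbModel",
  representation(components = "list", skeleton = "Skeleton"))

setValidity("LimbModel", function(object) {
  if (is.null(names(object@components)) ||
      any(names(object@components) == ""))
    return("components must be a named list")
  if (!all(vapply(object@components, is, logical(1), "TriangleMesh")))
    return("all components must be TriangleMesh objects")
  unmapped <- setdiff(names(object@components),
                      names(object@skeleton@componentMap))
  if (length(unmapped))
    return(sprintf("components not mapped to a skeleton bone: %s",
                   paste(unmapped, collapse = ", ")))
  TRUE
})

#' Construct a LimbModel
#' @param components named list of [TriangleMesh-class].
#' @param skeleton a [Skeleton-class].
#' @return A [LimbModel-class] object.
#' @export
LimbModel <- function(components, skeleton) {
  new("LimbModel", components = components, skeleton = skeleton)
}

#' CorrespondenceSet: registered subjects on the reference topology
#'
#' Result of [buildCorrespondences()]: for every subject, each component is
#' represented on the reference topology (reference vertex count and faces,
#' subject geometry), still in the subject's original world pose, together
#' with the similarity transform that carried the reference component onto
#' the subject.
#'
#' @slot reference the reference [LimbModel-class].
#' @slot subjects list (per subject) of named lists of [TriangleMesh-class].
#' @slot transforms list (per subject) of named lists of 4x4 matrices T_ij.
#' @slot subjectIds character.
#' @export
setClass("CorrespondenceSet",
  representation(reference = "LimbModel", subjects = "list",
                 transforms = "list", subjectIds = "character"))

setValidity("CorrespondenceSet", function(object) {
  refc <- object@reference@components
  for (s in object@subjects) {
    for (nm in names(s)) {
      if (!nm %in% names(refc)) return("unknown component in subject")
      if (nrow(s[[nm]]@vertices) != nrow(refc[[nm]]@vertices))
        return(sprintf("component %s does not match reference vertex count",
                       nm))
    }
  }
  TRUE
})

#' NormalizedLimb: a scale- and pose-normalized subject
#'
#' @slot model the normalized [LimbModel-class] (components plus per-subject
#'   skeleton frames in the normalized coordinate system).
#' @slot theta named numeric; recovered optimal flexion angle per joint
#'   (radians) that was applied during normalization.
#' @slot scale numeric; global scale factor that was applied.
#' @export
setClass("NormalizedLimb",
  representation(model = "LimbModel", theta = "numeric", scale = "numeric"))

#' LimbSSM: the statistical shape model archive
#'
#' Mean composite shape vector, orthonormal variation modes, mode standard
#' deviations, per-bone intrinsic means of the rotation-axis directions, the
#' shape-vector layout, the reference topology, and the training vectors.
#'
#' @slot mean numeric mean shape vector (length 3F).
#' @slot modes matrix 3F x K of orthonormal mode columns.
#' @slot sigma numeric(K); mode standard deviations, descending.
#' @slot mus named list of unit numeric(3); intrinsic mean axis per bone.
#' @slot layout shape-vector layout, see [shapeLayout()].
#' @slot reference the reference [LimbModel-class] (topology carrier).
#' @slot training matrix 3F x L of the training shape vectors.
#' @export
setClass("LimbSSM",
  representation(mean = "numeric", modes = "matrix", sigma = "numeric",
                 mus = "list", layout = "list", reference = "LimbModel",
                 training = "matrix"))

setValidity("LimbSSM", function(object) {
  K <- ncol(object@modes)
  if (length(object@sigma) != K) return("sigma length != number of modes")
  if (K > 1 && any(diff(object@sigma) > 1e-9))
    return("sigma must be sorted descending")
  if (any(object@sigma < -1e-12)) return("sigma must be non-negative")
  if (K > 0) {
    G <- crossprod(object@modes)
    if (max(abs(G - diag(K))) > 1e-6)
      return("mode columns must be orthonormal")
  }
  for (mu in object@mus)
    if (abs(sqrt(sum(mu^2)) - 1) > 1e-6)
      return("intrinsic means must be unit vectors")
  TRUE
})

#' @describeIn TriangleMesh-class number of vertices
#' @param x a TriangleMesh
#' @export
nVertices <- function(x) nrow(x@vertices)

#' @describeIn TriangleMesh-class number of faces
#' @export
nFaces <- function(x) nrow(x@faces)

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh '%s': %d vertices, %d faces\n",
              object@name, nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton: %d bones (%s), %d mapped components, joints: %s\n",
              length(object@boneIds), paste(object@boneIds, collapse = ">"),
              length(object@componentMap),
              paste(names(object@jointMap), collapse = ", ")))
})

setMethod("show", "LimbModel", function(object) {
  nv <- sum(vapply(object@components, nVertices, integer(1)))
  cat(sprintf("LimbModel: %d components (%d vertices total), %d skeleton bones\n",
              length(object@components), nv,
              length(object@skeleton@boneIds)))
})

setMethod("show", "CorrespondenceSet", function(object) {
  cat(sprintf("CorrespondenceSet: %d subjects on reference topology (%d components)\n",
              length(object@subjects), length(object@reference@components)))
})

setMethod("show", "NormalizedLimb", function(object) {
  cat(sprintf("NormalizedLimb: scale factor %.4f, flexion normalization (rad): %s\n",
              object@scale,
              paste(sprintf("%s=%.4f", names(object@theta), object@theta),
                    collapse = ", ")))
})

setMethod("show", "LimbSSM", function(object) {
  cat(sprintf(
    "LimbSSM: %d modes over %d training shapes, shape vector length %d\n",
    ncol(object@modes), ncol(object@training), length(object@mean)))
  if (length(object@sigma)) {
    v <- object@sigma^2
    cat(sprintf("  leading mode sds: %s (first mode explains %.1f%% variance)\n",
                paste(sprintf("%.3g", head(object@sigma, 3)), collapse = ", "),
                100 * v[1] / sum(v)))
  }
})

#' Accessors for LimbSSM
#'
#' @param ssm a [LimbSSM-class].
#' @return `numModes`: integer; `modeVariances`: numeric vector of per-mode
#'   variances; `meanShape`: the mean composite shape vector.
#' @export
numModes <- function(ssm) ncol(ssm@modes)

#' @rdname numModes
#' @export
modeVariances <- function(ssm) ssm@sigma^2

#' @rdname numModes
#' @export
meanShape <- function(ssm) ssm@mean
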