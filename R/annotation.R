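## Reference-model annotation file: the skeleton (bones, parents, frames,
## joint-surface vertex sets, component map) and the biometric landmark
## schema, as one YAML document, so a reference model built elsewhere can be
## used with this pipeline.

#' Write / read a limb annotation file
#'
#' Serializes a [Skeleton-class] plus a landmark schema (named list of
#' `list(component =, idx =)` vertex sets, see [computeBiometric()]) to a
#' single YAML file and back.
#'
#' @param skeleton a [Skeleton-class].
#' @param schema landmark schema list (may be `NULL`).
#' @param path YAML file path.
#' @return `path` invisibly (`writeLimbAnnotation`); a list with elements
#'   `skeleton` and `schema` (`readLimbAnnotation`).
#' @export
writeLimbAnnotation <- function(skeleton, schema, path) {
  doc <- list(
    skeleton = list(
      boneIds = as.list(skeleton@boneIds),
      parents = as.list(setNames(
        ifelse(is.na(skeleton@parents), "none", skeleton@parents),
        names(skeleton@parents))),
      axes = lapply(skeleton@axes, function(a)
        list(x = as.numeric(a[, 1]), y = as.numeric(a[, 2]),
             z = as.numeric(a[, 3]))),
      origins = lapply(skeleton@origins, as.numeric),
      componentMap = as.list(skeleton@componentMap),
      jointMap = as.list(skeleton@jointMap),
      boneComponent = as.list(skeleton@boneComponent),
      jointSurface = lapply(skeleton@jointSurface, function(js)
        list(component = js$component, idx = as.integer(js$idx)))),
    landmarks = if (is.null(schema)) list() else
      lapply(schema, function(l)
        list(component = l$component, idx = as.integer(l$idx))),
    groundComponent = attr(schema, "groundComponent"))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname writeLimbAnnotation
#' @export
readLimbAnnotation <- function(path) {
  doc <- yaml::read_yaml(path)
  sk <- doc$skeleton
  boneIds <- unlist(sk$boneIds)
  parents <- unlist(sk$parents)[boneIds]
  parents[parents == "none"] <- NA_character_
  skeleton <- Skeleton(
    boneIds = boneIds,
    parents = parents,
    axes = lapply(sk$axes, function(a)
      cbind(as.numeric(a$x), as.numeric(a$y), as.numeric(a$z)))[boneIds],
    origins = lapply(sk$origins, as.numeric)[boneIds],
    componentMap = unlist(sk$componentMap),
    jointMap = if (length(sk$jointMap)) unlist(sk$jointMap)
               else character(0),
    boneComponent = if (length(sk$boneComponent)) unlist(sk$boneComponent)
                    else character(0),
    jointSurface = lapply(sk$jointSurface, function(js)
      list(component = js$component, idx = as.integer(js$idx))))
  schema <- lapply(doc$landmarks, function(l)
    list(component = l$component, idx = as.integer(l$idx)))
  if (!is.null(doc$groundComponent))
    attr(schema, "groundComponent") <- doc$groundComponent
  list(skeleton = skeleton, schema = schema)
}

#' Write / read a correspondence archive
#'
#' A [CorrespondenceSet-class] as a directory: one PLY per registered
#' component per subject plus a JSON manifest with the subject ids,
#' component names and the per-component similarity transforms.
#'
#' @param cs a [CorrespondenceSet-class].
#' @param dir archive directory (created if needed).
#' @param reference the reference [LimbModel-class] (needed to rebuild the
#'   set when reading).
#' @return `dir` invisibly (`writeCorrespondences`); a
#'   [CorrespondenceSet-class] (`readCorrespondences`).
#' @export
writeCorrespondences <- function(cs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comps <- names(cs@reference@components)
  for (i in seq_along(cs@subjects)) {
    sd <- file.path(dir, cs@subjectIds[i])
    dir.create(sd, showWarnings = FALSE)
    for (nm in comps)
      writeMesh(cs@subjects[[i]][[nm]], file.path(sd, paste0(nm, ".ply")))
  }
  manifest <- list(
    subjects = cs@subjectIds,
    components = comps,
    transforms = lapply(cs@transforms, function(tr)
      lapply(tr, function(T) as.numeric(T))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeCorrespondences
#' @export
readCorrespondences <- function(dir, reference) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  ids <- man$subjects
  comps <- man$components
  subjects <- lapply(ids, function(id) {
    out <- lapply(comps, function(nm)
      readMesh(file.path(dir, id, paste0(nm, ".ply")), name = nm))
    names(out) <- comps
    out
  })
  transforms <- lapply(seq_along(ids), function(i)
    lapply(setNames(comps, comps), function(nm)
      matrix(as.numeric(man$transforms[[i]][[nm]]), 4, 4)))
  new("CorrespondenceSet", reference = reference, subjects = subjects,
      transforms = transforms, subjectIds = ids)
}
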