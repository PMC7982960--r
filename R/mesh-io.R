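## Triangle-mesh readers/writers: PLY (ascii + binary little-endian), OBJ,
## STL (ascii + binary), legacy VTK polydata (ascii). All of them preserve
## the vertex order of the file exactly — vertex index is the correspondence
## carrier — and refuse non-triangular faces.

plyTypeSize <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                 short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                 int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)

plyReadScalar <- function(raw, offset, type) {
  sz <- plyTypeSize[[type]]
  bytes <- raw[(offset + 1L):(offset + sz)]
  val <- switch(type,
    char = , int8 = readBin(bytes, "integer", 1, 1, signed = TRUE),
    uchar = , uint8 = readBin(bytes, "integer", 1, 1, signed = FALSE),
    short = , int16 = readBin(bytes, "integer", 1, 2, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", 1, 2, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(bytes, "integer", 1, 4, endian = "little"),
    float = , float32 = readBin(bytes, "double", 1, 4, endian = "little"),
    double = , float64 = readBin(bytes, "double", 1, 8, endian = "little"),
    stop(sprintf("unsupported PLY property type '%s'", type)))
  list(value = val, offset = offset + sz)
}

readPLY <- function(path, name) {
  raw <- readBin(path, "raw", file.info(path)$size)
  ## locate the header end on the raw bytes (the binary payload may
  ## contain NUL bytes, so no full rawToChar first)
  pos <- grepRaw("end_header\n", raw, fixed = TRUE)
  marker <- 11L
  if (!length(pos)) {
    pos <- grepRaw("end_header\r\n", raw, fixed = TRUE)
    marker <- 12L
  }
  if (!length(pos))
    stop(sprintf("'%s': not a PLY file (no end_header)", path))
  hdrEnd <- pos[1] + marker - 1L
  header <- strsplit(rawToChar(raw[seq_len(hdrEnd)]), "\r?\n")[[1]]
  header <- trimws(header)
  if (!identical(header[1], "ply"))
    stop(sprintf("'%s': not a PLY file", path))
  fmtLine <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(fmtLine, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("'%s': unsupported PLY format '%s'", path, fmt))

  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, countType = tok[3],
                                    type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop(sprintf("'%s': PLY has no vertex element", path))
  if (is.null(elements$face)) stop(sprintf("'%s': PLY has no face element", path))

  if (fmt == "ascii") {
    body <- strsplit(rawToChar(raw[(hdrEnd + 1L):length(raw)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    i <- 0L
    verts <- NULL
    faces <- NULL
    for (el in elements) {
      rows <- body[(i + 1L):(i + el$count)]
      i <- i + el$count
      if (el$name == "vertex") {
        m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
        idx <- match(c("x", "y", "z"), names(el$props))
        if (anyNA(idx)) stop(sprintf("'%s': PLY vertex lacks x/y/z", path))
        verts <- m[, idx, drop = FALSE]
      } else if (el$name == "face") {
        fl <- strsplit(trimws(rows), "\\s+")
        counts <- vapply(fl, function(t) as.integer(t[1]), integer(1))
        bad <- which(counts != 3L)
        if (length(bad))
          stop(sprintf("'%s': face %d is not a triangle (%d vertices)",
                       path, bad[1], counts[bad[1]]))
        faces <- do.call(rbind, lapply(fl, function(t)
          as.integer(t[2:4]))) + 1L
      }
    }
  } else {
    offset <- hdrEnd
    verts <- NULL
    faces <- NULL
    for (el in elements) {
      if (el$name == "vertex") {
        allScalar <- !vapply(el$props, `[[`, logical(1), "list")
        types <- vapply(el$props, `[[`, character(1), "type")
        if (!all(allScalar))
          stop(sprintf("'%s': list property on PLY vertex unsupported", path))
        m <- matrix(0, el$count, length(types))
        for (r in seq_len(el$count)) {
          for (cix in seq_along(types)) {
            res <- plyReadScalar(raw, offset, types[cix])
            m[r, cix] <- res$value
            offset <- res$offset
          }
        }
        idx <- match(c("x", "y", "z"), names(el$props))
        if (anyNA(idx)) stop(sprintf("'%s': PLY vertex lacks x/y/z", path))
        verts <- m[, idx, drop = FALSE]
      } else if (el$name == "face") {
        prop <- el$props[[1]]
        faces <- matrix(0L, el$count, 3)
        for (r in seq_len(el$count)) {
          res <- plyReadScalar(raw, offset, prop$countType)
          offset <- res$offset
          if (res$value != 3L)
            stop(sprintf("'%s': face %d is not a triangle (%d vertices)",
                         path, r, res$value))
          for (cix in 1:3) {
            res <- plyReadScalar(raw, offset, prop$type)
            faces[r, cix] <- res$value
            offset <- res$offset
          }
        }
        faces <- faces + 1L
      } else {
        stop(sprintf("'%s': unsupported binary PLY element '%s'",
                     path, el$name))
      }
    }
  }
  TriangleMesh(verts, faces, name = name)
}

readOBJ <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                 function(t) as.numeric(t[2:4])))
  faces <- lapply(seq_along(flines), function(i) {
    tok <- strsplit(trimws(flines[i]), "\\s+")[[1]][-1]
    if (length(tok) != 3L)
      stop(sprintf("'%s': face %d is not a triangle (%d vertices)",
                   path, i, length(tok)))
    as.integer(vapply(strsplit(tok, "/"), `[[`, character(1), 1))
  })
  TriangleMesh(verts, do.call(rbind, faces), name = name)
}

readSTL <- function(path, name) {
  raw <- readBin(path, "raw", file.info(path)$size)
  probe <- raw[seq_len(min(512L, length(raw)))]
  isAscii <- length(grepRaw("solid", probe, fixed = TRUE)) > 0 &&
    length(grepRaw("facet", probe, fixed = TRUE)) > 0
  if (isAscii) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                   function(t) as.numeric(t[2:4])))
  } else {
    n <- readBin(raw[81:84], "integer", 1, 4, endian = "little")
    ## Each facet record: 12 floats (normal + 3 vertices) + 2 attr bytes.
    ## Parse per record to honor the attribute bytes.
    verts <- matrix(0, n * 3L, 3)
    off <- 84L
    for (f in seq_len(n)) {
      tri <- readBin(raw[(off + 1L):(off + 48L)], "double", 12, size = 4,
                     endian = "little")
      verts[(3L * f - 2L):(3L * f), ] <- matrix(tri[4:12], 3, 3, byrow = TRUE)
      off <- off + 50L
    }
  }
  if (is.null(verts) || nrow(verts) %% 3L != 0L)
    stop(sprintf("'%s': malformed STL", path))
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  TriangleMesh(verts, faces, name = name)
}

readVTK <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^# vtk DataFile", lines[1]))
    stop(sprintf("'%s': not a legacy VTK file", path))
  if (!any(grepl("^ASCII", lines)))
    stop(sprintf("'%s': only ASCII legacy VTK supported", path))
  if (!any(grepl("DATASET\\s+POLYDATA", lines)))
    stop(sprintf("'%s': VTK dataset is not POLYDATA", path))
  pIdx <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(trimws(lines[pIdx]), "\\s+")[[1]][2])
  nums <- numeric(0)
  i <- pIdx + 1L
  while (length(nums) < 3L * np) {
    nums <- c(nums, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  verts <- matrix(nums[seq_len(3L * np)], ncol = 3, byrow = TRUE)
  fIdx <- grep("^POLYGONS", lines)[1]
  nf <- as.integer(strsplit(trimws(lines[fIdx]), "\\s+")[[1]][2])
  ints <- integer(0)
  i <- fIdx + 1L
  while (i <= length(lines) && length(ints) < 4L * nf &&
         !grepl("^[A-Z]", lines[i])) {
    ints <- c(ints, as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  faces <- matrix(0L, nf, 3)
  off <- 0L
  for (f in seq_len(nf)) {
    cnt <- ints[off + 1L]
    if (cnt != 3L)
      stop(sprintf("'%s': face %d is not a triangle (%d vertices)",
                   path, f, cnt))
    faces[f, ] <- ints[(off + 2L):(off + 4L)] + 1L
    off <- off + 4L
  }
  TriangleMesh(verts, faces, name = name)
}

meshFormatFromPath <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ply", "obj", "stl", "vtk"))
    stop(sprintf("cannot infer mesh format from extension '.%s'", ext))
  ext
}

#' Read a triangle mesh
#'
#' Reads PLY (ascii or binary little-endian), OBJ, STL (ascii or binary), or
#' legacy ascii VTK polydata. The vertex order of the file is preserved
#' exactly (no deduplication or reindexing) so that vertex indices can carry
#' anatomical correspondence. Non-triangular faces are a format error that
#' names the offending face.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"ply"`, `"obj"`, `"stl"`, `"vtk"`.
#' @param name component label stored in the mesh; defaults to the file stem.
#' @return A [TriangleMesh-class].
#' @export
readMesh <- function(path, format = "auto",
                     name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: '%s'", path))
  format <- match.arg(format, c("auto", "ply", "obj", "stl", "vtk"))
  if (format == "auto") format <- meshFormatFromPath(path)
  switch(format,
         ply = readPLY(path, name),
         obj = readOBJ(path, name),
         stl = readSTL(path, name),
         vtk = readVTK(path, name))
}

#' Write a triangle mesh
#'
#' @param mesh a [TriangleMesh-class].
#' @param path output path.
#' @param format one of `"auto"`, `"ply"`, `"obj"`, `"stl"`, `"vtk"`.
#' @param binary for PLY/STL: write the binary little-endian flavor.
#' @param digits significant digits for ascii output.
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path, format = "auto", binary = FALSE,
                      digits = 9) {
  stopifnot(is(mesh, "TriangleMesh"))
  format <- match.arg(format, c("auto", "ply", "obj", "stl", "vtk"))
  if (format == "auto") format <- meshFormatFromPath(path)
  V <- mesh@vertices
  F <- mesh@faces
  fmtNum <- function(x) formatC(x, digits = digits, format = "g")
  if (format == "ply") {
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      hdr <- c("ply", "format binary_little_endian 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices", "end_header")
      writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
      writeBin(as.numeric(t(V)), con, size = 4, endian = "little")
      for (f in seq_len(nrow(F))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(F[f, ] - 1L), con, size = 4, endian = "little")
      }
    } else {
      hdr <- c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices", "end_header")
      vl <- apply(V, 1, function(r) paste(fmtNum(r), collapse = " "))
      fl <- apply(F, 1, function(r)
        paste(c(3L, r - 1L), collapse = " "))
      writeLines(c(hdr, vl, fl), path)
    }
  } else if (format == "obj") {
    vl <- apply(V, 1, function(r) paste("v", paste(fmtNum(r), collapse = " ")))
    fl <- apply(F, 1, function(r) paste("f", paste(r, collapse = " ")))
    writeLines(c(vl, fl), path)
  } else if (format == "stl") {
    tri <- V[t(F), , drop = FALSE]
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(raw(80), con)
      writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
      for (f in seq_len(nrow(F))) {
        a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c3 <- V[F[f, 3], ]
        n <- crossProduct3(b - a, c3 - a)
        nn <- sqrt(sum(n^2))
        if (nn > 0) n <- n / nn
        writeBin(as.numeric(c(n, a, b, c3)), con, size = 4,
                 endian = "little")
        writeBin(raw(2), con)
      }
    } else {
      out <- c(sprintf("solid %s", mesh@name))
      for (f in seq_len(nrow(F))) {
        a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c3 <- V[F[f, 3], ]
        n <- crossProduct3(b - a, c3 - a)
        nn <- sqrt(sum(n^2))
        if (nn > 0) n <- n / nn
        out <- c(out,
                 sprintf("  facet normal %s", paste(fmtNum(n), collapse = " ")),
                 "    outer loop",
                 sprintf("      vertex %s", paste(fmtNum(a), collapse = " ")),
                 sprintf("      vertex %s", paste(fmtNum(b), collapse = " ")),
                 sprintf("      vertex %s", paste(fmtNum(c3), collapse = " ")),
                 "    endloop", "  endfacet")
      }
      writeLines(c(out, sprintf("endsolid %s", mesh@name)), path)
    }
  } else if (format == "vtk") {
    out <- c("# vtk DataFile Version 3.0", mesh@name, "ASCII",
             "DATASET POLYDATA",
             sprintf("POINTS %d float", nrow(V)),
             apply(V, 1, function(r) paste(fmtNum(r), collapse = " ")),
             sprintf("POLYGONS %d %d", nrow(F), 4L * nrow(F)),
             apply(F, 1, function(r) paste(c(3L, r - 1L), collapse = " ")))
    writeLines(out, path)
  }
  invisible(path)
}
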