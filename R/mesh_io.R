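# Mesh file input/output: PLY (ascii and binary little-endian) and OBJ, with
# the per-vertex scalar texture stored either as a named PLY vertex property
# (default name "texture") or in a sidecar CSV with header "vertex,value"
# (0-based vertex indices on disk).

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)
.ply_is_float <- c(float = TRUE, float32 = TRUE, double = TRUE, float64 = TRUE)

.ply_read_raw <- function(raw, off, type, n = 1L) {
  sz <- .ply_type_size[[type]]
  what <- if (isTRUE(.ply_is_float[type])) "double" else "integer"
  bytes <- raw[off + seq_len(sz * n)]
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16"))
  # uint/uint32 exceed readBin's signed 4-byte support only above 2^31;
  # mesh indices never get there in practice
  val <- readBin(bytes, what = what, n = n, size = sz,
                 endian = "little", signed = if (sz < 4) signed else TRUE)
  list(value = val, off = off + sz * n)
}

#' Read a textured surface from PLY or OBJ
#'
#' PLY supports both ascii and binary little-endian encodings; the per-vertex
#' texture is taken from a named vertex property (default `"texture"`), from a
#' sidecar CSV (`vertex,value`, 0-based indices), or defaults to zeros.
#'
#' @param path file path.
#' @param format `"ply"`, `"obj"` or `"auto"` (by extension).
#' @param texture_source a PLY vertex-property name, the path of a sidecar
#'   CSV, or `"none"` for a zero texture. The default looks for a property
#'   called `texture` and falls back to zeros.
#' @return a [textured_surface()].
#' @export
read_surface <- function(path, format = c("auto", "ply", "obj"),
                         texture_source = "texture") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  }
  res <- if (format == "ply") read_ply(path) else read_obj(path)
  V <- nrow(res$vertices)
  bad <- which(res$faces < 1L | res$faces > V, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("%s: face record %d references out-of-range vertex %d",
                 path, bad[1, 1], res$faces[bad[1, 1], bad[1, 2]] - 1L))
  mesh <- triangle_mesh(res$vertices, res$faces, validate = FALSE)
  texture <- NULL
  if (is.null(texture_source) || identical(texture_source, "none")) {
    texture <- numeric(V)
  } else if (file.exists(texture_source) &&
             grepl("\\.csv$", texture_source, ignore.case = TRUE)) {
    df <- read.csv(texture_source)
    if (!all(c("vertex", "value") %in% names(df)))
      stop(sprintf("%s: sidecar CSV needs columns vertex,value", texture_source))
    if (nrow(df) != V)
      stop(sprintf("%s: %d texture records for %d vertices",
                   texture_source, nrow(df), V))
    texture <- numeric(V)
    texture[df$vertex + 1L] <- df$value
  } else if (!is.null(res$properties[[texture_source]])) {
    texture <- res$properties[[texture_source]]
  } else if (identical(texture_source, "texture")) {
    texture <- numeric(V)   # default property absent: zero texture
  } else {
    stop(sprintf("%s: no vertex property or sidecar named '%s'",
                 path, texture_source))
  }
  textured_surface(mesh, texture)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii lines
  lines <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop(sprintf("%s: unexpected end of PLY header", path))
    lines <- c(lines, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(lines) > 1000L) stop(sprintf("%s: malformed PLY header", path))
  }
  if (!identical(trimws(lines[1]), "ply"))
    stop(sprintf("%s: not a PLY file", path))
  fmt_line <- grep("^format", lines, value = TRUE)
  if (length(fmt_line) != 1L) stop(sprintf("%s: missing PLY format line", path))
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("%s: unsupported PLY format '%s'", path, fmt))
  # parse element/property declarations
  elements <- list()
  cur <- NULL
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, ctype = tok[3], type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop(sprintf("%s: PLY must declare vertex and face elements", path))

  if (fmt == "ascii") {
    payload <- readLines(con)
    payload <- payload[nzchar(trimws(payload))]
    out <- ply_parse_ascii(elements, payload, path)
  } else {
    raw <- readBin(con, "raw", n = file.size(path))
    out <- ply_parse_binary(elements, raw, path)
  }
  vx <- out$vertex
  need <- c("x", "y", "z")
  if (!all(need %in% names(vx)))
    stop(sprintf("%s: vertex element lacks x/y/z properties", path))
  verts <- cbind(vx$x, vx$y, vx$z)
  faces <- out$face_index + 1L
  props <- vx[setdiff(names(vx), need)]
  list(vertices = verts, faces = faces, properties = props)
}

ply_parse_ascii <- function(elements, payload, path) {
  pos <- 1L
  out <- list()
  for (el in elements) {
    if (el$name == "vertex") {
      rows <- payload[pos:(pos + el$count - 1L)]
      pos <- pos + el$count
      mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
      if (ncol(mat) != length(el$props))
        stop(sprintf("%s: vertex record has wrong field count", path))
      out$vertex <- stats::setNames(lapply(seq_along(el$props),
                                           function(j) mat[, j]),
                                    names(el$props))
    } else if (el$name == "face") {
      rows <- payload[pos:(pos + el$count - 1L)]
      pos <- pos + el$count
      fl <- lapply(strsplit(trimws(rows), "\\s+"), as.integer)
      idx <- lapply(seq_along(fl), function(i) {
        r <- fl[[i]]
        if (r[1] != 3L)
          stop(sprintf("%s: face record %d is not a triangle", path, i))
        r[2:4]
      })
      out$face_index <- do.call(rbind, idx)
    } else {
      pos <- pos + el$count   # skip unknown elements
    }
  }
  out
}

ply_parse_binary <- function(elements, raw, path) {
  off <- 0L
  out <- list()
  for (el in elements) {
    fixed <- !vapply(el$props, function(p) p$list, logical(1))
    if (el$name == "vertex") {
      if (!all(fixed)) stop(sprintf("%s: list-valued vertex property", path))
      sizes <- vapply(el$props, function(p) .ply_type_size[[p$type]], 1L)
      stride <- sum(sizes)
      starts <- off + c(0L, cumsum(sizes))[seq_along(sizes)]
      cols <- vector("list", length(sizes))
      for (j in seq_along(sizes)) {
        p <- el$props[[j]]
        sz <- sizes[j]
        idx <- outer(seq_len(sz), (seq_len(el$count) - 1L) * stride, "+") +
          starts[j]
        cols[[j]] <- .ply_read_raw(raw[as.vector(idx)] , 0L, p$type,
                                   n = el$count)$value
      }
      out$vertex <- stats::setNames(cols, names(el$props))
      off <- off + stride * el$count
    } else if (el$name == "face") {
      lp <- el$props[[1]]
      if (!lp$list) stop(sprintf("%s: face element must be a list property", path))
      csz <- .ply_type_size[[lp$ctype]]
      isz <- .ply_type_size[[lp$type]]
      # fast path: constant arity 3
      stride <- csz + 3L * isz
      counts_idx <- off + (seq_len(el$count) - 1L) * stride
      counts <- .ply_read_raw(raw[as.vector(outer(seq_len(csz), counts_idx, "+"))],
                              0L, lp$ctype, n = el$count)$value
      if (all(counts == 3L)) {
        idx <- outer(seq_len(3L * isz), counts_idx, "+") + csz
        vals <- .ply_read_raw(raw[as.vector(idx)], 0L, lp$type,
                              n = 3L * el$count)$value
        out$face_index <- matrix(vals, ncol = 3, byrow = TRUE)
        off <- off + stride * el$count
      } else {
        bad <- which(counts != 3L)[1]
        stop(sprintf("%s: face record %d is not a triangle", path, bad))
      }
    } else {
      if (el$count > 0L) stop(sprintf("%s: unsupported extra element '%s'",
                                      path, el$name))
    }
  }
  out
}

#' Write a textured surface to PLY or OBJ
#'
#' PLY vertices are written as double precision so that write/read round
#' trips preserve coordinates and texture exactly. For OBJ (which has no
#' per-vertex scalar slot) a non-zero texture is written to a sidecar CSV.
#'
#' @param surface a [textured_surface()] (or bare [triangle_mesh()]).
#' @param path output path.
#' @param format `"ply"`, `"obj"` or `"auto"` (by extension).
#' @param binary write binary little-endian PLY instead of ascii.
#' @param texture_property PLY vertex property name for the texture.
#' @param sidecar path for the OBJ sidecar CSV; default replaces the
#'   extension with `.texture.csv`.
#' @return the path, invisibly.
#' @export
write_surface <- function(surface, path, format = c("auto", "ply", "obj"),
                          binary = FALSE, texture_property = "texture",
                          sidecar = NULL) {
  format <- match.arg(format)
  if (inherits(surface, "triangle_mesh"))
    surface <- textured_surface(surface)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  mesh <- surface$mesh
  V <- nrow(mesh$vertices)
  if (format == "ply") {
    hdr <- c("ply",
             sprintf("format %s 1.0",
                     if (binary) "binary_little_endian" else "ascii"),
             sprintf("element vertex %d", V),
             "property double x", "property double y", "property double z",
             sprintf("property double %s", texture_property),
             sprintf("element face %d", nrow(mesh$faces)),
             "property list uchar int vertex_indices",
             "end_header")
    vx <- cbind(mesh$vertices, surface$texture)
    f0 <- mesh$faces - 1L
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
      writeBin(as.vector(t(vx)), con, size = 8, endian = "little")
      for (i in seq_len(nrow(f0))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f0[i, ]), con, size = 4, endian = "little")
      }
    } else {
      body <- c(apply(vx, 1, function(r)
        paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
              collapse = " ")),
        paste(3L, f0[, 1], f0[, 2], f0[, 3]))
      writeLines(c(hdr, body), path)
    }
  } else {
    lines <- c(sprintf("v %.10g %.10g %.10g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]),
               sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]))
    writeLines(lines, path)
    if (any(surface$texture != 0)) {
      if (is.null(sidecar))
        sidecar <- sub("\\.obj$", ".texture.csv", path, ignore.case = TRUE)
      write.csv(data.frame(vertex = seq_len(V) - 1L, value = surface$texture),
                sidecar, row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L || length(flines) == 0L)
    stop(sprintf("%s: OBJ has no v/f records", path))
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)),
                                          "\\s+"), function(t) as.numeric(t[1:3])))
  faces <- do.call(rbind, lapply(seq_along(flines), function(i) {
    tok <- strsplit(trimws(sub("^f", "", flines[i])), "\\s+")[[1]]
    tok <- sub("/.*$", "", tok)   # drop texture/normal slots
    if (length(tok) != 3L)
      stop(sprintf("%s: face record %d is not a triangle", path, i))
    as.integer(tok)
  }))
  list(vertices = verts, faces = faces, properties = list())  # OBJ is 1-based
}
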