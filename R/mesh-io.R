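#' Read a triangle mesh from OBJ or PLY
#'
#' Parses Wavefront OBJ (`v`/`f` records; texture and normal indices in face
#' records are ignored) or Stanford PLY (ascii and binary_little_endian).
#' Color, texture and other per-vertex payloads are skipped. Quad faces are
#' fan-triangulated by default since scanner exports vary; set
#' `triangulate_quads = FALSE` to reject non-triangular faces instead.
#'
#' @param path file path.
#' @param format `"obj"` or `"ply"`; guessed from the extension when `NULL`.
#' @param triangulate_quads fan-triangulate polygonal faces with more than 3
#'   vertices instead of erroring.
#' @param orient_axis outward orientation axis passed to [triangle_mesh()].
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL, triangulate_quads = TRUE,
                      orient_axis = c(0, 0, 1)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "ply"))
  parsed <- if (format == "obj") parse_obj(path, triangulate_quads)
            else parse_ply(path, triangulate_quads)
  triangle_mesh(parsed$vertices, parsed$faces, orient_axis = orient_axis)
}

parse_obj <- function(path, triangulate_quads) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(sub("^v\\s+", "", vlines), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- fan_triangulate(lapply(strsplit(sub("^f\\s+", "", flines), "\\s+"),
                                  function(tok) {
                                    as.integer(vapply(strsplit(tok, "/"),
                                                      `[`, "", 1))
                                  }), triangulate_quads)
  if (is.null(verts)) verts <- matrix(0, 0, 3)
  list(vertices = verts, faces = faces)
}

fan_triangulate <- function(face_list, triangulate_quads) {
  out <- vector("list", length(face_list))
  for (i in seq_along(face_list)) {
    idx <- face_list[[i]]
    if (length(idx) < 3) stop("face with fewer than 3 vertices")
    if (length(idx) > 3 && !triangulate_quads)
      stop("non-triangular face found and triangulation is disabled")
    k <- length(idx) - 2
    out[[i]] <- cbind(rep(idx[1], k), idx[2:(k + 1)], idx[3:(k + 2)])
  }
  fm <- do.call(rbind, out)
  if (is.null(fm)) fm <- matrix(0L, 0, 3)
  fm
}

ply_type_info <- function(type) {
  switch(type,
    char = , int8 = list(what = "integer", size = 1, signed = TRUE),
    uchar = , uint8 = list(what = "integer", size = 1, signed = FALSE),
    short = , int16 = list(what = "integer", size = 2, signed = TRUE),
    ushort = , uint16 = list(what = "integer", size = 2, signed = FALSE),
    int = , int32 = list(what = "integer", size = 4, signed = TRUE),
    uint = , uint32 = list(what = "integer", size = 4, signed = TRUE),
    float = , float32 = list(what = "numeric", size = 4, signed = TRUE),
    double = , float64 = list(what = "numeric", size = 8, signed = TRUE),
    stop("unsupported PLY scalar type: ", type))
}

parse_ply <- function(path, triangulate_quads) {
  con <- file(path, "rb"); on.exit(close(con))
  # header is always ascii lines terminated by \n
  header <- character()
  repeat {
    line <- readBin(con, "raw", n = 256)
    # read header byte-wise to keep the binary payload position exact
    seek(con, -length(line), origin = "current")
    ln <- character(0)
    buf <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1)
      if (length(b) == 0) stop("unexpected end of PLY header")
      if (b == as.raw(10)) break
      buf <- c(buf, b)
    }
    ln <- trimws(rawToChar(buf))
    header <- c(header, ln)
    if (ln == "end_header") break
    if (length(header) > 1000) stop("PLY header too long")
  }
  if (header[1] != "ply") stop("not a PLY file")
  fmt_line <- header[startsWith(header, "format")]
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  # parse elements/properties
  elements <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop("PLY file has no vertex element")

  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    pos <- 1
    verts <- NULL; faces_raw <- list()
    for (el in elements) {
      if (el$count == 0) next
      chunk <- rest[pos:(pos + el$count - 1)]; pos <- pos + el$count
      toks <- strsplit(trimws(chunk), "\\s+")
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        xi <- match(c("x", "y", "z"), pn)
        if (anyNA(xi)) stop("PLY vertex element lacks x/y/z")
        verts <- t(vapply(toks, function(t) as.numeric(t[xi]), numeric(3)))
      } else if (el$name == "face") {
        faces_raw <- lapply(toks, function(t) {
          n <- as.integer(t[1]); as.integer(t[2:(1 + n)]) + 1L
        })
      }
    }
    faces <- fan_triangulate(faces_raw, triangulate_quads)
  } else {
    verts <- NULL; faces_raw <- list()
    for (el in elements) {
      if (el$name == "vertex") {
        listless <- !any(vapply(el$props, `[[`, TRUE, "list"))
        if (!listless) stop("list property in PLY vertex element unsupported")
        infos <- lapply(el$props, function(p) ply_type_info(p$type))
        pn <- vapply(el$props, `[[`, "", "name")
        vals <- matrix(NA_real_, el$count, length(infos))
        # homogeneous fast path: all properties same type
        sizes <- vapply(infos, `[[`, 0, "size")
        whats <- vapply(infos, `[[`, "", "what")
        if (length(unique(whats)) == 1 && length(unique(sizes)) == 1) {
          raw_all <- readBin(con, whats[1], n = el$count * length(infos),
                             size = sizes[1], endian = "little",
                             signed = infos[[1]]$signed)
          vals <- matrix(as.numeric(raw_all), el$count, length(infos),
                         byrow = TRUE)
        } else {
          for (i in seq_len(el$count))
            for (j in seq_along(infos))
              vals[i, j] <- as.numeric(
                readBin(con, infos[[j]]$what, 1, size = infos[[j]]$size,
                        endian = "little", signed = infos[[j]]$signed))
        }
        xi <- match(c("x", "y", "z"), pn)
        if (anyNA(xi)) stop("PLY vertex element lacks x/y/z")
        verts <- vals[, xi, drop = FALSE]
      } else if (el$name == "face") {
        p <- el$props[[1]]
        if (!p$list) stop("PLY face element must have a list property")
        cti <- ply_type_info(p$count_type); iti <- ply_type_info(p$type)
        faces_raw <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          n <- readBin(con, cti$what, 1, size = cti$size, endian = "little",
                       signed = cti$signed)
          faces_raw[[i]] <- readBin(con, iti$what, n, size = iti$size,
                                    endian = "little", signed = iti$signed) + 1L
        }
      } else {
        stop("unsupported extra element in binary PLY: ", el$name)
      }
    }
    faces <- fan_triangulate(faces_raw, triangulate_quads)
  }
  list(vertices = verts, faces = faces)
}

#' Write a triangle mesh to OBJ or PLY
#'
#' Writes standard ASCII OBJ, or ASCII / binary little-endian PLY. When
#' `vertex_scalars` is supplied (one value per vertex, e.g. a heritability or
#' curvature map), PLY output carries per-vertex `red/green/blue` uchar colors
#' from the viridis colormap (low value = dark violet, high = yellow), and a
#' sidecar CSV `<path>.values.csv` with columns `vertex_id,value` stores the
#' raw numbers; OBJ output writes the sidecar CSV only.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format `"obj"` or `"ply"`; guessed from the extension when `NULL`.
#' @param vertex_scalars optional numeric vector, one value per vertex.
#' @param binary write binary little-endian PLY instead of ascii.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, vertex_scalars = NULL,
                       binary = FALSE) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "ply"))
  if (!is.null(vertex_scalars)) {
    if (length(vertex_scalars) != n_vertices(mesh))
      stop("vertex_scalars must have one value per vertex")
    utils::write.csv(
      data.frame(vertex_id = seq_len(n_vertices(mesh)), value = vertex_scalars),
      paste0(path, ".values.csv"), row.names = FALSE)
  }
  v <- mesh$vertices; f <- mesh$faces
  if (format == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
                 sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), con)
    return(invisible(path))
  }
  cols <- NULL
  if (!is.null(vertex_scalars)) cols <- scalar_colors(vertex_scalars)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z")
  if (!is.null(cols))
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  if (!binary) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    if (is.null(cols)) {
      writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    } else {
      writeLines(sprintf("%.9g %.9g %.9g %d %d %d", v[, 1], v[, 2], v[, 3],
                         cols[, 1], cols[, 2], cols[, 3]), con)
    }
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    for (i in seq_len(nrow(v))) {
      writeBin(as.numeric(v[i, ]), con, size = 4, endian = "little")
      if (!is.null(cols))
        writeBin(as.raw(cols[i, ]), con)
    }
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

# viridis colormap as uchar RGB rows; constant input maps to the low end
scalar_colors <- function(values, palette = "viridis") {
  rng <- range(values)
  t <- if (diff(rng) == 0) rep(0, length(values))
       else (values - rng[1]) / diff(rng)
  ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, palette))
  round(ramp(t))
}
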