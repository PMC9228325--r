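#' Read and write triangulated meshes
#'
#' Formats are selected by file extension: PLY (ASCII or binary
#' little-endian), OBJ (polygon faces are fan-triangulated with a
#' warning) and STL (ASCII or binary; vertices are welded on read).
#' Round trips preserve vertex coordinates to float32 precision (PLY/STL
#' store single precision) and face indices exactly.
#'
#' @param mesh a [mesh3t()] object.
#' @param path file path ending in .ply, .obj or .stl.
#' @param binary write binary PLY/STL (default) or ASCII.
#' @return `read_mesh()` returns a [mesh3t()]; `write_mesh()` returns the
#'   path invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh$vertices, mesh$faces, path, binary = binary),
         obj = write_obj(mesh, path),
         stl = write_stl(mesh, path, binary = binary),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  out <- switch(ext,
                ply = read_ply(path),
                obj = read_obj(path),
                stl = read_stl(path),
                stop("unsupported mesh format: .", ext))
  mesh3t(out$vertices, out$faces)
}

# ------------------------------------------------------------------- PLY

write_ply <- function(V, F = NULL, path, N = NULL, binary = TRUE) {
  nv <- nrow(V)
  nf <- if (is.null(F)) 0L else nrow(F)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment written by heifer3d",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (!is.null(N))
    hdr <- c(hdr, "property float nx", "property float ny", "property float nz")
  if (nf > 0)
    hdr <- c(hdr, sprintf("element face %d", nf),
             "property list uchar int vertex_indices")
  hdr <- c(hdr, "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  vdat <- if (is.null(N)) V else cbind(V, N)
  if (binary) {
    writeBin(as.numeric(t(vdat)), con, size = 4, endian = "little")
    if (nf > 0) {
      # interleave uchar 3 with three int32 per face
      fm <- t(F - 1L)
      for (i in seq_len(nf)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(fm[, i]), con, size = 4, endian = "little")
      }
    }
  } else {
    writeLines(apply(vdat, 1, function(r)
      paste(formatC(r, format = "g", digits = 9), collapse = " ")), con)
    if (nf > 0)
      writeLines(paste(3L, F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  }
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln)) stop("truncated PLY header in ", path)
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  fmt <- sub("^format\\s+(\\S+).*", "\\1", grep("^format", hdr, value = TRUE))
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  # parse elements and their properties in order
  elems <- list()
  cur <- NULL
  for (ln in hdr) {
    if (grepl("^element ", ln)) {
      p <- strsplit(ln, "\\s+")[[1]]
      cur <- p[2]
      elems[[cur]] <- list(count = as.integer(p[3]), props = list())
    } else if (grepl("^property ", ln) && !is.null(cur)) {
      p <- strsplit(ln, "\\s+")[[1]]
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1]] <- p[-1]
    }
  }
  if (is.null(elems$vertex)) stop("PLY without vertex element")
  sizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
             int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
             float = 4, float32 = 4, double = 8, float64 = 8)
  rdscalar <- function(type, n = 1) {
    sz <- sizes[[type]]
    what <- if (type %in% c("float", "float32", "double", "float64"))
      "double" else "integer"
    v <- readBin(con, what, n = n, size = sz, endian = "little",
                 signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    if (length(v) < n)
      stop(sprintf("truncated PLY at byte offset %d in %s", seek(con), path))
    v
  }
  V <- NULL
  Fc <- NULL
  N <- NULL
  for (en in names(elems)) {
    el <- elems[[en]]
    islist <- vapply(el$props, function(p) p[1] == "list", TRUE)
    if (en == "vertex") {
      pn <- vapply(el$props, function(p) p[length(p)], "")
      pt <- vapply(el$props, function(p) p[1], "")
      if (fmt == "ascii") {
        dat <- matrix(scan(con, n = el$count * length(pn), quiet = TRUE),
                      ncol = length(pn), byrow = TRUE)
      } else {
        if (length(unique(pt)) == 1) {
          dat <- matrix(rdscalar(pt[1], el$count * length(pn)),
                        ncol = length(pn), byrow = TRUE)
        } else {
          dat <- matrix(0, el$count, length(pn))
          for (i in seq_len(el$count))
            for (j in seq_along(pt)) dat[i, j] <- rdscalar(pt[j])
        }
      }
      V <- dat[, match(c("x", "y", "z"), pn), drop = FALSE]
      if (all(c("nx", "ny", "nz") %in% pn))
        N <- dat[, match(c("nx", "ny", "nz"), pn), drop = FALSE]
    } else if (en == "face") {
      if (!any(islist)) stop("PLY face element without index list")
      faces <- vector("list", el$count)
      if (fmt == "ascii") {
        for (i in seq_len(el$count)) {
          row <- scan(con, nlines = 1, quiet = TRUE)
          faces[[i]] <- row[seq_len(row[1]) + 1]
        }
      } else {
        lp <- el$props[[which(islist)[1]]]
        for (i in seq_len(el$count)) {
          cnt <- rdscalar(lp[2])
          faces[[i]] <- rdscalar(lp[3], cnt)
        }
      }
      Fc <- fan_triangulate(faces, "PLY")
    } else {
      # skip unknown fixed-size elements (binary only safe when scalar)
      if (fmt == "ascii") scan(con, nlines = el$count, quiet = TRUE)
    }
  }
  list(vertices = V, faces = (Fc %||% matrix(integer(0), 0, 3)) + 1L,
       normals = N)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fan_triangulate <- function(faces, what) {
  sizes <- lengths(faces)
  if (any(sizes < 3)) stop(what, " face with fewer than 3 vertices")
  if (any(sizes > 3))
    warning(sprintf("%d non-triangular %s faces fan-triangulated",
                    sum(sizes > 3), what))
  do.call(rbind, lapply(faces, function(f) {
    if (length(f) == 3) matrix(f, 1) else
      cbind(f[1], f[2:(length(f) - 1)], f[3:length(f)])
  }))
}

# ------------------------------------------------------------------- OBJ

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# written by heifer3d",
               sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]),
               sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3])), con)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  V <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE), ncol = 3,
              byrow = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  faces <- lapply(strsplit(sub("^f ", "", fl), "\\s+"), function(p) {
    idx <- as.integer(sub("/.*", "", p))
    if (any(is.na(idx))) stop("malformed OBJ face")
    idx
  })
  Fc <- fan_triangulate(faces, "OBJ")
  list(vertices = V, faces = Fc)
}

# ------------------------------------------------------------------- STL

write_stl <- function(mesh, path, binary = TRUE) {
  V <- mesh$vertices
  F <- mesh$faces
  N <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw("heifer3d binary STL"), raw(80 - 19)), con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(F))) {
      writeBin(as.numeric(c(N[i, ], t(V[F[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid heifer3d", con)
    for (i in seq_len(nrow(F))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", N[i, 1], N[i, 2],
                           N[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g", V[F[i, ], 1],
                           V[F[i, ], 2], V[F[i, ], 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid heifer3d", con)
  }
  invisible(path)
}

read_stl <- function(path) {
  head <- readBin(path, "raw", n = 80)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") && {
    txt <- readLines(path, n = 2, warn = FALSE)
    length(txt) > 1 && grepl("facet", txt[2])
  }
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    tri <- matrix(scan(text = sub("^\\s*vertex", "", vl), quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    rec <- readBin(con, "raw", n = nf * 50)
    if (length(rec) < nf * 50)
      stop("truncated binary STL at byte ", 84 + length(rec))
    idx <- rep(seq(0, by = 50, length.out = nf), each = 36) +
      rep(13:48, times = nf)
    tri <- matrix(readBin(rec[idx], "double", n = nf * 9, size = 4,
                          endian = "little"), ncol = 3, byrow = TRUE)
  }
  # weld identical vertices (float32 exact match)
  key <- paste(tri[, 1], tri[, 2], tri[, 3])
  uk <- !duplicated(key)
  V <- tri[uk, , drop = FALSE]
  Fc <- matrix(match(key, key[uk]), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = Fc)
}

# ---------------------------------------------------------- point clouds

#' Read and write point clouds
#'
#' PLY clouds carry per-vertex normals (`nx, ny, nz`) when present; XYZ is
#' whitespace-separated text with 3 (or 6, with normals) columns.
#'
#' @param cloud a [point_cloud()].
#' @param path file ending in .ply or .xyz.
#' @param binary write binary PLY.
#' @return `read_point_cloud()` returns a [point_cloud()].
#' @export
write_point_cloud <- function(cloud, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    write_ply(cloud$points, NULL, path, N = cloud$normals, binary = binary)
  } else if (ext == "xyz") {
    dat <- if (is.null(cloud$normals)) cloud$points
           else cbind(cloud$points, cloud$normals)
    utils::write.table(dat, path, row.names = FALSE, col.names = FALSE)
  } else stop("unsupported point-cloud format: .", ext)
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    out <- read_ply(path)
    point_cloud(out$vertices, out$normals)
  } else if (ext == "xyz") {
    dat <- as.matrix(read.table(path))
    if (ncol(dat) >= 6) point_cloud(dat[, 1:3], dat[, 4:6])
    else point_cloud(dat[, 1:3])
  } else stop("unsupported point-cloud format: .", ext)
}

# --------------------------------------------------------------- tables

unit_factor <- function(suffix) {
  switch(suffix,
         m = 1, cm = 1e-2, mm = 1e-3, m2 = 1, m3 = 1, kg = 1,
         stop("unknown unit suffix '_", suffix, "'"))
}

normalize_table <- function(df, id_cols) {
  id_cols <- c(id_cols, "age_days")
  out <- df[, intersect(id_cols, names(df)), drop = FALSE]
  for (nm in setdiff(names(df), id_cols)) {
    parts <- strsplit(nm, "_")[[1]]
    suffix <- parts[length(parts)]
    base <- paste(parts[-length(parts)], collapse = "_")
    if (base == "") {
      out[[nm]] <- df[[nm]]
      next
    }
    v <- df[[nm]] * unit_factor(suffix)
    if (any(v < 0, na.rm = TRUE)) stop("negative values in column ", nm)
    out[[base]] <- v
  }
  if ("age_days" %in% names(out)) names(out)[names(out) == "age_days"] <- "age"
  out
}

#' Read trait and weighing tables
#'
#' CSV columns carry their unit as a suffix (`hg_cm`, `bsa_m2`,
#' `volume_m3`, `bw_kg`, ...); values are normalised to SI on input.
#' Duplicate (animal, age) rows are an error; a missing quality column
#' defaults to 4 with a warning.
#'
#' @param traits_path CSV with `animal_id`, `age_days`, trait columns and
#'   optionally `quality`.
#' @param weights_path CSV with `animal_id`, `age_days`, `bw_kg`.
#' @return list with `traits` and `weights` data.frames in SI units.
#' @export
read_tables <- function(traits_path, weights_path) {
  tr <- normalize_table(read.csv(traits_path), c("animal_id", "quality"))
  wt <- normalize_table(read.csv(weights_path), "animal_id")
  for (df in list(tr, wt))
    if (anyDuplicated(df[, c("animal_id", "age")]))
      stop("duplicate (animal_id, age) rows")
  if (!("quality" %in% names(tr))) {
    warning("no quality column; defaulting all records to score 4")
    tr$quality <- 4L
  }
  list(traits = tr, weights = wt)
}

#' Write a trait table with explicit units
#'
#' @param traits trait records in SI units (as from [measure_all()]).
#' @param path output CSV path.
#' @param units length unit for the linear traits: m, cm or mm.
#' @return the path, invisibly.
#' @export
write_traits <- function(traits, path, units = c("m", "cm", "mm")) {
  units <- match.arg(units)
  f <- 1 / unit_factor(units)
  out <- data.frame(animal_id = traits$animal_id, age_days = traits$age)
  for (tr in c("hg", "wh", "cd", "hw", "kw"))
    if (tr %in% names(traits))
      out[[paste0(tr, "_", units)]] <- traits[[tr]] * f
  if ("bsa" %in% names(traits)) out$bsa_m2 <- traits$bsa
  if ("volume" %in% names(traits)) out$volume_m3 <- traits$volume
  if ("quality" %in% names(traits)) out$quality <- traits$quality
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
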