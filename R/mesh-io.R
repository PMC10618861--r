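# Readers/writers for the three supported mesh formats. Polygonal faces are
# fan-triangulated on read; STL soup is welded back into indexed topology.

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl)) stop("no geometry found in OBJ: ", path)
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  F <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(x) {
    idx <- as.integer(vapply(strsplit(x, "/"), `[`, character(1), 1))
    if (length(idx) < 3) stop("degenerate face in OBJ")
    cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
  }))
  list(vertices = V, faces = F)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L, short = 2L, ushort = 2L,
                   int16 = 2L, uint16 = 2L, int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  nl <- which(raw == as.raw(10L))
  end_pat <- "end_header"
  # locate header end by scanning line starts
  hdr_lines <- character()
  start <- 1L
  body_at <- NA_integer_
  for (p in nl) {
    ln <- rawToChar(raw[start:(p - 1L)])
    ln <- sub("\r$", "", ln)
    hdr_lines <- c(hdr_lines, ln)
    start <- p + 1L
    if (identical(trimws(ln), end_pat)) {
      body_at <- start
      break
    }
  }
  if (is.na(body_at)) stop("no end_header in PLY: ", path)
  if (!identical(trimws(hdr_lines[1]), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()
  cur <- NULL
  for (ln in hdr_lines[-1]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(n = as.integer(tok[3]), props = list())
    }
    if (tok[1] == "property") {
      if (tok[2] == "list") {
        elements[[cur]]$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3],
                                                type = tok[4])
      } else {
        elements[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY lacks vertex/face elements")
  nv <- elements$vertex$n
  nf <- elements$face$n
  vprops <- elements$vertex$props
  if (identical(fmt, "ascii")) {
    rest <- strsplit(rawToChar(raw[body_at:length(raw)]), "\n", fixed = TRUE)[[1]]
    rest <- trimws(rest)
    rest <- rest[nzchar(rest)]
    vtok <- strsplit(rest[seq_len(nv)], "\\s+")
    Vall <- do.call(rbind, lapply(vtok, as.numeric))
    colnames(Vall) <- names(vprops)[seq_len(ncol(Vall))]
    ftok <- strsplit(rest[nv + seq_len(nf)], "\\s+")
    F <- do.call(rbind, lapply(ftok, function(x) {
      k <- as.integer(x[1])
      idx <- as.integer(x[2:(1 + k)]) + 1L
      cbind(idx[1], idx[2:(k - 1)], idx[3:k])
    }))
  } else {
    if (!identical(fmt, "binary_little_endian"))
      stop("unsupported PLY format: ", fmt)
    pos <- body_at
    rd <- function(type, n = 1L) {
      sz <- ply_type_size[[type]]
      bytes <- raw[pos:(pos + n * sz - 1L)]
      pos <<- pos + n * sz
      if (type %in% c("float", "float32", "double", "float64")) {
        readBin(bytes, "double", n, size = sz, endian = "little")
      } else {
        readBin(bytes, "integer", n, size = sz, endian = "little",
                signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
      }
    }
    types <- vapply(vprops, `[[`, character(1), "type")
    if (length(unique(types)) == 1L) {
      Vall <- matrix(rd(types[1], nv * length(vprops)), nv, length(vprops), byrow = TRUE)
    } else {
      Vall <- matrix(0, nv, length(vprops))
      for (i in seq_len(nv))
        for (j in seq_along(vprops)) Vall[i, j] <- rd(types[j])
    }
    colnames(Vall) <- names(vprops)
    fp <- elements$face$props[[1]]
    Flist <- vector("list", nf)
    for (i in seq_len(nf)) {
      k <- rd(fp$count_type)
      idx <- rd(fp$type, k) + 1L
      Flist[[i]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])
    }
    F <- do.call(rbind, Flist)
  }
  list(vertices = Vall[, c("x", "y", "z"), drop = FALSE], faces = F)
}

write_ply <- function(mesh, path, binary = FALSE, scalars = NULL) {
  V <- mesh$vertices
  F <- mesh$faces
  extra <- ""
  if (!is.null(scalars))
    extra <- paste0(sprintf("property float %s\n", names(scalars)), collapse = "")
  hdr <- sprintf(paste0(
    "ply\nformat %s 1.0\nelement vertex %d\n",
    "property double x\nproperty double y\nproperty double z\n%s",
    "element face %d\nproperty list uchar int vertex_indices\nend_header\n"),
    if (binary) "binary_little_endian" else "ascii", nrow(V), extra, nrow(F))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(hdr, con, eos = NULL)
    for (i in seq_len(nrow(V))) {
      writeBin(as.numeric(V[i, ]), con, size = 8, endian = "little")
      if (!is.null(scalars))
        for (s in scalars) writeBin(as.numeric(s[i]), con, size = 4, endian = "little")
    }
    for (i in seq_len(nrow(F))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(F[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeChar(hdr, con, eos = NULL)
    vl <- sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
    if (!is.null(scalars))
      for (s in scalars) vl <- paste(vl, sprintf("%.7g", s))
    writeLines(vl, con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  }
  invisible(path)
}

read_stl <- function(path) {
  # binary STL iff the 84-byte prelude announces a face count matching size
  sz <- file.info(path)$size
  con <- file(path, "rb")
  hdr <- readBin(con, "raw", 80)
  n <- tryCatch(readBin(con, "integer", 1, size = 4, endian = "little"),
                error = function(e) -1L)
  is_binary <- !is.na(n) && length(n) == 1 && (80 + 4 + 50 * as.numeric(n)) == sz
  if (is_binary) {
    tri <- matrix(0, n * 3, 3)
    for (i in seq_len(n)) {
      vals <- readBin(con, "double", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
    close(con)
  } else {
    close(con)
    lines <- trimws(readLines(path, warn = FALSE))
    vl <- lines[startsWith(lines, "vertex")]
    tri <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
    if (is.null(tri) || nrow(tri) %% 3 != 0) stop("malformed ASCII STL")
  }
  # weld duplicate vertices to recover shared topology
  key <- apply(signif(tri, 12), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  V <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F)
}

write_stl <- function(mesh, path, binary = FALSE) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  nrm <- cbind((b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
               (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
               (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(F))) {
      writeBin(as.numeric(c(nrm[i, ], a[i, ], b[i, ], cc[i, ])), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(F))) {
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                   "outer loop",
                   sprintf("vertex %.9g %.9g %.9g", c(a[i, 1], b[i, 1], cc[i, 1]),
                           c(a[i, 2], b[i, 2], cc[i, 2]), c(a[i, 3], b[i, 3], cc[i, 3])),
                   "endloop", "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}
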