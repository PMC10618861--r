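# VertebraMesh container and mesh validation/repair. A mesh is a closed,
# consistently wound triangle surface; it may consist of several disjoint
# closed components (the synthetic vertebrae are rigid assemblies).

#' Construct a vertebra mesh
#'
#' The central mesh container: vertices in millimetres, 1-based triangle
#' indices, an optional name (e.g. "C3") and optional zygapophyseal facet
#' patches given as face-index vectors under the labels `left_pre`,
#' `right_pre`, `left_post`, `right_post`. Patches may be absent on terminal
#' vertebrae.
#'
#' @param vertices n x 3 numeric matrix (mm)
#' @param faces m x 3 integer matrix of 1-based vertex indices
#' @param name vertebra label
#' @param facet_patches named list of integer face-index vectors
#' @param centrum_faces optional face indices of the vertebral body, used by
#'   spacing measurements; when `NULL` the whole mesh stands in
#' @return object of class `vmesh`
#' @export
vertebra_mesh <- function(vertices, faces, name = "", facet_patches = list(),
                          centrum_faces = NULL) {
  vertices <- as_points(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (length(facet_patches)) {
    bad <- vapply(facet_patches, function(fx) {
      length(fx) == 0 || any(fx < 1) || any(fx > nrow(faces))
    }, logical(1))
    if (any(bad))
      stop("invalid facet patch(es): ", paste(names(facet_patches)[bad], collapse = ", "))
    all_f <- unlist(facet_patches)
    if (anyDuplicated(all_f)) stop("facet patches are not pairwise disjoint")
  }
  structure(list(vertices = vertices, faces = faces, name = name,
                 facet_patches = facet_patches, centrum_faces = centrum_faces),
            class = "vmesh")
}

#' @export
print.vmesh <- function(x, ...) {
  cat(sprintf("<vmesh '%s': %d vertices, %d faces, %d facet patches>\n",
              x$name, nrow(x$vertices), nrow(x$faces), length(x$facet_patches)))
  invisible(x)
}

#' Signed volume of a triangle mesh
#'
#' Divergence-theorem volume; positive for consistently outward-wound closed
#' surfaces (summed over components for multi-component meshes).
#'
#' @param mesh a `vmesh`
#' @return volume in cubic mm
#' @export
signed_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# undirected edge table with counts and direction balance
edge_table <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  fwd <- e[, 1] < e[, 2]
  dirbal <- tapply(ifelse(fwd, 1L, -1L), key, sum)
  list(edges = e, key = key, count = cnt, dirbal = dirbal)
}

#' Validate mesh invariants
#'
#' Checks edge-manifoldness (every edge in exactly two faces), consistent
#' outward winding (each undirected edge used once per direction, signed
#' volume positive) and optionally surface self-intersection.
#'
#' @param mesh a `vmesh`
#' @param check_self also run the (slower) self-intersection test
#' @return list with `ok` plus defect counts: `boundary_edges`,
#'   `nonmanifold_edges`, `misoriented_edges`, `signed_volume`,
#'   `self_intersections`
#' @export
validate_mesh <- function(mesh, check_self = FALSE) {
  et <- edge_table(mesh$faces)
  boundary <- sum(et$count == 1)
  nonmanifold <- sum(et$count > 2)
  misoriented <- sum(et$count == 2 & abs(et$dirbal[names(et$count)]) != 0)
  sv <- signed_volume(mesh)
  selfx <- if (check_self) cpp_self_intersections(mesh$vertices, mesh$faces) else 0L
  ok <- boundary == 0 && nonmanifold == 0 && misoriented == 0 && sv > 0 && selfx == 0
  list(ok = ok, boundary_edges = boundary, nonmanifold_edges = nonmanifold,
       misoriented_edges = misoriented, signed_volume = sv,
       self_intersections = selfx)
}

assert_valid_mesh <- function(mesh, check_self = FALSE) {
  d <- validate_mesh(mesh, check_self = check_self)
  if (!d$ok) {
    stop(sprintf(paste0("mesh '%s' failed validation: %d boundary edges, ",
                        "%d non-manifold edges, %d misoriented edges, ",
                        "%d self-intersections, signed volume %.6g"),
                 mesh$name, d$boundary_edges, d$nonmanifold_edges,
                 d$misoriented_edges, d$self_intersections, d$signed_volume))
  }
  invisible(mesh)
}

#' Fill small holes in a mesh
#'
#' Boundary loops shorter than `max_hole_edges` are fan-triangulated with
#' winding consistent with the surrounding surface; larger defects raise an
#' error (they need manual repair, as in any scan-processing pipeline).
#'
#' @param mesh a `vmesh`
#' @param max_hole_edges largest loop length that is filled (default 100)
#' @return repaired `vmesh`
#' @export
repair_mesh <- function(mesh, max_hole_edges = 100) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bnd <- e[key %in% names(cnt)[cnt == 1], , drop = FALSE]
  if (nrow(bnd) == 0) return(mesh)
  # hole boundary must be walked against the existing directed edges
  bnd <- bnd[, c(2, 1), drop = FALSE]
  nxt <- stats::setNames(bnd[, 2], as.character(bnd[, 1]))
  used <- stats::setNames(rep(FALSE, nrow(bnd)), as.character(bnd[, 1]))
  newF <- list()
  for (s in as.character(bnd[, 1])) {
    if (used[[s]]) next
    loop <- as.integer(s)
    cur <- s
    repeat {
      used[[cur]] <- TRUE
      nx <- unname(nxt[cur])
      if (is.na(nx)) stop("open (non-loop) boundary; cannot repair")
      if (nx == loop[1]) break
      loop <- c(loop, nx)
      cur <- as.character(nx)
    }
    if (length(loop) > max_hole_edges)
      stop(sprintf("hole with %d boundary edges exceeds max_hole_edges = %d",
                   length(loop), max_hole_edges))
    if (length(loop) >= 3)
      newF[[length(newF) + 1]] <-
        cbind(loop[1], loop[2:(length(loop) - 1)], loop[3:length(loop)])
  }
  mesh$faces <- rbind(F, do.call(rbind, newF))
  mesh
}

#' Load a vertebra mesh from OBJ, PLY or STL
#'
#' Facet-patch annotations are picked up from a JSON sidecar
#' `<stem>.facets.json` (a map from patch label to 1-based face indices, or
#' from vertebra name to such maps) when present.
#'
#' @param path mesh file (.obj, .ply, .stl)
#' @param validate enforce mesh invariants (error with defect counts if
#'   violated)
#' @param name vertebra label; defaults to the file stem
#' @param annotations optional path to a JSON facet annotation file,
#'   overriding sidecar lookup
#' @return a `vmesh`
#' @export
load_mesh <- function(path, validate = TRUE, name = NULL, annotations = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    obj = read_obj(path),
    ply = read_ply(path),
    stl = read_stl(path),
    stop("unsupported mesh format '", ext, "' (use OBJ, PLY or STL)"))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  patches <- list()
  centrum <- NULL
  if (is.null(annotations)) {
    cand <- paste0(tools::file_path_sans_ext(path), ".facets.json")
    if (file.exists(cand)) annotations <- cand
  }
  if (!is.null(annotations)) {
    ann <- jsonlite::read_json(annotations, simplifyVector = TRUE)
    if (!is.null(ann[[name]])) ann <- ann[[name]]
    centrum <- as.integer(ann[["centrum"]])
    if (length(centrum) == 0) centrum <- NULL
    ann <- ann[names(ann) %in% c("left_pre", "right_pre", "left_post", "right_post")]
    patches <- lapply(ann, as.integer)
  }
  mesh <- vertebra_mesh(raw$vertices, raw$faces, name = name,
                        facet_patches = patches, centrum_faces = centrum)
  if (validate) assert_valid_mesh(mesh)
  mesh
}

#' Write a mesh to OBJ, PLY or STL
#'
#' @param mesh a `vmesh`
#' @param path output file; format chosen by extension
#' @param binary write binary PLY/STL instead of ASCII
#' @param annotations also write the facet sidecar `<stem>.facets.json`
#' @return `path`, invisibly
#' @export
write_mesh <- function(mesh, path, binary = FALSE, annotations = !is.null(mesh$facet_patches) &&
                         length(mesh$facet_patches) > 0) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path, binary = binary),
    stl = write_stl(mesh, path, binary = binary),
    stop("unsupported mesh format '", ext, "'"))
  if (isTRUE(annotations)) {
    ann <- mesh$facet_patches
    if (!is.null(mesh$centrum_faces)) ann$centrum <- mesh$centrum_faces
    jsonlite::write_json(ann, paste0(tools::file_path_sans_ext(path), ".facets.json"))
  }
  invisible(path)
}
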