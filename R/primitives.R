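# Geometric primitives shared across modules: algebraic sphere fitting,
# facet-patch summaries, patch extrusion, and simple closed test meshes.

#' Least-squares sphere fit
#'
#' Algebraic (linear least-squares) fit of a sphere to 3-D points, the
#' estimator used for intervertebral centres of rotation: the sphere is fit
#' to the ventral outline of the postzygapophyseal facets and its centre
#' defines the joint COR. Deterministic, no initialisation.
#'
#' @param points n x 3 matrix, n >= 4, not all coplanar
#' @return list with `center` (length 3), `radius` (mm) and `rms` residual
#' @export
fit_sphere <- function(points) {
  P <- as_points(points)
  if (nrow(P) < 4) stop("sphere fit needs at least 4 points")
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1e-300))
    stop("sphere fit under-determined: points are (nearly) coplanar")
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  r <- sqrt(rowSums(sweep(P, 2, center)^2))
  list(center = unname(center), radius = unname(radius),
       rms = sqrt(mean((r - radius)^2)))
}

face_normals <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Summarise a zygapophyseal facet patch
#'
#' @param mesh a `vmesh` with facet annotations
#' @param label one of `left_pre`, `right_pre`, `left_post`, `right_post`
#' @return a `facet_patch`: parent, side, kind, face indices, area-weighted
#'   centroid, unit mean normal and area (mm^2)
#' @export
facet_patch <- function(mesh, label) {
  fx <- mesh$facet_patches[[label]]
  if (is.null(fx) || !length(fx))
    stop(sprintf("vertebra '%s' has no facet patch '%s'", mesh$name, label))
  F <- mesh$faces[fx, , drop = FALSE]
  V <- mesh$vertices
  n2 <- face_normals(V, F)                       # length = 2 * area
  areas <- sqrt(rowSums(n2^2)) / 2
  area <- sum(areas)
  if (area <= 0) stop("zero-area facet patch '", label, "'")
  cent <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
           V[F[, 3], , drop = FALSE]) / 3
  centroid <- colSums(cent * areas) / area
  mn <- colSums(n2) / 2
  mn <- mn / sqrt(sum(mn^2))
  parts <- strsplit(label, "_")[[1]]
  structure(list(parent = mesh$name, side = parts[1], kind = parts[2], faces = fx,
                 vertices = V[sort(unique(as.vector(F))), , drop = FALSE],
                 face_matrix = F, centroid = centroid, mean_normal = mn, area = area),
            class = "facet_patch")
}

#' Vertices belonging to a facet patch
#'
#' @param mesh a `vmesh`
#' @param labels patch labels (default: both postzygapophyseal patches, the
#'   point set the COR sphere is fitted to)
#' @param boundary_only restrict to the patch boundary ("ventral outline")
#'   vertices instead of the full patch vertex set
#' @return matrix of vertex coordinates
#' @export
patch_vertices <- function(mesh, labels = c("left_post", "right_post"),
                           boundary_only = FALSE) {
  out <- lapply(labels, function(lb) {
    fx <- mesh$facet_patches[[lb]]
    if (is.null(fx)) stop("vertebra '", mesh$name, "' lacks patch '", lb, "'")
    F <- mesh$faces[fx, , drop = FALSE]
    if (boundary_only) {
      e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
      key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      once <- key %in% names(which(table(key) == 1))
      idx <- unique(as.vector(e[once, , drop = FALSE]))
    } else {
      idx <- unique(as.vector(F))
    }
    mesh$vertices[idx, , drop = FALSE]
  })
  do.call(rbind, out)
}

# directed boundary edges of a face subset, in the subset's winding
patch_boundary_edges <- function(F) {
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[key %in% names(which(table(key) == 1)), , drop = FALSE]
}

#' Extrude a facet patch into a closed prism
#'
#' Sweeps the patch surface along a direction to produce a watertight prism:
#' the translated patch on top, the reversed patch at the bottom and side
#' walls along the patch boundary. This is the programmatic stand-in for the
#' manual "duplicate the facet and move it up through the joint space" step
#' used to build articulation test volumes.
#'
#' @param patch a `facet_patch`, or a `vmesh` together with `label`
#' @param direction unit extrusion direction; defaults to the patch mean
#'   normal
#' @param distance extrusion length (mm), > 0
#' @param label patch label when `patch` is a `vmesh`
#' @return closed `vmesh` prism
#' @export
extrude_patch <- function(patch, direction = NULL, distance, label = NULL) {
  if (inherits(patch, "vmesh")) patch <- facet_patch(patch, label)
  if (!inherits(patch, "facet_patch")) stop("need a facet_patch or vmesh + label")
  if (!is.numeric(distance) || distance <= 0) stop("extrusion distance must be > 0")
  if (patch$area <= 0) stop("zero-area patch")
  dir <- if (is.null(direction)) patch$mean_normal else direction / sqrt(sum(direction^2))
  F <- patch$face_matrix
  idx <- sort(unique(as.vector(F)))
  remap <- match(F, idx)
  dim(remap) <- dim(F)
  Vb <- patch$vertices  # note: patch$vertices already subset in this order
  nv <- nrow(Vb)
  Vt <- sweep(Vb, 2, dir * distance, `+`)
  Fb <- remap[, c(1, 3, 2), drop = FALSE]             # bottom, reversed
  Ft <- remap + nv                                    # top, original winding
  be <- patch_boundary_edges(remap)
  walls <- rbind(cbind(be[, 1], be[, 2], be[, 2] + nv),
                 cbind(be[, 1], be[, 2] + nv, be[, 1] + nv))
  vertebra_mesh(rbind(Vb, Vt), rbind(Fb, Ft, walls),
                name = paste0(patch$parent, ":", patch$side, "_", patch$kind, "_prism"))
}

# ------------------------------------------------------------ test shapes

#' Canonical closed meshes
#'
#' `mesh_cube` builds an axis-aligned box; `mesh_icosphere` a subdivided
#' icosahedron (subdiv 0 = 20 faces, each level quadruples). Used as fixture
#' geometry and by the collision-oracle tests.
#'
#' @param center box/sphere centre
#' @param dims box edge lengths (length 3)
#' @param R optional 3x3 rotation applied about the centre
#' @return a `vmesh`
#' @export
mesh_cube <- function(center = c(0, 0, 0), dims = c(1, 1, 1), R = diag(3)) {
  h <- dims / 2
  V <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]), z = c(-h[3], h[3])))
  # vertices ordered (---,+--, -+-, ++-, --+, +-+, -++, +++)
  F <- rbind(c(1, 3, 4), c(1, 4, 2),    # z = -h
             c(5, 6, 8), c(5, 8, 7),    # z = +h
             c(1, 2, 6), c(1, 6, 5),    # y = -h
             c(3, 7, 8), c(3, 8, 4),    # y = +h
             c(1, 5, 7), c(1, 7, 3),    # x = -h
             c(2, 4, 8), c(2, 8, 6))    # x = +h
  V <- sweep(V %*% t(R), 2, center, `+`)
  vertebra_mesh(V, F, name = "cube")
}

#' @param subdiv subdivision level of the icosphere
#' @param radius sphere radius
#' @rdname mesh_cube
#' @export
mesh_icosphere <- function(subdiv = 2, radius = 1, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (V[a, ] + V[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      V <<- rbind(V, m)
      mid_cache[[key]] <- nrow(V)
      nrow(V)
    }
    Fn <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(F))) {
      a <- F[i, 1]; b <- F[i, 2]; cc <- F[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      Fn <- rbind(Fn, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    F <- Fn
  }
  vertebra_mesh(sweep(V * radius, 2, center, `+`), F, name = "icosphere")
}

# rigidly transform every vertex of a mesh
transform_mesh <- function(mesh, T) {
  mesh$vertices <- transform_points(T, mesh$vertices)
  mesh
}

# concatenate closed components into one vmesh, offsetting face indices
merge_components <- function(parts, name = "") {
  nvs <- vapply(parts, function(p) nrow(p$vertices), integer(1))
  nfs <- vapply(parts, function(p) nrow(p$faces), integer(1))
  voff <- cumsum(c(0L, head(nvs, -1)))
  V <- do.call(rbind, lapply(parts, `[[`, "vertices"))
  F <- do.call(rbind, Map(function(p, o) p$faces + o, parts, voff))
  foff <- cumsum(c(0L, head(nfs, -1)))
  patches <- list()
  centrum <- integer(0)
  for (i in seq_along(parts)) {
    for (lb in names(parts[[i]]$facet_patches))
      patches[[lb]] <- c(patches[[lb]], parts[[i]]$facet_patches[[lb]] + foff[i])
    if (!is.null(parts[[i]]$centrum_faces))
      centrum <- c(centrum, parts[[i]]$centrum_faces + foff[i])
  }
  vertebra_mesh(V, F, name = name, facet_patches = patches,
                centrum_faces = if (length(centrum)) centrum else NULL)
}
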