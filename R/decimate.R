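# Quadric-error-metric edge-collapse decimation. Keeps the mesh closed and
# manifold (link-condition + normal-flip guards) and errors out if the
# requested reduction would change the enclosed volume beyond tolerance.

#' Decimate a mesh to a target face count
#'
#' Garland-Heckbert style edge collapses ordered by quadric error. Collapses
#' that would pinch the surface (link condition) or flip triangle normals
#' are skipped, which preserves watertightness. Facet-patch annotations are
#' re-mapped to the nearest surviving faces.
#'
#' @param mesh a `vmesh`
#' @param target_faces requested maximum face count (>= 4)
#' @param vol_tol maximum allowed relative change of signed volume
#'   (default 0.05)
#' @return decimated `vmesh`
#' @export
decimate_mesh <- function(mesh, target_faces, vol_tol = 0.05) {
  if (!is.numeric(target_faces) || target_faces < 4)
    stop("target_faces must be >= 4")
  if (nrow(mesh$faces) <= target_faces) return(mesh)
  vol0 <- signed_volume(mesh)

  V <- mesh$vertices
  F <- mesh$faces
  nv <- nrow(V)
  nf <- nrow(F)
  f_alive <- rep(TRUE, nf)
  v_alive <- rep(TRUE, nv)

  # per-vertex quadrics (4x4), initialised from incident face planes
  Q <- vector("list", nv)
  for (i in seq_len(nv)) Q[[i]] <- matrix(0, 4, 4)
  nrm <- face_normals(V, F)
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, 1e-300)
  dpl <- -rowSums(nrm * V[F[, 1], , drop = FALSE])
  for (i in seq_len(nf)) {
    p <- c(nrm[i, ], dpl[i])
    K <- tcrossprod(p)
    for (v in F[i, ]) Q[[v]] <- Q[[v]] + K
  }

  vf <- vector("list", nv)  # incident alive faces
  for (i in seq_len(nf)) for (v in F[i, ]) vf[[v]] <- c(vf[[v]], i)

  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  E <- unique(e)
  ecost <- rep(NA_real_, nrow(E))
  etarget <- matrix(NA_real_, nrow(E), 3)
  e_alive <- rep(TRUE, nrow(E))

  edge_cost <- function(a, b) {
    Qe <- Q[[a]] + Q[[b]]
    A <- Qe[1:3, 1:3]
    rhs <- -Qe[1:3, 4]
    mid <- (V[a, ] + V[b, ]) / 2
    v <- tryCatch({
      x <- solve(A, rhs)
      if (sum((x - mid)^2) > 4 * sum((V[a, ] - V[b, ])^2)) mid else x
    }, error = function(err) mid)
    h <- c(v, 1)
    list(cost = max(0, drop(h %*% Qe %*% h)), target = v)
  }
  for (i in seq_len(nrow(E))) {
    ec <- edge_cost(E[i, 1], E[i, 2])
    ecost[i] <- ec$cost
    etarget[i, ] <- ec$target
  }

  n_alive_faces <- nf

  neighbors <- function(v) {
    fs <- vf[[v]]
    fs <- fs[f_alive[fs]]
    setdiff(unique(as.vector(F[fs, , drop = FALSE])), v)
  }

  while (n_alive_faces > target_faces) {
    cand <- which(e_alive)
    if (!length(cand)) break
    ord <- cand[order(ecost[cand])]
    collapsed <- FALSE
    for (ei in ord) {
      a <- E[ei, 1]
      b <- E[ei, 2]
      if (!v_alive[a] || !v_alive[b] || a == b) {
        e_alive[ei] <- FALSE
        next
      }
      shared <- intersect(vf[[a]][f_alive[vf[[a]]]], vf[[b]][f_alive[vf[[b]]]])
      if (length(shared) != 2) next  # boundary or non-manifold locally
      third <- setdiff(unique(as.vector(F[shared, , drop = FALSE])), c(a, b))
      if (!setequal(intersect(neighbors(a), neighbors(b)), third)) next  # link cond.
      vnew <- etarget[ei, ]
      # flip / degeneracy guard on surviving incident faces
      aff <- setdiff(unique(c(vf[[a]][f_alive[vf[[a]]]], vf[[b]][f_alive[vf[[b]]]])), shared)
      ok <- TRUE
      for (fi in aff) {
        tri <- F[fi, ]
        P_old <- V[tri, , drop = FALSE]
        P_new <- P_old
        P_new[tri == a | tri == b, ] <- matrix(vnew, sum(tri == a | tri == b), 3,
                                               byrow = TRUE)
        n_old <- crossv(P_old[2, ] - P_old[1, ], P_old[3, ] - P_old[1, ])
        n_new <- crossv(P_new[2, ] - P_new[1, ], P_new[3, ] - P_new[1, ])
        if (sum(n_new^2) < 1e-18 || sum(n_old * n_new) <= 0) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next

      # commit: b merges into a at vnew
      V[a, ] <- vnew
      for (fi in shared) {
        f_alive[fi] <- FALSE
        n_alive_faces <- n_alive_faces - 1
      }
      relabel <- vf[[b]][f_alive[vf[[b]]]]
      for (fi in relabel) F[fi, F[fi, ] == b] <- a
      vf[[a]] <- unique(c(vf[[a]], vf[[b]]))
      v_alive[b] <- FALSE
      Q[[a]] <- Q[[a]] + Q[[b]]
      e_alive[ei] <- FALSE
      # rewire edges touching b, refresh costs around a
      touch_b <- which(e_alive & (E[, 1] == b | E[, 2] == b))
      for (ti in touch_b) {
        x <- if (E[ti, 1] == b) E[ti, 2] else E[ti, 1]
        if (x == a) {
          e_alive[ti] <- FALSE
        } else {
          E[ti, ] <- c(min(a, x), max(a, x))
        }
      }
      # drop duplicate edges around a
      around <- which(e_alive & (E[, 1] == a | E[, 2] == a))
      if (length(around) > 1) {
        key <- paste(E[around, 1], E[around, 2])
        e_alive[around[duplicated(key)]] <- FALSE
        around <- around[!duplicated(key)]
      }
      for (ti in around) {
        ec <- edge_cost(E[ti, 1], E[ti, 2])
        ecost[ti] <- ec$cost
        etarget[ti, ] <- ec$target
      }
      collapsed <- TRUE
      break
    }
    if (!collapsed) break
  }

  keepf <- which(f_alive)
  keepv <- sort(unique(as.vector(F[keepf, , drop = FALSE])))
  Fnew <- matrix(match(F[keepf, ], keepv), ncol = 3)
  Vnew <- V[keepv, , drop = FALSE]

  out <- vertebra_mesh(Vnew, Fnew, name = mesh$name)
  d <- validate_mesh(out)
  if (d$boundary_edges > 0 || d$nonmanifold_edges > 0 || d$misoriented_edges > 0)
    stop(sprintf("decimation broke watertightness (%d boundary, %d non-manifold edges)",
                 d$boundary_edges, d$nonmanifold_edges))
  vol1 <- d$signed_volume
  if (abs(vol1 - vol0) > vol_tol * abs(vol0))
    stop(sprintf("decimation changed volume by %.1f%% (tolerance %.1f%%)",
                 100 * abs(vol1 - vol0) / abs(vol0), 100 * vol_tol))

  # re-map annotations to nearest surviving face centroids
  remap_faces <- function(fx) {
    oldc <- (mesh$vertices[mesh$faces[fx, 1], , drop = FALSE] +
             mesh$vertices[mesh$faces[fx, 2], , drop = FALSE] +
             mesh$vertices[mesh$faces[fx, 3], , drop = FALSE]) / 3
    newc <- (Vnew[Fnew[, 1], , drop = FALSE] + Vnew[Fnew[, 2], , drop = FALSE] +
             Vnew[Fnew[, 3], , drop = FALSE]) / 3
    unique(vapply(seq_len(nrow(oldc)), function(i) {
      which.min(colSums((t(newc) - oldc[i, ])^2))
    }, integer(1)))
  }
  taken <- integer(0)
  patches <- list()
  for (lb in names(mesh$facet_patches)) {
    fx <- setdiff(remap_faces(mesh$facet_patches[[lb]]), taken)
    if (!length(fx)) stop("facet patch '", lb, "' lost during decimation")
    patches[[lb]] <- fx
    taken <- c(taken, fx)
  }
  out$facet_patches <- patches
  if (!is.null(mesh$centrum_faces)) out$centrum_faces <- remap_faces(mesh$centrum_faces)
  out
}

crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
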