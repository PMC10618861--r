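# Quantitative outputs: cosine-corrected pose space, alpha-shape volumes
# with the critical-alpha fallback, per-axis extrema, whole-chain sums,
# maximum neck-turn composition and spherical frame projection export.

#' Cosine-correct Euler pose coordinates
#'
#' Removes the distortion of Euler-angle space under the package's rotation
#' order (roll first, then yaw, then pitch): at yaw = +/-90 deg the roll and
#' pitch axes coincide, so equal roll displacements near extreme yaw span
#' less orientation space. The corrected coordinates are
#' (roll * cos(yaw), yaw, pitch), still in degrees, which makes pose-space
#' volumes comparable across joints. Yaw beyond +/-90 deg triggers a warning
#' and clamps the cosine at 0.
#'
#' @param poses n x 3 matrix of (roll, yaw, pitch) degrees
#' @return n x 3 matrix of corrected coordinates
#' @export
cosine_correct <- function(poses) {
  P <- matrix(as.numeric(as.matrix(poses)), ncol = 3)
  cy <- cos(deg2rad(P[, 2]))
  if (any(abs(P[, 2]) > 90)) {
    warning("yaw beyond +/-90 degrees: cosine clamped at 0")
    cy <- pmax(cy, 0)
  }
  out <- cbind(roll = P[, 1] * cy, yaw = P[, 2], pitch = P[, 3])
  out
}

#' Total corrected volume of a pose grid
#'
#' Sums the cosine-corrected volumes of all grid cells (midpoint rule over
#' yaw). Over the full Euler grid roll, pitch in [-180, 180] and yaw in
#' [-90, 90] this approaches the analytic 360 * 360 * (360 / pi) cubed
#' degrees, the total orientation-space volume.
#'
#' @param grid a [pose_grid()]
#' @return volume in cubed degrees
#' @export
corrected_grid_volume <- function(grid) {
  s <- grid$step
  yaxis <- grid_axis(grid$yaw, s)
  ymid <- (head(yaxis, -1) + tail(yaxis, -1)) / 2
  roll_extent <- diff(range(grid_axis(grid$roll, s)))
  pitch_extent <- diff(range(grid_axis(grid$pitch, s)))
  roll_extent * pitch_extent * sum(cos(deg2rad(ymid)) * s)
}

# circumradii and volumes of tetrahedra on the original coordinates
tet_metrics <- function(P, tets) {
  a <- P[tets[, 1], , drop = FALSE]
  b <- P[tets[, 2], , drop = FALSE] - a
  cc <- P[tets[, 3], , drop = FALSE] - a
  d <- P[tets[, 4], , drop = FALSE] - a
  det3v <- function(u, v, w) {
    u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
      u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
      u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
  }
  D <- 2 * det3v(b, cc, d)
  rb <- rowSums(b^2)
  rc <- rowSums(cc^2)
  rd <- rowSums(d^2)
  ux <- (rb * (cc[, 2] * d[, 3] - cc[, 3] * d[, 2]) -
         b[, 2] * (rc * d[, 3] - cc[, 3] * rd) +
         b[, 3] * (rc * d[, 2] - cc[, 2] * rd))
  uy <- (b[, 1] * (rc * d[, 3] - cc[, 3] * rd) -
         rb * (cc[, 1] * d[, 3] - cc[, 3] * d[, 1]) +
         b[, 3] * (cc[, 1] * rd - rc * d[, 1]))
  uz <- (b[, 1] * (cc[, 2] * rd - rc * d[, 2]) -
         b[, 2] * (cc[, 1] * rd - rc * d[, 1]) +
         rb * (cc[, 1] * d[, 2] - cc[, 2] * d[, 1]))
  vol <- abs(D / 2) / 6
  r <- sqrt(ux^2 + uy^2 + uz^2) / abs(D)
  r[!is.finite(r)] <- Inf
  list(radius = r, volume = vol)
}

# deterministic sub-resolution jitter to put grid-like data into general
# position before triangulating; combinatorics only, metrics are computed
# on the original coordinates
general_position_jitter <- function(P, eps) {
  n <- nrow(P)
  h <- function(k) {
    x <- sin(seq_len(n) * 12.9898 + k * 78.233) * 43758.5453
    (x - floor(x)) - 0.5
  }
  P + eps * cbind(h(1), h(2), h(3))
}

#' Alpha-shape volume of a 3-D point set
#'
#' Delaunay-based alpha complex: tetrahedra with circumradius at most the
#' alpha radius are retained and their volumes summed. If the critical alpha
#' (the smallest alpha radius whose shape encloses all points as one solid
#' region) exceeds the preset alpha, the critical value is used instead --
#' the fallback used when a preset alpha of 50 degrees would leave points
#' outside the hull.
#'
#' @param points n x 3 matrix (for ROM work: cosine-corrected poses, deg)
#' @param alpha preset alpha radius (default 50)
#' @return list: `volume` (cubed units), `alpha_used`, `critical_alpha`,
#'   `n_tets` retained
#' @export
alpha_shape_volume <- function(points, alpha = 50) {
  P <- unique(as_points(points))
  if (nrow(P) < 4) {
    warning("fewer than 4 distinct points: alpha-shape volume is 0")
    return(list(volume = 0, alpha_used = alpha, critical_alpha = NA_real_, n_tets = 0L))
  }
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc, nu = 0, nv = 0)$d
  scale <- max(sv[1], 1e-12)
  if (sv[3] < 1e-9 * scale) {
    warning("points are (nearly) coplanar: alpha-shape volume is 0")
    return(list(volume = 0, alpha_used = alpha, critical_alpha = NA_real_, n_tets = 0L))
  }
  span <- max(apply(P, 2, function(x) diff(range(x))))
  Pj <- general_position_jitter(P, 1e-7 * span)
  dt <- cpp_delaunay3(Pj)
  tets <- dt$tets
  tm <- tet_metrics(P, tets)
  # flat slivers are artefacts of the symbolic perturbation of cospherical /
  # coplanar inputs: they carry no volume and, in the unperturbed limit, are
  # part of the interface between their neighbours -- so they participate in
  # coverage/connectivity from alpha = 0 on and never gate the filter
  sliver <- tm$volume < 1e-9 * span^3
  tm$radius[sliver] <- 0
  ord <- order(tm$radius)

  # critical alpha: smallest circumradius threshold at which every input
  # point is a vertex of some retained tet and the retained tets form a
  # single face-connected solid
  m <- nrow(tets)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  face_key <- function(t, f) {
    v <- sort(tets[t, -f])
    paste(v[1], v[2], v[3])
  }
  face_owner <- new.env(hash = TRUE, parent = emptyenv())
  covered <- rep(FALSE, nrow(P))
  n_cov <- 0L
  n_comp <- 0L
  critical <- Inf
  for (k in seq_len(m)) {
    t <- ord[k]
    n_comp <- n_comp + 1L
    for (v in tets[t, ]) {
      if (!covered[v]) {
        covered[v] <- TRUE
        n_cov <- n_cov + 1L
      }
    }
    for (f in 1:4) {
      key <- face_key(t, f)
      o <- face_owner[[key]]
      if (is.null(o)) {
        face_owner[[key]] <- t
      } else {
        ra <- find(o)
        rb <- find(t)
        if (ra != rb) {
          parent[ra] <- rb
          n_comp <- n_comp - 1L
        }
      }
    }
    if (n_cov == nrow(P) && n_comp == 1L) {
      critical <- tm$radius[t]
      break
    }
  }
  alpha_used <- max(alpha, critical)
  keep <- tm$radius <= alpha_used * (1 + 1e-12)
  list(volume = sum(tm$volume[keep]), alpha_used = alpha_used,
       critical_alpha = critical, n_tets = sum(keep))
}

#' Summarise one joint's viable pose set
#'
#' @param records pose records from [sweep_joint()]
#' @param joint joint label (defaults to the records' attribute)
#' @param alpha preset alpha radius for the ROM volume
#' @return a `rom_envelope`: viable and cosine-corrected pose sets, the
#'   alpha-shape volume (cubed degrees), alpha used, and per-axis extrema of
#'   the raw viable angles
#' @export
rom_envelope <- function(records, joint = attr(records, "joint"), alpha = 50) {
  viable <- as.matrix(records[records$viable == 1, c("roll", "yaw", "pitch")])
  if (nrow(viable) == 0) {
    warning("joint ", joint, " has no viable poses")
    ext <- data.frame(axis = c("roll", "yaw", "pitch"), min = 0, max = 0)
    return(structure(list(joint = joint, viable_poses = viable,
                          corrected_poses = viable, alpha_used = alpha,
                          critical_alpha = NA_real_, volume = 0, extrema = ext),
                     class = "rom_envelope"))
  }
  corrected <- cosine_correct(viable)
  asv <- suppressWarnings(alpha_shape_volume(corrected, alpha))
  ext <- data.frame(axis = c("roll", "yaw", "pitch"),
                    min = apply(viable, 2, min), max = apply(viable, 2, max))
  structure(list(joint = joint, viable_poses = viable, corrected_poses = corrected,
                 alpha_used = asv$alpha_used, critical_alpha = asv$critical_alpha,
                 volume = asv$volume, extrema = ext),
            class = "rom_envelope")
}

#' @export
print.rom_envelope <- function(x, ...) {
  cat(sprintf("<rom_envelope %s: %d viable poses, volume %.0f deg^3 (alpha %.1f)>\n",
              x$joint, nrow(x$viable_poses), x$volume, x$alpha_used))
  invisible(x)
}

#' Per-axis extrema and whole-chain summed ROM
#'
#' Sums the per-joint signed extrema of each rotation axis over the chain
#' (maximal viable rotations of the interacting sweep, summed across all
#' joints), the whole-neck mobility summary.
#'
#' @param envelopes list of `rom_envelope`, one per joint
#' @return a `chain_summary`: per-joint extrema table plus `summed_pos`,
#'   `summed_neg` and `summed_range` per axis
#' @export
extrema_and_sums <- function(envelopes) {
  if (!length(envelopes)) stop("need at least one joint envelope")
  per_joint <- do.call(rbind, lapply(envelopes, function(e) {
    cbind(data.frame(joint = e$joint), e$extrema)
  }))
  ax <- c("roll", "yaw", "pitch")
  pos <- vapply(ax, function(a) sum(per_joint$max[per_joint$axis == a]), numeric(1))
  neg <- vapply(ax, function(a) sum(per_joint$min[per_joint$axis == a]), numeric(1))
  structure(list(per_joint = per_joint, volumes = vapply(envelopes, `[[`,
                                                         numeric(1), "volume"),
                 summed_pos = pos, summed_neg = neg, summed_range = pos - neg),
            class = "chain_summary")
}

#' @export
print.chain_summary <- function(x, ...) {
  cat("<chain_summary>\n  summed range (deg):",
      sprintf("roll %.1f, yaw %.1f, pitch %.1f", x$summed_range["roll"],
              x$summed_range["yaw"], x$summed_range["pitch"]), "\n")
  invisible(x)
}

#' Compose the maximum neck-turn pose
#'
#' For each joint picks the viable pose with maximal deflection by the
#' priority yaw, then roll, then pitch (lexicographic argmax), holds
#' excluded joints at ONP (the joint-exclusion experiment used to emulate a
#' reduced cervical count), poses the whole chain and reports -- but does
#' not enforce -- whole-chain self-collisions between non-adjacent
#' vertebrae.
#'
#' @param chain a `vchain`
#' @param envelopes list of `rom_envelope` aligned with the chain's joints
#' @param exclude_joints joint labels (or indices) held at ONP
#' @return list: `poses` (n_joints x 3), `transforms`, `summed` per axis,
#'   `self_collisions` (data.frame of colliding non-adjacent vertebra pairs)
#' @export
max_turn_pose <- function(chain, envelopes, exclude_joints = character()) {
  nj <- length(chain$joints)
  if (length(envelopes) != nj) stop("need one envelope per joint")
  excl <- if (is.numeric(exclude_joints)) as.integer(exclude_joints)
          else match(exclude_joints,
                     vapply(seq_len(nj), function(j) joint_label(chain, j), character(1)))
  poses <- matrix(0, nj, 3, dimnames = list(NULL, c("roll", "yaw", "pitch")))
  for (j in seq_len(nj)) {
    if (j %in% excl) next
    vp <- envelopes[[j]]$viable_poses
    if (nrow(vp) == 0) stop("joint ", j, " has an empty viable set")
    ord <- order(-vp[, "yaw"], -vp[, "roll"], -vp[, "pitch"])
    poses[j, ] <- vp[ord[1], ]
  }
  tf <- pose_chain(chain, poses)
  n <- length(chain$vertebrae)
  world <- lapply(seq_len(n), function(k) transform_mesh(chain$vertebrae[[k]], tf[[k]]))
  hits <- list()
  for (a in seq_len(n - 2)) {
    for (b in (a + 2):n) {
      if (cpp_meshes_intersect(world[[a]]$vertices, world[[a]]$faces,
                               world[[b]]$vertices, world[[b]]$faces))
        hits[[length(hits) + 1]] <- data.frame(a = world[[a]]$name, b = world[[b]]$name)
    }
  }
  list(poses = poses, transforms = tf, summed = colSums(poses),
       self_collisions = if (length(hits)) do.call(rbind, hits)
                         else data.frame(a = character(), b = character()))
}

#' Export a spherical frame projection point cloud
#'
#' Maps every viable pose to the direction of the rotated joint long-axis on
#' the unit sphere, with the roll angle attached as a per-point scalar, and
#' optionally writes a PLY point cloud for external viewing.
#'
#' @param envelope a `rom_envelope`
#' @param frame the corresponding `joint_frame`
#' @param path optional output PLY path
#' @return n x 4 matrix (x, y, z, roll), invisibly when writing
#' @export
sfp_export <- function(envelope, frame, path = NULL) {
  vp <- envelope$viable_poses
  if (nrow(vp) == 0) stop("empty viable set")
  dirs <- t(apply(vp, 1, function(p) {
    as.numeric(frame$axes %*% joint_rotation(p[1], p[2], p[3]) %*% c(1, 0, 0))
  }))
  out <- cbind(dirs, roll = vp[, "roll"])
  colnames(out) <- c("x", "y", "z", "roll")
  if (!is.null(path)) {
    m <- list(vertices = dirs, faces = matrix(integer(0), 0, 3))
    write_ply(m, path, binary = FALSE, scalars = list(roll = vp[, "roll"]))
    return(invisible(out))
  }
  out
}

#' Principal-axis slope of the roll-yaw coupling
#'
#' Convenience metric: slope of the first principal axis of the viable
#' (roll, yaw) scatter, quantifying how tightly roll and yaw interact
#' (values near 1 indicate strongly coupled, diagonally oriented pose
#' spaces).
#'
#' @param envelope a `rom_envelope`
#' @return slope dyaw/droll of the first principal component
#' @export
roll_yaw_slope <- function(envelope) {
  vp <- envelope$viable_poses
  if (nrow(vp) < 3) return(NA_real_)
  pc <- prcomp(vp[, c("roll", "yaw")])
  unname(pc$rotation[2, 1] / pc$rotation[1, 1])
}
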