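# Vertebral chains: osteological neutral pose (ONP), joint coordinate
# systems at sphere-fit centres of rotation, hierarchical forward
# kinematics, and intervertebral spacing control.

submesh <- function(mesh, faces) {
  F <- mesh$faces[faces, , drop = FALSE]
  idx <- sort(unique(as.vector(F)))
  list(vertices = mesh$vertices[idx, , drop = FALSE],
       faces = matrix(match(F, idx), ncol = 3))
}

centrum_submesh <- function(mesh) {
  if (!is.null(mesh$centrum_faces)) return(submesh(mesh, mesh$centrum_faces))
  list(vertices = mesh$vertices, faces = mesh$faces)
}

#' Build a joint coordinate frame
#'
#' The centre of rotation is the centre of a sphere fitted to the
#' postzygapophyseal facet outline of the anterior (cranial) vertebra. Axes:
#' x along the caudal-to-cranial series direction (roll), y dorsal (yaw),
#' z latero-lateral (pitch), right-handed. Positive angles are clockwise
#' roll seen from anterior, yaw to the right, dorsal pitch.
#'
#' @param anterior anterior vertebra `vmesh`, already placed (e.g. in ONP)
#' @param posterior posterior vertebra `vmesh`; used for the series
#'   direction (may be `NULL` when `x_hint` is given)
#' @param x_hint explicit series direction (caudal to cranial)
#' @param up dorsal reference direction (default +y)
#' @param boundary_only fit the sphere to the facet boundary ("ventral
#'   outline") vertices only, rather than the full patch vertex set
#' @return a `joint_frame`: `cor`, `axes` (3x3, columns x/y/z), vertebra
#'   names, `fit_radius`, `fit_rms`
#' @export
build_joint_frame <- function(anterior, posterior = NULL, x_hint = NULL,
                              up = c(0, 1, 0), boundary_only = FALSE) {
  pts <- patch_vertices(anterior, c("left_post", "right_post"),
                        boundary_only = boundary_only)
  fit <- fit_sphere(pts)
  if (is.null(x_hint)) {
    if (is.null(posterior)) stop("need posterior vertebra or x_hint for the long axis")
    x_hint <- colMeans(anterior$vertices) - colMeans(posterior$vertices)
  }
  x <- x_hint / sqrt(sum(x_hint^2))
  y <- up - sum(up * x) * x
  ny <- sqrt(sum(y^2))
  if (ny < 1e-9) stop("up direction is parallel to the long axis")
  y <- y / ny
  z <- crossv(x, y)
  axes <- cbind(x, y, z)
  structure(list(cor = fit$center, axes = axes,
                 anterior = anterior$name,
                 posterior = if (is.null(posterior)) NA_character_ else posterior$name,
                 fit_radius = fit$radius, fit_rms = fit$rms),
            class = "joint_frame")
}

#' Assemble a vertebral chain
#'
#' Vertebrae are ordered caudal to cranial; joint j connects vertebra j
#' (posterior) to vertebra j+1 (anterior). Joint frames are fitted from the
#' meshes as placed by `onp_transforms`. With `check_onp` the all-zero pose
#' is verified to be viable (collision-free and articulated on both sides)
#' at every joint.
#'
#' @param vertebrae list of `vmesh` in local coordinates
#' @param onp_transforms list of 4x4 rigid transforms placing each vertebra
#'   in the osteological neutral pose
#' @param spacing optional data.frame of per-joint gaps (filled by
#'   [measure_spacing()] if omitted)
#' @param check_onp verify ONP viability
#' @return object of class `vchain`
#' @export
vertebral_chain <- function(vertebrae, onp_transforms, spacing = NULL,
                            check_onp = TRUE) {
  n <- length(vertebrae)
  stopifnot(n >= 2, length(onp_transforms) == n)
  world <- Map(transform_mesh, vertebrae, onp_transforms)
  joints <- vector("list", n - 1)
  for (j in seq_len(n - 1)) {
    joints[[j]] <- build_joint_frame(world[[j + 1]], world[[j]])
  }
  chain <- structure(list(vertebrae = vertebrae, onp_transforms = onp_transforms,
                          joints = joints, spacing = spacing), class = "vchain")
  if (is.null(spacing)) chain$spacing <- measure_spacing(chain)
  if (check_onp) {
    for (j in seq_len(n - 1)) {
      rec <- classify_pose(chain, j, c(0, 0, 0))
      if (!rec$viable)
        stop(sprintf(paste0("ONP invariant violated at joint %d (%s): ",
                            "collision_free=%d articulated L/R=%d/%d"),
                     j, joint_label(chain, j), rec$collision_free,
                     rec$articulated_left, rec$articulated_right))
    }
  }
  chain
}

#' @export
print.vchain <- function(x, ...) {
  cat(sprintf("<vchain: %d vertebrae, %d joints (%s)>\n", length(x$vertebrae),
              length(x$joints),
              paste(vapply(seq_along(x$joints), function(j) joint_label(x, j),
                           character(1)), collapse = ", ")))
  invisible(x)
}

joint_label <- function(chain, j) {
  paste0(chain$vertebrae[[j]]$name, "-", chain$vertebrae[[j + 1]]$name)
}

joint_index <- function(chain, joint) {
  if (is.numeric(joint)) return(as.integer(joint))
  labs <- vapply(seq_along(chain$joints), function(j) joint_label(chain, j), character(1))
  j <- match(joint, labs)
  if (is.na(j)) stop("unknown joint '", joint, "'; have: ", paste(labs, collapse = ", "))
  j
}

# world-placed mesh of vertebra k under given per-vertebra transforms
world_mesh <- function(chain, k, transforms = chain$onp_transforms) {
  transform_mesh(chain$vertebrae[[k]], transforms[[k]])
}

#' Forward kinematics of a chain
#'
#' Composes per-joint rotations hierarchically: actuating joint j rigidly
#' moves every vertebra cranial to j and leaves caudal vertebrae untouched.
#' All-zero input reproduces the ONP transforms exactly.
#'
#' @param chain a `vchain`
#' @param joint_angles (n_joints x 3) matrix of (roll, yaw, pitch) degrees,
#'   or a vector of length 3 * n_joints
#' @return list of per-vertebra 4x4 world transforms
#' @export
pose_chain <- function(chain, joint_angles) {
  nj <- length(chain$joints)
  A <- matrix(joint_angles, ncol = 3)
  if (nrow(A) != nj)
    stop(sprintf("expected %d joint angle triples, got %d", nj, nrow(A)))
  out <- vector("list", nj + 1)
  out[[1]] <- chain$onp_transforms[[1]]
  Acc <- diag(4)
  for (j in seq_len(nj)) {
    if (all(A[j, ] == 0)) {
      G <- diag(4)
    } else {
      G <- joint_pose_transform(chain$joints[[j]]$cor, chain$joints[[j]]$axes,
                                A[j, 1], A[j, 2], A[j, 3])
    }
    Acc <- Acc %*% G
    out[[j + 1]] <- Acc %*% chain$onp_transforms[[j + 1]]
  }
  out
}

#' Measure intervertebral spacing
#'
#' Per joint: minimum distance between the adjacent centra (`body_gap`),
#' minimum distance between the facing zygapophyseal facets (`zyg_gap`), and
#' both normalised by the posterior vertebra's centrum length.
#'
#' @param chain a `vchain`
#' @return data.frame, one row per joint
#' @export
measure_spacing <- function(chain) {
  n <- length(chain$vertebrae)
  rows <- lapply(seq_len(n - 1), function(j) {
    post <- world_mesh(chain, j)
    ant <- world_mesh(chain, j + 1)
    cb <- centrum_submesh(post)
    ca <- centrum_submesh(ant)
    body_gap <- cpp_min_distance(ca$vertices, ca$faces, cb$vertices, cb$faces)
    pre <- submesh(post, unlist(post$facet_patches[c("left_pre", "right_pre")]))
    pst <- submesh(ant, unlist(ant$facet_patches[c("left_post", "right_post")]))
    zyg_gap <- cpp_min_distance(pst$vertices, pst$faces, pre$vertices, pre$faces)
    x <- chain$joints[[j]]$axes[, 1]
    ext <- range(cb$vertices %*% x)
    L <- diff(ext)
    data.frame(joint = joint_label(chain, j), body_gap = body_gap, zyg_gap = zyg_gap,
               centrum_length = L, body_ratio = body_gap / L, zyg_ratio = zyg_gap / L)
  })
  do.call(rbind, rows)
}

#' Adjust intervertebral spacing to target ratios
#'
#' Translates each vertebra (and everything cranial to it) within the joint
#' x-y plane so that the measured body gap and zygapophyseal gap match the
#' requested fractions of the posterior centrum length. The ONP invariants
#' are re-checked after placement.
#'
#' @param chain a `vchain`
#' @param body_gap_ratio,zyg_gap_ratio target gap / centrum-length fractions
#'   (> 0)
#' @param tol acceptable absolute deviation of the achieved ratios
#' @return re-spaced `vchain`
#' @export
set_spacing <- function(chain, body_gap_ratio, zyg_gap_ratio, tol = 0.01) {
  if (body_gap_ratio <= 0 || zyg_gap_ratio <= 0) stop("spacing ratios must be > 0")
  n <- length(chain$vertebrae)
  onp <- chain$onp_transforms
  for (j in seq_len(n - 1)) {
    post <- transform_mesh(chain$vertebrae[[j]], onp[[j]])
    cb <- centrum_submesh(post)
    pre <- submesh(post, unlist(post$facet_patches[c("left_pre", "right_pre")]))
    x <- chain$joints[[j]]$axes[, 1]
    y <- chain$joints[[j]]$axes[, 2]
    L <- diff(range(cb$vertices %*% x))
    measure <- function(d) {
      Tj <- rigid_transform(diag(3), d[1] * x + d[2] * y)
      ant <- transform_mesh(chain$vertebrae[[j + 1]], Tj %*% onp[[j + 1]])
      ca <- centrum_submesh(ant)
      pst <- submesh(ant, unlist(ant$facet_patches[c("left_post", "right_post")]))
      c(body = cpp_min_distance(ca$vertices, ca$faces, cb$vertices, cb$faces),
        zyg = cpp_min_distance(pst$vertices, pst$faces, pre$vertices, pre$faces))
    }
    obj <- function(d) {
      g <- measure(d)
      (g[1] / L - body_gap_ratio)^2 + (g[2] / L - zyg_gap_ratio)^2
    }
    fit <- optim(c(0, 0), obj, method = "Nelder-Mead",
                 control = list(maxit = 120, reltol = 1e-10))
    g <- measure(fit$par)
    if (any(g <= 1e-9) ||
        abs(g[1] / L - body_gap_ratio) > tol || abs(g[2] / L - zyg_gap_ratio) > tol)
      stop(sprintf(paste0("requested spacing infeasible at joint %s: achieved ",
                          "ratios (%.3f, %.3f) vs targets (%.3f, %.3f)"),
                   joint_label(chain, j), g[1] / L, g[2] / L, body_gap_ratio,
                   zyg_gap_ratio))
    shift <- rigid_transform(diag(3), fit$par[1] * x + fit$par[2] * y)
    for (k in (j + 1):n) onp[[k]] <- shift %*% onp[[k]]
  }
  out <- vertebral_chain(chain$vertebrae, onp, check_onp = TRUE)
  out$ground_truth <- chain$ground_truth
  out
}

# ------------------------------------------------------------------- ONP

# 2-D silhouette overlap of two face sets after dropping one coordinate.
# Symmetric containment fraction (Dice-like), estimated from fixed
# barycentric sample points weighted by projected triangle area.
silhouette_overlap <- function(VA, FA, VB, FB, drop_axis) {
  keep <- setdiff(1:3, drop_axis)
  A2 <- VA[, keep, drop = FALSE]
  B2 <- VB[, keep, drop = FALSE]
  bary <- rbind(c(1, 1, 1) / 3,
                c(2, 1, 1) / 4, c(1, 2, 1) / 4, c(1, 1, 2) / 4,
                c(4, 1, 1) / 6, c(1, 4, 1) / 6, c(1, 1, 4) / 6)
  samples <- function(P2, F) {
    a <- P2[F[, 1], , drop = FALSE]
    b <- P2[F[, 2], , drop = FALSE]
    cc <- P2[F[, 3], , drop = FALSE]
    ar <- abs((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
              (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])) / 2
    pts <- lapply(seq_len(nrow(bary)), function(i) {
      bary[i, 1] * a + bary[i, 2] * b + bary[i, 3] * cc
    })
    list(pts = do.call(rbind, pts), w = rep(ar, nrow(bary)))
  }
  inside_frac <- function(S, P2, F) {
    if (sum(S$w) <= 0) return(0)
    a <- P2[F[, 1], , drop = FALSE]
    b <- P2[F[, 2], , drop = FALSE]
    cc <- P2[F[, 3], , drop = FALSE]
    P <- S$pts
    inside <- rep(FALSE, nrow(P))
    for (t in seq_len(nrow(F))) {
      d1 <- (P[, 1] - a[t, 1]) * (b[t, 2] - a[t, 2]) - (P[, 2] - a[t, 2]) * (b[t, 1] - a[t, 1])
      d2 <- (P[, 1] - b[t, 1]) * (cc[t, 2] - b[t, 2]) - (P[, 2] - b[t, 2]) * (cc[t, 1] - b[t, 1])
      d3 <- (P[, 1] - cc[t, 1]) * (a[t, 2] - cc[t, 2]) - (P[, 2] - cc[t, 2]) * (a[t, 1] - cc[t, 1])
      inside <- inside | (d1 <= 0 & d2 <= 0 & d3 <= 0) | (d1 >= 0 & d2 >= 0 & d3 >= 0)
    }
    sum(S$w[inside]) / sum(S$w)
  }
  SA <- samples(A2, FA)
  SB <- samples(B2, FB)
  (inside_frac(SA, B2, FB) + inside_frac(SB, A2, FA)) / 2
}

#' Refine the osteological neutral pose of one joint
#'
#' Finds the rigid transform of the anterior vertebra that maximises the
#' summed overlap of the facing zygapophyseal facet silhouettes projected
#' onto the sagittal, frontal and transverse planes, without bone
#' interpenetration. The optimiser is a local refiner around
#' `initial_guess` (derivative-free Nelder-Mead over 3 rotations + 3
#' translations about the postzygapophyseal sphere centre); a rough manual
#' placement remains the caller's responsibility, as it was in the original
#' workflow. Because silhouette overlap alone is flat when one facet's
#' silhouette sits fully inside the other, a small tangential
#' centroid-alignment term breaks the tie toward centred facets.
#'
#' @param anterior anterior vertebra `vmesh` (will be moved)
#' @param posterior posterior vertebra `vmesh` (fixed)
#' @param initial_guess 4x4 rigid starting transform for the anterior
#'   vertebra
#' @param overlap_floor minimum acceptable mean overlap fraction
#' @param maxit Nelder-Mead iteration budget per restart
#' @return list: `transform` (4x4), `overlap` (mean silhouette overlap in
#'   [0,1]), `score` (full objective), `par` (rot deg / trans mm)
#' @export
align_onp <- function(anterior, posterior, initial_guess = diag(4),
                      overlap_floor = 0.5, maxit = 250) {
  for (lb in c("left_post", "right_post"))
    if (is.null(anterior$facet_patches[[lb]]))
      stop("anterior vertebra lacks patch '", lb, "'")
  for (lb in c("left_pre", "right_pre"))
    if (is.null(posterior$facet_patches[[lb]]))
      stop("posterior vertebra lacks patch '", lb, "'")

  ant0 <- transform_mesh(anterior, initial_guess)
  pivot <- fit_sphere(patch_vertices(ant0, c("left_post", "right_post")))$center

  pre <- lapply(c(left = "left_pre", right = "right_pre"), function(lb)
    facet_patch(posterior, lb))
  pre_sub <- lapply(pre, function(p) list(V = p$vertices, F = {
    idx <- sort(unique(as.vector(p$face_matrix)))
    matrix(match(p$face_matrix, idx), ncol = 3)
  }))

  score_fn <- function(par, with_dice = TRUE) {
    R <- rot_x(par[1]) %*% rot_y(par[2]) %*% rot_z(par[3])
    T <- rigid_transform(diag(3), par[4:6]) %*% rotation_about(R, pivot)
    moved <- transform_mesh(ant0, T)
    total <- 0
    tangential <- 0
    gap_spread <- 0
    for (side in c("left", "right")) {
      pp <- facet_patch(moved, paste0(side, "_post"))
      if (with_dice) {
        idx <- sort(unique(as.vector(pp$face_matrix)))
        Fp <- matrix(match(pp$face_matrix, idx), ncol = 3)
        for (ax in 1:3)
          total <- total + silhouette_overlap(pp$vertices, Fp,
                                              pre_sub[[side]]$V, pre_sub[[side]]$F, ax)
      }
      d <- pp$centroid - pre[[side]]$centroid
      nrm <- pre[[side]]$mean_normal
      dt <- d - sum(d * nrm) * nrm
      tangential <- tangential + sum(dt^2)
      # a congruently seated facet pair has uniform clearance across the
      # facet; the spread of the point-to-facet distances pins the pose
      # where silhouette overlap alone is flat
      gd <- cpp_points_mesh_distance(pp$vertices, pre_sub[[side]]$V,
                                     pre_sub[[side]]$F)
      gap_spread <- gap_spread + stats::var(gd)
    }
    pen <- if (cpp_meshes_intersect(moved$vertices, moved$faces, posterior$vertices,
                                    posterior$faces)) 10 else 0
    total - 30 * tangential - 400 * gap_spread - pen
  }

  best <- list(par = rep(0, 6), value = score_fn(rep(0, 6)))
  for (restart in 1:2) {
    fit <- optim(best$par, function(p) -score_fn(p), method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10,
                                parscale = c(1, 1, 1, 0.2, 0.2, 0.2) /
                                  restart^2))
    if (-fit$value > best$value) best <- list(par = fit$par, value = -fit$value)
  }
  # polish on the smooth terms only (tangential centroid alignment and gap
  # uniformity): their joint optimum is the congruently seated pose, and
  # dropping the piecewise-constant silhouette term lets Nelder-Mead converge
  # tightly instead of stalling on its plateaus
  smooth_fn <- function(p) -score_fn(p, with_dice = FALSE)
  for (scale in c(1, 0.25)) {
    fit <- optim(best$par, smooth_fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12,
                                parscale = scale * c(0.5, 0.5, 0.5, 0.1, 0.1, 0.1)))
    best$par <- fit$par
  }
  par <- best$par
  R <- rot_x(par[1]) %*% rot_y(par[2]) %*% rot_z(par[3])
  T <- rigid_transform(diag(3), par[4:6]) %*% rotation_about(R, pivot) %*% initial_guess
  # mean silhouette overlap over 6 plane/side combinations
  moved <- transform_mesh(anterior, T)
  overlap <- 0
  for (side in c("left", "right")) {
    pp <- facet_patch(moved, paste0(side, "_post"))
    idx <- sort(unique(as.vector(pp$face_matrix)))
    Fp <- matrix(match(pp$face_matrix, idx), ncol = 3)
    for (ax in 1:3)
      overlap <- overlap + silhouette_overlap(pp$vertices, Fp, pre_sub[[side]]$V,
                                              pre_sub[[side]]$F, ax) / 6
  }
  if (overlap < overlap_floor)
    stop(sprintf("ONP refinement failed: overlap %.2f below floor %.2f", overlap,
                 overlap_floor))
  list(transform = T, overlap = overlap, score = best$value, par = par)
}
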