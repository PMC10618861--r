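# Parametric generator of stylised, watertight vertebra meshes and
# articulated fixture chains. Vertebrae are rigid assemblies of closed
# components (centrum, spinous process, four zygapophyseal plates) rather
# than anatomically continuous bones; what matters for osteological ROM is
# the contact geometry the paper identifies as ROM-governing: caudally
# angled centrum faces, pre/postzygapophyseal facet length and width,
# anterior facet tilt, dorsal lateral ridges on the prezygapophyses, and
# spinous processes. Both postzygapophyseal facets of a vertebra lie exactly
# on one sphere centred at the intended joint COR, so rotations about that
# COR slide the facets along the articular sphere -- the geometric rationale
# for the sphere-fit COR.

#' Parameters of a synthetic vertebra
#'
#' All lengths in mm, angles in degrees. Defaults describe a mid-cervical
#' vertebra of a small arboreal mammal (centrum roughly 12 x 8 mm).
#'
#' @param centrum_length,centrum_radius centrum cylinder dimensions
#' @param centrum_face_tilt tilt of the cranial centrum face about the
#'   latero-lateral axis, pivoted at its dorsal edge; 0 = square faces,
#'   > 0 = caudally angled ventral edge (conical, cranially tapering side
#'   view)
#' @param prezyg_length,postzyg_length cranio-caudal arc length of the
#'   articular facets
#' @param facet_tilt anterior tilt of the facet patch centre away from
#'   vertical
#' @param facet_width lateral (arc) width of the articular facets
#' @param lateral_ridge_height height of the dorsally pointing lateral ridge
#'   on the prezygapophyses (0 disables the ridge)
#' @param facet_sphere_radius radius of the postzygapophyseal articular
#'   sphere; its centre is the intended COR
#' @param spinous_height,spinous_length,spinous_lean,spinous_halfwidth
#'   spinous process slab dimensions; the slab leans caudally by
#'   `spinous_lean` degrees
#' @param neural_canal_radius vertical clearance between centrum and neural
#'   arch/spinous base
#' @param cor_height height of the COR above the centrum axis
#' @param plate_thickness radial thickness of the zygapophyseal plates
#' @param facet_lateral_angle lateral angle of the facet patch centre seen
#'   from the COR
#' @param ridge_width,ridge_clearance lateral extent of the ridge wedge and
#'   the articular-free strip between facet and ridge
#' @param n_centrum_segments,facet_nu,facet_nv tessellation density
#' @param seed reserved for noisy variants; the noise-free generator is
#'   fully deterministic
#' @return list of class `vertebra_params`
#' @export
vertebra_params <- function(centrum_length = 12, centrum_radius = 4,
                            centrum_face_tilt = 15, prezyg_length = 5,
                            postzyg_length = 4, facet_tilt = 20, facet_width = 3.5,
                            lateral_ridge_height = 1.2, facet_sphere_radius = 6,
                            spinous_height = 7, spinous_length = 6, spinous_lean = 15,
                            spinous_halfwidth = 0.3, neural_canal_radius = 1.5,
                            cor_height = 4.5, plate_thickness = 1,
                            facet_lateral_angle = 45, ridge_width = 2,
                            ridge_clearance = 0.3, n_centrum_segments = 24,
                            facet_nu = 5, facet_nv = 4, seed = 1L) {
  p <- as.list(environment())
  lens <- c("centrum_length", "centrum_radius", "prezyg_length", "postzyg_length",
            "facet_width", "facet_sphere_radius", "spinous_height", "spinous_length",
            "neural_canal_radius", "plate_thickness")
  for (nm in lens) if (p[[nm]] <= 0) stop(nm, " must be > 0")
  for (nm in c("centrum_face_tilt", "facet_tilt"))
    if (p[[nm]] < 0 || p[[nm]] > 60) stop(nm, " must be within [0, 60] degrees")
  if (p$lateral_ridge_height < 0) stop("lateral_ridge_height must be >= 0")
  class(p) <- "vertebra_params"
  p
}

# articular geometry shared by the two vertebrae of one joint; derived from
# the posterior (caudal) vertebra's parameters
joint_spec <- function(p_post, p_ant = p_post, body_gap_ratio = 0.10,
                       zyg_gap_ratio = 0.05) {
  L <- p_post$centrum_length
  body_gap <- body_gap_ratio * L
  # the cranial face's dorsal edge stays at +L/2, so the dorsal body gap
  # equals the axial gap regardless of face tilt
  list(R = p_post$facet_sphere_radius,
       g = zyg_gap_ratio * L,
       body_gap = body_gap,
       axial_gap = body_gap,
       facet_tilt = p_post$facet_tilt,
       facet_width = p_post$facet_width,
       lateral_angle = p_post$facet_lateral_angle,
       prezyg_length = p_post$prezyg_length,
       postzyg_length = p_ant$postzyg_length,
       ridge_height = p_post$lateral_ridge_height,
       ridge_width = p_post$ridge_width,
       ridge_clearance = p_post$ridge_clearance,
       plate_thickness = p_post$plate_thickness,
       cor_height = p_post$cor_height)
}

# direction from the COR to the sphere point at craniocaudal angle u and
# lateral angle v (degrees); t = anterior facet tilt
facet_dir <- function(u, v, t) {
  a <- deg2rad(t + u)
  b <- deg2rad(v)
  cbind(sin(a) * cos(b), cos(a) * cos(b), sin(b))
}

# closed slab between two (nu+1) x (nv+1) vertex grids (outer above inner).
# Returns V, F and the outer/inner face index ranges.
grid_shell <- function(Vout, Vin, nu, nv) {
  idx <- function(i, j) (j - 1L) * (nu + 1L) + i
  quads <- expand.grid(i = seq_len(nu), j = seq_len(nv))
  a <- idx(quads$i, quads$j)
  b <- idx(quads$i + 1L, quads$j)
  cc <- idx(quads$i + 1L, quads$j + 1L)
  d <- idx(quads$i, quads$j + 1L)
  Ftop <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  n <- nrow(Vout)
  Fbot <- Ftop[, c(1, 3, 2)] + n
  be <- patch_boundary_edges(Ftop)
  walls <- rbind(cbind(be[, 1] + n, be[, 2] + n, be[, 2]),
                 cbind(be[, 1] + n, be[, 2], be[, 1]))
  V <- rbind(Vout, Vin)
  F <- rbind(Ftop, Fbot, walls)
  m <- vertebra_mesh(V, F)
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  list(mesh = m, outer = seq_len(nrow(Ftop)), inner = nrow(Ftop) + seq_len(nrow(Fbot)))
}

# spherical slab between radii r_out (outer grid, radius may vary by lateral
# column) and r_in around `cor`
sphere_slab <- function(cor, t, us, vs, r_out_col, r_in, nu) {
  grid_pts <- function(radii_by_col) {
    P <- matrix(0, (nu + 1) * length(vs), 3)
    for (j in seq_along(vs)) {
      d <- facet_dir(us, vs[j], t)
      P[(j - 1L) * (nu + 1L) + seq_len(nu + 1L), ] <-
        sweep(d * radii_by_col[j], 2, cor, `+`)
    }
    P
  }
  grid_shell(grid_pts(r_out_col), grid_pts(rep(r_in, length(vs))), nu,
             length(vs) - 1L)
}

# zygapophyseal plate on the articular sphere around `cor`.
# kind "pre": articular surface is the OUTER surface at radius R - g
#   (facing away from the COR).
# kind "post": articular surface is the INNER surface at radius R
#   (facing the COR).
zyg_plate <- function(cor, spec, kind, arc_length, nu, nv) {
  R_art <- if (kind == "post") spec$R else spec$R - spec$g
  t <- spec$facet_tilt
  du <- (arc_length / spec$R) * 180 / pi
  dv <- (spec$facet_width / spec$R) * 180 / pi
  v0 <- spec$lateral_angle - dv / 2
  us <- seq(-du / 2, du / 2, length.out = nu + 1)
  vs <- seq(v0, v0 + dv, length.out = nv + 1)
  r_out <- if (kind == "post") R_art + spec$plate_thickness else R_art
  r_in <- if (kind == "post") R_art else R_art - spec$plate_thickness
  sh <- sphere_slab(cor, t, us, vs, rep(r_out, length(vs)), r_in, nu)
  art_faces <- if (kind == "post") sh$inner else sh$outer
  list(mesh = sh$mesh, articular_faces = art_faces)
}

# dorsally pointing lateral ridge of the prezygapophysis: a wedge lateral of
# the articular facet whose top rises from the facet level to ridge height
# across its width, and which runs longer cranio-caudally than the facet
# itself (as the ridges do along the pedicles). The wedge profile makes the
# roll contact angle decrease smoothly as the ridge gets taller.
ridge_wedge <- function(cor, spec, nu) {
  R_base <- spec$R - spec$g
  t <- spec$facet_tilt
  du <- 1.8 * (spec$prezyg_length / spec$R) * 180 / pi
  dv <- (spec$facet_width / spec$R) * 180 / pi
  dvc <- (spec$ridge_clearance / spec$R) * 180 / pi
  dvr <- (spec$ridge_width / spec$R) * 180 / pi
  v1 <- spec$lateral_angle + dv / 2
  us <- seq(-du / 2, du / 2, length.out = nu + 1)
  vs <- c(v1 + dvc, v1 + dvc + dvr / 2, v1 + dvc + dvr)
  r_out <- R_base + spec$ridge_height * c(0, 0.5, 1)
  sphere_slab(cor, t, us, vs, r_out, R_base - spec$plate_thickness, nu)$mesh
}

# mirror a component through the sagittal plane (z = 0)
mirror_z <- function(mesh) {
  mesh$vertices[, 3] <- -mesh$vertices[, 3]
  mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

centrum_mesh <- function(p) {
  n <- p$n_centrum_segments
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  y <- p$centrum_radius * cos(th)
  z <- p$centrum_radius * sin(th)
  # conical centrum: caudal face square, cranial face pivoted about its
  # dorsal edge so the ventral edge is angled caudally ("caudally angled
  # ventral edges"); tilt strictly removes ventral material
  tn <- tan(deg2rad(p$centrum_face_tilt))
  L <- p$centrum_length
  r <- p$centrum_radius
  xc <- rep(-L / 2, length(y))
  xr <- L / 2 - (r - y) * tn
  V <- rbind(cbind(xc, y, z), cbind(xr, y, z), c(-L / 2, 0, 0),
             c(L / 2 - r * tn, 0, 0))
  cc <- 2L * n + 1L
  cr <- 2L * n + 2L
  i1 <- seq_len(n)
  i2 <- c(seq_len(n)[-1], 1L)
  F <- rbind(cbind(i1, n + i1, n + i2),
             cbind(i1, n + i2, i2),
             cbind(cc, i1, i2),
             cbind(cr, n + i2, n + i1))
  m <- vertebra_mesh(V, F)
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m$centrum_faces <- seq_len(nrow(m$faces))
  m
}

# neural-arch roof: the transverse bony bridge between pedicles. Mostly
# inert at moderate poses, but it restores enough bone continuity that
# extreme combined poses collide instead of slipping through the gaps of the
# stylised assembly.
arch_mesh <- function(p) {
  y1 <- p$centrum_radius + 2 * p$neural_canal_radius - 0.15
  y0 <- y1 - 1.5
  x0 <- -0.3 * p$centrum_length
  x1 <- 0.3 * p$centrum_length
  w <- 0.4 * p$centrum_radius
  V <- rbind(c(x0, y0, -w), c(x1, y0, -w), c(x0, y1, -w), c(x1, y1, -w),
             c(x0, y0, w), c(x1, y0, w), c(x0, y1, w), c(x1, y1, w))
  m <- vertebra_mesh(V, mesh_cube()$faces)
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

spinous_mesh <- function(p) {
  y0 <- p$centrum_radius + 2 * p$neural_canal_radius
  y1 <- y0 + p$spinous_height
  x1 <- 0
  x0 <- x1 - p$spinous_length
  lean <- p$spinous_height * tan(deg2rad(p$spinous_lean))
  w <- p$spinous_halfwidth
  # vertex order follows mesh_cube: (---,+--,-+-,++-,--+,+-+,-++,+++) in (x,y,z)
  V <- rbind(c(x0, y0, -w), c(x1, y0, -w), c(x0 - lean, y1, -w), c(x1 - lean, y1, -w),
             c(x0, y0, w), c(x1, y0, w), c(x0 - lean, y1, w), c(x1 - lean, y1, w))
  F <- mesh_cube()$faces
  m <- vertebra_mesh(V, F)
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Generate a synthetic vertebra
#'
#' Builds a watertight, bilaterally mirror-symmetric vertebra mesh with
#' annotated facet patches and known articular geometry. The postzygapophyseal
#' facets lie exactly on a sphere of radius `facet_sphere_radius` centred at
#' the intended caudal joint COR, so `fit_sphere` recovers the ground truth.
#'
#' @param params a [vertebra_params()] list
#' @param name vertebra label
#' @param caudal_joint,cranial_joint joint geometry from [joint_spec()]
#'   (internal), `TRUE` for a default spec derived from `params`, or `FALSE`
#'   to omit the corresponding facet plates (terminal vertebrae)
#' @param body_gap_ratio,zyg_gap_ratio default joint spacing as fractions of
#'   centrum length, used when joint specs are derived from `params`
#' @param check run the full validity check (watertight, symmetric,
#'   self-intersection free); disable inside tight loops
#' @return a `vmesh`; attribute `ground_truth` holds the local COR positions,
#'   sphere radius and gap sizes
#' @export
make_vertebra <- function(params = vertebra_params(), name = "V",
                          caudal_joint = TRUE, cranial_joint = TRUE,
                          body_gap_ratio = 0.10, zyg_gap_ratio = 0.05,
                          check = TRUE) {
  p <- params
  if (isTRUE(caudal_joint)) caudal_joint <- joint_spec(p, p, body_gap_ratio, zyg_gap_ratio)
  if (isTRUE(cranial_joint)) cranial_joint <- joint_spec(p, p, body_gap_ratio, zyg_gap_ratio)
  has_cd <- is.list(caudal_joint)
  has_cr <- is.list(cranial_joint)
  L <- p$centrum_length

  parts <- list()
  patches <- list()
  face_off <- 0L
  push <- function(mesh, art_label = NULL, art_faces = NULL) {
    parts[[length(parts) + 1L]] <<- mesh
    if (!is.null(art_label)) patches[[art_label]] <<- art_faces + face_off
    face_off <<- face_off + nrow(mesh$faces)
  }

  push(centrum_mesh(p))
  push(spinous_mesh(p))
  push(arch_mesh(p))

  cor_cd <- cor_cr <- NULL
  if (has_cd) {
    s <- caudal_joint
    cor_cd <- c(-L / 2 - s$axial_gap / 2, s$cor_height, 0)
    pl <- zyg_plate(cor_cd, s, "post", s$postzyg_length, p$facet_nu, p$facet_nv)
    push(pl$mesh, "left_post", pl$articular_faces)
    mir <- mirror_z(pl$mesh)
    push(mir, "right_post", pl$articular_faces)
  }
  if (has_cr) {
    s <- cranial_joint
    cor_cr <- c(L / 2 + s$axial_gap / 2, s$cor_height, 0)
    pl <- zyg_plate(cor_cr, s, "pre", s$prezyg_length, p$facet_nu, p$facet_nv)
    push(pl$mesh, "left_pre", pl$articular_faces)
    mir <- mirror_z(pl$mesh)
    push(mir, "right_pre", pl$articular_faces)
    if (s$ridge_height > 0) {
      rw <- ridge_wedge(cor_cr, s, p$facet_nu)
      push(rw)
      push(mirror_z(rw))
    }
  }

  mesh <- merge_components(parts, name = name)
  mesh$facet_patches <- patches

  if (check) {
    d <- validate_mesh(mesh, check_self = TRUE)
    if (!d$ok) {
      if (d$self_intersections > 0)
        stop(sprintf(paste0("parameter combination produces self-intersecting ",
                            "geometry (%d crossing triangle pairs); reduce facet/",
                            "ridge extent or increase clearances"),
                     d$self_intersections))
      stop("generated mesh failed validation")
    }
  }
  attr(mesh, "ground_truth") <- list(
    cor_caudal = cor_cd, cor_cranial = cor_cr,
    facet_sphere_radius = if (has_cd) caudal_joint$R else NA_real_,
    caudal_joint = if (has_cd) caudal_joint else NULL,
    cranial_joint = if (has_cr) cranial_joint else NULL,
    params = p)
  mesh
}

#' Recipe for a synthetic fixture chain
#'
#' @param n_vertebrae chain length, caudal to cranial (>= 2); a CC8 neck
#'   minus C1 corresponds to 7 vertebrae / 6 joints
#' @param params base [vertebra_params()]
#' @param body_gap_ratio,zyg_gap_ratio joint spacing as fractions of the
#'   posterior vertebra's centrum length
#' @param param_overrides optional list: `param_overrides[[k]]` is a named
#'   list of parameter changes for vertebra k (cranio-caudal gradients)
#' @return list of class `chain_recipe`
#' @export
chain_recipe <- function(n_vertebrae = 4, params = vertebra_params(),
                         body_gap_ratio = 0.10, zyg_gap_ratio = 0.05,
                         param_overrides = NULL) {
  if (n_vertebrae < 2) stop("need at least 2 vertebrae")
  if (body_gap_ratio <= 0 || zyg_gap_ratio <= 0) stop("spacing ratios must be > 0")
  structure(list(n = n_vertebrae, params = params, body_gap_ratio = body_gap_ratio,
                 zyg_gap_ratio = zyg_gap_ratio, param_overrides = param_overrides),
            class = "chain_recipe")
}

#' Generate an articulated fixture chain in ONP
#'
#' Vertebrae are generated with matching articular geometry at every joint
#' and placed caudal to cranial along +x with the recipe's spacing; the
#' all-zero pose is viable at every joint by construction. Ground-truth
#' joint CORs are exposed for recovery tests.
#'
#' @param recipe a [chain_recipe()]
#' @param check_onp verify the ONP invariants (no adjacent collision, both
#'   sides articulated) for every joint
#' @return a `vchain` (see [vertebral_chain()])
#' @export
make_chain <- function(recipe, check_onp = TRUE) {
  n <- recipe$n
  plist <- lapply(seq_len(n), function(k) {
    ov <- recipe$param_overrides
    ovk <- if (!is.null(ov) && length(ov) >= k) ov[[k]] else NULL
    if (is.null(ovk)) recipe$params
    else do.call(vertebra_params, modifyList(unclass(recipe$params), ovk))
  })
  specs <- lapply(seq_len(n - 1), function(j) {
    joint_spec(plist[[j]], plist[[j + 1]], recipe$body_gap_ratio, recipe$zyg_gap_ratio)
  })
  meshes <- vector("list", n)
  for (k in seq_len(n)) {
    meshes[[k]] <- make_vertebra(
      plist[[k]], name = paste0("V", k),
      caudal_joint = if (k > 1) specs[[k - 1]] else FALSE,
      cranial_joint = if (k < n) specs[[k]] else FALSE,
      check = FALSE)
  }
  # world placement along +x
  xs <- numeric(n)
  for (k in 2:n) {
    xs[k] <- xs[k - 1] + plist[[k - 1]]$centrum_length / 2 + specs[[k - 1]]$axial_gap +
      plist[[k]]$centrum_length / 2
  }
  onp <- lapply(xs, function(x) rigid_transform(diag(3), c(x, 0, 0)))
  gt_cors <- lapply(seq_len(n - 1), function(j) {
    gt <- attr(meshes[[j + 1]], "ground_truth")
    gt$cor_caudal + c(xs[j + 1], 0, 0)
  })
  chain <- vertebral_chain(meshes, onp, check_onp = check_onp,
                           spacing = data.frame(
                             joint = paste0("V", 1:(n - 1), "-V", 2:n),
                             body_gap = vapply(specs, `[[`, numeric(1), "body_gap"),
                             zyg_gap = vapply(specs, `[[`, numeric(1), "g"),
                             axial_gap = vapply(specs, `[[`, numeric(1), "axial_gap")))
  chain$ground_truth <- list(cors = gt_cors, specs = specs, recipe = recipe)
  chain
}

#' Perturb a chain's neutral pose and spacing
#'
#' Sensitivity-analysis tool: applies small random rotations to every
#' vertebra about its caudal joint COR (emulating observer variability when
#' orienting vertebrae in ONP) and rescales the intervertebral gaps. If a
#' draw breaks ONP viability it is resampled up to `max_retry` times.
#'
#' @param chain a `vchain`
#' @param onp_rotation_sd standard deviation of the per-axis perturbation
#'   rotations (degrees), >= 0
#' @param spacing_scale multiplicative factor on the intervertebral gaps
#' @param seed RNG seed
#' @param max_retry resampling cap
#' @return perturbed `vchain`
#' @export
perturb_chain <- function(chain, onp_rotation_sd = 0, spacing_scale = 1, seed = 1L,
                          max_retry = 10L) {
  if (onp_rotation_sd < 0) stop("onp_rotation_sd must be >= 0")
  if (spacing_scale <= 0) stop("spacing_scale must be > 0")
  if (onp_rotation_sd == 0 && spacing_scale == 1) return(chain)
  n <- length(chain$vertebrae)
  set.seed(as.integer(seed))
  for (attempt in seq_len(max_retry)) {
    onp <- chain$onp_transforms
    # rescale gaps: shift vertebra k by the accumulated extra gap
    if (spacing_scale != 1) {
      extra <- 0
      for (k in 2:n) {
        extra <- extra + (spacing_scale - 1) * chain$spacing$axial_gap[k - 1]
        onp[[k]] <- rigid_transform(diag(3), c(extra, 0, 0)) %*% onp[[k]]
      }
    }
    if (onp_rotation_sd > 0) {
      for (k in 2:n) {
        # total rotation angle ~ N(0, sd) about a uniformly random axis
        ax <- rnorm(3)
        ax <- ax / sqrt(sum(ax^2))
        ang <- rnorm(1, 0, onp_rotation_sd)
        K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
        R <- diag(3) + sin(deg2rad(ang)) * K + (1 - cos(deg2rad(ang))) * K %*% K
        cor_k <- transform_points(onp[[k]],
                                  attr(chain$vertebrae[[k]], "ground_truth")$cor_caudal)
        onp[[k]] <- rotation_about(R, as.numeric(cor_k)) %*% onp[[k]]
      }
    }
    out <- tryCatch(
      vertebral_chain(chain$vertebrae, onp, check_onp = TRUE, spacing = chain$spacing),
      error = function(e) NULL)
    if (!is.null(out)) {
      out$ground_truth <- chain$ground_truth
      return(out)
    }
  }
  stop("perturbation broke ONP viability in all ", max_retry, " attempts")
}
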