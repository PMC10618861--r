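# Exhaustive sampling of the interacting roll/yaw/pitch grid per joint and
# viability classification. A pose is viable when the adjacent bone meshes
# do not intersect (Boolean-intersection criterion) and the anterior
# vertebra still intersects both left and right articulation gap volumes
# (disarticulation at 0 percent facet overlap).

#' Define a rotational pose grid
#'
#' A regular grid over (roll, yaw, pitch) in degrees. Bounds must contain 0
#' on every axis so that the ONP itself is sampled; the default step of 2
#' degrees matches the sampling the method was designed around.
#'
#' @param roll,yaw,pitch length-2 (min, max) bounds in degrees
#' @param step grid increment in degrees (> 0)
#' @return object of class `pose_grid`
#' @export
pose_grid <- function(roll = c(-90, 90), yaw = c(-90, 90), pitch = c(-90, 60),
                      step = 2) {
  if (step <= 0) stop("step must be > 0")
  for (b in list(roll = roll, yaw = yaw, pitch = pitch)) {
    if (length(b) != 2 || b[1] > b[2]) stop("bounds must be (min, max)")
    if (b[1] > 0 || b[2] < 0) stop("bounds must contain 0 (the ONP)")
  }
  structure(list(roll = roll, yaw = yaw, pitch = pitch, step = step),
            class = "pose_grid")
}

grid_axis <- function(bounds, step) seq(bounds[1], bounds[2], by = step)

#' @export
print.pose_grid <- function(x, ...) {
  n <- nrow(grid_points(x))
  cat(sprintf("<pose_grid: roll [%g,%g] yaw [%g,%g] pitch [%g,%g], step %g, %d poses>\n",
              x$roll[1], x$roll[2], x$yaw[1], x$yaw[2], x$pitch[1], x$pitch[2],
              x$step, n))
  invisible(x)
}

#' Enumerate grid poses
#'
#' @param grid a `pose_grid`
#' @return matrix with columns roll, yaw, pitch (roll varying fastest)
#' @export
grid_points <- function(grid) {
  g <- expand.grid(roll = grid_axis(grid$roll, grid$step),
                   yaw = grid_axis(grid$yaw, grid$step),
                   pitch = grid_axis(grid$pitch, grid$step))
  as.matrix(g)
}

#' Test two meshes for collision
#'
#' True iff the surfaces cross or one mesh's interior contains the other
#' (the accept/reject behaviour of a Boolean mesh intersection, without
#' constructing the intersection mesh). Symmetric in its arguments.
#'
#' @param mesh_a,mesh_b watertight `vmesh` objects, already posed
#' @param check validate watertightness first
#' @return logical
#' @export
test_collision <- function(mesh_a, mesh_b, check = TRUE) {
  if (check) {
    for (m in list(mesh_a, mesh_b)) {
      d <- validate_mesh(m)
      if (d$boundary_edges > 0 || d$nonmanifold_edges > 0)
        stop(sprintf("mesh '%s' is not watertight (%d boundary edges)", m$name,
                     d$boundary_edges))
    }
  }
  cpp_meshes_intersect(mesh_a$vertices, mesh_a$faces, mesh_b$vertices, mesh_b$faces)
}

#' Build articulation gap volumes for a joint
#'
#' For each side, the posterior vertebra's prezygapophyseal facet is
#' extruded along its mean normal far enough to fill the joint space
#' (facet gap plus a margin of `margin_factor` gaps, so the default prism
#' length is twice the ONP facet gap). The prisms live in the posterior
#' vertebra's frame: they stay put while the anterior vertebra is animated,
#' and a pose counts as articulated on a side only if the moving anterior
#' vertebra still intersects that side's prism.
#'
#' @param chain a `vchain`
#' @param joint joint index or label
#' @param margin_factor extra prism length in units of the ONP facet gap
#' @return list with `left` and `right` prism `vmesh`, plus the gap used
#' @export
build_articulation_volumes <- function(chain, joint, margin_factor = 1) {
  j <- joint_index(chain, joint)
  post <- world_mesh(chain, j)
  for (lb in c("left_pre", "right_pre"))
    if (is.null(post$facet_patches[[lb]]))
      stop("posterior vertebra '", post$name, "' lacks patch '", lb, "'")
  gap <- chain$spacing$zyg_gap[j]
  if (is.null(gap) || !is.finite(gap)) {
    ant <- world_mesh(chain, j + 1)
    pre <- submesh(post, unlist(post$facet_patches[c("left_pre", "right_pre")]))
    pst <- submesh(ant, unlist(ant$facet_patches[c("left_post", "right_post")]))
    gap <- cpp_min_distance(pst$vertices, pst$faces, pre$vertices, pre$faces)
  }
  dist <- gap * (1 + margin_factor)
  list(left = extrude_patch(facet_patch(post, "left_pre"), distance = dist),
       right = extrude_patch(facet_patch(post, "right_pre"), distance = dist),
       gap = gap, length = dist)
}

sweep_inputs <- function(chain, j, margin_factor = 1) {
  ant <- world_mesh(chain, j + 1)
  post <- world_mesh(chain, j)
  vols <- build_articulation_volumes(chain, j, margin_factor)
  jf <- chain$joints[[j]]
  list(ant = ant, post = post, vols = vols, jf = jf)
}

records_from_flags <- function(angles, flags) {
  data.frame(roll = angles[, 1], yaw = angles[, 2], pitch = angles[, 3],
             collision_free = flags[, 1], articulated_left = flags[, 2],
             articulated_right = flags[, 3],
             viable = as.integer(flags[, 1] & flags[, 2] & flags[, 3]))
}

#' Classify a single joint pose
#'
#' Runs the collision test between the joint's adjacent vertebrae and the
#' articulation test against both gap prisms, with all other joints held at
#' ONP. Geometry errors annotate the record (pose scored non-viable) rather
#' than aborting.
#'
#' @param chain a `vchain`
#' @param joint joint index or label
#' @param pose length-3 (roll, yaw, pitch) in degrees
#' @param margin_factor see [build_articulation_volumes()]
#' @return one-row data.frame: pose angles, `collision_free`,
#'   `articulated_left`, `articulated_right`, `viable` (0/1 coding)
#' @export
classify_pose <- function(chain, joint, pose, margin_factor = 1) {
  j <- joint_index(chain, joint)
  angles <- matrix(as.numeric(pose), 1, 3)
  rec <- tryCatch({
    si <- sweep_inputs(chain, j, margin_factor)
    flags <- cpp_sweep_joint(si$ant$vertices, si$ant$faces, si$post$vertices,
                             si$post$faces, si$vols$left$vertices, si$vols$left$faces,
                             si$vols$right$vertices, si$vols$right$faces,
                             si$jf$cor, si$jf$axes, angles)
    records_from_flags(angles, flags)
  }, error = function(e) {
    r <- records_from_flags(angles, matrix(0L, 1, 3))
    r$error <- conditionMessage(e)
    r
  })
  rec
}

#' Exhaustively sweep one joint over a pose grid
#'
#' Produces exactly one record per grid point, deterministically: only the
#' swept joint is actuated, all other joints stay at ONP. The exhaustive
#' grid is evaluated in compiled code; results can be written as a CSV with
#' columns roll, yaw, pitch, collision_free, articulated_left,
#' articulated_right, viable.
#'
#' @param chain a `vchain`
#' @param joint joint index or label
#' @param grid a [pose_grid()]
#' @param csv optional output CSV path
#' @param margin_factor see [build_articulation_volumes()]
#' @return data.frame of pose records, with attributes `joint` and `grid`
#' @export
sweep_joint <- function(chain, joint, grid, csv = NULL, margin_factor = 1) {
  j <- joint_index(chain, joint)
  si <- sweep_inputs(chain, j, margin_factor)
  angles <- grid_points(grid)
  flags <- cpp_sweep_joint(si$ant$vertices, si$ant$faces, si$post$vertices,
                           si$post$faces, si$vols$left$vertices, si$vols$left$faces,
                           si$vols$right$vertices, si$vols$right$faces,
                           si$jf$cor, si$jf$axes, angles)
  rec <- records_from_flags(angles, flags)
  attr(rec, "joint") <- joint_label(chain, j)
  attr(rec, "grid") <- grid
  if (!is.null(csv)) data.table::fwrite(rec, csv)
  rec
}

#' Sweep every joint of a chain
#'
#' @param chain a `vchain`
#' @param grid a [pose_grid()]
#' @param csv_dir optional directory for per-joint CSVs
#' @param margin_factor see [build_articulation_volumes()]
#' @return named list of record data.frames, one per joint
#' @export
sweep_chain <- function(chain, grid, csv_dir = NULL, margin_factor = 1) {
  out <- list()
  for (j in seq_along(chain$joints)) {
    lab <- joint_label(chain, j)
    csv <- if (!is.null(csv_dir)) file.path(csv_dir, paste0("sweep_", lab, ".csv"))
    out[[lab]] <- sweep_joint(chain, j, grid, csv = csv, margin_factor = margin_factor)
  }
  out
}
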