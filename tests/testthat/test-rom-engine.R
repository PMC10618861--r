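# collision testing, articulation volumes, pose classification, sweeps

test_that("collision test handles disjoint, overlapping and nested meshes", {
  a <- mesh_cube()
  expect_false(test_collision(a, mesh_cube(center = c(2, 0, 0))))
  expect_true(test_collision(a, mesh_cube(center = c(0.5, 0, 0))))
  expect_true(test_collision(a, mesh_cube(dims = c(3, 3, 3))))  # containment
  # symmetry in arguments
  b <- mesh_icosphere(2, radius = 0.4, center = c(0.6, 0.2, 0))
  expect_equal(test_collision(a, b), test_collision(b, a))
  expect_error(test_collision(local({
    bad <- mesh_cube()
    bad$faces <- bad$faces[-1, ]
    bad
  }), a), "not watertight")
})

test_that("collision test is invariant under joint rigid transforms", {
  set.seed(13)
  for (i in 1:10) {
    a <- mesh_cube(center = runif(3, -1, 1), dims = runif(3, 0.5, 2))
    b <- mesh_icosphere(2, radius = runif(1, 0.3, 1.2), center = runif(3, -1, 1))
    base <- test_collision(a, b, check = FALSE)
    T <- random_rigid()
    expect_equal(test_collision(osteoROM:::transform_mesh(a, T),
                                osteoROM:::transform_mesh(b, T), check = FALSE),
                 base)
  }
})

test_that("articulation volumes behave as gap-filling prisms", {
  ch <- chain2()
  vols <- build_articulation_volumes(ch, 1)
  expect_equal(signed_volume(vols$left), signed_volume(vols$right), tolerance = 1e-6)
  expect_equal(vols$length, 2 * vols$gap)

  ant <- osteoROM:::world_mesh(ch, 2)
  # at ONP the anterior vertebra intersects both prisms
  expect_true(test_collision(ant, vols$left, check = FALSE))
  expect_true(test_collision(ant, vols$right, check = FALSE))
  # translated dorsally by 10 facet gaps, the articulating facets intersect
  # neither prism (the stylised assembly's centrum passes through the prism
  # band at that height, so the whole-bone check needs a larger offset)
  pst <- osteoROM:::submesh(ant, unlist(ant$facet_patches[c("left_post", "right_post")]))
  up10 <- transform_points(rigid_transform(diag(3), c(0, 10 * vols$gap, 0)),
                           pst$vertices)
  expect_false(osteoROM:::cpp_meshes_intersect(up10, pst$faces, vols$left$vertices,
                                               vols$left$faces))
  expect_false(osteoROM:::cpp_meshes_intersect(up10, pst$faces, vols$right$vertices,
                                               vols$right$faces))
  up <- osteoROM:::transform_mesh(ant, rigid_transform(diag(3), c(0, 25 * vols$gap, 0)))
  expect_false(test_collision(up, vols$left, check = FALSE))
  expect_false(test_collision(up, vols$right, check = FALSE))
  expect_error(build_articulation_volumes(chain2(), 5), "unknown joint|subscript")
})

test_that("classify_pose applies the paper's two criteria with 0/1 coding", {
  ch <- chain2()
  rec <- classify_pose(ch, 1, c(0, 0, 0))
  expect_equal(rec$viable, 1L)
  expect_equal(rec$viable, rec$collision_free * rec$articulated_left *
                 rec$articulated_right)

  # short facets: pitch beyond the facet-overlap arc disarticulates.
  # arc limit ~ (prezyg + postzyg) / (2 R) = (2.5 + 3) / 12 rad ~ 26 deg
  short <- chain2_with(prezyg_length = 2.5, postzyg_length = 3,
                       centrum_face_tilt = 30)
  beyond <- classify_pose(short, 1, c(0, 0, -32))
  expect_false(beyond$articulated_left == 1 && beyond$articulated_right == 1)
  expect_equal(beyond$viable, 0L)
  within <- classify_pose(short, 1, c(0, 0, -20))
  expect_equal(within$viable, 1L)
})

test_that("tall spinous processes stop dorsal pitch by bone contact", {
  tall <- chain2_with(spinous_height = 11, spinous_length = 8, spinous_lean = 32,
                      prezyg_length = 6, postzyg_length = 5)
  # bracket the contact angle with the collision test directly
  posed_collides <- function(theta) {
    tf <- pose_chain(tall, matrix(c(0, 0, theta), 1))
    test_collision(osteoROM:::transform_mesh(tall$vertebrae[[2]], tf[[2]]),
                   osteoROM:::transform_mesh(tall$vertebrae[[1]], tf[[1]]),
                   check = FALSE)
  }
  lo <- 0; hi <- 60
  expect_false(posed_collides(lo))
  expect_true(posed_collides(hi))
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    if (posed_collides(mid)) hi <- mid else lo <- mid
  }
  contact <- (lo + hi) / 2
  expect_equal(classify_pose(tall, 1, c(0, 0, contact + 2))$collision_free, 0L)
  expect_equal(classify_pose(tall, 1, c(0, 0, contact - 2))$collision_free, 1L)
})

test_that("sweep_joint enumerates the exact grid and matches per-pose checks", {
  ch <- chain2()
  rec <- sweep_joint(ch, 1, pose_grid(c(-2, 2), c(-2, 2), c(-2, 2), step = 2))
  expect_equal(nrow(rec), 27)

  one <- sweep_joint(ch, 1, pose_grid(c(0, 0), c(0, 0), c(0, 0), step = 2))
  expect_equal(nrow(one), 1)
  expect_equal(one$viable, 1L)

  # order independence: per-pose classification reproduces a random subset of
  # the sweep in shuffled order
  g <- pose_grid(c(-20, 20), c(-20, 20), c(-20, 20), step = 4)
  full <- sweep_joint(ch, 1, g)
  set.seed(4)
  idx <- sample(nrow(full), 60)
  for (i in idx) {
    r <- classify_pose(ch, 1, as.numeric(full[i, 1:3]))
    expect_equal(r$viable, full$viable[i])
    expect_equal(r$collision_free, full$collision_free[i])
  }
})

test_that("sweep CSV output round-trips", {
  ch <- chain2()
  csv <- withr::local_tempfile(fileext = ".csv")
  rec <- sweep_joint(ch, 1, pose_grid(c(-10, 10), c(-10, 10), c(-10, 10), step = 5),
                     csv = csv)
  back <- as.data.frame(data.table::fread(csv))
  expect_equal(back, rec, ignore_attr = TRUE)
  expect_named(back, c("roll", "yaw", "pitch", "collision_free",
                       "articulated_left", "articulated_right", "viable"))
})

test_that("grid refinement never removes viable poses at shared grid points", {
  ch <- chain2()
  coarse <- sweep_joint(ch, 1, pose_grid(c(-16, 16), c(-16, 16), c(-16, 16), step = 8))
  fine <- sweep_joint(ch, 1, pose_grid(c(-16, 16), c(-16, 16), c(-16, 16), step = 4))
  key_c <- pose_key(coarse[coarse$viable == 1, ])
  key_f <- pose_key(fine[fine$viable == 1, ])
  expect_true(all(key_c %in% key_f))
  # and identical classification at the shared points
  shared <- merge(coarse, fine, by = c("roll", "yaw", "pitch"))
  expect_equal(shared$viable.x, shared$viable.y)
})

test_that("growing the gap-prism margin can only grow the articulated set", {
  ch <- chain2()
  g <- pose_grid(c(-16, 16), c(-16, 16), c(-16, 16), step = 8)
  small <- sweep_joint(ch, 1, g, margin_factor = 0.5)
  big <- sweep_joint(ch, 1, g, margin_factor = 2)
  art <- function(r) r$articulated_left == 1 & r$articulated_right == 1
  expect_true(all(!art(small) | art(big)))
})

test_that("pose grids validate their invariants", {
  expect_error(pose_grid(step = 0), "step")
  expect_error(pose_grid(roll = c(10, 40)), "contain 0")
  g <- pose_grid(c(-10, 10), c(-4, 4), c(0, 0), step = 2)
  expect_equal(nrow(grid_points(g)), 11 * 5 * 1)
})
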