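# cosine correction, alpha shapes, chain summaries, max turn, SFP export

test_that("cosine correction rescales roll by cos(yaw)", {
  expect_equal(cosine_correct(cbind(12, 0, 7)), cbind(roll = 12, yaw = 0, pitch = 7))
  expect_equal(cosine_correct(cbind(10, 90, 5))[1, 1], 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cosine_correct(cbind(10, 60, 0))[1, 1], 5, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_warning(out <- cosine_correct(cbind(10, 120, 0)), "clamped")
  expect_equal(out[1, 1], 0, ignore_attr = TRUE)
})

test_that("delaunay tetrahedralisation reproduces the convex hull volume", {
  # expected value frozen from an independent scipy.spatial.ConvexHull run on
  # the identical point set (set.seed(7); matrix(runif(150), 50, 3))
  set.seed(7)
  P <- matrix(runif(150), 50, 3)
  d <- osteoROM:::cpp_delaunay3(osteoROM:::general_position_jitter(P, 1e-9))
  tm <- osteoROM:::tet_metrics(P, d$tets)
  expect_equal(sum(tm$volume), 0.491408174084, tolerance = 1e-9)
  # every input point is a vertex of the triangulation
  expect_setequal(unique(as.vector(d$tets)), seq_len(50))
})

test_that("alpha-shape volume matches closed-form oracles", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  as1 <- alpha_shape_volume(tet, alpha = 1000)
  expect_equal(as1$volume, 1 / 6, tolerance = 1e-9)

  g <- as.matrix(expand.grid(seq(0, 18, 2), seq(0, 18, 2), seq(0, 18, 2)))
  as2 <- alpha_shape_volume(g, alpha = 50)
  expect_equal(as2$volume, 5832, tolerance = 0.02)
  expect_equal(as2$alpha_used, 50)
  expect_lt(as2$critical_alpha, 2)
})

test_that("critical alpha engages for split clusters and degenerate input is 0", {
  cube <- as.matrix(expand.grid(seq(0, 1, 0.25), seq(0, 1, 0.25), seq(0, 1, 0.25)))
  two <- rbind(cube, sweep(cube, 2, c(101, 0, 0), `+`))
  as3 <- alpha_shape_volume(two, alpha = 50)
  expect_gt(as3$critical_alpha, 50)
  expect_equal(as3$alpha_used, as3$critical_alpha)
  expect_gte(as3$volume, 2)  # both cubes plus the bridging tets

  expect_warning(z1 <- alpha_shape_volume(tet <- matrix(rnorm(9), 3, 3)), "4 distinct")
  expect_equal(z1$volume, 0)
  flat <- cbind(matrix(runif(60), 30, 2), 1)
  expect_warning(z2 <- alpha_shape_volume(flat), "coplanar")
  expect_equal(z2$volume, 0)
})

test_that("alpha-shape volume is monotone in the point set at fixed alpha", {
  set.seed(31)
  P <- matrix(rnorm(240), ncol = 3)
  sub <- P[1:40, ]
  a_sub <- alpha_shape_volume(sub, alpha = 1e6)
  a_all <- alpha_shape_volume(P, alpha = 1e6)
  expect_gte(a_all$volume, a_sub$volume - 1e-9)
})

test_that("cosine correction makes displaced pose sets comparable", {
  # equal orientation-space extents centred at yaw 0 vs yaw 60: the raw
  # Euler boxes differ by 1/cos(60) = 2 in roll, corrected volumes agree
  e <- 10
  mk <- function(y0, half_roll) {
    as.matrix(expand.grid(roll = seq(-half_roll, half_roll, length.out = 17),
                          yaw = seq(y0 - e, y0 + e, length.out = 11),
                          pitch = seq(-10, 10, length.out = 11)))
  }
  A <- mk(0, 10)
  B <- mk(60, 20)
  vA <- alpha_shape_volume(cosine_correct(A), alpha = 1e6)$volume
  vB <- alpha_shape_volume(cosine_correct(B), alpha = 1e6)$volume
  expect_lt(abs(vA - vB) / vA, 0.05)
})

test_that("extrema and sums partition across joints", {
  ch <- chain2()
  g <- pose_grid(c(-12, 12), c(-12, 12), c(-12, 12), step = 4)
  rec <- sweep_joint(ch, 1, g)
  env <- rom_envelope(rec)

  s1 <- extrema_and_sums(list(env))
  vr <- env$viable_poses
  expect_equal(unname(s1$summed_range["roll"]),
               max(vr[, "roll"]) - min(vr[, "roll"]))
  expect_equal(s1$summed_range, s1$summed_pos - s1$summed_neg)

  s7 <- extrema_and_sums(rep(list(env), 7))
  expect_equal(s7$summed_range, 7 * s1$summed_range)

  # persistence round trip: sums from CSV equal sums from memory exactly
  csv <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(rec, csv)
  env2 <- rom_envelope(as.data.frame(data.table::fread(csv)), joint = env$joint)
  s2 <- extrema_and_sums(list(env2))
  expect_identical(s1$summed_range, s2$summed_range)
  expect_identical(s1$summed_pos, s2$summed_pos)
})

test_that("empty viable sets contribute zeros with a warning", {
  rec <- data.frame(roll = 0, yaw = 0, pitch = 0, collision_free = 0L,
                    articulated_left = 0L, articulated_right = 0L, viable = 0L)
  expect_warning(env <- rom_envelope(rec, joint = "empty"), "no viable poses")
  expect_equal(env$volume, 0)
  s <- extrema_and_sums(list(env))
  expect_equal(unname(s$summed_range), c(0, 0, 0))
})

test_that("max_turn_pose picks the lexicographic maximum and honours exclusions", {
  ch <- chain4()
  g <- pose_grid(c(-16, 16), c(-16, 16), c(-16, 16), step = 4)
  envs <- lapply(sweep_chain(ch, g), rom_envelope)

  # constructed viable set: priority yaw, then roll, then pitch
  fake <- envs[[1]]
  fake$viable_poses <- matrix(c(0, 10, 0, 8, 10, -4, 8, 10, 6), ncol = 3,
                              byrow = TRUE, dimnames = list(NULL, c("roll", "yaw", "pitch")))
  mt <- max_turn_pose(ch, list(fake, envs[[2]], envs[[3]]))
  expect_equal(unname(mt$poses[1, ]), c(8, 10, 6))

  # single viable pose is chosen as-is
  single <- fake
  single$viable_poses <- matrix(c(2, 4, -2), 1, 3,
                                dimnames = list(NULL, c("roll", "yaw", "pitch")))
  mt1 <- max_turn_pose(ch, list(single, envs[[2]], envs[[3]]))
  expect_equal(unname(mt1$poses[1, ]), c(2, 4, -2))

  # excluding the caudal-most joint removes exactly its max yaw from the sum
  full <- max_turn_pose(ch, envs)
  without <- max_turn_pose(ch, envs, exclude_joints = "V1-V2")
  expect_equal(full$summed["yaw"] - without$summed["yaw"],
               unname(full$poses[1, "yaw"]), ignore_attr = TRUE)
  expect_s3_class(full$self_collisions, "data.frame")
})

test_that("spherical frame projections map poses to unit directions", {
  ch <- chain2()
  jf <- ch$joints[[1]]

  onp_only <- structure(list(joint = "j", viable_poses = matrix(c(0, 0, 0), 1, 3,
    dimnames = list(NULL, c("roll", "yaw", "pitch")))), class = "rom_envelope")
  out <- sfp_export(onp_only, jf)
  expect_equal(unname(out[1, 1:3]), unname(jf$axes[, 1]), tolerance = 1e-12)

  yaw_sweep <- onp_only
  yaw_sweep$viable_poses <- cbind(roll = 0, yaw = seq(-90, 90, 10), pitch = 0)
  pts <- sfp_export(yaw_sweep, jf)
  expect_equal(nrow(pts), 19)               # bijection with the viable poses
  expect_equal(rowSums(pts[, 1:3]^2), rep(1, 19), tolerance = 1e-12)
  # pure yaw keeps directions in the plane orthogonal to the yaw axis
  expect_equal(as.numeric(pts[, 1:3] %*% jf$axes[, 2]), rep(0, 19),
               tolerance = 1e-9)

  ply <- withr::local_tempfile(fileext = ".ply")
  sfp_export(yaw_sweep, jf, path = ply)
  expect_true(file.exists(ply))
  expect_equal(nrow(osteoROM:::read_ply(ply)$vertices), 19)
})
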