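# mesh I/O, validation, repair, decimation, sphere fit, patch extrusion

test_that("load_mesh reads a unit cube OBJ with invariants intact", {
  path <- withr::local_tempfile(fileext = ".obj")
  write_mesh(mesh_cube(), path)
  m <- load_mesh(path, validate = TRUE)
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$faces), 12)
  expect_true(validate_mesh(m)$ok)
  expect_equal(signed_volume(m), 1, tolerance = 1e-12)
})

test_that("a cube with one face removed fails validation with 4 boundary edges", {
  cu <- mesh_cube()
  cu$faces <- cu$faces[-c(11, 12), ]  # both triangles of the +x square face
  path <- withr::local_tempfile(fileext = ".obj")
  write_mesh(cu, path)
  expect_error(load_mesh(path, validate = TRUE), "4 boundary edges")
  expect_equal(validate_mesh(cu)$boundary_edges, 4)
  repaired <- repair_mesh(cu)
  expect_true(validate_mesh(repaired)$ok)
})

test_that("round trips through OBJ, PLY (ascii+binary) and STL preserve geometry", {
  v <- default_vertebra()
  vol <- signed_volume(v)
  for (spec in list(c("obj", FALSE), c("ply", FALSE), c("ply", TRUE), c("stl", TRUE),
                    c("stl", FALSE))) {
    path <- withr::local_tempfile(fileext = paste0(".", spec[1]))
    write_mesh(v, path, binary = as.logical(spec[2]), annotations = FALSE)
    m <- load_mesh(path, validate = TRUE)
    if (spec[1] != "stl") expect_equal(nrow(m$vertices), nrow(v$vertices))
    expect_equal(signed_volume(m), vol, tolerance = 1e-6)
  }
})

test_that("facet annotations survive the sidecar round trip", {
  v <- default_vertebra()
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(v, path, annotations = TRUE)
  m <- load_mesh(path)
  expect_setequal(names(m$facet_patches),
                  c("left_pre", "right_pre", "left_post", "right_post"))
  for (lb in names(v$facet_patches))
    expect_equal(sort(m$facet_patches[[lb]]), sort(v$facet_patches[[lb]]))
})

test_that("decimation respects face budget, watertightness and volume", {
  ic <- mesh_icosphere(3)
  expect_equal(nrow(ic$faces), 1280)
  d <- decimate_mesh(ic, 320)
  expect_lte(nrow(d$faces), 320)
  expect_true(validate_mesh(d)$ok)
  expect_lt(abs(signed_volume(d) - signed_volume(ic)) / signed_volume(ic), 0.05)
  # already under budget: unchanged
  expect_identical(decimate_mesh(ic, 5000), ic)
  expect_error(decimate_mesh(ic, 3), "target_faces")
})

test_that("decimation re-maps facet patches to surviving faces", {
  v <- default_vertebra()
  d <- decimate_mesh(v, 500)
  expect_lte(nrow(d$faces), 500)
  expect_setequal(names(d$facet_patches), names(v$facet_patches))
  for (lb in names(d$facet_patches)) expect_gt(length(d$facet_patches[[lb]]), 0)
  all_fx <- unlist(d$facet_patches)
  expect_equal(anyDuplicated(all_fx), 0)
})

test_that("fit_sphere recovers exact and noise-free spheres", {
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1),
               c(0, 0, -1))
  f <- fit_sphere(oct)
  expect_equal(f$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(f$radius, 1, tolerance = 1e-12)

  set.seed(11)
  u <- matrix(rnorm(600), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * 5, 2, c(1, 2, 3), `+`)
  f2 <- fit_sphere(pts)
  expect_equal(f2$center, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(f2$radius, 5, tolerance = 1e-9)
  expect_lt(f2$rms, 1e-9)
})

test_that("fit_sphere rejects degenerate input", {
  expect_error(fit_sphere(matrix(rnorm(9), 3, 3)), "at least 4")
  flat <- cbind(matrix(runif(40), 20, 2), 0)
  expect_error(fit_sphere(flat), "coplanar")
})

test_that("fit_sphere tolerates noise: centre error below 2% of radius", {
  # Monte-Carlo over seeds; isotropic noise sd = 5% of radius
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    u <- matrix(rnorm(1500), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * 5, 2, c(1, 2, 3), `+`) + matrix(rnorm(1500, 0, 0.25), ncol = 3)
    sqrt(sum((fit_sphere(pts)$center - c(1, 2, 3))^2))
  }, numeric(1))
  expect_lt(unname(quantile(errs, 0.95)), 0.02 * 5)
})

test_that("fit_sphere is equivariant under rigid transforms", {
  set.seed(3)
  u <- matrix(rnorm(90), ncol = 3)
  pts <- sweep(u / sqrt(rowSums(u^2)) * 2.5, 2, c(-1, 4, 2), `+`)
  f0 <- fit_sphere(pts)
  for (i in 1:5) {
    T <- random_rigid()
    f1 <- fit_sphere(transform_points(T, pts))
    expect_equal(f1$center, as.numeric(transform_points(T, f0$center)),
                 tolerance = 1e-9)
    expect_equal(f1$radius, f0$radius, tolerance = 1e-9)
  }
})

test_that("extrude_patch builds exact prisms and rejects bad input", {
  sq <- vertebra_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3), c(1, 3, 4)),
                      facet_patches = list(left_pre = c(1, 2)))
  pr <- extrude_patch(sq, label = "left_pre", distance = 2)
  expect_equal(signed_volume(pr), 2, tolerance = 1e-6)
  expect_true(validate_mesh(pr)$ok)
  expect_error(extrude_patch(sq, label = "left_pre", distance = 0), "distance")
})

test_that("curved-patch extrusion volume equals projected area x distance", {
  v <- default_vertebra()
  for (lb in names(v$facet_patches)) {
    p <- facet_patch(v, lb)
    pr <- extrude_patch(p, distance = 1.7)
    d <- validate_mesh(pr)
    expect_true(d$ok, info = lb)
    # straight extrusion: volume = (area projected onto the plane normal to
    # the direction) * distance, bounded above by total area * distance
    nrm <- p$mean_normal
    F <- p$face_matrix
    V <- v$vertices
    n2 <- osteoROM:::face_normals(V, F)
    proj <- sum(abs(n2 %*% nrm)) / 2
    expect_equal(signed_volume(pr), proj * 1.7, tolerance = 1e-9)
    expect_lte(signed_volume(pr), p$area * 1.7 + 1e-9)
  }
})

test_that("extruded prisms are watertight for random sub-patches", {
  v <- default_vertebra()
  set.seed(5)
  for (i in 1:25) {
    lb <- sample(names(v$facet_patches), 1)
    fx <- v$facet_patches[[lb]]
    # random contiguous subset: grow from a seed face by shared vertices
    take <- sample(fx, 1)
    while (length(take) < max(3, length(fx) %/% 2)) {
      verts <- unique(as.vector(v$faces[take, ]))
      nb <- fx[apply(matrix(v$faces[fx, ] %in% verts, ncol = 3), 1, any)]
      nb <- setdiff(nb, take)
      if (!length(nb)) break
      take <- c(take, nb[1])
    }
    m <- v
    m$facet_patches$sub <- take
    m$facet_patches[setdiff(names(m$facet_patches), "sub")] <- NULL
    pr <- extrude_patch(facet_patch(m, "sub"), distance = runif(1, 0.3, 3))
    d <- validate_mesh(pr)
    expect_true(d$boundary_edges == 0 && d$misoriented_edges == 0 &&
                d$signed_volume > 0)
  }
})
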