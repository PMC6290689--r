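test_that("triangle and vertex areas follow the cross-product formula", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)))
  expect_equal(surface_area(tri), 0.5)
  expect_equal(sum(vertex_areas(tri)), 0.5)
  expect_equal(vertex_areas(tri), rep(0.5 / 3, 3))

  # geometrically degenerate triangle (coincident coordinates) contributes 0
  deg <- surface_mesh(rbind(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1)),
                      rbind(c(1, 2, 3)))
  expect_equal(surface_area(deg), 0)
  # repeated vertex *index* is rejected outright
  expect_error(surface_mesh(tri$points, rbind(c(1, 1, 2))), "repeats")
})

test_that("sphere mesh area converges to 4 pi r^2", {
  sm <- wssvar:::.sphere_mesh(c(1, 2, 3), 1, 64, 48)
  mesh <- surface_mesh(sm$points, sm$triangles)
  expect_lt(relerr(surface_area(mesh), 4 * pi), 0.01)
  expect_equal(sum(vertex_areas(mesh)), surface_area(mesh))
})

test_that("clipping a tube at its mid-plane keeps exactly half the area", {
  mesh <- cylinder_fixture(x0 = -10, len = 10, n_axial = 37)  # rings off-plane
  mid <- clip_plane(c(-5, 0, 0), c(1, 0, 0), side = 1)
  kept <- clip_by_planes(mesh, mid, component = FALSE)
  expect_lt(relerr(surface_area(kept), surface_area(mesh) / 2), 1e-6)

  # exact splitting: kept + complement equals the original area
  comp <- clip_by_planes(mesh, clip_plane(mid$origin, mid$normal, -1),
                         component = FALSE)
  expect_lt(relerr(surface_area(kept) + surface_area(comp),
                   surface_area(mesh)), 1e-9)
})

test_that("a plane outside the bounding box leaves the mesh unchanged", {
  mesh <- cylinder_fixture(n_theta = 16, n_axial = 8)
  far <- clip_plane(c(100, 0, 0), c(-1, 0, 0), side = 1)
  out <- clip_by_planes(mesh, far, seed = mesh$points[1, ])
  expect_equal(surface_area(out), surface_area(mesh))
  expect_equal(nrow(out$triangles), nrow(mesh$triangles))
})

test_that("clip errors: empty region and seed on the discarded side", {
  mesh <- cylinder_fixture(n_theta = 16, n_axial = 8)
  away <- clip_plane(c(100, 0, 0), c(1, 0, 0), side = 1)
  expect_error(clip_by_planes(mesh, away, component = FALSE), "empty")
  mid <- clip_plane(c(-5, 0, 0), c(1, 0, 0), side = 1)
  expect_error(clip_by_planes(mesh, mid, seed = c(-9, 0, 1.225)), "seed")
})

test_that("clipping preserves interpolated field ranges", {
  set.seed(11)
  mesh <- cylinder_fixture(n_theta = 24, n_axial = 12)
  mesh$fields$wss <- runif(nrow(mesh$points), 0.5, 9)
  for (k in 1:10) {
    nrm <- rnorm(3)
    pl <- clip_plane(c(runif(1, -9, -1), 0, 0), nrm, sample(c(-1, 1), 1))
    kept <- tryCatch(clip_by_planes(mesh, pl, component = FALSE),
                     error = function(e) NULL)
    if (is.null(kept)) next
    expect_gte(min(kept$fields$wss), min(mesh$fields$wss) - 1e-12)
    expect_lte(max(kept$fields$wss), max(mesh$fields$wss) + 1e-12)
  }
})

test_that("the emitted sac planes recover the analytic sac area", {
  sub <- make_reference(reference_case())
  sac <- clip_by_planes(sub$mesh, sub$regions$sac_planes,
                        seed = sub$regions$sac_seed)
  expect_lt(relerr(surface_area(sac), sub$truth$sac$area), 0.01)
})

test_that("orthogonal and oblique cylinder sections match disc and ellipse", {
  mesh <- cylinder_fixture(radius = 1.225, n_theta = 96, n_axial = 60)
  ortho <- plane_section(mesh, list(origin = c(-5.1, 0, 0),
                                    normal = c(1, 0, 0)))
  expect_lt(relerr(ortho$area, pi * 1.225^2), 0.005)
  expect_lt(relerr(ortho$effective_diameter, 2.45), 0.005)
  expect_equal(ortho$effective_diameter, 2 * sqrt(ortho$area / pi))

  oblique <- plane_section(mesh, list(origin = c(-5.1, 0, 0),
                                      normal = c(cos(pi / 3), 0, sin(pi / 3))))
  expect_lt(relerr(oblique$area, pi * 1.225^2 / cos(pi / 3)), 0.005)

  expect_error(plane_section(mesh, list(origin = c(50, 0, 0),
                                        normal = c(1, 0, 0))),
               "intersect")
})

test_that("section area converges with refinement at order >= 1", {
  area_err <- vapply(c(16, 32, 64), function(nt) {
    mesh <- cylinder_fixture(radius = 1.225, n_theta = nt, n_axial = 10)
    s <- plane_section(mesh, list(origin = c(-5.05, 0, 0),
                                  normal = c(1, 0, 0)))
    abs(s$area - pi * 1.225^2)
  }, numeric(1))
  expect_true(all(diff(log(area_err)) < -log(2)))  # at least halves per doubling
})

test_that("the nearest-centroid loop is selected when a plane cuts twice", {
  # two parallel tubes; origin near the first one
  t1 <- wssvar:::.tube_mesh(c(-5, 0, 0), c(1, 0, 0), 10, 1, 32, 10)
  t2 <- wssvar:::.tube_mesh(c(-5, 10, 0), c(1, 0, 0), 10, 2, 32, 10)
  m <- wssvar:::.merge_meshes(list(t1, t2))
  mesh <- surface_mesh(m$points, m$triangles)
  s <- plane_section(mesh, list(origin = c(0, 0.5, 0), normal = c(1, 0, 0)))
  expect_equal(length(s$loops), 2L)
  expect_lt(relerr(s$area, pi), 0.01)  # the radius-1 tube, not radius-2
})

test_that("mean velocity integrates plug and Poiseuille profiles", {
  plug <- disc_patch_fixture(profile = function(rho) rep(50, length(rho)))
  expect_equal(as.numeric(mean_velocity(plug)), 50, tolerance = 1e-12)
  expect_identical(attr(mean_velocity(plug), "velocity_mode"), "vector")

  R <- 1.225
  pois <- disc_patch_fixture(
    radius = R, profile = function(rho) 2 * 49 * (1 - (rho / R)^2))
  expect_lt(relerr(as.numeric(mean_velocity(pois)), 49), 0.005)

  # magnitude mode equals vector mode for purely axial flow
  pois_mag <- disc_patch_fixture(
    radius = R, profile = function(rho) 2 * 49 * (1 - (rho / R)^2),
    magnitude_only = TRUE)
  expect_equal(as.numeric(mean_velocity(pois_mag)),
               as.numeric(mean_velocity(pois)))
  expect_identical(attr(mean_velocity(pois_mag), "velocity_mode"),
                   "magnitude")
})

test_that("vector-mode mean velocity ignores in-plane components", {
  base <- disc_patch_fixture()
  swirl <- disc_patch_fixture(extra_inplane = function(d)
    cbind(0, d$points[, 3], -d$points[, 2]) * 30)
  expect_equal(as.numeric(mean_velocity(swirl)),
               as.numeric(mean_velocity(base)))
})

test_that("flow rate applies the exact mm^2 cm/s -> mL/s factor", {
  expect_equal(flow_rate(4.714, 49.0), 0.01 * 4.714 * 49.0)
  expect_equal(flow_rate(4.714, 49.0), 2.30986)
  expect_equal(flow_rate(10, 0), 0)
  expect_error(flow_rate(0, 10), "area")
})

test_that("multi-slice averages behave like arithmetic means", {
  one <- list(geometry = 4.714, velocity = 49)
  five <- rep(list(one), 5)
  expect_equal(multi_slice_average(five), multi_slice_average(list(one)))
  mixed <- list(list(geometry = 4, velocity = 10),
                list(geometry = 5, velocity = 20),
                list(geometry = 6, velocity = 30))
  avg <- multi_slice_average(mixed)
  expect_equal(avg$area, 5)
  expect_equal(avg$velocity, 20)
  expect_equal(avg$diameter, 2 * sqrt(5 / pi))
  expect_error(multi_slice_average(list()), "1 and 5")
  expect_error(multi_slice_average(rep(list(one), 6)), "1 and 5")

  # a tapered tube's averaged diameter lies between the slice extremes
  areas <- pi * seq(1.1, 1.3, length.out = 5)^2
  tapered <- lapply(areas, function(a) list(geometry = a, velocity = 50))
  d <- multi_slice_average(tapered)$diameter
  expect_gt(d, 2.2)
  expect_lt(d, 2.6)
})
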