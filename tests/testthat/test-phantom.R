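test_that("stenotic radius profile passes through its control points", {
  ph <- make_stenotic_airway(base_radius = 10, stenosis_radius = 5,
                             stenosis_z = 40, vocal_cord_radius = 6,
                             vocal_cord_z = 20, axis_length = 80,
                             stenosis_sigma = 4)
  expect_equal(ph$radius_profile(0), 10, tolerance = 1e-9)
  expect_equal(ph$radius_profile(40), 5, tolerance = 1e-9)
  # midway between the apertures: analytic Gaussian dip value
  mid <- 10 - 5 * exp(-0.5 * ((30 - 40) / 4)^2)
  expect_equal(ph$radius_profile(30), mid)
  expect_gt(mid, 5)
  expect_lte(mid, 10)
  # profile positive over the whole axis
  expect_true(all(ph$radius_profile(seq(0, 80, by = 0.5)) > 0))
})

test_that("degenerate phantom parameters are rejected", {
  expect_error(make_stenotic_airway(stenosis_radius = 10), "non-stenotic")
  expect_error(make_stenotic_airway(stenosis_radius = -1), "positive")
  expect_error(make_stenotic_airway(vocal_cord_z = 50, stenosis_z = 40),
               "vocal_cord_z < stenosis_z")
  expect_error(make_stenotic_airway(albedo = 1.5), "albedo")
})

test_that("ray casting matches the closed-form ray/cylinder intersection", {
  # camera at z=5: wall hits land at z < 14, where the radius is base_radius
  # to ~1e-12 (the stenosis dip at z=40 is negligible there), so the hit
  # distance is r / sin(theta) for a ray at angle theta from the axis
  ph <- make_stenotic_airway()
  cam <- fixture_camera()
  rc <- ray_cast_depth(ph, 5, cam)
  for (px in list(c(1, 1), c(96, 96), c(1, 48), c(48, 1), c(96, 48))) {
    u <- px[2] - 1; v <- px[1] - 1
    x <- (u - cam$cx) / cam$fx; y <- (v - cam$cy) / cam$fy
    sin_theta <- sqrt(x^2 + y^2) / sqrt(x^2 + y^2 + 1)
    expect_equal(rc$depth$values[px[1], px[2]], 10 / sin_theta,
                 tolerance = 1e-5)
  }
  # near-axial ray: never reaches the wall, masked as lumen
  rc25 <- ray_cast_depth(ph, 25, cam)   # past the cords membrane
  expect_true(rc25$lumen_mask[48, 48])
  expect_true(rc25$lumen_mask[49, 49])
  # depth positive wherever a ray hit the surface
  expect_true(all(rc$depth$values[rc$depth$valid] > 0))
  # normals unit length at hits
  nn <- with(rc$normals, sqrt(nx^2 + ny^2 + nz^2))
  expect_equal(range(nn[rc$depth$valid]), c(1, 1), tolerance = 1e-9)
  expect_error(ray_cast_depth(ph, -3, cam), "inside the tube")
})

test_that("rendering follows the inverse-square law with gamma encoding", {
  cam1 <- camera_model(40, 40, 47.5, 47.5, 96, 96, gamma = 1)
  rays <- stenoscope:::camera_rays(cam1)
  head_on <- list(nx = -rays$dx, ny = -rays$dy, nz = -rays$dz)  # n.l = 1
  mk_cfg <- function(cam, quant = 16)
    render_config(cam, gain = 1, noise_sigma = 0, quantization = quant)
  d1 <- depth_map(matrix(1, 96, 96))
  # identity case: d=1, albedo=1, n.l=1, gain=1, gamma=1 -> intensity 1
  f1 <- render_frame(d1, head_on, 1, mk_cfg(cam1, quant = 8))
  expect_equal(unique(as.vector(f1)), 1)
  # doubling depth divides linear radiance by 4
  f2 <- render_frame(depth_map(matrix(2, 96, 96)), head_on, 1, mk_cfg(cam1))
  expect_equal(as.vector(f2)[1], 0.25, tolerance = 1e-4)
  # gamma-encoded pixel equals an independent scalar computation
  cam22 <- camera_model(40, 40, 47.5, 47.5, 96, 96, gamma = 2.2)
  d <- matrix(1.7, 96, 96)
  f3 <- render_frame(depth_map(d), head_on, 0.8, mk_cfg(cam22))
  expect_equal(as.vector(f3)[5], (0.8 / 1.7^2)^(1 / 2.2), tolerance = 1e-4)
  expect_error(camera_model(40, 40, 47.5, 47.5, 96, 96, gamma = 0), "gamma")
})

test_that("intensity is non-increasing with depth on straight wall sections", {
  kf <- fixture_keyframe()
  cfg <- kf$config; cfg$noise_sigma <- 0
  frame <- render_frame(kf$raycast$depth, kf$raycast$normals, 1, cfg)
  # wall pixels well away from both the rim and the bump shoulder
  sel <- kf$raycast$depth$valid & kf$raycast$hit_z > 28 & kf$raycast$hit_z < 34
  d <- kf$raycast$depth$values[sel]
  i <- frame[sel]
  o <- order(d)
  # allow one quantization level of slack
  expect_true(all(diff(i[o]) <= 1 / 255 + 1e-12))
})

test_that("sequence rendering is deterministic and darkest blob collapses at the transition", {
  ph <- make_stenotic_airway()
  tr <- axial_trajectory(ph, n_frames = 12, from = 18.5, to = 21.5)
  cfg <- render_config(seed = 11)
  s1 <- render_sequence(ph, tr, cfg)
  s2 <- render_sequence(ph, tr, cfg)
  expect_identical(s1$frames, s2$frames)
  Tt <- s1$ground_truth$transition_index
  expect_false(is.na(Tt))
  area_of <- function(f) {
    seg <- segment_dark_region(to_grayscale(f))
    if (is.null(seg)) 0 else seg$area_px
  }
  pre <- area_of(s1$frames[[Tt]])        # last frame before crossing
  post <- area_of(s1$frames[[Tt + 2]])
  # the half-occluded view gives way to the full stenosis disc: the mask
  # changes enough to break a 50% IoU tracker
  seg_pre <- segment_dark_region(to_grayscale(s1$frames[[Tt]]))
  seg_post <- segment_dark_region(to_grayscale(s1$frames[[Tt + 2]]))
  expect_lt(iou(seg_pre$mask, seg_post$mask), 0.5)
  # post-transition blob is centred at the principal point (aperture on axis)
  expect_lt(abs(seg_post$centroid["row"] - 47.5), 4)
  expect_lt(abs(seg_post$centroid["col"] - 47.5), 4)
  expect_gt(pre, 0)
  expect_gt(post, 0)
  # with no noise the render is a pure function of geometry
  cfg0 <- render_config(seed = 1, noise_sigma = 0)
  cfg0b <- render_config(seed = 99, noise_sigma = 0)
  a <- render_sequence(ph, axial_trajectory(ph, n_frames = 3), cfg0)
  b <- render_sequence(ph, axial_trajectory(ph, n_frames = 3), cfg0b)
  expect_identical(a$frames, b$frames)
  expect_error(axial_trajectory(ph, from = 10, to = 10), "increasing")
})
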