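test_that("the stenosis contour is the outer edge of the mask, in 3D", {
  cam <- camera_model(40, 40, 24, 24, 49, 49, gamma = 2.2)
  rays <- stenoscope:::camera_rays(cam)
  dm <- depth_map(5 / rays$dz)            # fronto-parallel plane z = 5
  pc <- backproject(dm, cam)
  mask <- (rays$u - 24)^2 + (rays$v - 24)^2 <= 8^2   # disc, radius 8 px
  contour <- stenosis_contour_3d(pc, mask)
  # ring of points just outside the disc, at a known metric radius
  rho <- sqrt(contour[, 1]^2 + contour[, 2]^2)
  r_in <- 5 * 8 / 40                      # z * tan at the disc edge
  expect_true(all(rho > r_in - 1e-9))
  expect_true(all(rho < 5 * 10.5 / 40))
  expect_true(all(abs(contour[, 3] - 5) < 1e-9))
  # contour points are a subset of the cloud
  idx <- attr(contour, "pixel_index")
  expect_true(all(idx %in% pc$pixel_index))
  # tiny mask: too few contour points after edge extraction is fine, but a
  # 2-pixel cloud restriction must error
  pc_small <- pc
  pc_small$pixel_index <- pc$pixel_index[1:2]
  pc_small$points <- pc$points[1:2, , drop = FALSE]
  expect_error(suppressWarnings(stenosis_contour_3d(pc_small, mask)),
               "fewer than 3")
})

test_that("total-least-squares plane fit recovers exact and jittered planes", {
  g <- expand.grid(x = seq(-1, 1, 0.2), y = seq(-1, 1, 0.2))
  flat <- cbind(g$x, g$y, 5)
  pl <- fit_plane(flat)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$offset, 5, tolerance = 1e-12)
  # x + z = 1
  tilted <- cbind(g$x, g$y, 1 - g$x)
  pl2 <- fit_plane(tilted)
  expect_equal(pl2$normal, c(1, 0, 1) / sqrt(2), tolerance = 1e-9)
  resid <- tilted %*% pl2$normal - pl2$offset
  expect_lt(max(abs(resid)), 1e-9)
  # symmetric Gaussian jitter sigma = 0.01 tilts the normal < 2 degrees
  set.seed(5)
  for (i in 1:10) {
    noisy <- flat + matrix(rnorm(length(flat), 0, 0.01), ncol = 3)
    pln <- fit_plane(noisy)
    ang <- acos(min(abs(sum(pln$normal * c(0, 0, 1))), 1)) * 180 / pi
    expect_lt(ang, 2)
  }
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_plane(line), "collinear")
})

test_that("Kasa circle fit is exact on circles and matches the circumcircle", {
  phi <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- cbind(cos(phi), sin(phi))
  f <- fit_circle(pts)
  expect_equal(f$center, c(0, 0), tolerance = 1e-12)
  expect_equal(f$diameter, 2, tolerance = 1e-12)
  expect_false(f$poor_fit)
  # jittered circle radius 3 centred (1, -2): diameter 6 within 0.05
  set.seed(9)
  phi2 <- runif(60, 0, 2 * pi)
  pts2 <- cbind(1 + 3 * cos(phi2), -2 + 3 * sin(phi2)) +
    matrix(rnorm(120, 0, 0.01), ncol = 2)
  f2 <- fit_circle(pts2)
  expect_equal(f2$diameter, 6, tolerance = 0.05 / 6)
  expect_equal(f2$center, c(1, -2), tolerance = 0.02)
  # three points: circumscribed circle, cross-checked with the closed form
  tri <- rbind(c(0, 0), c(4, 0), c(1, 3))
  f3 <- fit_circle(tri)
  # closed-form circumcentre from perpendicular bisectors
  ax <- tri[1, 1]; ay <- tri[1, 2]; bx <- tri[2, 1]; by <- tri[2, 2]
  cx <- tri[3, 1]; cy <- tri[3, 2]
  dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / dd
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / dd
  expect_equal(f3$center, c(ux, uy), tolerance = 1e-9)
  expect_equal(f3$diameter, 2 * sqrt((ax - ux)^2 + (ay - uy)^2),
               tolerance = 1e-9)
  expect_error(fit_circle(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("cross-sections of a cylinder recover the disc area", {
  pc <- cylinder_cloud(r = 4)
  pl <- fit_plane(cbind(c(1, -1, 0, 0), c(0, 0, 1, -1), 5))  # plane z = 5
  cs <- cross_section(pc, pl, slab_tolerance = 0.05)
  expect_equal(cs$area, pi * 16, tolerance = 0.05)
  expect_equal(cs$circle_diameter, 8, tolerance = 0.01)
  expect_false("sparse_section" %in% cs$flags)
  expect_error(cross_section(pc, pl, slab_tolerance = 0), "positive")
  # hull area is invariant to an in-plane rotation of the cloud
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pc_rot <- pc
  pc_rot$points <- pc$points %*% t(Rz)
  cs_rot <- cross_section(pc_rot, pl, slab_tolerance = 0.05)
  expect_equal(cs_rot$area, cs$area, tolerance = 1e-9)
  # boundary is ordered counter-clockwise (positive signed area)
  b <- cs$boundary_2d
  j <- c(2:nrow(b), 1)
  signed <- sum(b[, 1] * b[j, 2] - b[j, 1] * b[, 2]) / 2
  expect_gt(signed, 0)
  # a nearly empty slab flags sparsity
  pc_thin <- cylinder_cloud(r = 4, z = seq(4.99, 5.01, length.out = 2),
                            n_phi = 10)
  cs_thin <- cross_section(pc_thin, pl, slab_tolerance = 0.05)
  expect_true("sparse_section" %in% cs_thin$flags)
})

test_that("the reference sweep selects the widest section with first-offset ties", {
  # bulge: radius 6 around z = 5, radius 4 elsewhere
  bulge <- function(z) 4 + 2 * exp(-((z - 5) / 1.5)^2)
  pc <- cylinder_cloud(z = seq(1, 10, by = 0.02), radius_fun = bulge)
  sw <- sweep_reference_plane(pc, z_min = 1, z_max = 9, n_planes = 50,
                              slab_tolerance = 0.05)
  expect_equal(sw$section$area, pi * 36, tolerance = 0.05)
  expect_equal(sw$offsets[sw$index], 5, tolerance = 0.3)
  # argmax contract: no swept plane beats the returned section
  expect_true(all(sw$areas <= sw$section$area + 1e-12))
  # exact tie (identical rings) resolves to the offset nearest the camera
  two_rings <- cylinder_cloud(r = 3, z = c(2, 8), n_phi = 60)
  sw2 <- sweep_reference_plane(two_rings, z_min = 1, z_max = 9,
                               n_planes = 9, slab_tolerance = 0.2)
  expect_equal(sw2$index, 2L)   # offset 2 precedes offset 8
  expect_error(sweep_reference_plane(pc, 5, 5, 10, 0.05), "z_min < z_max")
})

test_that("stenosis indices follow their definitions, unclamped and flagged", {
  r <- compute_indices(10, 10, 3, 3)
  expect_equal(r$psa, 0); expect_equal(r$psd, 0)
  expect_length(r$flags, 0)
  r2 <- compute_indices(2.5, 10, 1.5, 3)
  expect_equal(r2$psa, 75); expect_equal(r2$psd, 50)
  r3 <- compute_indices(12, 10, 3, 3.1)
  expect_equal(r3$psa, -20)
  expect_true("reference_smaller_than_stenosis" %in% r3$flags)
  expect_error(compute_indices(0, 10, 1, 1), "positive")
  expect_error(compute_indices(1, 10, -1, 1), "positive")
})

test_that("keyframe measurement recovers phantom indices within tolerance", {
  kf <- fixture_keyframe()
  rep <- measure_keyframe(kf$frame, fixture_camera())
  expect_equal(rep$psa, 75, tolerance = 5 / 75)
  expect_equal(rep$psd, 50, tolerance = 5 / 50)
  # the paper-facing failure mode: nothing below the dark threshold
  expect_error(measure_keyframe(matrix(200, 96, 96), fixture_camera()),
               "segmentation stage")
})

test_that("PSA and PSD are invariant to the global scale of the cloud", {
  kf <- fixture_keyframe()
  cam <- fixture_camera()
  gray <- to_grayscale(kf$frame)
  seg <- segment_dark_region(gray)
  est <- estimate_depth(gray, cam, "tube_shading")
  cloud <- backproject(est$depth, cam)
  base <- measure_cloud(cloud, seg$mask)
  for (s in c(0.1, 10)) {
    scaled <- cloud
    scaled$points <- cloud$points * s
    m <- measure_cloud(scaled, seg$mask)
    expect_lt(abs(m$psa - base$psa), 1e-6)
    expect_lt(abs(m$psd - base$psd), 1e-6)
    # areas scale by s^2, diameters by s
    expect_equal(m$area_stenosis, base$area_stenosis * s^2,
                 tolerance = 1e-9)
    expect_equal(m$diameter_stenosis, base$diameter_stenosis * s,
                 tolerance = 1e-9)
  }
})
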