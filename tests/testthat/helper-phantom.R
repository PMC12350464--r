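# Shared fixtures, built once per test run and cached.

.fixtures <- new.env()

fixture_camera <- function() default_camera()

# a rendered 100-frame default-phantom sequence (seed 1)
fixture_sequence <- function() {
  if (is.null(.fixtures$seq)) {
    ph <- make_stenotic_airway()
    tr <- axial_trajectory(ph)
    .fixtures$seq <- render_sequence(ph, tr, render_config(seed = 1))
  }
  .fixtures$seq
}

# a single keyframe frame of the default phantom, with ground-truth geometry
fixture_keyframe <- function() {
  if (is.null(.fixtures$kf)) {
    ph <- make_stenotic_airway()
    cfg <- render_config(seed = 2)
    cfg$gain <- auto_gain(ph, 2, cfg)
    rc <- ray_cast_depth(ph, 20.2, cfg$camera)
    set.seed(2)
    frame <- render_frame(rc$depth, rc$normals, ph$albedo, cfg)
    .fixtures$kf <- list(phantom = ph, frame = frame, raycast = rc,
                         config = cfg, pose = 20.2)
  }
  .fixtures$kf
}

# analytic cylinder-surface point cloud: rings of radius r at axial steps
cylinder_cloud <- function(r = 4, z = seq(1, 10, by = 0.05), n_phi = 100,
                           radius_fun = NULL) {
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  g <- expand.grid(phi = phi, z = z)
  rr <- if (is.null(radius_fun)) r else radius_fun(g$z)
  pts <- cbind(x = rr * cos(g$phi), y = rr * sin(g$phi), z = g$z)
  structure(list(points = pts, pixel_index = seq_len(nrow(pts)),
                 dim = c(length(z), n_phi)),
            class = "point_cloud")
}

# synthetic tracking frames: bright background with one dark square
dark_square_frame <- function(h = 64, w = 64, row = 20, col = 20, size = 12,
                              bg = 200, fg = 0) {
  m <- matrix(bg, h, w)
  m[row:(row + size - 1), col:(col + size - 1)] <- fg
  m
}
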