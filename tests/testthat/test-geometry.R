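test_that("total-least-squares plane fit recovers known planes", {
  set.seed(101)
  pts <- cbind(runif(40, -2, 2), runif(40, -2, 2), 0)
  pl <- fit_plane(pts)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl$rms_residual_mm, 0, tolerance = 1e-12)

  # circle tilted 30 degrees about x
  th <- 30 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  circ <- unit_circle(128) %*% t(R)
  pl2 <- fit_plane(circ)
  truth <- c(0, -sin(th), cos(th))
  ang <- acos(min(1, abs(sum(pl2$normal * truth))))
  expect_lt(ang, 1e-6)

  # residual of noisy planar points estimates the noise sd
  reps <- replicate(20, {
    noisy <- cbind(runif(200, -1, 1), runif(200, -1, 1), rnorm(200, sd = 0.01))
    fit_plane(noisy)$rms_residual_mm
  })
  expect_lt(abs(mean(reps) - 0.01) / 0.01, 0.3)

  line <- cbind(seq(0, 1, length.out = 10), seq(0, 2, length.out = 10), 0.5)
  expect_error(fit_plane(line), "collinear")
  expect_error(fit_plane(unit_circle()[1:5, ]), "at least 8")
})

test_that("arc extents measure principal in-plane width and height", {
  ext <- arc_extents(unit_circle(256))
  expect_equal(unname(ext), c(2, 2), tolerance = 1e-9)

  t <- seq(0, 2 * pi, length.out = 513)[-513]
  ell <- cbind(1.0 * cos(t), 0.8 * sin(t), 0)
  e2 <- arc_extents(ell)
  expect_equal(unname(e2), c(1.6, 2.0), tolerance = 1e-3)

  cn <- generate_canal(1.2, aspect = 0.79, n_points = 512)
  e3 <- arc_extents(cn$points)
  expect_equal(unname(e3["height_mm"] / e3["width_mm"]), 0.79, tolerance = 0.02)
})

test_that("linear deviation is the range of signed plane distances", {
  expect_equal(linear_deviation(unit_circle(128)), 0, tolerance = 1e-12)

  # symmetric sinusoidal warp of amplitude A spans 2A
  cn <- generate_canal(1, warp_amplitude_mm = 0.1, warp_cycles = 2, n_points = 512)
  expect_equal(linear_deviation(cn$points), 0.2, tolerance = 0.02 * 0.2)

  # one-sided bump of height A on an otherwise planar arc
  t <- seq(0, 2 * pi, length.out = 257)[-257]
  A <- 0.2
  bump <- ifelse(t < pi / 4, A * sin(4 * t)^2, 0)
  pts <- cbind(cos(t), sin(t), bump)
  ld <- linear_deviation(pts)
  expect_gt(ld, A * 0.95)
  expect_lt(ld, A * 1.15)   # bump height plus the small fit shift
})

test_that("inter-plane angles honour the reference-point orientation", {
  p1 <- fit_plane(unit_circle(64))
  pts2 <- unit_circle(64)[, c(1, 3, 2)]  # plane y = 0
  p2 <- fit_plane(pts2)
  expect_equal(interplane_angle(p1, p2, c(0, 1, 1)), 90, tolerance = 1e-9)
  expect_equal(interplane_angle(p1, p1, c(0, 0, 1)), 0, tolerance = 1e-9)

  # generator truth: canals installed at an obtuse angle triple
  b <- generate_labyrinth(angles_deg = c(109, 102, 104))
  ang <- measure_labyrinth(b)$angles_deg
  expect_equal(unname(ang), c(109, 102, 104), tolerance = 0.5 / 104)
})

test_that("cochlear coiling unwraps the azimuth about the axis", {
  ax <- list(origin = c(0, 0, 0), direction = c(0, 0, 1))
  t <- seq(0, 2 * pi, length.out = 257)      # closed sweep incl. the endpoint
  full <- cbind(cos(t), sin(t), 0)
  expect_equal(cochlear_coiling(full, ax), 360, tolerance = 1e-6)

  helix <- generate_cochlea(792, basal_radius_mm = 1, taper_per_turn_mm = 0.2,
                            height_mm = 1.5)
  expect_equal(cochlear_coiling(helix$points, helix$axis), 792, tolerance = 2 / 792)
  # orientation independence
  expect_equal(cochlear_coiling(helix$points[rev(seq_len(nrow(helix$points))), ], helix$axis),
               cochlear_coiling(helix$points, helix$axis))
  on_axis <- cbind(0, 0, seq(0, 1, length.out = 16))
  expect_error(cochlear_coiling(on_axis, ax), "axis")
})

test_that("cochlear profile gives height, basal width and aspect", {
  ax <- list(origin = c(0, 0, 0), direction = c(0, 0, 1))
  flat <- generate_cochlea(720, 1, height_mm = 0)
  prof <- cochlear_profile(flat$points, flat$axis)
  expect_equal(unname(prof["aspect_ratio"]), 0)

  tall <- generate_cochlea(1457, 1, taper_per_turn_mm = 0.18,
                           height_mm = 1.29 * (2 - 0.18 / 2))
  p2 <- cochlear_profile(tall$points, tall$axis)
  expect_equal(unname(p2["aspect_ratio"]), 1.29, tolerance = 0.02)

  # uniform scaling leaves the aspect unchanged
  p3 <- cochlear_profile(tall$points * 3.7,
                         list(origin = c(0, 0, 0), direction = c(0, 0, 1)))
  expect_equal(unname(p3["aspect_ratio"]), unname(p2["aspect_ratio"]), tolerance = 1e-9)
  expect_equal(unname(p3["height_mm"]), 3.7 * unname(p2["height_mm"]), tolerance = 1e-9)

  expect_warning(cochlear_profile(generate_cochlea(300, 1)$points, ax), "less than one turn")
})

test_that("sagittal index measures the below-plane share of the posterior arc", {
  lat <- fit_plane(unit_circle(64))            # plane z = 0
  t <- seq(0, 2 * pi, length.out = 129)[-129]
  dorsal <- c(0, 0, 1)

  above <- cbind(cos(t), 0.1 * sin(t), 1 + sin(t))   # entirely above z = 0
  expect_equal(sagittal_index(above, lat, dorsal), 0)

  centred <- cbind(cos(t), 0.1 * sin(t), sin(t))     # plane through span midpoint
  expect_equal(sagittal_index(centred, lat, dorsal), 50, tolerance = 1)

  # offset placing 30% of the span below the plane
  shifted <- cbind(cos(t), 0.1 * sin(t), sin(t) + (1 - 2 * 0.3))
  expect_equal(sagittal_index(shifted, lat, dorsal), 30, tolerance = 1)
})

test_that("measurements are rigid-motion invariant and scale correctly", {
  set.seed(77)
  cn <- generate_canal(1.46, aspect = 0.9, warp_amplitude_mm = 0.11,
                       warp_cycles = 2, n_points = 256)
  base_ext <- arc_extents(cn$points)
  base_ld <- linear_deviation(cn$points)
  for (i in 1:5) {
    moved <- rigid_motion(cn$points)
    expect_equal(unname(arc_extents(moved)), unname(base_ext), tolerance = 1e-9)
    expect_equal(linear_deviation(moved), base_ld, tolerance = 1e-9)
    expect_equal(fit_plane(moved)$rms_residual_mm, fit_plane(cn$points)$rms_residual_mm,
                 tolerance = 1e-9)
  }
  # lengths scale linearly under uniform scaling
  expect_equal(unname(arc_extents(2.5 * cn$points)), 2.5 * unname(base_ext),
               tolerance = 1e-9)
  expect_equal(linear_deviation(2.5 * cn$points), 2.5 * base_ld, tolerance = 1e-9)
  # angles are scale invariant
  b <- generate_labyrinth(angles_deg = c(95, 88, 101))
  b2 <- b
  for (nm in names(b2$canals)) b2$canals[[nm]]$points <- 2 * b2$canals[[nm]]$points
  expect_equal(measure_labyrinth(b2)$angles_deg, measure_labyrinth(b)$angles_deg,
               tolerance = 1e-9)
})

test_that("plane residual vanishes exactly when points are coplanar", {
  set.seed(5)
  n <- c(1, 2, 2); n <- n / sqrt(sum(n^2))
  fr_e1 <- c(2, -1, 0) / sqrt(5)
  fr_e2 <- c(n[2] * fr_e1[3] - n[3] * fr_e1[2],
             n[3] * fr_e1[1] - n[1] * fr_e1[3],
             n[1] * fr_e1[2] - n[2] * fr_e1[1])
  uv <- matrix(runif(60, -3, 3), ncol = 2)
  pts <- uv[, 1] %o% fr_e1 + uv[, 2] %o% fr_e2
  expect_lt(fit_plane(pts)$rms_residual_mm, 1e-9)
  warped <- pts + 0.001 * matrix(rnorm(90), ncol = 3)
  expect_gt(fit_plane(warped)$rms_residual_mm, 1e-9)
})
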