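test_that("coarse initialization recovers translations and axial rotations", {
  # an ellipsoidal blob fully inside the grid: translating it moves the
  # intensity centroid exactly, so the recovered shift is the oracle
  d <- c(48L, 48L, 48L)
  blob <- function(c1, c2, c3) {
    g <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
    v <- 100 + 1900 * (((g$i - c1) / 14)^2 + ((g$j - c2) / 9)^2 +
                         ((g$k - c3) / 6)^2 <= 1)
    volume3d(array(v, d), spacing_mm = 0.082)
  }
  fixed <- blob(24, 24, 24)
  moving <- blob(24 + 3, 24 - 2, 24 + 5)
  init <- initialize_transform(fixed, moving)
  expect_lt(max(abs(init$translation_mm - c(-3, 2, -5) * 0.082)), 0.082)
  expect_lt(tf_rotation_angle_deg(init), 2)

  # moving = fixed rotated 10 degrees about the axial axis (same FOV)
  ph <- make_phantom(tiny_spec())
  d2 <- dim(ph$volume$data)
  rot <- rigid_transform(angles_rad = c(10, 0, 0) * pi / 180)
  fu <- make_followup(ph, motion = rot, followup_slices = d2[1],
                      distal_margin_slices = 0L)
  init2 <- initialize_transform(ph$volume, fu$volume)
  expect_lt(tf_rotation_angle_deg(init2, fu$truth_transform), 2)

  flat <- volume3d(array(0, c(4, 4, 4)))
  expect_error(initialize_transform(flat, flat), "foreground")
})

test_that("mutual information behaves like an information measure", {
  ph <- make_phantom(tiny_spec(noise_sd = 60, seed = 3))
  v <- ph$volume
  mi_self <- mutual_information(v, v, rigid_transform(), bins = 32)
  # self-MI equals the marginal entropy of the binned intensities
  r <- range(v$data)
  b <- pmin(floor((as.numeric(v$data) - r[1]) / diff(r) * 32), 31)
  p <- tabulate(b + 1, 32) / length(b)
  p <- p[p > 0]
  expect_equal(as.numeric(mi_self), -sum(p * log(p)), tolerance = 1e-8)

  # independent noise volumes carry (almost) no mutual information
  set.seed(5)
  n1 <- volume3d(array(rnorm(40^3), c(40, 40, 40)))
  n2 <- volume3d(array(rnorm(40^3), c(40, 40, 40)))
  expect_lt(as.numeric(mutual_information(n1, n2, rigid_transform(), 16)),
            0.05)

  # invariant under linear intensity relabeling (bin-preserving)
  v2 <- volume3d(v$data * 2 + 500, spacing_mm = v$spacing_mm)
  expect_equal(as.numeric(mutual_information(v, v2, rigid_transform(), 32)),
               as.numeric(mi_self), tolerance = 1e-10)

  far <- rigid_transform(translation_mm = c(500, 0, 0))
  expect_error(mutual_information(v, v, far), "overlap")
})

test_that("rigid registration recovers a known motion under noise", {
  pair <- tiny_pair(noise_sd = 100, seed = 2,
                    motion = rigid_transform(
                      angles_rad = c(5, 0, 0) * pi / 180,
                      translation_mm = c(0.5, -0.3, 0.3)))
  reg <- register_rigid(pair$ph$volume, pair$fu$volume)
  err <- transform_errors(reg$transform, pair$fu$truth_transform, pair$ph)
  expect_lt(err["rot_deg"], 0.5)
  expect_lt(err["trans_vox"], 0.5)
  expect_gte(reg$mi_final, reg$mi_init)
})

test_that("registration of a volume onto itself stays at identity", {
  ph <- make_phantom(tiny_spec(noise_sd = 40, seed = 6))
  reg <- register_rigid(ph$volume, ph$volume, init = rigid_transform(),
                        params = registration_params(axial_sweep_mm = 0))
  expect_lt(tf_rotation_angle_deg(reg$transform), 0.2)
  expect_lt(max(abs(reg$transform$translation_mm)), 0.05)
  expect_gte(reg$mi_final, reg$mi_init)
})

test_that("trilinear re-slicing is exact at grid nodes and integer shifts", {
  ph <- make_phantom(tiny_spec(noise_sd = 80, seed = 4))
  v <- ph$volume
  # identity onto own grid: exact
  out <- resample_to_baseline(v, rigid_transform(), v)
  expect_equal(out$volume$data, v$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(out$valid))
  expect_equal(out$volume$frame, "baseline-registered")

  # pure integer-voxel translation: exact on the overlap
  sh <- rigid_transform(translation_mm = c(2, -3, 4) * 0.082)
  out2 <- resample_to_baseline(v, sh, v)
  d <- dim(v$data)
  expect_equal(out2$volume$data[3:d[1], 1:(d[2] - 3), 5:d[3]],
               v$data[1:(d[1] - 2), 4:d[2], 1:(d[3] - 4)],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_false(any(out2$valid[1:2, , ]))

  # constant volume stays constant on valid voxels under any transform
  cv <- volume3d(array(7, c(30, 30, 30)))
  tfr <- rigid_transform(angles_rad = c(0.2, -0.1, 0.3),
                         translation_mm = c(0.3, 0.2, -0.4))
  out3 <- resample_to_baseline(cv, tfr, cv)
  expect_true(all(abs(out3$volume$data[out3$valid] - 7) < 1e-9))
})

test_that("re-slicing forward then back reproduces the volume within blur", {
  # full acquisition-scale heads: the interpolation error concentrates in a
  # thin surface band, so it is judged at the geometry the pipeline measures
  ph <- make_phantom(phantom_spec(seed = 1))
  v <- ph$volume
  tfr <- rigid_transform(angles_rad = c(2, 1, -1.5) * pi / 180,
                         translation_mm = c(0.13, -0.21, 0.08))
  fwd <- resample_to_baseline(v, tfr, v)
  back <- resample_to_baseline(fwd$volume, tf_inverse(tfr), v)
  both <- fwd$valid & back$valid
  mae <- mean(abs(back$volume$data[both] - v$data[both]))
  expect_lt(mae, 0.02 * ph$spec$intensity_bone)
})

test_that("registration error stays within half a degree and half a voxel
           across random motions on noiseless phantoms", {
  ph <- make_phantom(tiny_spec())
  ph <- implant_lesion(ph, "erosion",
                       surface_point(ph, "MCH3", "palmar"), 2.5, "E1")
  set.seed(20)
  for (i in 1:5) {
    motion <- rigid_transform(
      angles_rad = runif(3, -10, 10) * pi / 180,
      translation_mm = c(runif(1, -2, 2), runif(2, -0.6, 0.6)))
    fu <- make_followup(ph, motion = motion, followup_slices = 128L,
                        distal_margin_slices = 24L)
    reg <- register_rigid(ph$volume, fu$volume)
    err <- transform_errors(reg$transform, fu$truth_transform, ph)
    expect_lt(err["rot_deg"], 0.5)
    expect_lt(err["trans_vox"], 0.5)
    expect_gte(reg$mi_final, reg$mi_init)
  }
})
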