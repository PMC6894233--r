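test_that("phantom geometry matches the acquisition it emulates", {
  spec <- tiny_spec(grid = c(110L, 48L, 88L))
  ph <- make_phantom(spec)
  expect_equal(axial_extent_mm(ph$volume), 9.02)
  # periosteal mask is exactly the at-or-inside-surface voxel set: every
  # cortex voxel is periosteal, no background voxel is
  expect_true(all(ph$periosteal[ph$cortex]))
  expect_true(all(ph$compartment[!ph$periosteal] == 0L))
  expect_setequal(unique(ph$compartment[ph$periosteal]), c(1L, 2L))
  # three-level intensity model
  expect_setequal(unique(as.numeric(ph$volume$data)),
                  c(spec$intensity_background, spec$intensity_trabecular,
                    spec$intensity_bone))
})

test_that("phantom generation is deterministic and rejects bad geometry", {
  a <- make_phantom(tiny_spec(noise_sd = 50, seed = 9))
  b <- make_phantom(tiny_spec(noise_sd = 50, seed = 9))
  expect_identical(a$volume$data, b$volume$data)
  c <- make_phantom(tiny_spec(noise_sd = 50, seed = 10))
  expect_false(identical(a$volume$data, c$volume$data))

  expect_error(make_phantom(tiny_spec(grid = c(64L, 10L, 20L))),
               "grid too small")
  expect_error(phantom_spec(cortex_thickness_mm = 5,
                            cortex_outer_radius_mm = 3.5),
               "cortex_thickness_mm")
})

test_that("solid-cortex limit empties the trabecular interior", {
  spec <- tiny_spec(radius = 1.4, thickness = 1.4)
  ph <- make_phantom(spec)
  trabecular <- sum(ph$volume$data == spec$intensity_trabecular)
  expect_equal(trabecular, 0)
})

test_that("implanted lesions hit their target volume to half a voxel", {
  ph <- make_phantom(tiny_spec())
  ph <- implant_lesion(ph, "enthesiophyte",
                       surface_point(ph, "MCH3", "palmar"), 3.4, "B1")
  rec <- ph$lesions$B1
  expect_lte(abs(rec$vol_t0_mm3 - 3.4), 0.082^3)
  expect_equal(rec$vol_t0_mm3, length(rec$mask_idx_t0) * 0.082^3)
  expect_equal(rec$compartment, "MCH3")
  expect_equal(rec$quadrant, "palmar")
  # enthesiophyte voxels all lie outside the unmodified periosteal surface
  expect_true(all(!ph$periosteal[rec$mask_idx_t0]))

  # single-voxel lesion
  ph <- implant_lesion(ph, "enthesiophyte",
                       surface_point(ph, "MCH2", "dorsal"), 0.082^3, "B2")
  expect_equal(length(ph$lesions$B2$mask_idx_t0), 1L)
  expect_equal(ph$lesions$B2$vol_t0_mm3, 0.082^3)
})

test_that("erosions break the cortex on >= 2 consecutive slices or are rejected", {
  ph <- make_phantom(tiny_spec())
  ph <- implant_lesion(ph, "erosion",
                       surface_point(ph, "MCH3", "dorsal"), 2.5, "E1")
  rec <- ph$lesions$E1
  # all voxels inside the periosteal surface, intensity carved to background
  expect_true(all(ph$periosteal[rec$mask_idx_t0]))
  expect_true(all(ph$volume$data[rec$mask_idx_t0] ==
                    ph$spec$intensity_background))
  d <- dim(ph$volume$data)
  cortex_slices <- sort(unique(
    (rec$mask_idx_t0[ph$cortex[rec$mask_idx_t0]] - 1) %% d[1] + 1))
  expect_gte(length(cortex_slices), 2)
  expect_true(any(diff(cortex_slices) == 1))

  # a one-voxel erosion cannot span two slices
  expect_error(implant_lesion(ph, "erosion",
                              surface_point(ph, "MCH2", "palmar"), 0.082^3),
               "two consecutive")
  # absurd volume exceeds the site capacity
  expect_error(implant_lesion(ph, "erosion",
                              surface_point(ph, "MCH2", "palmar"), 500),
               "exceeds")
})

test_that("follow-up rendering honours identity motion, deltas and extent", {
  pair <- tiny_pair(noise_sd = 0,
                    motion = rigid_transform(), deltas = c())
  ph <- pair$ph
  fu <- make_followup(ph, motion = rigid_transform(),
                      followup_slices = 128L, distal_margin_slices = 24L)
  # identity motion: overlapping slab equals baseline (zero noise)
  d1 <- dim(ph$volume$data)[1]
  expect_equal(fu$volume$data[24 + (1:d1), , ], ph$volume$data,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(axial_extent_mm(fu$volume), 128 * 0.082)
  # recorded truth transform carries the acquisition offset
  expect_equal(fu$truth_transform$translation_mm, c(-24 * 0.082, 0, 0))

  # requested growth lands within one voxel, masks are nested
  fu2 <- make_followup(ph, volume_deltas_mm3 = c(E1 = 0.6),
                       followup_slices = 128L, distal_margin_slices = 24L)
  rec <- fu2$lesions$E1
  expect_lte(abs((rec$vol_t5_mm3 - rec$vol_t0_mm3) - 0.6), 0.082^3)
  expect_true(all(rec$mask_idx_t0 %in% rec$mask_idx_t5))
  # 322-slice default emulates the long follow-up stack
  fu3 <- make_followup(ph)
  expect_equal(axial_extent_mm(fu3$volume), 26.404)

  expect_error(make_followup(ph, volume_deltas_mm3 = c(E1 = -99)), "negative")
  expect_error(make_followup(ph, volume_deltas_mm3 = c(NOPE = 1)), "unknown")
})

test_that("lesion volumes always equal mask cardinality times voxel volume", {
  pair <- tiny_pair()
  for (rec in pair$fu$lesions) {
    expect_equal(rec$vol_t0_mm3, length(rec$mask_idx_t0) * VOXVOL)
    expect_equal(rec$vol_t5_mm3, length(rec$mask_idx_t5) * VOXVOL)
  }
})
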