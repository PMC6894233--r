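test_that("periosteal segmentation recovers the ground-truth envelope", {
  # noiseless and noisy intact cortex; a wide erosion break is the job of
  # the reference-surface convention, not of re-segmentation
  for (ns in c(0, 60)) {
    ph <- make_phantom(tiny_spec(noise_sd = ns, seed = 8))
    lp <- lesion_params_for(ph$spec)
    seg <- segment_periosteal(ph$volume, lp$bone_threshold)
    dice <- 2 * sum(seg & ph$periosteal) / (sum(seg) + sum(ph$periosteal))
    expect_gte(dice, 0.99)
  }

  flat <- volume3d(array(100, c(10, 10, 10)))
  expect_error(segment_periosteal(flat, 500), "above every intensity")
  expect_error(segment_periosteal(ph$volume, 1e6), "above every intensity")
})

test_that("seeded growth measures erosions and enthesiophytes accurately", {
  ph <- make_phantom(tiny_spec(noise_sd = 100, seed = 12))  # 5% of bone
  ph <- implant_lesion(ph, "erosion",
                       surface_point(ph, "MCH3", "palmar"), 4.2, "E1")
  ph <- implant_lesion(ph, "enthesiophyte",
                       surface_point(ph, "MCH2", "ulnar"), 3.4, "B1")
  lp <- lesion_params_for(ph$spec)
  d <- dim(ph$volume$data)

  e <- segment_lesion(ph$volume, ph$periosteal,
                      arrayInd(ph$lesions$E1$mask_idx_t0[1], d)[1, ],
                      "erosion", lp, lesion_id = "E1")
  expect_lt(abs(e$volume_mm3 - ph$lesions$E1$vol_t0_mm3),
            0.05 * ph$lesions$E1$vol_t0_mm3)
  expect_true(e$cortical_break_ok)

  b <- segment_lesion(ph$volume, ph$periosteal,
                      arrayInd(ph$lesions$B1$mask_idx_t0[1], d)[1, ],
                      "enthesiophyte", lp, lesion_id = "B1")
  expect_lt(abs(b$volume_mm3 - ph$lesions$B1$vol_t0_mm3),
            0.05 * ph$lesions$B1$vol_t0_mm3)

  # a single implanted voxel measures exactly one voxel volume
  ph2 <- make_phantom(tiny_spec())
  ph2 <- implant_lesion(ph2, "enthesiophyte",
                        surface_point(ph2, "MCH3", "radial"), 0.082^3, "B2")
  lp2 <- lesion_params_for(ph2$spec)
  b2 <- segment_lesion(ph2$volume, ph2$periosteal,
                       arrayInd(ph2$lesions$B2$mask_idx_t0[1],
                                dim(ph2$volume$data))[1, ],
                       "enthesiophyte", lp2)
  expect_equal(b2$volume_mm3, 0.082^3)
})

test_that("seeds on the wrong side of the reference surface are rejected", {
  ph <- make_phantom(tiny_spec())
  lp <- lesion_params_for(ph$spec)
  expect_error(segment_lesion(ph$volume, ph$periosteal, c(2, 2, 2),
                              "erosion", lp),
               "outside the reference")
  inside <- arrayInd(which(ph$periosteal)[1], dim(ph$volume$data))[1, ]
  expect_error(segment_lesion(ph$volume, ph$periosteal, inside,
                              "enthesiophyte", lp),
               "inside the reference")
  # erosion seed inside bone but on healthy trabecular tissue: nothing grows
  expect_error(segment_lesion(ph$volume, ph$periosteal, inside,
                              "erosion", lp),
               "not compatible")
  expect_error(segment_lesion(ph$volume, ph$periosteal, c(0, 0, 0),
                              "erosion", lp),
               "outside the volume")
})

make_records <- function(ids, kind, comp, vols, centers) {
  data.frame(lesion_id = ids, kind = kind, compartment = comp,
             quadrant = "palmar", volume_mm3 = vols,
             centroid_1 = centers[, 1], centroid_2 = centers[, 2],
             centroid_3 = centers[, 3], timepoint = "t0")
}

test_that("lesion pairing matches by proximity with deterministic tie-breaks", {
  b <- make_records(c("A", "B"), "erosion", "MCH2", c(2, 3),
                    rbind(c(0, 0, 0), c(5, 5, 5)))
  f <- make_records(c("A2", "B2", "C2"), "erosion", "MCH2", c(2.5, 3.5, 1),
                    rbind(c(0.1, 0, 0), c(5, 5.1, 5), c(9, 9, 9)))
  p <- pair_lesions(b, f)
  expect_equal(sort(p$status), c("matched", "matched", "new"))
  expect_equal(p$delta_mm3[p$lesion_id == "A"], 0.5)
  expect_equal(p$vol_t0_mm3[p$status == "new"], 0)

  # identical sets: all matched with zero delta
  p2 <- pair_lesions(b, b)
  expect_true(all(p2$status == "matched"))
  expect_true(all(p2$delta_mm3 == 0))

  # two equidistant candidates: the lower follow-up lesion id wins
  f3 <- make_records(c("Z", "Y"), "erosion", "MCH2", c(1, 1),
                     rbind(c(0.5, 0, 0), c(-0.5, 0, 0)))
  b3 <- make_records("A", "erosion", "MCH2", 2, rbind(c(0, 0, 0)))
  p3 <- pair_lesions(b3, f3)
  expect_equal(p3$vol_t5_mm3[p3$lesion_id == "A"], 1)
  expect_equal(p3$lesion_id[p3$status == "new"], "Z")

  # kind and compartment gate the match even at distance zero
  f4 <- make_records("A4", "enthesiophyte", "MCH2", 2, rbind(c(0, 0, 0)))
  p4 <- pair_lesions(b3, f4)
  expect_setequal(p4$status, c("lost", "new"))
})

test_that("pairing is symmetric under swapping the time points", {
  set.seed(33)
  mk <- function(n, prefix) {
    make_records(sprintf("%s%02d", prefix, 1:n), "erosion", "MCH3",
                 runif(n, 1, 5), matrix(runif(3 * n, 0, 8), n, 3))
  }
  b <- mk(8, "b")
  f <- mk(7, "f")
  fwd <- pair_lesions(b, f)
  rev <- pair_lesions(f, b)
  expect_equal(sum(fwd$status == "new"), sum(rev$status == "lost"))
  expect_equal(sum(fwd$status == "lost"), sum(rev$status == "new"))
  key <- function(p) p[order(p$lesion_id), ]
  expect_equal(sort(fwd$delta_mm3), sort(-rev$delta_mm3))
})
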