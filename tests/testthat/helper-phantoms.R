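# Small phantom fixtures built in code. Grids are kept well below the
# acquisition defaults so each test constructs its volumes in well under a
# second; geometry and intensity levels match the generator defaults.

tiny_spec <- function(noise_sd = 0, seed = 1L, grid = c(64L, 48L, 88L),
                      radius = 1.4, thickness = 0.4) {
  phantom_spec(grid_shape = as.integer(grid),
               cortex_outer_radius_mm = radius,
               cortex_thickness_mm = thickness,
               noise_sd = noise_sd, seed = seed)
}

# A lesioned baseline + follow-up pair under a modest known motion.
tiny_pair <- function(noise_sd = 0, seed = 1L,
                      motion = rigid_transform(
                        angles_rad = c(3, 1, -2) * pi / 180,
                        translation_mm = c(0.4, -0.2, 0.3)),
                      deltas = c(E1 = 0.6, B1 = 1.0)) {
  ph <- make_phantom(tiny_spec(noise_sd = noise_sd, seed = seed))
  ph <- implant_lesion(ph, "erosion",
                       surface_point(ph, "MCH3", "palmar"), 3.0, "E1")
  ph <- implant_lesion(ph, "enthesiophyte",
                       surface_point(ph, "MCH2", "ulnar"), 2.0, "B1")
  fu <- make_followup(ph, motion = motion, volume_deltas_mm3 = deltas,
                      followup_slices = 128L, distal_margin_slices = 24L)
  list(ph = ph, fu = fu)
}

# Target-registration-style errors of a recovered transform against truth:
# rotation geodesic angle (degrees) and displacement at the bone centroid
# (voxels).
transform_errors <- function(recovered, truth, phantom) {
  sp <- phantom$spec$voxel_size_mm
  ctr <- (dim(phantom$volume$data) - 1) * sp / 2
  rot <- tf_rotation_angle_deg(recovered, truth)
  tr <- sqrt(sum((tf_apply(recovered, ctr) - tf_apply(truth, ctr))^2)) / sp
  c(rot_deg = rot, trans_vox = tr)
}

VOXVOL <- 0.082^3
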