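#' End-to-end phantom measurement pipeline
#'
#' Runs the full baseline-indexed measurement chain on a simulated pair:
#' registration of the follow-up onto the baseline grid (or the ground-truth
#' transform, for isolating volumetry from registration), trilinear
#' re-slicing, slice matching, ROI definition, seeded segmentation of every
#' ground-truth lesion at both time points using baseline seeds propagated
#' into follow-up space, pairing, and SDC-thresholded classification.
#'
#' Boundary trimming follows the rule: trim the three boundary slices
#' whenever no lesion touches the would-be-trimmed slabs; otherwise keep
#' them with a warning, so no lesion is clipped by the guard band.
#'
#' @param phantom a lesioned [make_phantom] result.
#' @param followup a [make_followup] result.
#' @param reg_params [registration_params] for the rigid registration.
#' @param les_params [lesion_params]; default derived from the phantom's
#'   intensity model.
#' @param sdc per-kind SDC thresholds ([default_sdc]).
#' @param use_truth_transform skip registration and use the simulated
#'   ground-truth motion.
#' @param use_truth_surface use the phantom's ground-truth periosteal mask
#'   as reference surface (default); otherwise [segment_periosteal] is run
#'   on the baseline volume.
#' @return list with `transform`, `registration` (`NULL` when the truth
#'   transform is used), `resampled`, `slice_range`, `roi`, `records_t0`,
#'   `records_t5`, `pairs`, `dynamics`.
#' @export
quantify_pair <- function(phantom, followup,
                          reg_params = registration_params(),
                          les_params = NULL,
                          sdc = default_sdc(),
                          use_truth_transform = FALSE,
                          use_truth_surface = TRUE) {
  stopifnot(inherits(phantom, "phantom"))
  spec <- phantom$spec
  if (is.null(les_params)) les_params <- lesion_params_for(spec)

  registration <- NULL
  if (use_truth_transform) {
    transform <- followup$truth_transform
  } else {
    registration <- register_rigid(phantom$volume, followup$volume,
                                   params = reg_params)
    transform <- registration$transform
  }
  res <- resample_to_baseline(followup$volume, transform, phantom$volume,
                              fill = spec$intensity_background)

  surface <- if (use_truth_surface) phantom$periosteal else
    segment_periosteal(phantom$volume, les_params$bone_threshold)

  sr <- match_slices(phantom$volume, res$volume, res$valid,
                     bone_mask = surface)
  d <- dim(phantom$volume$data)
  trim <- TRUE
  if (sr$n_slices >= 7) {
    slab <- c(sr$start:(sr$start + 2), (sr$end - 2):sr$end)
    touched <- any(vapply(followup$lesions, function(l) {
      idx <- c(l$mask_idx_t0, l$mask_idx_t5)
      any(((idx - 1) %% d[1] + 1) %in% slab)
    }, TRUE))
    if (touched) {
      warning("lesions touch the boundary slices; keeping them untrimmed")
      trim <- FALSE
    }
  }
  roi <- define_roi(phantom$volume, surface, sr, trim_boundary = trim)

  seg_one <- function(vol, lesion, timepoint) {
    seed <- arrayInd(lesion$mask_idx_t0[1], d)[1, ]
    tryCatch(
      segment_lesion(vol, surface, seed, lesion$kind, les_params,
                     lesion_id = lesion$lesion_id,
                     compartment = lesion$compartment,
                     quadrant = lesion$quadrant,
                     roi = roi, timepoint = timepoint),
      error = function(e) {
        # fully resorbed (or never formed) at this time point
        structure(list(lesion_id = lesion$lesion_id, kind = lesion$kind,
                       compartment = lesion$compartment,
                       quadrant = lesion$quadrant, seed = seed,
                       mask = array(FALSE, d), volume_mm3 = 0,
                       centroid_mm = (seed - 1) * spec$voxel_size_mm,
                       timepoint = timepoint, cortical_break_ok = NA,
                       touches_boundary = FALSE),
                  class = "lesion_record")
      })
  }
  records_t0 <- lapply(followup$lesions, seg_one, vol = phantom$volume,
                       timepoint = "t0")
  records_t5 <- lapply(followup$lesions, seg_one, vol = res$volume,
                       timepoint = "t5")
  pairs <- pair_lesions(lesion_table(records_t0), lesion_table(records_t5))
  dynamics <- lesion_dynamics(pairs, sdc)
  list(transform = transform, registration = registration, resampled = res,
       slice_range = sr, roi = roi,
       records_t0 = records_t0, records_t5 = records_t5,
       pairs = pairs, dynamics = dynamics)
}
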