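#' Segment the periosteal (outer cortical) envelope
#'
#' Thresholds the volume at a bone threshold, closes small cortical
#' interruptions (binary dilation then per-slice hole filling then erosion
#' with a spherical element) and returns the filled mask: every voxel at or
#' inside the outer cortical surface.
#'
#' @param volume a [volume3d].
#' @param bone_threshold intensity separating bone from everything else;
#'   must lie strictly between the volume minimum and maximum.
#' @param closing_radius_vox radius (voxels) of the morphological closing.
#' @return logical array (the periosteal mask).
#' @export
segment_periosteal <- function(volume, bone_threshold,
                               closing_radius_vox = 2) {
  stopifnot(inherits(volume, "volume3d"))
  r <- range(volume$data)
  if (bone_threshold >= r[2])
    stop("bone_threshold is above every intensity; no bone voxels")
  bin <- volume$data >= bone_threshold
  if (!any(bin)) stop("no bone voxels above threshold")
  d <- dim(volume$data)
  m <- cpp_binary_dilate(bin, d, closing_radius_vox)
  m <- cpp_fill_slices(m, d)
  m <- cpp_binary_erode(m, d, closing_radius_vox)
  m | bin
}

#' Parameters for seeded lesion segmentation
#'
#' @param erosion_max_intensity upper intensity bound for erosion growth
#'   (erosions are resorption cavities at soft-tissue/background density);
#'   grown voxels satisfy `v <= erosion_max_intensity`.
#' @param bone_threshold bone-vs-soft-tissue threshold used for periosteal
#'   segmentation (cortical bone against trabecular/soft tissue).
#' @param enthesiophyte_min_intensity lower intensity bound for
#'   enthesiophyte growth. New bone is measured against *background*, so an
#'   interpolation-neutral threshold sits midway between background and
#'   bone, not at `bone_threshold`; a midway threshold keeps re-sliced
#'   (trilinearly blurred) volumes unbiased.
#' @param cortex_shell_vox thickness (voxels) of the surface shell used to
#'   test that an erosion contacts a cortical break.
#' @return an object of class `lesion_params`.
#' @export
lesion_params <- function(erosion_max_intensity, bone_threshold,
                          enthesiophyte_min_intensity = bone_threshold,
                          cortex_shell_vox = 2) {
  structure(list(erosion_max_intensity = erosion_max_intensity,
                 bone_threshold = bone_threshold,
                 enthesiophyte_min_intensity = enthesiophyte_min_intensity,
                 cortex_shell_vox = cortex_shell_vox),
            class = "lesion_params")
}

#' Default lesion parameters for a phantom's intensity model
#' @param spec a [phantom_spec].
#' @return a [lesion_params] with each threshold midway between the two
#'   intensity levels meeting at the boundary it detects: erosion cavities
#'   against trabecular bone, cortical bone against trabecular tissue, and
#'   enthesiophyte bone against background.
#' @export
lesion_params_for <- function(spec) {
  lesion_params(
    erosion_max_intensity = (spec$intensity_background +
                               spec$intensity_trabecular) / 2,
    bone_threshold = (spec$intensity_trabecular + spec$intensity_bone) / 2,
    enthesiophyte_min_intensity = (spec$intensity_background +
                                     spec$intensity_bone) / 2)
}

#' Semi-automated segmentation of one lesion
#'
#' Seeded region growing (6-connectivity) reproducing the two lesion
#' definitions. An *erosion* is the connected low-intensity region grown
#' from a seed inside the reference periosteal surface, clipped to the
#' surface interior; it is flagged when it fails to contact a cortical break
#' on at least two consecutive axial slices. An *enthesiophyte* is the
#' connected bone-intensity region grown from a seed outside the reference
#' surface, clipped to the exterior, so that growth is always measured
#' against the same (baseline) anatomical envelope at both time points.
#'
#' @param volume a [volume3d] (baseline or registered follow-up, both on the
#'   baseline grid).
#' @param reference_surface logical array: the baseline periosteal mask used
#'   as the fixed anatomical reference.
#' @param seed 1-based voxel coordinate of the seed point.
#' @param kind `"erosion"` or `"enthesiophyte"`.
#' @param params a [lesion_params].
#' @param lesion_id identifier carried into the record.
#' @param compartment,quadrant annotation labels carried into the record.
#' @param roi optional [define_roi] result; the grown region is clipped to
#'   it and flagged when it touches the ROI boundary.
#' @param timepoint label (`"t0"` or `"t5"`).
#' @return an object of class `lesion_record`: id, kind, labels, seed, the
#'   grown `mask`, `volume_mm3`, `centroid_mm` and flags
#'   (`cortical_break_ok`, `touches_boundary`).
#' @export
segment_lesion <- function(volume, reference_surface, seed,
                           kind = c("erosion", "enthesiophyte"), params,
                           lesion_id = NA_character_,
                           compartment = NA_character_,
                           quadrant = NA_character_,
                           roi = NULL, timepoint = "t0") {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "lesion_params"),
            identical(dim(volume$data), dim(reference_surface)))
  d <- dim(volume$data)
  seed <- as.integer(round(seed))
  if (any(seed < 1) || any(seed > d)) stop("seed outside the volume")
  s_lin <- seed[1] + (seed[2] - 1) * d[1] + (seed[3] - 1) * d[1] * d[2]
  inside <- reference_surface[s_lin]
  if (kind == "erosion" && !inside)
    stop("erosion seed lies outside the reference periosteal surface")
  if (kind == "enthesiophyte" && inside)
    stop("enthesiophyte seed lies inside the reference periosteal surface")

  if (kind == "erosion") {
    mask <- cpp_region_grow(volume$data, d, seed, -Inf,
                            params$erosion_max_intensity,
                            as.logical(reference_surface))
  } else {
    mask <- cpp_region_grow(volume$data, d, seed,
                            params$enthesiophyte_min_intensity, Inf,
                            !reference_surface)
  }
  if (!any(mask))
    stop("seed intensity is not compatible with a ", kind,
         " at this location")

  touches_boundary <- FALSE
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_mask"))
    rim_idx <- c(roi$range$start, roi$range$end)
    touches_boundary <- any(mask[rim_idx, , ])
    keep <- array(FALSE, dim = d)
    keep[roi$range$start:roi$range$end, , ] <- TRUE
    mask <- mask & keep
  }

  break_ok <- NA
  if (kind == "erosion") {
    shell <- reference_surface &
      !cpp_binary_erode(reference_surface, d, params$cortex_shell_vox)
    hit <- which(mask & shell)
    slices <- sort(unique((hit - 1) %% d[1] + 1))
    break_ok <- length(slices) >= 2 && any(diff(slices) == 1)
  }

  vv <- voxel_volume_mm3(volume)
  idx <- which(mask)
  centroid <- if (length(idx)) {
    i0 <- (idx - 1) %% d[1]
    j0 <- ((idx - 1) %/% d[1]) %% d[2]
    k0 <- (idx - 1) %/% (d[1] * d[2])
    c(mean(i0), mean(j0), mean(k0)) * volume$spacing_mm
  } else rep(NA_real_, 3)

  structure(list(lesion_id = lesion_id, kind = kind,
                 compartment = compartment, quadrant = quadrant,
                 seed = seed, mask = mask,
                 volume_mm3 = length(idx) * vv,
                 centroid_mm = centroid,
                 timepoint = timepoint,
                 cortical_break_ok = break_ok,
                 touches_boundary = touches_boundary),
            class = "lesion_record")
}

#' @export
print.lesion_record <- function(x, ...) {
  cat(sprintf("<lesion_record> %s %s (%s, %s): %.3f mm^3 at %s\n",
              x$lesion_id, x$kind, x$compartment, x$quadrant, x$volume_mm3,
              x$timepoint))
  invisible(x)
}

#' Tabulate a list of lesion records
#' @param records list of [segment_lesion] results.
#' @return data frame with one row per record.
#' @export
lesion_table <- function(records) {
  data.frame(
    lesion_id = vapply(records, `[[`, "", "lesion_id"),
    kind = vapply(records, `[[`, "", "kind"),
    compartment = vapply(records, `[[`, "", "compartment"),
    quadrant = vapply(records, `[[`, "", "quadrant"),
    volume_mm3 = vapply(records, `[[`, 0, "volume_mm3"),
    centroid_1 = vapply(records, function(r) r$centroid_mm[1], 0),
    centroid_2 = vapply(records, function(r) r$centroid_mm[2], 0),
    centroid_3 = vapply(records, function(r) r$centroid_mm[3], 0),
    timepoint = vapply(records, `[[`, "", "timepoint"),
    row.names = NULL)
}

#' Pair lesions across time points
#'
#' Greedy nearest-centroid matching of baseline and follow-up lesion tables
#' (both measured in baseline space): candidate pairs share kind and
#' compartment and lie within the distance gate; pairs are matched in order
#' of increasing centroid distance, ties broken by baseline then follow-up
#' lesion id. Unmatched follow-up lesions are `new` (baseline volume 0, so
#' their change equals their follow-up volume); unmatched baseline lesions
#' are `lost`.
#'
#' @param baseline,followup data frames from [lesion_table] (columns
#'   `lesion_id`, `kind`, `compartment`, `volume_mm3`, `centroid_1..3`).
#' @param max_centroid_distance_mm matching gate, mm (default 1.0, about 12
#'   voxels at 0.082 mm).
#' @return a `lesion_pair` data frame: `lesion_id`, `kind`, `compartment`,
#'   `quadrant`, `vol_t0_mm3`, `vol_t5_mm3`, `delta_mm3`, `status`.
#' @export
pair_lesions <- function(baseline, followup, max_centroid_distance_mm = 1.0) {
  cen <- function(x) as.matrix(x[, c("centroid_1", "centroid_2", "centroid_3")])
  nb <- nrow(baseline)
  nf <- nrow(followup)
  cand <- NULL
  if (nb > 0 && nf > 0) {
    cb <- cen(baseline)
    cf <- cen(followup)
    pairs <- expand.grid(b = seq_len(nb), f = seq_len(nf))
    dist <- sqrt(rowSums((cb[pairs$b, , drop = FALSE] -
                            cf[pairs$f, , drop = FALSE])^2))
    same <- baseline$kind[pairs$b] == followup$kind[pairs$f] &
      baseline$compartment[pairs$b] == followup$compartment[pairs$f]
    keep <- same & dist <= max_centroid_distance_mm
    cand <- data.frame(b = pairs$b[keep], f = pairs$f[keep],
                       dist = dist[keep])
    cand <- cand[order(cand$dist, baseline$lesion_id[cand$b],
                       followup$lesion_id[cand$f]), , drop = FALSE]
  }
  used_b <- logical(nb)
  used_f <- logical(nf)
  match_b <- integer(0)
  match_f <- integer(0)
  if (!is.null(cand)) {
    for (r in seq_len(nrow(cand))) {
      b <- cand$b[r]
      f <- cand$f[r]
      if (used_b[b] || used_f[f]) next
      used_b[b] <- TRUE
      used_f[f] <- TRUE
      match_b <- c(match_b, b)
      match_f <- c(match_f, f)
    }
  }
  rows <- list()
  if (length(match_b)) {
    rows$matched <- data.frame(
      lesion_id = baseline$lesion_id[match_b],
      kind = baseline$kind[match_b],
      compartment = baseline$compartment[match_b],
      quadrant = baseline$quadrant[match_b],
      vol_t0_mm3 = baseline$volume_mm3[match_b],
      vol_t5_mm3 = followup$volume_mm3[match_f],
      status = "matched")
  }
  if (any(!used_f)) {
    nf_ <- which(!used_f)
    rows$new <- data.frame(
      lesion_id = followup$lesion_id[nf_],
      kind = followup$kind[nf_],
      compartment = followup$compartment[nf_],
      quadrant = followup$quadrant[nf_],
      vol_t0_mm3 = 0,
      vol_t5_mm3 = followup$volume_mm3[nf_],
      status = "new")
  }
  if (any(!used_b)) {
    nb_ <- which(!used_b)
    rows$lost <- data.frame(
      lesion_id = baseline$lesion_id[nb_],
      kind = baseline$kind[nb_],
      compartment = baseline$compartment[nb_],
      quadrant = baseline$quadrant[nb_],
      vol_t0_mm3 = baseline$volume_mm3[nb_],
      vol_t5_mm3 = 0,
      status = "lost")
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(lesion_id = character(), kind = character(),
                      compartment = character(), quadrant = character(),
                      vol_t0_mm3 = numeric(), vol_t5_mm3 = numeric(),
                      status = character())
  out$delta_mm3 <- out$vol_t5_mm3 - out$vol_t0_mm3
  rownames(out) <- NULL
  out[, c("lesion_id", "kind", "compartment", "quadrant",
          "vol_t0_mm3", "vol_t5_mm3", "delta_mm3", "status")]
}
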