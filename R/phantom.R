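#' Specification of a metacarpal-head digital phantom
#'
#' Describes a paired-timepoint HR-pQCT phantom: two metacarpal heads (MCH2
#' and MCH3) rendered as hemispherically capped cylindrical cortical shells in
#' one grid, with a trabecular interior and a three-level piecewise-constant
#' intensity model plus optional additive Gaussian noise. Defaults emulate the
#' XtremeCT acquisition the pipeline targets: isotropic 0.082 mm voxels and a
#' baseline stack of 110 axial slices (9.02 mm). The axial axis is array
#' axis 1; slice 1 is the distal end of the scan.
#'
#' @param grid_shape integer vector, voxels per axis (axial first).
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param cortex_outer_radius_mm outer (periosteal) radius of the MCH3 head;
#'   MCH2 is scaled by `mch2_radius_factor`, which also breaks the in-plane
#'   mirror symmetry that would otherwise make principal-axis initialization
#'   ambiguous.
#' @param cortex_thickness_mm cortical shell thickness, must be smaller than
#'   the outer radius.
#' @param intensity_bone,intensity_trabecular,intensity_background intensity
#'   levels, arbitrary units (scanner calibration is out of scope).
#' @param noise_sd additive Gaussian noise SD, same units.
#' @param seed integer seed; all randomness in phantom construction flows from
#'   it through one generator per call.
#' @param mch2_radius_factor radius ratio MCH2 / MCH3, in (0, 1].
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(110L, 104L, 200L),
                         voxel_size_mm = 0.082,
                         cortex_outer_radius_mm = 3.5,
                         cortex_thickness_mm = 0.6,
                         intensity_bone = 2000,
                         intensity_trabecular = 800,
                         intensity_background = 100,
                         noise_sd = 0,
                         seed = 1L,
                         mch2_radius_factor = 0.9) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            voxel_size_mm > 0, noise_sd >= 0,
            cortex_outer_radius_mm > 0,
            mch2_radius_factor > 0, mch2_radius_factor <= 1)
  if (cortex_thickness_mm <= 0 || cortex_thickness_mm > cortex_outer_radius_mm)
    stop("cortex_thickness_mm must lie in (0, cortex_outer_radius_mm]")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 cortex_outer_radius_mm = cortex_outer_radius_mm,
                 cortex_thickness_mm = cortex_thickness_mm,
                 intensity_bone = intensity_bone,
                 intensity_trabecular = intensity_trabecular,
                 intensity_background = intensity_background,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 mch2_radius_factor = mch2_radius_factor),
            class = "phantom_spec")
}

# Head layout: centres are placed off-lattice (quarter-voxel offset) so that
# no voxel sits exactly on a head axis; both caps share one apex plane.
head_layout <- function(spec) {
  sp <- spec$voxel_size_mm
  d <- spec$grid_shape
  r3 <- spec$cortex_outer_radius_mm
  r2 <- r3 * spec$mch2_radius_factor
  cy <- (d[2] / 2 - 0.25) * sp
  cz2 <- (d[3] * 0.27 - 0.25) * sp
  cz3 <- (d[3] * 0.73 - 0.25) * sp
  apex <- r3 + 2 * sp
  list(list(name = "MCH2", radius = r2, cy = cy, cz = cz2, apex = apex),
       list(name = "MCH3", radius = r3, cy = cy, cz = cz3, apex = apex))
}

check_layout_fits <- function(spec, heads) {
  sp <- spec$voxel_size_mm
  d <- spec$grid_shape
  ext <- (d - 1) * sp
  for (h in heads) {
    if (h$cy - h$radius < sp || h$cy + h$radius > ext[2] - sp ||
        h$cz - h$radius < sp || h$cz + h$radius > ext[3] - sp ||
        h$apex - h$radius < 0 || h$apex >= ext[1])
      stop("grid too small to contain the metacarpal heads; ",
           "enlarge grid_shape or shrink cortex_outer_radius_mm")
  }
  sep <- abs(heads[[1]]$cz - heads[[2]]$cz)
  if (sep < heads[[1]]$radius + heads[[2]]$radius + 2 * sp)
    stop("grid too small: the two heads overlap in-plane")
  invisible(TRUE)
}

# Render the signed depth below the periosteal surface for both heads on a
# grid whose axial physical coordinates are (0:(d1-1)) * sp + axial_offset.
# Geometry: hemispherical cap (distal, axial <= apex) on a cylindrical shaft
# (proximal, extending through the end of the grid).
render_geometry <- function(spec, dims, axial_offset_mm = 0) {
  sp <- spec$voxel_size_mm
  heads <- head_layout(spec)
  x <- (seq_len(dims[1]) - 1) * sp + axial_offset_mm
  y <- (seq_len(dims[2]) - 1) * sp
  z <- (seq_len(dims[3]) - 1) * sp
  depth <- NULL
  comp <- NULL
  for (hi in seq_along(heads)) {
    h <- heads[[hi]]
    ax2 <- pmax(h$apex - x, 0)^2        # axial term: 0 on the shaft
    dyz2 <- outer((y - h$cy)^2, (z - h$cz)^2, "+")
    dh <- h$radius - sqrt(outer(ax2, dyz2, "+"))
    if (is.null(depth)) {
      depth <- dh
      comp <- array(hi, dim = dims)
    } else {
      take <- dh > depth
      depth[take] <- dh[take]
      comp[take] <- hi
    }
  }
  periosteal <- depth >= 0
  cortex <- periosteal & depth < spec$cortex_thickness_mm
  intensity <- array(spec$intensity_background, dim = dims)
  intensity[periosteal] <- spec$intensity_trabecular
  intensity[cortex] <- spec$intensity_bone
  comp[!periosteal] <- 0L
  list(intensity = intensity, periosteal = periosteal, cortex = cortex,
       compartment = comp, heads = heads)
}

#' Generate the baseline phantom volume
#'
#' Renders the two-head metacarpal phantom described by a [phantom_spec]:
#' a three-level intensity volume (cortical bone, trabecular interior,
#' background), the ground-truth periosteal mask (voxels at or inside the
#' outer cortical surface), the cortical shell and the compartment labels.
#' Deterministic for a fixed spec and seed.
#'
#' @param spec a [phantom_spec].
#' @return an object of class `phantom` with elements `volume` ([volume3d]),
#'   `periosteal`, `cortex` (logical arrays), `compartment` (integer array,
#'   0 = background, 1 = MCH2, 2 = MCH3), `heads`, `spec`, and an initially
#'   empty `lesions` list.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  heads <- head_layout(spec)
  check_layout_fits(spec, heads)
  g <- render_geometry(spec, spec$grid_shape)
  noise <- NULL
  data <- g$intensity
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, array(
      stats::rnorm(prod(spec$grid_shape), 0, spec$noise_sd),
      dim = spec$grid_shape))
    data <- data + noise
  }
  structure(list(volume = volume3d(data, spacing_mm = spec$voxel_size_mm,
                                   frame = "baseline"),
                 base = g$intensity, noise = noise,
                 periosteal = g$periosteal, cortex = g$cortex,
                 compartment = g$compartment, heads = g$heads,
                 spec = spec, lesions = list()),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("<phantom> %d x %d x %d voxels, %d lesion(s)\n",
              d[1], d[2], d[3], length(x$lesions)))
  invisible(x)
}

# Nearest head and the projection of a voxel-coordinate point onto its
# periosteal surface (physical mm). `vox` is a 1-based voxel coordinate.
project_to_surface <- function(phantom, vox) {
  sp <- phantom$spec$voxel_size_mm
  p <- (as.numeric(vox) - 1) * sp
  best <- NULL
  for (hi in seq_along(phantom$heads)) {
    h <- phantom$heads[[hi]]
    axis_pt <- c(max(p[1], h$apex), h$cy, h$cz)
    dvec <- p - axis_pt
    dn <- sqrt(sum(dvec^2))
    if (dn < 1e-9) next
    gap <- abs(h$radius - dn)
    if (is.null(best) || gap < best$gap) {
      surf <- axis_pt + dvec / dn * h$radius
      best <- list(head = hi, gap = gap, surface_mm = surf, axis_pt = axis_pt)
    }
  }
  if (is.null(best)) stop("lesion centre lies on a head axis; move it")
  best
}

quadrant_of <- function(direction) {
  # in-plane direction (axes 2 and 3) relative to the head axis
  if (abs(direction[2]) >= abs(direction[3])) {
    if (direction[2] >= 0) "palmar" else "dorsal"
  } else {
    if (direction[3] >= 0) "ulnar" else "radial"
  }
}

#' Convenience: a surface point on a phantom head
#'
#' Returns a 1-based voxel coordinate on (or just outside, for
#' enthesiophytes) the periosteal surface of the requested compartment, in
#' the requested quadrant, at an axial position on the shaft.
#'
#' @param phantom a [make_phantom] result.
#' @param compartment `"MCH2"` or `"MCH3"`.
#' @param quadrant `"palmar"`, `"dorsal"`, `"ulnar"` or `"radial"`.
#' @param axial_mm axial position, mm; defaults to just proximal of the cap
#'   equator.
#' @param outward_mm radial offset added beyond the surface (use ~1 voxel for
#'   enthesiophyte seeds), mm.
#' @return length-3 voxel coordinate (may be fractional).
#' @export
surface_point <- function(phantom, compartment = c("MCH3", "MCH2"),
                          quadrant = c("palmar", "dorsal", "ulnar", "radial"),
                          axial_mm = NULL, outward_mm = 0) {
  compartment <- match.arg(compartment)
  quadrant <- match.arg(quadrant)
  hi <- if (compartment == "MCH2") 1L else 2L
  h <- phantom$heads[[hi]]
  if (is.null(axial_mm)) axial_mm <- h$apex + 2 * phantom$spec$voxel_size_mm
  dir <- switch(quadrant,
                palmar = c(0, 1, 0), dorsal = c(0, -1, 0),
                ulnar = c(0, 0, 1), radial = c(0, 0, -1))
  p <- c(axial_mm, h$cy, h$cz) + dir * (h$radius + outward_mm)
  p / phantom$spec$voxel_size_mm + 1
}

# Deterministically ranked candidate voxels for a lesion: the n eligible
# voxels nearest (physical distance) to the surface anchor. Erosions select
# inside the periosteal mask, enthesiophytes outside it. Ties broken by
# linear index, so masks at different target volumes are nested.
lesion_voxels <- function(phantom, anchor_mm, kind, n) {
  sp <- phantom$spec$voxel_size_mm
  d <- dim(phantom$volume$data)
  rmax <- phantom$spec$cortex_outer_radius_mm *
    (if (kind == "erosion") 2.2 else 1.5)
  r <- max((3 * n * sp^3 / (2 * pi))^(1 / 3) + 2 * sp, 4 * sp)
  repeat {
    lo <- pmax(floor(anchor_mm / sp - r / sp) + 1, 1)
    hi <- pmin(ceiling(anchor_mm / sp + r / sp) + 1, d)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    sub <- phantom$periosteal[ii, jj, kk, drop = FALSE]
    if (kind != "erosion") sub <- !sub
    dist2 <- outer(outer(((ii - 1) * sp - anchor_mm[1])^2,
                         ((jj - 1) * sp - anchor_mm[2])^2, "+"),
                   ((kk - 1) * sp - anchor_mm[3])^2, "+")
    eligible <- which(sub & dist2 <= r^2)
    if (length(eligible) >= n || r > rmax) break
    r <- r * 1.4
  }
  if (length(eligible) < n)
    stop("target volume exceeds the space available at this site")
  # map sub-box indices to full-grid linear indices
  sd_ <- c(length(ii), length(jj), length(kk))
  e0 <- eligible - 1
  i <- e0 %% sd_[1]
  j <- (e0 %/% sd_[1]) %% sd_[2]
  k <- e0 %/% (sd_[1] * sd_[2])
  lin_idx <- (lo[1] + i) + (lo[2] + j - 1) * d[1] + (lo[3] + k - 1) * d[1] * d[2]
  ord <- order(dist2[eligible], lin_idx)
  lin_idx[ord][seq_len(n)]
}

apply_lesions_to <- function(phantom, intensity, idx_list, kinds) {
  for (i in seq_along(idx_list)) {
    idx <- idx_list[[i]]
    if (length(idx) == 0) next
    intensity[idx] <- if (kinds[i] == "erosion")
      phantom$spec$intensity_background else phantom$spec$intensity_bone
  }
  intensity
}

refresh_volume <- function(phantom) {
  data <- apply_lesions_to(phantom, phantom$base,
                           lapply(phantom$lesions, `[[`, "mask_idx_t0"),
                           vapply(phantom$lesions, `[[`, "", "kind"))
  if (!is.null(phantom$noise)) data <- data + phantom$noise
  phantom$volume <- volume3d(data, spacing_mm = phantom$spec$voxel_size_mm,
                             frame = "baseline")
  phantom
}

#' Implant a ground-truth lesion into a phantom
#'
#' Erosions are carved as the set of periosteal-interior voxels nearest to a
#' cortical surface anchor (a spherical-cap-like defect), with intensity set
#' to the background level; the carve must break the cortical shell on at
#' least two consecutive axial slices, mirroring the imaging definition of an
#' erosion. Enthesiophytes are domes of bone-intensity voxels added just
#' outside the unmodified periosteal surface. The voxel count is
#' `round(target_volume_mm3 / voxel_volume)`, so the achieved ground-truth
#' volume is within half a voxel volume of the target.
#'
#' @param phantom a [make_phantom] result.
#' @param kind `"erosion"` or `"enthesiophyte"`.
#' @param center approximate 1-based voxel coordinate of the lesion site; it
#'   is projected onto the nearest periosteal surface.
#' @param target_volume_mm3 requested lesion volume, mm^3 (> 0).
#' @param lesion_id identifier; defaults to `"L<n>"`.
#' @return the phantom with the lesion applied and a `GroundTruthLesion`
#'   record appended to `phantom$lesions` (fields: `lesion_id`, `kind`,
#'   `compartment`, `quadrant`, `center_vox`, `anchor_mm`, `vol_t0_mm3`,
#'   `mask_idx_t0`).
#' @export
implant_lesion <- function(phantom, kind = c("erosion", "enthesiophyte"),
                           center, target_volume_mm3, lesion_id = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  kind <- match.arg(kind)
  if (target_volume_mm3 <= 0) stop("target_volume_mm3 must be positive")
  vv <- voxel_volume_mm3(phantom$volume)
  n <- max(1L, as.integer(round(target_volume_mm3 / vv)))
  proj <- project_to_surface(phantom, center)
  idx <- lesion_voxels(phantom, proj$surface_mm, kind, n)
  if (kind == "erosion") {
    cx <- idx[phantom$cortex[idx]]
    slices <- sort(unique((cx - 1) %% dim(phantom$volume$data)[1] + 1))
    if (length(slices) < 2 || !any(diff(slices) == 1))
      stop("erosion too small to break the outer cortical margin on at ",
           "least two consecutive axial slices")
  }
  if (is.null(lesion_id)) lesion_id <- paste0("L", length(phantom$lesions) + 1)
  dirvec <- proj$surface_mm - proj$axis_pt
  rec <- list(lesion_id = lesion_id, kind = kind,
              compartment = phantom$heads[[proj$head]]$name,
              quadrant = quadrant_of(dirvec),
              center_vox = round(proj$surface_mm / phantom$spec$voxel_size_mm) + 1,
              anchor_mm = proj$surface_mm,
              vol_t0_mm3 = n * vv,
              mask_idx_t0 = idx)
  phantom$lesions[[lesion_id]] <- rec
  refresh_volume(phantom)
}

#' Ground-truth lesion mask as a logical array
#' @param record a lesion record from `phantom$lesions` or from
#'   [make_followup] ground truth.
#' @param dims grid dimensions of the volume the mask lives on.
#' @param timepoint `"t0"` or `"t5"`.
#' @return logical array.
#' @export
lesion_mask_array <- function(record, dims, timepoint = c("t0", "t5")) {
  timepoint <- match.arg(timepoint)
  m <- array(FALSE, dim = dims)
  idx <- record[[paste0("mask_idx_", timepoint)]]
  if (length(idx)) m[idx] <- TRUE
  m
}

#' Render the follow-up acquisition of a phantom
#'
#' Applies the requested per-lesion volume changes (re-selected from each
#' lesion's deterministic voxel ranking, so grown masks contain their
#' baseline masks), re-renders the anatomy on an axially extended grid, and
#' samples it into a moved follow-up frame. The follow-up stack is longer
#' than baseline (default 322 slices, 26.404 mm) and starts
#' `distal_margin_slices` slices distal to the baseline scan start, so even
#' under identity motion the recorded ground-truth transform carries the
#' axial offset between the two acquisitions; registration must recover it.
#'
#' @param phantom a lesioned [make_phantom] result.
#' @param motion extra rigid motion ([rigid_transform]) of the follow-up
#'   frame, composed on top of the axial acquisition offset. Its rotation is
#'   applied about the baseline grid centre (repositioning rotates the
#'   anatomy, not the scanner origin). The recorded ground truth maps
#'   follow-up physical coordinates into baseline physical coordinates.
#' @param volume_deltas_mm3 named numeric vector of volume changes (mm^3) per
#'   lesion id; lesions not named are unchanged. Deltas must keep volumes
#'   non-negative.
#' @param noise_sd follow-up noise SD; defaults to the spec's `noise_sd`.
#' @param followup_slices axial extent of the follow-up stack.
#' @param distal_margin_slices slices acquired distal to the baseline start.
#' @return list with `volume` (the follow-up [volume3d]),
#'   `truth_transform` (follow-up to baseline [rigid_transform]),
#'   `lesions` (records updated with `vol_t5_mm3` and `mask_idx_t5` on the
#'   baseline grid) and `distal_margin_slices`.
#' @export
make_followup <- function(phantom, motion = rigid_transform(),
                          volume_deltas_mm3 = numeric(),
                          noise_sd = NULL, followup_slices = 322L,
                          distal_margin_slices = 80L) {
  stopifnot(inherits(phantom, "phantom"), inherits(motion, "rigid_transform"))
  spec <- phantom$spec
  sp <- spec$voxel_size_mm
  vv <- sp^3
  if (is.null(noise_sd)) noise_sd <- spec$noise_sd
  lesions <- phantom$lesions
  for (id in names(lesions)) {
    delta <- if (id %in% names(volume_deltas_mm3)) volume_deltas_mm3[[id]] else 0
    v5 <- lesions[[id]]$vol_t0_mm3 + delta
    if (v5 < -vv / 2) stop("volume delta drives lesion ", id, " negative")
    n5 <- max(0L, as.integer(round(v5 / vv)))
    lesions[[id]]$vol_t5_mm3 <- n5 * vv
    lesions[[id]]$mask_idx_t5 <- if (n5 > 0)
      lesion_voxels(phantom, lesions[[id]]$anchor_mm, lesions[[id]]$kind, n5)
    else integer()
  }
  unknown <- setdiff(names(volume_deltas_mm3), names(lesions))
  if (length(unknown)) stop("unknown lesion ids in volume_deltas_mm3: ",
                            paste(unknown, collapse = ", "))

  d <- spec$grid_shape
  ext_dims <- c(as.integer(followup_slices), d[2], d[3])
  offset_mm <- -distal_margin_slices * sp
  g <- render_geometry(spec, ext_dims, axial_offset_mm = offset_mm)
  # lesion masks live on the baseline grid; shift axially into the extended grid
  shift_idx <- function(idx) {
    i <- (idx - 1) %% d[1]
    rest <- (idx - 1) %/% d[1]
    keep <- i + distal_margin_slices < ext_dims[1]
    (i[keep] + distal_margin_slices) + rest[keep] * ext_dims[1] + 1
  }
  ext <- apply_lesions_to(phantom, g$intensity,
                          lapply(lesions, function(l) shift_idx(l$mask_idx_t5)),
                          vapply(lesions, `[[`, "", "kind"))

  center <- (d - 1) * sp / 2
  motion_c <- rigid_transform(
    rotation = motion$rotation,
    translation_mm = center + motion$translation_mm -
      as.numeric(motion$rotation %*% center))
  truth <- tf_compose(motion_c, rigid_transform(
    translation_mm = c(-distal_margin_slices * sp, 0, 0)))
  # follow-up physical -> extended-grid physical (extended origin is
  # distal_margin_slices below baseline slice 1)
  M <- tf_matrix(tf_compose(rigid_transform(
    translation_mm = c(distal_margin_slices * sp, 0, 0)), truth))
  res <- cpp_resample_rigid(ext, ext_dims, rep(sp, 3), M,
                            c(as.integer(followup_slices), d[2], d[3]),
                            rep(sp, 3), spec$intensity_background)
  data <- res$data
  if (noise_sd > 0)
    data <- data + with_seed(spec$seed + 1L, array(
      stats::rnorm(length(data), 0, noise_sd), dim = dim(data)))
  list(volume = volume3d(data, spacing_mm = sp, frame = "followup"),
       truth_transform = truth,
       lesions = lesions,
       distal_margin_slices = as.integer(distal_margin_slices))
}

#' Ground-truth lesion manifest as a data frame
#'
#' @param lesions a lesion-record list (`phantom$lesions` or
#'   `make_followup()$lesions`).
#' @return data frame with one row per lesion: id, kind, compartment,
#'   quadrant, centre voxel, and per-timepoint true volumes (t5 `NA` before
#'   [make_followup]).
#' @export
phantom_manifest <- function(lesions) {
  if (length(lesions) == 0)
    return(data.frame(lesion_id = character(), kind = character(),
                      compartment = character(), quadrant = character(),
                      center_zyx = character(), vol_t0_mm3 = numeric(),
                      vol_t5_mm3 = numeric()))
  data.frame(
    lesion_id = vapply(lesions, `[[`, "", "lesion_id"),
    kind = vapply(lesions, `[[`, "", "kind"),
    compartment = vapply(lesions, `[[`, "", "compartment"),
    quadrant = vapply(lesions, `[[`, "", "quadrant"),
    center_zyx = vapply(lesions, function(l)
      paste(round(l$center_vox), collapse = ","), ""),
    vol_t0_mm3 = vapply(lesions, `[[`, 0, "vol_t0_mm3"),
    vol_t5_mm3 = vapply(lesions, function(l)
      if (is.null(l$vol_t5_mm3)) NA_real_ else l$vol_t5_mm3, 0),
    row.names = NULL)
}
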