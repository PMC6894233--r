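#' Slice matching of baseline and registered follow-up volumes
#'
#' After baseline-indexed registration, finds the maximal contiguous axial
#' range over which the registered follow-up has valid (non-filled) data
#' across the full in-plane bone extent of the baseline, so that both time
#' points are measured on exactly matched slices.
#'
#' @param baseline the baseline [volume3d].
#' @param registered_followup the [resample_to_baseline] output volume
#'   (present for interface completeness; the decision uses `valid`).
#' @param valid logical validity array from [resample_to_baseline].
#' @param bone_mask logical array of baseline bone voxels defining the
#'   in-plane extent that must be covered; default: thresholded foreground.
#' @return an object of class `slice_range`: `start`, `end` (1-based,
#'   inclusive, identical on both time points since both live on the
#'   baseline grid) and `n_slices`.
#' @export
match_slices <- function(baseline, registered_followup, valid,
                         bone_mask = NULL) {
  stopifnot(identical(dim(baseline$data), dim(valid)))
  if (is.null(bone_mask))
    bone_mask <- baseline$data > foreground_threshold(baseline)
  d <- dim(valid)
  ok <- vapply(seq_len(d[1]), function(i) {
    b <- bone_mask[i, , ]
    !any(b & !valid[i, , ])
  }, TRUE)
  has_bone <- vapply(seq_len(d[1]), function(i) any(bone_mask[i, , ]), TRUE)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  # candidate runs must be fully co-localized AND contain bone
  cand <- which(runs$values &
                  vapply(seq_along(runs$values), function(r)
                    any(has_bone[starts[r]:ends[r]]), TRUE))
  if (length(cand) == 0)
    stop("no axial slice is fully co-localized; registration ",
         "or acquisition overlap failed")
  best <- cand[which.max(runs$lengths[cand])]
  structure(list(start = starts[best], end = ends[best],
                 n_slices = runs$lengths[best]),
            class = "slice_range")
}

#' @export
print.slice_range <- function(x, ...) {
  cat(sprintf("<slice_range> slices %d..%d (%d slices)\n",
              x$start, x$end, x$n_slices))
  invisible(x)
}

#' Define the co-localized measurement region of interest
#'
#' Builds the measurement ROI on the baseline grid: metacarpal bone voxels
#' (the periosteal mask) restricted to the matched slice range, with the
#' three proximal and three distal boundary slices removed when trimming is
#' requested (guarding against boundary effects of the matched slab), and
#' non-metacarpal components removed. Components are kept when they reach
#' the proximal face of the trimmed range (metacarpal shafts continue
#' proximally; phalangeal stubs and debris float distally) and are at least
#' 1% of the largest such component.
#'
#' @param volume the baseline [volume3d] (used for dimensions).
#' @param periosteal logical array: bone (periosteal-interior) voxels, from
#'   segmentation or phantom ground truth.
#' @param slice_range a [match_slices] result.
#' @param trim_boundary drop 3 slices at each end of the range.
#' @param trim_slices how many boundary slices to drop at each end.
#' @return an object of class `roi_mask`: `mask` (logical array), `range`
#'   (the trimmed slice range actually used) and `provenance` (counts of
#'   voxels excluded as out-of-range, boundary, or non-metacarpal).
#' @export
define_roi <- function(volume, periosteal, slice_range, trim_boundary = TRUE,
                       trim_slices = 3L) {
  stopifnot(inherits(slice_range, "slice_range"),
            identical(dim(volume$data), dim(periosteal)))
  if (!any(periosteal)) stop("periosteal mask is empty")
  d <- dim(periosteal)
  s0 <- slice_range$start
  s1 <- slice_range$end
  total_bone <- sum(periosteal)
  in_range <- array(FALSE, dim = d)
  in_range[s0:s1, , ] <- TRUE
  n_out_of_range <- sum(periosteal & !in_range)
  if (trim_boundary) {
    if (slice_range$n_slices < 2 * trim_slices + 1)
      stop("slice range too short to trim ", trim_slices,
           " boundary slices at each end")
    s0 <- s0 + trim_slices
    s1 <- s1 - trim_slices
  }
  trimmed <- array(FALSE, dim = d)
  trimmed[s0:s1, , ] <- TRUE
  n_boundary <- sum(periosteal & in_range & !trimmed)
  mask <- periosteal & trimmed
  if (!any(mask)) stop("nothing left in the ROI after trimming")

  lab <- cpp_label_components(mask, d)
  sizes <- tabulate(lab[lab > 0])
  proximal_labels <- unique(lab[s1, , ])
  proximal_labels <- proximal_labels[proximal_labels > 0]
  if (length(proximal_labels) == 0) {
    keep <- which.max(sizes)
  } else {
    ref <- max(sizes[proximal_labels])
    keep <- proximal_labels[sizes[proximal_labels] >= 0.01 * ref]
  }
  sel <- array(lab %in% keep & lab > 0, dim = d)
  n_nonmetacarpal <- sum(mask & !sel)
  structure(list(mask = sel,
                 range = structure(list(start = s0, end = s1,
                                        n_slices = s1 - s0 + 1),
                                   class = "slice_range"),
                 provenance = list(non_bone = prod(d) - total_bone,
                                   out_of_range = n_out_of_range,
                                   boundary_slices = n_boundary,
                                   non_metacarpal = n_nonmetacarpal)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d voxels on slices %d..%d\n",
              sum(x$mask), x$range$start, x$range$end))
  invisible(x)
}
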