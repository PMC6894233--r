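#' Registration parameters
#'
#' Settings for mutual-information rigid registration. The optimizer is a
#' deterministic derivative-free coordinate (pattern) search with a fixed
#' multi-resolution schedule, chosen so that repeated runs are bitwise
#' reproducible.
#'
#' @param bins joint-histogram bins for mutual information (>= 8).
#' @param levels integer downsampling factors, coarse to fine.
#' @param init_step_mm initial translation step at the finest level, mm
#'   (scaled by the level factor at coarser levels).
#' @param init_step_deg initial rotation step at the finest level, degrees.
#' @param tol_mm,tol_deg convergence tolerances: the search stops once the
#'   step sizes fall below these.
#' @param max_iter maximum accepted-move sweeps per level.
#' @param axial_sweep_mm half-range of the deterministic axial-translation
#'   sweep performed at the coarsest level before the pattern search.
#'   Scans at the two time points cover different axial extents, so the
#'   centroid-based initialization is systematically biased along the scan
#'   axis; the sweep removes that bias. Set to 0 to disable.
#' @param fill background fill value for voxels mapping outside the moving
#'   volume (`NULL`: the moving volume's minimum).
#' @return an object of class `registration_params`.
#' @export
registration_params <- function(bins = 32L, levels = c(4L, 2L, 1L),
                                init_step_mm = 0.3, init_step_deg = 1,
                                tol_mm = 0.005, tol_deg = 0.02,
                                max_iter = 200L, axial_sweep_mm = 4,
                                fill = NULL) {
  stopifnot(bins >= 8, tol_mm > 0, tol_deg > 0, all(levels >= 1),
            levels[length(levels)] == 1, axial_sweep_mm >= 0)
  structure(list(bins = as.integer(bins), levels = as.integer(levels),
                 init_step_mm = init_step_mm, init_step_deg = init_step_deg,
                 tol_mm = tol_mm, tol_deg = tol_deg,
                 max_iter = as.integer(max_iter),
                 axial_sweep_mm = axial_sweep_mm, fill = fill),
            class = "registration_params")
}

foreground_threshold <- function(vol) {
  r <- range(vol$data)
  r[1] + 0.5 * diff(r)
}

foreground_stats <- function(vol, threshold = NULL) {
  if (is.null(threshold)) threshold <- foreground_threshold(vol)
  idx <- which(vol$data > threshold)
  if (length(idx) == 0) stop("no foreground voxels above threshold; ",
                             "cannot initialize registration")
  d <- dim(vol$data)
  i0 <- (idx - 1) %% d[1]
  j0 <- ((idx - 1) %/% d[1]) %% d[2]
  k0 <- (idx - 1) %/% (d[1] * d[2])
  pts <- cbind(i0 * vol$spacing_mm[1], j0 * vol$spacing_mm[2],
               k0 * vol$spacing_mm[3])
  ctr <- colMeans(pts)
  cov <- crossprod(sweep(pts, 2, ctr)) / nrow(pts)
  list(centroid = ctr, cov = cov, n = nrow(pts))
}

#' Coarse alignment from image centroids and principal axes
#'
#' Initializes the follow-up-to-baseline rigid transform by aligning the
#' intensity centroids of the thresholded foregrounds and rotating the
#' principal axes of the moving foreground onto those of the fixed one. The
#' fourfold axis-sign ambiguity is resolved toward the smallest rotation.
#'
#' @param fixed,moving baseline and follow-up [volume3d] volumes.
#' @param threshold foreground threshold; default halfway between each
#'   volume's minimum and maximum.
#' @return a [rigid_transform] mapping moving physical coordinates into
#'   fixed physical coordinates.
#' @export
initialize_transform <- function(fixed, moving, threshold = NULL) {
  fs <- foreground_stats(fixed, threshold)
  ms <- foreground_stats(moving, threshold)
  ef <- eigen(fs$cov, symmetric = TRUE)$vectors
  em <- eigen(ms$cov, symmetric = TRUE)$vectors
  # Principal axes are defined up to axis order and sign (and the two scans
  # need not rank them identically when their fields of view differ), so
  # search all 24 proper signed permutations and keep the smallest rotation.
  best <- NULL
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (pm in perms) for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    for (s3 in c(1, -1)) {
      Q <- matrix(0, 3, 3)
      Q[cbind(pm, 1:3)] <- c(s1, s2, s3)
      R <- ef %*% Q %*% t(em)
      if (det(R) < 0) next
      tr <- sum(diag(R))
      if (is.null(best) || tr > best$tr) best <- list(R = R, tr = tr)
    }
  }
  R <- best$R
  rigid_transform(rotation = R,
                  translation_mm = fs$centroid - as.numeric(R %*% ms$centroid))
}

#' Mutual information between two volumes under a rigid transform
#'
#' Resamples the moving volume through `transform` onto the fixed grid (on
#' the fly, trilinear) and computes the mutual information, in nats, of the
#' joint intensity histogram over the overlap. Intensities are min/max
#' normalized per volume before binning, so the metric is invariant to any
#' monotone relabeling that preserves bin assignments.
#'
#' @param fixed,moving [volume3d] volumes.
#' @param transform a [rigid_transform] (moving physical to fixed physical).
#' @param bins histogram bins.
#' @return scalar MI in nats (>= 0), with attribute `n_overlap`.
#' @export
mutual_information <- function(fixed, moving, transform = rigid_transform(),
                               bins = 32L) {
  Minv <- tf_matrix(tf_inverse(transform))
  fr <- range(fixed$data)
  mr <- range(moving$data)
  r <- cpp_mi_rigid(fixed$data, dim(fixed$data), fixed$spacing_mm,
                    moving$data, dim(moving$data), moving$spacing_mm,
                    Minv, as.integer(bins), fr[1], fr[2], mr[1], mr[2])
  if (r$n == 0) stop("empty overlap between fixed and moving volumes")
  structure(r$mi, n_overlap = r$n)
}

downsample_volume <- function(vol, factor) {
  if (factor == 1) return(vol)
  r <- cpp_downsample(vol$data, dim(vol$data), as.integer(factor))
  volume3d(r$data, spacing_mm = vol$spacing_mm * factor, frame = vol$frame)
}

#' Rigid registration by mutual-information maximization
#'
#' Baseline-indexed registration: finds the rigid transform maximizing the
#' mutual information of the follow-up volume resampled onto the baseline
#' grid, starting from `init` (typically [initialize_transform]). A
#' deterministic pattern search over the 6 pose parameters (rotation about
#' the fixed foreground centroid, plus translation) runs over a fixed
#' coarse-to-fine resolution schedule; steps are halved when no parameter
#' move improves the metric, until the tolerances are met. The returned
#' full-resolution MI never falls below the MI at `init`.
#'
#' @param fixed,moving [volume3d] volumes (baseline, follow-up).
#' @param init initial [rigid_transform]; default [initialize_transform].
#' @param params a [registration_params].
#' @return list with `transform`, `mi_init`, `mi_final` (full-resolution),
#'   `converged` (steps reached tolerance everywhere) and `n_eval`.
#' @export
register_rigid <- function(fixed, moving, init = NULL,
                           params = registration_params()) {
  stopifnot(inherits(params, "registration_params"))
  if (is.null(init)) init <- initialize_transform(fixed, moving)
  center <- foreground_stats(fixed)$centroid
  bins <- params$bins

  # pose p = (3 angles rad, 3 shifts mm) as a perturbation about `center`,
  # composed with a base transform
  pose_tf <- function(p, base) tf_compose(
    rigid_about_center(p[1:3], p[4:6], center), base)
  n_eval <- 0L
  mi_at <- function(p, base, fx, mv) {
    n_eval <<- n_eval + 1L
    Minv <- tf_matrix(tf_inverse(pose_tf(p, base)))
    fr <- range(fx$data)
    mr <- range(mv$data)
    r <- cpp_mi_rigid(fx$data, dim(fx$data), fx$spacing_mm,
                      mv$data, dim(mv$data), mv$spacing_mm,
                      Minv, bins, fr[1], fr[2], mr[1], mr[2])
    if (r$n == 0) -Inf else r$mi
  }

  pattern_search <- function(p, cur, base, fx, mv, step_ang, step_tr) {
    converged <- TRUE
    iter <- 0L
    repeat {
      improved <- FALSE
      for (d6 in 1:6) {
        st <- if (d6 <= 3) step_ang else step_tr
        for (sgn in c(1, -1)) {
          cand <- p
          cand[d6] <- cand[d6] + sgn * st
          val <- mi_at(cand, base, fx, mv)
          if (val > cur + 1e-12) {
            p <- cand
            cur <- val
            improved <- TRUE
            break
          }
        }
      }
      if (!improved) {
        step_ang <- step_ang / 2
        step_tr <- step_tr / 2
        if (step_ang < params$tol_deg * pi / 180 && step_tr < params$tol_mm)
          break
      } else {
        iter <- iter + 1L
        if (iter >= params$max_iter) {
          converged <- FALSE
          break
        }
      }
    }
    list(p = p, mi = cur, converged = converged)
  }

  coarse_level <- function(base) {
    lev <- params$levels[1]
    fx <- downsample_volume(fixed, lev)
    mv <- downsample_volume(moving, lev)
    p <- rep(0, 6)
    cur <- mi_at(p, base, fx, mv)
    if (params$axial_sweep_mm > 0) {
      # centroid initialization is biased along the scan axis when the two
      # acquisitions cover different extents; sweep it out deterministically
      for (dz in seq(-params$axial_sweep_mm, params$axial_sweep_mm,
                     by = lev * fixed$spacing_mm[1])) {
        cand <- p
        cand[4] <- dz
        val <- mi_at(cand, base, fx, mv)
        if (val > cur) {
          cur <- val
          p <- cand
        }
      }
    }
    pattern_search(p, cur, base, fx, mv,
                   params$init_step_deg * pi / 180 * lev,
                   params$init_step_mm * lev)
  }

  # Two deterministic starts: the principal-axes initialization and a
  # centroid-only (identity-rotation) fallback, which is more reliable when
  # field-of-view truncation tilts the apparent principal axes. The
  # coarsest level is optimized from both and the better basin kept.
  centroid_init <- rigid_transform(
    translation_mm = center - foreground_stats(moving)$centroid)
  starts <- list(init, centroid_init)
  coarse <- lapply(starts, coarse_level)
  pick <- which.max(vapply(coarse, `[[`, 0, "mi"))
  base <- starts[[pick]]
  p <- coarse[[pick]]$p
  converged <- coarse[[pick]]$converged

  for (lev in params$levels[-1]) {
    fx <- downsample_volume(fixed, lev)
    mv <- downsample_volume(moving, lev)
    cur <- mi_at(p, base, fx, mv)
    res <- pattern_search(p, cur, base, fx, mv,
                          params$init_step_deg * pi / 180 * lev,
                          params$init_step_mm * lev)
    p <- res$p
    converged <- converged && res$converged
  }

  mi_init <- as.numeric(mutual_information(fixed, moving, init, bins))
  mi_final <- as.numeric(mutual_information(fixed, moving,
                                            pose_tf(p, base), bins))
  if (mi_final < mi_init) {
    # the schedule wandered off; keep the initialization
    base <- init
    p <- rep(0, 6)
    mi_final <- mi_init
    converged <- FALSE
  }
  list(transform = pose_tf(p, base), mi_init = mi_init, mi_final = mi_final,
       converged = converged, n_eval = n_eval)
}

#' Re-slice the follow-up volume into baseline space
#'
#' Resamples `moving` onto the grid of `reference` by trilinear
#' interpolation through the rigid transform (baseline-indexed re-slicing:
#' the baseline volume itself is never resampled). Voxels whose pre-image
#' falls outside the moving volume receive the fill value and are flagged
#' invalid; downstream measurement must exclude them.
#'
#' @param moving the follow-up [volume3d].
#' @param transform a [rigid_transform] mapping moving physical coordinates
#'   into reference (baseline) physical coordinates.
#' @param reference the baseline [volume3d] providing the output grid.
#' @param fill fill value (`NULL`: minimum of `moving`).
#' @return list with `volume` (a [volume3d] in the `"baseline-registered"`
#'   frame) and `valid` (logical array).
#' @export
resample_to_baseline <- function(moving, transform, reference, fill = NULL) {
  if (is.null(fill)) fill <- min(moving$data)
  Minv <- tf_matrix(tf_inverse(transform))
  r <- cpp_resample_rigid(moving$data, dim(moving$data), moving$spacing_mm,
                          Minv, dim(reference$data), reference$spacing_mm,
                          fill)
  list(volume = volume3d(r$data, spacing_mm = reference$spacing_mm,
                         frame = "baseline-registered"),
       valid = r$valid)
}
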