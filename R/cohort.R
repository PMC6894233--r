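#' DAPSA score from its five components
#'
#' Disease Activity index for PSoriatic Arthritis: the plain sum of tender
#' joint count, swollen joint count, patient pain VAS (cm), patient global
#' VAS (cm) and CRP (mg/dL).
#'
#' @param tender_joint_count,swollen_joint_count joint counts (>= 0).
#' @param patient_pain_vas_cm,patient_global_vas_cm visual-analogue scales
#'   in cm (0-10).
#' @param crp_mg_dl C-reactive protein, mg/dL (>= 0).
#' @return numeric score(s).
#' @export
dapsa_score <- function(tender_joint_count, swollen_joint_count,
                        patient_pain_vas_cm, patient_global_vas_cm,
                        crp_mg_dl) {
  args <- list(tender_joint_count, swollen_joint_count, patient_pain_vas_cm,
               patient_global_vas_cm, crp_mg_dl)
  if (any(vapply(args, function(a) any(a < 0), TRUE)))
    stop("DAPSA components must be non-negative")
  if (any(patient_pain_vas_cm > 10) || any(patient_global_vas_cm > 10))
    stop("VAS components must be on the 0-10 cm scale")
  tender_joint_count + swollen_joint_count + patient_pain_vas_cm +
    patient_global_vas_cm + crp_mg_dl
}

#' DAPSA disease-activity category
#'
#' Half-open bands: remission (REM) at DAPSA <= 4, low disease activity
#' (LDA) in (4, 14], moderate (MDA) in (14, 28], high (HDA) above 28. The
#' bands tile `[0, Inf)`. Note that the LDA *target* (DAPSA <= 14) includes
#' remission; use [dapsa_lda_met] for target attainment.
#'
#' @param score DAPSA score(s), >= 0.
#' @return factor with levels `REM`, `LDA`, `MDA`, `HDA`.
#' @export
dapsa_category <- function(score) {
  if (any(score < 0)) stop("DAPSA score must be non-negative")
  cut(score, breaks = c(-Inf, 4, 14, 28, Inf),
      labels = c("REM", "LDA", "MDA", "HDA"), right = TRUE)
}

#' @rdname dapsa_category
#' @export
dapsa_lda_met <- function(score) score <= 14

#' Derive patient groups: sustained DAPSA-LDA and long-term TNFi
#'
#' A patient is in the SDL group when the DAPSA low-disease-activity target
#' (score <= 14) is met at both baseline and 5 years; in the TNFi group when
#' exposed to a TNF inhibitor throughout the 5-year interval. Patients with
#' a missing time point are excluded with a warning.
#'
#' @param patients data frame with columns `patient_id`, `dapsa_t0`,
#'   `dapsa_t5`, `tnfi_throughout` (logical).
#' @return the patients with logical columns `sdl` and `tnfi` added.
#' @export
assign_groups <- function(patients) {
  need <- c("patient_id", "dapsa_t0", "dapsa_t5", "tnfi_throughout")
  stopifnot(all(need %in% names(patients)))
  miss <- is.na(patients$dapsa_t0) | is.na(patients$dapsa_t5)
  if (any(miss)) {
    warning(sum(miss), " patient(s) excluded: missing DAPSA at a time point")
    patients <- patients[!miss, , drop = FALSE]
  }
  patients$sdl <- dapsa_lda_met(patients$dapsa_t0) &
    dapsa_lda_met(patients$dapsa_t5)
  patients$tnfi <- as.logical(patients$tnfi_throughout)
  patients
}

#' Pearson chi-square on a 2x2 progression table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square, the test
#' that reproduces the study's printed lesion-level group comparisons.
#'
#' @param tab 2x2 matrix: rows = groups, columns = progressed / not.
#' @return list with `statistic`, `df`, `p_value` (`NA` on an empty margin).
#' @export
progression_chisq <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = NA_real_, df = 1L, p_value = NA_real_))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

join_lesion_groups <- function(dynamics, patients, grouping) {
  stopifnot("patient_id" %in% names(dynamics),
            grouping %in% c("sdl", "tnfi"))
  idx <- match(dynamics$patient_id, patients$patient_id)
  if (anyNA(idx)) stop("every lesion must map to a grouped patient")
  patients[[grouping]][idx]
}

#' Lesion-level progression-count comparison between patient groups
#'
#' Builds the 2x2 progressed-vs-not table of one lesion kind across the two
#' patient groups (lesion-level denominators, matching the study's printed
#' tables) and applies the uncorrected Pearson chi-square.
#'
#' @param dynamics a [lesion_dynamics] table with a `patient_id` column.
#' @param patients an [assign_groups] result.
#' @param kind `"erosion"` or `"enthesiophyte"`.
#' @param grouping `"sdl"` or `"tnfi"`.
#' @return list of class `group_comparison`: the 2x2 `table`, per-group
#'   progressed fractions, `statistic`, `p_value`.
#' @export
compare_progression_counts <- function(dynamics, patients, kind,
                                       grouping = c("sdl", "tnfi")) {
  grouping <- match.arg(grouping)
  sub <- dynamics[dynamics$kind == kind, , drop = FALSE]
  grp <- join_lesion_groups(sub, patients, grouping)
  prog <- sub$category == "progression"
  tab <- rbind(`in_group` = c(sum(prog & grp), sum(!prog & grp)),
               `out_group` = c(sum(prog & !grp), sum(!prog & !grp)))
  colnames(tab) <- c("progressed", "not_progressed")
  ct <- progression_chisq(tab)
  structure(list(grouping = grouping, kind = kind, outcome = "progression counts",
                 table = tab,
                 proportion_in = tab[1, 1] / sum(tab[1, ]),
                 proportion_out = tab[2, 1] / sum(tab[2, ]),
                 statistic = ct$statistic, p_value = ct$p_value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by %s (%s): p = %s\n",
              x$outcome, x$grouping, x$kind,
              format(x$p_value, digits = 3)))
  invisible(x)
}

two_group_test <- function(a, b, alpha = 0.05) {
  # Normality gate (Shapiro-Wilk at alpha) selecting Welch t or
  # Mann-Whitney; degenerate variance falls back to the rank test.
  degenerate <- stats::sd(a) == 0 || stats::sd(b) == 0
  normal <- !degenerate &&
    length(a) >= 3 && length(b) >= 3 &&
    stats::shapiro.test(a)$p.value > alpha &&
    stats::shapiro.test(b)$p.value > alpha
  if (normal) {
    t <- stats::t.test(a, b)
    list(test = "t", statistic = unname(t$statistic), p_value = t$p.value)
  } else {
    if (identical(sort(a), sort(b)))
      return(list(test = "wilcoxon", statistic = NA_real_, p_value = 1))
    w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    list(test = "wilcoxon", statistic = unname(w$statistic),
         p_value = w$p.value)
  }
}

#' Mean volume-change comparison between patient groups
#'
#' Per-group mean and SD of the per-lesion volume change of one kind, with a
#' two-group test selected by a Shapiro-Wilk normality gate (alpha = 0.05):
#' Welch t when both groups pass, Mann-Whitney rank test otherwise
#' (including degenerate-variance groups).
#'
#' @inheritParams compare_progression_counts
#' @return list of class `group_comparison` with per-group `n`, `mean`,
#'   `sd`, the chosen `test` and `p_value`.
#' @export
compare_mean_deltas <- function(dynamics, patients, kind,
                                grouping = c("sdl", "tnfi")) {
  grouping <- match.arg(grouping)
  sub <- dynamics[dynamics$kind == kind, , drop = FALSE]
  grp <- join_lesion_groups(sub, patients, grouping)
  a <- sub$delta_mm3[grp]
  b <- sub$delta_mm3[!grp]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 lesions per group")
  tt <- two_group_test(a, b)
  structure(list(grouping = grouping, kind = kind, outcome = "mean delta",
                 n_in = length(a), mean_in = mean(a), sd_in = stats::sd(a),
                 n_out = length(b), mean_out = mean(b), sd_out = stats::sd(b),
                 test = tt$test, statistic = tt$statistic,
                 p_value = tt$p_value),
            class = "group_comparison")
}

#' Paired test of baseline vs follow-up lesion volumes
#'
#' Tests whether lesion volumes changed between time points: Shapiro-Wilk
#' gate (alpha = 0.05) on the paired differences selects the paired t test
#' (differences compatible with a Gaussian) or the Wilcoxon signed-rank
#' test; two-sided. All-zero differences give p = 1 with a flag.
#'
#' @param volumes_t0,volumes_t5 equal-length paired volume series (mm^3),
#'   n >= 3.
#' @return list with `test`, `statistic`, `p_value`, `mean_change`,
#'   `sd_change`, `all_zero`.
#' @export
paired_change_test <- function(volumes_t0, volumes_t5) {
  stopifnot(length(volumes_t0) == length(volumes_t5))
  n <- length(volumes_t0)
  if (n < 3) stop("need at least 3 pairs")
  d <- volumes_t5 - volumes_t0
  if (all(d == 0))
    return(list(test = "none", statistic = NA_real_, p_value = 1,
                mean_change = 0, sd_change = 0, all_zero = TRUE))
  normal <- length(d) <= 5000 && stats::sd(d) > 0 &&
    stats::shapiro.test(d)$p.value > 0.05
  if (normal) {
    t <- stats::t.test(volumes_t5, volumes_t0, paired = TRUE)
    res <- list(test = "paired_t", statistic = unname(t$statistic),
                p_value = t$p.value)
  } else {
    w <- suppressWarnings(stats::wilcox.test(volumes_t5, volumes_t0,
                                             paired = TRUE, exact = FALSE))
    res <- list(test = "wilcoxon_signed_rank",
                statistic = unname(w$statistic), p_value = w$p.value)
  }
  c(res, list(mean_change = mean(d), sd_change = stats::sd(d),
              all_zero = FALSE))
}

#' Monte-Carlo conditional permutation p-value for a 2x2 table
#'
#' Independent oracle for [progression_chisq]: permutes group labels against
#' outcomes (conditioning on both margins) and estimates the mid-p of the
#' chi-square statistic — the fraction of permutations strictly exceeding
#' the observed statistic plus half the fraction tying it. The mid-p
#' convention is used because the conditional distribution of a 2x2 table is
#' discrete with substantial point mass at the observed statistic, and the
#' asymptotic chi-square p-value approximates the mid-p, not the inclusive
#' tail.
#'
#' @param tab 2x2 matrix.
#' @param n_perm number of permutations.
#' @return list with `p_value` (mid-p) and its Monte-Carlo standard error.
#' @export
permutation_chisq_p <- function(tab, n_perm = 2000) {
  tab <- as.matrix(tab)
  obs <- progression_chisq(tab)$statistic
  grp <- rep(c(TRUE, FALSE), times = rowSums(tab))
  out <- rep(c(TRUE, FALSE), times = c(sum(tab[, 1]), sum(tab[, 2])))
  stat_of <- function(g) {
    t2 <- rbind(c(sum(out & g), sum(!out & g)),
                c(sum(out & !g), sum(!out & !g)))
    s <- progression_chisq(t2)$statistic
    if (is.na(s)) 0 else s
  }
  stats <- vapply(seq_len(n_perm), function(i) stat_of(sample(grp)), 0)
  p <- mean(stats > obs + 1e-12) + 0.5 * mean(abs(stats - obs) <= 1e-12)
  list(p_value = p, mc_se = sqrt(max(p * (1 - p), 1e-12) / n_perm))
}

#' Assemble the study-style report
#'
#' Produces the tabular outputs of a full analysis run: lesion counts per
#' kind and compartment at both time points with new-lesion counts; mean
#' (SD) per-lesion volumes and paired change tests; the dynamics summary
#' (counts, proportions, per-category change); group comparisons
#' (progression counts and mean changes by SDL and TNFi grouping); and the
#' cumulative-probability series. Formatting helpers round volumes to one
#' decimal and proportions to 0.1%.
#'
#' @param dynamics a [lesion_dynamics] table with `patient_id`.
#' @param patients an [assign_groups] result.
#' @return list of class `study_report` with elements `counts`, `volumes`,
#'   `dynamics_summary`, `group_counts`, `group_deltas`,
#'   `cumulative`.
#' @export
build_report <- function(dynamics, patients = NULL) {
  kinds <- c("erosion", "enthesiophyte")
  counts <- do.call(rbind, lapply(kinds, function(kd) {
    sub <- dynamics[dynamics$kind == kd, , drop = FALSE]
    comps <- sort(unique(sub$compartment))
    rows <- lapply(c(list(NULL), as.list(comps)), function(cp) {
      s <- if (is.null(cp)) sub else sub[sub$compartment == cp, , drop = FALSE]
      data.frame(kind = kd, compartment = if (is.null(cp)) "total" else cp,
                 n_baseline = sum(s$status != "new"),
                 n_followup = sum(s$status != "lost"),
                 n_new = sum(s$status == "new"))
    })
    do.call(rbind, rows)
  }))
  volumes <- do.call(rbind, lapply(kinds, function(kd) {
    sub <- dynamics[dynamics$kind == kd, , drop = FALSE]
    if (nrow(sub) < 3)
      return(data.frame(kind = kd, n = nrow(sub), mean_t0 = NA_real_,
                        sd_t0 = NA_real_, mean_t5 = NA_real_, sd_t5 = NA_real_,
                        mean_change = NA_real_, sd_change = NA_real_,
                        p_value = NA_real_, test = NA_character_))
    pt <- paired_change_test(sub$vol_t0_mm3, sub$vol_t5_mm3)
    data.frame(kind = kd, n = nrow(sub),
               mean_t0 = mean(sub$vol_t0_mm3), sd_t0 = stats::sd(sub$vol_t0_mm3),
               mean_t5 = mean(sub$vol_t5_mm3), sd_t5 = stats::sd(sub$vol_t5_mm3),
               mean_change = pt$mean_change, sd_change = pt$sd_change,
               p_value = pt$p_value, test = pt$test)
  }))
  group_counts <- NULL
  group_deltas <- NULL
  if (!is.null(patients) && "patient_id" %in% names(dynamics)) {
    combos <- expand.grid(kind = kinds, grouping = c("sdl", "tnfi"),
                          stringsAsFactors = FALSE)
    group_counts <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      gc <- compare_progression_counts(dynamics, patients, combos$kind[i],
                                       combos$grouping[i])
      data.frame(kind = gc$kind, grouping = gc$grouping,
                 progressed_in = gc$table[1, 1], n_in = sum(gc$table[1, ]),
                 progressed_out = gc$table[2, 1], n_out = sum(gc$table[2, ]),
                 pct_in = round(100 * gc$proportion_in, 1),
                 pct_out = round(100 * gc$proportion_out, 1),
                 statistic = gc$statistic, p_value = gc$p_value)
    }))
    group_deltas <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      gd <- compare_mean_deltas(dynamics, patients, combos$kind[i],
                                combos$grouping[i])
      data.frame(kind = gd$kind, grouping = gd$grouping,
                 n_in = gd$n_in, mean_in = gd$mean_in, sd_in = gd$sd_in,
                 n_out = gd$n_out, mean_out = gd$mean_out, sd_out = gd$sd_out,
                 test = gd$test, p_value = gd$p_value)
    }))
  }
  structure(list(counts = counts, volumes = volumes,
                 dynamics_summary = summarize_dynamics(dynamics),
                 group_counts = group_counts, group_deltas = group_deltas,
                 cumulative = cumulative_probability_data(dynamics)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\nLesion counts:\n")
  print(x$counts)
  cat("\nVolumes (mm^3):\n")
  v <- x$volumes
  for (i in seq_len(nrow(v)))
    cat(sprintf("  %-14s n=%3d  t0 %.1f (%.1f)  t5 %.1f (%.1f)  change %.1f (%.1f), p %s\n",
                v$kind[i], v$n[i], v$mean_t0[i], v$sd_t0[i], v$mean_t5[i],
                v$sd_t5[i], v$mean_change[i], v$sd_change[i],
                format.pval(v$p_value[i], digits = 2)))
  cat("\nDynamics:\n")
  print(x$dynamics_summary)
  if (!is.null(x$group_counts)) {
    cat("\nGroup progression counts:\n")
    print(x$group_counts)
    cat("\nGroup mean changes:\n")
    print(x$group_deltas)
  }
  invisible(x)
}
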