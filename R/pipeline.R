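# End-to-end orchestration: single-subject analysis, healthy-cohort
# calibration and rater-statistics evaluation.

#' Analyze one FA sequence end to end
#'
#' Runs the full chain: noisy-frame exclusion, eye classification,
#' registration, AIF extraction, normalization, slope fitting,
#' thresholding and rendering.  Deterministic given inputs and parameters;
#' the returned manifest records every parameter needed to reproduce the
#' outputs.
#'
#' @param seq an [fa_sequence()] (e.g. from [read_fa_sequence()]).
#' @param artery_roi an [roi_mask()] with role `"artery"`.
#' @param threshold a [derive_threshold()] result, a bare slope value, or
#'   `NULL` to skip scoring/rendering.
#' @param disc_roi optional optic-disc [roi_mask()]; when given it takes
#'   precedence over automatic disc detection for the exclusion mask.
#' @param min_corr noisy-frame exclusion threshold (default 0.5).
#' @param upsample registration sub-pixel factor (default 100).
#' @param fit_start_s late-phase fit start (default 120 s).
#' @param border_margin border exclusion width in px (default 8).
#' @param aif_floor_frac AIF floor as fraction of its max (default 0.1).
#' @return list of class `fa_analysis` with `slope_map`, `rgb_map`,
#'   `summary` (abnormal fraction, threshold, exclusions, reference
#'   index, eye), `registration`, `aif`, `exclusion_mask`, `manifest`.
#' @export
analyze_sequence <- function(seq, artery_roi, threshold = NULL,
                             disc_roi = NULL, min_corr = 0.5,
                             upsample = 100L, fit_start_s = 120,
                             border_margin = 8L, aif_floor_frac = 0.1) {
  seq <- flag_noisy_frames(seq, min_corr)
  eye <- tryCatch(classify_eye(seq), error = function(e) "unknown")
  reg <- register_sequence(seq, upsample = upsample)
  aif <- compute_aif(reg$registered, artery_roi, floor_frac = aif_floor_frac)
  nseq <- normalize_sequence(reg$registered, aif)
  smap <- fit_slope_map(nseq, fit_start_s = fit_start_s)
  excl <- border_mask(seq$pixel_dims, border_margin)
  if (is.null(disc_roi)) {
    # automatic stand-in: the detected bright component is dilated to
    # cover the physiologically leaky disc fringe; a manual disc ROI
    # takes precedence when supplied
    disc_det <- tryCatch(
      detect_optic_disc(reg$registered$frames[[reg$reference_index]]),
      error = function(e) NULL)
    if (!is.null(disc_det)) excl <- excl | dilate_mask(disc_det$mask, 8L)
  } else excl <- excl | disc_roi$mask
  frac <- NA_real_
  rgb <- NULL
  thr_val <- NA_real_
  if (!is.null(threshold)) {
    thr_val <- if (inherits(threshold, "permeability_threshold"))
      threshold$slope_threshold else threshold
    frac <- abnormal_fraction(smap, thr_val, excl)
    rgb <- render_map(smap, thr_val)
  }
  n_excluded <- sum(!usable_idx(seq))
  structure(list(
    slope_map = smap, rgb_map = rgb,
    summary = list(abnormal_fraction = frac, slope_threshold = thr_val,
                   frames_total = length(seq$frames),
                   frames_excluded = n_excluded,
                   frames_fitted = smap$n_points,
                   reference_index = reg$reference_index, eye = eye,
                   version = as.character(utils::packageVersion("reticad"))),
    registration = reg, aif = aif, exclusion_mask = excl,
    manifest = list(min_corr = min_corr, upsample = upsample,
                    fit_start_s = fit_start_s,
                    border_margin = border_margin,
                    aif_floor_frac = aif_floor_frac,
                    n_frames = length(seq$frames))),
    class = "fa_analysis")
}

#' @export
print.fa_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<fa_analysis> %s eye, %d/%d frames used, ",
                     "reference %d\n"),
              s$eye, s$frames_total - s$frames_excluded, s$frames_total,
              s$reference_index))
  if (!is.na(s$abnormal_fraction))
    cat(sprintf("  abnormal fraction %.4f at threshold %.3g /s\n",
                s$abnormal_fraction, s$slope_threshold))
  invisible(x)
}

#' Calibrate the pathological threshold on a healthy cohort
#'
#' @param slope_maps list of healthy-subject [slope_map()]s.
#' @param exclusion_masks per-subject exclusion masks (see
#'   [mean_cumulative_histogram()]).
#' @param percentile healthy quantile defining the threshold (default
#'   0.995).
#' @param grid_size CDF grid resolution (default 2048).
#' @return list with `threshold` (a `permeability_threshold`) and
#'   `cum_hist`.
#' @export
calibrate_cohort <- function(slope_maps, exclusion_masks = NULL,
                             percentile = 0.995, grid_size = 2048L) {
  ch <- mean_cumulative_histogram(slope_maps, exclusion_masks, grid_size)
  list(threshold = derive_threshold(ch, percentile), cum_hist = ch)
}

#' Rater-statistics evaluation of two reading modalities
#'
#' Computes, for paired ratings of the same eyes under conventional FA
#' reading and computed permeability maps: Fleiss' kappa per modality
#' (with qualitative band), the bootstrap CI for the kappa difference,
#' averaged sensitivity/specificity of the map readings against a gold
#' standard, per-eye consensus scores, and the exact one-tailed McNemar
#' test on the consensus improvement.
#'
#' @param grids_fa,grids_map data.frames as from [read_rater_grids()],
#'   covering the same eyes and raters.
#' @param gold named binary vector of gold-standard diagnoses (names =
#'   eye ids).
#' @param n_boot,seed bootstrap parameters (see [bootstrap_kappa_diff()]).
#' @return list of statistics (see Details).
#' @export
evaluate_raters <- function(grids_fa, grids_map, gold, n_boot = 10000L,
                            seed = 1L) {
  tab_fa <- rating_table(grids_fa)
  tab_map <- rating_table(grids_map)
  stopifnot(identical(rownames(tab_fa), rownames(tab_map)))
  k_fa <- fleiss_kappa(tab_fa)
  k_map <- fleiss_kappa(tab_map)
  boot <- bootstrap_kappa_diff(tab_map, tab_fa, n_boot = n_boot, seed = seed)
  gold <- gold[rownames(tab_map)]
  if (anyNA(gold)) stop("gold standard missing for some eyes")
  ss <- sens_spec(tab_map, gold)
  cons <- function(grids) {
    eyes <- sort(unique(grids$eye_id))
    vapply(eyes, function(e) {
      rows <- grids[grids$eye_id == e, ]
      g <- lapply(seq_len(nrow(rows)), function(i)
        as.numeric(rows[i, paste0("sq_", 1:9)]))
      consensus_score(g)$eye_score
    }, numeric(1))
  }
  c_fa <- cons(grids_fa); c_map <- cons(grids_map)
  p_mcnemar <- mcnemar_one_tailed(a = as.integer(c_fa >= 0.5),
                                  b = as.integer(c_map >= 0.5))
  list(kappa_fa = k_fa, kappa_fa_band = kappa_band(k_fa),
       kappa_map = k_map, kappa_map_band = kappa_band(k_map),
       kappa_diff = boot$diff, kappa_diff_ci = c(boot$ci_low, boot$ci_high),
       sensitivity = ss$sensitivity, specificity = ss$specificity,
       consensus_fa = c_fa, consensus_map = c_map,
       mcnemar_p = p_mcnemar)
}

#' Run a full cohort study on synthetic subjects in one call
#'
#' For every subject of a [generate_cohort()] result the sequence is
#' quality-filtered, registered, normalized to its arterial input
#' function and slope-fitted; the pathological threshold is calibrated on
#' the healthy subjects' mean cumulative histogram and every subject is
#' scored against it.  ROIs come from the phantom truth (standing in for
#' the manually drawn artery/disc regions), re-rendered at each
#' registered stack's reference position.
#'
#' @param cohort list from [generate_cohort()].
#' @param percentile healthy quantile for the threshold (default 0.995).
#' @param border_margin border exclusion in px (default 8).
#' @param min_corr,upsample,fit_start_s stage parameters (defaults 0.5,
#'   100, 120).
#' @return list with `threshold`, `cum_hist`, `fractions` (per subject),
#'   `groups`, and `subjects` (per-subject list: `slope_map`, `excl`,
#'   `registration`, `truth`).
#' @export
cohort_study <- function(cohort, percentile = 0.995, border_margin = 8L,
                         min_corr = 0.5, upsample = 100L,
                         fit_start_s = 120) {
  subjects <- lapply(cohort, function(subj) {
    seq <- flag_noisy_frames(subj$sequence, min_corr)
    reg <- register_sequence(seq, upsample = upsample)
    mk <- phantom_masks_at(subj$truth,
                           subj$truth$true_shifts[[reg$reference_index]])
    aif <- compute_aif(reg$registered, mk$artery_mask)
    smap <- fit_slope_map(normalize_sequence(reg$registered, aif),
                          fit_start_s = fit_start_s)
    excl <- border_mask(seq$pixel_dims, border_margin) | mk$disc_mask$mask
    list(slope_map = smap, excl = excl, registration = reg,
         masks = mk, truth = subj$truth, group = subj$group)
  })
  groups <- vapply(subjects, `[[`, character(1), "group")
  healthy <- subjects[groups == "healthy"]
  if (!length(healthy)) stop("cohort has no healthy subjects to calibrate on")
  cal <- calibrate_cohort(lapply(healthy, `[[`, "slope_map"),
                          lapply(healthy, `[[`, "excl"),
                          percentile = percentile)
  fractions <- vapply(subjects, function(s)
    abnormal_fraction(s$slope_map, cal$threshold, s$excl), numeric(1))
  list(threshold = cal$threshold, cum_hist = cal$cum_hist,
       fractions = fractions, groups = groups, subjects = subjects)
}

#' Write a phantom to disk in the package's exchange formats
#'
#' Frames as 32-bit float TIFFs plus `meta.json` in `dir`; ground truth
#' (ROIs as run-length JSON, leak map as float TIFF, true shifts as CSV)
#' under `dir/truth/` so frame readers see only frames.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  tdir <- file.path(dir, "truth")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  seq <- phantom$sequence
  meta <- list()
  for (i in seq_along(seq$frames)) {
    fn <- sprintf("frame_%03d.tif", i - 1L)
    write_tiff(seq$frames[[i]]$pixels, file.path(dir, fn), bits = 32L)
    meta[[fn]] <- seq$frames[[i]]$t
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  write_roi(phantom$truth$artery_mask, file.path(tdir, "artery.json"))
  write_roi(phantom$truth$disc_mask, file.path(tdir, "disc.json"))
  write_tiff(phantom$truth$leak_map, file.path(tdir, "leak_map.tif"))
  sh <- phantom$truth$true_shifts
  utils::write.csv(data.frame(
    frame = seq_along(sh) - 1L,
    d_row = vapply(sh, `[[`, numeric(1), "d_row"),
    d_col = vapply(sh, `[[`, numeric(1), "d_col")),
    file.path(tdir, "true_shifts.csv"), row.names = FALSE)
  invisible(dir)
}
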