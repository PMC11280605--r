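#' Signal-to-noise ratio of an image, in dB
#'
#' Ratio between the mean signal inside an ROI and the standard deviation of
#' the background noise, expressed in decibels. The default `20 log10`
#' convention treats the inputs as amplitude images; `db = 10` is available
#' for sensitivity checks on power-like quantities.
#'
#' @param image numeric matrix.
#' @param roi logical mask of the signal region.
#' @param background logical mask of the noise region (disjoint from ROIs).
#' @param db dB convention: 20 (amplitude, default) or 10.
#' @return SNR in dB; `Inf` (with attribute `zero_background = TRUE`) when
#'   the background standard deviation is zero.
#' @export
snr_db <- function(image, roi, background, db = 20) {
  s <- mean(image[roi])
  n <- stats::sd(image[background])
  if (n == 0) {
    out <- Inf
    attr(out, "zero_background") <- TRUE
    return(out)
  }
  db * log10(s / n)
}

#' Frequency-averaged SNR of an image series, in dB
#'
#' Arithmetic mean of the per-offset [snr_db()] values over the included
#' offsets — the image-quality summary used to compare reconstructions.
#'
#' @param images an [image_series()].
#' @param roi,background logical masks.
#' @param include offsets (Hz) to include; defaults to all.
#' @param db dB convention.
#' @return list with `averaged_db` and the per-offset vector `per_offset_db`.
#' @export
averaged_snr <- function(images, roi, background,
                         include = images$grid$offsets_hz, db = 20) {
  if (!length(include)) stop("offset selection is empty")
  idx <- vapply(include, function(w) offset_index(images$grid, w), 1L)
  per <- vapply(idx, function(w)
    as.numeric(snr_db(images$data[, , w], roi, background, db)), 0)
  list(averaged_db = mean(per),
       per_offset_db = stats::setNames(per, images$grid$offsets_hz[idx]))
}

#' Per-ROI mean and standard deviation of a map
#'
#' Population statistics (divisor n) of a 2D map within each named ROI, e.g.
#' of an MTR-asymmetry map. `NA` pixels (masked background) are dropped.
#'
#' @param map numeric matrix.
#' @param rois named list of logical masks.
#' @return data frame with columns `roi`, `mean`, `sd`, `n`.
#' @export
roi_statistics <- function(map, rois) {
  stopifnot(length(rois) > 0, !is.null(names(rois)))
  rows <- lapply(names(rois), function(nm) {
    v <- map[rois[[nm]]]
    v <- v[is.finite(v)]
    if (!length(v)) stop(sprintf("ROI '%s' is empty", nm))
    data.frame(roi = nm, mean = mean(v),
               sd = sqrt(mean((v - mean(v))^2)), n = length(v))
  })
  do.call(rbind, rows)
}

#' Uncertainty reduction between two sets of per-ROI standard deviations
#'
#' Summarises how much a method reduces the spread of MTR-asymmetry
#' estimates over all ROIs: `100 * (1 - aggregate(sd_new)/aggregate(sd_ref))`
#' with the aggregate being the unweighted mean over ROIs. The per-ROI
#' reductions and their mean are also reported, since aggregation conventions
#' differ between the ratio-of-means and mean-of-ratios forms.
#'
#' @param sd_ref per-ROI standard deviations of the reference method.
#' @param sd_new per-ROI standard deviations of the new method (same ROIs).
#' @return list with `reduction_pct` (ratio of aggregates), `aggregate_ref`,
#'   `aggregate_new`, `per_roi_pct`, `mean_per_roi_pct`.
#' @export
uncertainty_reduction <- function(sd_ref, sd_new) {
  if (length(sd_ref) != length(sd_new))
    stop("sd_ref and sd_new must cover the same ROIs")
  agg_ref <- mean(sd_ref)
  agg_new <- mean(sd_new)
  if (agg_ref <= 0) stop("reference aggregate must be > 0")
  per <- 100 * (1 - sd_new / sd_ref)
  list(reduction_pct = 100 * (1 - agg_new / agg_ref),
       aggregate_ref = agg_ref, aggregate_new = agg_new,
       per_roi_pct = per, mean_per_roi_pct = mean(per))
}

#' Contrast-to-noise ratio of a map between an ROI and a reference region
#'
#' `(mean(map[roi]) - mean(map[reference])) / sd(map[reference])` — used to
#' quantify whether a CEST effect remains detectable against the surrounding
#' tissue in a noisy MTR-asymmetry map.
#'
#' @param map numeric matrix (may contain `NA` at masked pixels).
#' @param roi,reference logical masks.
#' @return dimensionless CNR.
#' @export
contrast_to_noise <- function(map, roi, reference) {
  a <- map[roi]; a <- a[is.finite(a)]
  b <- map[reference]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("empty ROI after masking")
  (mean(a) - mean(b)) / stats::sd(b)
}

#' Evaluation report for one or two reconstructions
#'
#' Computes the per-offset and averaged SNR, the MTR-asymmetry map at each
#' pool frequency, and per-ROI asymmetry statistics for a reconstruction;
#' when a second reconstruction is given, adds the paired comparison
#' (SNR difference and per-ROI uncertainty reduction).
#'
#' @param result a `cest_recon`.
#' @param scene the [build_phantom()] scene providing ROI masks.
#' @param reference optional second `cest_recon` to compare against
#'   (conventionally the baseline).
#' @param db dB convention for [snr_db()].
#' @return list of class `cest_eval`.
#' @export
evaluate_recon <- function(result, scene, reference = NULL, db = 20) {
  rois <- scene$roi_masks
  bg <- rois[[scene$background]]
  sig_rois <- rois[setdiff(names(rois), scene$background)]
  snr <- averaged_snr(result$images, Reduce(`|`, sig_rois), bg, db = db)
  pools <- result$images$grid$pool_offsets_hz
  mtr <- lapply(pools, function(w) mtr_asymmetry_map(result$images, w))
  names(mtr) <- paste0(pools, "Hz")
  stats <- lapply(mtr, roi_statistics, rois = sig_rois)
  out <- list(averaged_snr_db = snr$averaged_db,
              per_offset_snr_db = snr$per_offset_db,
              mtr_maps = mtr, roi_stats = stats)
  if (!is.null(reference)) {
    ref_eval <- evaluate_recon(reference, scene, db = db)
    out$comparison <- list(
      snr_diff_db = snr$averaged_db - ref_eval$averaged_snr_db,
      uncertainty = lapply(names(stats), function(nm)
        uncertainty_reduction(ref_eval$roi_stats[[nm]]$sd, stats[[nm]]$sd)))
    names(out$comparison$uncertainty) <- names(stats)
  }
  structure(out, class = "cest_eval")
}
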