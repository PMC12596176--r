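#' Per-ROI HU statistics
#'
#' Mean, sample SD (n-1 denominator) and coefficient of variation over all
#' voxels of a mask.  The CoV is the ratio of the SD to the absolute mean
#' (air has negative mean HU but is reported with a positive CoV), and is
#' 0 when the mean is exactly 0.
#'
#' @param vol a [voxel_volume()].
#' @param mask an [roi_mask()] (non-empty).
#' @return A one-row data.frame: `label, n_voxels, mean_hu, sd_hu, cov`.
#' @examples
#' v <- voxel_volume(array(-1000, c(4, 4, 4)), c(1, 1, 1))
#' roi_stats(v, roi_mask("air", 1:16, c(4, 4, 4)))
#' @export
roi_stats <- function(vol, mask) {
  v <- mask_values(as_voxel_volume(vol), mask)
  if (length(v) < 2L) stopf("mask '%s' has fewer than 2 voxels", mask$label)
  m <- mean(v); s <- sd(v)
  data.frame(label = mask$label, n_voxels = length(v), mean_hu = m,
             sd_hu = s, cov = if (m != 0) s / abs(m) else 0,
             stringsAsFactors = FALSE)
}

#' HU statistics for a set of masks
#' @param vol a [voxel_volume()].
#' @param masks list of [roi_mask()]s.
#' @return data.frame with one row per mask.
#' @export
roi_stats_table <- function(vol, masks) {
  do.call(rbind, lapply(masks, function(m) roi_stats(vol, m)))
}

#' Low-attenuation-area percentages
#'
#' Percentage of masked voxels strictly below each threshold.  The default
#' thresholds are the emphysema (-950 HU) and gas-trapping (-856 HU)
#' surrogates.
#'
#' @param vol a [voxel_volume()].
#' @param mask an [roi_mask()].
#' @param thresholds HU thresholds (strict less-than).
#' @return A one-row data.frame `label, laa950, laa856` (columns named
#'   `laa<|threshold|>` for non-default thresholds), values in percent.
#' @export
laa <- function(vol, mask, thresholds = c(-950, -856)) {
  v <- mask_values(as_voxel_volume(vol), mask)
  if (!length(v)) stopf("mask '%s' is empty", mask$label)
  pct <- vapply(thresholds, function(th) 100 * mean(v < th), 0)
  out <- data.frame(label = mask$label, stringsAsFactors = FALSE)
  for (i in seq_along(thresholds))
    out[[paste0("laa", abs(thresholds[i]))]] <- pct[i]
  out
}

#' Differences of per-insert statistics against a reference protocol
#'
#' Matches ROI labels between a candidate and a reference statistics table
#' and reports signed and absolute mean-HU differences and SD differences,
#' plus a `mean +/- SD (range)` summary of the absolute mean differences
#' across matched labels.
#'
#' @param stats,ref data.frames as returned by [roi_stats_table()] (columns
#'   `label, mean_hu, sd_hu`).
#' @return data.frame with columns `label, delta_mean_hu, abs_delta_mean_hu,
#'   delta_sd_hu`; the summary is in attribute `summary` (list with `mean`,
#'   `sd`, `min`, `max` of the absolute mean differences) and in attribute
#'   `summary_text`.
#' @export
diff_vs_reference <- function(stats, ref) {
  common <- intersect(stats$label, ref$label)
  if (!length(common)) stopf("no matching ROI labels between tables")
  i <- match(common, stats$label); j <- match(common, ref$label)
  d <- stats$mean_hu[i] - ref$mean_hu[j]
  out <- data.frame(label = common,
                    delta_mean_hu = d,
                    abs_delta_mean_hu = abs(d),
                    delta_sd_hu = stats$sd_hu[i] - ref$sd_hu[j],
                    stringsAsFactors = FALSE)
  s <- list(mean = mean(abs(d)),
            sd = if (length(d) > 1) sd(abs(d)) else 0,
            min = min(abs(d)), max = max(abs(d)))
  attr(out, "summary") <- s
  attr(out, "summary_text") <- sprintf("%.1f ± %.1f HU (range %.1f–%.1f HU)",
                                       s$mean, s$sd, s$min, s$max)
  out
}
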