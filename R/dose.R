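#' Effective-dose parameters
#'
#' Chest CT effective dose is estimated as
#' `CTDIvol (mGy) x scan length (cm) x k`, with the chest conversion
#' factor k = 0.027 mSv/(mGy cm) and a 30 cm scan length for the
#' standardized lung protocol.
#'
#' @param scan_length scan length in cm.
#' @param k_factor chest conversion factor in mSv/(mGy cm).
#' @return A `dose_params` list.
#' @export
dose_params <- function(scan_length = 30, k_factor = 0.027) {
  if (!is.finite(scan_length) || scan_length <= 0) stopf("scan_length must be > 0")
  if (!is.finite(k_factor) || k_factor <= 0) stopf("k_factor must be > 0")
  structure(list(scan_length = scan_length, k_factor = k_factor),
            class = "dose_params")
}

#' Effective dose from CTDIvol
#'
#' Full precision is retained; round only at display time (2 decimals,
#' half away from zero) via [format_msv()].
#'
#' @param ctdi_vol CTDIvol in mGy (vectorized, >= 0).
#' @param params a [dose_params()].
#' @return Effective dose in mSv.
#' @examples
#' effective_dose(2.22)          # 1.7982, displays as 1.80
#' @export
effective_dose <- function(ctdi_vol, params = dose_params()) {
  if (any(!is.finite(ctdi_vol)) || any(ctdi_vol < 0))
    stopf("ctdi_vol must be >= 0")
  ctdi_vol * params$scan_length * params$k_factor
}

#' @rdname effective_dose
#' @export
format_msv <- function(ctdi_vol, params = dose_params()) {
  sprintf("%.2f", round_half_up(effective_dose(ctdi_vol, params), 2))
}

#' Percent dose reduction relative to a reference CTDIvol
#'
#' @param reference_ctdi reference CTDIvol in mGy (> 0).
#' @param low_ctdi candidate CTDIvol in mGy (vectorized).
#' @return Reduction in percent: `100 * (reference - low) / reference`.
#' @export
percent_reduction <- function(reference_ctdi, low_ctdi) {
  if (!is.finite(reference_ctdi) || reference_ctdi <= 0)
    stopf("reference_ctdi must be > 0")
  100 * (reference_ctdi - low_ctdi) / reference_ctdi
}

#' Summary of dose reductions across protocols
#'
#' @param reductions numeric vector of percent reductions (length >= 2).
#' @return List with `mean`, `sd` (sample SD), `min`, `max`.
#' @export
summarize_reductions <- function(reductions) {
  if (length(reductions) < 2L) stopf("need at least 2 reduction values")
  list(mean = mean(reductions), sd = sd(reductions),
       min = min(reductions), max = max(reductions))
}

#' Bundle one protocol's metrics into a record
#'
#' @param meta a [protocol_meta()] with a valid CTDIvol.
#' @param roi_stats data.frame from [roi_stats_table()] (or equivalent
#'   columns `label, mean_hu, sd_hu`).
#' @param laa optional data.frame of LAA percentages.
#' @param mtf_summary optional named list/vector of MTF cutoffs in
#'   cycles/cm (e.g. `in_plane_f50, in_plane_f20, z_f50, z_f20`).
#' @param params a [dose_params()].
#' @return A `protocol_record` with `effective_dose` precomputed (and
#'   always recomputable from the metadata).
#' @export
protocol_record <- function(meta, roi_stats, laa = NULL, mtf_summary = NULL,
                            params = dose_params()) {
  if (!inherits(meta, "protocol_meta")) stopf("meta must be a protocol_meta")
  if (is.na(meta$ctdi_vol)) stopf("protocol record needs a CTDIvol")
  structure(list(meta = meta, roi_stats = roi_stats, laa = laa,
                 mtf_summary = mtf_summary,
                 effective_dose = effective_dose(meta$ctdi_vol, params),
                 params = params),
            class = "protocol_record")
}

#' @export
print.protocol_record <- function(x, ...) {
  cat(sprintf("<protocol_record> %s / %s: CTDIvol %.2f mGy (%s mSv), %d ROIs\n",
              x$meta$scanner_label, x$meta$recon_label, x$meta$ctdi_vol,
              format_msv(x$meta$ctdi_vol, x$params), nrow(x$roi_stats)))
  invisible(x)
}

record_primary <- function(rec, primary_labels) {
  i <- match(primary_labels, rec$roi_stats$label)
  if (anyNA(i)) return(NULL)
  rec$roi_stats[i, , drop = FALSE]
}

mtf_score <- function(rec) {
  if (is.null(rec$mtf_summary)) return(NA_real_)
  mean(unlist(rec$mtf_summary), na.rm = TRUE)
}

#' Select the optimal low-dose protocol against a reference
#'
#' Implements the two-stage harmonization rule.  Stage 1: each candidate
#' is scored by its total absolute mean-HU difference from the reference
#' over the primary inserts (air and the two water vials) and by its MTF
#' summary; a candidate that uniquely minimizes the HU difference (no
#' other candidate within `hu_tie_tol`) and is also MTF-preferred (within
#' `mtf_tie_tol` cycles/cm of the best MTF) is selected outright.
#' Stage 2: when candidates tie on the HU difference, or the HU- and
#' MTF-preferred candidates disagree, the candidate with the lowest
#' summed HU SD over the primary inserts is selected to minimize image
#' noise.
#'
#' @param candidates list of [protocol_record()]s (names become candidate
#'   ids; unnamed lists use scanner/recon labels).
#' @param reference the reference-standard [protocol_record()].
#' @param hu_tie_tol HU-difference tie tolerance (HU).
#' @param mtf_tie_tol MTF tie tolerance (cycles/cm).
#' @param primary_labels insert labels with known ground truth used for
#'   scoring.
#' @return List with `selected` (candidate id), `stage`
#'   (`"hu_mtf"` or `"sd_tiebreak"`) and `audit`, a data.frame recording
#'   every per-candidate comparison.
#' @export
select_protocol <- function(candidates, reference, hu_tie_tol = 5,
                            mtf_tie_tol = 0.1,
                            primary_labels = c("air", "water_vial_1",
                                               "water_vial_2")) {
  if (!length(candidates)) stopf("no candidates supplied")
  if (is.null(names(candidates)))
    names(candidates) <- vapply(candidates, function(r)
      paste(r$meta$scanner_label, r$meta$recon_label, r$meta$ctdi_vol,
            sep = "_"), "")
  refp <- record_primary(reference, primary_labels)
  if (is.null(refp))
    stopf("reference lacks primary labels (%s)",
          paste(primary_labels, collapse = ", "))
  rows <- lapply(names(candidates), function(id) {
    cp <- record_primary(candidates[[id]], primary_labels)
    if (is.null(cp))
      stopf("candidate '%s' lacks primary labels (%s)", id,
            paste(primary_labels, collapse = ", "))
    data.frame(id = id,
               dhu = sum(abs(cp$mean_hu - refp$mean_hu)),
               mtf = mtf_score(candidates[[id]]),
               sd_sum = sum(cp$sd_hu),
               stringsAsFactors = FALSE)
  })
  audit <- do.call(rbind, rows)
  audit <- audit[order(audit$id), , drop = FALSE]   # order-invariant
  best_dhu <- min(audit$dhu)
  audit$hu_tied <- audit$dhu <= best_dhu + hu_tie_tol
  best_mtf <- if (all(is.na(audit$mtf))) NA_real_ else max(audit$mtf, na.rm = TRUE)
  audit$mtf_preferred <- !is.na(audit$mtf) & audit$mtf >= best_mtf - mtf_tie_tol
  hu_winner <- audit$id[which.min(audit$dhu)]
  tie <- sum(audit$hu_tied) > 1L
  mtf_ok <- is.na(best_mtf) ||
    audit$mtf_preferred[audit$id == hu_winner]
  if (!tie && mtf_ok) {
    selected <- hu_winner; stage <- "hu_mtf"
  } else {
    pool <- audit[audit$hu_tied, , drop = FALSE]
    selected <- pool$id[order(pool$sd_sum, pool$id)][1]
    stage <- "sd_tiebreak"
  }
  audit$selected <- audit$id == selected
  list(selected = selected, stage = stage, audit = audit)
}

#' Assemble a protocol comparison report
#'
#' Collects per-candidate difference tables against the reference, the
#' dose-reduction summary, and (when MTF summaries are present) the
#' selection outcome.
#'
#' @param reference a [protocol_record()].
#' @param candidates list of [protocol_record()]s.
#' @param params a [dose_params()].
#' @param select run [select_protocol()] on the candidates.
#' @param ... passed to [select_protocol()].
#' @return A `comparison_report`: list with `reference`, `candidates`,
#'   `deltas` (per candidate), `dose_summary` (per-protocol percent
#'   reduction plus mean/sd/min/max when 2+ candidates) and `selected`.
#' @export
build_report <- function(reference, candidates, params = dose_params(),
                         select = TRUE, ...) {
  if (!length(candidates)) {
    candidates <- list()
  }
  if (is.null(names(candidates)) && length(candidates))
    names(candidates) <- vapply(candidates, function(r)
      paste(r$meta$scanner_label, r$meta$recon_label, r$meta$ctdi_vol,
            sep = "_"), "")
  deltas <- lapply(candidates, function(r)
    diff_vs_reference(r$roi_stats, reference$roi_stats))
  red <- vapply(candidates, function(r)
    percent_reduction(reference$meta$ctdi_vol, r$meta$ctdi_vol), 0)
  dose_summary <- list(
    reference_ctdi = reference$meta$ctdi_vol,
    reference_effective_dose = effective_dose(reference$meta$ctdi_vol, params),
    candidate_ctdi = vapply(candidates, function(r) r$meta$ctdi_vol, 0),
    candidate_effective_dose = vapply(candidates, function(r)
      effective_dose(r$meta$ctdi_vol, params), 0),
    percent_reduction = red)
  if (length(red) >= 2) dose_summary$reduction_summary <- summarize_reductions(red)
  sel <- if (select && length(candidates) &&
             !any(vapply(candidates, function(r) is.null(r$mtf_summary), TRUE)))
    select_protocol(candidates, reference, ...) else NULL
  structure(list(reference = reference, candidates = candidates,
                 deltas = deltas, dose_summary = dose_summary,
                 selected = sel$selected, selection = sel),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> reference %.2f mGy, %d candidate(s)\n",
              x$dose_summary$reference_ctdi, length(x$candidates)))
  if (length(x$dose_summary$percent_reduction))
    cat("  reductions vs reference (%):",
        paste(sprintf("%.0f", x$dose_summary$percent_reduction), collapse = ", "),
        "\n")
  if (!is.null(x$selected)) cat("  selected:", x$selected, "\n")
  invisible(x)
}

#' Write report tables as CSV
#'
#' Emits a per-insert statistics table (one row per protocol x insert),
#' a dose table and, when present, the selection audit trail.
#'
#' @param report a [build_report()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- c(list(reference = report$reference), report$candidates)
  stats <- do.call(rbind, lapply(names(recs), function(id) {
    s <- recs[[id]]$roi_stats
    cbind(protocol = id, s)
  }))
  write.csv(stats, file.path(dir, "insert_stats.csv"), row.names = FALSE)
  ds <- report$dose_summary
  dose <- data.frame(protocol = c("reference", names(report$candidates)),
                     ctdi_vol = c(ds$reference_ctdi, ds$candidate_ctdi),
                     effective_dose_msv = c(ds$reference_effective_dose,
                                            ds$candidate_effective_dose),
                     percent_reduction = c(0, ds$percent_reduction))
  write.csv(dose, file.path(dir, "dose.csv"), row.names = FALSE)
  if (!is.null(report$selection))
    write.csv(report$selection$audit, file.path(dir, "selection_audit.csv"),
              row.names = FALSE)
  invisible(dir)
}
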