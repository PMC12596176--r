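#' Per-protocol scalar metadata
#'
#' One scanner / reconstruction / dose combination.  `ctdi_vol` is the
#' scanner-reported volumetric CT dose index (mGy); `scan_length` is the
#' z-axis coverage in cm used for effective-dose arithmetic (30 cm for the
#' standard chest protocol).
#'
#' @param scanner_label,recon_label free-text scanner and reconstruction
#'   identifiers.
#' @param ctdi_vol CTDIvol in mGy (> 0, or `NA` when unknown).
#' @param scan_length scan length in cm.
#' @param kvp,rotation_time,pitch informational acquisition text.
#' @return A `protocol_meta`.
#' @export
protocol_meta <- function(scanner_label = "", recon_label = "",
                          ctdi_vol = NA_real_, scan_length = 30,
                          kvp = "", rotation_time = "", pitch = "") {
  ctdi_vol <- as.numeric(ctdi_vol)
  if (!is.na(ctdi_vol) && ctdi_vol <= 0) stopf("ctdi_vol must be > 0")
  if (!is.finite(scan_length) || scan_length <= 0)
    stopf("scan_length must be > 0")
  structure(list(scanner_label = as.character(scanner_label),
                 recon_label = as.character(recon_label),
                 ctdi_vol = ctdi_vol, scan_length = scan_length,
                 kvp = as.character(kvp),
                 rotation_time = as.character(rotation_time),
                 pitch = as.character(pitch)),
            class = "protocol_meta")
}

#' @export
print.protocol_meta <- function(x, ...) {
  cat(sprintf("<protocol_meta> %s / %s, CTDIvol %s mGy, scan length %g cm\n",
              x$scanner_label, x$recon_label,
              ifelse(is.na(x$ctdi_vol), "?", format(x$ctdi_vol)),
              x$scan_length))
  invisible(x)
}

#' Write / read protocol metadata as a JSON sidecar
#' @param meta a [protocol_meta()].
#' @param path JSON path.
#' @return `write_protocol_meta` returns `path` invisibly;
#'   `read_protocol_meta` returns a [protocol_meta()].
#' @export
write_protocol_meta <- function(meta, path) {
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol_meta
#' @export
read_protocol_meta <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  protocol_meta(x$scanner_label %||% "", x$recon_label %||% "",
                x$ctdi_vol %||% NA_real_, x$scan_length %||% 30,
                x$kvp %||% "", x$rotation_time %||% "", x$pitch %||% "")
}

#' Read a pre-tabulated per-protocol metrics table
#'
#' Ingests a CSV of per-insert HU statistics in long form (columns
#' `protocol, scanner, recon, ctdi_vol, label, mean_hu, sd_hu`), as
#' published harmonization tables are laid out, and returns one data.frame
#' per protocol with CoV recomputed from full precision.
#'
#' @param path CSV path.
#' @return Named list of data.frames (one per protocol) with columns
#'   `label, mean_hu, sd_hu, cov` and attributes `scanner`, `recon`,
#'   `ctdi_vol`.
#' @export
read_metrics_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("protocol", "label", "mean_hu", "sd_hu")
  if (!all(need %in% names(df)))
    stopf("metrics CSV must have columns: %s", paste(need, collapse = ", "))
  out <- list()
  for (p in unique(df$protocol)) {
    sub <- df[df$protocol == p, , drop = FALSE]
    tab <- data.frame(label = sub$label, mean_hu = sub$mean_hu,
                      sd_hu = sub$sd_hu,
                      cov = ifelse(sub$mean_hu != 0,
                                   sub$sd_hu / abs(sub$mean_hu), 0),
                      stringsAsFactors = FALSE)
    attr(tab, "scanner") <- sub$scanner[1] %||% ""
    attr(tab, "recon") <- sub$recon[1] %||% ""
    attr(tab, "ctdi_vol") <- sub$ctdi_vol[1] %||% NA_real_
    out[[p]] <- tab
  }
  out
}
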