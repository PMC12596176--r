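#' Bundled multi-scanner harmonization example data
#'
#' The package ships two small measured datasets from a multi-scanner
#' low-dose harmonization campaign: a per-protocol dose table
#' (`load_protocol_doses()`) covering two standard-dose and ten low-dose
#' protocols, and a full worked harmonization example
#' (`load_example_harmonization()`) comparing four dose/reconstruction
#' candidates on one scanner (SOMATOM Drive) against the low-dose
#' reference protocol, with per-insert HU statistics, MTF cutoffs and
#' lung-sample LAA values.
#'
#' @return `load_protocol_doses()`: data.frame with columns
#'   `protocol, group ("standard"/"low"), scanner, ctdi_vol,
#'   published_effective_dose`.
#' @export
load_protocol_doses <- function() {
  read.csv(system.file("extdata", "protocol_doses.csv", package = "lungqct",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

#' @rdname load_protocol_doses
#' @return `load_example_harmonization()`: list with `reference` (a
#'   [protocol_record()]) and `candidates` (named list of four
#'   [protocol_record()]s).
#' @export
load_example_harmonization <- function() {
  metrics <- read_metrics_csv(system.file("extdata",
                                          "harmonization_metrics.csv",
                                          package = "lungqct", mustWork = TRUE))
  mtf <- read.csv(system.file("extdata", "harmonization_mtf.csv",
                              package = "lungqct", mustWork = TRUE),
                  stringsAsFactors = FALSE)
  laa <- read.csv(system.file("extdata", "harmonization_laa.csv",
                              package = "lungqct", mustWork = TRUE),
                  stringsAsFactors = FALSE)
  mk <- function(p) {
    tab <- metrics[[p]]
    mrow <- mtf[mtf$protocol == p, -1, drop = FALSE]
    protocol_record(
      protocol_meta(scanner_label = attr(tab, "scanner"),
                    recon_label = attr(tab, "recon"),
                    ctdi_vol = attr(tab, "ctdi_vol")),
      roi_stats = tab,
      laa = laa[laa$protocol == p, -1, drop = FALSE],
      mtf_summary = as.list(mrow))
  }
  ids <- setdiff(names(metrics), "force_ref")
  list(reference = mk("force_ref"),
       candidates = stats::setNames(lapply(ids, mk), ids))
}
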