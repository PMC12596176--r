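## shared fixtures: desk-scale phantom grids and analytic references

## coarse full-phantom grid (fast); z extent depends on configuration
phantom_fixture <- function(config = "iv", seed = 1L, ctdi = 2.22,
                            noise_sd_ref = 15, psf = c(0.5, 0.54),
                            spacing = c(1.5, 1.5, 2.0)) {
  nz <- if (config == "iv") 88L else 72L
  lay <- build_layout(config)
  rt <- rasterize(lay, spacing, c(300L, 160L, nz))
  acq <- acquisition_model(ctdi, noise_sd_at_reference = noise_sd_ref,
                           psf_sigma_inplane = psf[1], psf_sigma_z = psf[2],
                           seed = seed)
  list(layout = lay, truth = rt$volume, labels = rt$labels,
       scan = simulate_scan(rt$volume, acq), acq = acq)
}

## closed-form Gaussian MTF cutoffs, in cycles/cm
gauss_cutoff <- function(sigma_mm, level) {
  10 * sqrt(log(1 / level) / (2 * pi^2 * sigma_mm^2))
}

## brute-force two-pass mean/SD oracle
brute_stats <- function(v) {
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  c(mean = m, sd = s)
}

## independent re-statement of the two-stage selection rule, written as a
## plain enumeration over candidates (oracle for select_protocol)
oracle_select <- function(tab, hu_tie_tol = 5, mtf_tie_tol = 0.1) {
  tab <- tab[order(tab$id), ]
  best <- min(tab$dhu)
  tied <- tab$dhu <= best + hu_tie_tol
  hu_winner <- tab$id[which.min(tab$dhu)]
  mtf_ok <- tab$mtf[tab$id == hu_winner] >= max(tab$mtf) - mtf_tie_tol
  if (sum(tied) == 1 && mtf_ok) return(hu_winner)
  pool <- tab[tied, ]
  pool$id[order(pool$sd_sum, pool$id)][1]
}

## wrap a plain metric table into a protocol_record
make_record <- function(id, ctdi, means, sds, mtf = NULL,
                        labels = c("air", "water_vial_1", "water_vial_2")) {
  protocol_record(
    protocol_meta(scanner_label = id, ctdi_vol = ctdi),
    roi_stats = data.frame(label = labels, mean_hu = means, sd_hu = sds,
                           stringsAsFactors = FALSE),
    mtf_summary = mtf)
}
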