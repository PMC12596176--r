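test_that("effective dose is the CTDIvol x length x k product", {
  expect_equal(effective_dose(2.22), 1.7982)
  expect_identical(format_msv(2.22), "1.80")
  expect_identical(format_msv(3.43), "2.78")
  expect_equal(effective_dose(0), 0)
  ## linearity
  x <- c(0.5, 1.7, 4.1)
  expect_equal(effective_dose(3 * x), 3 * effective_dose(x))
  expect_error(effective_dose(-1), ">= 0")
})

test_that("published dose rows are reproduced after display rounding", {
  d <- load_protocol_doses()
  computed <- round_half_up(effective_dose(d$ctdi_vol), 2)
  match_row <- abs(computed - d$published_effective_dose) < 1e-9
  ## two rows are known rounding anomalies in the published table
  expect_gte(sum(match_row), 10)
  anomalies <- d$protocol[!match_row]
  expect_setequal(anomalies,
                  c("definition_asplus_standard", "brilliance_ict"))
  ## the anomalous rows differ by exactly one display unit
  expect_true(all(abs(computed[!match_row] -
                      d$published_effective_dose[!match_row]) <= 0.011))
})

test_that("percent reductions behave and summarize correctly", {
  expect_equal(percent_reduction(7.32, 2.22), 69.67, tolerance = 1e-3)
  expect_identical(round_half_up(percent_reduction(7.32, 2.22)), 70)
  expect_equal(percent_reduction(7.32, 4.23), 42.21, tolerance = 1e-2)
  expect_equal(percent_reduction(5, 5), 0)
  expect_error(percent_reduction(0, 1), "> 0")

  expect_equal(summarize_reductions(c(69.7, 42.2))$mean, 55.95)
  s0 <- summarize_reductions(c(3, 3, 3))
  expect_equal(s0$sd, 0)
  expect_error(summarize_reductions(50), "at least 2")
})

test_that("selection reproduces the published worked example", {
  ex <- load_example_harmonization()
  sel <- select_protocol(ex$candidates, ex$reference)
  expect_identical(sel$selected, "drive_admire5_3.43")
  expect_identical(sel$stage, "sd_tiebreak")
  ## audit trail records every candidate's scores
  expect_setequal(sel$audit$id, names(ex$candidates))
  expect_equal(sel$audit$dhu[sel$audit$id == "drive_admire5_3.43"], 22.8,
               tolerance = 1e-9)
  expect_equal(sel$audit$sd_sum[sel$audit$id == "drive_admire5_3.43"], 58.7,
               tolerance = 1e-9)

  ## single candidate selects trivially
  one <- select_protocol(ex$candidates[1], ex$reference)
  expect_identical(one$selected, names(ex$candidates)[1])

  ## permuting candidates never changes the selection
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    again <- select_protocol(ex$candidates[perm], ex$reference)
    expect_identical(again$selected, sel$selected)
  }

  nofield <- ex$candidates
  nofield[[1]]$roi_stats <- nofield[[1]]$roi_stats[-1, ]
  expect_error(select_protocol(nofield, ex$reference), "primary labels")
})

test_that("selection equals exhaustive enumeration on random tables", {
  set.seed(51)
  for (trial in 1:40) {
    n <- sample(2:6, 1)
    ref <- make_record("ref", 7.32, c(-1000, 0, 0), c(15, 25, 25))
    cands <- list()
    tab <- NULL
    for (i in seq_len(n)) {
      means <- c(-1000, 0, 0) + rnorm(3, 0, 8)
      sds <- c(15, 25, 25) * runif(3, 0.6, 1.6)
      mtf <- runif(1, 3, 4.5)
      id <- sprintf("cand_%02d", i)
      cands[[id]] <- make_record(id, runif(1, 2, 5), means, sds,
                                 mtf = list(in_plane_f50 = mtf))
      tab <- rbind(tab, data.frame(
        id = id,
        dhu = sum(abs(means - c(-1000, 0, 0))),
        mtf = mtf, sd_sum = sum(sds)))
    }
    got <- select_protocol(cands, ref)$selected
    expect_identical(got, oracle_select(tab))
  }
})

test_that("comparison reports assemble deltas, doses and the selection", {
  ex <- load_example_harmonization()
  rep0 <- build_report(ex$reference, ex$candidates["drive_admire5_3.43"],
                       select = FALSE)
  expect_equal(rep0$dose_summary$percent_reduction[[1]],
               percent_reduction(2.22, 3.43))

  ## reference against itself: zero deltas, zero reduction
  self <- build_report(ex$reference, list(self = ex$reference))
  expect_true(all(self$deltas$self$delta_mean_hu == 0))
  expect_equal(unname(self$dose_summary$percent_reduction), 0)

  full <- build_report(ex$reference, ex$candidates)
  expect_identical(full$selected, "drive_admire5_3.43")
  ## dose summary is self-consistent with its own CTDIvol list
  ds <- full$dose_summary
  expect_equal(unname(ds$percent_reduction),
               100 * (ds$reference_ctdi - unname(ds$candidate_ctdi)) /
                 ds$reference_ctdi)
  expect_equal(unname(ds$candidate_effective_dose),
               unname(ds$candidate_ctdi) * 30 * 0.027)

  out <- write_report_csv(full, file.path(tempdir(), "rep"))
  expect_true(file.exists(file.path(out, "insert_stats.csv")))
  expect_true(file.exists(file.path(out, "dose.csv")))
  expect_true(file.exists(file.path(out, "selection_audit.csv")))
})
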