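fake_barcode <- function(sample_id, nonN, flags = character(0)) {
  seq <- if (nonN > 0) paste(rep("A", nonN), collapse = "") else ""
  structure(list(sample_id = sample_id, sequence = seq,
                 nonN_length = as.integer(nonN),
                 span = c(0L, as.integer(nonN)),
                 coverage = integer(0), flags = flags),
            class = "consensus_barcode")
}

test_that("success rates reproduce printed percentages from their counts", {
  s <- success_rates(941, 506, 489)
  expect_equal(s$pct_recovered, 53.8)
  expect_equal(s$pct_acceptable, 52.0)

  s2 <- success_rates(941, 867, 824, n_genera = 819,
                      n_genera_acceptable = 727)
  expect_equal(s2$pct_recovered, 92.1)
  expect_equal(s2$pct_acceptable, 87.6)
  expect_equal(s2$pct_genera, 88.8)

  zero <- success_rates(10, 0, 0)
  expect_equal(zero$pct_recovered, 0)
  expect_error(success_rates(10, 5, 6), "n_acceptable")
  expect_error(success_rates(10, 11, 5), "n_recovered")
})

test_that("rounding is half-up to one decimal", {
  expect_equal(round_half_up(53.75, 1), 53.8)
  expect_equal(round_half_up(52.05, 1), 52.1)
  expect_equal(round_half_up(87.64, 1), 87.6)
  expect_equal(round_half_up(-1.25, 1), -1.3)
})

test_that("success summary counts recovery, compliance and genus success", {
  ids <- format_sample_id("CCDB-31120", all_wells()[1:6, ])
  rec <- specimen_record(
    ids,
    taxonomy = data.frame(phylum = "Arthropoda", class = "Insecta",
                          order = "Diptera", family = "F",
                          genus = c("G1", "G1", "G2", "G3", "G3", "G4"),
                          species = paste0("G sp", 1:6)),
    collection_year = 2000L)
  barcodes <- list(
    fake_barcode(ids[1], 658),            # acceptable
    fake_barcode(ids[2], 0, "no_reads"),  # nothing
    fake_barcode(ids[3], 120, "short"),   # recovered, not acceptable
    fake_barcode(ids[4], 301),            # acceptable (just over 300)
    fake_barcode(ids[5], 300),            # exactly 300: NOT acceptable
    fake_barcode(ids[6], 500, "contaminated"))
  s <- success_summary(barcodes, rec)
  expect_equal(s$n_total, 6L)
  expect_equal(s$n_recovered, 5L)
  expect_equal(s$n_acceptable, 3L)
  expect_equal(s$n_flagged, 1L)
  expect_equal(s$n_genera, 4L)
  expect_equal(s$n_genera_acceptable, 3L)  # G1 (via ids[1]), G3, G4
  expect_error(success_summary(barcodes[c(1, 1)], rec[1:2, ]), "duplicate")
})

test_that("failure tracking combines disjoint passes with consistent totals", {
  first <- success_rates(941, 506, 489, n_flagged = 17)
  rerun <- success_rates(418, 366, 335, n_flagged = 16)
  ft <- failure_tracking_summary(first, rerun)
  expect_equal(ft$pct_rerun_recovered, 87.6)
  expect_equal(ft$combined$n_recovered, 506L + 366L)
  expect_equal(ft$combined$n_acceptable, 489L + 335L)
  expect_equal(ft$combined$n_flagged, 33L)

  # rerun on zero specimens leaves the first pass unchanged
  ft0 <- failure_tracking_summary(first, success_rates(0, 0, 0))
  expect_equal(ft0$combined$n_recovered, first$n_recovered)
  expect_equal(ft0$combined$pct_recovered, first$pct_recovered)

  # the rerun may only contain first-pass failures
  expect_error(failure_tracking_summary(first, success_rates(500, 100, 50)),
               "exceeds")

  ft2 <- set_combined_genus_success(ft, 819, 727)
  expect_equal(ft2$combined$pct_genera, 88.8)

  # overlapping recovered sets are impossible by construction: the rerun
  # can never report more recoveries than specimens it re-attempted
  expect_error(success_rates(418, 430, 100), "n_recovered")
})

test_that("age-length regression matches the normal-equations oracle", {
  ids <- format_sample_id("CCDB-31120", all_wells()[1:10, ])
  years <- c(1920L, 1935L, 1950L, 1961L, 1972L, 1980L, 1991L, 2000L,
             2008L, 2016L)
  lens <- c(102L, 160L, 240L, 300L, 361L, 415L, 470L, 520L, 570L, 640L)
  rec <- specimen_record(ids, collection_year = years)
  barcodes <- Map(fake_barcode, ids, lens)
  r <- age_length_regression(rec, barcodes, analysis_year = 2017)

  # independent oracle: closed-form normal equations
  age <- 2017 - years
  n <- length(age)
  sxx <- sum((age - mean(age))^2)
  sxy <- sum((age - mean(age)) * (lens - mean(lens)))
  slope <- sxy / sxx
  intercept <- mean(lens) - slope * mean(age)
  fitted <- intercept + slope * age
  ss_res <- sum((lens - fitted)^2)
  ss_tot <- sum((lens - mean(lens))^2)
  r2 <- 1 - ss_res / ss_tot
  se <- sqrt(ss_res / (n - 2) / sxx)
  p <- 2 * pt(abs(slope / se), df = n - 2, lower.tail = FALSE)

  expect_equal(r$slope, slope, tolerance = 1e-9)
  expect_equal(r$intercept, intercept, tolerance = 1e-9)
  expect_equal(r$r_squared, r2, tolerance = 1e-9)
  expect_equal(r$p_value, p, tolerance = 1e-9)

  # colinear points: R^2 exactly 1; constant lengths: R^2 0
  lin <- Map(fake_barcode, ids, 600 - 2 * age)
  expect_equal(age_length_regression(rec, lin, analysis_year = 2017)$r_squared,
               1)
  const <- Map(fake_barcode, ids, rep(400L, 10))
  rc <- age_length_regression(rec, const, analysis_year = 2017)
  expect_equal(rc$r_squared, 0)

  # flagged records are excluded on request
  flagged <- barcodes
  flagged[[1]] <- fake_barcode(ids[1], lens[1], flags = "contaminated")
  r_excl <- age_length_regression(rec, flagged, exclude_flagged = TRUE,
                                  analysis_year = 2017)
  expect_equal(r_excl$n, 9L)

  expect_error(age_length_regression(rec[1:2, ], barcodes[1:2],
                                     analysis_year = 2017), "at least 3")
})

test_that("assignment report totals are sums of their cells", {
  m <- matrix(c(1263L, 1333L, 2403L, 0L), nrow = 2,
              dimnames = list(c("bin_match", "id_engine"),
                              c("genus", "species")))
  rep <- assignment_report(m)
  expect_equal(rep["bin_match", "total"], 3666L)
  expect_equal(rep["total", "total"], 4999L)
  expect_equal(rep["total", "genus"], 2596L)

  zero <- assignment_report(matrix(0L, 2, 2,
                                   dimnames = dimnames(m)))
  expect_true(all(zero == 0L))

  f <- tempfile(fileext = ".tsv")
  write_assignment_report(rep, f)
  expect_equal(nrow(read.delim(f)), 3)
})
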