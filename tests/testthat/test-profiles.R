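test_that("profile summaries compute totals, percentages and sulfation", {
  p <- tibble::tibble(region = "r1", analyte = c("D0a0", "D0a4"),
                      amount = c(3, 1))
  s <- summarize_profiles(p)
  expect_equal(s$total_pmol, 4)
  expect_equal(s$avg_sulfation, 0.25)
  rel <- relative_abundance(p)
  expect_equal(sort(rel$rel_pct), c(25, 75))

  tri <- tibble::tibble(region = "r1", analyte = "D2S6", amount = 5)
  expect_equal(summarize_profiles(tri)$avg_sulfation, 3)
})

test_that("zero-total profiles yield undefined statistics with a warning", {
  p0 <- tibble::tibble(region = "r1", analyte = c("D0a0", "D0a4"),
                       amount = c(0, 0))
  expect_warning(s <- summarize_profiles(p0), "zero total")
  expect_equal(s$total_pmol, 0)
  expect_true(is.na(s$avg_sulfation))
  expect_warning(r <- relative_abundance(p0), "undefined")
  expect_true(all(is.na(r$rel_pct)))
  neg <- tibble::tibble(region = "r1", analyte = "D0a0", amount = -1)
  expect_error(summarize_profiles(neg), "non-negative")
})

test_that("6S/4S ratio follows its definition and guards", {
  mk <- function(a6, a4) tibble::tibble(analyte = c("D0a6", "D0a4"),
                                        amount = c(a6, a4))
  expect_equal(ratio_6s4s(mk(2, 1)), 2)
  expect_equal(ratio_6s4s(mk(1, 1)), 1)
  expect_warning(r <- ratio_6s4s(mk(1, 0)), "D0a4")
  expect_true(is.na(r))
  hs <- tibble::tibble(analyte = "D0A0", amount = 1)
  expect_error(ratio_6s4s(hs), "CS")
})

test_that("N/O ratios follow the sulfate-group counting convention", {
  mono <- tibble::tibble(analyte = c("D0S0", "D2A0+D0A6"), amount = c(1, 2))
  expect_equal(no_ratios(mono, warn = FALSE)$no_mono, 0.5)

  di <- tibble::tibble(analyte = "D2S0+D0S6", amount = 3)
  expect_equal(no_ratios(di, warn = FALSE)$no_di, 1)

  tri <- tibble::tibble(analyte = "D2S6", amount = 1)
  expect_equal(no_ratios(tri, warn = FALSE)$no_total, 0.5)

  full <- tibble::tibble(
    analyte = c("D0S0", "D2A0+D0A6", "D2S0+D0S6", "D2A6", "D2S6", "D0A0"),
    amount = c(1, 1, 1, 1, 1, 5))
  expect_equal(no_ratios(full, warn = FALSE)$no_total, 0.5)

  cs <- tibble::tibble(analyte = "D0a0", amount = 1)
  expect_error(no_ratios(cs), "HS")
  # zero denominators are undefined, not zero or infinite
  only_n <- tibble::tibble(analyte = "D0S0", amount = 1)
  w <- testthat::capture_warnings(r <- no_ratios(only_n))
  expect_true(all(grepl("undefined", w)) && length(w) == 3)
  expect_true(is.na(r$no_mono) && is.na(r$no_total))
})

test_that("profile metrics satisfy conservation, bounds, scale invariance
           and the brute-force N/O oracle", {
  set.seed(42)
  for (k in 1:200) {
    cls <- if (k %% 2 == 0) "CS" else "HS"
    p <- random_profile(cls)
    if (sum(p$amount) == 0) next
    rel <- relative_abundance(p)
    expect_equal(sum(rel$rel_pct), 100, tolerance = 1e-12)
    s <- suppressWarnings(summarize_profiles(p))
    expect_true(s$avg_sulfation >= 0 && s$avg_sulfation <= 3)
    # scaling by c > 0 changes only the total
    c0 <- stats::runif(1, 0.1, 10)
    p2 <- dplyr::mutate(p, amount = amount * c0)
    s2 <- suppressWarnings(summarize_profiles(p2))
    expect_equal(s2$total_pmol, c0 * s$total_pmol)
    expect_equal(s2$avg_sulfation, s$avg_sulfation)
    expect_equal(s2$ratio_6s4s, s$ratio_6s4s)
    expect_equal(s2$no_total, s$no_total)
    if (cls == "HS") {
      expect_equal(s$no_total, oracle_no_total(p$analyte, p$amount))
    }
  }
  # avg_sulfation is 0 iff only non-sulfated analytes carry amount
  ns <- tibble::tibble(region = "r", analyte = c("D0a0", "D0a4"),
                       amount = c(2, 0))
  expect_equal(suppressWarnings(summarize_profiles(ns))$avg_sulfation, 0)
})

test_that("area calibration divides by response factors and guards zeros", {
  areas <- tibble::tibble(analyte = c("D0a0", "D0a4"), area = c(1000, 0))
  rf <- tibble::tibble(analyte = c("D0a0", "D0a4"),
                       response_factor = c(100, 50))
  out <- calibrate_areas(areas, rf)
  expect_equal(out$amount, c(10, 0))
  expect_message(out1 <- calibrate_areas(areas), "response-factor")
  expect_equal(out1$amount, areas$area)
  bad_rf <- tibble::tibble(analyte = "D0a0", response_factor = 100)
  areas2 <- tibble::tibble(analyte = c("D0a0", "D0a4"), area = c(5, 5))
  expect_error(calibrate_areas(areas2, bad_rf), "D0a4")
})
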