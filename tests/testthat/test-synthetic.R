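test_that("generator is deterministic under a fixed seed and validates
           its configuration", {
  cfg <- synthetic_config(seed = 5)
  m1 <- generate_metadata(cfg)
  m2 <- generate_metadata(cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 22)
  expect_equal(dplyr::n_distinct(m1$patient), 7)
  expect_true(all(is.na(m1$mucin[m1$morphology == "normal"])))
  expect_true(all(is.na(m1$stroma[m1$morphology == "normal"])))
  sc <- c(m1$mucin, m1$stroma)
  expect_true(all(sc[!is.na(sc)] %in% 1:3))

  g1 <- generate_gag_dataset(cfg, m1)
  g2 <- generate_gag_dataset(cfg, m1)
  expect_identical(g1, g2)
  p1 <- generate_protein_dataset(cfg, m1)
  expect_identical(p1, generate_protein_dataset(cfg, m1))
  # a different seed changes values but not the truth structure
  cfg2 <- synthetic_config(seed = 6)
  g3 <- generate_gag_dataset(cfg2, m1)
  expect_identical(g1$truth$expected, g3$truth$expected)
  expect_false(identical(g1$amounts$amount, g3$amounts$amount))

  empty <- generate_metadata(synthetic_config(n_patients = 0))
  expect_equal(nrow(empty), 0)

  expect_error(synthetic_config(morphology_probs = c(normal = 0.5,
                                                     solid = 0.2,
                                                     tubular = 0.1,
                                                     papillary = 0.1)),
               "sum to 1")
  expect_error(synthetic_config(de_fraction = 1.5), "de_fraction")
  bad_base <- list(CS = c(D0a0 = 0.5), HS = c(D0A0 = 1))
  expect_error(synthetic_config(gag_baseline = bad_base), "sum to 1")
})

test_that("noise-free GAG profiles reproduce the planted group
           composition exactly", {
  cfg <- synthetic_config(seed = 2, noise_cv = 0)
  meta <- two_group_metadata(2, 2)
  sim <- generate_gag_dataset(cfg, meta)
  s <- summarize_profiles(sim$amounts)
  truth <- sim$truth$expected |>
    dplyr::rename(analyte_amount = "expected_amount")
  for (cls in c("CS", "HS")) {
    for (grp in c("normal", "solid")) {
      te <- truth[truth$gag_class == cls & truth$group == grp, ]
      planted <- sum(te$analyte_amount / sum(te$analyte_amount) *
                       analyte_info(te$analyte)$total_sulfates)
      rg <- meta$region[meta$morphology == grp][1]
      got <- s$avg_sulfation[s$region == rg & s$gag_class == cls]
      expect_equal(got, planted, tolerance = 1e-12)
    }
  }
})

test_that("planted total-amount multipliers are recovered from simulated
           cohorts", {
  meta <- two_group_metadata(5, 5, group_b = "papillary")
  ratios <- vapply(1:50, function(i) {
    cfg <- synthetic_config(seed = 1000 + i)
    sim <- generate_gag_dataset(cfg, meta)
    s <- summarize_profiles(sim$amounts)
    s <- dplyr::left_join(s, meta[, c("region", "morphology")],
                          by = "region")
    cs <- s[s$gag_class == "CS", ]
    mean(cs$total_pmol[cs$morphology == "papillary"]) /
      mean(cs$total_pmol[cs$morphology == "normal"])
  }, numeric(1))
  planted <- synthetic_config()$total_multiplier$CS[["papillary"]]
  expect_lt(abs(mean(ratios) - planted) / planted, 0.15)
})

test_that("a zero N-to-O shift leaves N/O ratios unshifted between groups", {
  cfg <- synthetic_config(seed = 7, n_penalty = 1, sulfated_boost = c(CS = 1, HS = 1),
                          shift_6s4s = c(normal = 1, solid = 1,
                                         tubular = 1, papillary = 1))
  meta <- two_group_metadata(10, 10)
  sim <- generate_gag_dataset(cfg, meta)
  s <- summarize_profiles(sim$amounts) |>
    dplyr::left_join(meta[, c("region", "morphology")], by = "region")
  hs <- s[s$gag_class == "HS", ]
  p <- exact_rank_p(hs$no_total[hs$morphology == "normal"],
                    hs$no_total[hs$morphology == "solid"])
  expect_gt(p, 0.05)
})

test_that("planted fold changes are detected and estimated from the
           protein matrix", {
  cfg <- synthetic_config(seed = 17, n_proteins = 100, de_fraction = 0.3,
                          de_fc_range = c(2, 4))
  meta <- two_group_metadata(10, 10)
  sim <- generate_protein_dataset(cfg, meta)
  grouping <- derive_groups(meta, "morphology")
  filt <- filter_quantified(sim$matrix, grouping)
  res <- compare_groups(filt, grouping, "normal", "solid")
  joined <- dplyr::inner_join(res, sim$truth, by = "feature")
  # estimated fold changes track the planted ones
  de <- joined[joined$is_de, ]
  expect_gte(stats::cor(de$fold_change.x, de$fold_change.y,
                        method = "spearman"), 0.9)
  # missingness off: the filter removes nothing
  cfg0 <- synthetic_config(seed = 18, missing_mcar = 0, censor_quantile = 0)
  sim0 <- generate_protein_dataset(cfg0, meta)
  expect_false(anyNA(sim0$matrix))
  expect_equal(nrow(filter_quantified(sim0$matrix, grouping)),
               cfg0$n_proteins)
})
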