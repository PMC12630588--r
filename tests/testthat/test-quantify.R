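test_that("accessibility is the in-vivo-label share of the pair", {
  expect_equal(measurementAccessibility(1000, 0, "forward"), 100)
  expect_equal(measurementAccessibility(500, 500, "forward"), 50)
  expect_equal(measurementAccessibility(618, 382, "forward"), 61.8)
  expect_equal(measurementAccessibility(382, 618, "swap"), 61.8)
  expect_error(measurementAccessibility(-1, 10, "forward"), "non-negative")
  expect_error(measurementAccessibility(0, 0, "forward"))
})

test_that("complementarity, scale invariance and clipping hold on random areas", {
  set.seed(7)
  light <- rlnorm(500, 10, 2)
  heavy <- rlnorm(500, 10, 2)
  fwd <- measurementAccessibility(light, heavy, "forward")
  swp <- measurementAccessibility(light, heavy, "swap")
  expect_equal(fwd + swp, rep(100, 500))
  for (c in c(1e-6, 0.5, 3, 1e8)) {
    expect_equal(measurementAccessibility(c * light, c * heavy, "forward"),
                 fwd)
  }
  expect_true(all(fwd >= 0 & fwd <= 100))
})

test_that("QC filters use inclusive thresholds and report the first failing rule", {
  df <- makeMeasurementDf(6)
  df$determinant_factor <- c(0.9, 0.4, 0.5, 0.9, 0.3, 0.9)
  df$profile_score <- c(0.9, 0.9, 0.5, 0.49, 0.3, 0.9)
  df$rt_shift <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  res <- applyQCFilters(CPPMeasurements(df, "forward"))
  # 0.5 is retained (inclusive); 0.4 rejected; first failing rule reported
  expect_equal(nrow(measurements(res$retained)), 2)
  expect_equal(res$rejected$reason,
               c("determinant_factor", "profile_score",
                 "determinant_factor", "rt_shift"))
  # retained + rejected = input
  expect_equal(nrow(measurements(res$retained)) + nrow(res$rejected),
               nrow(df))
  # rt shift can be allowed by configuration
  res2 <- applyQCFilters(CPPMeasurements(df, "forward"),
                         FilterConfig(allowRtShift = TRUE))
  expect_equal(nrow(measurements(res2$retained)), 3)
})

test_that("missing QC values pass by default and reject in strict mode", {
  df <- makeMeasurementDf(2)
  df$determinant_factor <- c(NA, 0.9)
  expect_warning(
    res <- applyQCFilters(CPPMeasurements(df, "forward")),
    "missing QC")
  expect_equal(nrow(measurements(res$retained)), 2)
  res_strict <- applyQCFilters(CPPMeasurements(df, "forward"),
                               FilterConfig(treatMissingQC = FALSE))
  expect_equal(res_strict$rejected$reason, "missing_qc")
})

test_that("site aggregation reports mean, sem and counts over pooled measurements", {
  df <- makeMeasurementDf(3, replicate = c("r1", "r1", "r2"),
                          light = c(60, 62, 64), heavy = c(40, 38, 36))
  sites <- aggregateSites(CPPMeasurements(df, "forward"))
  expect_equal(sites$mean_accessibility, 62)
  expect_equal(sites$sem, sd(c(60, 62, 64)) / sqrt(3), tolerance = 1e-12)
  expect_equal(round(sites$sem, 4), 1.1547)
  expect_equal(sites$n_measurements, 3)
  expect_equal(sites$n_replicates, 2)
  expect_false(sites$single_measurement)
})

test_that("single and constant measurement groups get sem zero", {
  one <- makeMeasurementDf(1, light = 987, heavy = 13)
  s1 <- aggregateSites(CPPMeasurements(one, "forward"))
  expect_equal(s1$mean_accessibility, 98.7)
  expect_equal(s1$sem, 0)
  expect_true(s1$single_measurement)
  same <- makeMeasurementDf(4, light = 50, heavy = 50)
  s2 <- aggregateSites(CPPMeasurements(same, "forward"))
  expect_equal(s2$mean_accessibility, 50)
  expect_equal(s2$sem, 0)
})

test_that("aggregation stays within the measurement range and supports replicate mode", {
  set.seed(3)
  df <- makeMeasurementDf(12, replicate = rep(c("r1", "r2", "r3"), 4),
                          light = runif(12, 100, 900),
                          heavy = runif(12, 100, 900))
  x <- CPPMeasurements(df, "forward")
  acc <- measurementAccessibility(df$light_area, df$heavy_area, "forward")
  pooled <- aggregateSites(x)
  expect_gte(pooled$mean_accessibility, min(acc))
  expect_lte(pooled$mean_accessibility, max(acc))
  byrep <- aggregateSites(x, mode = "replicate")
  repmeans <- tapply(acc, df$replicate, mean)
  expect_equal(byrep$mean_accessibility, mean(repmeans))
  expect_equal(byrep$sem, sd(repmeans) / sqrt(3))
})

test_that("label-swap reconciliation classifies concordance and orphans", {
  fwd <- data.frame(protein = "P13569", residue = c(273, 283, 464),
                    label = c("K273", "K283", "K464"), condition = "wt",
                    mean_accessibility = c(61.8, 95.0, 99.7))
  swp <- data.frame(protein = "P13569", residue = c(273, 283, 536),
                    label = c("K273", "K283", "K536"), condition = "wt",
                    mean_accessibility = c(60.0, 60.0, 98.8))
  m <- mergeLabelSwap(fwd, swp, tolerance = 10)
  expect_equal(m$consistency$absolute_difference, c(1.8, 35.0))
  expect_equal(m$consistency$concordant, c(TRUE, FALSE))
  expect_equal(m$forwardOnly$residue, 464)
  expect_equal(m$swapOnly$residue, 536)
})
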