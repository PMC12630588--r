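test_that("identical seeds produce identical experiments", {
  e1 <- generateExperiment(k273Design(42))
  e2 <- generateExperiment(k273Design(42))
  expect_identical(measurements(e1$forward), measurements(e2$forward))
  expect_identical(measurements(e1$swap), measurements(e2$swap))
  e3 <- generateExperiment(k273Design(43))
  expect_false(identical(measurements(e1$forward),
                         measurements(e3$forward)))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generateExperiment(k273Design(42)))
  expect_identical(runif(1), before)
})

test_that("row counts follow the design grid", {
  truth <- expand.grid(protein = "P1", residue = c(10, 20),
                       condition = c("a", "b"), stringsAsFactors = FALSE)
  truth$true_accessibility <- 60
  d <- SyntheticDesign(truth = truth, replicates = c(a = 3L, b = 3L),
                       peptidesPerSite = 2, charges = 2, seed = 7)
  e <- generateExperiment(d)
  # 2 sites x 2 conditions x 3 replicates x 2 peptides x 1 charge
  expect_equal(nrow(measurements(e$forward)), 24)
  expect_equal(nrow(measurements(e$swap)), 24)
})

test_that("degenerate truths of 0 and 100 give point-mass areas", {
  d <- SyntheticDesign(
    truth = data.frame(protein = "P1", residue = c(10, 20), condition = "a",
                       true_accessibility = c(100, 0)),
    replicates = c(a = 3L), qcFailFraction = 0, seed = 5)
  m <- measurements(generateExperiment(d)$forward)
  expect_true(all(m$heavy_area[m$residue == 10] == 0))
  expect_true(all(m$light_area[m$residue == 20] == 0))
  expect_true(all(is.finite(m$light_area + m$heavy_area)))
})

test_that("paired swap tables are exactly complementary to the forward run", {
  d <- k273Design(12)
  e <- generateExperiment(d)
  fwd <- measurements(e$forward)
  swp <- measurements(e$swap)
  key <- function(m) paste(m$residue, m$condition, m$replicate, m$peptide,
                           m$charge)
  i <- match(key(fwd), key(swp))
  ok <- !is.na(i)
  x_fwd <- measurementAccessibility(fwd$light_area, fwd$heavy_area,
                                    "forward")
  raw_light_share <- 100 * swp$light_area[i[ok]] /
    (swp$light_area[i[ok]] + swp$heavy_area[i[ok]])
  expect_equal(x_fwd[ok] + raw_light_share, rep(100, sum(ok)))
  # read with swap orientation, the same accessibility is recovered
  x_swp <- measurementAccessibility(swp$light_area[i[ok]],
                                    swp$heavy_area[i[ok]], "swap")
  expect_equal(x_swp, x_fwd[ok])
})

test_that("swap runs can use fewer replicates, as in label-swap designs", {
  d <- k273Design(3, swapReplicates = c(wt = 2L, dF508 = 2L))
  e <- generateExperiment(d)
  expect_equal(sort(unique(measurements(e$swap)$replicate)),
               c("rep1", "rep2"))
  expect_equal(sort(unique(measurements(e$forward)$replicate)),
               paste0("rep", 1:4))
})

test_that("empirical accessibility converges to the truth (law of large numbers)", {
  d <- SyntheticDesign(
    truth = data.frame(protein = "P1", residue = 10, condition = "a",
                       true_accessibility = 60),
    replicates = c(a = 1000L), peptidesPerSite = 1, charges = 2,
    qcFailFraction = 0, seed = 77)
  m <- measurements(generateExperiment(d)$forward)
  acc <- measurementAccessibility(m$light_area, m$heavy_area, "forward")
  expect_equal(length(acc), 1000)
  expect_lt(abs(mean(acc) - 60), 0.5)
  # Beta precision kappa = 200 implies ~3.5 pp spread at 60%
  expect_lt(abs(sd(acc) - sqrt(0.6 * 0.4 / 201) * 100), 0.5)
})

test_that("injected QC failures occur at the configured rate and kinds", {
  d <- SyntheticDesign(
    truth = data.frame(protein = "P1", residue = 10, condition = "a",
                       true_accessibility = 60),
    replicates = c(a = 500L), peptidesPerSite = 1, charges = 2,
    qcFailFraction = 0.2, seed = 9)
  m <- measurements(generateExperiment(d)$forward)
  res <- applyQCFilters(CPPMeasurements(m, "forward"))
  frac <- nrow(res$rejected) / nrow(m)
  expect_gt(frac, 0.13)
  expect_lt(frac, 0.27)
  expect_true(all(res$rejected$reason %in%
                    c("determinant_factor", "profile_score", "rt_shift")))
  # and a zero fraction injects none
  d0 <- k273Design(9, qcFailFraction = 0)
  m0 <- measurements(generateExperiment(d0)$forward)
  expect_equal(nrow(applyQCFilters(CPPMeasurements(m0, "forward"))$rejected),
               0)
})

test_that("the recovery report computes per-site bias and flags orphans", {
  d <- k273Design(15, qcFailFraction = 0)
  e <- generateExperiment(d)
  sites <- aggregateSites(e$forward)
  rec <- recoveryReport(e$truth, sites)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$bias, rec$estimate - rec$true_accessibility)
  expect_true(all(abs(rec$bias) < 5))
  bogus <- sites
  bogus$residue <- 999
  expect_error(recoveryReport(e$truth, bogus), "absent from truth")
})

test_that("a noise-free limit yields zero bias", {
  d <- SyntheticDesign(
    truth = data.frame(protein = "P1", residue = 10,
                       condition = c("a", "b"),
                       true_accessibility = c(0, 100)),
    replicates = c(a = 3L, b = 3L), qcFailFraction = 0, seed = 2)
  e <- generateExperiment(d)
  rec <- recoveryReport(e$truth, aggregateSites(e$forward))
  expect_equal(rec$bias, c(0, 0))
})
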