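test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  # groups {1,2} vs {3,4}: SSB = 4, SSW = 1, df = (1, 2) -> F = 8
  a <- siteAnova(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
  expect_equal(a$F, 8)
  expect_equal(a$p, 0.1055728, tolerance = 1e-6)
  expect_equal(c(a$df1, a$df2), c(1, 2))
  # identical groups -> F = 0, p = 1
  b <- siteAnova(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3))
  expect_equal(b$F, 0)
  expect_equal(b$p, 1)
  # agreement with the classical equal-variance oneway.test oracle
  set.seed(21)
  vals <- rnorm(30); grp <- rep(c("a", "b", "c"), 10)
  ours <- siteAnova(vals, grp)
  ref <- oneway.test(vals ~ grp, var.equal = TRUE)
  expect_equal(ours$F, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("underpowered and degenerate sites are handled explicitly", {
  expect_equal(siteAnova(c(1, 2, 3), c("a", "a", "a"))$status, "skipped")
  expect_equal(siteAnova(c(1, 2, 3), c("a", "a", "b"))$status, "skipped")
  expect_equal(siteAnova(rep(5, 6), rep(c("a", "b"), 3))$status, "skipped")
  d <- siteAnova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_equal(d$status, "degenerate")
  expect_equal(d$F, Inf)
  expect_gt(d$p, 0)
})

test_that("ANOVA F is invariant to shift and positive scaling", {
  set.seed(5)
  vals <- runif(24, 40, 90); grp <- rep(c("a", "b", "c"), each = 8)
  f0 <- siteAnova(vals, grp)$F
  expect_equal(siteAnova(vals + 17, grp)$F, f0, tolerance = 1e-9)
  expect_equal(siteAnova(vals * 3.7, grp)$F, f0, tolerance = 1e-9)
})

test_that("BH step-up matches the textbook example and the p.adjust oracle", {
  expect_equal(adjustPValues(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(adjustPValues(0.042, "BH"), 0.042)  # m = 1
  set.seed(101)
  for (i in 1:1000) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    p <- pmin(pmax(p, 1e-300), 1)
    expect_equal(adjustPValues(p, "BH"), p.adjust(p, "BH"),
                 tolerance = 1e-12)
  }
  expect_identical(adjustPValues(numeric(0), "BH"), numeric(0))
  expect_error(adjustPValues(c(0.2, 0), "BH"), "\\(0, 1\\]")
  expect_error(adjustPValues(c(0.2, 1.4), "BH"), "\\(0, 1\\]")
})

test_that("two-stage BKY q-values match an independent reference vector", {
  # reference computed with the two-stage sharpened step-up at alpha = 0.05
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
         0.216, 0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569,
         0.594, 0.696, 0.762, 0.94, 0.942, 0.975, 0.986)
  expected <- c(0.0252, 0.1008, 0.21168, 0.21168, 0.21168, 0.252, 0.2664,
                0.495, 0.495, 0.495, 0.495, 0.495, 0.495, 0.495, 0.537075,
                0.537075, 0.569223529412, 0.787831578947, 0.787831578947,
                0.87696, 0.9144, 0.993888, 0.993888, 0.993888, 0.993888)
  expect_equal(adjustPValues(p, "BKY"), expected, tolerance = 1e-9)
  # sharpening can undercut BH when many hypotheses are non-null
  p2 <- c(rep(1e-6, 8), 0.2, 0.9)
  expect_true(all(adjustPValues(p2, "BKY") <= adjustPValues(p2, "BH")))
})

test_that("BKY controls the false discovery rate on seeded null/alternative mixtures", {
  set.seed(2024)
  m <- 100; m0 <- 80
  reps <- 2000
  fdp <- matrix(NA_real_, reps, 2,
                dimnames = list(NULL, c("BH", "BKY")))
  for (r in seq_len(reps)) {
    p <- c(runif(m0), rbeta(m - m0, 0.15, 1))
    is_null <- c(rep(TRUE, m0), rep(FALSE, m - m0))
    for (meth in c("BH", "BKY")) {
      rej <- adjustPValues(p, meth) <= 0.05
      fdp[r, meth] <- if (any(rej)) sum(rej & is_null) / sum(rej) else 0
    }
  }
  mc_err <- apply(fdp, 2, sd) / sqrt(reps)
  expect_lte(mean(fdp[, "BKY"]), 0.05 + 3 * mc_err[["BKY"]])
  expect_lte(mean(fdp[, "BH"]), 0.05 + 3 * mc_err[["BH"]])
})

test_that("no-effect synthetic accessibilities yield nominal rejection rates", {
  set.seed(99)
  n_sites <- 20; reps <- 1000
  frac <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("BH", "BKY")))
  for (r in seq_len(reps)) {
    p <- vapply(seq_len(n_sites), function(s) {
      vals <- 100 * rbeta(12, 0.6 * 200, 0.4 * 200)
      siteAnova(vals, rep(c("a", "b"), each = 6))$p
    }, numeric(1))
    for (meth in c("BH", "BKY"))
      frac[r, meth] <- mean(adjustPValues(p, meth) <= 0.05)
  }
  for (meth in c("BH", "BKY")) {
    mc_err <- sd(frac[, meth]) / sqrt(reps)
    expect_lte(mean(frac[, meth]), 0.05 + 3 * mc_err)
  }
})

test_that("significance tiers follow the configured q cutoffs", {
  expect_equal(significanceTier(c(5e-5, 1.5e-4, 0.01)),
               c("****", "***", "ns"))
  expect_equal(significanceTier(1e-4), "****")   # inclusive boundary
  expect_equal(significanceTier(2e-4), "***")
  expect_equal(significanceTier(0.5, cutoffs = c("*" = 0.6)), "*")
  expect_error(significanceTier(0.1, cutoffs = c(a = 0.2, b = 0.1)))
  # tiers are monotone in q
  q <- sort(runif(50, 1e-6, 1))
  tiers <- significanceTier(q)
  expect_true(all(diff(match(tiers, c("****", "***", "ns"))) >= 0))
})

test_that("cross-condition comparison wires ANOVA, FDR and tiers per site", {
  d <- SyntheticDesign(
    truth = data.frame(protein = "P13569",
                       residue = rep(c(273, 283), each = 2),
                       condition = rep(c("wt", "dF508"), 2),
                       true_accessibility = c(61.8, 95.0, 98.7, 98.9)),
    replicates = c(wt = 4L, dF508 = 4L), qcFailFraction = 0, seed = 31)
  x <- generateExperiment(d)$forward
  res <- compareConditions(x, "BKY")
  expect_equal(res$residue, c(273, 283))
  k273 <- res[res$residue == 273, ]
  expect_equal(k273$status, "ok")
  expect_lt(k273$q_value, 1e-4)
  expect_equal(k273$tier, "****")
  expect_true(all(res$conditions == "dF508;wt"))
})

test_that("the condition matrix flags missing cells instead of imputing", {
  st <- data.frame(protein = "P13569", residue = c(273, 273, 283),
                   label = c("K273", "K273", "K283"),
                   condition = c("wt", "Trikafta", "wt"),
                   mean_accessibility = c(61.8, 81.5, 98.7),
                   sem = c(1, 1, 0.2))
  m <- conditionMatrix(st, conditions = c("wt", "Trikafta", "VX809"))
  expect_equal(nrow(m), 6)  # 2 sites x 3 conditions
  expect_equal(sum(m$missing), 3)
  k273_wt <- m[m$residue == 273 & m$condition == "wt", ]
  expect_equal(k273_wt$mean_accessibility, 61.8)
  # single condition: matrix reduces to the site table values
  m1 <- conditionMatrix(st[st$condition == "wt", ])
  expect_equal(nrow(m1), 2)
  expect_false(any(m1$missing))
})
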