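test_that("Harrell's C handles perfect, mixed and fully tied orderings", {
  expect_equal(harrellC(c(3, 5, 8), c(1, 1, 1), c(3, 2, 1))$c, 1)
  # pairs: (1,2) concordant, (1,3) discordant, (2,3) unusable
  expect_equal(harrellC(c(2, 4, 6), c(1, 0, 1), c(1.0, 0.5, 1.2))$c, 0.5)
  expect_equal(harrellC(c(2, 4, 6), c(1, 1, 1), c(1, 1, 1))$c, 0.5)
  expect_error(harrellC(c(1, 2), c(0, 0), c(1, 2)), "event")
})

test_that("Harrell's C equals the O(n^2) pair-enumeration oracle", {
  for (s in 1:25) {
    f <- randomSurvFixture(sample(5:60, 1), seed = s)
    expect_equal(harrellC(f$times, f$events, f$scores)$c,
                 bruteC(f$times, f$events, f$scores), tolerance = 1e-12)
  }
})

test_that("bootstrap CI for C is seeded and sensible", {
  f <- randomSurvFixture(80, seed = 9)
  a <- harrellC(f$times, f$events, f$scores, nBoot = 50, seed = 4)
  b <- harrellC(f$times, f$events, f$scores, nBoot = 50, seed = 4)
  expect_identical(a$ci, b$ci)
  expect_true(a$ci[1] <= a$c && a$c <= a$ci[2])
})

test_that("log-rank test matches hand evaluation and its symmetries", {
  # duplicated groups: identical survival experience
  lr0 <- logrankTest(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                     rep(c("a", "b"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)
  # hand-evaluated O/E/V over the four event times
  lr <- logrankTest(c(1, 2, 1.5, 3), c(1, 1, 1, 1), c(1, 1, 2, 2))
  expect_equal(lr$chisq, 0.6153846, tolerance = 1e-6)
  # relabeling invariance
  lr2 <- logrankTest(c(1, 2, 1.5, 3), c(1, 1, 1, 1), c(2, 2, 1, 1))
  expect_equal(lr$chisq, lr2$chisq, tolerance = 1e-12)
  expect_error(logrankTest(c(1, 2), c(1, 1), c(1, 1)), "two groups")
})

test_that("Kaplan-Meier estimate is the product-limit step function", {
  km <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv(0), 1)
  expect_equal(km$surv(1), 2 / 3, tolerance = 1e-12)
  expect_equal(km$surv(2.5), 2 / 3, tolerance = 1e-12)
  expect_equal(km$surv(3), 0)
  # no events: flat at 1
  km0 <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km0$surv(c(0, 2, 10)), c(1, 1, 1))
  # nonincreasing from 1 on a random fixture
  f <- randomSurvFixture(60, seed = 3)
  km1 <- kmEstimate(f$times, f$events)
  expect_true(all(diff(km1$table$surv) <= 1e-12))
  expect_true(all(km1$table$surv <= 1))
})

test_that("time-dependent AUC reduces to rank-sum AUC without censoring", {
  a <- tdAUC(c(1, 2, 10, 12), c(1, 1, 1, 1), c(0.9, 0.8, 0.2, 0.1), 5)
  expect_equal(a$auc, 1)
  for (s in 1:20) {
    set.seed(s)
    n <- sample(20:80, 1)
    times <- rexp(n, 0.1) + 0.1
    scores <- rnorm(n)
    h <- quantile(times, runif(1, 0.2, 0.8))
    got <- tdAUC(times, rep(1, n), scores, h)$auc
    expect_equal(got, rankAUC(as.integer(times <= h), scores),
                 tolerance = 1e-12)
  }
})

test_that("time-dependent AUC is antisymmetric under score negation", {
  f <- randomSurvFixture(80, seed = 13)
  h <- median(f$times)
  a <- tdAUC(f$times, f$events, f$scores, h)$auc
  b <- tdAUC(f$times, f$events, -f$scores, h)$auc
  expect_equal(a, 1 - b, tolerance = 1e-12)
  expect_error(tdAUC(f$times, f$events, f$scores, max(f$times) + 1),
               "horizon")
})

test_that("Cox tables recover planted effects and flag degenerate input", {
  # planted log-HR of 1 on one dimension
  co <- simulateDECohort(300, nFeatures = 4, prognosticIdx = 1, beta = 1,
                         seed = 21)
  d <- cbind(co$records, x = co$pde[, 1], z = co$pde[, 2],
             const = 1)
  tab <- coxTable(d, c("x"), endpoint = "OS")
  se <- (log(tab$hi) - log(tab$hr)) / 1.96
  expect_lt(abs(log(tab$hr) - 1), 2 * se)
  # null covariate CI covers 1 in >= 90% of 50 simulated seeds
  covered <- vapply(1:50, function(s) {
    cs <- simulateDECohort(120, nFeatures = 2, prognosticIdx = 1, beta = 0,
                           censorRate = 0.5, seed = 100 + s)
    t1 <- coxTable(cbind(cs$records, x = cs$pde[, 2]), "x", "OS")
    t1$lo <= 1 && 1 <= t1$hi
  }, logical(1))
  expect_gte(mean(covered), 0.9)
  # constant covariate flagged, not an error
  tc <- coxTable(d, c("x", "const"), endpoint = "OS", mode = "multivariable")
  expect_equal(tc$flag[tc$covariate == "const"], "constant")
})

test_that("baseline clinical model is deterministic noise under the null", {
  co <- simulateDECohort(260, prognosticIdx = 1:3, beta = c(1, 1, -1),
                         seed = 31)
  bm <- baselineModel(co$records, endpoint = "OS")
  lp1 <- predictBaseline(bm, co$records)
  expect_identical(lp1, predictBaseline(bm, co$records))
  # covariate-order invariance of the linear predictor
  bm2 <- baselineModel(co$records, endpoint = "OS",
                       covariates = rev(bm$covariates))
  expect_equal(lp1, predictBaseline(bm2, co$records), tolerance = 1e-8)
  # clinical covariates are pure noise: C near 1/2, while the planted
  # linear predictor discriminates
  cBase <- harrellC(co$records$os_time, co$records$os_event, lp1)$c
  cTrue <- harrellC(co$records$os_time, co$records$os_event, co$lp)$c
  expect_lt(abs(cBase - 0.5), 0.12)
  expect_gt(cTrue, 0.65)
})

test_that("clinicopathological risk rule follows the high/intermediate logic", {
  rec <- data.frame(
    ln_metastasis = c(0, 0, 1, 0), parametrial_invasion = c(0, 0, 0, 1),
    margin_positive = 0, lvsi = c(1, 1, 0, 0), dsi_deep = c(0, 1, 0, 0),
    tumor_size_cm = c(3, 3, 3, 3))
  expect_equal(clinicalRiskStatus(rec), c("low", "high", "high", "high"))
  expect_equal(as.character(lnCountGroup(c(0, 1, 2, 3, 7))),
               c("0", "1-2", "1-2", ">2", ">2"))
})

test_that("subgroup comparison reports non-evaluable sparse strata", {
  co <- simulateDECohort(120, prognosticIdx = 1:3, beta = c(1, 1, -1),
                         seed = 41)
  rs <- data.frame(patient_id = co$records$patient_id,
                   score = co$lp,
                   group = ifelse(co$lp >= median(co$lp), "high", "low"),
                   stringsAsFactors = FALSE)
  strata <- c(rep("A", 110), rep("B", 10))
  res <- subgroupKM(rs, co$records, strata, endpoint = "OS")
  expect_true(res$evaluable[res$stratum == "A"])
  expect_true(is.finite(res$chisq[res$stratum == "A"]))
  sparse <- c(rep("A", 117), rep("B", 3))
  res2 <- subgroupKM(rs, co$records, sparse, endpoint = "OS")
  expect_false(res2$evaluable[res2$stratum == "B"])
})

test_that("Fisher exact p matches exhaustive enumeration and conventions", {
  tabs <- list(matrix(c(7, 3, 49, 3), 2, byrow = TRUE),
               matrix(c(12, 3, 44, 3), 2, byrow = TRUE),
               matrix(c(18, 2, 33, 4), 2, byrow = TRUE),
               matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
  for (tab in tabs)
    expect_equal(fisherExact2x2(tab)$p, fisherOracle(tab), tolerance = 1e-9)
  expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  set.seed(7)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExact2x2(tab)$p, fisherOracle(tab), tolerance = 1e-9)
  }
  zm <- fisherExact2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(zm$p, 1)
  expect_equal(zm$flag, "zero-margin")
})

test_that("continuity-corrected chi-square enforces the expected-count rule", {
  pp <- chisqYates2x2(matrix(c(10, 10, 20, 20), 2, byrow = TRUE))
  expect_equal(pp$chisq, 0, tolerance = 1e-12)
  expect_equal(pp$p, 1, tolerance = 1e-12)
  # correction shrinks the statistic
  tab <- matrix(c(20, 12, 114, 43), 2, byrow = TRUE)
  un <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  expect_lt(chisqYates2x2(tab)$chisq, unname(un))
  expect_error(chisqYates2x2(matrix(c(2, 1, 30, 40), 2, byrow = TRUE)),
               "fisherExact2x2")
})

test_that("cohort-characteristics test rule picks Fisher vs chi-square", {
  expect_equal(table1Test(matrix(c(7, 3, 49, 3), 2, byrow = TRUE))$method,
               "fisher")
  expect_equal(table1Test(matrix(c(20, 12, 114, 43), 2, byrow = TRUE))$method,
               "chisq-yates")
  rxc <- matrix(c(8, 3, 5, 2, 9, 1), 3, 2, byrow = TRUE)
  res <- table1Test(rxc)
  expect_equal(res$method, "fisher")
  expect_true(res$p > 0 && res$p <= 1)
})
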