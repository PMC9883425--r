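test_that("RMS normalization follows the score formula exactly", {
  expect_equal(rmsNormalize(c(3, 4)), c(0.8485, 1.1314), tolerance = 5e-5)
  expect_equal(rmsNormalize(rep(2.5, 7)), rep(1, 7))
  for (s in 1:10) {
    set.seed(s)
    sig <- rnorm(sample(3:40, 1))
    sc <- rmsNormalize(sig)
    expect_equal(sum(sc^2), length(sig), tolerance = 1e-9)
  }
  expect_error(rmsNormalize(rep(0, 5)), "all zero")
})

test_that("signature fitting recovers a planted log-hazard", {
  co <- simulateDECohort(300, nFeatures = 8, prognosticIdx = 1, beta = 1,
                         censorRate = 0.5, seed = 19)
  rownames(co$pde) <- co$records$patient_id
  fit <- fitSignature(co$pde, co$records, 1L, endpoint = "OS")
  expect_gt(fit$beta[1], 0.7)
  expect_lt(fit$beta[1], 1.3)
  expect_equal(fit$rmsNorm, sqrt(mean(fit$signatures^2)), tolerance = 1e-12)
  # all-censored input is an error
  rec0 <- co$records; rec0$os_event <- 0
  expect_error(fitSignature(co$pde, rec0, 1L, "OS"), "events")
})

test_that("null features stay within 2 standard errors most of the time", {
  inside <- vapply(1:200, function(s) {
    co <- simulateDECohort(300, nFeatures = 2, prognosticIdx = 1, beta = 0,
                           censorRate = 0.5, seed = 2000 + s)
    rownames(co$pde) <- co$records$patient_id
    fit <- fitSignature(co$pde, co$records, 2L, "OS")
    se <- sqrt(diag(fit$fit$var))[1]
    abs(fit$beta[1]) < 2 * se
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("cutpoint search separates well-separated risk clusters", {
  # low-score cluster: censored late; high-score cluster: events early —
  # the log-rank scan must cut between the clusters
  set.seed(8)
  scores <- c(runif(20, 0, 0.5), runif(20, 2.8, 3.3))
  # one late event in the low cluster so the between-cluster cut satisfies
  # the at-least-one-event-per-group scan constraint
  rec <- data.frame(patient_id = sprintf("P%02d", 1:40),
                    os_time = c(runif(20, 80, 100), runif(20, 5, 20)),
                    os_event = c(1, rep(0, 19), rep(1, 20)))
  rec$dfs_time <- rec$os_time; rec$dfs_event <- rec$os_event
  cp <- findCutpoint(scores, rec, "OS")
  expect_gt(cp$cutpoint, 0.5)
  expect_lt(cp$cutpoint, 2.8)
  # returned chi-square equals the log-rank recomputed at that cutpoint
  lr <- logrankTest(rec$os_time, rec$os_event, scores >= cp$cutpoint)
  expect_equal(cp$chisq, lr$chisq, tolerance = 1e-9)
  # scan table respects group-size bounds
  expect_true(all(cp$scan$n_low >= 4 & cp$scan$n_high >= 4))
  expect_error(findCutpoint(rep(1, 40), rec, "OS"), "all scores")
})

test_that("applying a model freezes training normalization and cutpoint", {
  co <- simulateDECohort(200, prognosticIdx = 1:3, beta = c(1, 1, -1),
                         censorRate = 0.6, seed = 23)
  rownames(co$pde) <- co$records$patient_id
  model <- fitRiskModel(co$pde, co$records, 1:5, endpoint = "OS")
  rs <- applyRiskModel(model, co$pde)
  # training scores reproduce exactly from the frozen constants
  sig <- drop(co$pde[, 1:5] %*% model@beta)
  expect_equal(rs$signature, unname(sig), tolerance = 1e-12)
  expect_equal(rs$score, unname(sig / model@rmsNorm), tolerance = 1e-12)
  expect_equal(sum(rs$score^2), nrow(co$pde), tolerance = 1e-9)
  # group flips exactly at the cutpoint
  expect_true(all((rs$score >= model@cutpoint) == (rs$group == "high")))
  expect_true(model@cutpoint > min(rs$score) && model@cutpoint < max(rs$score))
  # score is monotone in a positive-coefficient feature
  j <- which(model@beta > 0)[1]
  if (!is.na(j)) {
    pde2 <- co$pde; pde2[1, j] <- pde2[1, j] + 1
    rs2 <- applyRiskModel(model, pde2)
    expect_gt(rs2$score[1], rs$score[1])
  }
  # ranking by score equals ranking by signature
  expect_identical(order(rs$score), order(rs$signature))
  expect_error(applyRiskModel(model, co$pde[, 1:3]), "selected features")
})

test_that("risk model serializes to JSON faithfully", {
  co <- simulateDECohort(150, censorRate = 0.6, seed = 29)
  rownames(co$pde) <- co$records$patient_id
  model <- fitRiskModel(co$pde, co$records, 1:4, endpoint = "DFS")
  p <- withr::local_tempfile(fileext = ".json")
  writeRiskModel(model, p)
  x <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(x$endpoint, "DFS")
  expect_equal(unlist(x$beta), model@beta, tolerance = 1e-12)
  expect_equal(x$cutpoint, model@cutpoint, tolerance = 1e-12)
})
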