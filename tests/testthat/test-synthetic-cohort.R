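test_that("cohort simulation is reproducible and respects invariants", {
  a <- simulateCohort(30, c(3, 5), seed = 42)
  b <- simulateCohort(30, c(3, 5), seed = 42)
  expect_identical(a, b)                        # same seed, identical output
  c2 <- simulateCohort(30, c(3, 5), seed = 43)
  expect_false(identical(a$records, c2$records))
  expect_true(all(a$records$dfs_time <= a$records$os_time))
  expect_true(all(a$records$os_time > 0))
  expect_true(all(vapply(a$features, function(f)
    ncol(featureMatrix(f)) == 2048L, logical(1))))
  expect_true(all(vapply(a$features, function(f)
    all(featureMatrix(f) >= 0), logical(1))))
  expect_error(simulateCohort(1, c(2, 3)), "nPatients")
  expect_error(simulateCohort(10, c(0, 3)), "positive")
})

test_that("realized censoring tracks the target rate", {
  for (cr in c(0.2, 0.6, 0.9)) {
    co <- simulateCohort(250, c(2, 3),
                         truth = groundTruth(censorRate = cr), seed = 7)
    expect_lt(abs(mean(1 - co$records$os_event) - cr), 0.1)
  }
  # default study conditions: ~10% deaths, ~19% recurrences
  co <- simulateCohort(300, c(2, 3), seed = 8)
  expect_lt(abs(mean(co$records$os_event) - 0.10), 0.06)
  expect_lt(abs(mean(co$records$dfs_event) - 0.19), 0.08)
})

test_that("null effects force chance concordance; strong effects do not", {
  null <- simulateCohort(300, c(2, 3),
                         truth = groundTruth(betaTrue = rep(0, 10),
                                             censorRate = 0.2),
                         seed = 11)
  lp <- drop(null$latent[, 1:3] %*% c(1, 1, -1))
  cNull <- harrellC(null$records$os_time, null$records$os_event, lp)$c
  expect_lt(abs(cNull - 0.5), 0.05)
  strong <- simulateCohort(300, c(2, 3),
                           truth = groundTruth(prognosticIdx = 1L,
                                               betaTrue = c(2, rep(0, 9)),
                                               censorRate = 0.2),
                           seed = 11)
  cStrong <- harrellC(strong$records$os_time, strong$records$os_event,
                      strong$latent[, 1])$c
  expect_gt(cStrong, 0.7)
})

test_that("Kaplan-Meier median matches the Weibull closed form (beta = 0)", {
  co <- simulateCohort(500, c(2, 3),
                       truth = groundTruth(betaTrue = rep(0, 10),
                                           censorRate = 0.2),
                       seed = 13)
  km <- kmEstimate(co$records$os_time, co$records$os_event)
  kmMedian <- km$table$time[which(km$table$surv <= 0.5)[1]]
  closedForm <- co$truth$baselineScale * log(2)^(1 / co$truth$baselineShape)
  expect_lt(abs(kmMedian - closedForm) / closedForm, 0.15)
})

test_that("toy slides are seeded, masked and color-shift aware", {
  sl <- simulateToySlides(3, imageSize = 96, patchSize = 32, seed = 3)
  expect_length(sl$images, 3)
  # each slide yields at least one tissue patch
  for (i in 1:3) {
    g <- tileROI(sl$images[[i]], sl$masks[[i]], 32, 32, 0.5)
    expect_gt(nrow(g), 0)
  }
  # distinct seeds give distinct pixel content
  sl2 <- simulateToySlides(3, imageSize = 96, patchSize = 32, seed = 4)
  expect_false(identical(sl$images[[1]], sl2$images[[1]]))
  # identity stain shift: all slides share one color scale exactly
  slId <- simulateToySlides(4, imageSize = 96, patchSize = 32,
                            stainShift = "identity", seed = 5)
  bg <- vapply(slId$images, function(im) im[1, 1, 1], numeric(1))
  expect_true(all(bg == bg[1]))
  expect_error(simulateToySlides(2, imageSize = 16, patchSize = 64),
               "at least one patch")
})

test_that("ground-truth validation rejects malformed parameters", {
  expect_error(groundTruth(censorRate = 1), "censorRate")
  expect_error(groundTruth(prognosticIdx = 11), "prognosticIdx")
  expect_error(groundTruth(betaTrue = c(1, 2)), "betaTrue")
  expect_error(groundTruth(noiseSd = -1), "noiseSd")
})

test_that("cohort files round-trip through CSV", {
  co <- simulateCohort(5, c(2, 2), seed = 17)
  d <- withr::local_tempdir()
  writeCohort(co, d)
  back <- read.csv(file.path(d, "cohort.csv"), stringsAsFactors = FALSE)
  expect_equal(back$patient_id, co$records$patient_id)
  expect_equal(back$os_time, co$records$os_time, tolerance = 1e-9)
  f1 <- as.matrix(read.csv(file.path(d, "features", "P001.csv")))
  expect_equal(unname(f1), unname(featureMatrix(co$features[[1]])),
               tolerance = 1e-9)
})
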