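test_that("selection rejects degenerate requests", {
  co <- simulateDECohort(60, censorRate = 0.6, seed = 3)
  rownames(co$pde) <- co$records$patient_id
  expect_error(stabilitySelect(co$pde, co$records, "OS", nRepeats = 0),
               "nRepeats")
  rec0 <- co$records; rec0$os_event <- 0
  expect_error(stabilitySelect(co$pde, rec0, "OS", nRepeats = 5),
               "zero events")
  # constant columns are dropped with a warning and never selected
  pde2 <- co$pde; pde2[, 7] <- 1
  expect_warning(sel <- stabilitySelect(pde2, co$records, "OS",
                                        nRepeats = 5, seed = 1),
                 "constant")
  expect_false(7L %in% selectedIdx(sel))
  expect_equal(selectionFrequency(sel)[7], 0L)
})

test_that("selected set size and ordering follow the frequency ranking", {
  co <- simulateDECohort(100, prognosticIdx = 1:3, beta = c(1, 1, -1),
                         censorRate = 0.6, seed = 11)
  rownames(co$pde) <- co$records$patient_id
  sel <- stabilitySelect(co$pde, co$records, "OS", nRepeats = 20, seed = 5)
  expect_length(selectedIdx(sel), round(0.15 * 128))   # top 15% of 128 = 19
  f <- selectionFrequency(sel)
  s <- selectedIdx(sel)
  expect_true(all(f[s] >= max(f[-s])))                 # ranking respected
  expect_equal(f[s][1], max(f))
  # exact-count override (the 18-feature variant)
  sel18 <- stabilitySelect(co$pde, co$records, "OS", nRepeats = 20,
                           seed = 5, exactCount = 18)
  expect_length(selectedIdx(sel18), 18)
  expect_equal(selectedIdx(sel18), selectedIdx(sel)[1:18])
})

test_that("selection frequencies are invariant to patient row order", {
  co <- simulateDECohort(80, censorRate = 0.6, seed = 13)
  rownames(co$pde) <- co$records$patient_id
  sel1 <- stabilitySelect(co$pde, co$records, "OS", nRepeats = 10, seed = 2)
  perm <- sample(nrow(co$pde))
  sel2 <- stabilitySelect(co$pde[perm, ], co$records[perm, ], "OS",
                          nRepeats = 10, seed = 2)
  expect_identical(selectionFrequency(sel1), selectionFrequency(sel2))
})

test_that("duplicated feature columns earn near-identical frequencies", {
  co <- simulateDECohort(120, prognosticIdx = 2, beta = 1.2,
                         censorRate = 0.6, seed = 17)
  pde <- co$pde
  pde[, 10] <- pde[, 2]                    # exact duplicate of a signal column
  rownames(pde) <- co$records$patient_id
  sel <- stabilitySelect(pde, co$records, "OS", nRepeats = 30, seed = 3)
  f <- selectionFrequency(sel)
  # the ridge component of the elastic net shares duplicates: the two
  # frequencies may differ only through per-subsample tie-breaking
  expect_lt(abs(f[2] - f[10]), 0.35 * 30)
  expect_gt(f[2] + f[10], 0)
})

test_that("pure-noise features show no self-selection bias", {
  # On a fixed null cohort the subsample repeats share the data, so a
  # noise feature with a chance marginal association is legitimately
  # selected often: frequencies must track that chance association, not
  # any structural preference such as feature index.
  co <- simulateDECohort(150, prognosticIdx = 1, beta = 0,
                         censorRate = 0.6, seed = 19)
  rownames(co$pde) <- co$records$patient_id
  sel <- stabilitySelect(co$pde, co$records, "OS", nRepeats = 200, seed = 1)
  f <- selectionFrequency(sel)
  z <- vapply(seq_len(128), function(j) {
    ft <- survival::coxph(
      survival::Surv(co$records$os_time, co$records$os_event) ~ co$pde[, j])
    abs(stats::coef(ft)) / sqrt(ft$var[1, 1])
  }, numeric(1))
  expect_lt(abs(cor(f, seq_len(128), method = "spearman")), 0.2)
  expect_gt(cor(f, z, method = "spearman"), 0.5)
  # and the tail is modest: no feature selected in most repeats
  expect_lt(max(f), 0.5 * 200)
})

test_that("repeat-count comparison emits one evaluated row per grid entry", {
  co <- simulateDECohort(140, prognosticIdx = 1:3, beta = c(1, 1, -1),
                         censorRate = 0.6, seed = 23)
  rownames(co$pde) <- co$records$patient_id
  sp <- splitCohort(co$records, seed = 4)
  tab <- compareRepeatCounts(co$pde, co$records, sp, "OS",
                             repeatGrid = c(10L, 20L), seed = 6)
  expect_equal(tab$n_repeats, c(10L, 20L))
  expect_true(all(tab$c_index_test >= 0 & tab$c_index_test <= 1))
  expect_true(all(tab$n_selected == 19))
})
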