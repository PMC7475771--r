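# A tiny hand-built measure table: 2 participants x 2 modes x 5 times x 1
# measure, with controllable values.
toy_cells <- function(active, sham, measure = "PrC",
                      pids = c("P01", "P02")) {
  grid <- expand.grid(participant_id = pids,
                      tms_time = c("BIP_only", "E30_BIP", "E70_BIP",
                                   "BIP_L150", "BIP_L190"),
                      stringsAsFactors = FALSE)
  rbind(
    data.frame(grid[1], tms_mode = "active", tms_time = grid$tms_time,
               measure = measure, value = active, n = 96L,
               defined = !is.na(active), stringsAsFactors = FALSE),
    data.frame(grid[1], tms_mode = "sham", tms_time = grid$tms_time,
               measure = measure, value = sham, n = 96L,
               defined = !is.na(sham), stringsAsFactors = FALSE))
}

test_that("sham normalization subtracts the within-participant baseline", {
  cells <- toy_cells(active = 0.6, sham = 0.7)
  d <- sham_normalize(cells)
  expect_true(all(abs(d$delta - (-0.1)) < 1e-12))
  # identical tables -> all zeros
  d0 <- sham_normalize(toy_cells(active = 0.42, sham = 0.42))
  expect_true(all(d0$delta == 0))
  # undefined sham cell propagates
  cells$value[cells$tms_mode == "sham"][1] <- NA
  dna <- sham_normalize(cells)
  expect_true(anyNA(dna$delta))
  expect_false(all(dna$defined))
})

test_that("the early-vs-late contrast is the difference of epoch means", {
  cells <- toy_cells(active = 0.5, sham = 0.5)
  d <- sham_normalize(cells)
  # early deltas -0.1, late deltas 0
  d$delta[d$tms_time %in% c("E30_BIP", "E70_BIP")] <- -0.1
  d$delta[d$tms_time %in% c("BIP_L150", "BIP_L190")] <- 0
  cv <- early_late_contrast(d, "PrC")
  expect_true(all(abs(cv$values - (-0.1)) < 1e-12))
  expect_equal(cv$df, length(cv$values) - 1L)
  # all deltas equal -> zero contrast
  d$delta <- 0.07
  expect_true(all(early_late_contrast(d, "PrC")$values == 0))
  # one undefined member: average the defined members by default
  d$delta <- rep(c(-0.2, -0.1, 0, 0), each = 2)[seq_len(nrow(d))]
  d$delta[d$tms_time == "E30_BIP" & d$participant_id == "P01"] <- NA
  d$delta[d$tms_time == "E70_BIP"] <- -0.1
  d$delta[d$tms_time %in% c("BIP_L150", "BIP_L190")] <- 0
  cv2 <- early_late_contrast(d, "PrC")
  expect_equal(unname(cv2$values["P01"]), -0.1)
  # the strict policy drops that participant instead
  cv3 <- early_late_contrast(d, "PrC", na_policy = "strict")
  expect_false("P01" %in% names(cv3$values))
})

test_that("fine contrasts difference two single onsets", {
  cells <- toy_cells(active = 0.5, sham = 0.5)
  d <- sham_normalize(cells)
  d$delta[d$tms_time == "E30_BIP"] <- -0.12
  d$delta[d$tms_time == "BIP_L190"] <- -0.04
  fc <- fine_contrast(d, "PrC", "E30_BIP", "BIP_L190")
  expect_true(all(abs(fc$values - (-0.08)) < 1e-12))
  # identical times -> zero vector
  expect_true(all(fine_contrast(d, "PrC", "E30_BIP", "E30_BIP")$values == 0))
})

test_that("one-sample t matches hand arithmetic and handles edge cases", {
  x <- c(0.02, -0.05, 0.01, -0.03, -0.06, 0.04, -0.08, -0.01)
  tr <- one_sample_t(x)
  se <- sd(x) / sqrt(length(x))
  expect_equal(tr$t, mean(x) / se, tolerance = 1e-12)
  expect_equal(tr$df, 7L)
  expect_equal(tr$p, 2 * pt(-abs(mean(x) / se), 7), tolerance = 1e-12)
  expect_equal(tr$cohens_d, mean(x) / sd(x), tolerance = 1e-12)
  expect_equal(tr$ci95,
               mean(x) + qt(c(0.025, 0.975), 7) * se, tolerance = 1e-12)
  # symmetric zero-mean vector
  tr0 <- one_sample_t(c(-1, 1, -2, 2))
  expect_equal(tr0$t, 0)
  expect_equal(tr0$p, 1)
  # constant nonzero vector: infinite t, flagged
  trc <- one_sample_t(c(0.3, 0.3, 0.3))
  expect_true(is.infinite(trc$t))
  expect_equal(trc$flag, "constant_vector")
})

test_that("paired t equals the one-sample t on differences exactly", {
  a <- c(0.5, 0.4, 0.6, 0.3, 0.5)
  b <- c(0.45, 0.42, 0.5, 0.35, 0.42)
  pt_ <- paired_t(a, b)
  ot <- one_sample_t(a - b)
  expect_identical(pt_$t, ot$t)
  expect_identical(pt_$p, ot$p)
  # a = b -> t = 0 (constant zero differences)
  expect_true(is.nan(paired_t(a, a)$t))
  # shift by a constant -> mean equals the shift
  expect_equal(paired_t(a + 0.1, a)$mean, 0.1)
})

test_that("the double-baseline identity holds to machine precision", {
  sim <- small_cohort(8)
  cells <- measure_table(sim$trials, measures = "PrC")
  d <- sham_normalize(cells)
  cv <- early_late_contrast(d, "PrC")
  early <- tapply(d$delta[d$tms_time %in% c("E30_BIP", "E70_BIP")],
                  d$participant_id[d$tms_time %in% c("E30_BIP", "E70_BIP")],
                  mean)
  late <- tapply(d$delta[d$tms_time %in% c("BIP_L150", "BIP_L190")],
                 d$participant_id[d$tms_time %in% c("BIP_L150", "BIP_L190")],
                 mean)
  pt_ <- paired_t(early[names(cv$values)], late[names(cv$values)])
  ot <- one_sample_t(cv)
  expect_equal(pt_$t, ot$t, tolerance = 1e-12)
  expect_equal(pt_$p, ot$p, tolerance = 1e-12)
})

test_that("within-subject SEs remove between-subject offsets", {
  # pure subject offsets: identical condition profiles -> SEs all zero
  profile <- seq(0.1, 1.0, by = 0.1)
  cells <- do.call(rbind, lapply(1:6, function(i) {
    grid <- expand.grid(tms_mode = c("active", "sham"),
                        tms_time = c("BIP_only", "E30_BIP", "E70_BIP",
                                     "BIP_L150", "BIP_L190"),
                        stringsAsFactors = FALSE)
    data.frame(participant_id = sprintf("P%02d", i), grid,
               measure = "PrC", value = profile + i * 0.05, n = 96L,
               defined = TRUE, stringsAsFactors = FALSE)
  }))
  ws <- within_subject_se(cells, "PrC")
  expect_equal(nrow(ws), 10L)
  expect_true(all(ws$se < 1e-12))
  # brute-force oracle on noisy data
  noisy <- cells
  noisy$value <- noisy$value + withr::with_seed(9, rnorm(nrow(noisy), 0, 0.05))
  ws2 <- within_subject_se(noisy, "PrC")
  mat <- matrix(NA_real_, 6, 10)
  conds <- paste(ws2$tms_mode, ws2$tms_time)
  for (i in 1:6) for (j in 1:10) {
    mat[i, j] <- noisy$value[noisy$participant_id == sprintf("P%02d", i) &
                               paste(noisy$tms_mode, noisy$tms_time) == conds[j]]
  }
  centred <- mat - rowMeans(mat) + mean(mat)
  manual <- apply(centred, 2, sd) / sqrt(6) * sqrt(10 / 9)
  expect_equal(ws2$se, manual, tolerance = 1e-12)
})

test_that("run_report emits the full measure census deterministically", {
  sim <- small_cohort(10)
  rep1 <- run_report(sim$trials)
  expect_equal(rep1$report$measure,
               c("PcU", "PrC", "PCm", "BrC", "PrA", "BrA", "PrS", "BrS"))
  expect_true(all(is.finite(rep1$report$t)))
  expect_true(all(rep1$report$p >= 0 & rep1$report$p <= 1))
  expect_true(all(rep1$report$ci_low <= rep1$report$mean &
                    rep1$report$mean <= rep1$report$ci_high))
  # deterministic re-run
  rep2 <- run_report(sim$trials)
  expect_identical(rep1$report, rep2$report)
})

test_that("measure-scope exclusions never leak into other measures", {
  sim <- small_cohort(10)
  rep <- run_report(sim$trials)
  excl <- rep$exclusions
  pcu_dropped <- excl$participant_id[excl$rule == "chance_pcu" & excl$excluded]
  # the screen fired for someone in this cohort yet PrC keeps everyone
  n_total <- length(unique(sim$trials$participant_id))
  prc_row <- rep$report[rep$report$measure == "PrC", ]
  expect_equal(prc_row$n + prc_row$n_outliers, n_total)
  pcu_row <- rep$report[rep$report$measure == "PcU", ]
  expect_equal(pcu_row$n + pcu_row$n_outliers, n_total - length(pcu_dropped))
  # removing the PcU screen changes only PcU rows
  rep_all <- run_report(sim$trials, report_config(chance_alpha = 1 - 1e-12))
  other <- rep$report$measure != "PcU"
  expect_equal(rep$report[other, ], rep_all$report[other, ],
               tolerance = 1e-12)
})

test_that("Chauvenet exclusions stay inside their analysis vector", {
  sim <- small_cohort(10)
  rep <- run_report(sim$trials)
  excl <- rep$exclusions
  ch <- excl[excl$rule == "chauvenet", ]
  if (nrow(ch) > 0) {
    expect_true(all(ch$scope == "vector_point"))
    # the flagged participant remains in every other contrast
    for (i in seq_len(nrow(ch))) {
      meas <- sub("outlier on '([A-Za-z]+) .*", "\\1", ch$detail[i])
      others <- setdiff(names(rep$contrasts), meas)
      present <- vapply(others, function(m)
        ch$participant_id[i] %in% names(rep$contrasts[[m]]$values),
        logical(1))
      expect_true(any(present))
    }
  }
  # n_outliers bookkeeping matches the exclusion report
  expect_equal(sum(rep$report$n_outliers), nrow(ch))
})

test_that("the fine-contrast gate follows the reliability rule", {
  sim <- small_cohort(10)
  cfg_closed <- report_config(fine_alpha = 0, bf_upper = Inf, bf_lower = 0)
  rep_closed <- run_report(sim$trials, cfg_closed)
  expect_length(rep_closed$fine, 0L)
  expect_true(any(grepl("gate closed", rep_closed$log)))
  cfg_open <- report_config(fine_alpha = 1)
  rep_open <- run_report(sim$trials, cfg_open)
  expect_length(rep_open$fine, 8L)
})
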