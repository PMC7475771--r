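# The published allocation table, reproduced row for row.
allocation_table <- data.frame(
  stimulus = c("arrow_left", "arrow_left", "non_arrow", "non_arrow",
               "absent", "absent", "absent"),
  resp_something = c("yes", "no", "yes", "yes", "yes", "yes", "no"),
  resp_arrow = c("yes", "no", "yes", "no", "yes", "no", "no"),
  class = c("HIT", "MISS", "FA", "CR", "FA", "FA", "CR"),
  stringsAsFactors = FALSE)

test_that("the conscious-detection allocation table is reproduced verbatim", {
  got <- classify_trials(allocation_table$stimulus,
                         allocation_table$resp_something,
                         allocation_table$resp_arrow, scheme = "PrC")
  expect_equal(got, allocation_table$class)
  # both arrow stimuli behave identically
  got_r <- classify_trials(sub("_left", "_right", allocation_table$stimulus),
                           allocation_table$resp_something,
                           allocation_table$resp_arrow, scheme = "PrC")
  expect_equal(got_r, allocation_table$class)
})

test_that("combinations absent from the table are unclassified, not coerced", {
  expect_equal(classify_trials("arrow_left", "yes", "no", "PrC"),
               "UNCLASSIFIED")
  expect_equal(classify_trials("non_arrow", "no", "no", "PrC"),
               "UNCLASSIFIED")
  # permissive completion is available but off by default
  expect_equal(classify_trials("arrow_left", "yes", "no", "PrC",
                               strict_table1 = FALSE), "MISS")
  expect_equal(classify_trials("non_arrow", "no", "no", "PrC",
                               strict_table1 = FALSE), "CR")
})

test_that("classification is total and illogical under every scheme", {
  combos <- expand.grid(stimulus = c("arrow_left", "arrow_right",
                                     "non_arrow", "absent"),
                        s = c("yes", "no"), a = c("yes", "no"),
                        stringsAsFactors = FALSE)
  for (scheme in c("PrC", "PrA", "PrS")) {
    cls <- classify_trials(combos$stimulus, combos$s, combos$a, scheme)
    expect_false(anyNA(cls))
    expect_true(all(cls %in% c("HIT", "MISS", "FA", "CR",
                               "UNCLASSIFIED", "ILLOGICAL")))
    # the illogical pattern is illogical everywhere
    expect_true(all(cls[combos$s == "no" & combos$a == "yes"] == "ILLOGICAL"))
  }
})

test_that("question-specific schemes use their own signal definitions", {
  # arrow question: arrow trials are signal, absent trials are noise
  expect_equal(classify_trials("arrow_left", "yes", "yes", "PrA"), "HIT")
  expect_equal(classify_trials("arrow_left", "yes", "no", "PrA"), "MISS")
  expect_equal(classify_trials("absent", "yes", "yes", "PrA"), "FA")
  expect_equal(classify_trials("absent", "no", "no", "PrA"), "CR")
  # non-arrow sits outside the arrow-question signal/noise definition
  expect_equal(classify_trials("non_arrow", "yes", "no", "PrA"),
               "UNCLASSIFIED")
  expect_equal(classify_trials("non_arrow", "yes", "yes", "PrA"),
               "UNCLASSIFIED")
  # something question: arrow and non-arrow are signal
  expect_equal(classify_trials("non_arrow", "yes", "no", "PrS"), "HIT")
  expect_equal(classify_trials("non_arrow", "no", "no", "PrS"), "MISS")
  expect_equal(classify_trials("absent", "yes", "no", "PrS"), "FA")
  expect_equal(classify_trials("absent", "no", "no", "PrS"), "CR")
})

test_that("rates come from raw counts with no smoothing", {
  r <- sdt_rates(list(hits = 8, misses = 2, fas = 3, crs = 7))
  expect_identical(r$hit_rate, 8 / 10)
  expect_identical(r$fa_rate, 3 / 10)
  expect_equal(sdt_rates(list(hits = 0, misses = 10, fas = 0, crs = 10))[1:2],
               list(hit_rate = 0, fa_rate = 0))
  expect_equal(sdt_rates(list(hits = 5, misses = 0, fas = 0, crs = 5))[1:2],
               list(hit_rate = 1, fa_rate = 0))
  # empty denominator: undefined flag, not an exception
  r0 <- sdt_rates(list(hits = 0, misses = 0, fas = 3, crs = 7))
  expect_true(is.na(r0$hit_rate))
  expect_false(r0$defined)
})

test_that("Pr and Br match hand computation exactly on small counts", {
  expect_identical(pr_sensitivity(0.8, 0.3), 0.5)
  expect_identical(pr_sensitivity(1.0, 0.0), 1.0)
  expect_equal(pr_sensitivity(0.37, 0.37), 0)
  expect_identical(br_criterion(0.3, 0.5), 0.6)
  expect_identical(br_criterion(0.0, 0.73), 0.0)
  expect_true(is.na(br_criterion(0.2, 1.0)))
  # exact rational arithmetic on integer-count fractions
  counts <- list(hits = 7, misses = 5, fas = 2, crs = 9)
  r <- sdt_rates(counts)
  expect_identical(r$hit_rate, 7 / 12)
  expect_identical(pr_sensitivity(r$hit_rate, r$fa_rate), 7 / 12 - 2 / 11)
  expect_identical(br_criterion(r$fa_rate,
                                pr_sensitivity(r$hit_rate, r$fa_rate)),
                   (2 / 11) / (1 - (7 / 12 - 2 / 11)))
})

test_that("pr is monotone in its rates and br in the false alarm rate", {
  hr <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(pr_sensitivity(hr, 0.3)) > 0))
  expect_true(all(diff(pr_sensitivity(0.7, hr)) < 0))
  expect_true(all(diff(br_criterion(hr, 0.4)) > 0))
})

test_that("unseen discrimination counts only double-denied arrow trials", {
  tt <- make_trials(
    stimulus = rep("arrow_left", 10),
    resp_arrow = "no", resp_something = "no",
    resp_direction = c(rep("left", 7), rep("right", 3)))
  p <- pcu(tt)
  expect_equal(p$value, 0.7)
  expect_equal(p$n, 10L)
  # denial must be double, and the stimulus an arrow
  tt2 <- rbind(make_trial(stimulus = "arrow_left", resp_arrow = "no",
                          resp_something = "yes", resp_direction = "left"),
               make_trial(stimulus = "non_arrow", resp_arrow = "no",
                          resp_something = "no", resp_direction = "left"))
  p2 <- pcu(tt2)
  expect_false(p2$defined)
  expect_equal(p2$n, 0L)
})

test_that("the detection-without-identification measure follows its recipe", {
  # 96 arrow trials: 2 acknowledged-but-misdirected, rest misses
  tt <- make_trials(
    stimulus = rep("arrow_left", 96),
    resp_arrow = c(rep("yes", 2), rep("no", 94)),
    resp_something = c(rep("yes", 2), rep("no", 94)),
    resp_direction = c(rep("right", 2), rep("left", 94)))
  m <- pcm(tt)
  expect_equal(m$value, 2 / 96)
  expect_equal(m$n, 96L)
  # perfect direction discrimination -> numerator empty, value 0, defined
  tt$resp_direction <- "left"
  m2 <- pcm(tt)
  expect_identical(m2$value, 0)
  expect_true(m2$defined)
  # no arrow trials -> undefined
  expect_false(pcm(make_trial(stimulus = "absent"))$defined)
})

test_that("parametric d' and c follow the inverse-normal transform", {
  expect_equal(dprime_c(list(hits = 6, misses = 4, fas = 6, crs = 4))$dprime, 0)
  d <- dprime_c(list(hits = 8, misses = 2, fas = 3, crs = 7))
  expect_equal(d$dprime, qnorm(0.8) - qnorm(0.3), tolerance = 1e-12)
  expect_equal(d$c, -(qnorm(0.8) + qnorm(0.3)) / 2, tolerance = 1e-12)
  # extreme rates clamp to [1/(2N), 1 - 1/(2N)] and stay finite
  x <- dprime_c(list(hits = 10, misses = 0, fas = 0, crs = 10))
  expect_true(is.finite(x$dprime))
  expect_equal(x$dprime, qnorm(1 - 1 / 20) - qnorm(1 / 20), tolerance = 1e-12)
})

test_that("measure_table enumerates every cell and records denominators", {
  sim <- small_cohort(2)
  cells <- measure_table(sim$trials)
  expect_equal(nrow(cells), 2L * 2L * 5L * 8L)
  expect_setequal(unique(cells$measure),
                  c("PrC", "BrC", "PrA", "BrA", "PrS", "BrS", "PcU", "PCm"))
  # PcU n is the count of qualifying (double-denied arrow) trials
  one <- cells[cells$measure == "PcU" & cells$tms_mode == "sham" &
                 cells$tms_time == "BIP_only" &
                 cells$participant_id == "P01", ]
  tt <- sim$trials[sim$trials$participant_id == "P01" &
                     sim$trials$tms_mode == "sham" &
                     sim$trials$tms_time == "BIP_only" &
                     !sim$trials$blink, ]
  expect_equal(one$n, pcu(tt)$n)
  expect_equal(one$value, pcu(tt)$value)
  # idempotent
  expect_identical(cells, measure_table(sim$trials))
})

test_that("per-cell measures agree with direct single-cell computation", {
  sim <- small_cohort(2)
  cells <- measure_table(sim$trials, measures = c("PrC", "BrC", "dprime"))
  tt <- sim$trials[sim$trials$participant_id == "P02" &
                     sim$trials$tms_mode == "active" &
                     sim$trials$tms_time == "E30_BIP" &
                     !sim$trials$blink, ]
  counts <- sdt_counts(tt, "PrC")
  r <- sdt_rates(counts)
  pick <- function(m) cells$value[cells$participant_id == "P02" &
                                    cells$tms_mode == "active" &
                                    cells$tms_time == "E30_BIP" &
                                    cells$measure == m]
  expect_equal(pick("PrC"), pr_sensitivity(r$hit_rate, r$fa_rate))
  expect_equal(pick("BrC"),
               br_criterion(r$fa_rate, pr_sensitivity(r$hit_rate, r$fa_rate)))
  expect_equal(pick("dprime"), dprime_c(counts)$dprime)
})

test_that("non-parametric and parametric sensitivity agree across observers", {
  # equal-variance Gaussian observers spanning a range of strengths
  strengths <- seq(0.6, 3.2, length.out = 14)
  prc <- dpr <- numeric(length(strengths))
  for (i in seq_along(strengths)) {
    p <- observer_params(signal_strength = strengths[i], lapse_rate = 0)
    sim <- withr::with_seed(500 + i, {
      d <- generate_design(design_spec(seed = 500 + i))
      simulate_trials(p, d)
    })
    counts <- sdt_counts(sim, "PrC")
    r <- sdt_rates(counts)
    prc[i] <- pr_sensitivity(r$hit_rate, r$fa_rate)
    dpr[i] <- dprime_c(counts)$dprime
  }
  expect_gt(cor(prc, dpr, method = "spearman"), 0.9)
})
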