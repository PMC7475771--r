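#' Sham-normalize a measure table
#'
#' Every measure is assessed relative to the within-participant sham
#' baseline: for each participant x TMS-time x measure, the active value
#' minus the sham value.  Undefined cells propagate (`delta = NA`).
#'
#' @param cells A [measure_table()] data.frame.
#' @return A data.frame with columns `participant_id`, `tms_time`,
#'   `measure`, `delta`, `n_active`, `n_sham`, `defined`.
#' @export
sham_normalize <- function(cells) {
  act <- cells[cells$tms_mode == "active", ]
  shm <- cells[cells$tms_mode == "sham", ]
  m <- merge(act, shm, by = c("participant_id", "tms_time", "measure"),
             suffixes = c("_active", "_sham"), all = TRUE)
  data.frame(
    participant_id = m$participant_id,
    tms_time = m$tms_time,
    measure = m$measure,
    delta = m$value_active - m$value_sham,
    n_active = m$n_active, n_sham = m$n_sham,
    defined = !is.na(m$value_active - m$value_sham),
    stringsAsFactors = FALSE)
}

new_contrast_vector <- function(name, values, meta = list()) {
  values <- values[!is.na(values)]
  structure(list(name = name, values = values,
                 df = length(values) - 1L, meta = meta),
            class = "contrast_vector")
}

#' @export
print.contrast_vector <- function(x, ...) {
  cat(sprintf("contrast '%s': n = %d, mean = %.4f, sd = %.4f\n",
              x$name, length(x$values), mean(x$values),
              stats::sd(x$values)))
  invisible(x)
}

#' Early-versus-late temporal contrast
#'
#' The unit of all temporal inference: per participant, the mean of the
#' sham-normalized deltas at the two early TMS onsets (30 and 70 ms)
#' minus the mean at the two late onsets (150 and 190 ms).  The sign
#' convention is early-minus-late: a negative value means the early
#' intervention suppressed the measure more than the late one.
#'
#' When one member of a pair is undefined the default policy averages
#' the defined members (maximizing data use, flagged in the metadata);
#' `na_policy = "strict"` drops the participant instead.
#'
#' @param deltas A [sham_normalize()] table.
#' @param measure Which measure to contrast.
#' @param na_policy `"average_defined"` or `"strict"`.
#' @return A `contrast_vector` (named per-participant values).
#' @export
early_late_contrast <- function(deltas, measure,
                                na_policy = c("average_defined", "strict")) {
  na_policy <- match.arg(na_policy)
  d <- deltas[deltas$measure == measure, ]
  side_mean <- function(times, pid) {
    v <- d$delta[d$participant_id == pid & d$tms_time %in% times]
    if (na_policy == "strict" && anyNA(v)) return(NA_real_)
    if (all(is.na(v))) return(NA_real_)
    mean(v, na.rm = TRUE)
  }
  pids <- sort(unique(d$participant_id))
  vals <- vapply(pids, function(p)
    side_mean(TMS_TIMES_EARLY, p) - side_mean(TMS_TIMES_LATE, p),
    numeric(1))
  names(vals) <- pids
  n_partial <- sum(!is.na(vals) & vapply(pids, function(p)
    anyNA(d$delta[d$participant_id == p &
                    d$tms_time %in% c(TMS_TIMES_EARLY, TMS_TIMES_LATE)]),
    logical(1)))
  new_contrast_vector(
    paste(measure, "early_vs_late"), vals,
    meta = list(sign_convention = "early_minus_late",
                na_policy = na_policy, n_partial = n_partial))
}

#' Fine-grained temporal contrast between two TMS onsets
#'
#' Per participant, delta at `time_a` minus delta at `time_b` (e.g. the
#' 30 ms vs. 190 ms comparison).  Fine contrasts are only warranted when
#' the coarse early-vs-late analysis shows a reliable effect; the gate is
#' enforced in [run_report()], not here.
#'
#' @param deltas A [sham_normalize()] table.
#' @param measure Which measure.
#' @param time_a,time_b TMS-time levels.
#' @return A `contrast_vector`.
#' @export
fine_contrast <- function(deltas, measure, time_a, time_b) {
  stopifnot(time_a %in% TMS_TIMES, time_b %in% TMS_TIMES)
  d <- deltas[deltas$measure == measure, ]
  pids <- sort(unique(d$participant_id))
  val_at <- function(p, tt) {
    v <- d$delta[d$participant_id == p & d$tms_time == tt]
    if (length(v) == 0L) NA_real_ else v[1]
  }
  vals <- vapply(pids, function(p)
    val_at(p, time_a) - val_at(p, time_b), numeric(1))
  names(vals) <- pids
  new_contrast_vector(
    sprintf("%s %s_vs_%s", measure, time_a, time_b), vals,
    meta = list(sign_convention = paste(time_a, "minus", time_b)))
}

#' One-sample t-test with effect size
#'
#' Classical one-sample t against `mu`, two-sided p, 95% CI, and Cohen's
#' d = (mean - mu) / SD of the analysis vector.  A constant vector (zero
#' SD) yields an infinite t, flagged rather than an error.
#'
#' @param x Numeric vector or `contrast_vector`.
#' @param mu Null value.
#' @return A `test_result` list: `t`, `df`, `p`, `mean`, `ci95`,
#'   `cohens_d`, `n`, `flag`.
#' @export
one_sample_t <- function(x, mu = 0) {
  if (inherits(x, "contrast_vector")) x <- x$values
  x <- x[!is.na(x)]
  n <- length(x)
  stopifnot(n >= 2L)
  m <- mean(x); s <- stats::sd(x)
  tt <- if (s > 0) tryCatch(stats::t.test(x, mu = mu), error = function(e) NULL)
        else NULL
  if (is.null(tt)) {   # (essentially) constant vector
    tval <- if (isTRUE(all.equal(m, mu))) NaN else sign(m - mu) * Inf
    return(structure(list(t = tval, df = n - 1L,
                          p = if (is.nan(tval)) 1 else 0,
                          mean = m, ci95 = c(m, m),
                          cohens_d = if (is.nan(tval)) 0 else sign(m - mu) * Inf,
                          n = n, flag = "constant_vector"),
                     class = "test_result"))
  }
  ci <- tt$conf.int
  attributes(ci) <- NULL
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean = m,
                 ci95 = ci, cohens_d = (m - mu) / s,
                 n = n, flag = NA_character_),
            class = "test_result")
}

#' Paired t-test
#'
#' Identical to a one-sample t-test on the paired differences `a - b`
#' (this identity is the definition here, so the double-baseline identity
#' — paired test of early vs. late deltas equals the one-sample test of
#' the early-minus-late contrast — holds to machine precision).
#'
#' @param a,b Paired numeric vectors.
#' @return A `test_result`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  one_sample_t(a - b, mu = 0)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, mean = %.4f, 95%% CI [%.4f, %.4f], d = %.3f, n = %d\n",
              x$df, x$t, x$p, x$mean, x$ci95[1], x$ci95[2], x$cohens_d, x$n))
  invisible(x)
}

#' Within-subject standard errors (Cousineau-Morey)
#'
#' Condition-wise standard errors appropriate for repeated-measures
#' designs: each participant's condition profile is centred on the grand
#' mean (removing between-subject offsets) and the per-condition SE of
#' the centred data is inflated by the Morey factor `sqrt(k / (k - 1))`
#' for `k` conditions.  Only participants with all `k` cells defined
#' contribute.
#'
#' @param cells A [measure_table()] data.frame.
#' @param measure Which measure.
#' @return A data.frame `tms_mode`, `tms_time`, `mean`, `se`, `n`; `se`
#'   is `NA` (flagged by attribute) when fewer than 2 conditions exist.
#' @export
within_subject_se <- function(cells, measure) {
  d <- cells[cells$measure == measure, ]
  cond <- paste(d$tms_mode, d$tms_time, sep = ":")
  wide <- stats::reshape(
    data.frame(pid = d$participant_id, cond = cond, value = d$value),
    idvar = "pid", timevar = "cond", direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^value\\.", "", colnames(mat))
  k <- ncol(mat)
  if (k < 2L) {
    out <- data.frame(tms_mode = sub(":.*", "", colnames(mat)),
                      tms_time = sub(".*:", "", colnames(mat)),
                      mean = colMeans(mat, na.rm = TRUE), se = NA_real_,
                      n = colSums(!is.na(mat)))
    attr(out, "flag") <- "single_condition"
    return(out)
  }
  complete <- stats::complete.cases(mat)
  mat_c <- mat[complete, , drop = FALSE]
  n <- nrow(mat_c)
  centred <- mat_c - rowMeans(mat_c) + mean(mat_c)
  morey <- sqrt(k / (k - 1))
  data.frame(
    tms_mode = sub(":.*", "", colnames(mat)),
    tms_time = sub(":.*$", "", sub("^[^:]*:", "", colnames(mat))),
    mean = colMeans(mat, na.rm = TRUE),
    se = apply(centred, 2, stats::sd) / sqrt(n) * morey,
    n = rep(n, k),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Pipeline configuration
#'
#' @param measures Measures to report, in report row order.
#' @param likelihood Data model for the half-normal/uniform Bayes factors.
#' @param strict_table1 Literal allocation-table reading.
#' @param chauvenet_interpretation Passed to [chauvenet()].
#' @param chance_alpha Alpha of the above-chance PcU screen.
#' @param fine_alpha,bf_upper,bf_lower Gate for fine-grained contrasts:
#'   opened when the coarse contrast has `p < fine_alpha` or BF_main
#'   outside `[bf_lower, bf_upper]`.
#' @param fine_times The fine contrast pair (default 30 ms vs. 190 ms).
#' @param na_policy Passed to [early_late_contrast()].
#' @param include_bayes Compute Bayes factors? (Disable for large
#'   simulation studies where only signs and p-values are needed.)
#' @param uniform_ranges Named list measure -> uniform prior range width;
#'   default: PrC 0.5 (threshold level to floor); PcU peak-to-chance,
#'   computed from the data.
#' @return A `report_config` list.
#' @export
report_config <- function(measures = c("PcU", "PrC", "PCm", "BrC",
                                       "PrA", "BrA", "PrS", "BrS"),
                          likelihood = c("t", "normal"),
                          strict_table1 = TRUE,
                          chauvenet_interpretation = "exceedance",
                          chance_alpha = 0.05,
                          fine_alpha = 0.05, bf_upper = 3, bf_lower = 1 / 3,
                          fine_times = c("E30_BIP", "BIP_L190"),
                          na_policy = "average_defined",
                          include_bayes = TRUE,
                          uniform_ranges = list(PrC = 0.5, PcU = "peak_to_chance")) {
  structure(list(
    measures = measures, likelihood = match.arg(likelihood),
    strict_table1 = strict_table1,
    chauvenet_interpretation = chauvenet_interpretation,
    chance_alpha = chance_alpha, fine_alpha = fine_alpha,
    bf_upper = bf_upper, bf_lower = bf_lower, fine_times = fine_times,
    na_policy = na_policy, include_bayes = include_bayes,
    uniform_ranges = uniform_ranges
  ), class = "report_config")
}

#' Run the full analysis pipeline
#'
#' Applies the pre-registered exclusion order (trial-level blink filter,
#' participant-level rules, the measure-scope above-chance PcU screen,
#' then vector-scope Chauvenet outliers), computes all requested
#' measures, sham-normalizes them, forms the early-vs-late contrast per
#' measure, runs the one-sample t-test with Cohen's d, and — when
#' enabled — the three Bayes factors with both prior directions for the
#' half-normal family.  Fine-grained contrasts (default 30 ms vs 190 ms)
#' are computed only for measures whose coarse contrast passes the
#' reliability gate.
#'
#' @param trials A validated trial table (multi-participant).
#' @param config A [report_config()].
#' @return A `tmsight_report` list: `report` (one row per measure, the
#'   publication-style summary), `fine` (gated fine contrasts),
#'   `exclusions`, `contrasts`, `deltas`, `cells`, `log`, `config`.
#' @export
run_report <- function(trials, config = report_config()) {
  validate_trials(trials)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  n0 <- nrow(trials)
  trials <- blink_filter(trials)
  say("blink filter: %d of %d trials removed", n0 - nrow(trials), n0)

  excl <- participant_exclusions(trials)
  drop_pids <- unique(excl$participant_id[excl$excluded])
  if (length(drop_pids)) {
    say("participant-level exclusions: %s", paste(drop_pids, collapse = ", "))
    trials <- trials[!(trials$participant_id %in% drop_pids), , drop = FALSE]
  } else say("participant-level exclusions: none")

  cells <- measure_table(trials, measures = config$measures,
                         strict_table1 = config$strict_table1)

  ## measure-scope screen: baseline (sham, pooled over times) PcU above chance
  pcu_excluded <- character(0)
  if ("PcU" %in% config$measures) {
    for (pid in unique(trials$participant_id)) {
      sham <- trials[trials$participant_id == pid &
                       trials$tms_mode == "sham", , drop = FALSE]
      pc <- pcu(sham)
      if (!pc$defined) { pcu_excluded <- c(pcu_excluded, pid); next }
      ct <- chance_test_pcu(pc$value, pc$n, alpha = config$chance_alpha)
      if (ct$excluded) pcu_excluded <- c(pcu_excluded, pid)
    }
    say("above-chance PcU screen: %d participant(s) excluded from PcU analyses",
        length(pcu_excluded))
    if (length(pcu_excluded))
      excl <- rbind(excl, data.frame(
        participant_id = pcu_excluded, rule = "chance_pcu",
        scope = "measure_pcu_only", excluded = TRUE,
        detail = "baseline sham PcU not above chance",
        stringsAsFactors = FALSE))
  }

  deltas <- sham_normalize(cells)

  rows <- list(); contrasts <- list(); fine <- list()
  for (meas in config$measures) {
    d <- deltas
    if (meas == "PcU" && length(pcu_excluded))
      d <- d[!(d$participant_id %in% pcu_excluded), ]
    cv <- early_late_contrast(d, meas, na_policy = config$na_policy)
    out_idx <- if (length(cv$values) >= 3L)
      chauvenet(cv$values, interpretation = config$chauvenet_interpretation)
    else integer(0)
    n_out <- length(out_idx)
    if (n_out) {
      excl <- rbind(excl, data.frame(
        participant_id = names(cv$values)[out_idx], rule = "chauvenet",
        scope = "vector_point", excluded = TRUE,
        detail = sprintf("outlier on '%s'", cv$name),
        stringsAsFactors = FALSE))
      cv$values <- cv$values[-out_idx]
      cv$df <- length(cv$values) - 1L
    }
    contrasts[[meas]] <- cv
    tr <- one_sample_t(cv)

    bf <- bayes_block(cv, tr, d, meas, cells, config)
    rows[[meas]] <- data.frame(
      measure = meas, t = tr$t, p = tr$p, df = tr$df, mean = tr$mean,
      ci_low = tr$ci95[1], ci_high = tr$ci95[2], d = tr$cohens_d,
      bf_main_early = bf$main_early, bf_main_late = bf$main_late,
      bf_uni_early = bf$uni_early, bf_uni_late = bf$uni_late,
      bf_jzs = bf$jzs, n_outliers = n_out, n = tr$n,
      stringsAsFactors = FALSE)

    gate <- isTRUE(tr$p < config$fine_alpha) ||
      (is.finite(bf$main_early) &&
         (bf$main_early >= config$bf_upper || bf$main_early <= config$bf_lower)) ||
      (is.finite(bf$main_late) &&
         (bf$main_late >= config$bf_upper || bf$main_late <= config$bf_lower))
    if (gate) {
      fc <- fine_contrast(d, meas, config$fine_times[1], config$fine_times[2])
      fine[[meas]] <- list(contrast = fc, test = one_sample_t(fc))
      say("fine contrast computed for %s (%s vs %s)", meas,
          config$fine_times[1], config$fine_times[2])
    } else say("fine contrast gate closed for %s", meas)
  }

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, fine = fine, exclusions = excl,
                 contrasts = contrasts, deltas = deltas, cells = cells,
                 log = log, config = config),
            class = "tmsight_report")
}

## Bayes factors for one measure's early-vs-late contrast.
bayes_block <- function(cv, tr, deltas, meas, cells, config) {
  out <- list(main_early = NA_real_, main_late = NA_real_,
              uni_early = NA_real_, uni_late = NA_real_, jzs = NA_real_)
  if (!config$include_bayes || length(cv$values) < 3L) return(out)
  lik <- likelihood_summary(cv$values)

  ## orthogonal active/sham contrast (mean delta across all five times)
  d <- deltas[deltas$measure == meas, ]
  per_pid <- tapply(d$delta, d$participant_id, mean, na.rm = TRUE)
  orth <- mean(per_pid, na.rm = TRUE)
  prior_sd <- if (isTRUE(abs(orth) > 0)) abs(orth) / 2 else NA_real_
  if (is.finite(prior_sd)) {
    out$main_early <- bf_half_normal(lik, prior_sd, "negative",
                                     likelihood = config$likelihood)$bf
    out$main_late <- bf_half_normal(lik, prior_sd, "positive",
                                    likelihood = config$likelihood)$bf
  }

  rng <- config$uniform_ranges[[meas]]
  if (!is.null(rng)) {
    width <- if (identical(rng, "peak_to_chance")) {
      grp <- cells[cells$measure == meas, ]
      peak <- max(tapply(grp$value, paste(grp$tms_mode, grp$tms_time),
                         mean, na.rm = TRUE), na.rm = TRUE)
      peak - 0.5
    } else as.numeric(rng)
    if (is.finite(width) && width > 0) {
      out$uni_early <- bf_uniform(lik, -width, 0,
                                  likelihood = config$likelihood)$bf
      out$uni_late <- bf_uniform(lik, 0, width,
                                 likelihood = config$likelihood)$bf
    }
  }
  out$jzs <- bf_jzs(tr$t, tr$n)$bf
  out
}

#' @export
print.tmsight_report <- function(x, digits = 3, ...) {
  cat("tmsight report: early-vs-late temporal contrasts",
      "(sign convention early minus late)\n")
  print(format(x$report, digits = digits), row.names = FALSE)
  if (length(x$fine)) {
    cat("\nfine contrasts (gate open):\n")
    for (m in names(x$fine)) {
      cat(" ", x$fine[[m]]$contrast$name, ": ")
      print(x$fine[[m]]$test)
    }
  }
  invisible(x)
}
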