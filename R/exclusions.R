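#' Same-button strategy check on 'unseen' trials
#'
#' A participant who persistently presses the same left/right button while
#' reflectively unaware defeats the purpose of the unseen-discrimination
#' measure.  Unseen trials are those with "no" to both detection questions
#' (any stimulus).  Exclusion fires when one direction accounts for 75% or
#' more of unseen-trial responses (inclusive boundary).
#'
#' @param trials One participant's trial table.
#' @return List with `rate` (max one-direction proportion), `excluded`,
#'   `n_unseen`, and `flag` ("no_unseen_trials" when undefined).
#' @export
same_button_rate <- function(trials) {
  unseen <- trials$resp_arrow == "no" & trials$resp_something == "no"
  n <- sum(unseen, na.rm = TRUE)
  if (n == 0L)
    return(list(rate = NA_real_, excluded = FALSE, n_unseen = 0L,
                flag = "no_unseen_trials"))
  p_left <- mean(trials$resp_direction[which(unseen)] == "left")
  rate <- max(p_left, 1 - p_left)
  list(rate = rate, excluded = rate >= 0.75, n_unseen = n, flag = NA_character_)
}

#' All-negative responding under one experimental condition
#'
#' Responding "no" to every yes/no question under a whole condition (for
#' example, all active-TMS trials) indicates expectation-driven rather
#' than stimulus-driven responding.
#'
#' @param trials One participant's trial table.
#' @param tms_mode Condition to inspect (`"active"` or `"sham"`).
#' @return List with `all_negative` and `flag` ("empty_condition").
#' @export
all_negative <- function(trials, tms_mode = "active") {
  sub <- trials[trials$tms_mode == tms_mode, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(list(all_negative = FALSE, flag = "empty_condition"))
  list(all_negative = all(sub$resp_arrow == "no") &&
         all(sub$resp_something == "no"),
       flag = NA_character_)
}

#' Illogical-response rate
#'
#' Exclusion fires when illogical responses ("yes" to arrow?, "no" to
#' something?) occur on strictly more than 2.5% of trials.
#'
#' @param trials One participant's trial table.
#' @return List with `rate` and `excluded`.
#' @export
illogical_rate <- function(trials) {
  rate <- mean(is_illogical(trials), na.rm = TRUE)
  list(rate = rate, excluded = isTRUE(rate > 0.025))
}

#' Above-chance screen for unseen discrimination
#'
#' One-tailed z-test of PcU against chance (0.5) using the null binomial
#' standard error `sqrt(0.25 / n)`.  Participants whose baseline (sham)
#' PcU is not significantly above chance are excluded from PcU analyses
#' only — a participant without demonstrable residual capacity cannot
#' inform questions about its temporal dynamics.
#'
#' @param pcu_value Pooled sham PcU for one participant.
#' @param n_trials Number of trials contributing to that PcU.
#' @param alpha One-tailed alpha for retention (default 0.05).
#' @return List with `z`, `p` (one-tailed), `excluded`.
#' @export
chance_test_pcu <- function(pcu_value, n_trials, alpha = 0.05) {
  stopifnot(n_trials >= 1)
  z <- (pcu_value - 0.5) / sqrt(0.25 / n_trials)
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(z = z, p = p, excluded = p >= alpha)
}

#' Chauvenet's outlier criterion for an analysis vector
#'
#' Fits a normal distribution to the vector (sample mean and SD, candidate
#' points included) and excludes, in a single pass, every point whose
#' two-tailed exceedance probability multiplied by the number of points
#' falls below 0.5.  Applied per analysis vector: an exclusion here never
#' removes the participant from any other analysis.
#'
#' The classical reading of "likelihood" is the tail (exceedance)
#' probability; `interpretation = "density"` offers the alternative
#' reading — normal density at the point times n below 0.5 — for
#' sensitivity checks.
#'
#' @param x Numeric vector (n >= 3).
#' @param interpretation `"exceedance"` (classical) or `"density"`.
#' @return Integer vector of excluded indices (possibly empty), with
#'   attribute `flag = "zero_sd"` when the vector is degenerate.
#' @export
chauvenet <- function(x, interpretation = c("exceedance", "density")) {
  interpretation <- match.arg(interpretation)
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 3L)
  mu <- mean(x); sdv <- stats::sd(x)
  if (!is.finite(sdv) || sdv == 0)
    return(structure(integer(0), flag = "zero_sd"))
  crit <- if (interpretation == "exceedance") {
    2 * stats::pnorm(abs(x - mu) / sdv, lower.tail = FALSE)
  } else {
    stats::dnorm(x, mu, sdv) * sdv        # standardized density
  }
  which(crit * n < 0.5)
}

#' Remove blink-contaminated trials
#'
#' A blink is identified by a shift in pupil position greater than 1
#' degree followed by a transitory (under 1 s, but non-zero) loss of the
#' pupil signal, coincident with stimulus presentation.  Either a
#' precomputed `blink` flag on the trial table or a `pupil_events` table
#' (columns `shift_deg`, `loss_s`, `coincident`, row-aligned with
#' `trials`) can drive the rule.
#'
#' @param trials A trial table.
#' @param pupil_events Optional per-trial pupil summary.
#' @return The retained trials (blink trials removed).
#' @export
blink_filter <- function(trials, pupil_events = NULL) {
  if (is.null(pupil_events)) {
    drop <- isTRUE_vec(trials$blink)
  } else {
    stopifnot(nrow(pupil_events) == nrow(trials))
    drop <- pupil_events$shift_deg > 1.0 &
      pupil_events$loss_s > 0 & pupil_events$loss_s < 1.0 &
      isTRUE_vec(pupil_events$coincident)
  }
  trials[!drop, , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Participant-level exclusion report
#'
#' Applies the participant-scope rules (same-button strategy,
#' all-negative responding, illogical-response rate) to every participant
#' and reports each firing with its triggering statistic.  Measure-scope
#' (above-chance PcU) and vector-scope (Chauvenet) rules are applied
#' inside [run_report()], where their narrower scope lives.
#'
#' @param trials A validated multi-participant trial table.
#' @return A data.frame with columns `participant_id`, `rule`, `scope`,
#'   `excluded`, `detail` — one row per participant x rule evaluated.
#' @export
participant_exclusions <- function(trials) {
  out <- lapply(split(trials, trials$participant_id), function(tt) {
    pid <- tt$participant_id[1]
    sb <- same_button_rate(tt)
    an <- all_negative(tt, "active")
    il <- illogical_rate(tt)
    data.frame(
      participant_id = pid,
      rule = c("same_button", "all_negative", "illogical_rate"),
      scope = "participant_all",
      excluded = c(sb$excluded, an$all_negative, il$excluded),
      detail = c(
        sprintf("max same-direction rate %.3f on %d unseen trials%s",
                sb$rate, sb$n_unseen,
                ifelse(is.na(sb$flag), "", paste0(" [", sb$flag, "]"))),
        sprintf("all-negative under active TMS: %s%s", an$all_negative,
                ifelse(is.na(an$flag), "", paste0(" [", an$flag, "]"))),
        sprintf("illogical rate %.4f", il$rate)),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
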