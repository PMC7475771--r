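#' Classify trials into signal detection classes
#'
#' The primary conscious-detection scheme (`"PrC"`) follows the published
#' allocation table verbatim.  Response columns are the answers to the
#' "something?" and "arrow?" questions:
#'
#' | stimulus  | something? | arrow? | class |
#' |-----------|------------|--------|-------|
#' | arrow     | yes        | yes    | HIT   |
#' | arrow     | no         | no     | MISS  |
#' | non-arrow | yes        | yes    | FA    |
#' | non-arrow | yes        | no     | CR    |
#' | absent    | yes        | yes    | FA    |
#' | absent    | yes        | no     | FA    |
#' | absent    | no         | no     | CR    |
#'
#' A non-arrow answered "yes/no" counts as a correct rejection, not a hit,
#' because participants treat the task as detection of the *arrow*.
#' Combinations absent from the table (arrow with something = yes, arrow =
#' no; non-arrow with a double "no") map to `UNCLASSIFIED` under the
#' literal reading; `strict_table1 = FALSE` completes them permissively
#' (MISS and CR respectively) for sensitivity analysis.  The illogical
#' pattern (arrow? = yes, something? = no) maps to `ILLOGICAL` under every
#' scheme and never enters a measure denominator.
#'
#' Question-specific schemes use a single question against its own signal
#' definition: `"PrA"` scores arrow-present trials as signal via the
#' arrow? response, with stimulus-absent trials supplying false alarms and
#' correct rejections (non-arrow trials are unclassified); `"PrS"` scores
#' arrow and non-arrow trials as signal via the something? response, again
#' with absent trials as the noise class.
#'
#' @param stimulus,resp_something,resp_arrow Character vectors (recycled).
#' @param scheme `"PrC"`, `"PrA"` or `"PrS"`.
#' @param strict_table1 Literal reading of the allocation table?
#' @return Character vector of classes
#'   (`HIT`/`MISS`/`FA`/`CR`/`UNCLASSIFIED`/`ILLOGICAL`).
#' @export
classify_trials <- function(stimulus, resp_something, resp_arrow,
                            scheme = c("PrC", "PrA", "PrS"),
                            strict_table1 = TRUE) {
  scheme <- match.arg(scheme)
  n <- max(length(stimulus), length(resp_something), length(resp_arrow))
  stimulus <- rep_len(stimulus, n)
  resp_something <- rep_len(resp_something, n)
  resp_arrow <- rep_len(resp_arrow, n)
  out <- rep("UNCLASSIFIED", n)

  yy <- resp_something == "yes" & resp_arrow == "yes"
  yn <- resp_something == "yes" & resp_arrow == "no"
  nn <- resp_something == "no" & resp_arrow == "no"
  illogical <- resp_something == "no" & resp_arrow == "yes"
  arrow <- stimulus %in% ARROW_STIMULI
  nonarrow <- stimulus == "non_arrow"
  absent <- stimulus == "absent"

  if (scheme == "PrC") {
    out[arrow & yy] <- "HIT"
    out[arrow & nn] <- "MISS"
    out[nonarrow & yy] <- "FA"
    out[nonarrow & yn] <- "CR"
    out[absent & (yy | yn)] <- "FA"
    out[absent & nn] <- "CR"
    if (!strict_table1) {
      out[arrow & yn] <- "MISS"     # saw something but not the arrow
      out[nonarrow & nn] <- "CR"    # denied everything, nothing to detect
    }
  } else if (scheme == "PrA") {
    ans_yes <- resp_arrow == "yes"
    out[arrow & ans_yes] <- "HIT"
    out[arrow & !ans_yes] <- "MISS"
    out[absent & ans_yes] <- "FA"
    out[absent & !ans_yes] <- "CR"
  } else {                          # PrS
    ans_yes <- resp_something == "yes"
    signal <- arrow | nonarrow
    out[signal & ans_yes] <- "HIT"
    out[signal & !ans_yes] <- "MISS"
    out[absent & ans_yes] <- "FA"
    out[absent & !ans_yes] <- "CR"
  }
  out[illogical] <- "ILLOGICAL"
  out[is.na(stimulus) | is.na(resp_something) | is.na(resp_arrow)] <- NA
  out
}

#' Tally signal detection counts for a set of trials
#'
#' @param trials A trial table (one analysis cell, or any subset).
#' @inheritParams classify_trials
#' @return An `sdt_counts` object: hits, misses, fas, crs, unclassified
#'   (which includes illogical trials — they enter no class).
#' @export
sdt_counts <- function(trials, scheme = "PrC", strict_table1 = TRUE) {
  cls <- classify_trials(trials$stimulus, trials$resp_something,
                         trials$resp_arrow, scheme = scheme,
                         strict_table1 = strict_table1)
  structure(list(
    hits = sum(cls == "HIT"), misses = sum(cls == "MISS"),
    fas = sum(cls == "FA"), crs = sum(cls == "CR"),
    unclassified = sum(cls %in% c("UNCLASSIFIED", "ILLOGICAL")),
    scheme = scheme
  ), class = "sdt_counts")
}

#' Hit and false alarm rates from raw counts
#'
#' `hit_rate = hits / (hits + misses)`, `fa_rate = fas / (fas + crs)`.
#' No smoothing constant is ever added: an empty denominator yields `NA`
#' with `defined = FALSE` rather than an adjusted rate, keeping the
#' non-parametric measures free of analyst-generated pseudo-responses.
#'
#' @param counts An [sdt_counts()] object or a list with fields
#'   `hits`, `misses`, `fas`, `crs`.
#' @return List with `hit_rate`, `fa_rate`, `defined`.
#' @export
sdt_rates <- function(counts) {
  hr <- if (counts$hits + counts$misses > 0)
    counts$hits / (counts$hits + counts$misses) else NA_real_
  far <- if (counts$fas + counts$crs > 0)
    counts$fas / (counts$fas + counts$crs) else NA_real_
  list(hit_rate = hr, fa_rate = far, defined = !is.na(hr) && !is.na(far))
}

#' Non-parametric sensitivity: Pr = hit rate - false alarm rate
#'
#' @param hit_rate,fa_rate Rates in \[0, 1\]; `NA` propagates.
#' @return Pr in \[-1, 1\].
#' @export
pr_sensitivity <- function(hit_rate, fa_rate) hit_rate - fa_rate

#' Non-parametric criterion: Br = false alarm rate / (1 - Pr)
#'
#' Higher Br means a more liberal criterion (more "yes" reports regardless
#' of the stimulus).  Undefined (NA) when Pr = 1: the denominator is zero.
#'
#' @param fa_rate False alarm rate.
#' @param pr Matching Pr value.
#' @return Br >= 0, or `NA` when undefined.
#' @export
br_criterion <- function(fa_rate, pr) {
  ifelse(!is.na(pr) & pr >= 1, NA_real_, fa_rate / (1 - pr))
}

#' 'Unseen' discrimination capacity (PcU)
#'
#' Proportion of correct left/right judgements restricted to arrow-present
#' trials on which the participant denied awareness twice ("no" to both
#' the arrow? and something? questions).  Above-chance PcU (> 0.5) is the
#' signature of residual capacity without reported awareness.
#'
#' @param trials A trial table (one analysis cell).
#' @return List with `value`, `n` (qualifying trials), `defined`.
#' @export
pcu <- function(trials) {
  qual <- trials$resp_arrow == "no" & trials$resp_something == "no" &
    trials$stimulus %in% ARROW_STIMULI
  n <- sum(qual, na.rm = TRUE)
  if (n == 0L) return(list(value = NA_real_, n = 0L, defined = FALSE))
  correct <- direction_correct(trials$stimulus[which(qual)],
                               trials$resp_direction[which(qual)])
  list(value = mean(correct), n = n, defined = TRUE)
}

direction_correct <- function(stimulus, resp_direction) {
  truth <- ifelse(stimulus == "arrow_left", "left",
                  ifelse(stimulus == "arrow_right", "right", NA))
  resp_direction == truth
}

#' Detection-without-identification measure (PCm)
#'
#' Numerator: trials on which awareness was acknowledged on both detection
#' questions ("yes"/"yes") but the left/right judgement was wrong — the
#' response profile of reported phenomenal awareness without access.
#' Denominator: all arrow-present trials in the cell.  Alternative
#' numerator/denominator predicates (functions of the trial table
#' returning a logical vector) can be supplied to explore measure
#' variants without changing the default.
#'
#' @param trials A trial table (one analysis cell).
#' @param numerator,denominator Optional predicate functions.
#' @return List with `value`, `n` (denominator trials), `defined`.
#' @export
pcm <- function(trials, numerator = NULL, denominator = NULL) {
  den <- if (is.null(denominator))
    trials$stimulus %in% ARROW_STIMULI & !is_illogical(trials)
  else denominator(trials)
  n <- sum(den, na.rm = TRUE)
  if (n == 0L) return(list(value = NA_real_, n = 0L, defined = FALSE))
  num <- if (is.null(numerator)) {
    trials$resp_arrow == "yes" & trials$resp_something == "yes" &
      trials$stimulus %in% ARROW_STIMULI &
      !direction_correct(trials$stimulus, trials$resp_direction)
  } else numerator(trials)
  list(value = sum(num, na.rm = TRUE) / n, n = n, defined = TRUE)
}

#' Parametric sensitivity and criterion (d', c)
#'
#' Classical equal-variance Gaussian measures from the same counts,
#' provided for comparison with the primary non-parametric measures.
#' Extreme rates are clamped to \[1/(2N), 1 - 1/(2N)\] per rate (N being
#' that rate's trial count) so the normal quantiles stay finite; the
#' non-parametric measures need no such correction.
#'
#' @param counts An [sdt_counts()] object.
#' @return List with `dprime`, `c`, `defined`.
#' @export
dprime_c <- function(counts) {
  r <- sdt_rates(counts)
  if (!r$defined) return(list(dprime = NA_real_, c = NA_real_,
                              defined = FALSE))
  n_sig <- counts$hits + counts$misses
  n_noise <- counts$fas + counts$crs
  hr <- min(max(r$hit_rate, 1 / (2 * n_sig)), 1 - 1 / (2 * n_sig))
  far <- min(max(r$fa_rate, 1 / (2 * n_noise)), 1 - 1 / (2 * n_noise))
  zh <- stats::qnorm(hr); zf <- stats::qnorm(far)
  list(dprime = zh - zf, c = -(zh + zf) / 2, defined = TRUE)
}

#' Per-cell table of derived measures
#'
#' Computes every requested measure for each participant x TMS-mode x
#' TMS-time cell and returns a tidy table.  Trials flagged as blinks and
#' illogical trials never enter a measure (illogical trials contribute to
#' no SDT class and are excluded from the PcU/PCm numerators and
#' denominators); upstream participant-level exclusions are the caller's
#' responsibility (see [run_report()]).
#'
#' @param trials A validated trial table.
#' @param measures Character vector drawn from
#'   `c("PrC","BrC","PrA","BrA","PrS","BrS","PcU","PCm","dprime","c")`.
#' @param strict_table1 Passed to [classify_trials()].
#' @param pcm_numerator,pcm_denominator Optional PCm predicates.
#' @param drop_blinks Remove trials with `blink = TRUE` first?
#' @return A data.frame with columns `participant_id`, `tms_mode`,
#'   `tms_time`, `measure`, `value`, `n`, `defined`.  `n` is the number of
#'   trials in the relevant denominator (signal trials for Pr, noise
#'   trials for Br, qualifying trials for PcU, arrow trials for PCm).
#' @export
measure_table <- function(trials,
                          measures = c("PrC", "BrC", "PrA", "BrA",
                                       "PrS", "BrS", "PcU", "PCm"),
                          strict_table1 = TRUE,
                          pcm_numerator = NULL, pcm_denominator = NULL,
                          drop_blinks = TRUE) {
  stopifnot(all(measures %in% MEASURES))
  if (drop_blinks) trials <- trials[!trials$blink, , drop = FALSE]
  cell <- interaction(trials$participant_id, trials$tms_mode,
                      trials$tms_time, drop = TRUE, lex.order = TRUE,
                      sep = "\r")

  ## indicator matrix -> one rowsum() pass gives all counts per cell
  ind <- cell_indicators(trials, strict_table1,
                         pcm_numerator, pcm_denominator)
  counts <- rowsum(ind, cell)
  key <- do.call(rbind, strsplit(rownames(counts), "\r", fixed = TRUE))
  out <- lapply(measures, function(m)
    measure_from_counts(m, counts, key))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

cell_indicators <- function(trials, strict_table1,
                            pcm_numerator, pcm_denominator) {
  ind <- matrix(0, nrow(trials), 0)
  for (scheme in c("PrC", "PrA", "PrS")) {
    cls <- classify_trials(trials$stimulus, trials$resp_something,
                           trials$resp_arrow, scheme = scheme,
                           strict_table1 = strict_table1)
    for (k in c("HIT", "MISS", "FA", "CR")) {
      ind <- cbind(ind, as.numeric(cls == k))
      colnames(ind)[ncol(ind)] <- paste0(scheme, "_", k)
    }
  }
  dd <- trials$resp_arrow == "no" & trials$resp_something == "no" &
    trials$stimulus %in% ARROW_STIMULI
  corr <- direction_correct(trials$stimulus, trials$resp_direction)
  pcm_den <- if (is.null(pcm_denominator))
    trials$stimulus %in% ARROW_STIMULI & !is_illogical(trials)
  else pcm_denominator(trials)
  pcm_num <- if (is.null(pcm_numerator)) {
    trials$resp_arrow == "yes" & trials$resp_something == "yes" &
      trials$stimulus %in% ARROW_STIMULI & !corr
  } else pcm_numerator(trials)
  ind <- cbind(ind,
               pcu_n = as.numeric(dd),
               pcu_correct = as.numeric(dd & corr),
               pcm_den = as.numeric(pcm_den),
               pcm_num = as.numeric(pcm_num))
  ind
}

## Turn the per-cell count matrix into tidy rows for one measure.
measure_from_counts <- function(measure, counts, key) {
  base <- data.frame(participant_id = key[, 1], tms_mode = key[, 2],
                     tms_time = key[, 3], measure = measure,
                     stringsAsFactors = FALSE)
  scheme <- switch(measure,
                   PrC = , BrC = , dprime = , c = "PrC",
                   PrA = , BrA = "PrA", PrS = , BrS = "PrS", NA)
  if (!is.na(scheme)) {
    h <- counts[, paste0(scheme, "_HIT")]
    m <- counts[, paste0(scheme, "_MISS")]
    f <- counts[, paste0(scheme, "_FA")]
    cr <- counts[, paste0(scheme, "_CR")]
    hr <- ifelse(h + m > 0, h / (h + m), NA_real_)
    far <- ifelse(f + cr > 0, f / (f + cr), NA_real_)
    pr <- hr - far
    if (measure %in% c("PrC", "PrA", "PrS")) {
      base$value <- pr; base$n <- as.integer(h + m)
    } else if (measure %in% c("BrC", "BrA", "BrS")) {
      base$value <- ifelse(!is.na(pr) & pr >= 1, NA_real_, far / (1 - pr))
      base$n <- as.integer(f + cr)
    } else {                         # dprime / c with the clamping rule
      hc <- pmin(pmax(hr, 1 / (2 * (h + m))), 1 - 1 / (2 * (h + m)))
      fc <- pmin(pmax(far, 1 / (2 * (f + cr))), 1 - 1 / (2 * (f + cr)))
      base$value <- if (measure == "dprime") stats::qnorm(hc) - stats::qnorm(fc)
                    else -(stats::qnorm(hc) + stats::qnorm(fc)) / 2
      base$n <- as.integer(h + m + f + cr)
    }
  } else if (measure == "PcU") {
    n <- counts[, "pcu_n"]
    base$value <- ifelse(n > 0, counts[, "pcu_correct"] / n, NA_real_)
    base$n <- as.integer(n)
  } else {                            # PCm
    n <- counts[, "pcm_den"]
    base$value <- ifelse(n > 0, counts[, "pcm_num"] / n, NA_real_)
    base$n <- as.integer(n)
  }
  base$defined <- !is.na(base$value)
  base
}
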