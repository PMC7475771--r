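#' Zero TMS effect map
#'
#' @return Named list (one element per TMS-time condition) of
#'   `list(d_signal = 0, d_criteria = 0, d_direction = 0)`.
#' @export
zero_tms_effects <- function() {
  eff <- lapply(TMS_TIMES, function(t)
    list(d_signal = 0, d_criteria = 0, d_direction = 0))
  names(eff) <- TMS_TIMES
  eff
}

#' TMS effect map emulating the study's qualitative signature
#'
#' Additive effects on the evidence mean (`d_signal`, sensitivity), on
#' both report criteria (`d_criteria`; negative = more liberal) and on
#' the left/right channel d' (`d_direction`), applied on active-TMS
#' trials only.  The default emulates the reported pattern: a masking
#' pulse that suppresses detection on every active condition, stronger
#' sensitivity suppression at the early onsets (30/70 ms), and a
#' criterion shift dominated by the late onsets (150/190 ms).
#'
#' @param bip,early30,early70,late150,late190 Per-condition effect
#'   triplets `c(d_signal, d_criteria, d_direction)`.
#' @return Named effect map suitable for [observer_params()].
#' @export
tms_effects_signature <- function(bip = c(-0.239, 0, -0.385),
                                  early30 = c(-0.426, 0, -0.503),
                                  early70 = c(-0.321, 0, -0.304),
                                  late150 = c(-0.300, -0.10, -0.263),
                                  late190 = c(-0.280, -0.15, -0.178)) {
  as_eff <- function(v) list(d_signal = v[1], d_criteria = v[2],
                             d_direction = v[3])
  list(BIP_only = as_eff(bip), E30_BIP = as_eff(early30),
       E70_BIP = as_eff(early70), BIP_L150 = as_eff(late150),
       BIP_L190 = as_eff(late190))
}

#' Parameters of the generative observer
#'
#' A data-shape emulator of a participant performing the task, not a
#' brain model.  Detection: a single evidence sample
#' `e ~ Normal(strength, 1)` per trial (strength 0 on stimulus-absent
#' trials) is compared against two criteria; "something?" is answered yes
#' when `e > criterion_something` and "arrow?" when
#' `e > criterion_arrow`.  Requiring
#' `criterion_arrow >= criterion_something` guarantees logically ordered
#' answers; lapses (each response flipped independently with
#' `lapse_rate`) generate the residual illogical responses.
#' Discrimination: an independent left/right channel answers correctly
#' with probability `pnorm(direction_sensitivity / sqrt(2))` — the
#' simplest structure that yields above-chance 'unseen' discrimination
#' whenever `direction_sensitivity > 0`, independent of the detection
#' state.  On active trials the `tms_effects` triplet of the trial's
#' TMS-time condition is added: `d_signal` to the evidence mean of
#' stimulus-present trials, `d_criteria` to both criteria, `d_direction`
#' to the direction-channel d' (floored at 0).
#'
#' @param signal_strength Arrow evidence mean, in evidence SD units;
#'   the default is calibrated to a sham PrC of about 0.5.
#' @param nonarrow_strength Evidence mean of the non-arrow stimulus.
#' @param criterion_something,criterion_arrow Report criteria.
#' @param direction_sensitivity d' of the left/right channel; the default
#'   puts baseline (sham) 'unseen' accuracy near 0.74, which the default
#'   masking-pulse effect suppresses to about 0.65.
#' @param lapse_rate Per-response flip probability, in \[0, 0.05\].
#' @param blink_rate Per-trial probability of a blink flag.
#' @param tms_effects Effect map, see [tms_effects_signature()].
#' @return An `observer_params` object.
#' @export
observer_params <- function(signal_strength = 2.1436,
                            nonarrow_strength = 0.8,
                            criterion_something = 1.6,
                            criterion_arrow = 2.0,
                            direction_sensitivity = 0.954,
                            lapse_rate = 0.02,
                            blink_rate = 0.002,
                            tms_effects = zero_tms_effects()) {
  stopifnot(signal_strength >= 0, nonarrow_strength >= 0,
            criterion_arrow >= criterion_something,
            lapse_rate >= 0, lapse_rate <= 0.05,
            direction_sensitivity >= 0,
            all(TMS_TIMES %in% names(tms_effects)))
  structure(list(signal_strength = signal_strength,
                 nonarrow_strength = nonarrow_strength,
                 criterion_something = criterion_something,
                 criterion_arrow = criterion_arrow,
                 direction_sensitivity = direction_sensitivity,
                 lapse_rate = lapse_rate, blink_rate = blink_rate,
                 tms_effects = tms_effects),
            class = "observer_params")
}

## Effective parameters for one (mode, time) cell.
effective_params <- function(params, tms_mode, tms_time) {
  eff <- if (tms_mode == "active") params$tms_effects[[tms_time]]
         else list(d_signal = 0, d_criteria = 0, d_direction = 0)
  list(signal = params$signal_strength + eff$d_signal,
       nonarrow = params$nonarrow_strength + eff$d_signal,
       c_s = params$criterion_something + eff$d_criteria,
       c_a = params$criterion_arrow + eff$d_criteria,
       d_dir = max(params$direction_sensitivity + eff$d_direction, 0))
}

#' Expected (analytic) measures for one condition cell
#'
#' Closed Gaussian-tail forms for the expected hit/false-alarm rates and
#' derived measures of the generative observer, lapses included — the
#' joint response distribution mixes the three latent evidence states
#' with independent per-response flips.  Serves as the calibration target
#' and as an oracle for Monte-Carlo agreement checks.
#'
#' @param params An [observer_params()].
#' @param tms_mode,tms_time Condition cell.
#' @return List: `hit_rate`, `fa_rate`, `prc`, `brc`, `pcu`,
#'   `p_illogical` (per-trial probability of an illogical pattern,
#'   averaged over the stimulus mix).
#' @export
expected_measures <- function(params, tms_mode = "sham",
                              tms_time = "BIP_only") {
  ep <- effective_params(params, tms_mode, tms_time)
  lam <- params$lapse_rate
  ## joint response distribution for one stimulus with evidence mean mu:
  ## rows = (something, arrow) in {yy, yn, ny, nn}
  joint <- function(mu) {
    p_hi <- stats::pnorm(ep$c_a, mu, 1, lower.tail = FALSE)  # e > c_a
    p_lo <- stats::pnorm(ep$c_s, mu, 1)                      # e <= c_s
    p_mid <- 1 - p_hi - p_lo                                 # c_s < e <= c_a
    flip <- function(p_yes) c(yes = p_yes * (1 - lam) + (1 - p_yes) * lam)
    ## state-wise (something_yes, arrow_yes): hi=(1,1), mid=(1,0), lo=(0,0)
    states <- rbind(hi = c(1, 1), mid = c(1, 0), lo = c(0, 0))
    w <- c(hi = p_hi, mid = p_mid, lo = p_lo)
    out <- c(yy = 0, yn = 0, ny = 0, nn = 0)
    for (s in rownames(states)) {
      ps <- flip(states[s, 1]); pa <- flip(states[s, 2])
      out <- out + w[s] * c(yy = ps * pa, yn = ps * (1 - pa),
                            ny = (1 - ps) * pa, nn = (1 - ps) * (1 - pa))
    }
    out
  }
  ja <- joint(ep$signal); jn <- joint(ep$nonarrow); j0 <- joint(0)
  ## classification: arrow yy=HIT nn=MISS; non-arrow yy=FA yn=CR;
  ## absent yy,yn=FA nn=CR; ny is illogical everywhere
  hit_rate <- ja[["yy"]] / (ja[["yy"]] + ja[["nn"]])
  fa <- jn[["yy"]] + j0[["yy"]] + j0[["yn"]]
  cr <- jn[["yn"]] + j0[["nn"]]
  fa_rate <- fa / (fa + cr)
  prc <- hit_rate - fa_rate
  brc <- if (prc < 1) fa_rate / (1 - prc) else NA_real_
  p_dir <- stats::pnorm(ep$d_dir / sqrt(2))
  pcu_exp <- p_dir * (1 - lam) + (1 - p_dir) * lam   # lapse flips direction
  ## stimulus mix: arrow .5, non-arrow .25, absent .25
  p_illogical <- 0.5 * ja[["ny"]] + 0.25 * jn[["ny"]] + 0.25 * j0[["ny"]]
  list(hit_rate = hit_rate, fa_rate = fa_rate, prc = prc, brc = brc,
       pcu = pcu_exp, p_illogical = p_illogical)
}

#' Calibrate the arrow strength to a target baseline PrC
#'
#' Mirrors the luminance-calibration procedure: monotone bisection on
#' `signal_strength` until the expected sham PrC is within `tol` of the
#' target.  (In the laboratory the dial is target luminance and the
#' function is estimated psychometrically; here the analytic expectation
#' stands in for the psychometric fit.)
#'
#' @param params An [observer_params()]; all fields except
#'   `signal_strength` are held fixed.
#' @param target_prc Target baseline PrC (default 0.5, threshold level).
#' @param tol Acceptable |PrC - target| (default 0.01).
#' @param bracket Search interval for the strength.
#' @return The calibrated `signal_strength`.
#' @export
calibrate_signal <- function(params, target_prc = 0.5, tol = 0.01,
                             bracket = c(0, 8)) {
  prc_at <- function(s) {
    p <- params; p$signal_strength <- s
    expected_measures(p, "sham", "BIP_only")$prc
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (target_prc < prc_at(lo) - tol || target_prc > prc_at(hi) + tol)
    stop(sprintf("target PrC %.3f is infeasible in bracket [%g, %g] (range %.3f..%.3f)",
                 target_prc, lo, hi, prc_at(lo), prc_at(hi)))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    v <- prc_at(mid)
    if (abs(v - target_prc) <= tol) return(mid)
    if (v < target_prc) lo <- mid else hi <- mid
  }
  stop("calibration did not converge")
}

#' Simulate responses for a design
#'
#' Fills the response and blink columns of a design skeleton according to
#' the generative model in [observer_params()].  Vectorized over trials;
#' deterministic given the RNG state (callers seed via
#' [simulate_cohort()] or `withr::with_seed`).
#'
#' @param params An [observer_params()].
#' @param design A trial table from [generate_design()] (responses may be
#'   `NA`; they are overwritten).
#' @return The completed trial table.
#' @export
simulate_trials <- function(params, design) {
  n <- nrow(design)
  eff <- params$tms_effects
  idx <- match(design$tms_time, TMS_TIMES)
  active <- design$tms_mode == "active"
  eff_vec <- function(field)
    vapply(TMS_TIMES, function(t) eff[[t]][[field]], numeric(1))
  d_sig <- ifelse(active, eff_vec("d_signal")[idx], 0)
  d_cri <- ifelse(active, eff_vec("d_criteria")[idx], 0)
  d_dir <- ifelse(active, eff_vec("d_direction")[idx], 0)

  arrow <- design$stimulus %in% ARROW_STIMULI
  present <- design$stimulus != "absent"
  mu <- ifelse(arrow, params$signal_strength,
               ifelse(design$stimulus == "non_arrow",
                      params$nonarrow_strength, 0))
  mu <- ifelse(present, pmax(mu + d_sig, 0), 0)
  e <- stats::rnorm(n, mu, 1)
  c_s <- params$criterion_something + d_cri
  c_a <- params$criterion_arrow + d_cri
  resp_something <- e > c_s
  resp_arrow <- e > c_a

  d_eff <- pmax(params$direction_sensitivity + d_dir, 0)
  correct <- stats::runif(n) < stats::pnorm(d_eff / sqrt(2))
  truth <- ifelse(design$stimulus == "arrow_left", "left",
                  ifelse(design$stimulus == "arrow_right", "right", NA))
  resp_direction <- ifelse(arrow,
                           ifelse(correct, truth,
                                  ifelse(truth == "left", "right", "left")),
                           sample(DIRECTIONS, n, replace = TRUE))

  ## independent lapses flip each response
  lam <- params$lapse_rate
  flip1 <- stats::runif(n) < lam
  flip2 <- stats::runif(n) < lam
  flip3 <- stats::runif(n) < lam
  resp_something <- xor(resp_something, flip1)
  resp_arrow <- xor(resp_arrow, flip2)
  resp_direction <- ifelse(flip3,
                           ifelse(resp_direction == "left", "right", "left"),
                           resp_direction)

  design$resp_something <- ifelse(resp_something, "yes", "no")
  design$resp_arrow <- ifelse(resp_arrow, "yes", "no")
  design$resp_direction <- resp_direction
  design$blink <- stats::runif(n) < params$blink_rate
  design
}

#' Simulate a cohort of observers
#'
#' Draws per-participant parameters around `params` (independent normal
#' deviations; criteria shift jointly so their ordering is preserved),
#' generates each participant's factorial design, and simulates all
#' responses.  Fully deterministic under `seed`.
#'
#' @param n_participants Cohort size.
#' @param params Population-level [observer_params()].
#' @param design Optional [design_spec()]; defaults to the standard
#'   12 + 12 blocks of 80 trials.  Its `n_participants`/`seed` fields are
#'   overridden by this function's arguments.
#' @param between SDs of the between-participant deviations:
#'   `signal`, `criterion` (a joint shift of both criteria),
#'   `direction`.
#' @param seed Integer seed.
#' @return List with `trials` (the full cohort trial table) and
#'   `participants` (a data.frame logging each drawn parameter set).
#' @export
simulate_cohort <- function(n_participants, params = observer_params(),
                            design = NULL,
                            between = list(signal = 0.15, criterion = 0.15,
                                           direction = 0.25),
                            seed = 1L) {
  if (is.null(design)) design <- design_spec()
  spec <- design_spec(n_participants = n_participants,
                      blocks_active = design$blocks_active,
                      blocks_sham = design$blocks_sham,
                      trials_per_block = design$trials_per_block,
                      reps_per_condition = design$reps_per_condition,
                      seed = seed)
  withr::with_seed(seed, {
    skeleton <- generate_design(spec)
    pids <- unique(skeleton$participant_id)
    plog <- vector("list", length(pids))
    parts <- vector("list", length(pids))
    for (i in seq_along(pids)) {
      p <- params
      p$signal_strength <- max(params$signal_strength +
                                 stats::rnorm(1, 0, between$signal), 0.05)
      shift <- stats::rnorm(1, 0, between$criterion)
      p$criterion_something <- params$criterion_something + shift
      p$criterion_arrow <- params$criterion_arrow + shift
      p$direction_sensitivity <- max(params$direction_sensitivity +
                                       stats::rnorm(1, 0, between$direction), 0)
      sub <- skeleton[skeleton$participant_id == pids[i], , drop = FALSE]
      parts[[i]] <- simulate_trials(p, sub)
      plog[[i]] <- data.frame(
        participant_id = pids[i],
        signal_strength = p$signal_strength,
        criterion_something = p$criterion_something,
        criterion_arrow = p$criterion_arrow,
        direction_sensitivity = p$direction_sensitivity,
        lapse_rate = p$lapse_rate, stringsAsFactors = FALSE)
    }
    trials <- do.call(rbind, parts)
    rownames(trials) <- NULL
    list(trials = trials, participants = do.call(rbind, plog))
  })
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates cohorts under a known TMS effect map and runs the
#' measurement pipeline (measures, sham normalization, early-vs-late
#' contrast, one-sample t-test) on each, summarizing how often each
#' contrast's sign and significance recover the generating truth.  Bayes
#' factors are skipped here: sign and p-value recovery are the targets.
#'
#' @param true_effects TMS effect map (see [tms_effects_signature()]).
#' @param n_cohorts Number of simulated cohorts.
#' @param n_participants Cohort size.
#' @param params Baseline [observer_params()] (its `tms_effects` are
#'   replaced by `true_effects`).
#' @param design Optional [design_spec()].
#' @param measures Measures to track.
#' @param alpha Significance level for the recovery tally.
#' @param seed Integer seed; cohort c uses `seed + c`.
#' @return List with `per_cohort` (measure, cohort, mean, t, p) and
#'   `summary` (per measure: proportion of negative means, proportion
#'   significantly negative, proportion with p < alpha of either sign,
#'   mean contrast).
#' @export
recovery_experiment <- function(true_effects, n_cohorts = 20,
                                n_participants = 40,
                                params = observer_params(),
                                design = NULL,
                                measures = c("PrC", "PcU", "BrC"),
                                alpha = 0.05, seed = 1L) {
  params$tms_effects <- true_effects
  rows <- vector("list", n_cohorts * length(measures))
  k <- 0L
  for (cohort in seq_len(n_cohorts)) {
    sim <- simulate_cohort(n_participants, params = params, design = design,
                           seed = seed + cohort)
    cells <- measure_table(sim$trials, measures = measures)
    deltas <- sham_normalize(cells)
    for (m in measures) {
      cv <- early_late_contrast(deltas, m)
      tr <- one_sample_t(cv)
      k <- k + 1L
      rows[[k]] <- data.frame(cohort = cohort, measure = m,
                              mean = tr$mean, t = tr$t, p = tr$p,
                              stringsAsFactors = FALSE)
    }
  }
  per_cohort <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(measures, function(m) {
    d <- per_cohort[per_cohort$measure == m, ]
    data.frame(measure = m,
               prop_negative = mean(d$mean < 0),
               prop_sig_negative = mean(d$p < alpha & d$mean < 0),
               prop_sig = mean(d$p < alpha),
               mean_contrast = mean(d$mean),
               stringsAsFactors = FALSE)
  }))
  list(per_cohort = per_cohort, summary = summ)
}
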