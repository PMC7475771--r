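# Small deterministic fixtures built in code.

# One fully-specified trial row; override any field.
make_trial <- function(stimulus = "arrow_left", resp_arrow = "no",
                       resp_something = "no", resp_direction = "left",
                       tms_mode = "sham", tms_time = "BIP_only",
                       participant_id = "P01", block_index = 1L,
                       question_order = 1L, blink = FALSE) {
  data.frame(participant_id = participant_id, block_index = block_index,
             tms_mode = tms_mode, tms_time = tms_time, stimulus = stimulus,
             resp_arrow = resp_arrow, resp_something = resp_something,
             resp_direction = resp_direction, question_order = question_order,
             blink = blink, stringsAsFactors = FALSE)
}

make_trials <- function(...) {
  args <- list(...)
  n <- max(vapply(args, length, 0L), 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(make_trial, lapply(args, function(a) a[[min(i, length(a))]]))
  }))
}

# A small simulated cohort shared by several tests (lazy, cached).
cohort_cache <- new.env()
small_cohort <- function(n = 12, seed = 101, effects = tms_effects_signature()) {
  key <- paste0("c", n, "_", seed)
  if (is.null(cohort_cache[[key]])) {
    p <- observer_params(tms_effects = effects)
    cohort_cache[[key]] <- simulate_cohort(n, params = p, seed = seed)
  }
  cohort_cache[[key]]
}

# Independent Riemann-sum oracle for the half-normal / uniform Bayes
# factors (midpoint rule on a fine fixed grid; never calls the package's
# quadrature path).
riemann_bf_half_normal <- function(mean_diff, se, df, prior_sd,
                                   direction = "positive",
                                   likelihood = "t", n_grid = 200000L) {
  if (direction == "negative") mean_diff <- -mean_diff
  lik <- function(theta) {
    if (likelihood == "t") dt((mean_diff - theta) / se, df = df) / se
    else dnorm(mean_diff, theta, se)
  }
  hi <- 10 * prior_sd
  h <- hi / n_grid
  theta <- (seq_len(n_grid) - 0.5) * h
  num <- sum(lik(theta) * 2 * dnorm(theta, 0, prior_sd)) * h
  num / lik(0)
}

riemann_bf_uniform <- function(mean_diff, se, df, lower, upper,
                               likelihood = "t", n_grid = 200000L) {
  lik <- function(theta) {
    if (likelihood == "t") dt((mean_diff - theta) / se, df = df) / se
    else dnorm(mean_diff, theta, se)
  }
  h <- (upper - lower) / n_grid
  theta <- lower + (seq_len(n_grid) - 0.5) * h
  (sum(lik(theta)) * h / (upper - lower)) / lik(0)
}

# JZS oracle via the effect-size parameterization: noncentral-t
# likelihood integrated against a Cauchy(0, r) prior on delta.
cauchy_bf_jzs <- function(t, n, r = 0.707) {
  nu <- n - 1
  # dt(..., ncp) warns about its final-digit precision; irrelevant at the
  # tolerances used here
  num <- suppressWarnings(integrate(function(delta)
    dt(t, df = nu, ncp = sqrt(n) * delta) * dcauchy(delta, 0, r),
    lower = -Inf, upper = Inf, rel.tol = 1e-8)$value)
  num / dt(t, df = nu)
}
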