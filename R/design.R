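#' Specify the factorial design of a masking session
#'
#' The experiment crosses 4 stimulus conditions (left arrow, right arrow,
#' non-arrow, stimulus absent) with 5 temporal TMS conditions (the masking
#' pulse in isolation, plus an extra pulse at 30, 70, 150 or 190 ms).  Each
#' block repeats every unique condition `reps_per_condition` times, so a
#' block holds `20 * reps_per_condition` trials; each participant completes
#' `blocks_active` active-TMS and `blocks_sham` sham blocks.  The default
#' spec (12 + 12 blocks of 80 trials) yields 1920 trials per participant.
#'
#' @param n_participants Number of participants to generate.
#' @param blocks_active,blocks_sham Blocks per TMS mode.
#' @param trials_per_block Trials per block; must equal
#'   `20 * reps_per_condition`.
#' @param reps_per_condition Repetitions of each stimulus x TMS-time cell
#'   per block.
#' @param seed Integer seed controlling the randomized orderings.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_participants = 1L, blocks_active = 12L,
                        blocks_sham = 12L, trials_per_block = 80L,
                        reps_per_condition = 4L, seed = 1L) {
  spec <- structure(list(
    n_participants = as.integer(n_participants),
    blocks_active = as.integer(blocks_active),
    blocks_sham = as.integer(blocks_sham),
    trials_per_block = as.integer(trials_per_block),
    reps_per_condition = as.integer(reps_per_condition),
    seed = as.integer(seed)
  ), class = "design_spec")
  validate_design_spec(spec)
  spec
}

validate_design_spec <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  with(spec, {
    if (n_participants < 1L) stop("design_spec: n_participants must be >= 1")
    if (blocks_active < 1L || blocks_sham < 1L)
      stop("design_spec: block counts must be >= 1")
    if (trials_per_block != reps_per_condition * 20L)
      stop("design_spec: trials_per_block must equal reps_per_condition * 20 ",
           "(4 stimuli x 5 TMS conditions); got ", trials_per_block)
  })
  invisible(spec)
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "design_spec: %d participant(s), %d active + %d sham blocks of %d trials (%d reps/condition), seed %d\n",
    x$n_participants, x$blocks_active, x$blocks_sham, x$trials_per_block,
    x$reps_per_condition, x$seed))
  invisible(x)
}

#' Generate the trial sequence for a design
#'
#' Produces one row per trial with the design factors filled in and the
#' response columns set to `NA` (to be filled by a human dataset or by
#' [simulate_trials()]).  Within every block each of the 20 unique
#' (stimulus, TMS time) cells appears exactly `reps_per_condition` times in
#' randomized order.  Question orders (1..6) are assigned in runs of four
#' consecutive blocks, the run order randomized per participant; active and
#' sham blocks are balanced within each run where the counts allow, and
#' globally otherwise.  Deterministic under `spec$seed`.
#'
#' @param spec A [design_spec()].
#' @return A `data.frame` of trials (see [read_trials()] for the schema).
#' @export
generate_design <- function(spec) {
  validate_design_spec(spec)
  withr::with_seed(spec$seed, {
    out <- lapply(seq_len(spec$n_participants), function(p)
      generate_participant_design(spec, sprintf("P%02d", p)))
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  })
}

## One participant's blocks: question orders in runs of four, modes
## balanced within each run when possible (2 active + 2 sham per run of 4).
generate_participant_design <- function(spec, pid) {
  n_blocks <- spec$blocks_active + spec$blocks_sham
  q_runs <- sample(6L)                       # order of the six question orders
  q_per_block <- rep(rep(q_runs, each = 4L), length.out = n_blocks)

  balanced <- spec$blocks_active == spec$blocks_sham && n_blocks %% 4L == 0L
  if (balanced) {
    mode_per_block <- unlist(lapply(seq_len(n_blocks / 4L), function(i)
      sample(c("active", "active", "sham", "sham"))), use.names = FALSE)
  } else {
    mode_per_block <- sample(rep(c("active", "sham"),
                                 c(spec$blocks_active, spec$blocks_sham)))
  }

  cells <- expand.grid(stimulus = STIMULI, tms_time = TMS_TIMES,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_trial <- n_blocks * spec$trials_per_block
  block_index <- rep(seq_len(n_blocks), each = spec$trials_per_block)
  cell_idx <- rep(rep(seq_len(20L), spec$reps_per_condition), n_blocks)
  ## shuffle within block with one vectorized order() call
  shuffle <- order(block_index, stats::runif(n_trial))
  cell_idx <- cell_idx[shuffle]

  data.frame(
    participant_id = pid,
    block_index = block_index,
    tms_mode = mode_per_block[block_index],
    tms_time = cells$tms_time[cell_idx],
    stimulus = cells$stimulus[cell_idx],
    resp_arrow = NA_character_,
    resp_something = NA_character_,
    resp_direction = NA_character_,
    question_order = q_per_block[block_index],
    blink = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Validate a trial table
#'
#' Checks column presence and enum tokens row by row.  Trials with the
#' illogical response pattern (`resp_arrow == "yes"` while
#' `resp_something == "no"`) are deliberately accepted: they feed the
#' illogical-rate exclusion rule and must be representable.
#'
#' @param trials A data.frame of trials.
#' @param allow_na_responses Accept `NA` responses (a design skeleton)?
#' @return `trials`, invisibly, or an error naming the offending rows.
#' @export
validate_trials <- function(trials, allow_na_responses = FALSE) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols))
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  check_enum <- function(col, levels, allow_na = allow_na_responses) {
    x <- trials[[col]]
    bad <- !(x %in% levels) & !(allow_na & is.na(x))
    if (any(bad))
      stop(sprintf("invalid %s token '%s' at row %d (allowed: %s)",
                   col, as.character(x[which(bad)[1]]), which(bad)[1],
                   paste(levels, collapse = ", ")))
  }
  check_enum("tms_mode", TMS_MODES, allow_na = FALSE)
  check_enum("tms_time", TMS_TIMES, allow_na = FALSE)
  check_enum("stimulus", STIMULI, allow_na = FALSE)
  check_enum("resp_arrow", YESNO)
  check_enum("resp_something", YESNO)
  check_enum("resp_direction", DIRECTIONS)
  if (any(trials$block_index < 1L))
    stop("block_index must be >= 1 (row ",
         which(trials$block_index < 1L)[1], ")")
  if (!all(trials$question_order %in% 1:6))
    stop("question_order must be in 1..6 (row ",
         which(!(trials$question_order %in% 1:6))[1], ")")
  if (!is.logical(trials$blink) && !all(trials$blink %in% c(0, 1)))
    stop("blink must be logical")
  invisible(trials)
}

#' Flag illogical response patterns
#'
#' A trial is illogical when the participant reports seeing the arrow but
#' denies seeing anything at all ("yes" to arrow?, "no" to something?).
#'
#' @param trials A trial table.
#' @return Logical vector, one element per trial.
#' @export
is_illogical <- function(trials) {
  trials$resp_arrow == "yes" & trials$resp_something == "no"
}

#' Read a trial table from CSV
#'
#' Expects the canonical long layout, one row per trial (see
#' [write_trials()]).  Foreign layouts can be adapted with a column-mapping
#' configuration: a YAML/JSON file (or a list) with elements `columns`
#' (foreign name -> canonical name) and optionally `tokens` (per canonical
#' column, foreign token -> canonical token).
#'
#' @param path CSV file path.
#' @param mapping Optional mapping: a list or a path to a YAML/JSON file.
#' @param allow_na_responses Accept unset responses?
#' @return A validated trial `data.frame`.
#' @export
read_trials <- function(path, mapping = NULL, allow_na_responses = FALSE) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  if (file.size(path) == 0L) stop("empty trial file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) df <- apply_column_mapping(df, mapping)
  for (col in c("resp_arrow", "resp_something", "resp_direction"))
    if (col %in% names(df)) df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA
  if ("blink" %in% names(df)) df$blink <- as.logical(df$blink)
  validate_trials(df, allow_na_responses = allow_na_responses)
  df[TRIAL_COLUMNS]
}

apply_column_mapping <- function(df, mapping) {
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- read_config(mapping)
  if (!is.null(mapping$columns)) {
    cols <- unlist(mapping$columns)
    hit <- names(df) %in% names(cols)
    names(df)[hit] <- cols[names(df)[hit]]
  }
  if (!is.null(mapping$tokens)) {
    for (col in names(mapping$tokens)) {
      tok <- unlist(mapping$tokens[[col]])
      hit <- df[[col]] %in% names(tok)
      df[[col]][hit] <- tok[df[[col]][hit]]
    }
  }
  df
}

## YAML or JSON config loader (extension-sniffed, YAML parses JSON too).
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Write a trial table to CSV
#'
#' Canonical column order and stable lowercase enum spellings; an empty
#' table produces a header-only file, so write/read round-trips are exact.
#'
#' @param trials A validated trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials, allow_na_responses = TRUE)
  utils::write.csv(trials[TRIAL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
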