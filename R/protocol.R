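# Training protocol scheduler: the three-step masking progression per maze
# (map view -> sighted trial -> map view -> half-masked trial -> blindfold
# trials x3), retry-until-success, a per-session navigation time budget and
# the 14-day intervention structure.

#' Protocol configuration
#'
#' The default per-maze step sequence reconstructs the three-step blindfold
#' training progression: an allocentric map view, a fully sighted trial, a
#' second map view, a trial with half the maze masked, then
#' `blindfold_repeats` blindfold trials. Failed trials are re-issued until
#' they succeed when `retry_until_success` is set. A session ends when the
#' navigation time budget is spent or the maze list is exhausted.
#'
#' @param steps List of steps, each `list(type = "MAP_VIEW")` or
#'   `list(type = "TRIAL", mode = <mask mode>)`. `NULL` builds the default
#'   sequence from `blindfold_repeats`.
#' @param blindfold_repeats Blindfold trials per maze (default 3).
#' @param session_nav_budget Navigation seconds per daily session
#'   (default 1500, i.e. 25 minutes).
#' @param n_days Days in the intervention (default 14).
#' @param retry_until_success Re-issue failed trials (default `TRUE`).
#' @param dt Seconds per action (default 2).
#' @param time_cap Per-trial time limit in seconds (default 180).
#' @param mask_fraction Fraction of wall edges hidden in `HALF_MASK`
#'   (default 0.5).
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(steps = NULL, blindfold_repeats = 3,
                            session_nav_budget = 1500, n_days = 14,
                            retry_until_success = TRUE, dt = 2,
                            time_cap = 180, mask_fraction = 0.5) {
  stopifnot(blindfold_repeats >= 1, session_nav_budget > 0, n_days >= 1,
            dt > 0, time_cap > 0)
  if (is.null(steps)) {
    steps <- c(
      list(list(type = "MAP_VIEW"),
           list(type = "TRIAL", mode = "FULL_VISION"),
           list(type = "MAP_VIEW"),
           list(type = "TRIAL", mode = "HALF_MASK")),
      rep(list(list(type = "TRIAL", mode = "BLINDFOLD")), blindfold_repeats)
    )
  }
  structure(
    list(steps = steps, blindfold_repeats = blindfold_repeats,
         session_nav_budget = session_nav_budget, n_days = n_days,
         retry_until_success = retry_until_success, dt = dt,
         time_cap = time_cap, mask_fraction = mask_fraction),
    class = "protocol_config")
}

#' Protocol cursor: the scheduler state between trials
#'
#' @param cfg A [protocol_config()].
#' @param n_mazes Number of mazes available in the session.
#' @return An object of class `protocol_cursor` pointing at the first step
#'   of the first maze.
#' @export
protocol_cursor <- function(cfg, n_mazes) {
  structure(
    list(cfg = cfg, n_mazes = n_mazes, maze_idx = 1L, step_idx = 0L,
         retry = 0L, nav_time = 0, map_views = list()),
    class = "protocol_cursor")
}

# advance past (and log) MAP_VIEW steps; position step_idx on the next
# TRIAL step, moving to the next maze when the sequence is exhausted
advance_cursor <- function(cur) {
  repeat {
    cur$step_idx <- cur$step_idx + 1L
    if (cur$step_idx > length(cur$cfg$steps)) {
      cur$maze_idx <- cur$maze_idx + 1L
      cur$step_idx <- 0L
      if (cur$maze_idx > cur$n_mazes) return(cur)  # exhausted
      next
    }
    step <- cur$cfg$steps[[cur$step_idx]]
    if (step$type == "MAP_VIEW") {
      cur$map_views[[length(cur$map_views) + 1L]] <-
        list(maze_idx = cur$maze_idx, step_idx = cur$step_idx)
      next
    }
    cur$retry <- 1L
    return(cur)
  }
}

#' Next trial under the protocol
#'
#' Given the cursor and the outcome of the last issued trial, either
#' re-issues the same trial (failure with retry-until-success), advances
#' along the step sequence and maze list, or ends the session when the
#' navigation budget is spent or no mazes remain. Map-view steps are logged
#' on the cursor as zero-cost allocentric exposure events.
#'
#' @param cursor A `protocol_cursor`.
#' @param last_success `NULL` before the first trial, otherwise whether the
#'   last issued trial succeeded.
#' @return List with `spec` (either `"SESSION_END"` or a trial spec
#'   `list(maze_idx, mode, condition, retry)`) and the updated `cursor`.
#' @export
next_trial <- function(cursor, last_success = NULL) {
  cfg <- cursor$cfg
  if (cursor$nav_time >= cfg$session_nav_budget) {
    return(list(spec = "SESSION_END", cursor = cursor))
  }
  if (!is.null(last_success) && !last_success && cfg$retry_until_success) {
    cursor$retry <- cursor$retry + 1L
  } else {
    cursor <- advance_cursor(cursor)
    if (cursor$maze_idx > cursor$n_mazes) {
      return(list(spec = "SESSION_END", cursor = cursor))
    }
  }
  step <- cfg$steps[[cursor$step_idx]]
  list(spec = list(maze_idx = cursor$maze_idx, mode = step$mode,
                   condition = unname(MASK_CONDITION[step$mode]),
                   retry = cursor$retry),
       cursor = cursor)
}

#' Run one daily training session
#'
#' Drives [next_trial()], [run_trial()] and [score_trial()] until
#' `SESSION_END`. All randomness (mask subsets, the agent's exploration)
#' is drawn from one RNG stream seeded with `seed`, so a session replays
#' bit-identically from `(mazes, agent params, seed)`.
#'
#' @param agent An [hw_agent()] (its experience counter advances as trials
#'   complete and carries across sessions).
#' @param mazes List of `hw_maze` objects, in protocol order.
#' @param cfg A [protocol_config()].
#' @param day 1-based day index recorded in the log.
#' @param seed Integer seed for the session stream.
#' @return An object of class `hw_session`: `day`, `seed`, `trials`,
#'   `scores`, `specs` (maze/condition/retry per trial), `map_views`,
#'   `total_nav_time` (s).
#' @export
run_session <- function(agent, mazes, cfg = protocol_config(), day = 1L,
                        seed = 1L) {
  stopifnot(length(mazes) >= 1)
  with_local_seed(seed, function() {
    cursor <- protocol_cursor(cfg, length(mazes))
    trials <- list(); scores <- list(); specs <- list()
    last_success <- NULL
    repeat {
      nx <- next_trial(cursor, last_success)
      cursor <- nx$cursor
      if (identical(nx$spec, "SESSION_END")) break
      spec <- nx$spec
      m <- mazes[[spec$maze_idx]]
      mask <- mask_spec(spec$mode, fraction = cfg$mask_fraction,
                        seed = sample.int(.Machine$integer.max - 1L, 1L))
      policy <- agent_policy(agent, m, spec$condition)
      trial <- run_trial(m, policy, mask = mask, dt = cfg$dt,
                         time_cap = cfg$time_cap, observations = FALSE)
      sc <- score_trial(m, trial)
      agent_record_trial(agent)
      cursor$nav_time <- cursor$nav_time + trial$duration
      k <- length(trials) + 1L
      trials[[k]] <- trial; scores[[k]] <- sc; specs[[k]] <- spec
      last_success <- sc$success
    }
    structure(
      list(day = as.integer(day), seed = as.integer(seed),
           trials = trials, scores = scores, specs = specs,
           map_views = cursor$map_views,
           total_nav_time = cursor$nav_time),
      class = "hw_session")
  })
}

#' @export
print.hw_session <- function(x, ...) {
  nsucc <- sum(vapply(x$scores, function(s) s$success, logical(1)))
  cat(sprintf("<hw_session> day %d: %d trials (%d successes), %.0f s navigation\n",
              x$day, length(x$trials), nsucc, x$total_nav_time))
  invisible(x)
}

#' Run the full multi-day training protocol
#'
#' Runs `cfg$n_days` daily sessions. The agent's experience carries across
#' days (its exploration rate decays with accumulated trials); per-day
#' session seeds are derived deterministically from `master_seed`.
#'
#' @param params An [agent_params()] specification (a fresh agent is
#'   created, so repeated calls with the same seed are identical).
#' @param mazes List of `hw_maze` objects.
#' @param cfg A [protocol_config()].
#' @param master_seed Integer master seed.
#' @return List of `hw_session` logs, one per day.
#' @export
run_protocol <- function(params, mazes, cfg = protocol_config(),
                         master_seed = 1L) {
  day_seeds <- with_local_seed(master_seed, function() {
    sample.int(.Machine$integer.max - 1L, cfg$n_days)
  })
  agent <- hw_agent(params)
  lapply(seq_len(cfg$n_days), function(day) {
    run_session(agent, mazes, cfg, day = day, seed = day_seeds[day])
  })
}
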