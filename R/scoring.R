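# Trial scoring and the daily spatial-memory training score. Success rule:
# reach the goal within the 3-minute window with a trial score strictly
# above 70. The daily score for a training strategy is the number of
# successful trials divided by the total corresponding training time in
# hours.

#' Score a terminated trial
#'
#' The score starts at 100 and is penalized for deviation from the optimal
#' path, entries into the error zone, and wall collisions:
#' `score = clamp(100 - w_path * excess_path_ratio * 100
#'                    - w_zone * errorzone_entries - w_coll * collisions,
#'                0, 100)`,
#' where `excess_path_ratio = (moves - optimal_moves) / optimal_moves`
#' compares the number of cell-to-cell moves against the shortest path
#' (turn actions are free), and an error-zone entry is a maximal run of
#' consecutive trajectory positions inside [error_zones()]. The penalty
#' weights are a documented reconstruction, not an attempt at any app's
#' proprietary constants.
#'
#' Success requires outcome `GOAL`, duration at most `time_limit` (3
#' minutes) and a score strictly above `success_cutoff` (70). Timed-out
#' trials are scored but never successful.
#'
#' @param m The `hw_maze` the trial ran on.
#' @param trial An `hw_trial` from [run_trial()].
#' @param w_path Weight on the excess-path penalty (default 1.0).
#' @param w_zone Points lost per error-zone entry (default 10).
#' @param w_coll Points lost per collision (default 2).
#' @param corridor_radius Error-zone corridor radius in cells (default 1).
#' @param success_cutoff Minimum score, exceeded strictly (default 70).
#' @param time_limit Success time window in seconds (default 180).
#' @return An object of class `hw_trial_score`: `score` (0-100),
#'   `excess_path_ratio`, `errorzone_entries`, `collisions`, `duration`,
#'   `success`.
#' @export
score_trial <- function(m, trial, w_path = 1.0, w_zone = 10, w_coll = 2,
                        corridor_radius = 1, success_cutoff = 70,
                        time_limit = 180) {
  if (trial$maze_id != m$id) {
    stop(structure(
      class = c("hwnav_maze_mismatch", "error", "condition"),
      list(message = paste0("trial recorded on maze '", trial$maze_id,
                            "' but scoring against '", m$id, "'"),
           call = NULL)))
  }
  if (trial$outcome == "RUNNING") {
    stop("cannot score a trial that has not terminated", call. = FALSE)
  }
  optimal <- shortest_path(m)$length
  excess <- (trial$moves - optimal) / optimal
  zone <- error_zone_mask(m, corridor_radius)
  tr <- trial$trajectory
  in_zone <- zone[cbind(tr$row + 1L, tr$col + 1L)]
  runs <- rle(in_zone)
  entries <- sum(runs$values)
  score <- 100 - w_path * excess * 100 - w_zone * entries -
    w_coll * trial$collisions
  score <- max(0, min(100, score))
  structure(
    list(score = score,
         excess_path_ratio = excess,
         errorzone_entries = entries,
         collisions = trial$collisions,
         duration = trial$duration,
         success = score > success_cutoff &&
           trial$duration <= time_limit &&
           trial$outcome == "GOAL"),
    class = "hw_trial_score")
}

#' @export
print.hw_trial_score <- function(x, ...) {
  cat(sprintf("<hw_trial_score> %.1f/100 (%s): excess path %.2f, %d zone entries, %d collisions, %.0f s\n",
              x$score, if (x$success) "success" else "fail",
              x$excess_path_ratio, x$errorzone_entries, x$collisions,
              x$duration))
  invisible(x)
}

#' Daily training score for one strategy
#'
#' The daily spatial-memory training score for a training strategy is the
#' number of successfully completed trials divided by the total
#' corresponding training time in hours.
#'
#' @param trials List of `hw_trial` records, all from the same condition.
#' @param scores Matching list of `hw_trial_score` objects.
#' @param condition Condition label (`"AV"`, `"A50V"`, `"A"` or
#'   `"overall"`); all trials must carry it unless `condition = "overall"`.
#' @return An object of class `hw_daily_score`: `condition`,
#'   `successful_trials`, `n_trials`, `training_time` (hours), `value`
#'   (successes per hour).
#' @export
daily_training_score <- function(trials, scores, condition) {
  if (length(trials) == 0L) {
    stop(structure(
      class = c("hwnav_undefined_score", "error", "condition"),
      list(message = "daily score undefined for an empty trial list",
           call = NULL)))
  }
  if (length(trials) != length(scores)) {
    stop("trials and scores must have equal length", call. = FALSE)
  }
  conds <- vapply(trials, function(t) t$condition, character(1))
  if (condition != "overall" && any(conds != condition)) {
    stop(structure(
      class = c("hwnav_condition_mismatch", "error", "condition"),
      list(message = paste0("trials with conditions {",
                            paste(unique(conds), collapse = ","),
                            "} passed for condition ", condition),
           call = NULL)))
  }
  hours <- sum(vapply(trials, function(t) t$duration, numeric(1))) / 3600
  if (hours <= 0) {
    stop(structure(
      class = c("hwnav_undefined_score", "error", "condition"),
      list(message = "daily score undefined for zero training time",
           call = NULL)))
  }
  nsucc <- sum(vapply(scores, function(s) s$success, logical(1)))
  structure(
    list(condition = condition,
         successful_trials = nsucc,
         n_trials = length(trials),
         training_time = hours,
         value = nsucc / hours),
    class = "hw_daily_score")
}

#' @export
print.hw_daily_score <- function(x, ...) {
  cat(sprintf("<hw_daily_score> %s: %d/%d successes in %.2f h -> %.1f per hour\n",
              x$condition, x$successful_trials, x$n_trials,
              x$training_time, x$value))
  invisible(x)
}

#' Per-condition and overall daily scores for a session
#'
#' Splits a session's scored trials by training strategy and returns one
#' daily score per condition present plus an `overall` score pooling all
#' trials.
#'
#' @param session An `hw_session` from [run_session()] (or any list with
#'   `trials` and `scores` elements).
#' @return Named list of `hw_daily_score` objects: one per condition
#'   present, plus `overall`.
#' @export
aggregate_conditions <- function(session) {
  trials <- session$trials
  scores <- session$scores
  if (length(trials) == 0L) {
    stop(structure(
      class = c("hwnav_undefined_score", "error", "condition"),
      list(message = "session contains no scored trials", call = NULL)))
  }
  conds <- vapply(trials, function(t) t$condition, character(1))
  out <- list()
  for (cond in intersect(c("AV", "A50V", "A"), unique(conds))) {
    sel <- conds == cond
    out[[cond]] <- daily_training_score(trials[sel], scores[sel], cond)
  }
  out$overall <- daily_training_score(trials, scores, "overall")
  out
}

#' Tabulate daily scores across a multi-day protocol run
#'
#' @param logs List of `hw_session` logs from [run_protocol()].
#' @return Data frame with columns `day, condition, n_trials, n_success,
#'   time_h, score` (the daily score table CSV layout), one row per
#'   day x condition plus an `overall` row per day.
#' @export
daily_score_table <- function(logs) {
  rows <- lapply(logs, function(sess) {
    agg <- aggregate_conditions(sess)
    do.call(rbind, lapply(agg, function(a) {
      data.frame(day = sess$day, condition = a$condition,
                 n_trials = a$n_trials, n_success = a$successful_trials,
                 time_h = a$training_time, score = a$value)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
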