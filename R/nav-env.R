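# Egocentric navigation environment: the agent occupies a cell with one of
# eight headings and acts by swiping FORWARD, TURN_L45 or TURN_R45. Every
# action costs one tick of the discrete clock (dt seconds). Visual masking
# controls what the Observation shows but never alters the dynamics.

ACTIONS <- c("FORWARD", "TURN_L45", "TURN_R45")

# maps a masking mode to the training-strategy condition label used in
# logs and scores: audio+visual, audio+50% visual, audio only
MASK_CONDITION <- c(FULL_VISION = "AV", HALF_MASK = "A50V", BLINDFOLD = "A")

#' Visual mask specification
#'
#' The three training strategies differ only in what the participant sees:
#' `FULL_VISION` shows every wall, `HALF_MASK` hides a random fraction
#' (default 50%) of the wall edges, drawn once per trial from `seed`, and
#' `BLINDFOLD` hides everything so navigation relies on spatial memory and
#' the auditory cues.
#'
#' @param mode One of `"FULL_VISION"`, `"HALF_MASK"`, `"BLINDFOLD"`.
#' @param fraction Proportion of wall edges hidden in `HALF_MASK`
#'   (in `[0, 1]`, default 0.5).
#' @param seed Integer seed fixing the hidden subset for the trial.
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(mode = c("FULL_VISION", "HALF_MASK", "BLINDFOLD"),
                      fraction = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction <= 1)
  structure(list(mode = mode, fraction = fraction, seed = as.integer(seed)),
            class = "mask_spec")
}

# every physical wall edge: interior walls plus the implicit perimeter
# (perimeter edges pair an in-range cell with its out-of-range neighbor)
all_wall_edges <- function(m) {
  H <- m$height; W <- m$width
  per <- c(
    edge_key(rep(0L, W), 0:(W - 1L), rep(-1L, W), 0:(W - 1L)),
    edge_key(rep(H - 1L, W), 0:(W - 1L), rep(H, W), 0:(W - 1L)),
    edge_key(0:(H - 1L), rep(0L, H), 0:(H - 1L), rep(-1L, H)),
    edge_key(0:(H - 1L), rep(W - 1L, H), 0:(H - 1L), rep(W, H))
  )
  sort(c(m$walls, per))
}

#' Apply a visual mask to a maze
#'
#' Returns the wall edges that remain visible under the mask. In
#' `HALF_MASK`, `floor(fraction * n_edges)` edges are hidden, drawn
#' uniformly at random once from the mask seed (the subset is fixed for the
#' whole trial).
#'
#' @param m An `hw_maze`.
#' @param mask A [mask_spec()].
#' @return Character vector of visible wall edge keys.
#' @export
apply_mask <- function(m, mask) {
  edges <- all_wall_edges(m)
  switch(mask$mode,
    FULL_VISION = edges,
    BLINDFOLD = character(0),
    HALF_MASK = {
      n_hide <- floor(mask$fraction * length(edges))
      hidden <- with_local_seed(mask$seed, function() {
        sample(edges, n_hide)
      })
      setdiff(edges, hidden)
    }
  )
}

new_agent_state <- function(m, dt, time_cap) {
  structure(
    list(position = list(row = m$start$row, col = m$start$col),
         heading = m$start$heading,
         steps_taken = 0L, elapsed = 0,
         terminated = FALSE, outcome = "RUNNING",
         dt = dt, time_cap = time_cap),
    class = "hw_agent_state")
}

build_observation <- function(state, m, mask, visible, cfg, event) {
  audio <- sonify_state(state, m, cfg)
  vis_cells <- if (mask$mode == "BLINDFOLD") {
    matrix(integer(0), ncol = 2)
  } else {
    as.matrix(expand.grid(row = 0:(m$height - 1L), col = 0:(m$width - 1L)))
  }
  list(visible_walls = visible, visible_cells = vis_cells,
       audio = audio, events = event)
}

#' Reset the navigation environment
#'
#' Places the agent at the maze start pose with the clock at zero and draws
#' the masked wall subset for the trial.
#'
#' @param m A valid `hw_maze`.
#' @param mask A [mask_spec()].
#' @param dt Seconds per action on the discrete clock (default 2).
#' @param time_cap Trial time limit in seconds (default 180, the 3-minute
#'   success window).
#' @param cfg [sonifier_config()] used for the auditory cues.
#' @return List with elements `state` (class `hw_agent_state`) and `obs`
#'   (the initial Observation: `visible_walls`, `visible_cells`, `audio`,
#'   `events`).
#' @export
env_reset <- function(m, mask = mask_spec(), dt = 2, time_cap = 180,
                      cfg = sonifier_config()) {
  stopifnot(dt > 0, time_cap > 0)
  state <- new_agent_state(m, dt, time_cap)
  visible <- apply_mask(m, mask)
  list(state = state,
       obs = build_observation(state, m, mask, visible, cfg, character(0)))
}

# dynamics kernel shared by env_step() and the fast trial loop: applies one
# action and returns c(row, col, heading_idx, event_code)
# event codes: 0 none, 1 FOOTSTEP, 2 COLLISION, 3 GOAL_REACHED
step_core <- function(m, od, row, col, hidx, action) {
  event <- 0L
  if (action == "FORWARD") {
    if (od[row + 1L, col + 1L, hidx]) {
      row <- row + HEADING_DROW[hidx]
      col <- col + HEADING_DCOL[hidx]
      event <- if (row == m$goal$row && col == m$goal$col) 3L else 1L
    } else {
      event <- 2L
    }
  } else if (action == "TURN_L45") {
    hidx <- ((hidx - 2L) %% 8L) + 1L
  } else if (action == "TURN_R45") {
    hidx <- (hidx %% 8L) + 1L
  } else {
    stop("unknown action: ", action, call. = FALSE)
  }
  c(row, col, hidx, event)
}

EVENT_NAMES <- c("FOOTSTEP", "COLLISION", "GOAL_REACHED")

#' Advance the environment by one action
#'
#' `TURN_L45`/`TURN_R45` rotate the heading by 45 degrees in place;
#' `FORWARD` moves one cell along the heading unless the edge ahead is
#' blocked, in which case the position is unchanged and a `COLLISION` is
#' emitted. Every successful forward step emits a `FOOTSTEP`. Each action
#' advances the clock by `dt`; reaching the goal terminates with outcome
#' `GOAL`, and exceeding the time cap terminates with `TIMEOUT`.
#'
#' @param state An `hw_agent_state` (not yet terminated).
#' @param action One of `"FORWARD"`, `"TURN_L45"`, `"TURN_R45"`.
#' @param m The `hw_maze` being navigated.
#' @param mask The trial's [mask_spec()].
#' @param cfg [sonifier_config()] for the auditory cues.
#' @return List with updated `state` and `obs`.
#' @export
env_step <- function(state, action, m, mask = mask_spec(),
                     cfg = sonifier_config()) {
  if (state$terminated) {
    stop("env_step() called on a terminated trial", call. = FALSE)
  }
  od <- open_dirs(m)
  res <- step_core(m, od, state$position$row, state$position$col,
                   heading_index(state$heading), action)
  state$position <- list(row = res[1], col = res[2])
  state$heading <- HEADINGS[res[3]]
  state$steps_taken <- state$steps_taken + 1L
  state$elapsed <- state$steps_taken * state$dt
  events <- if (res[4] > 0L) EVENT_NAMES[res[4]] else character(0)
  if (res[4] == 3L) {
    state$terminated <- TRUE
    state$outcome <- "GOAL"
  } else if (state$elapsed > state$time_cap) {
    state$terminated <- TRUE
    state$outcome <- "TIMEOUT"
  }
  visible <- apply_mask(m, mask)
  list(state = state,
       obs = build_observation(state, m, mask, visible, cfg, events))
}

#' Run one navigation trial under a policy
#'
#' Repeatedly queries `policy` for an action until the trial terminates
#' (goal reached or time cap exceeded) and returns the full trial record:
#' trajectory, events, timing and outcome. The trial is deterministic given
#' the maze, the policy's own randomness and the mask seed.
#'
#' @param m A valid `hw_maze`.
#' @param policy Function `(state, obs) -> action`. When
#'   `observations = FALSE` the `obs` argument is `NULL` (cheaper for
#'   policies, such as the synthetic agent, that play from state alone).
#' @param mask [mask_spec()] for the trial; sets the condition label.
#' @param dt,time_cap Clock settings as in [env_reset()].
#' @param cfg [sonifier_config()].
#' @param observations Build a full Observation for every step
#'   (default `TRUE`).
#' @return An object of class `hw_trial`: maze id, condition, mask, outcome
#'   (`GOAL`/`TIMEOUT`), `duration` (s), `steps_taken` (actions), `moves`
#'   (successful forward steps), `collisions`, and a `trajectory` data frame
#'   with columns `step, action, row, col, heading, event`.
#' @export
run_trial <- function(m, policy, mask = mask_spec(), dt = 2, time_cap = 180,
                      cfg = sonifier_config(), observations = TRUE) {
  stopifnot(dt > 0, time_cap > 0)
  od <- open_dirs(m)
  visible <- if (observations) apply_mask(m, mask) else NULL
  state <- new_agent_state(m, dt, time_cap)
  max_steps <- ceiling(time_cap / dt) + 1L
  act_v <- character(max_steps); row_v <- integer(max_steps)
  col_v <- integer(max_steps); head_v <- character(max_steps)
  ev_v <- character(max_steps)
  n <- 0L
  collisions <- 0L; moves <- 0L
  row <- state$position$row; col <- state$position$col
  hidx <- heading_index(state$heading)
  obs <- if (observations) {
    build_observation(state, m, mask, visible, cfg, character(0))
  } else NULL
  while (!state$terminated) {
    action <- tryCatch(policy(state, obs), error = function(e) {
      stop(structure(
        class = c("hwnav_policy_error", "error", "condition"),
        list(message = paste0("policy failed at step ", n, ": ",
                              conditionMessage(e)), call = NULL)))
    })
    res <- step_core(m, od, row, col, hidx, action)
    row <- res[1]; col <- res[2]; hidx <- res[3]
    n <- n + 1L
    act_v[n] <- action; row_v[n] <- row; col_v[n] <- col
    head_v[n] <- HEADINGS[hidx]
    ev_v[n] <- if (res[4] > 0L) EVENT_NAMES[res[4]] else ""
    if (res[4] == 1L) moves <- moves + 1L
    if (res[4] == 2L) collisions <- collisions + 1L
    if (res[4] == 3L) moves <- moves + 1L
    state$position <- list(row = row, col = col)
    state$heading <- HEADINGS[hidx]
    state$steps_taken <- n
    state$elapsed <- n * dt
    if (res[4] == 3L) {
      state$terminated <- TRUE; state$outcome <- "GOAL"
    } else if (state$elapsed > time_cap) {
      state$terminated <- TRUE; state$outcome <- "TIMEOUT"
    }
    if (observations && !state$terminated) {
      obs <- build_observation(state, m, mask, visible, cfg,
                               if (nzchar(ev_v[n])) ev_v[n] else character(0))
    }
  }
  traj <- data.frame(
    step = 0:n,
    action = c(NA_character_, act_v[seq_len(n)]),
    row = c(m$start$row, row_v[seq_len(n)]),
    col = c(m$start$col, col_v[seq_len(n)]),
    heading = c(m$start$heading, head_v[seq_len(n)]),
    event = c("", ev_v[seq_len(n)]),
    stringsAsFactors = FALSE
  )
  structure(
    list(maze_id = m$id,
         condition = unname(MASK_CONDITION[mask$mode]),
         mask = mask,
         outcome = state$outcome,
         duration = state$elapsed,
         steps_taken = n,
         moves = moves,
         collisions = collisions,
         dt = dt, time_cap = time_cap,
         trajectory = traj),
    class = "hw_trial")
}

#' @export
print.hw_trial <- function(x, ...) {
  cat(sprintf("<hw_trial> maze %s, condition %s: %s in %.0f s (%d actions, %d moves, %d collisions)\n",
              x$maze_id, x$condition, x$outcome, x$duration,
              x$steps_taken, x$moves, x$collisions))
  invisible(x)
}

#' Write and read trial trajectories as CSV
#'
#' The header row group carries the trial-level fields
#' (`maze_id, condition, mask_seed, outcome, duration_s, collisions`);
#' the trajectory side-file holds one row per step.
#'
#' @param trial An `hw_trial`.
#' @param summary_path,trajectory_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_trial_csv <- function(trial, summary_path, trajectory_path) {
  summ <- data.frame(
    maze_id = trial$maze_id, condition = trial$condition,
    mask_seed = trial$mask$seed, outcome = trial$outcome,
    duration_s = trial$duration, steps = trial$steps_taken,
    moves = trial$moves, collisions = trial$collisions)
  utils::write.csv(summ, summary_path, row.names = FALSE)
  utils::write.csv(trial$trajectory, trajectory_path, row.names = FALSE)
  invisible(c(summary_path, trajectory_path))
}
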