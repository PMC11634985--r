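# Synthetic learner. The agent follows the optimal next step toward the
# goal with probability 1 - eps and explores uniformly over the three
# actions otherwise. Its per-step error rate decays logarithmically with
# accumulated experience and is scaled per condition, so simulated training
# produces logarithmic daily learning curves with the blindfold condition
# hardest.

#' Synthetic agent parameters
#'
#' The per-step error probability is
#' `eps = clamp(eps0 * m_condition / (1 + kappa * ln(1 + experience / exp_scale)), 0, 1)`,
#' where `experience` counts trials completed so far (across days),
#' `exp_scale` is the experience timescale in trials (default 45, about
#' one daily session), and the condition multipliers satisfy
#' `m_AV <= m_A50V <= m_A` so that the audiovisual strategy is easiest and
#' blindfold navigation hardest. Measuring experience in units of
#' `exp_scale` makes the error rate decay on the scale of days, which is
#' what produces day-level logarithmic learning curves; with raw trial
#' counts the logarithm would saturate within the first session.
#'
#' @param eps0 Initial error probability in `[0, 1]`.
#' @param kappa Learning-rate constant (>= 0).
#' @param multipliers Named numeric vector `c(AV = , A50V = , A = )`,
#'   non-decreasing in that order.
#' @param exp_scale Experience timescale in trials (> 0).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(eps0 = 0.35, kappa = 0.25,
                         multipliers = c(AV = 0.75, A50V = 1.0, A = 1.2),
                         exp_scale = 45) {
  stopifnot(eps0 >= 0, eps0 <= 1, kappa >= 0, exp_scale > 0,
            all(c("AV", "A50V", "A") %in% names(multipliers)))
  mm <- multipliers[c("AV", "A50V", "A")]
  if (is.unsorted(mm)) {
    stop("condition multipliers must satisfy m_AV <= m_A50V <= m_A",
         call. = FALSE)
  }
  structure(list(eps0 = eps0, kappa = kappa, multipliers = mm,
                 exp_scale = exp_scale),
            class = "agent_params")
}

#' Instantiate an agent
#'
#' The agent holds its parameters plus a mutable experience counter (an
#' environment), which [run_session()] advances as trials complete.
#'
#' @param params An [agent_params()].
#' @return An object of class `hw_agent`.
#' @export
hw_agent <- function(params = agent_params()) {
  state <- new.env(parent = emptyenv())
  state$experience <- 0L
  structure(list(params = params, state = state), class = "hw_agent")
}

agent_record_trial <- function(agent) {
  agent$state$experience <- agent$state$experience + 1L
  invisible(agent)
}

#' Current per-step error probability
#'
#' @param agent An [hw_agent()].
#' @param condition Condition label (`"AV"`, `"A50V"`, `"A"`).
#' @return Error probability in `[0, 1]`.
#' @export
agent_epsilon <- function(agent, condition) {
  p <- agent$params
  eps <- p$eps0 * unname(p$multipliers[condition]) /
    (1 + p$kappa * log1p(agent$state$experience / p$exp_scale))
  max(0, min(1, eps))
}

# greedy move direction per cell: the direction whose successor minimizes
# (distance-to-goal + step cost); ties prefer the lexicographically
# smallest successor. Memoised on the maze cache.
best_dir_field <- function(m) {
  if (!is.null(m$cache$best_dir)) return(m$cache$best_dir)
  dist <- dist_field(m, from = m$goal, metric = "cost", diagonal = TRUE)
  od <- open_dirs(m)
  H <- m$height; W <- m$width
  bd <- matrix(NA_integer_, H, W)
  for (r in 0:(H - 1L)) for (cc in 0:(W - 1L)) {
    if (r == m$goal$row && cc == m$goal$col) next
    best <- NA_integer_; bestval <- Inf; bestsucc <- c(Inf, Inf)
    for (d in 1:8) {
      if (!od[r + 1L, cc + 1L, d]) next
      rr <- r + HEADING_DROW[d]; ccn <- cc + HEADING_DCOL[d]
      val <- dist[rr + 1L, ccn + 1L] + if (d %% 2L == 0L) SQRT2 else 1
      better <- val < bestval - 1e-9 ||
        (abs(val - bestval) < 1e-9 &&
           (rr < bestsucc[1] || (rr == bestsucc[1] && ccn < bestsucc[2])))
      if (better) {
        best <- d; bestval <- val; bestsucc <- c(rr, ccn)
      }
    }
    bd[r + 1L, cc + 1L] <- best
  }
  m$cache$best_dir <- bd
  bd
}

#' One agent action
#'
#' With probability `1 - eps` the agent takes the next step of the optimal
#' route from its current cell (turning toward the required heading first,
#' then moving forward); with probability `eps` it takes a uniformly random
#' action. Draws come from the caller's RNG stream.
#'
#' @param agent An [hw_agent()].
#' @param state An `hw_agent_state`.
#' @param m The `hw_maze`.
#' @param condition Condition label for the error multiplier.
#' @return An action string.
#' @export
agent_act <- function(agent, state, m, condition) {
  agent_policy(agent, m, condition)(state, NULL)
}

# fast closure used by run_session: captures the per-maze greedy field once
agent_policy <- function(agent, m, condition) {
  bd <- best_dir_field(m)
  astate <- agent$state
  p <- agent$params
  mult <- unname(p$multipliers[condition])
  force(mult)
  function(state, obs) {
    eps <- p$eps0 * mult / (1 + p$kappa * log1p(astate$experience / p$exp_scale))
    if (eps > 0 && stats::runif(1) < eps) {
      return(ACTIONS[sample.int(3L, 1L)])
    }
    d_star <- bd[state$position$row + 1L, state$position$col + 1L]
    diff <- heading_turn_diff(state$heading, HEADINGS[d_star])
    if (diff == 0L) "FORWARD" else if (diff > 0L) "TURN_R45" else "TURN_L45"
  }
}

#' Generate a synthetic behavioral dataset from the logarithmic model
#'
#' Draws daily overall training scores directly from the two-parameter
#' logarithmic learning model `Y = a ln(x) + b` with additive Gaussian
#' noise: `y_x = a ln(x) + b + N(0, noise_sd)` for days `x = 1..n_days`.
#' This direct generator feeds the statistics layer; the mechanistic agent
#' above feeds the environment and protocol layers.
#'
#' @param a Curve slope (score units per `ln(day)`).
#' @param b Curve intercept (score units; the expected day-1 score).
#' @param noise_sd Standard deviation of the daily score noise (default 5).
#' @param n_days Number of days (>= 3, default 14).
#' @param seed Integer seed; the caller's RNG is left untouched.
#' @return An object of class `behavior_dataset`: data frame `data` with
#'   columns `day`, `score`, plus the generating parameters.
#' @export
generate_behavior_dataset <- function(a, b, noise_sd = 5, n_days = 14,
                                      seed = 1L) {
  stopifnot(n_days >= 3, noise_sd >= 0)
  if (b + a * log(n_days) <= 0) {
    warning("degenerate parameters: expected score non-positive at day ",
            n_days, call. = FALSE)
  }
  x <- seq_len(n_days)
  y <- with_local_seed(seed, function() {
    a * log(x) + b + stats::rnorm(n_days, 0, noise_sd)
  })
  structure(
    list(data = data.frame(day = x, score = y),
         a = a, b = b, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "behavior_dataset")
}

#' Write a behavioral dataset as CSV with a JSON parameter sidecar
#'
#' @param ds A `behavior_dataset`.
#' @param csv_path Output CSV path (columns `day, score`); the generating
#'   parameters are written alongside as `<csv_path>.json`.
#' @return Invisibly, the CSV path.
#' @export
write_behavior_csv <- function(ds, csv_path) {
  utils::write.csv(ds$data, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(a = ds$a, b = ds$b, noise_sd = ds$noise_sd, seed = ds$seed),
    paste0(csv_path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

# mean daily overall score across protocol replicates; the curve the
# calibration fits
simulate_mean_daily_scores <- function(params, mazes, cfg, seeds) {
  per_seed <- vapply(seeds, function(s) {
    logs <- run_protocol(params, mazes, cfg, master_seed = s)
    vapply(logs, function(sess) aggregate_conditions(sess)$overall$value,
           numeric(1))
  }, numeric(cfg$n_days))
  rowMeans(per_seed)
}

#' Calibrate the agent to a target logarithmic learning curve
#'
#' Grid search over `(eps0, kappa)`: for each candidate, the mean daily
#' overall training score across `n_seeds` protocol replicates is fitted
#' with [fit_log_curve()], and the candidate minimizing the worse of the
#' two relative parameter errors is kept. Calibration succeeds when both
#' fitted parameters land within `tol` of the targets.
#'
#' @param target_a,target_b Target curve parameters (score units).
#' @param mazes Maze set to train on (default [hw_fixture_mazes()]).
#' @param cfg [protocol_config()] to run under.
#' @param eps0_grid,kappa_grid Candidate parameter grids.
#' @param n_seeds Protocol replicates per candidate (default 20).
#' @param tol Relative tolerance on each parameter (default 0.15).
#' @param base_seed Seed from which replicate master seeds are derived.
#' @return An object of class `hw_calibration`: `params` (the winning
#'   [agent_params()]), `achieved_a`, `achieved_b`, `rel_err_a`,
#'   `rel_err_b`, `within_tol`, `fit` (the winning curve fit), and the full
#'   grid `report`.
#' @export
calibrate_agent <- function(target_a, target_b,
                            mazes = hw_fixture_mazes(),
                            cfg = protocol_config(),
                            eps0_grid = seq(0.25, 0.45, by = 0.05),
                            kappa_grid = c(0.2, 0.35, 0.5),
                            n_seeds = 20, tol = 0.15, base_seed = 99L) {
  stopifnot(target_b > 0, target_b + target_a * log(cfg$n_days) > 0)
  seeds <- with_local_seed(base_seed, function() {
    sample.int(.Machine$integer.max - 1L, n_seeds)
  })
  grid <- expand.grid(eps0 = eps0_grid, kappa = kappa_grid)
  report <- vector("list", nrow(grid))
  fits <- vector("list", nrow(grid))
  best_i <- NA_integer_; best_err <- Inf
  for (i in seq_len(nrow(grid))) {
    params <- agent_params(eps0 = grid$eps0[i], kappa = grid$kappa[i])
    y <- simulate_mean_daily_scores(params, mazes, cfg, seeds)
    fit <- fit_log_curve(seq_len(cfg$n_days), y)
    fits[[i]] <- fit
    rel_a <- abs(fit$a_hat - target_a) / abs(target_a)
    rel_b <- abs(fit$b_hat - target_b) / abs(target_b)
    err <- max(rel_a, rel_b)
    report[[i]] <- data.frame(
      eps0 = grid$eps0[i], kappa = grid$kappa[i],
      a_hat = fit$a_hat, b_hat = fit$b_hat,
      rel_err_a = rel_a, rel_err_b = rel_b, err = err)
    if (err < best_err) {
      best_err <- err; best_i <- i
    }
  }
  report <- do.call(rbind, report)
  best <- report[best_i, ]
  params <- agent_params(eps0 = best$eps0, kappa = best$kappa)
  fit <- fits[[best_i]]
  structure(
    list(params = params,
         achieved_a = fit$a_hat, achieved_b = fit$b_hat,
         rel_err_a = best$rel_err_a, rel_err_b = best$rel_err_b,
         within_tol = best$rel_err_a <= tol && best$rel_err_b <= tol,
         tol = tol, fit = fit, report = report,
         seeds = seeds),
    class = "hw_calibration")
}

#' @export
print.hw_calibration <- function(x, ...) {
  cat(sprintf("<hw_calibration> eps0=%.3f kappa=%.3f -> a=%.2f b=%.2f (rel err %.1f%% / %.1f%%, %s tol %.0f%%)\n",
              x$params$eps0, x$params$kappa, x$achieved_a, x$achieved_b,
              100 * x$rel_err_a, 100 * x$rel_err_b,
              if (x$within_tol) "within" else "OUTSIDE", 100 * x$tol))
  invisible(x)
}
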