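# Shared fixtures and independent oracles used across the test files.

open_maze <- function(width = 6, height = 6,
                      start = list(row = height - 1, col = 0, heading = "N"),
                      goal = list(row = 0, col = width - 1)) {
  hw_maze("open", width, height, start = start, goal = goal)
}

# corner-to-corner open maze used in the geometry examples
corner_maze <- function() {
  hw_maze("corner", 6, 6,
          start = list(row = 0, col = 0, heading = "SE"),
          goal = list(row = 5, col = 5))
}

FIXTURE_MAZES <- hw_fixture_mazes()

# independent shortest-path oracle: igraph Dijkstra over the legal-move
# graph (edges enumerated by brute force from the maze definition, not via
# the package's open-direction cache)
igraph_path_cost <- function(m, diagonal = TRUE) {
  H <- m$height; W <- m$width
  wall <- function(r1, c1, r2, c2) {
    key <- if (r1 < r2 || (r1 == r2 && c1 <= c2)) {
      paste0(r1, ",", c1, "-", r2, ",", c2)
    } else {
      paste0(r2, ",", c2, "-", r1, ",", c1)
    }
    key %in% m$walls
  }
  id <- function(r, cc) r * W + cc + 1L
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  deltas <- list(c(-1, 0), c(0, 1), c(1, 0), c(0, -1))
  if (diagonal) {
    deltas <- c(deltas, list(c(-1, 1), c(1, 1), c(1, -1), c(-1, -1)))
  }
  for (r in 0:(H - 1)) for (cc in 0:(W - 1)) for (d in deltas) {
    rr <- r + d[1]; ccn <- cc + d[2]
    if (rr < 0 || rr >= H || ccn < 0 || ccn >= W) next
    if (abs(d[1]) + abs(d[2]) == 1) {
      if (wall(r, cc, rr, ccn)) next
      w <- 1
    } else {
      # diagonal: all four wall segments at the crossed corner must be open
      if (wall(r, cc, r, ccn) || wall(r, cc, rr, cc) ||
          wall(rr, ccn, r, ccn) || wall(rr, ccn, rr, cc)) next
      w <- sqrt(2)
    }
    from <- c(from, id(r, cc)); to <- c(to, id(rr, ccn)); wt <- c(wt, w)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = TRUE,
    vertices = data.frame(name = 1:(H * W)))
  igraph::distances(g, v = as.character(id(m$start$row, m$start$col)),
                    to = as.character(id(m$goal$row, m$goal$col)),
                    weights = wt, mode = "out")[1, 1]
}

# brute-force wall-distance oracle: march one cell at a time, checking the
# wall set directly
ray_march_oracle <- function(m, row, col, heading) {
  H <- m$height; W <- m$width
  wall <- function(r1, c1, r2, c2) {
    key <- if (r1 < r2 || (r1 == r2 && c1 <= c2)) {
      paste0(r1, ",", c1, "-", r2, ",", c2)
    } else {
      paste0(r2, ",", c2, "-", r1, ",", c1)
    }
    key %in% m$walls
  }
  dmap <- list(N = c(-1, 0), NE = c(-1, 1), E = c(0, 1), SE = c(1, 1),
               S = c(1, 0), SW = c(1, -1), W = c(0, -1), NW = c(-1, -1))
  d <- dmap[[heading]]
  steps <- 0L
  repeat {
    rr <- row + d[1]; ccn <- col + d[2]
    if (rr < 0 || rr >= H || ccn < 0 || ccn >= W) return(steps)
    blocked <- if (abs(d[1]) + abs(d[2]) == 1) {
      wall(row, col, rr, ccn)
    } else {
      wall(row, col, row, ccn) || wall(row, col, rr, col) ||
        wall(rr, ccn, row, ccn) || wall(rr, ccn, rr, col)
    }
    if (blocked) return(steps)
    row <- rr; col <- ccn
    steps <- steps + 1L
  }
}

# Benjamini-Hochberg step-up by its textbook definition
bh_bruteforce <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= (seq_len(n) / n) * q)
  rej <- logical(n)
  if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# deterministic policy following the maze's optimal route (turn toward the
# next path cell, then step forward); independent of the agent module
perfect_policy <- function(m) {
  path <- shortest_path(m)
  dmap <- c(`-1,0` = "N", `-1,1` = "NE", `0,1` = "E", `1,1` = "SE",
            `1,0` = "S", `1,-1` = "SW", `0,-1` = "W", `-1,-1` = "NW")
  i <- new.env(); i$next_cell <- 2L
  function(state, obs) {
    tgt <- path$cells[i$next_cell, ]
    dr <- tgt[1] - state$position$row
    dc <- tgt[2] - state$position$col
    want <- dmap[[paste0(dr, ",", dc)]]
    cur <- state$heading
    if (cur == want) {
      i$next_cell <- i$next_cell + 1L
      return("FORWARD")
    }
    idx <- function(h) match(h, c("N", "NE", "E", "SE", "S", "SW", "W", "NW"))
    diff <- (idx(want) - idx(cur)) %% 8
    if (diff >= 1 && diff <= 4) "TURN_R45" else "TURN_L45"
  }
}

# list-driven policy for scripted action sequences
scripted_policy <- function(actions) {
  i <- new.env(); i$k <- 0L
  function(state, obs) {
    i$k <- i$k + 1L
    actions[[min(i$k, length(actions))]]
  }
}
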