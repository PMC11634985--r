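# Seeded generator for Hebb-Williams style stand-in mazes. The classic
# apparatus is a square arena entered at one corner and exited at the
# opposite corner, with interior barriers of graded complexity; the fixture
# set mimics those proportions with randomly placed thin walls.

# run `fn` under a private RNG stream without disturbing the caller's RNG
with_local_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

all_interior_edges <- function(width, height) {
  keys <- character(0)
  for (r in 0:(height - 1L)) for (cc in 0:(width - 1L)) {
    if (cc + 1L < width) keys <- c(keys, edge_key(r, cc, r, cc + 1L))
    if (r + 1L < height) keys <- c(keys, edge_key(r, cc, r + 1L, cc))
  }
  keys
}

#' Generate a random Hebb-Williams style maze
#'
#' Draws interior walls one at a time in random order, keeping a candidate
#' wall only if the goal remains reachable from the start and no cell
#' becomes isolated. `n_walls` therefore grades the maze complexity. The
#' start is the bottom-left corner facing north and the goal the top-right
#' corner, the classic arena layout.
#'
#' @param id Maze identifier.
#' @param n_walls Number of interior walls to attempt (the achieved number
#'   can be lower if candidates are rejected).
#' @param width,height Grid dimensions (default 6x6).
#' @param seed Integer seed; the generator is deterministic given
#'   `(seed, n_walls, width, height)` and does not disturb the global RNG.
#' @return A valid `hw_maze`.
#' @export
generate_maze <- function(id, n_walls, width = 6, height = 6, seed = 1) {
  with_local_seed(seed, function() {
    start <- list(row = height - 1L, col = 0L, heading = "N")
    goal <- list(row = 0L, col = width - 1L)
    cand <- sample(all_interior_edges(width, height))
    walls <- character(0)
    added <- 0L
    probe <- function(ws) {
      m <- hw_maze(id, width, height, start, goal, walls = ws,
                   validate = FALSE)
      d <- dist_field(m, from = goal, metric = "steps", diagonal = TRUE)
      all(is.finite(d))  # every cell reachable => goal reachable, none sealed
    }
    for (w in cand) {
      if (added >= n_walls) break
      trial <- c(walls, w)
      if (probe(trial)) {
        walls <- trial
        added <- added + 1L
      }
    }
    hw_maze(id, width, height, start, goal, walls = walls)
  })
}

#' The fixture maze set
#'
#' Twelve seeded 6x6 mazes of graded wall complexity (2 to 13 interior
#' walls), standing in for a digitized Hebb-Williams series. They are
#' synthetic stand-ins generated by [generate_maze()], not digitizations of
#' the historical apparatus. The grade is chosen so that an error-free
#' navigator completes the default training protocol at roughly 150
#' successful trials per hour, leaving realistic headroom above trained
#' human-scale performance.
#'
#' @param n Number of mazes (default 12, max 12).
#' @return A list of `hw_maze` objects named `hw01` ... `hw12`.
#' @export
hw_fixture_mazes <- function(n = 12) {
  stopifnot(n >= 1, n <= 12)
  complexity <- seq(2L, 13L)[seq_len(n)]
  lapply(seq_len(n), function(k) {
    generate_maze(sprintf("hw%02d", k), n_walls = complexity[k],
                  seed = 7000L + k)
  }) |> stats::setNames(sprintf("hw%02d", seq_len(n)))
}
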