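# Shortest-path geometry on the maze grid. Movement rules: orthogonal steps
# cost 1; diagonal steps cost sqrt(2) and are subject to no corner cutting.
# The "steps" metric counts every move as 1 regardless of direction.

SQRT2 <- sqrt(2)

# Dijkstra distance field from a single cell over the whole grid.
# metric "cost" weighs diagonals sqrt(2); "steps" counts moves.
# Returns a height x width numeric matrix (Inf = unreachable).
dist_field <- function(m, from, metric = c("cost", "steps"), diagonal = TRUE) {
  metric <- match.arg(metric)
  key <- sprintf("dist_%s_%s_%d_%d", metric, diagonal, from$row, from$col)
  if (!is.null(m$cache[[key]])) return(m$cache[[key]])
  H <- m$height; W <- m$width
  od <- open_dirs(m)
  dirs <- if (diagonal) 1:8 else c(1L, 3L, 5L, 7L)
  stepcost <- ifelse(dirs %% 2L == 0L,
                     if (metric == "cost") SQRT2 else 1, 1)
  dist <- matrix(Inf, H, W)
  done <- matrix(FALSE, H, W)
  dist[from$row + 1L, from$col + 1L] <- 0
  repeat {
    # grids are tiny (<= a few hundred cells): linear min scan is fine
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0L) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    r <- (u - 1L) %% H; cc <- (u - 1L) %/% H
    for (k in seq_along(dirs)) {
      d <- dirs[k]
      if (!od[r + 1L, cc + 1L, d]) next
      rr <- r + HEADING_DROW[d]; ccn <- cc + HEADING_DCOL[d]
      alt <- dist[u] + stepcost[k]
      if (alt < dist[rr + 1L, ccn + 1L] - 1e-12) {
        dist[rr + 1L, ccn + 1L] <- alt
      }
    }
  }
  m$cache[[key]] <- dist
  dist
}

#' Minimum-cost path from start to goal
#'
#' Computes a minimum-cost path under the movement rules: orthogonal steps
#' cost 1; when `diagonal = TRUE`, diagonal steps cost `sqrt(2)` and must
#' not cut corners. Ties are broken deterministically by preferring the
#' lexicographically smallest successor cell (row, then col).
#'
#' @param m An `hw_maze`.
#' @param diagonal Allow diagonal moves (default `TRUE`).
#' @param from Optional start cell (list with `row`, `col`); defaults to the
#'   maze start.
#' @return An object of class `hw_path`: a list with `cells` (a matrix of
#'   0-based `(row, col)` positions, start first, goal last), `length`
#'   (number of moves) and `cost` (total move cost).
#' @export
shortest_path <- function(m, diagonal = TRUE, from = NULL) {
  if (is.null(from)) from <- m$start
  dist <- dist_field(m, from = m$goal, metric = "cost", diagonal = diagonal)
  if (!is.finite(dist[from$row + 1L, from$col + 1L])) {
    stop(structure(
      class = c("hwnav_no_path", "error", "condition"),
      list(message = sprintf("no path from (%d,%d) to goal (%d,%d) in maze '%s'",
                             from$row, from$col, m$goal$row, m$goal$col, m$id),
           call = NULL)))
  }
  od <- open_dirs(m)
  dirs <- if (diagonal) 1:8 else c(1L, 3L, 5L, 7L)
  r <- from$row; cc <- from$col
  cells <- matrix(c(r, cc), ncol = 2)
  cost <- 0
  while (!(r == m$goal$row && cc == m$goal$col)) {
    best <- NULL
    for (d in dirs) {
      if (!od[r + 1L, cc + 1L, d]) next
      rr <- r + HEADING_DROW[d]; ccn <- cc + HEADING_DCOL[d]
      sc <- if (d %% 2L == 0L) SQRT2 else 1
      if (abs(dist[rr + 1L, ccn + 1L] + sc -
              dist[r + 1L, cc + 1L]) < 1e-9) {
        if (is.null(best) || rr < best[1] || (rr == best[1] && ccn < best[2])) {
          best <- c(rr, ccn, sc)
        }
      }
    }
    r <- best[1]; cc <- best[2]; cost <- cost + best[3]
    cells <- rbind(cells, c(r, cc))
  }
  structure(list(cells = unname(cells), length = nrow(cells) - 1L, cost = cost),
            class = "hw_path")
}

#' @export
print.hw_path <- function(x, ...) {
  cat(sprintf("<hw_path> %d moves, cost %.3f: (%d,%d) -> (%d,%d)\n",
              x$length, x$cost,
              x$cells[1, 1], x$cells[1, 2],
              x$cells[nrow(x$cells), 1], x$cells[nrow(x$cells), 2]))
  invisible(x)
}

#' Error zone: cells far from the optimal corridor
#'
#' The error zone is the set of cells whose minimum step distance (every
#' move counts 1, diagonals included) to any cell of the shortest path
#' exceeds `corridor_radius`. Entering it penalizes the trial score. The
#' start and goal lie on the path and are never in the zone.
#'
#' @param m An `hw_maze`.
#' @param corridor_radius Non-negative integer corridor half-width in cells
#'   (default 1).
#' @param diagonal Movement rule used for the path and the distance metric.
#' @return Matrix of 0-based `(row, col)` zone cells (possibly 0 rows).
#' @seealso [error_zone_mask()] for the full logical grid.
#' @export
error_zones <- function(m, corridor_radius = 1, diagonal = TRUE) {
  stopifnot(corridor_radius >= 0)
  mask <- error_zone_mask(m, corridor_radius, diagonal)
  idx <- which(mask, arr.ind = TRUE)
  cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L)
}

#' @rdname error_zones
#' @return `error_zone_mask()` returns a `height` x `width` logical matrix,
#'   `TRUE` where the cell is in the error zone.
#' @export
error_zone_mask <- function(m, corridor_radius = 1, diagonal = TRUE) {
  key <- sprintf("zone_%g_%s", corridor_radius, diagonal)
  if (!is.null(m$cache[[key]])) return(m$cache[[key]])
  p <- shortest_path(m, diagonal = diagonal)
  # multi-source BFS in the steps metric from all path cells
  dmin <- matrix(Inf, m$height, m$width)
  for (i in seq_len(nrow(p$cells))) {
    d <- dist_field(m, from = list(row = p$cells[i, 1], col = p$cells[i, 2]),
                    metric = "steps", diagonal = diagonal)
    dmin <- pmin(dmin, d)
  }
  mask <- dmin > corridor_radius
  m$cache[[key]] <- mask
  mask
}
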