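# Hebb-Williams style grid mazes: a width x height cell grid with thin wall
# barriers on edges between orthogonally adjacent cells. The perimeter is
# implicitly fully walled and never stored.

edge_key <- function(r1, c1, r2, c2) {
  swap <- (r1 > r2) | (r1 == r2 & c1 > c2)
  a1 <- ifelse(swap, r2, r1); b1 <- ifelse(swap, c2, c1)
  a2 <- ifelse(swap, r1, r2); b2 <- ifelse(swap, c1, c2)
  paste0(a1, ",", b1, "-", a2, ",", b2)
}

# parse "r1,c1-r2,c2" back into a 4-column integer matrix
edge_unkey <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(integer(0), ncol = 4,
                  dimnames = list(NULL, c("r1", "c1", "r2", "c2"))))
  }
  parts <- do.call(rbind, strsplit(keys, "[,-]"))
  m <- matrix(as.integer(parts), ncol = 4)
  colnames(m) <- c("r1", "c1", "r2", "c2")
  m
}

#' Construct a Hebb-Williams style grid maze
#'
#' A maze is a `height` x `width` grid of cells with thin walls placed on
#' edges between orthogonally adjacent cells. The outer perimeter is
#' implicitly walled. The start pose carries a heading; the goal is a cell.
#' Coordinates are 0-based with row 0 at the top of the allocentric map.
#'
#' @param id Character maze identifier.
#' @param width,height Grid dimensions in cells.
#' @param start List with `row`, `col`, `heading` (the entry pose).
#' @param goal List with `row`, `col` (the exit cell).
#' @param walls Either a character vector of canonical edge keys
#'   (`"r1,c1-r2,c2"`) or a list of wall edges, each edge a pair of
#'   `c(row, col)` cells. Duplicate edges collapse (set semantics).
#' @param validate If `TRUE` (default) the maze must pass [validate_maze()];
#'   violations raise an error of class `hwnav_invalid_maze`.
#' @return An object of class `hw_maze`.
#' @seealso [load_maze()], [validate_maze()], [shortest_path()]
#' @examples
#' m <- hw_maze("open6", 6, 6,
#'              start = list(row = 5, col = 0, heading = "N"),
#'              goal = list(row = 0, col = 5))
#' print(m)
#' @export
hw_maze <- function(id, width, height, start, goal, walls = character(),
                    validate = TRUE) {
  if (is.list(walls)) {
    walls <- vapply(walls, function(e) {
      e1 <- as.integer(e[[1]]); e2 <- as.integer(e[[2]])
      edge_key(e1[1], e1[2], e2[1], e2[2])
    }, character(1))
  }
  m <- structure(
    list(
      id = as.character(id),
      width = as.integer(width),
      height = as.integer(height),
      start = list(row = as.integer(start$row), col = as.integer(start$col),
                   heading = as.character(start$heading)),
      goal = list(row = as.integer(goal$row), col = as.integer(goal$col)),
      walls = sort(unique(as.character(walls))),
      cache = new.env(parent = emptyenv())
    ),
    class = "hw_maze"
  )
  if (validate) {
    v <- validate_maze(m)
    if (length(v) > 0) {
      stop(structure(
        class = c("hwnav_invalid_maze", "error", "condition"),
        list(message = paste0("invalid maze '", m$id, "':\n  ",
                              paste(v, collapse = "\n  ")),
             call = sys.call(-1))))
    }
  }
  m
}

in_range <- function(m, row, col) {
  row >= 0L & row < m$height & col >= 0L & col < m$width
}

#' Validate a maze against its structural invariants
#'
#' Checks that the grid dimensions are positive, that start and goal are
#' in-range and distinct, that the start heading is a compass value, that
#' every wall edge joins orthogonally adjacent in-range cells, and that the
#' goal is reachable from the start under the movement rules.
#'
#' @param m An `hw_maze` (possibly constructed with `validate = FALSE`).
#' @return A character vector of violation messages; `character(0)` means
#'   the maze is valid. Violations are data, not errors.
#' @export
validate_maze <- function(m) {
  v <- character()
  if (m$width < 1L || m$height < 1L) {
    v <- c(v, sprintf("dimensions: width/height must be >= 1 (got %dx%d)",
                      m$width, m$height))
  }
  if (!in_range(m, m$start$row, m$start$col)) {
    v <- c(v, sprintf("start: cell (%d,%d) out of range",
                      m$start$row, m$start$col))
  }
  if (!m$start$heading %in% HEADINGS) {
    v <- c(v, sprintf("start: unknown heading '%s'", m$start$heading))
  }
  if (!in_range(m, m$goal$row, m$goal$col)) {
    v <- c(v, sprintf("goal: cell (%d,%d) out of range",
                      m$goal$row, m$goal$col))
  }
  if (m$start$row == m$goal$row && m$start$col == m$goal$col) {
    v <- c(v, sprintf("start/goal: start equals goal at (%d,%d)",
                      m$start$row, m$start$col))
  }
  e <- edge_unkey(m$walls)
  for (i in seq_len(nrow(e))) {
    ok_range <- in_range(m, e[i, "r1"], e[i, "c1"]) &&
      in_range(m, e[i, "r2"], e[i, "c2"])
    adj <- abs(e[i, "r1"] - e[i, "r2"]) + abs(e[i, "c1"] - e[i, "c2"]) == 1L
    if (!ok_range) {
      v <- c(v, sprintf("wall %s: cell out of range", m$walls[i]))
    } else if (!adj) {
      v <- c(v, sprintf("wall %s: cells are not orthogonally adjacent",
                        m$walls[i]))
    }
  }
  # reachability only meaningful if everything else is structurally sound
  if (length(v) == 0) {
    d <- dist_field(m, from = m$goal, metric = "steps", diagonal = TRUE)
    if (!is.finite(d[m$start$row + 1L, m$start$col + 1L])) {
      v <- c(v, sprintf("reachability: goal (%d,%d) unreachable from start (%d,%d)",
                        m$goal$row, m$goal$col, m$start$row, m$start$col))
    }
  }
  v
}

# TRUE if a single step from (row, col) along `heading` is legal: the target
# is in range, the crossed orthogonal edge is unwalled, and a diagonal step
# does not cut a corner (all four wall segments meeting at the crossed
# corner must be open).
step_open <- function(m, row, col, heading) {
  open_dirs(m)[row + 1L, col + 1L, heading_index(heading)]
}

# height x width x 8 logical array of legal single steps, memoised per maze
open_dirs <- function(m) {
  if (!is.null(m$cache$open_dirs)) return(m$cache$open_dirs)
  H <- m$height; W <- m$width
  wallset <- m$walls
  blocked_edge <- function(r1, c1, r2, c2) edge_key(r1, c1, r2, c2) %in% wallset
  arr <- array(FALSE, dim = c(H, W, 8L))
  for (r in 0:(H - 1L)) for (cc in 0:(W - 1L)) for (d in 1:8) {
    rr <- r + HEADING_DROW[d]; ccn <- cc + HEADING_DCOL[d]
    if (rr < 0L || rr >= H || ccn < 0L || ccn >= W) next
    if (d %% 2L == 1L) {           # orthogonal
      arr[r + 1L, cc + 1L, d] <- !blocked_edge(r, cc, rr, ccn)
    } else {                       # diagonal: no corner cutting
      arr[r + 1L, cc + 1L, d] <-
        !blocked_edge(r, cc, r, ccn) && !blocked_edge(r, cc, rr, cc) &&
        !blocked_edge(rr, ccn, r, ccn) && !blocked_edge(rr, ccn, rr, cc)
    }
  }
  m$cache$open_dirs <- arr
  arr
}

#' Distance along a heading to the nearest wall
#'
#' Marches cell by cell from `p` along heading `h` and counts how many cells
#' are traversable before a blocked edge (interior wall or perimeter) stops
#' the ray. A return of 0 means the immediately adjacent edge ahead is
#' blocked. Diagonal rays obey the no-corner-cutting rule.
#'
#' @param m An `hw_maze`.
#' @param p List or vector with `row` and `col` (0-based).
#' @param h Heading string.
#' @return Integer distance in cell units, in `[0, max(width, height)]`.
#' @export
wall_distance <- function(m, p, h) {
  r <- as.integer(p[["row"]]); cc <- as.integer(p[["col"]])
  if (!in_range(m, r, cc)) stop("position out of range", call. = FALSE)
  od <- open_dirs(m)
  di <- heading_index(h)
  d <- 0L
  while (od[r + 1L, cc + 1L, di]) {
    r <- r + HEADING_DROW[di]; cc <- cc + HEADING_DCOL[di]
    d <- d + 1L
  }
  d
}

#' @export
print.hw_maze <- function(x, ...) {
  cat(sprintf("<hw_maze '%s'> %dx%d cells, %d interior walls\n",
              x$id, x$width, x$height, length(x$walls)))
  cat(sprintf("  start (%d,%d) facing %s -> goal (%d,%d)\n",
              x$start$row, x$start$col, x$start$heading,
              x$goal$row, x$goal$col))
  cat(render_maze(x), sep = "\n")
  invisible(x)
}

#' Render the allocentric top view of a maze as ASCII art
#'
#' @param m An `hw_maze`.
#' @param path Optional `hw_path` (from [shortest_path()]) whose cells are
#'   marked with `*`.
#' @return Character vector of lines (`S` start, `G` goal, `*` path).
#' @export
render_maze <- function(m, path = NULL) {
  H <- m$height; W <- m$width
  wallset <- m$walls
  has_wall <- function(r1, c1, r2, c2) edge_key(r1, c1, r2, c2) %in% wallset
  mark <- matrix(" ", H, W)
  if (!is.null(path)) {
    for (i in seq_len(nrow(path$cells))) {
      mark[path$cells[i, 1] + 1L, path$cells[i, 2] + 1L] <- "*"
    }
  }
  mark[m$start$row + 1L, m$start$col + 1L] <- "S"
  mark[m$goal$row + 1L, m$goal$col + 1L] <- "G"
  lines <- character(2L * H + 1L)
  lines[1] <- paste0("+", paste(rep("--+", W), collapse = ""))
  for (r in 0:(H - 1L)) {
    body <- "|"
    for (cc in 0:(W - 1L)) {
      right <- if (cc == W - 1L) "|" else if (has_wall(r, cc, r, cc + 1L)) "|" else " "
      body <- paste0(body, mark[r + 1L, cc + 1L], " ", right)
    }
    lines[2L * r + 2L] <- body
    bottom <- "+"
    for (cc in 0:(W - 1L)) {
      seg <- if (r == H - 1L) "--" else if (has_wall(r, cc, r + 1L, cc)) "--" else "  "
      bottom <- paste0(bottom, seg, "+")
    }
    lines[2L * r + 3L] <- bottom
  }
  lines
}

#' Read and write mazes as JSON
#'
#' The on-disk dialect is
#' `{"id", "width", "height", "start": {"row","col","heading"},
#' "goal": {"row","col"}, "walls": [[[r1,c1],[r2,c2]], ...]}`.
#' In strict mode unknown top-level keys are rejected; otherwise they are
#' dropped with a warning. Round-tripping preserves the wall set, start and
#' goal exactly.
#'
#' @param path File path.
#' @param strict Reject unknown top-level keys (default `TRUE`).
#' @return `load_maze()` returns a validated `hw_maze`; `save_maze()`
#'   returns `path` invisibly.
#' @export
load_maze <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("maze file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop(structure(
      class = c("hwnav_format_error", "error", "condition"),
      list(message = paste0("cannot parse maze JSON '", path, "': ",
                            conditionMessage(e)), call = NULL)))
  )
  known <- c("id", "width", "height", "start", "goal", "walls")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    if (strict) {
      stop(structure(
        class = c("hwnav_format_error", "error", "condition"),
        list(message = paste0("unknown keys in maze file: ",
                              paste(extra, collapse = ", ")), call = NULL)))
    }
    warning("ignoring unknown maze keys: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  missing <- setdiff(known, names(raw))
  if (length(missing) > 0) {
    stop(structure(
      class = c("hwnav_format_error", "error", "condition"),
      list(message = paste0("maze file missing keys: ",
                            paste(missing, collapse = ", ")), call = NULL)))
  }
  walls <- lapply(raw$walls, function(e) {
    list(c(e[[1]][[1]], e[[1]][[2]]), c(e[[2]][[1]], e[[2]][[2]]))
  })
  hw_maze(id = raw$id, width = raw$width, height = raw$height,
          start = raw$start, goal = raw$goal, walls = walls)
}

#' @rdname load_maze
#' @param m An `hw_maze` to serialize.
#' @export
save_maze <- function(m, path) {
  e <- edge_unkey(m$walls)
  walls <- lapply(seq_len(nrow(e)), function(i) {
    list(c(e[i, "r1"], e[i, "c1"]), c(e[i, "r2"], e[i, "c2"]))
  })
  obj <- list(id = m$id, width = m$width, height = m$height,
              start = m$start, goal = m$goal, walls = walls)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
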