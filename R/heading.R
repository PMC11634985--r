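# Compass geometry shared by the maze and navigation modules.
#
# Cells are 0-based (row, col), row 0 at the top of the allocentric map, so
# "N" decreases the row index. The eight headings advance clockwise in 45
# degree increments.

HEADINGS <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

# row/col displacement of a single step along each heading, indexed 1..8
# in the order of HEADINGS
HEADING_DROW <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
HEADING_DCOL <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Heading utilities
#'
#' Headings are the eight compass directions at 45 degree increments,
#' stored as the strings `"N", "NE", ..., "NW"`. `turn_heading()` rotates a
#' heading by a number of 45 degree increments (positive = clockwise), so
#' `turn_heading(h, 1)` is a right swipe and `turn_heading(h, -1)` a left
#' swipe.
#'
#' @param heading A heading string, one of `"N","NE","E","SE","S","SW","W","NW"`.
#' @param n45 Integer number of 45 degree clockwise increments (may be
#'   negative for counter-clockwise).
#' @return `turn_heading()` returns the rotated heading string;
#'   `heading_index()` the 1-based index into the clockwise compass order;
#'   `heading_delta()` an integer vector `c(drow, dcol)`.
#' @examples
#' turn_heading("N", 1)   # "NE"
#' turn_heading("N", -1)  # "NW"
#' heading_delta("SE")    # c(1, 1)
#' @export
turn_heading <- function(heading, n45) {
  i <- heading_index(heading)
  HEADINGS[((i - 1L + as.integer(n45)) %% 8L) + 1L]
}

#' @rdname turn_heading
#' @export
heading_index <- function(heading) {
  i <- match(heading, HEADINGS)
  if (any(is.na(i))) {
    stop("unknown heading: ", paste(heading[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

#' @rdname turn_heading
#' @export
heading_delta <- function(heading) {
  i <- heading_index(heading)
  c(HEADING_DROW[i], HEADING_DCOL[i])
}

is_diagonal_heading <- function(heading) {
  heading_index(heading) %% 2L == 0L
}

# signed number of 45-degree clockwise turns taking `from` to `to`,
# in -3..4 (180 degrees reported as +4, i.e. ties broken clockwise)
heading_turn_diff <- function(from, to) {
  d <- (heading_index(to) - heading_index(from)) %% 8L
  if (d > 4L) d - 8L else d
}
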