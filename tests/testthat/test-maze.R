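# Maze representation, validation, JSON I/O and geometric queries.

test_that("maze JSON loading honors set semantics and rejects bad files", {
  f <- tempfile(fileext = ".json")
  writeLines('{"id":"open6","width":6,"height":6,
    "start":{"row":5,"col":0,"heading":"N"},
    "goal":{"row":0,"col":5},"walls":[]}', f)
  m <- load_maze(f)
  expect_s3_class(m, "hw_maze")
  expect_length(m$walls, 0)

  # duplicated wall edge collapses to one (set semantics)
  writeLines('{"id":"dup","width":6,"height":6,
    "start":{"row":5,"col":0,"heading":"N"},
    "goal":{"row":0,"col":5},
    "walls":[[[0,0],[0,1]],[[0,1],[0,0]]]}', f)
  m2 <- load_maze(f)
  expect_length(m2$walls, 1)

  # sealing off the goal must be rejected; BFS reachability agrees
  writeLines('{"id":"sealed","width":3,"height":3,
    "start":{"row":2,"col":0,"heading":"N"},
    "goal":{"row":0,"col":2},
    "walls":[[[0,1],[0,2]],[[1,2],[0,2]],[[1,1],[1,2]],[[1,2],[2,2]]]}', f)
  expect_error(load_maze(f), class = "hwnav_invalid_maze")

  writeLines('{"id":"x","width":6,"height":6,"bogus":1,
    "start":{"row":5,"col":0,"heading":"N"},
    "goal":{"row":0,"col":5},"walls":[]}', f)
  expect_error(load_maze(f), class = "hwnav_format_error")
  expect_warning(m3 <- load_maze(f, strict = FALSE), "bogus")
  expect_s3_class(m3, "hw_maze")

  writeLines("not json {", f)
  expect_error(load_maze(f), class = "hwnav_format_error")
})

test_that("validate_maze reports violations as data", {
  expect_length(validate_maze(open_maze()), 0)

  m <- hw_maze("bad", 6, 6, start = list(row = 0, col = 0, heading = "N"),
               goal = list(row = 0, col = 0), validate = FALSE)
  v <- validate_maze(m)
  expect_length(v, 1)
  expect_match(v, "start equals goal")

  m2 <- hw_maze("diagwall", 6, 6,
                start = list(row = 5, col = 0, heading = "N"),
                goal = list(row = 0, col = 5),
                walls = list(list(c(0, 0), c(1, 1))), validate = FALSE)
  v2 <- validate_maze(m2)
  expect_length(v2, 1)
  expect_match(v2, "not orthogonally adjacent")
})

test_that("shortest paths match closed forms on the open maze", {
  m <- corner_maze()
  p <- shortest_path(m)
  expect_equal(p$length, 5)
  expect_equal(p$cost, 5 * sqrt(2), tolerance = 1e-12)
  # deterministic tie-break: the straight diagonal is lexicographically first
  expect_equal(p$cells[, 1], 0:5)
  expect_equal(p$cells[, 2], 0:5)

  p4 <- shortest_path(m, diagonal = FALSE)
  expect_equal(p4$length, 10)
  expect_equal(p4$cost, 10)
})

test_that("shortest-path costs equal the independent Dijkstra oracle on all fixtures", {
  for (m in FIXTURE_MAZES) {
    for (diag in c(TRUE, FALSE)) {
      expect_equal(shortest_path(m, diagonal = diag)$cost,
                   igraph_path_cost(m, diagonal = diag),
                   tolerance = 1e-9,
                   label = sprintf("%s diagonal=%s", m$id, diag))
    }
  }
})

test_that("shortest-path cost is invariant under maze transposition", {
  transpose_maze <- function(m) {
    e <- do.call(rbind, strsplit(m$walls, "[,-]"))
    walls <- lapply(seq_len(nrow(e)), function(i) {
      v <- as.integer(e[i, ])
      list(c(v[2], v[1]), c(v[4], v[3]))
    })
    hw_maze(paste0(m$id, "_t"), m$height, m$width,
            start = list(row = m$start$col, col = m$start$row, heading = "N"),
            goal = list(row = m$goal$col, col = m$goal$row),
            walls = if (length(walls)) walls else character())
  }
  for (m in FIXTURE_MAZES[c(2, 5, 9, 12)]) {
    mt <- transpose_maze(m)
    expect_equal(shortest_path(mt)$cost, shortest_path(m)$cost,
                 tolerance = 1e-9, label = m$id)
  }
})

test_that("wall_distance matches the brute-force ray march everywhere", {
  m <- open_maze()
  expect_equal(wall_distance(m, list(row = 0, col = 0), "E"), 5)
  withwall <- hw_maze("w", 6, 6,
                      start = list(row = 5, col = 0, heading = "N"),
                      goal = list(row = 0, col = 5),
                      walls = list(list(c(5, 0), c(4, 0))))
  expect_equal(wall_distance(withwall, list(row = 5, col = 0), "N"), 0)

  for (m in FIXTURE_MAZES[c(3, 8, 12)]) {
    for (r in 0:5) for (cc in 0:5) for (h in c("N", "NE", "E", "SE",
                                               "S", "SW", "W", "NW")) {
      expect_equal(wall_distance(m, list(row = r, col = cc), h),
                   ray_march_oracle(m, r, cc, h),
                   label = sprintf("%s (%d,%d) %s", m$id, r, cc, h))
      expect_lte(wall_distance(m, list(row = r, col = cc), h), 6)
    }
  }
})

test_that("error zones enumerate off-corridor cells and shrink with radius", {
  m <- corner_maze()
  # radius covering the whole grid: no cell is in the zone
  expect_equal(nrow(error_zones(m, corridor_radius = 10)), 0)
  # radius 0 on the diagonal route: exactly the 30 off-diagonal cells
  z0 <- error_zones(m, corridor_radius = 0)
  expect_equal(nrow(z0), 30)
  expect_true(all(z0[, "row"] != z0[, "col"]))

  for (m in FIXTURE_MAZES[c(4, 10)]) {
    prev <- error_zone_mask(m, 0)
    for (r in 1:6) {
      cur <- error_zone_mask(m, r)
      expect_true(all(prev | !cur), label = sprintf("%s r=%d", m$id, r))
      prev <- cur
    }
  }
})

test_that("save/load round-trips every fixture maze", {
  for (m in FIXTURE_MAZES) {
    f <- tempfile(fileext = ".json")
    save_maze(m, f)
    m2 <- load_maze(f)
    expect_identical(m2$walls, m$walls, label = m$id)
    expect_identical(m2$start, m$start, label = m$id)
    expect_identical(m2$goal, m$goal, label = m$id)
    unlink(f)
  }
  shipped <- system.file("extdata", "synthetic_hw07.json", package = "hwnav")
  expect_identical(load_maze(shipped)$walls, FIXTURE_MAZES$hw07$walls)
})

test_that("maze generation is deterministic and graded", {
  m1 <- generate_maze("g", 8, seed = 123)
  m2 <- generate_maze("g", 8, seed = 123)
  expect_identical(m1$walls, m2$walls)
  expect_length(m1$walls, 8)
  expect_length(validate_maze(m1), 0)
  # ASCII rendering covers the full grid
  lines <- render_maze(m1)
  expect_length(lines, 13)
  expect_match(paste(lines, collapse = ""), "S")
  expect_match(paste(lines, collapse = ""), "G")
})
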