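wall_between <- function(height = 2.5) {
  maze_layout(coords = data.frame(id = 1:2, x = c(0, 10), y = 0),
              walls = data.frame(x1 = 5, y1 = -3, x2 = 5, y2 = 3,
                                 height = height))
}

test_that("line of sight respects interpolated heights at crossings", {
  empty <- maze_layout(coords = data.frame(id = 1:2, x = c(0, 10), y = 0),
                       walls = data.frame())
  expect_true(line_of_sight(empty, c(0, 0, 1.4), c(10, 0, 1.4)))

  l <- wall_between(2.5)
  expect_false(line_of_sight(l, c(0, 0, 1.4), c(10, 0, 1.4)))
  expect_true(line_of_sight(l, c(0, 0, 5.3), c(10, 0, 5.3)))
  # sightline descending over the wall: height at the crossing (midway)
  # is (5.3 + 1.4) / 2 = 3.35 > 2.5
  expect_true(line_of_sight(l, c(0, 0, 5.3), c(10, 0, 1.4)))
  # but from further back the crossing happens lower
  expect_false(line_of_sight(l, c(-40, 0, 5.3), c(10, 0, 1.4)))
})

test_that("an endpoint exactly on a wall is treated as blocked", {
  l <- wall_between(2.5)
  expect_false(line_of_sight(l, c(5, 0, 1.4), c(10, 0, 1.4)))
})

test_that("raising both endpoints never destroys visibility", {
  for (s in 1:5) {
    lay <- random_wall_layout(8, seed = 100 + s)
    lay$walls$height <- withr::with_seed(s, runif(nrow(lay$walls), 1, 8))
    withr::with_seed(200 + s, {
      pts <- cbind(runif(20, -15, 15), runif(20, -15, 15))
      h <- runif(20, 0.5, 6)
      dh <- runif(20, 0, 4)
    })
    for (i in seq(1, 19, by = 2)) {
      lo <- line_of_sight(lay, c(pts[i, ], h[i]), c(pts[i + 1, ], h[i]))
      hi <- line_of_sight(lay, c(pts[i, ], h[i] + dh[i]),
                          c(pts[i + 1, ], h[i] + dh[i]))
      if (lo) expect_true(hi)
    }
  }
})

test_that("pointing-pair classification reproduces the task design", {
  pairs <- classify_pointing_pairs(packaged_maze_layout(), eye_height = 1.4)
  expect_equal(nrow(pairs), 72)
  expect_equal(sum(pairs$visible), 16)
  expect_equal(sum(!pairs$visible), 56)
  # visibility is exactly the route-consecutive pairs, and symmetric
  expect_equal(pairs$visible, abs(pairs$origin - pairs$target) == 1)
  flipped <- pairs
  names(flipped)[1:2] <- c("target", "origin")
  m <- merge(pairs, flipped, by = c("origin", "target"))
  expect_equal(m$visible.x, m$visible.y)
})

test_that("a straight two-location corridor is fully intervisible", {
  lay <- realize_layout(route_spec(
    locations = data.frame(id = 1:2, name = c("a", "b")),
    legs = data.frame(from = 1, to = 2, length = 10),
    turns = data.frame(at = integer(), angle = numeric())))
  pairs <- classify_pointing_pairs(lay, eye_height = 1.4)
  expect_equal(nrow(pairs), 2)
  expect_true(all(pairs$visible))
})

test_that("isovists behave analytically in degenerate environments", {
  open_box <- maze_layout(coords = data.frame(id = 1, x = 0, y = 0),
                          walls = data.frame(),
                          bounds = c(-10, -10, 10, 10))
  expect_equal(isovist(open_box, 1, 1.4)$scale_ratio, 1.0, tolerance = 1e-6)

  # infinite wall bisecting the square: exactly half visible
  half <- maze_layout(coords = data.frame(id = 1, x = -5, y = 0),
                      walls = data.frame(x1 = 0, y1 = -10, x2 = 0, y2 = 10,
                                         height = 100),
                      bounds = c(-10, -10, 10, 10))
  expect_equal(isovist(half, 1, 1.4, angular_resolution = 0.1)$scale_ratio,
               0.5, tolerance = 0.005)

  expect_error(isovist(open_box, 1, angular_resolution = 2), "resolution")
  outside <- maze_layout(coords = data.frame(id = 1, x = 50, y = 0),
                         walls = data.frame(),
                         bounds = c(-10, -10, 10, 10))
  expect_error(isovist(outside, 1), "outside")
})

test_that("elevated isovists are at least as large as ground isovists", {
  lay <- packaged_maze_layout()
  for (loc in c(1, 3, 5, 7, 9)) {
    g <- isovist(lay, loc, eye_height = 1.4, angular_resolution = 0.5)
    e <- isovist(lay, loc, eye_height = 5.3, angular_resolution = 0.5)
    expect_gte(e$scale_ratio, g$scale_ratio - 1e-9)
  }
  # hedges are below the elevated eye: the whole bounds become visible
  # (up to the angular discretization of the sweep)
  e <- isovist(lay, 5, eye_height = 5.3, angular_resolution = 0.5)
  expect_equal(e$scale_ratio, 1.0, tolerance = 1e-3)
})

test_that("sweep isovist areas agree with the rasterized oracle within 2%", {
  for (s in 1:4) {
    n_walls <- c(3, 6, 8, 10)[s]
    lay <- random_wall_layout(n_walls, seed = 40 + s)
    iso <- isovist(lay, 1, eye_height = 1.4, angular_resolution = 0.25)
    oracle <- raster_visible_area(lay, 1, eye_height = 1.4, n = 150)
    expect_equal(iso$area, oracle, tolerance = 0.02)
  }
})

test_that("isovist GeoJSON export carries the polygon and metadata", {
  lay <- random_wall_layout(5, seed = 7)
  iso <- isovist(lay, 1, eye_height = 1.4, angular_resolution = 1)
  gj <- jsonlite::fromJSON(isovist_geojson(iso), simplifyVector = FALSE)
  expect_equal(gj$geometry$type, "Polygon")
  expect_equal(gj$properties$scale_ratio, iso$scale_ratio)
  expect_equal(length(gj$geometry$coordinates[[1]]), nrow(iso$polygon) + 1)
})

test_that("landmark visibility realizes the designed perspective manipulation", {
  lay <- packaged_maze_layout()
  # at the third location, ground view: own landmark is the only
  # non-adjacent one visible
  own <- lay$landmarks$name[3]
  adj <- lay$landmarks$name[c(2, 4)]
  g3 <- visible_landmarks(lay, 3, eye_height = 1.4)
  expect_true(own %in% g3)
  expect_setequal(setdiff(g3, adj), own)
  # exactly one landmark gained from the elevated perspective at the
  # locations that offered it
  for (loc in c(2, 4, 6, 8)) {
    g <- visible_landmarks(lay, loc, eye_height = 1.4)
    e <- visible_landmarks(lay, loc, eye_height = 5.3)
    expect_true(all(g %in% e))
    expect_equal(length(e) - length(g), 1)
  }
  # without walls every landmark is visible
  open <- maze_layout(coords = lay$coords, walls = data.frame(),
                      landmarks = lay$landmarks)
  expect_setequal(visible_landmarks(open, 1, 1.4), lay$landmarks$name)
})
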