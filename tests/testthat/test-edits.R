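test_that("an empty edit list is the identity", {
  spec <- maze_route()
  expect_equal(apply_edits(spec, list()), spec)
})

test_that("deleting a leg translates the downstream sub-route rigidly", {
  spec <- maze_route()
  base <- realize_layout(spec)
  cut <- realize_layout(apply_edits(spec, edit_delete_leg(5, 6)))
  # the removed leg ran 22 m north; everything from location 6 on moves
  # back by exactly that vector, and location 6 fuses onto location 5
  expect_equal(cut$coords$x[6:9], base$coords$x[6:9])
  expect_equal(cut$coords$y[6:9], base$coords$y[6:9] - 22)
  expect_equal(unname(unlist(cut$coords[6, c("x", "y")])),
               unname(unlist(cut$coords[5, c("x", "y")])),
               tolerance = 1e-12)
  # upstream untouched
  expect_equal(cut$coords[1:5, ], base$coords[1:5, ])
})

test_that("leg lengths can be matched to another leg exactly", {
  spec <- apply_edits(maze_route(),
                      edit_set_leg_length(6, 7, match_leg = c(8, 9)))
  expect_identical(spec$legs$length[spec$legs$from == 6],
                   spec$legs$length[spec$legs$from == 8])
})

test_that("sub-route rotation is rigid downstream", {
  spec <- maze_route()
  base <- realize_layout(spec)
  rot <- realize_layout(apply_edits(spec, edit_rotate_subroute(7, -90)))
  d <- function(lay, i, j) {
    sqrt(diff(lay$coords$x[c(i, j)])^2 + diff(lay$coords$y[c(i, j)])^2)
  }
  for (p in list(c(7, 8), c(8, 9), c(7, 9))) {
    expect_equal(d(rot, p[1], p[2]), d(base, p[1], p[2]), tolerance = 1e-9)
  }
  expect_equal(rot$coords[1:7, ], base$coords[1:7, ])
})

test_that("dangling edit references are reported by name", {
  spec <- maze_route()
  expect_error(apply_edits(spec, edit_delete_leg(4, 6)), "delete_leg")
  expect_error(apply_edits(spec, edit_set_leg_length(1, 2, match_leg = c(9, 10))),
               "match_leg")
  expect_error(apply_edits(spec, edit_rotate_subroute(1, 90)),
               "rotate_subroute")
  expect_error(edit_set_leg_length(1, 2), "exactly one")
  expect_error(edit_set_leg_length(1, 2, length = -3) |>
                 apply_edits(spec = spec), "positive")
})

test_that("the packaged alternative representation composes the three edits", {
  spec <- maze_route()
  alt <- alternative_route(spec)
  # compressed leg equals the final leg
  expect_identical(alt$legs$length[alt$legs$from == 6],
                   spec$legs$length[spec$legs$from == 8])
  # still realizable (non-self-intersecting) under the default rotation
  lay <- realize_layout(alt)
  expect_equal(nrow(lay$coords), 9)
  # the rotated tail keeps its internal geometry (rigid motion): the
  # angle at location 8 and the pairwise distances are preserved
  base <- realize_layout(spec)
  d <- function(lay, i, j) {
    sqrt(diff(lay$coords$x[c(i, j)])^2 + diff(lay$coords$y[c(i, j)])^2)
  }
  for (p in list(c(7, 8), c(8, 9), c(7, 9))) {
    expect_equal(d(lay, p[1], p[2]), d(base, p[1], p[2]), tolerance = 1e-9)
  }
  ang_at8 <- function(l) {
    v1 <- c(l$coords$x[7] - l$coords$x[8], l$coords$y[7] - l$coords$y[8])
    v2 <- c(l$coords$x[9] - l$coords$x[8], l$coords$y[9] - l$coords$y[8])
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  expect_equal(ang_at8(lay), ang_at8(base), tolerance = 1e-9)
})

test_that("inverse edits restore untouched leg lengths", {
  spec <- maze_route()
  alt <- alternative_route(spec)
  undone <- apply_edits(alt, list(
    edit_rotate_subroute(7, 90),
    edit_set_leg_length(6, 7, length = spec$legs$length[spec$legs$from == 6])
  ))
  keep <- undone$legs$from != 5
  expect_equal(undone$legs$length[keep],
               spec$legs$length[spec$legs$from != 5])
  expect_equal(undone$turns$angle[undone$turns$at %in% c(3, 4, 7, 8)],
               spec$turns$angle[spec$turns$at %in% c(3, 4, 7, 8)])
})

test_that("alternative directions for the distorted section differ substantially", {
  correct <- packaged_maze_layout()
  alt <- fixture_alternative_layout()
  # pointing from the start toward the displaced sixth location
  expect_gt(angular_error(true_direction(correct, 3, 6),
                          true_direction(alt, 3, 6)), 90)
  # locations upstream of the edits keep their geometry
  expect_equal(true_direction(correct, 1, 4), true_direction(alt, 1, 4))
})

test_that("model comparison is invariant under a global rigid motion", {
  pair <- toy_layout_pair()
  recs <- tibble::tibble(
    participant = "p1", session = 1L, origin = 1L, target = 3L,
    judged = withr::with_seed(3, rvonmises(12, 80, 10)))
  trials <- data.frame(origin = 1L, target = 3L)
  base <- compare_models(recs, trials, pair$correct, pair$alternative)

  move <- function(lay, th, dx, dy) {
    co <- lay$coords
    r <- th * pi / 180
    x <- co$x * cos(r) + co$y * sin(r) + dx
    y <- -co$x * sin(r) + co$y * cos(r) + dy
    maze_layout(data.frame(id = co$id, x = x, y = y), data.frame())
  }
  # rotate both candidate layouts and the judged azimuths together
  th <- 73
  recs_rot <- recs
  recs_rot$judged <- az_norm(recs$judged + th)
  rot <- compare_models(recs_rot, trials,
                        move(pair$correct, th, 5, -11),
                        move(pair$alternative, th, 5, -11))
  expect_equal(base$mean_error_correct, rot$mean_error_correct,
               tolerance = 1e-9)
  expect_equal(base$mean_error_alternative, rot$mean_error_alternative,
               tolerance = 1e-9)
  expect_equal(base$better_fit, rot$better_fit)
})
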