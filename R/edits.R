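#' Composable route edits
#'
#' Constructors for the three distortion operations out of which
#' alternative ("misremembered") maze representations are composed. Edits
#' apply to the intrinsic [route_spec()], never to coordinates, so every
#' edited route re-realizes deterministically:
#'
#' * `edit_delete_leg(from, to)` — forgetting a segment: the leg is
#'   removed and its endpoints fuse into one node; the downstream
#'   sub-route translates rigidly toward the upstream one, and the turn
#'   angles remembered at the two fused locations are summed at the joint.
#' * `edit_set_leg_length(from, to, length)` — misremembered leg length
#'   (alignment): one leg is rescaled, either to an explicit length in
#'   meters or to match another leg via `match_leg = c(a, b)`.
#' * `edit_rotate_subroute(at, angle)` — misjudging a turn: the signed
#'   angle (degrees, positive clockwise) is added to the turn at the given
#'   interior location, rigidly rotating everything downstream.
#'
#' @param from,to Location ids identifying a leg of the route.
#' @param length New length in meters (`edit_set_leg_length`).
#' @param match_leg Alternative to `length`: `c(a, b)` naming the leg
#'   whose length should be copied.
#' @param at Interior location id carrying the turn to modify.
#' @param angle Signed angle in degrees to add to the turn.
#' @return A `maze_edit` object.
#' @seealso [apply_edits()], [alternative_route()]
#' @export
edit_delete_leg <- function(from, to) {
  structure(list(type = "delete_leg", from = from, to = to),
            class = "maze_edit")
}

#' @rdname edit_delete_leg
#' @export
edit_set_leg_length <- function(from, to, length = NULL, match_leg = NULL) {
  if (is.null(length) == is.null(match_leg)) {
    stop("give exactly one of `length` or `match_leg`")
  }
  structure(list(type = "set_leg_length", from = from, to = to,
                 length = length, match_leg = match_leg),
            class = "maze_edit")
}

#' @rdname edit_delete_leg
#' @export
edit_rotate_subroute <- function(at, angle) {
  structure(list(type = "rotate_subroute", at = at, angle = angle),
            class = "maze_edit")
}

#' @export
print.maze_edit <- function(x, ...) {
  cat("<maze_edit>", x$type,
      switch(x$type,
             delete_leg = sprintf("(%s,%s)", x$from, x$to),
             set_leg_length = sprintf("(%s,%s) -> %s", x$from, x$to,
                                      if (is.null(x$length))
                                        sprintf("match (%s,%s)",
                                                x$match_leg[1], x$match_leg[2])
                                      else paste0(x$length, " m")),
             rotate_subroute = sprintf("at %s by %+g deg", x$at, x$angle)),
      "\n")
  invisible(x)
}

find_leg <- function(spec, from, to, edit_name) {
  i <- which(spec$legs$from == from & spec$legs$to == to)
  if (length(i) != 1) {
    stop(sprintf("edit %s references leg (%s,%s), which does not exist",
                 edit_name, from, to))
  }
  i
}

#' Apply a sequence of route edits
#'
#' Edits are applied in order to the intrinsic route description;
#' coordinates are re-derived afterwards with [realize_layout()]. An empty
#' edit list returns the spec unchanged.
#'
#' @param spec A [route_spec()].
#' @param edits A list of `maze_edit` objects.
#' @return The edited [route_spec()].
#' @export
apply_edits <- function(spec, edits) {
  validate_route_spec(spec)
  if (inherits(edits, "maze_edit")) edits <- list(edits)
  for (e in edits) {
    stopifnot(inherits(e, "maze_edit"))
    spec <- switch(
      e$type,
      delete_leg = {
        i <- find_leg(spec, e$from, e$to, "delete_leg")
        legs <- spec$legs[-i, ]
        turns <- spec$turns
        ang_from <- turns$angle[turns$at == e$from]
        ang_to <- turns$angle[turns$at == e$to]
        turns <- turns[!(turns$at %in% c(e$from, e$to)), ]
        # outgoing leg (if any) now departs the fused node carrying the
        # sum of the turns remembered at both fused locations
        if (any(legs$from == e$to)) {
          turns <- dplyr::bind_rows(
            turns,
            tibble::tibble(
              at = e$to,
              angle = sum(ang_from, ang_to)
            ))
          turns <- turns[order(match(turns$at, spec$locations$id)), ]
        }
        coin <- spec$coincident
        coin[[as.character(e$to)]] <- e$from
        route_spec(spec$locations, legs, turns, coincident = coin)
      },
      set_leg_length = {
        i <- find_leg(spec, e$from, e$to, "set_leg_length")
        new_len <- if (!is.null(e$length)) {
          e$length
        } else {
          j <- find_leg(spec, e$match_leg[1], e$match_leg[2],
                        "set_leg_length (match_leg)")
          spec$legs$length[j]
        }
        if (new_len <= 0) stop("new leg length must be positive")
        legs <- spec$legs
        legs$length[i] <- new_len
        route_spec(spec$locations, legs, spec$turns,
                   coincident = spec$coincident)
      },
      rotate_subroute = {
        turns <- spec$turns
        j <- which(turns$at == e$at)
        if (length(j) != 1) {
          stop(sprintf(
            "edit rotate_subroute references location %s, which has no turn",
            e$at))
        }
        turns$angle[j] <- turns$angle[j] + e$angle
        route_spec(spec$locations, spec$legs, turns,
                   coincident = spec$coincident)
      },
      stop("unknown edit type: ", e$type)
    )
  }
  spec
}

#' The packaged alternative maze representation
#'
#' The single unified distorted representation hypothesized to generate
#' the systematic pointing-error modes on the nine-location route: the
#' composition of (1) forgetting the leg between locations 5 and 6,
#' (2) compressing the leg between locations 6 and 7 to the length of the
#' leg between locations 8 and 9, and (3) rotating the sub-route carrying
#' the last three target locations by a quarter turn at location 7.
#'
#' The quarter turn's handedness is not constrained by the route
#' description itself; the default `rotation_sign = -1`
#' (counter-clockwise, folding the tail toward the maze body) keeps the
#' packaged route non-self-intersecting and is config-overridable.
#'
#' @param spec A nine-location [route_spec()] shaped like [maze_route()].
#' @param rotation_sign `+1` or `-1`, the sign of the 90-degree rotation.
#' @return The edited [route_spec()].
#' @examples
#' alt <- alternative_route(maze_route())
#' alt
#' @export
alternative_route <- function(spec, rotation_sign = -1) {
  validate_route_spec(spec)
  if (nrow(spec$locations) != 9 || nrow(spec$legs) != 8) {
    stop("alternative_route expects the nine-location route shape")
  }
  stopifnot(rotation_sign %in% c(-1, 1))
  apply_edits(spec, list(
    edit_delete_leg(5, 6),
    edit_set_leg_length(6, 7, match_leg = c(8, 9)),
    edit_rotate_subroute(7, rotation_sign * 90)
  ))
}
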