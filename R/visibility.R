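#' 2.5-D line-of-sight test
#'
#' Tests whether a straight sightline between two points in space clears
#' every hedge wall it crosses in plan view. For each wall segment crossed
#' by the planar projection of the sightline, the sightline's linearly
#' interpolated height at the crossing must strictly exceed the wall
#' height. An endpoint lying exactly on a wall at or below the wall height
#' counts as a crossing and is treated as blocked. Walls are opaque from
#' both sides.
#'
#' @param layout A [maze_layout()].
#' @param from,to Numeric `c(x, y, height)` in meters; must differ in plan
#'   view.
#' @return `TRUE` if the sightline is unobstructed.
#' @examples
#' l <- maze_layout(coords = data.frame(id = 1:2, x = c(0, 10), y = 0),
#'                  walls = data.frame(x1 = 5, y1 = -2, x2 = 5, y2 = 2,
#'                                     height = 2.5))
#' line_of_sight(l, c(0, 0, 1.4), c(10, 0, 1.4)) # blocked
#' line_of_sight(l, c(0, 0, 5.3), c(10, 0, 5.3)) # clears the hedge
#' @export
line_of_sight <- function(layout, from, to) {
  stopifnot(inherits(layout, "maze_layout"),
            length(from) == 3, length(to) == 3)
  if (sqrt(sum((from[1:2] - to[1:2])^2)) < 1e-12) {
    stop("from and to coincide in plan view")
  }
  w <- layout$walls
  if (!nrow(w)) return(TRUE)
  eps <- 1e-9
  dx <- to[1] - from[1]
  dy <- to[2] - from[2]
  ex <- w$x2 - w$x1
  ey <- w$y2 - w$y1
  rx <- w$x1 - from[1]
  ry <- w$y1 - from[2]
  denom <- dx * ey - dy * ex
  para <- abs(denom) < eps
  t <- ifelse(para, NA_real_, (rx * ey - ry * ex) / denom)
  s <- ifelse(para, NA_real_, (rx * dy - ry * dx) / denom)
  crossing <- !para & t >= -eps & t <= 1 + eps & s >= -eps & s <= 1 + eps
  if (any(crossing)) {
    tc <- pmin(pmax(t[crossing], 0), 1)
    h <- from[3] + (to[3] - from[3]) * tc
    if (any(h <= w$height[crossing] + eps)) return(FALSE)
  }
  # collinear overlap: sightline running along a wall
  col <- which(para & abs(rx * dy - ry * dx) < eps * max(1, abs(dx), abs(dy)))
  for (i in col) {
    l2 <- dx^2 + dy^2
    t3 <- ((w$x1[i] - from[1]) * dx + (w$y1[i] - from[2]) * dy) / l2
    t4 <- ((w$x2[i] - from[1]) * dx + (w$y2[i] - from[2]) * dy) / l2
    lo <- max(min(t3, t4), 0)
    hi <- min(max(t3, t4), 1)
    if (lo <= hi + eps) {
      h <- from[3] + (to[3] - from[3]) * c(lo, hi)
      if (any(h <= w$height[i] + eps)) return(FALSE)
    }
  }
  TRUE
}

#' Classify all ordered pointing pairs as visible or non-visible
#'
#' Evaluates ground-style intervisibility for every ordered pair of maze
#' locations: both endpoints are placed at the location coordinates at a
#' single eye height, so visibility is symmetric in origin and target. On
#' the packaged layout at the ground eye height this reproduces the
#' pointing-task design: 72 ordered trials, of which the 16
#' route-consecutive pairs are visible and the remaining 56 are blocked by
#' hedges.
#'
#' @param layout A [maze_layout()] with at least two locations.
#' @param eye_height Eye height in meters for both endpoints (default:
#'   the layout's ground eye height).
#' @return A tibble with columns `origin`, `target`, `visible`, one row
#'   per ordered pair (`n * (n - 1)` rows).
#' @examples
#' pairs <- classify_pointing_pairs(packaged_maze_layout())
#' table(pairs$visible)
#' @export
classify_pointing_pairs <- function(layout,
                                    eye_height = layout$eye_heights[["ground"]]) {
  stopifnot(inherits(layout, "maze_layout"))
  ids <- layout$coords$id
  if (length(ids) < 2) stop("layout needs at least 2 locations")
  grid <- expand.grid(target = ids, origin = ids)[, c("origin", "target")]
  grid <- grid[grid$origin != grid$target, ]
  co <- layout$coords
  vis <- vapply(seq_len(nrow(grid)), function(i) {
    a <- co[match(grid$origin[i], co$id), ]
    b <- co[match(grid$target[i], co$id), ]
    line_of_sight(layout, c(a$x, a$y, eye_height), c(b$x, b$y, eye_height))
  }, logical(1))
  tibble::tibble(origin = grid$origin, target = grid$target, visible = vis)
}

#' Isovist (visible region) at a maze location
#'
#' Computes the region of the environment directly visible from a
#' viewpoint at a given eye height — the operationalization of
#' *geographic scale* as the visible-area fraction. Only walls whose
#' height exceeds the eye height occlude; the region is clipped to the
#' layout bounds. The polygon is built by an angular ray sweep at a
#' configurable resolution, so its area converges to the exact visibility
#' polygon's area as the resolution shrinks.
#'
#' @param layout A [maze_layout()].
#' @param location A location id; its coordinates must lie inside the
#'   layout bounds.
#' @param eye_height Eye height in meters.
#' @param angular_resolution Sweep step in degrees, in `(0, 1]`
#'   (default 0.25).
#' @return An object of class `isovist`: viewpoint, boundary polygon
#'   (matrix of x, y), `area` in square meters, and `scale_ratio` =
#'   area / bounds area.
#' @export
isovist <- function(layout, location,
                    eye_height = layout$eye_heights[["ground"]],
                    angular_resolution = 0.25) {
  stopifnot(inherits(layout, "maze_layout"))
  if (!(angular_resolution > 0 && angular_resolution <= 1)) {
    stop("angular_resolution must be in (0, 1]")
  }
  co <- layout$coords
  idx <- match(location, co$id)
  if (is.na(idx)) stop("unknown location id")
  v <- c(co$x[idx], co$y[idx])
  b <- layout$bounds
  if (v[1] < b["xmin"] - 1e-9 || v[1] > b["xmax"] + 1e-9 ||
      v[2] < b["ymin"] - 1e-9 || v[2] > b["ymax"] + 1e-9) {
    stop("viewpoint lies outside the layout bounds")
  }
  occ <- layout$walls[layout$walls$height > eye_height, , drop = FALSE]
  # bounds rectangle acts as a final opaque enclosure
  rect <- tibble::tibble(
    x1 = c(b["xmin"], b["xmax"], b["xmax"], b["xmin"]),
    y1 = c(b["ymin"], b["ymin"], b["ymax"], b["ymax"]),
    x2 = c(b["xmax"], b["xmax"], b["xmin"], b["xmin"]),
    y2 = c(b["ymin"], b["ymax"], b["ymax"], b["ymin"])
  )
  segs <- rbind(occ[, c("x1", "y1", "x2", "y2")], rect)
  theta <- seq(0, 360 - angular_resolution, by = angular_resolution)
  rad <- theta * pi / 180
  dirx <- sin(rad)
  diry <- cos(rad)
  radius <- rep(Inf, length(theta))
  eps <- 1e-9
  for (i in seq_len(nrow(segs))) {
    ex <- segs$x2[i] - segs$x1[i]
    ey <- segs$y2[i] - segs$y1[i]
    rx <- segs$x1[i] - v[1]
    ry <- segs$y1[i] - v[2]
    denom <- dirx * ey - diry * ex
    ok <- abs(denom) > eps
    r <- (rx * ey - ry * ex) / denom
    s <- (rx * diry - ry * dirx) / denom
    hit <- ok & s >= -eps & s <= 1 + eps & r > eps
    radius[hit] <- pmin(radius[hit], r[hit])
  }
  radius[!is.finite(radius)] <- 0
  px <- v[1] + radius * dirx
  py <- v[2] + radius * diry
  n <- length(px)
  nxt <- c(2:n, 1)
  area <- 0.5 * abs(sum(px * py[nxt] - px[nxt] * py))
  bounds_area <- (b[["xmax"]] - b[["xmin"]]) * (b[["ymax"]] - b[["ymin"]])
  structure(
    list(viewpoint = c(x = v[1], y = v[2], height = eye_height),
         polygon = cbind(x = px, y = py),
         area = area,
         scale_ratio = area / bounds_area,
         angular_resolution = angular_resolution),
    class = "isovist"
  )
}

#' @export
print.isovist <- function(x, ...) {
  cat(sprintf(
    "<isovist> viewpoint (%.1f, %.1f) at %.1f m; area %.1f m^2; scale ratio %.3f\n",
    x$viewpoint["x"], x$viewpoint["y"], x$viewpoint["height"],
    x$area, x$scale_ratio))
  invisible(x)
}

#' Export an isovist as a GeoJSON polygon
#'
#' @param iso An [isovist()].
#' @param path Optional file path; if `NULL` the GeoJSON string is
#'   returned.
#' @return The path (invisibly) or a JSON string.
#' @export
isovist_geojson <- function(iso, path = NULL) {
  stopifnot(inherits(iso, "isovist"))
  ring <- rbind(iso$polygon, iso$polygon[1, , drop = FALSE])
  gj <- list(
    type = "Feature",
    geometry = list(type = "Polygon",
                    coordinates = list(unname(split(ring, row(ring)[, 1])))),
    properties = list(kind = "isovist",
                      eye_height_m = unname(iso$viewpoint["height"]),
                      area_m2 = iso$area,
                      scale_ratio = iso$scale_ratio)
  )
  if (is.null(path)) {
    jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Landmarks visible from a maze location
#'
#' A landmark counts as visible when an unblocked 2.5-D sightline connects
#' the viewpoint (location coordinates at the given eye height) to the
#' *top* of the landmark column. A location's own landmark is always
#' visible (the sightline is vertical and crosses no walls). On the
#' packaged layout this realizes the designed perspective manipulation:
#' at locations 2, 4, 6, and 8 exactly one additional landmark is visible
#' from the elevated eye height compared to the ground eye height.
#'
#' @param layout A [maze_layout()] with landmarks.
#' @param location A location id.
#' @param eye_height Eye height in meters.
#' @return Character vector of visible landmark names.
#' @export
visible_landmarks <- function(layout, location,
                              eye_height = layout$eye_heights[["ground"]]) {
  stopifnot(inherits(layout, "maze_layout"), !is.null(layout$landmarks))
  co <- layout$coords
  idx <- match(location, co$id)
  if (is.na(idx)) stop("unknown location id")
  v <- c(co$x[idx], co$y[idx], eye_height)
  lm <- layout$landmarks
  vis <- vapply(seq_len(nrow(lm)), function(i) {
    if (sqrt((lm$x[i] - v[1])^2 + (lm$y[i] - v[2])^2) < 1e-9) return(TRUE)
    line_of_sight(layout, v, c(lm$x[i], lm$y[i], lm$height[i]))
  }, logical(1))
  lm$name[vis]
}
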