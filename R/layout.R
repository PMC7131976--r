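#' Construct a maze layout object
#'
#' A `maze_layout` is a realized 2.5-D environment: planar location
#' coordinates (x east, y north, meters), hedge wall segments with heights,
#' columnar landmarks with heights, and a bounding rectangle. Layouts are
#' normally derived from a [route_spec()] via [realize_layout()]; this
#' constructor is exported so that ad-hoc environments (e.g. arbitrary wall
#' sets for visibility experiments) can be built directly.
#'
#' @param coords Data frame with columns `id`, `x`, `y`.
#' @param walls Data frame with columns `x1`, `y1`, `x2`, `y2`, `height`.
#' @param landmarks Optional data frame with columns `location`, `name`,
#'   `x`, `y`, `height`.
#' @param bounds Numeric `c(xmin, ymin, xmax, ymax)`; defaults to the
#'   envelope of walls, coordinates, and landmarks.
#' @param eye_heights Named numeric vector of viewing heights in meters.
#' @param spec The originating [route_spec()], if any.
#' @param corridor_width,hedge_height Realization parameters, if any.
#' @return An object of class `maze_layout`.
#' @export
maze_layout <- function(coords, walls, landmarks = NULL, bounds = NULL,
                        eye_heights = c(ground = 1.4, elevated = 5.3),
                        spec = NULL, corridor_width = NA_real_,
                        hedge_height = NA_real_) {
  coords <- tibble::as_tibble(coords)
  walls <- tibble::as_tibble(walls)
  stopifnot(all(c("id", "x", "y") %in% names(coords)))
  if (nrow(walls)) {
    stopifnot(all(c("x1", "y1", "x2", "y2", "height") %in% names(walls)))
  } else {
    walls <- tibble::tibble(x1 = numeric(), y1 = numeric(),
                            x2 = numeric(), y2 = numeric(),
                            height = numeric())
  }
  if (!is.null(landmarks)) landmarks <- tibble::as_tibble(landmarks)
  if (is.null(bounds)) {
    xs <- c(coords$x, walls$x1, walls$x2,
            if (!is.null(landmarks)) landmarks$x)
    ys <- c(coords$y, walls$y1, walls$y2,
            if (!is.null(landmarks)) landmarks$y)
    bounds <- c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
  } else {
    bounds <- stats::setNames(as.numeric(bounds),
                              c("xmin", "ymin", "xmax", "ymax"))
  }
  structure(
    list(coords = coords, walls = walls, landmarks = landmarks,
         bounds = bounds, eye_heights = eye_heights, spec = spec,
         corridor_width = corridor_width, hedge_height = hedge_height),
    class = "maze_layout"
  )
}

#' @export
print.maze_layout <- function(x, ...) {
  cat(sprintf("<maze_layout> %d locations, %d walls, %d landmarks\n",
              nrow(x$coords), nrow(x$walls),
              if (is.null(x$landmarks)) 0L else nrow(x$landmarks)))
  b <- x$bounds
  cat(sprintf("  bounds: [%.1f, %.1f] x [%.1f, %.1f] m\n",
              b["xmin"], b["xmax"], b["ymin"], b["ymax"]))
  cat("  eye heights (m):",
      paste(names(x$eye_heights), x$eye_heights, sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Realize a route specification as a planar maze layout
#'
#' Deterministically converts an intrinsic route description into planar
#' coordinates and hedge walls. The gauge is fixed: the first location sits
#' at the origin and the first leg heads due north; positive turn angles
#' are clockwise. Each leg is flanked by two parallel hedge walls at
#' `corridor_width / 2` on either side of the centerline, mitered together
#' at turns, with cap walls closing the corridor half a width beyond the
#' terminal locations. One landmark is placed at every location.
#'
#' @param spec A [route_spec()].
#' @param corridor_width Corridor width in meters (default 3).
#' @param hedge_height Hedge wall height in meters (default 2.5, between
#'   the ground and elevated eye heights so that ground sightlines are
#'   blocked while elevated sightlines clear the hedges).
#' @param landmark_heights Numeric vector of landmark heights in meters,
#'   recycled across locations (default 1).
#' @param eye_heights Named numeric vector of viewing heights.
#' @return A [maze_layout()].
#' @examples
#' layout <- realize_layout(maze_route(),
#'                          landmark_heights = c(1, 1, 2.45, 1, 1, 1, 2.45, 1, 1))
#' layout
#' @export
realize_layout <- function(spec, corridor_width = 3, hedge_height = 2.5,
                           landmark_heights = 1,
                           eye_heights = c(ground = 1.4, elevated = 5.3)) {
  validate_route_spec(spec)
  if (corridor_width <= 0) stop("corridor_width must be positive")
  legs <- spec$legs
  nlegs <- nrow(legs)
  turn_at <- stats::setNames(spec$turns$angle, spec$turns$at)

  pos <- list()
  pos[[as.character(legs$from[1])]] <- c(0, 0)
  heading <- 0
  headings <- numeric(nlegs)
  for (i in seq_len(nlegs)) {
    if (i > 1) {
      ang <- turn_at[as.character(legs$from[i])]
      if (!is.na(ang)) heading <- heading + ang
    }
    headings[i] <- az_norm(heading)
    from_key <- as.character(legs$from[i])
    if (is.null(pos[[from_key]])) {
      # location fused with an earlier one by an edit
      anchor <- as.character(spec$coincident[[from_key]])
      pos[[from_key]] <- pos[[anchor]]
    }
    u <- c(sin(headings[i] * pi / 180), cos(headings[i] * pi / 180))
    pos[[as.character(legs$to[i])]] <- pos[[from_key]] + legs$length[i] * u
  }
  # any remaining fused locations inherit their anchor's position
  for (nm in names(spec$coincident)) {
    if (is.null(pos[[nm]])) {
      pos[[nm]] <- pos[[as.character(spec$coincident[[nm]])]]
    }
  }
  ids <- spec$locations$id
  coords <- tibble::tibble(
    id = ids,
    x = vapply(as.character(ids), function(k) pos[[k]][1], numeric(1)),
    y = vapply(as.character(ids), function(k) pos[[k]][2], numeric(1))
  )

  check_route_self_intersection(legs, pos)

  walls <- corridor_walls(legs, pos, headings, corridor_width, hedge_height)

  lm_h <- rep_len(landmark_heights, length(ids))
  landmarks <- tibble::tibble(
    location = ids, name = spec$locations$name,
    x = coords$x, y = coords$y, height = lm_h
  )
  maze_layout(coords, walls, landmarks,
              eye_heights = eye_heights, spec = spec,
              corridor_width = corridor_width, hedge_height = hedge_height)
}

# error if any two non-consecutive legs cross or overlap
check_route_self_intersection <- function(legs, pos) {
  nlegs <- nrow(legs)
  if (nlegs < 3) return(invisible())
  seg <- lapply(seq_len(nlegs), function(i) {
    rbind(pos[[as.character(legs$from[i])]], pos[[as.character(legs$to[i])]])
  })
  for (i in seq_len(nlegs - 2)) {
    for (j in seq((i + 2), nlegs)) {
      if (segments_cross(seg[[i]][1, ], seg[[i]][2, ],
                         seg[[j]][1, ], seg[[j]][2, ])) {
        stop(sprintf(
          "route self-intersects: leg (%d,%d) collides with leg (%d,%d)",
          legs$from[i], legs$to[i], legs$from[j], legs$to[j]))
      }
    }
  }
  invisible()
}

# do closed segments p1-p2 and p3-p4 share any point?
segments_cross <- function(p1, p2, p3, p4, eps = 1e-9) {
  d1 <- p2 - p1
  d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  r <- p3 - p1
  if (abs(denom) < eps) {
    # parallel: collinear overlap?
    if (abs(r[1] * d1[2] - r[2] * d1[1]) > eps) return(FALSE)
    l2 <- sum(d1^2)
    if (l2 < eps) return(sum((p3 - p1)^2) < eps)
    t3 <- sum((p3 - p1) * d1) / l2
    t4 <- sum((p4 - p1) * d1) / l2
    return(max(min(t3, t4), 0) <= min(max(t3, t4), 1) + eps)
  }
  t <- (r[1] * d2[2] - r[2] * d2[1]) / denom
  s <- (r[1] * d1[2] - r[2] * d1[1]) / denom
  t >= -eps && t <= 1 + eps && s >= -eps && s <= 1 + eps
}

# two offset wall polylines (mitered at turns) plus end caps
corridor_walls <- function(legs, pos, headings, width, height) {
  d <- width / 2
  nlegs <- nrow(legs)
  u <- cbind(sin(headings * pi / 180), cos(headings * pi / 180))
  starts <- t(vapply(as.character(legs$from), function(k) pos[[k]],
                     numeric(2)))
  ends <- t(vapply(as.character(legs$to), function(k) pos[[k]], numeric(2)))

  side_polyline <- function(normals) {
    pts <- matrix(NA_real_, nlegs + 1, 2)
    pts[1, ] <- starts[1, ] - u[1, ] * d + normals[1, ] * d
    if (nlegs >= 2) {
      for (j in seq_len(nlegs - 1)) {
        node <- ends[j, ]
        cr <- u[j, 1] * u[j + 1, 2] - u[j, 2] * u[j + 1, 1]
        if (abs(cr) < 1e-9) {
          pts[j + 1, ] <- node + normals[j, ] * d
        } else {
          a <- node + normals[j, ] * d
          b <- node + normals[j + 1, ] * d
          t <- ((b[1] - a[1]) * u[j + 1, 2] - (b[2] - a[2]) * u[j + 1, 1]) / cr
          pts[j + 1, ] <- a + t * u[j, ]
        }
      }
    }
    pts[nlegs + 1, ] <- ends[nlegs, ] + u[nlegs, ] * d + normals[nlegs, ] * d
    pts
  }
  left <- side_polyline(cbind(-u[, 2], u[, 1]))
  right <- side_polyline(cbind(u[, 2], -u[, 1]))

  seg_rows <- function(pts) {
    n <- nrow(pts) - 1
    tibble::tibble(x1 = pts[seq_len(n), 1], y1 = pts[seq_len(n), 2],
                   x2 = pts[seq_len(n) + 1, 1], y2 = pts[seq_len(n) + 1, 2])
  }
  walls <- dplyr::bind_rows(
    seg_rows(left),
    seg_rows(right),
    tibble::tibble(x1 = left[1, 1], y1 = left[1, 2],
                   x2 = right[1, 1], y2 = right[1, 2]),
    tibble::tibble(x1 = left[nlegs + 1, 1], y1 = left[nlegs + 1, 2],
                   x2 = right[nlegs + 1, 1], y2 = right[nlegs + 1, 2])
  )
  walls$height <- height
  walls
}

#' Packaged maze layout
#'
#' [realize_layout()] applied to the packaged route reconstruction
#' [maze_route()] with its tuned landmark heights, a 3 m corridor, and
#' 2.5 m hedges.
#'
#' @return A [maze_layout()].
#' @export
packaged_maze_layout <- function() {
  realize_layout(maze_route(),
                 corridor_width = 3, hedge_height = 2.5,
                 landmark_heights = maze_landmark_heights())
}

#' True direction between two maze locations
#'
#' Azimuth of the straight-line vector from the origin location to the
#' target location in a realized layout.
#'
#' @param layout A [maze_layout()].
#' @param origin,target Location ids; must differ and must not be
#'   coincident in the layout.
#' @return Azimuth in degrees clockwise from north.
#' @export
true_direction <- function(layout, origin, target) {
  stopifnot(inherits(layout, "maze_layout"))
  if (identical(origin, target)) stop("origin and target must differ")
  co <- layout$coords
  a <- co[match(origin, co$id), ]
  b <- co[match(target, co$id), ]
  if (anyNA(a$x) || anyNA(b$x)) stop("unknown location id")
  dx <- as.numeric(b$x - a$x)
  dy <- as.numeric(b$y - a$y)
  if (sqrt(dx^2 + dy^2) < 1e-9) {
    stop(sprintf("locations %s and %s are coincident; direction undefined",
                 origin, target))
  }
  unname(vector_azimuth(dx, dy))
}

#' Export a layout as GeoJSON
#'
#' Writes a FeatureCollection with the hedge walls as LineStrings, the
#' locations and landmarks as Points. Coordinates are planar meters (x
#' east, y north), not geographic.
#'
#' @param layout A [maze_layout()].
#' @param path Optional file path; if `NULL` the GeoJSON string is
#'   returned.
#' @return The path (invisibly) or a JSON string.
#' @export
layout_geojson <- function(layout, path = NULL) {
  stopifnot(inherits(layout, "maze_layout"))
  feat <- function(geometry, properties) {
    list(type = "Feature", geometry = geometry, properties = properties)
  }
  features <- c(
    lapply(seq_len(nrow(layout$walls)), function(i) {
      w <- layout$walls[i, ]
      feat(list(type = "LineString",
                coordinates = list(c(w$x1, w$y1), c(w$x2, w$y2))),
           list(kind = "wall", height_m = w$height))
    }),
    lapply(seq_len(nrow(layout$coords)), function(i) {
      p <- layout$coords[i, ]
      feat(list(type = "Point", coordinates = c(p$x, p$y)),
           list(kind = "location", id = p$id))
    }),
    if (!is.null(layout$landmarks)) {
      lapply(seq_len(nrow(layout$landmarks)), function(i) {
        l <- layout$landmarks[i, ]
        feat(list(type = "Point", coordinates = c(l$x, l$y)),
             list(kind = "landmark", name = l$name, height_m = l$height))
      })
    }
  )
  gj <- list(type = "FeatureCollection", features = features)
  if (is.null(path)) {
    jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Plot a maze layout
#'
#' Quick diagnostic plot of walls, locations, and landmarks; optionally
#' overlays an [isovist()] polygon.
#'
#' @param layout A [maze_layout()].
#' @param iso Optional `isovist` object to overlay.
#' @return A ggplot object.
#' @export
plot_maze <- function(layout, iso = NULL) {
  stopifnot(inherits(layout, "maze_layout"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = layout$walls,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2),
      colour = "darkgreen"
    )
  if (!is.null(iso)) {
    poly <- tibble::as_tibble(as.data.frame(iso$polygon))
    names(poly) <- c("x", "y")
    p <- p + ggplot2::geom_polygon(
      data = poly, ggplot2::aes(x = .data$x, y = .data$y),
      fill = "red", alpha = 0.25
    )
  }
  p +
    ggplot2::geom_point(data = layout$coords,
                        ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(data = layout$coords,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$id),
                       nudge_x = 1, nudge_y = 1, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m, east)", y = "y (m, north)")
}
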