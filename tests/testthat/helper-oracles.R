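# Independent oracles and small fixtures used across the suite.

# Brute-force rasterized visibility oracle: estimates the visible area
# from a viewpoint by dense line-of-sight tests on a grid of cell
# centers, at the same eye height as the viewpoint. Independent of the
# angular-sweep isovist implementation.
raster_visible_area <- function(layout, location, eye_height, n = 150) {
  b <- layout$bounds
  co <- layout$coords
  idx <- match(location, co$id)
  v <- c(co$x[idx], co$y[idx], eye_height)
  cx <- seq(b[["xmin"]], b[["xmax"]], length.out = n + 1)
  cx <- (cx[-1] + cx[-(n + 1)]) / 2
  cy <- seq(b[["ymin"]], b[["ymax"]], length.out = n + 1)
  cy <- (cy[-1] + cy[-(n + 1)]) / 2
  grid <- expand.grid(x = cx, y = cy)
  vis <- vapply(seq_len(nrow(grid)), function(i) {
    if (abs(grid$x[i] - v[1]) < 1e-9 && abs(grid$y[i] - v[2]) < 1e-9) {
      return(TRUE)
    }
    line_of_sight(layout, v, c(grid$x[i], grid$y[i], eye_height))
  }, logical(1))
  mean(vis) * (b[["xmax"]] - b[["xmin"]]) * (b[["ymax"]] - b[["ymin"]])
}

point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  l2 <- dx^2 + dy^2
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / l2, 0), 1)
  sqrt((x1 + t * dx - px)^2 + (y1 + t * dy - py)^2)
}

# random single-viewpoint environment with n opaque walls, none passing
# near the viewpoint at the origin
random_wall_layout <- function(n_walls, seed, size = 40) {
  withr::with_seed(seed, {
    mk <- function(m) {
      cx <- runif(m, -size / 2 + 2, size / 2 - 2)
      cy <- runif(m, -size / 2 + 2, size / 2 - 2)
      ang <- runif(m, 0, pi)
      len <- runif(m, 3, 12)
      tibble::tibble(x1 = cx - cos(ang) * len / 2,
                     y1 = cy - sin(ang) * len / 2,
                     x2 = cx + cos(ang) * len / 2,
                     y2 = cy + sin(ang) * len / 2,
                     height = 10)
    }
    walls <- mk(n_walls)
    while (any(bad <- point_segment_dist(0, 0, walls$x1, walls$y1,
                                         walls$x2, walls$y2) < 1)) {
      walls[bad, ] <- mk(sum(bad))
    }
    maze_layout(coords = data.frame(id = 1L, x = 0, y = 0), walls = walls,
                bounds = c(-size / 2, -size / 2, size / 2, size / 2))
  })
}

# direct numerical ML fit of a single von Mises by general-purpose
# optimization; independent cross-check of the closed-form/EM route
vm_mle_optim <- function(theta) {
  nll <- function(p) -sum(dvonmises(theta, p[1], exp(p[2]), log = TRUE))
  o <- stats::optim(c(circular_mean(theta), log(2)), nll)
  list(mu = az_norm(o$par[1]), kappa = exp(o$par[2]))
}

fixture_layout <- function() packaged_maze_layout()

fixture_alternative_layout <- function(rotation_sign = -1) {
  realize_layout(alternative_route(maze_route(), rotation_sign),
                 corridor_width = 3, hedge_height = 2.5,
                 landmark_heights = 1)
}

# tiny two-layout pair with clearly different target directions, for
# model-comparison tests without the full maze
toy_layout_pair <- function() {
  correct <- realize_layout(route_spec(
    locations = data.frame(id = 1:3, name = c("a", "b", "c")),
    legs = data.frame(from = 1:2, to = 2:3, length = c(10, 10)),
    turns = data.frame(at = 2, angle = 90)))
  alternative <- realize_layout(route_spec(
    locations = data.frame(id = 1:3, name = c("a", "b", "c")),
    legs = data.frame(from = 1:2, to = 2:3, length = c(10, 10)),
    turns = data.frame(at = 2, angle = -90)))
  list(correct = correct, alternative = alternative)
}
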