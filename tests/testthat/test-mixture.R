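test_that("single-component fits recover generating parameters", {
  a <- withr::with_seed(11, rvonmises(200, 90, 8))
  f <- fit_vonmises_mixture(a, K = 1)
  expect_lt(angular_error(f$mu, 90), 5)
  expect_lt(abs(f$kappa - 8) / 8, 0.25)
  # cross-check against an independent numerical ML fit
  o <- vm_mle_optim(a)
  expect_lt(angular_error(f$mu, o$mu), 0.5)
  expect_equal(f$kappa, o$kappa, tolerance = 0.02)
})

test_that("two-component fits recover balanced well-separated mixtures", {
  a <- withr::with_seed(12, c(rvonmises(100, 30, 8), rvonmises(100, 210, 8)))
  f <- fit_vonmises_mixture(a, K = 2, seed = 1)
  expect_lt(angular_error(f$mu[1], 30), 5)
  expect_lt(angular_error(f$mu[2], 210), 5)
  expect_lt(max(abs(f$weights - 0.5)), 0.05)
})

test_that("degenerate clusters hit the concentration cap with a warning", {
  expect_warning(f <- fit_vonmises_mixture(rep(123, 20), K = 1),
                 "kappa_max")
  expect_equal(f$mu, 123)
  expect_equal(f$kappa, 500)
})

test_that("insufficient data is rejected", {
  expect_error(fit_vonmises_mixture(1:4, K = 1), "at least 5")
  expect_error(fit_vonmises_mixture(1:9, K = 2), "at least 10")
  expect_error(select_modality(1:9), "at least 10")
})

test_that("EM log-likelihood is monotone non-decreasing", {
  for (s in 1:5) {
    a <- withr::with_seed(s, c(rvonmises(40, 20, 3), rvonmises(40, 150, 6)))
    f <- fit_vonmises_mixture(a, K = 2, seed = s)
    expect_true(all(diff(f$ll_trace) > -1e-7))
  }
})

test_that("mixture densities integrate to one over the circle", {
  for (par in list(c(0.4, 30, 5, 200, 2), c(0.15, 300, 50, 100, 0.5))) {
    dens <- function(t) {
      par[1] * dvonmises(t * 180 / pi, par[2], par[3]) +
        (1 - par[1]) * dvonmises(t * 180 / pi, par[4], par[5])
    }
    expect_equal(integrate(dens, 0, 2 * pi, rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
  }
})

test_that("fits are rotation-equivariant and seed-deterministic", {
  a <- withr::with_seed(21, c(rvonmises(60, 350, 8), rvonmises(60, 80, 8)))
  shift <- 137
  f0 <- select_modality(a, mixture_control(seed = 5))
  f1 <- select_modality(az_norm(a + shift), mixture_control(seed = 5))
  expect_equal(f0$modality, f1$modality)
  expect_setequal(round(az_norm(f0$mu + shift), 6), round(f1$mu, 6))
  expect_equal(sort(f0$kappa), sort(f1$kappa), tolerance = 1e-6)
  expect_equal(sort(f0$weights), sort(f1$weights), tolerance = 1e-6)
  # identical seed, identical result
  f2 <- select_modality(a, mixture_control(seed = 5))
  expect_identical(f0$mu, f2$mu)
})

test_that("modality selection enforces the separation floor", {
  a <- withr::with_seed(31, c(rvonmises(50, 100, 8), rvonmises(50, 110, 8)))
  f <- select_modality(a, mixture_control(seed = 1))
  expect_equal(f$modality, "unimodal")
})

test_that("confidence sectors shrink with information and separate modes", {
  big <- withr::with_seed(41, rvonmises(500, 200, 20))
  fb <- fit_vonmises_mixture(big, K = 1)
  sb <- mode_confidence_sector(fit = fb, B = 300, seed = 1)
  expect_lt(sb$width, 10)

  small <- withr::with_seed(42, rvonmises(20, 200, 2))
  fs <- fit_vonmises_mixture(small, K = 1)
  ss <- mode_confidence_sector(fit = fs, B = 300, seed = 1)
  expect_gt(ss$width, sb$width)

  # sectors contain their mean direction
  for (s in list(sb, ss)) {
    arc <- az_norm(s$hi - s$lo)
    off <- az_norm(s$mean_dir - s$lo)
    expect_lte(off, arc + 1e-9)
  }

  two <- withr::with_seed(43, c(rvonmises(80, 40, 8), rvonmises(80, 160, 8)))
  ft <- fit_vonmises_mixture(two, K = 2, seed = 2)
  st <- mode_confidence_sector(fit = ft, B = 300, seed = 3)
  # disjoint arcs: each sector stays within 60 degrees of its own mode
  expect_lt(st$width[1] / 2 + st$width[2] / 2,
            angular_error(ft$mu[1], ft$mu[2]))

  expect_error(mode_confidence_sector(fit = fb, B = 50), "at least 100")
})

test_that("the systematic mode is the one deviating more from truth", {
  mk <- function(mu, w) {
    structure(list(K = 2, mu = mu, weights = w, kappa = c(8, 8)),
              class = "vm_mixture")
  }
  expect_equal(label_systematic_mode(mk(c(105, 180), c(0.6, 0.4)), 100), 2)
  expect_equal(label_systematic_mode(mk(c(0, 120), c(0.6, 0.4)), 100), 1)
  expect_warning(
    idx <- label_systematic_mode(mk(c(60, 140), c(0.7, 0.3)), 100),
    "equidistant")
  expect_equal(idx, 2) # lower-weight tie rule
  f1 <- structure(list(K = 1), class = "vm_mixture")
  expect_error(label_systematic_mode(f1, 0), "K = 2")
})

test_that("per-target summaries aggregate participant means", {
  rec <- tidyr::expand_grid(participant = c("a", "b"), target = 1:3,
                            rep = 1:2)
  rec$error <- 0
  s0 <- per_target_error_summary(rec)
  expect_true(all(s0$mean_error == 0) && all(s0$q75 == 0))

  one <- data.frame(participant = "a", target = c(1, 1, 2), error = c(10, 20, 30))
  s1 <- per_target_error_summary(one)
  expect_equal(s1$mean_error, c(15, 30))
  expect_equal(s1$median_error, c(15, 30))
  expect_equal(s1$n_participants, c(1L, 1L))
})
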