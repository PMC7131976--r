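#' Control parameters for mixture fitting and modality selection
#'
#' Defaults: 20 random EM restarts, log-likelihood tolerance 1e-8,
#' concentration cap 500, minimum component weight 0.15, minimum mode
#' separation 30 degrees, 1000 bootstrap replicates. A two-component fit
#' is only declared bimodal when it wins on BIC *and* passes the weight
#' and separation floors, so tiny or barely separated secondary modes do
#' not count as systematic error structure.
#'
#' @param restarts Number of random EM restarts for `K = 2`.
#' @param tol Absolute convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @param kappa_max Concentration cap for near-degenerate clusters.
#' @param w_min Minimum admissible component weight for a bimodal verdict.
#' @param min_separation Minimum angular separation (degrees) between the
#'   two component mean directions for a bimodal verdict.
#' @param bootstrap_B Bootstrap replicates for confidence sectors.
#' @param seed Optional integer seed making fits deterministic.
#' @return A list of class `mixture_control`.
#' @export
mixture_control <- function(restarts = 20, tol = 1e-8, max_iter = 300,
                            kappa_max = 500, w_min = 0.15,
                            min_separation = 30, bootstrap_B = 1000,
                            seed = NULL) {
  stopifnot(restarts >= 1, tol > 0, max_iter >= 1, kappa_max > 0,
            w_min >= 0, w_min < 0.5, min_separation >= 0)
  structure(list(restarts = restarts, tol = tol, max_iter = max_iter,
                 kappa_max = kappa_max, w_min = w_min,
                 min_separation = min_separation,
                 bootstrap_B = bootstrap_B, seed = seed),
            class = "mixture_control")
}

# one EM run from a given initialization; angles in degrees.
# trig of the data is precomputed once; cos(theta - mu) expands to
# cos(theta) cos(mu) + sin(theta) sin(mu).
em_run <- function(theta, K, init, tol, max_iter, kappa_max) {
  n <- length(theta)
  rad <- theta * pi / 180
  ct <- cos(rad)
  st <- sin(rad)
  w <- init$weights
  mur <- init$mu * pi / 180
  kap <- init$kappa
  ll_trace <- numeric(max_iter)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  l2pi <- log(2 * pi)
  while (iter < max_iter) {
    iter <- iter + 1
    l1 <- log(w[1]) + kap[1] * (ct * cos(mur[1]) + st * sin(mur[1])) -
      l2pi - log_bessel_i0(kap[1])
    if (K == 1) {
      lse <- l1
      g1 <- NULL
    } else {
      l2 <- log(w[2]) + kap[2] * (ct * cos(mur[2]) + st * sin(mur[2])) -
        l2pi - log_bessel_i0(kap[2])
      m <- pmax(l1, l2)
      lse <- m + log(exp(l1 - m) + exp(l2 - m))
      g1 <- exp(l1 - lse)
    }
    ll <- sum(lse)
    ll_trace[iter] <- ll
    if (is.finite(ll) && iter > 1 && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    if (K == 1) {
      sw <- n
      S <- sum(st)
      C <- sum(ct)
      w <- 1
      mur <- atan2(S, C)
      kap <- a1_inv(min(sqrt(S^2 + C^2) / n, 1), kappa_max)
    } else {
      sw1 <- sum(g1)
      if (sw1 < 1e-8 || n - sw1 < 1e-8) {
        return(list(ok = FALSE, loglik = -Inf))
      }
      S <- c(sum(g1 * st), sum(st) - sum(g1 * st))
      C <- c(sum(g1 * ct), sum(ct) - sum(g1 * ct))
      sw <- c(sw1, n - sw1)
      w <- sw / n
      mur <- atan2(S, C)
      kap <- a1_inv(pmin(sqrt(S^2 + C^2) / sw, 1), kappa_max)
    }
  }
  mu <- az_norm(mur * 180 / pi)
  ord <- order(mu)
  list(ok = TRUE, weights = w[ord], mu = mu[ord], kappa = kap[ord],
       loglik = ll_trace[iter], ll_trace = ll_trace[seq_len(iter)],
       iterations = iter, converged = converged)
}

#' Fit a finite von Mises mixture to circular pointing data
#'
#' Maximum-likelihood fit of a `K`-component von Mises mixture by
#' expectation-maximization, best of `restarts` random initializations.
#' The log-likelihood is non-decreasing across EM iterations (the trace is
#' returned in `ll_trace`). `K = 1` uses the closed-form ML solution
#' (circular mean plus inverse-`A1` concentration). Concentrations are
#' capped at `kappa_max`; hitting the cap (a near-degenerate cluster)
#' raises a warning. Components are ordered by mean direction.
#'
#' @param angles Azimuths in degrees; at least `5 * K` values.
#' @param K Number of components, 1 or 2.
#' @param restarts Number of random EM restarts (`K = 2`).
#' @param seed Optional integer seed; given a seed the fit is
#'   deterministic.
#' @param tol,max_iter,kappa_max See [mixture_control()].
#' @return An object of class `vm_mixture` with elements `K`, `weights`,
#'   `mu`, `kappa`, `loglik`, `bic`, `n`, `ll_trace`, `converged`.
#' @examples
#' set.seed(1)
#' a <- c(rvonmises(100, 30, 8), rvonmises(100, 210, 8))
#' fit_vonmises_mixture(a, K = 2, seed = 1)
#' @export
fit_vonmises_mixture <- function(angles, K = 1, restarts = 20, seed = NULL,
                                 tol = 1e-8, max_iter = 300,
                                 kappa_max = 500) {
  stopifnot(K %in% c(1, 2))
  angles <- az_norm(angles[is.finite(angles)])
  n <- length(angles)
  if (n < 5 * K) {
    stop(sprintf("need at least %d angles to fit K = %d components", 5 * K, K))
  }
  run_all <- function() {
    if (K == 1) {
      p <- vm_ml(angles, kappa_max)
      ll <- sum(dvonmises(angles, p$mu, p$kappa, log = TRUE))
      return(list(ok = TRUE, weights = 1, mu = p$mu, kappa = p$kappa,
                  loglik = ll, ll_trace = ll, iterations = 1L,
                  converged = TRUE))
    }
    best <- list(ok = FALSE, loglik = -Inf)
    for (r in seq_len(restarts)) {
      init <- list(
        weights = rep(1 / K, K),
        mu = az_norm(angles[sample.int(n, K)] + runif(K, -20, 20)),
        kappa = runif(K, 1, 10)
      )
      res <- em_run(angles, K, init, tol, max_iter, kappa_max)
      if (res$ok && res$loglik > best$loglik) best <- res
    }
    if (!best$ok) stop("EM failed to produce a non-degenerate fit")
    best
  }
  best <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())
  if (any(best$kappa >= kappa_max - 1e-6)) {
    warning("concentration capped at kappa_max = ", kappa_max,
            " (near-degenerate cluster)")
  }
  p <- 3 * K - 1
  structure(
    list(K = K, weights = best$weights, mu = best$mu, kappa = best$kappa,
         loglik = best$loglik, bic = -2 * best$loglik + p * log(n),
         n = n, ll_trace = best$ll_trace, iterations = best$iterations,
         converged = best$converged, angles = angles),
    class = "vm_mixture"
  )
}

#' @export
print.vm_mixture <- function(x, ...) {
  cat(sprintf("<vm_mixture> K = %d, n = %d, logLik = %.2f, BIC = %.2f\n",
              x$K, x$n, x$loglik, x$bic))
  for (k in seq_len(x$K)) {
    cat(sprintf("  component %d: weight %.3f, mean %.1f deg, kappa %.2f\n",
                k, x$weights[k], x$mu[k], x$kappa[k]))
  }
  if (!is.null(x$modality)) cat("  modality:", x$modality, "\n")
  invisible(x)
}

#' Decide whether a pointing-direction sample is unimodal or bimodal
#'
#' Fits one- and two-component von Mises mixtures and declares the sample
#' bimodal only when the two-component model wins on BIC *and* both
#' component weights reach `w_min` *and* the mode separation reaches
#' `min_separation`. Bimodality in pooled pointing directions is the
#' signature of systematic (non-random) error: a subset of judgments
#' aimed at a direction predicted by a distorted representation of the
#' maze rather than the true one.
#'
#' @param angles Azimuths in degrees; at least 10 values.
#' @param control A [mixture_control()].
#' @return The selected `vm_mixture` fit with `$modality` set to
#'   `"unimodal"` or `"bimodal"` and `$candidates` holding both fits.
#' @export
select_modality <- function(angles, control = mixture_control()) {
  angles <- az_norm(angles[is.finite(angles)])
  if (length(angles) < 10) stop("need at least 10 angles")
  fit1 <- fit_vonmises_mixture(angles, K = 1, restarts = control$restarts,
                               seed = control$seed, tol = control$tol,
                               max_iter = control$max_iter,
                               kappa_max = control$kappa_max)
  fit2 <- suppressWarnings(
    fit_vonmises_mixture(angles, K = 2, restarts = control$restarts,
                         seed = control$seed, tol = control$tol,
                         max_iter = control$max_iter,
                         kappa_max = control$kappa_max))
  separation <- angular_error(fit2$mu[1], fit2$mu[2])
  bimodal <- fit2$bic < fit1$bic &&
    min(fit2$weights) >= control$w_min &&
    separation >= control$min_separation
  fit <- if (bimodal) fit2 else fit1
  fit$modality <- if (bimodal) "bimodal" else "unimodal"
  fit$criteria <- list(bic_unimodal = fit1$bic, bic_bimodal = fit2$bic,
                       separation = separation,
                       min_weight = min(fit2$weights))
  fit$candidates <- list(K1 = fit1, K2 = fit2)
  fit
}

#' Bootstrap confidence sectors for mixture mean directions
#'
#' Percentile bootstrap arcs for each component's mean direction: the
#' sample is resampled with replacement, the mixture refitted (initialized
#' at the point estimate), refitted components matched to the originals by
#' angular proximity, and the signed deviations of the refitted means
#' summarized by percentile quantiles. Arcs always contain the point
#' estimate and shrink as the sample grows.
#'
#' @param angles Azimuths the fit was computed from (defaults to the
#'   angles stored in the fit).
#' @param fit A converged `vm_mixture`.
#' @param level Coverage level (default 0.95).
#' @param B Bootstrap replicates; at least 100.
#' @param seed Optional integer seed.
#' @return A tibble with one row per component: `component`, `mean_dir`,
#'   `lo`, `hi` (azimuths of the arc ends, clockwise from `lo` to `hi`),
#'   and `width` in degrees.
#' @export
mode_confidence_sector <- function(angles = fit$angles, fit, level = 0.95,
                                   B = 1000, seed = NULL) {
  stopifnot(inherits(fit, "vm_mixture"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (B < 100) stop("B must be at least 100")
  angles <- az_norm(angles[is.finite(angles)])
  n <- length(angles)
  K <- fit$K
  boot_once <- function() {
    th <- angles[sample.int(n, n, replace = TRUE)]
    if (K == 1) {
      vm_ml(th)$mu
    } else {
      res <- em_run(th, K,
                    list(weights = fit$weights, mu = fit$mu,
                         kappa = fit$kappa),
                    tol = 1e-6, max_iter = 100, kappa_max = 500)
      if (!res$ok) return(rep(NA_real_, K))
      # match refitted components to the originals (identity vs swap)
      d_id <- sum(angular_error(res$mu, fit$mu))
      d_sw <- sum(angular_error(rev(res$mu), fit$mu))
      if (d_sw < d_id) rev(res$mu) else res$mu
    }
  }
  run <- function() vapply(seq_len(B), function(b) boot_once(), numeric(K))
  mus <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  mus <- matrix(mus, nrow = K)
  alpha <- 1 - level
  out <- lapply(seq_len(K), function(k) {
    dev <- signed_angle(fit$mu[k], mus[k, ])
    dev <- dev[is.finite(dev)]
    qs <- quantile(dev, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo <- min(qs[1], 0)
    hi <- max(qs[2], 0)
    tibble::tibble(component = k, mean_dir = fit$mu[k],
                   lo = az_norm(fit$mu[k] + lo),
                   hi = az_norm(fit$mu[k] + hi),
                   width = hi - lo, level = level)
  })
  dplyr::bind_rows(out)
}

#' Label the systematic mode of a bimodal fit
#'
#' In a two-component fit of pooled pointing directions, the component
#' whose mean direction deviates more from the correct direction is taken
#' to carry the systematic errors (the other mode represents judgments
#' consistent with the true layout). If both modes are equidistant from
#' the correct direction the lower-weight component is chosen, with a
#' warning — systematic errors are typically the minority regime.
#'
#' @param fit A `vm_mixture` with `K = 2`.
#' @param correct The correct (true) azimuth in degrees.
#' @return The systematic component index (1 or 2).
#' @export
label_systematic_mode <- function(fit, correct) {
  stopifnot(inherits(fit, "vm_mixture"))
  if (fit$K != 2) stop("systematic-mode labeling requires a K = 2 fit")
  d <- angular_error(fit$mu, correct)
  if (abs(d[1] - d[2]) < 1e-6) {
    warning("modes equidistant from the correct direction; ",
            "choosing the lower-weight component")
    return(which.min(fit$weights))
  }
  which.max(d)
}

#' Per-target summary of participant-averaged pointing errors
#'
#' Pointing errors made by a single participant toward the same target are
#' first averaged, then those participant-level means are summarized per
#' target (mean, median, quartiles). This is the aggregation under which
#' a distorted representation of the later route section shows up as
#' inflated errors for the affected target locations.
#'
#' @param records A data frame of pointing records with columns
#'   `participant`, `target`, `error`.
#' @return A tibble with one row per target: `target`, `n_participants`,
#'   `mean_error`, `median_error`, `q25`, `q75`.
#' @export
per_target_error_summary <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("participant", "target", "error") %in% names(records)))
  if (!nrow(records)) stop("no records")
  records |>
    dplyr::group_by(.data$participant, .data$target) |>
    dplyr::summarise(m = mean(.data$error), .groups = "drop") |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      mean_error = mean(.data$m),
      median_error = median(.data$m),
      q25 = quantile(.data$m, 0.25, names = FALSE),
      q75 = quantile(.data$m, 0.75, names = FALSE),
      .groups = "drop"
    )
}

#' Circular histogram (rose) of pointing directions
#'
#' @param angles Azimuths in degrees.
#' @param binwidth Bin width in degrees.
#' @param truth Optional correct azimuth drawn as a reference line.
#' @return A ggplot object in polar coordinates with north at the top.
#' @export
plot_pointing_rose <- function(angles, binwidth = 10, truth = NULL) {
  df <- tibble::tibble(angle = az_norm(angles))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$angle)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey40", colour = "white") +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 270),
                                labels = c("N", "E", "S", "W")) +
    ggplot2::labs(x = NULL, y = "count")
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_vline(xintercept = az_norm(truth),
                                 colour = "red")
  }
  p
}
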