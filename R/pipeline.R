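#' Run the full pointing-error analysis pipeline
#'
#' Orchestrates every stage end-to-end and writes its outputs plus a run
#' manifest to `out_dir`:
#'
#' 1. `pairs.csv` — visible/non-visible classification of all ordered
#'    pointing pairs at ground eye height;
#' 2. `participants.csv` — scored cohort: mean visible error, outlier
#'    exclusion (Q3 + 1.5 IQR on visible errors, per experiment pool),
#'    SOD median split (per experiment pool; the G group is pooled into
#'    both experiments, as in the study design);
#' 3. `records.csv` — pointing records of the included participants with
#'    true directions and absolute errors attached;
#' 4. `target_summary.csv` — per-target participant-averaged error
#'    summaries (non-visible trials);
#' 5. `fits.json` — von Mises mixture fit and modality verdict per
#'    non-visible trial (directions pooled across included participants
#'    and sessions), with bootstrap confidence sectors and the
#'    systematic-mode label for bimodal trials;
#' 6. `comparison.csv` — per participant x session correct-vs-alternative
#'    representation comparison over the bimodal trials;
#' 7. `preference.csv` — aggregated preference percentages per
#'    group x SOD x session cell plus per-session overall rows.
#'
#' The configuration is a YAML file or an equivalent list; see the
#' packaged example in `inst/extdata/example-config.yaml`. It must name a
#' layout (`"packaged"` or a route JSON path) and either a `simulate`
#' block (passed to [generator_config()]) or a `records` CSV. A single
#' master seed drives every stochastic stage through derived substream
#' seeds; re-running with an identical configuration reproduces identical
#' outputs. If a stage fails, earlier outputs are retained and the
#' manifest records the failure point.
#'
#' @param config Path to a YAML configuration file, or a list.
#' @return The run manifest (class `run_manifest`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stop("config needs an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  # --- resolve inputs before any stage runs ---------------------------
  if (identical(config$layout %||% "packaged", "packaged")) {
    spec <- maze_route()
    correct <- packaged_maze_layout()
  } else {
    lj <- read_route_json(config$layout)
    spec <- lj$spec
    correct <- realize_layout(spec, lj$corridor_width, lj$hedge_height)
  }
  rotation_sign <- config$alternative$rotation_sign %||% -1
  alt_layout <- realize_layout(
    alternative_route(spec, rotation_sign),
    correct$corridor_width, correct$hedge_height)

  if (is.null(config$simulate) && is.null(config$records)) {
    stop("config needs either a `simulate` block or a `records` CSV path")
  }
  mix <- config$mixture %||% list()
  control <- mixture_control(
    restarts = mix$restarts %||% 20,
    w_min = mix$w_min %||% 0.15,
    min_separation = mix$min_separation %||% 30,
    bootstrap_B = mix$bootstrap_B %||% 200)
  min_trial_n <- mix$min_trial_n %||% 10

  stages <- character()
  outputs <- character()
  manifest_path <- file.path(out_dir, "manifest.json")
  t_start <- Sys.time()
  fail_manifest <- function(stage, err) {
    m <- list(status = "failed", failed_stage = stage,
              error = conditionMessage(err), seed = seed,
              stages_completed = stages, outputs = outputs)
    jsonlite::write_json(m, manifest_path, auto_unbox = TRUE)
    stop(err)
  }
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) fail_manifest(name, e))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    stages <<- c(stages, name)
    res
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, file)
    path
  }

  # --- stage 1: visibility classification -----------------------------
  pairs <- run_stage("visibility", function() {
    p <- classify_pointing_pairs(correct)
    emit(p, "pairs.csv")
    p
  })

  # --- stage 2: cohort (simulate or load), scoring, exclusion, split --
  cohort <- run_stage("participants", function() {
    if (!is.null(config$simulate)) {
      gc_args <- config$simulate
      for (nm in c("n_per_group", "kappa_nonvisible", "session_kappa_mult",
                   "eligible_targets")) {
        if (!is.null(gc_args[[nm]])) gc_args[[nm]] <- unlist(gc_args[[nm]])
      }
      if (!is.null(gc_args$p_alt)) {
        gc_args$p_alt <- dplyr::bind_rows(gc_args$p_alt)
      }
      cfg <- do.call(generator_config, gc_args)
      coh <- simulate_cohort(cfg, correct, alt_layout, seed = seed)
      profiles <- coh$profiles
      records <- coh$records
    } else {
      records <- tibble::as_tibble(utils::read.csv(config$records))
      if (!nrow(records)) stop("no records")
      need <- c("participant", "group", "session", "origin", "target",
                "judged")
      miss <- setdiff(need, names(records))
      if (length(miss)) stop("records CSV lacks columns: ",
                             paste(miss, collapse = ", "))
      records <- dplyr::left_join(records, pairs,
                                  by = c("origin", "target"))
      records$truth <- vapply(seq_len(nrow(records)), function(i) {
        true_direction(correct, records$origin[i], records$target[i])
      }, numeric(1))
      records$error <- angular_error(records$judged, records$truth)
      profiles <- if (!is.null(config$participants)) {
        tibble::as_tibble(utils::read.csv(config$participants))
      } else {
        dplyr::distinct(records[, c("participant", "group")])
      }
      if (is.null(profiles$experiment)) {
        profiles$experiment <- ifelse(profiles$group == "E", 2L, 1L)
      }
    }

    vis_err <- records |>
      dplyr::filter(.data$visible) |>
      dplyr::group_by(.data$participant) |>
      dplyr::summarise(mean_visible_error = mean(.data$error),
                       .groups = "drop")
    profiles <- dplyr::left_join(profiles, vis_err, by = "participant")
    # exclusion per experiment pool (G is reused in experiment 2)
    pool_members <- function(e) {
      if (e == 1L) profiles$group %in% c("G", "G+E")
      else profiles$group %in% c("G", "E")
    }
    excluded <- character()
    for (e in sort(unique(profiles$experiment))) {
      m <- profiles[pool_members(e) & !is.na(profiles$mean_visible_error), ]
      if (nrow(m) >= 4) {
        excluded <- union(excluded, exclude_by_visible_error(
          setNames(m$mean_visible_error, m$participant)))
      }
    }
    profiles$excluded <- profiles$participant %in% excluded
    kept <- profiles[!profiles$excluded, ]
    # SOD median split per experiment pool, levels assigned by the
    # participant's recruiting experiment
    if (!is.null(kept$sod_score)) {
      lev <- setNames(rep(NA_character_, nrow(kept)), kept$participant)
      for (e in sort(unique(kept$experiment))) {
        pool <- kept[if (e == 1L) kept$group %in% c("G", "G+E") else
          kept$group %in% c("G", "E"), ]
        if (nrow(pool) >= 2) {
          pool$pool_id <- e
          sp <- sod_median_split(pool, pool = "pool_id")
          assign_to <- sp$participant[sp$experiment == e]
          lev[assign_to] <- sp$sod_level[match(assign_to, sp$participant)]
        }
      }
      profiles$sod_level <- lev[profiles$participant]
    }
    emit(profiles, "participants.csv")
    records <- records[records$participant %in% kept$participant, ]
    if (!nrow(records)) stop("no records after exclusion")
    list(profiles = profiles, records = records)
  })
  records <- cohort$records
  profiles <- cohort$profiles

  run_stage("records", function() emit(records, "records.csv"))

  run_stage("target_summary", function() {
    emit(per_target_error_summary(records[!records$visible, ]),
         "target_summary.csv")
  })

  # --- stage 5: mixture fits per non-visible trial --------------------
  fits <- run_stage("mixtures", function() {
    nv <- pairs[!pairs$visible, ]
    fl <- lapply(seq_len(nrow(nv)), function(i) {
      idx <- !records$visible & records$origin == nv$origin[i] &
        records$target == nv$target[i]
      ang <- records$judged[idx]
      truth <- true_direction(correct, nv$origin[i], nv$target[i])
      base <- list(origin = nv$origin[i], target = nv$target[i],
                   n = length(ang), truth = truth)
      if (length(ang) < min_trial_n) {
        return(c(base, list(modality = NA)))
      }
      ctl <- control
      ctl$seed <- (seed + i) %% 2147483647L
      fit <- select_modality(ang, ctl)
      out <- c(base, list(
        modality = fit$modality, K = fit$K, weights = fit$weights,
        mean_dir = fit$mu, kappa = fit$kappa, bic = fit$bic,
        bic_unimodal = fit$criteria$bic_unimodal,
        bic_bimodal = fit$criteria$bic_bimodal))
      if (fit$modality == "bimodal") {
        sect <- mode_confidence_sector(ang, fit, B = control$bootstrap_B,
                                       seed = ctl$seed)
        out$sectors <- sect
        out$systematic_component <- label_systematic_mode(fit, truth)
        out$systematic_deviation <- angular_error(
          fit$mu[out$systematic_component], truth)
      }
      out
    })
    path <- file.path(out_dir, "fits.json")
    jsonlite::write_json(fl, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
    outputs <<- c(outputs, "fits.json")
    fl
  })

  bimodal_trials <- dplyr::bind_rows(lapply(fits, function(f) {
    if (identical(f$modality, "bimodal")) {
      tibble::tibble(origin = f$origin, target = f$target)
    }
  }))

  comparison <- run_stage("comparison", function() {
    if (!nrow(bimodal_trials)) {
      stop("no bimodal trials detected; nothing to compare")
    }
    cmp <- compare_models(records, bimodal_trials, correct, alt_layout)
    emit(cmp, "comparison.csv")
    cmp
  })

  preference <- run_stage("preference", function() {
    prof <- profiles[!profiles$excluded & !is.na(profiles$sod_level), ]
    pref <- aggregate_preference(comparison, prof)
    overall <- pref$overall
    overall$group <- "(all)"
    overall$sod_level <- "(all)"
    emit(dplyr::bind_rows(pref$cells, overall), "preference.csv")
    pref
  })

  cfg_hash <- hash_object(config)
  layout_hash <- hash_object(list(correct$coords, correct$walls))
  manifest <- structure(
    list(status = "complete",
         created = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
         elapsed_s = round(as.numeric(Sys.time() - t_start,
                                      units = "secs"), 2),
         seed = seed, config_hash = cfg_hash, layout_hash = layout_hash,
         n_bimodal_trials = nrow(bimodal_trials),
         stages = stages,
         outputs = lapply(outputs, function(f) {
           list(file = f,
                md5 = unname(tools::md5sum(file.path(out_dir, f))))
         })),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest), manifest_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# md5 of the canonical JSON serialization of an R object
hash_object <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> status %s, seed %d, %d outputs, %.1fs\n",
              x$status, x$seed, length(x$outputs), x$elapsed_s))
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}
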