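test_that("perfectly correct pointers prefer the correct representation", {
  pair <- toy_layout_pair()
  trials <- data.frame(origin = c(1, 3), target = c(3, 1))
  dirs <- vapply(1:2, function(i) {
    true_direction(pair$correct, trials$origin[i], trials$target[i])
  }, numeric(1))
  recs <- tibble::tibble(participant = "p1", session = 1L,
                         origin = trials$origin, target = trials$target,
                         judged = dirs)
  cmp <- compare_models(recs, trials, pair$correct, pair$alternative)
  expect_equal(cmp$better_fit, "correct")
  expect_equal(cmp$mean_error_correct, 0)
  expect_true(is.na(cmp$error_reduction))
})

test_that("ties go to the correct representation", {
  pair <- toy_layout_pair()
  trials <- data.frame(origin = 1, target = 3)
  recs <- tibble::tibble(participant = "p1", session = 1L, origin = 1,
                         target = 3, judged = 10)
  cmp <- compare_models(recs, trials, pair$correct, pair$correct)
  expect_equal(cmp$better_fit, "correct")
})

test_that("alternative-generated pointers are recovered as alternative", {
  ll <- list(correct = packaged_maze_layout(),
             alternative = fixture_alternative_layout())
  p1 <- default_p_alt()
  p1$p <- 1
  cfg <- generator_config(n_per_group = c("G" = 10, "G+E" = 10, "E" = 10),
                          p_alt = p1,
                          kappa_nonvisible = c(low = 20, high = 20),
                          outlier_rate = 0, adoption = "participant")
  hits <- unlist(lapply(1:3, function(s) {
    coh <- simulate_cohort(cfg, ll$correct, ll$alternative, seed = s)
    nv <- coh$records[!coh$records$visible & coh$records$eligible, ]
    # restrict to trials whose two candidate directions differ clearly
    trials <- dplyr::distinct(nv[, c("origin", "target")])
    delta <- vapply(seq_len(nrow(trials)), function(i) {
      angular_error(
        true_direction(ll$correct, trials$origin[i], trials$target[i]),
        true_direction(ll$alternative, trials$origin[i], trials$target[i]))
    }, numeric(1))
    cmp <- compare_models(coh$records, trials[delta >= 30, ],
                          ll$correct, ll$alternative)
    cmp$better_fit == "alternative"
  }))
  expect_gte(mean(hits), 0.95)
})

test_that("records sampled from a layout prefer it increasingly with kappa", {
  ll <- list(correct = packaged_maze_layout(),
             alternative = fixture_alternative_layout())
  p0 <- default_p_alt()
  p0$p <- 0
  rate <- vapply(c(4, 8, 20), function(k) {
    cfg <- generator_config(n_per_group = c("G" = 8, "G+E" = 8, "E" = 8),
                            p_alt = p0,
                            kappa_nonvisible = c(low = k, high = k),
                            session_kappa_mult = c(1, 1), outlier_rate = 0)
    coh <- simulate_cohort(cfg, ll$correct, ll$alternative, seed = k)
    nv <- coh$records[!coh$records$visible & coh$records$eligible, ]
    trials <- dplyr::distinct(nv[, c("origin", "target")])
    cmp <- compare_models(coh$records, trials, ll$correct, ll$alternative)
    mean(cmp$better_fit == "correct")
  }, numeric(1))
  expect_true(all(diff(rate) >= 0) || rate[3] > 0.95)
  expect_gt(rate[3], 0.95)
  expect_gt(rate[1], 0.5)
})

test_that("participants without bimodal-trial records are dropped with a message", {
  pair <- toy_layout_pair()
  recs <- tibble::tibble(
    participant = c("p1", "p2"), session = 1L,
    origin = c(1, 3), target = c(3, 2), judged = c(45, 0))
  expect_message(
    cmp <- compare_models(recs, data.frame(origin = 1, target = 3),
                          pair$correct, pair$alternative),
    "p2")
  expect_equal(cmp$participant, "p1")
})

test_that("preference aggregation reports cells, gaps, and missing cells", {
  prof <- tidyr::expand_grid(group = c("G", "G+E", "E"),
                             sod_level = c("low", "high"),
                             idx = 1:10)
  prof$participant <- sprintf("p%03d", seq_len(nrow(prof)))
  # construct deterministic comparisons: low-SOD G participants prefer the
  # alternative at 0.8, high-SOD G at 0.2, everyone else at 0.5
  p_of <- function(g, s) {
    if (g == "G") ifelse(s == "low", 0.8, 0.2) else 0.5
  }
  cmp <- dplyr::bind_rows(lapply(seq_len(nrow(prof)), function(i) {
    p <- p_of(prof$group[i], prof$sod_level[i])
    tibble::tibble(participant = prof$participant[i], session = 1L,
                   better_fit = ifelse(prof$idx[i] <= round(10 * p),
                                       "alternative", "correct"),
                   error_reduction = ifelse(prof$idx[i] <= round(10 * p),
                                            0.6, NA))
  }))
  pref <- aggregate_preference(cmp, prof)
  cells <- pref$cells
  gap <- function(g) {
    abs(cells$pct_alternative[cells$group == g & cells$sod_level == "low"] -
          cells$pct_alternative[cells$group == g & cells$sod_level == "high"])
  }
  expect_equal(gap("G"), 60)
  expect_gt(gap("G"), max(gap("G+E"), gap("E")))
  expect_equal(pref$overall$pct_alternative,
               100 * mean(cmp$better_fit == "alternative"))

  # all-correct cohort: all zeros
  cmp0 <- cmp
  cmp0$better_fit <- "correct"
  cmp0$error_reduction <- NA_real_
  expect_true(all(aggregate_preference(cmp0, prof)$cells$pct_alternative == 0))

  # one participant per cell: percentages are 0 or 100
  one <- cmp[!duplicated(paste(prof$group, prof$sod_level)[
    match(cmp$participant, prof$participant)]), ]
  p1 <- aggregate_preference(one, prof)
  expect_true(all(p1$cells$pct_alternative[p1$cells$n > 0] %in% c(0, 100)))

  # a cell with nobody in it is missing, not zero
  cmp_part <- cmp[prof$group[match(cmp$participant, prof$participant)] != "E", ]
  pe <- aggregate_preference(cmp_part, prof)
  ecells <- pe$cells[pe$cells$group == "E", ]
  expect_true(all(ecells$n == 0))
  expect_true(all(is.na(ecells$pct_alternative)))
})
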