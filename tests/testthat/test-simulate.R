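test_that("generated trains are valid, deterministic, and invert segmentation", {
  cfg <- sim_config(seed = 5)
  a <- simulate_lick_train(cfg, "tail", 4, seed = 123)
  b <- simulate_lick_train(cfg, "tail", 4, seed = 123)
  expect_identical(a$timestamps, b$timestamps)     # determinism contract
  expect_silent(validate_lick_train(a))

  # segmentation at the configured threshold recovers the generator's
  # clusters exactly (pauses >= threshold, intervals one tick below)
  for (s in 1:25) {
    tr <- simulate_lick_train(cfg, sample(c("tail", "tunnel"), 1),
                              sample(c(4, 16), 1), seed = 800 + s)
    cl <- segment_clusters(tr, cfg$interbout_interval)
    expect_equal(nrow(cl), attr(tr, "n_true_clusters"))
  }

  # degenerate config: zero spread, fixed cluster size k = 5
  fixed <- sim_config(ili_sd = 0, cluster_size_dispersion = 0,
                      cluster_size_mean = matrix(5, 2, 2,
                        dimnames = list(c("tail", "tunnel"), c("4", "16"))),
                      subject_cv = 0, seed = 5)
  tr <- simulate_lick_train(fixed, "tunnel", 16, seed = 9)
  expect_true(all(segment_clusters(tr)$size == 5L))
})

test_that("infeasible configurations are rejected at construction", {
  expect_error(sim_config(ili_mean = 0.30), "infeasible")
  expect_error(sim_config(pause_shift = 0.10), "pause_shift")
  expect_error(sim_config(cluster_size_mean = matrix(0.5, 2, 2,
    dimnames = list(c("tail", "tunnel"), c("4", "16")))), ">= 1")
  expect_error(simulate_experiment(sim_config(n_per_group = 3)), "even")
})

test_that("simulated cluster sizes hit the configured mean (Monte Carlo)", {
  cfg <- sim_config(cluster_size_mean = matrix(5, 2, 2,
    dimnames = list(c("tail", "tunnel"), c("4", "16"))), subject_cv = 0,
    seed = 2)
  set.seed(42)
  sizes <- unlist(lapply(1:120, function(i) {
    summarize_session(simulate_lick_train(cfg, "tail", 4))$cluster_sizes
  }))
  expect_gt(length(sizes), 10000)
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 5), 3 * se)
})

test_that("the experiment has the crossover structure and proportional consumption", {
  cfg <- sim_config(n_per_group = 4L, sessions_per_phase = 2L,
                    session_duration = 240, seed = 11)
  ex <- simulate_experiment(cfg)
  expect_equal(nrow(ex$subjects), 8)
  expect_length(ex$trains, 8 * 2 * 2)              # subjects x phases x days
  expect_equal(nrow(ex$consumption), length(ex$trains))

  # counterbalanced crossover: half of each handling group starts on 4%
  first_day <- min(ex$consumption$session_day)
  first <- ex$consumption[ex$consumption$session_day == first_day, ]
  first$handling <- ex$subjects$handling[match(first$subject_id,
                                               ex$subjects$subject_id)]
  tab <- table(first$handling, first$concentration)
  expect_true(all(tab == 2))
  # each mouse sees both concentrations
  per_subj <- tapply(ex$consumption$concentration, ex$consumption$subject_id,
                     function(x) length(unique(x)))
  expect_true(all(per_subj == 2))

  # zero measurement noise -> mass exactly proportional to lick count
  cfg0 <- sim_config(n_per_group = 2L, sessions_per_phase = 1L,
                     session_duration = 120, consumption_noise_sd = 0, seed = 3)
  ex0 <- simulate_experiment(cfg0)
  licks <- vapply(ex0$trains, n_licks, integer(1))
  key <- paste(vapply(ex0$trains, function(t) t$subject_id, character(1)),
               vapply(ex0$trains, function(t) t$session_day, integer(1)))
  mass <- ex0$consumption$mass_consumed[
    match(key, paste(ex0$consumption$subject_id, ex0$consumption$session_day))]
  expect_equal(mass, licks * cfg0$volume_per_lick, tolerance = 1e-12)
})

test_that("master seed expands to per-subject substreams", {
  small <- simulate_experiment(sim_config(n_per_group = 4L, sessions_per_phase = 1L,
                                          session_duration = 120, seed = 21))
  big <- simulate_experiment(sim_config(n_per_group = 6L, sessions_per_phase = 1L,
                                        session_duration = 120, seed = 21))
  # tail-handled mice keep their index when the groups grow, so their data
  # are unchanged
  for (id in sprintf("m%02d", 1:4)) {
    t_small <- Filter(function(t) t$subject_id == id, small$trains)
    t_big <- Filter(function(t) t$subject_id == id, big$trains)
    expect_identical(lapply(t_small, `[[`, "timestamps"),
                     lapply(t_big, `[[`, "timestamps"))
  }
})

test_that("experiments round-trip through the on-disk CSV layout", {
  cfg <- sim_config(n_per_group = 2L, sessions_per_phase = 2L,
                    session_duration = 180, seed = 13)
  ex <- simulate_experiment(cfg)
  dir <- tempfile()
  paths <- write_experiment(ex, dir, medpc = TRUE)
  expect_true(all(file.exists(paths[c("metadata", "licks", "consumption",
                                      "ground_truth")])))
  back <- read_lick_csv(paths[["licks"]])
  orig <- Filter(function(t) n_licks(t) > 0, ex$trains)
  ord <- order(vapply(orig, function(t) paste(t$subject_id, sprintf("%03d", t$session_day)),
                      character(1)))
  orig <- orig[ord]
  expect_equal(lapply(back, `[[`, "timestamps"),
               lapply(orig, `[[`, "timestamps"))
  meta <- read_metadata_table(paths[["metadata"]])
  expect_equal(nrow(meta), 4)
  mp <- list.files(paths[["medpc_dir"]], full.names = TRUE)
  expect_length(mp, 16)   # 4 mice x 2 phases x 2 sessions
  tr <- read_medpc_file(mp[1])[[1]]
  expect_gt(n_licks(tr), 0)
})
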