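test_that("interbout rule: gaps at or above the threshold split clusters", {
  tr <- lick_train("a", c(0.00, 0.10, 0.20, 0.60, 0.70))
  expect_equal(segment_clusters(tr)$size, c(3L, 2L))

  # boundary semantics: "250 ms or longer" means a 0.25 s gap splits
  expect_equal(segment_clusters(lick_train("a", c(0.00, 0.25)))$size, c(1L, 1L))
  expect_equal(segment_clusters(lick_train("a", c(0.00, 0.24)))$size, 2L)

  # arithmetic noise just under the threshold still splits after rounding
  noisy <- lick_train("a", c(0.00, 0.25 - 1e-10))
  expect_equal(segment_clusters(noisy)$size, c(1L, 1L))

  expect_equal(segment_clusters(lick_train("a", 0.00))$size, 1L)
  expect_equal(nrow(segment_clusters(lick_train("a", numeric(0)))), 0)
})

test_that("cluster rows carry consistent indices, times and sizes", {
  tr <- random_train(80, seed = 11)
  cl <- segment_clusters(tr)
  expect_equal(cl$size, cl$end_index - cl$start_index + 1L)
  expect_equal(cl$start_time, tr$timestamps[cl$start_index])
  expect_equal(cl$end_time, tr$timestamps[cl$end_index])
  # partition: clusters are disjoint, ordered, and jointly cover all licks
  covered <- unlist(Map(seq, cl$start_index, cl$end_index))
  expect_equal(covered, seq_len(n_licks(tr)))
})

test_that("session summaries compute totals, means, and flag empty sessions", {
  tr <- lick_train("a", c(0.00, 0.10, 0.20, 0.60, 0.70), session_day = 22,
                   concentration = 4)
  s <- summarize_session(tr)
  expect_equal(s$total_licks, 5L)
  expect_equal(s$n_clusters, 2L)
  expect_equal(s$mean_cluster_size, 2.5)
  expect_equal(sum(s$cluster_sizes), s$total_licks)

  s0 <- summarize_session(lick_train("a", numeric(0)))
  expect_equal(s0$total_licks, 0L)
  expect_true(is.na(s0$mean_cluster_size))

  # all gaps below threshold: one cluster of N
  s1 <- summarize_session(lick_train("a", seq(0, 0.9, by = 0.1)))
  expect_equal(s1$n_clusters, 1L)
  expect_equal(s1$mean_cluster_size, 10)
})

test_that("engagement filter keeps strictly more than min_licks and reports the rest", {
  mk <- function(n) summarize_session(lick_train("a", round(seq_len(n) * 0.1, 2),
                                                 session_duration = n))
  res <- engagement_filter(list(mk(100), mk(101), mk(5)), min_licks = 100)
  expect_length(res$kept, 1)              # only the 101-lick session survives
  expect_equal(res$flagged$total_licks, c(100L, 5L))
  expect_match(res$flagged$reason[1], "<= 100")
  all_kept <- engagement_filter(list(mk(1), mk(2)), min_licks = 0)
  expect_length(all_kept$kept, 2)
})

test_that("subject means average session means, skipping flagged sessions", {
  tab <- data.frame(subject_id = "m1", session_day = 22:26, concentration = 4,
                    interbout_interval = 0.25, total_licks = 100,
                    n_clusters = 10, mean_cluster_size = c(2, 3, 4, 3, 3))
  expect_equal(subject_means(tab)$mean_cluster_size, 3)

  tab$mean_cluster_size[2] <- NA           # one empty day -> mean of remaining four
  expect_message(m <- subject_means(tab), "excluded")
  expect_equal(m$mean_cluster_size, 3)

  one <- tab[1, ]
  expect_equal(subject_means(one)$mean_cluster_size, 2)

  none <- tab; none$mean_cluster_size <- NA
  expect_warning(m <- suppressMessages(subject_means(none)), "no valid session")
  expect_true(is.na(m$mean_cluster_size))
})

test_that("threshold sweep reproduces single-threshold summaries and is monotone", {
  trains <- lapply(1:20, function(i) {
    tr <- random_train(60, seed = 100 + i)
    tr$subject_id <- sprintf("m%02d", i); tr$session_day <- 22L
    tr$concentration <- 4; tr
  })
  sw <- sweep_thresholds(trains, 0.25)
  direct <- summaries_table(lapply(trains, summarize_session))
  expect_equal(sw$mean_cluster_size, direct$mean_cluster_size)
  expect_equal(sw$n_clusters, direct$n_clusters)

  grid <- c(0.25, 0.5, 1, 2)
  sw <- sweep_thresholds(trains, grid)
  for (i in seq_along(trains)) {
    sub <- sw[sw$subject_id == trains[[i]]$subject_id, ]
    sub <- sub[order(sub$threshold), ]
    expect_true(all(diff(sub$n_clusters) <= 0))          # fewer clusters
    expect_true(all(diff(sub$mean_cluster_size) >= 0))   # larger means
    expect_equal(unique(sub$total_licks), 60L)           # licks invariant
  }
  # threshold above the whole session span: one cluster per train
  big <- sweep_thresholds(trains, 10000)
  expect_true(all(big$n_clusters == 1L))
})
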