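test_that("bout calling applies the one-minute immobility rule", {
  b <- call_sleep_bouts(c(0, 0, 0, 5, 0))
  expect_equal(b$start_minute, c(0, 4))
  expect_equal(b$length_min, c(3, 1))
  expect_equal(sum(b$length_min), 4)

  expect_equal(nrow(call_sleep_bouts(c(1, 2, 3))), 0)
  expect_equal(nrow(call_sleep_bouts(numeric(0))), 0)

  hour <- call_sleep_bouts(rep(0, 60))
  expect_equal(hour$start_minute, 0)
  expect_equal(hour$length_min, 60)
})

test_that("sleep minutes equal the sum of bout lengths on random traces", {
  set.seed(60)
  for (i in 1:20) {
    act <- rbinom(240, 1, 0.5) * runif(240, 0.1, 5)
    b <- call_sleep_bouts(act)
    expect_equal(sum(b$length_min), sum(act == 0))
    # bouts are maximal: neighbours of each bout are active
    for (j in seq_len(nrow(b))) {
      s <- b$start_minute[j]; e <- s + b$length_min[j]
      if (s > 0) expect_gt(act[s], 0)
      if (e < length(act)) expect_gt(act[e + 1], 0)
    }
  }
})

test_that("bout calling shifts but does not change under a leading wake minute", {
  act <- c(0, 0, 3, 0, 1, 0, 0)
  b0 <- call_sleep_bouts(act)
  b1 <- call_sleep_bouts(c(9, act))
  expect_equal(b1$start_minute, b0$start_minute + 1)
  expect_equal(b1$length_min, b0$length_min)
})

test_that("hourly summaries match hand-worked traces", {
  # all-zero 24 h: 60 sleep minutes every hour, single onset in hour 0
  act <- rep(0, 1440)
  s <- summarize_sleep(call_sleep_bouts(act), act)
  expect_equal(s$hourly$sleep_min, rep(60, 24))
  expect_equal(sum(s$hourly$n_transitions), 1)
  expect_equal(s$hourly$n_transitions[1], 1)
  expect_equal(s$hourly$mean_bout_len[1], 1440)

  # 1-minute alternation for one hour
  act2 <- rep(c(5, 0), 30)
  s2 <- summarize_sleep(call_sleep_bouts(act2), act2)
  expect_equal(s2$phase$sleep_min_per_h, 30)
  expect_equal(s2$phase$transitions_per_h, 30)
  expect_equal(s2$phase$mean_bout_len, 1)

  # transitions summed over hours equal the number of bouts
  set.seed(61)
  act3 <- rbinom(1440, 1, 0.7) * runif(1440, 0.1, 3)
  b3 <- call_sleep_bouts(act3)
  s3 <- summarize_sleep(b3, act3)
  expect_equal(sum(s3$hourly$n_transitions), nrow(b3))
})

test_that("phase split follows the 14:10 photoperiod", {
  act <- rep(0, 1440)
  s <- summarize_sleep(call_sleep_bouts(act), act)
  expect_equal(sum(s$hourly$phase == "light"), 14)
  expect_equal(sum(s$hourly$phase == "dark"), 10)
  expect_equal(s$hourly$phase[15], "dark")
})

test_that("genotype comparison: identical groups give null effect", {
  set.seed(62)
  vals <- rnorm(8, 10)
  scores <- data.frame(
    larva_id = sprintf("l%02d", 1:16),
    genotype = rep(c("hom", "wt"), each = 8),
    phase = "dark",
    sleep_min_per_h = c(vals, vals),
    stringsAsFactors = FALSE
  )
  cmp <- compare_genotypes(scores, c("hom", "wt"), "dark")
  expect_equal(cmp$effect, 0)
  expect_gte(cmp$p, 0.99)
})

test_that("exact permutation p equals the bitmask enumeration oracle", {
  set.seed(63)
  for (i in 1:5) {
    x <- round(rnorm(8, 10, 2), 2)
    scores <- data.frame(
      larva_id = sprintf("l%02d", 1:8),
      genotype = rep(c("hom", "wt"), each = 4),
      phase = "dark",
      sleep_min_per_h = x,
      stringsAsFactors = FALSE
    )
    cmp <- compare_genotypes(scores, c("hom", "wt"), "dark")
    expect_equal(cmp$method, "exact")
    expect_equal(cmp$p, oracle_perm_p(x, rep(c(TRUE, FALSE), each = 4)),
                 tolerance = 1e-12, info = paste("case", i))
  }
})

test_that("comparison requires two larvae per group", {
  scores <- data.frame(
    larva_id = c("a", "b", "c"), genotype = c("hom", "wt", "wt"),
    phase = "dark", sleep_min_per_h = c(1, 2, 3),
    stringsAsFactors = FALSE
  )
  expect_error(compare_genotypes(scores, c("hom", "wt"), "dark"),
               "at least two")
})

test_that("rebound analysis detects elevated post-deprivation sleep", {
  # identical groups: zero effect
  same <- data.frame(
    larva_id = sprintf("l%02d", 1:26),
    group = rep(c("deprived", "control"), each = 13),
    post_sleep_min = rep(seq(20, 44, 2), 2),
    window_min = 360
  )
  r0 <- rebound_analysis(same)
  expect_equal(r0$effect, 0)

  # planted rebound at the study's group size (n = 13 each)
  set.seed(64)
  cfgs <- list(
    deprived = list(day = list(sleep_min_per_hour = 10, mean_bout_len = 2),
                    night = list(sleep_min_per_hour = 20, mean_bout_len = 3)),
    control = list(day = list(sleep_min_per_hour = 5, mean_bout_len = 2),
                   night = list(sleep_min_per_hour = 16, mean_bout_len = 3))
  )
  sim <- simulate_activity_cohort(sleep_sim_config(
    n_larvae_per_genotype = 13, params = cfgs, seed = 65
  ))
  scores <- score_cohort(sim$cohort)
  day <- scores[scores$phase == "light", ]
  df <- data.frame(
    larva_id = day$larva_id, group = day$genotype,
    post_sleep_min = day$sleep_min_per_h * 14, window_min = 840
  )
  r1 <- rebound_analysis(df, seed = 66)
  expect_gt(r1$effect, 0)
  expect_lt(r1$p, 0.05)

  # mismatched windows abort
  bad <- df
  bad$window_min[1] <- 120
  expect_error(rebound_analysis(bad), "mismatch")
})
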