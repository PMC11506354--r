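make_event_set <- function(seed = 101, n_sessions = 3) {
  cfg <- simulation_config(n_sessions = n_sessions, seed = seed)
  segment_events(make_blocks(generate_survey(cfg)))
}

test_that("budgets sum to 100 percent and match a brute-force tally", {
  ev1 <- segment_events(blocks_at(c(0, 5, 10), state = "TRA"))
  b1 <- activity_budget(ev1, "ALL")
  expect_equal(b1$table$percent[b1$table$state == "TRA"], 100)
  expect_equal(sum(b1$table$percent), 100)

  set.seed(57)
  for (i in 1:40) {
    ev <- make_event_set(seed = 400 + i, n_sessions = 2)
    if (nrow(ev$blocks) == 0) next  # sessions without a single sighting
    for (scen in c("ALL", "ABSENT", "PRESENT")) {
      has <- switch(scen, ALL = TRUE,
                    ABSENT = any(!ev$blocks$vessel_present),
                    PRESENT = any(ev$blocks$vessel_present))
      if (!has) next
      b <- activity_budget(ev, scen)
      want <- oracle_budget(ev$blocks, scen)
      expect_equal(setNames(b$table$total_min, b$table$state), want)
      expect_equal(sum(b$table$percent), 100)
      expect_equal(sum(b$event_sums$minutes), b$total_minutes)
    }
    # scenario partition conserves minutes
    ba <- activity_budget(ev, "ABSENT")
    bp <- suppressWarnings(activity_budget(ev, "PRESENT"))
    ball <- activity_budget(ev, "ALL")
    expect_equal(ba$total_minutes + bp$total_minutes, ball$total_minutes)
  }
})

test_that("empty scenario selections are flagged, not fabricated", {
  ev <- segment_events(blocks_at(c(0, 5), state = "FEE"))
  expect_warning(b <- activity_budget(ev, "PRESENT"), "no blocks")
  expect_true(attr(b, "empty"))
  expect_equal(b$total_minutes, 0)
})

test_that("large simulated budgets approach the chain occupancy", {
  cfg <- simulation_config(n_sessions = 200, sighting_hazard = 0.2,
                           vessel_process = 0, seed = 71)
  ev <- segment_events(make_blocks(generate_survey(cfg)))
  b <- activity_budget(ev, "ALL")
  # stationary distribution of the control chain over reachable states
  P <- cfg$P_control[1:3, 1:3]
  pi_ <- Re(eigen(t(P))$vectors[, 1]); pi_ <- pi_ / sum(pi_)
  occ <- setNames(c(pi_, 0), behavior_states())
  for (s in c("FEE", "TRA")) {
    expect_lt(abs(b$table$percent[b$table$state == s] / 100 - occ[s]), 0.05)
  }
})

test_that("rare states are excluded from tests but never from budgets", {
  ev <- make_event_set(seed = 120, n_sessions = 4)
  counts <- table(factor(ev$blocks$state, levels = behavior_states()))
  out <- exclude_rare_states(ev, min_samples = 12)
  expect_equal(setNames(out$report$n_blocks, out$report$state),
               setNames(as.integer(counts), names(counts)))
  expect_equal(out$report$excluded, as.logical(counts < 12))
  expect_false(any(out$events$blocks$state %in%
                     out$report$state[out$report$excluded]))
  # event identity preserved for surviving blocks
  expect_true(all(out$events$blocks$event_id %in% ev$blocks$event_id))
  # thresholds 0 and "all abundant" exclude nothing
  none <- exclude_rare_states(ev, min_samples = 0)
  expect_false(any(none$report$excluded))
  expect_equal(nrow(none$events$blocks), nrow(ev$blocks))
})

test_that("a state observed 11 times falls below the default threshold", {
  b <- rbind(blocks_at(seq(0, by = 20, length.out = 12), state = "TRA"),
             blocks_at(seq(400, by = 20, length.out = 11), state = "SOC"))
  out <- exclude_rare_states(segment_events(b))
  expect_true(out$report$excluded[out$report$state == "SOC"])
  expect_false(out$report$excluded[out$report$state == "TRA"])
})

test_that("normality checks report Shapiro and Levene diagnostics", {
  set.seed(5)
  vals <- c(rnorm(30, 20, 3), rnorm(25, 22, 3))
  grp <- rep(c("A", "B"), c(30, 25))
  nc <- normality_checks(vals, grp)
  expect_equal(nrow(nc$shapiro), 2)
  expect_true(all(nc$shapiro$p_value > 0 & nc$shapiro$p_value <= 1))
  expect_s3_class(nc$levene, "vw_test")
  # identical constant vectors: Levene statistic 0
  const <- normality_checks(rep(5, 12), rep(c("A", "B"), 6))
  expect_equal(const$levene$statistic, 0)
  expect_error(normality_checks(1:4, c("A", "A", "B", "B")), "at least 3")

  # Shapiro p-values are roughly uniform under gaussian data,
  # and reject heavy-tailed data well above the nominal rate
  ps_norm <- ps_heavy <- numeric(60)
  for (i in 1:60) {
    set.seed(2000 + i)
    ps_norm[i] <- stats::shapiro.test(rnorm(50))$p.value
    ps_heavy[i] <- stats::shapiro.test(rt(50, df = 1.5))$p.value
  }
  expect_gt(mean(ps_norm > 0.5), 0.25)
  expect_lt(mean(ps_norm < 0.05), 0.2)
  expect_gt(mean(ps_heavy < 0.05), 0.5)
})

test_that("Mann-Whitney agrees with exhaustive permutation for all small samples", {
  set.seed(91)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(0:30, n1, replace = TRUE)  # ties likely
    y <- sample(0:30, n2, replace = TRUE)
    if (sd(c(x, y)) == 0) next
    got <- compare_budgets(x, y)
    expect_equal(got$method, "exact permutation")
    expect_equal(got$p_value, oracle_mw_exact(x, y))
    # U statistic agrees with the rank-sum identity
    rk <- rank(c(x, y))
    expect_equal(got$statistic, sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2)
  }
  # against wilcox.test where it is exact (no ties)
  for (i in 1:20) {
    x <- sample(1:1000, 6); y <- sample(1001:2000 + 0.5, 6)
    w <- stats::wilcox.test(x, y, exact = TRUE)
    got <- compare_budgets(x, y)
    expect_equal(got$p_value, w$p.value)
    expect_equal(got$statistic, unname(w$statistic))
  }
})

test_that("Mann-Whitney large-sample path is sane and degenerate ties warn", {
  set.seed(13)
  x <- rnorm(40, 10); y <- rnorm(45, 10)
  got <- compare_budgets(x, y)
  expect_equal(got$method, "normal approximation")
  w <- stats::wilcox.test(x, y, correct = TRUE)
  expect_lt(abs(got$p_value - w$p.value), 0.01)
  # identical samples: p near 1
  z <- rnorm(20)
  expect_gt(compare_budgets(z, z)$p_value, 0.9)
  expect_warning(res <- compare_budgets(rep(3, 5), rep(3, 4)), "tied")
  expect_equal(res$p_value, 1)
  # shifted distributions are detected reliably
  rej <- 0
  for (i in 1:40) {
    set.seed(3000 + i)
    if (compare_budgets(rnorm(30), rnorm(30) + 1.2)$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / 40, 0.9)
})

test_that("time-in-area summaries match direct recomputation", {
  ev <- segment_events(rbind(
    blocks_at(c(0, 5), state = "TRA", group = "G1"),
    blocks_at(40, state = "FEE", group = "G1", dur = 10 / 2)))
  s <- time_in_area_summary(ev, "ALL")
  expect_equal(s$mean, 7.5)
  expect_equal(s$min, 5); expect_equal(s$max, 10); expect_equal(s$n, 2)
  expect_equal(s$se, sd(c(10, 5)) / sqrt(2))
  one <- time_in_area_summary(segment_events(blocks_at(0, dur = 5)), "ALL")
  expect_equal(one$se, 0)
  expect_true(one$single_event)

  ev2 <- make_event_set(seed = 140)
  s2 <- time_in_area_summary(ev2, "PRESENT")
  per <- tapply(ev2$blocks$duration_min[ev2$blocks$vessel_present],
                ev2$blocks$event_id[ev2$blocks$vessel_present], sum)
  expect_equal(s2$mean, mean(per))
  expect_equal(s2$se, sd(per) / sqrt(length(per)))
  expect_equal(s2$n, length(per))
})
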