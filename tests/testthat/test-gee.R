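survey_rows <- function(seed = 301, n_sessions = 25) {
  cfg <- simulation_config(n_sessions = n_sessions, seed = seed)
  ev <- segment_events(make_blocks(generate_survey(cfg)))
  reaction_time_table(exclude_rare_states(ev)$events)
}

test_that("reaction-time table sums vessel-present minutes by event, state and reaction", {
  b <- rbind(blocks_at(c(0, 5, 10), state = "TRA", vessel = TRUE,
                       reaction = "NEU"))
  ev <- segment_events(b)
  rows <- reaction_time_table(ev)
  expect_equal(nrow(rows), 1)
  expect_equal(rows$time_min, 15)
  expect_equal(as.character(rows$behavior), "TRA")
  expect_equal(as.character(rows$reaction), "NEU")

  # no vessels anywhere: empty with a warning
  ev0 <- segment_events(blocks_at(c(0, 5), state = "FEE"))
  expect_warning(r0 <- reaction_time_table(ev0), "no vessel-present")
  expect_equal(nrow(r0), 0)

  # random surveys match the brute-force group-sum oracle
  for (s in 1:20) {
    cfg <- simulation_config(n_sessions = 2, seed = 500 + s)
    ev <- segment_events(make_blocks(generate_survey(cfg)))
    rows <- reaction_time_table(ev)
    want <- oracle_reaction_sums(ev$blocks)
    if (is.null(want)) {
      expect_equal(nrow(rows), 0)
    } else {
      got <- setNames(rows$time_min,
                      paste(rows$event_id, rows$behavior, rows$reaction,
                            sep = "|"))
      expect_equal(got[sort(names(got))],
                   want[sort(names(want))])
    }
  }
})

test_that("reaction budgets are percentages of exposure time", {
  rows <- data.frame(event_id = "E1",
                     behavior = "TRA",
                     reaction = c("NEU", "NEG", "POS"),
                     time_min = c(80, 16, 4))
  expect_equal(reaction_budget(rows),
               c(POS = 4, NEU = 80, NEG = 16))
  all_neu <- rows[1, ]
  expect_equal(unname(reaction_budget(all_neu)["NEU"]), 100)

  # Monte-Carlo recovery of the configured reaction mixture
  cfg <- simulation_config(n_sessions = 250, sighting_hazard = 0.2, seed = 61)
  ev <- segment_events(make_blocks(generate_survey(cfg)))
  rows_mc <- reaction_time_table(ev)
  rb <- reaction_budget(rows_mc)
  # expected mixture: reaction probabilities weighted by time per state
  vp <- ev$blocks[ev$blocks$vessel_present, ]
  w <- tapply(vp$duration_min, factor(vp$state, behavior_states()), sum)
  w[is.na(w)] <- 0; w <- w / sum(w)
  want <- 100 * as.numeric(w %*% cfg$reaction_probs)
  expect_true(all(abs(rb - want) < 2.5))
})

test_that("with independence working correlation and singleton clusters the fit is a gamma GLM", {
  for (link in c("log", "inverse")) {
    d <- generate_gee_dataset(
      120, c("(Intercept)" = if (link == "log") 2.5 else 0.1,
             reactionNEG = if (link == "log") -0.4 else 0.05,
             behaviorFEE = if (link == "log") 0.3 else -0.02),
      alpha = 0, dispersion = 0.4, link = link,
      cluster_sizes = function(n) rep(1L, n), seed = 12)
    f <- fit_gee(d, "M2", link = link, corstr = "independence")
    g <- stats::glm(time_min ~ reaction + behavior,
                    family = stats::Gamma(link = link), data = d,
                    control = stats::glm.control(epsilon = 1e-12))
    expect_lt(max(abs(f$coefficients - stats::coef(g))), 1e-6)
    expect_equal(f$alpha, 0)
  }
})

test_that("intercept-only log-link fit with forced independence is the log sample mean", {
  d <- generate_gee_dataset(80, c("(Intercept)" = 2), alpha = 0,
                            dispersion = 0.3, link = "log", seed = 14)
  f <- fit_gee(d, "M0", link = "log", corstr = "independence")
  expect_equal(unname(f$coefficients[1]), log(mean(d$time_min)),
               tolerance = 1e-9)
})

test_that("GEE recovers coefficients, alpha and dispersion on synthetic clusters", {
  truth <- c("(Intercept)" = 2.5, reactionPOS = -0.6, reactionNEG = -0.35,
             behaviorFEE = 0.25, behaviorSOC = -0.5)
  hits <- 0; n_rep <- 40
  alphas <- disps <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    d <- generate_gee_dataset(200, truth, alpha = 0.3, dispersion = 0.5,
                              link = "log", seed = 7000 + r)
    f <- fit_gee(d, "M2", link = "log")
    ok <- abs(f$coefficients[names(truth)] - truth) <=
      3 * f$robust_se[names(truth)]
    if (all(ok)) hits <- hits + 1
    alphas[r] <- f$alpha; disps[r] <- f$dispersion
  }
  expect_gte(hits / n_rep, 0.95)
  expect_lt(abs(mean(alphas) - 0.3), 0.1)
  expect_lt(abs(mean(disps) - 0.5), 0.1)
})

test_that("estimating equations are invariant to cluster duplication and relabeling", {
  rows <- survey_rows(seed = 305)
  f <- fit_gee(rows, "M2")
  # duplicate every cluster under fresh ids: same coefficient estimates
  dup <- rows
  dup$event_id <- paste0(dup$event_id, "_copy")
  doubled <- rbind(rows, dup)
  f2 <- fit_gee(doubled, "M2")
  # identical up to the small-sample denominator corrections in alpha/phi
  expect_equal(unname(f2$coefficients), unname(f$coefficients),
               tolerance = 1e-3)
  # robust SEs shrink by about sqrt(2) but are invariant to relabeling
  perm <- rows[sample(nrow(rows)), ]
  relabel <- setNames(sample(unique(rows$event_id)), unique(rows$event_id))
  perm$event_id <- unname(relabel[perm$event_id])
  f3 <- fit_gee(perm, "M2")
  expect_equal(unname(sort(f3$robust_se)), unname(sort(f$robust_se)),
               tolerance = 1e-8)
  expect_equal(f3$alpha, f$alpha, tolerance = 1e-8)
})

test_that("rank-deficient designs and degenerate comparisons fail loudly", {
  rows <- survey_rows(seed = 310)
  rows$behavior <- factor("TRA")  # one-level factor aliases the design
  expect_error(fit_gee(rows, "M2"), "aliased|contrasts")
  rows2 <- survey_rows(seed = 311)
  f1 <- fit_gee(rows2, "M1")
  expect_error(compare_models(f1, f1), "identical terms")
  f1b <- fit_gee(rows2[-seq_len(3), ], "M1")
  expect_error(compare_models(f1, f1b), "different rows")
  expect_error(fit_gee(rows2[rows2$time_min < 0, ], "M1"))
})

test_that("nested Wald comparison is calibrated under the null and powerful under the alternative", {
  # type-I error of M1 vs M2 when behavior truly has no effect
  n_rep <- 200; rej <- 0
  for (r in seq_len(n_rep)) {
    d <- generate_gee_dataset(
      150, c("(Intercept)" = 2.5, reactionPOS = -0.5, reactionNEG = -0.3),
      alpha = 0.3, dispersion = 0.5, link = "log", seed = 8000 + r)
    cmp <- compare_models(fit_gee(d, "M1", link = "log"),
                          fit_gee(d, "M2", link = "log"))
    expect_equal(cmp$df, 2)
    if (cmp$p_value < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.04)

  # power: a strong true interaction is detected by M2 vs M3
  rej_pow <- 0
  for (r in 1:30) {
    d <- generate_gee_dataset(
      150, c("(Intercept)" = 2.5, reactionNEG = -0.3, behaviorFEE = 0.3,
             "reactionNEG:behaviorFEE" = 1),
      alpha = 0.3, dispersion = 0.5, link = "log", seed = 8500 + r)
    cmp <- compare_models(fit_gee(d, "M2", link = "log"),
                          fit_gee(d, "M3", link = "log"))
    expect_equal(cmp$df, 4)
    if (cmp$p_value < 0.05) rej_pow <- rej_pow + 1
  }
  expect_gt(rej_pow / 30, 0.9)
})

test_that("negative working correlation is estimated when clusters compete", {
  # competitive clusters: one shared total split across rows induces
  # negative within-cluster association
  set.seed(99)
  n_cl <- 150
  rows <- do.call(rbind, lapply(seq_len(n_cl), function(i) {
    tot <- 40  # fixed cluster total: splitting it makes rows compete
    sh <- as.numeric(stats::rmultinom(1, 12, prob = rep(1 / 3, 3))) / 12
    data.frame(event_id = sprintf("E%03d", i),
               behavior = factor("TRA"),
               reaction = factor(c("NEU", "POS", "NEG"),
                                 levels = c("NEU", "POS", "NEG")),
               time_min = pmax(tot * sh, 1e-3))
  }))
  f <- fit_gee(rows, "M1", link = "log")
  expect_lt(f$alpha, 0)
})
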