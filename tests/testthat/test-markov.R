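test_that("transition counting follows runs, scenarios and event boundaries", {
  # three control TRA blocks: two TRA->TRA transitions
  ev <- segment_events(blocks_at(c(0, 5, 10), state = "TRA"))
  ct <- count_transitions(ev)
  expect_equal(ct$control$a["TRA", "TRA"], 2L)
  expect_equal(ct$control$n_transitions, 2L)
  expect_equal(ct$impact$n_transitions, 0L)

  # a single-block event contributes nothing (and is logged)
  one <- segment_events(blocks_at(0, state = "FEE"))
  expect_message(ct1 <- count_transitions(one), "single block")
  expect_equal(ct1$control$n_transitions + ct1$impact$n_transitions, 0L)

  # exposure rules disagree exactly on mixed pairs
  b <- rbind(block_row(start = 0, state = "FEE", vessel = FALSE),
             block_row(start = 5, state = "TRA", vessel = TRUE,
                       reaction = "NEU"))
  evm <- segment_events(b)
  pre <- count_transitions(evm, "preceding")
  suc <- count_transitions(evm, "succeeding")
  both <- count_transitions(evm, "both")
  expect_equal(pre$control$a["FEE", "TRA"], 1L)
  expect_equal(suc$impact$a["FEE", "TRA"], 1L)
  expect_equal(both$control$n_transitions + both$impact$n_transitions, 0L)
  expect_equal(both$n_dropped, 1L)
})

test_that("transition counts equal the pairwise-scan oracle under every exposure rule", {
  for (s in 1:40) {
    cfg <- simulation_config(n_sessions = 2, seed = 600 + s)
    ev <- segment_events(make_blocks(generate_survey(cfg)))
    for (rule in c("preceding", "succeeding", "both")) {
      got <- suppressMessages(count_transitions(ev, rule))
      want <- oracle_transitions(ev$blocks, rule)
      expect_identical(got$control$a, want$CONTROL)
      expect_identical(got$impact$a, want$IMPACT)
      # conservation: scenario split covers all consecutive pairs
      pairs_total <- sum(pmax(ev$events$n_blocks - 1L, 0L))
      expect_equal(got$control$n_transitions + got$impact$n_transitions +
                     got$n_dropped, pairs_total)
    }
  }
})

test_that("row normalization matches elementwise division and marks empty rows", {
  counts <- structure(list(scenario = "CONTROL",
                           a = matrix(c(2L, 0L, 0L, 0L,
                                        3L, 5L, 1L, 0L,
                                        0L, 0L, 0L, 0L,
                                        1L, 1L, 1L, 1L),
                                      4, 4, byrow = TRUE,
                                      dimnames = list(states4, states4)),
                           n_transitions = 16L),
                      class = "transition_counts")
  tm <- transition_probabilities(counts)
  expect_equal(tm$p["FEE", ], c(FEE = 1, TRA = 0, SOC = 0, RES = 0))
  expect_true(all(is.na(tm$p["SOC", ])))
  expect_equal(unname(tm$row_support), c(2L, 9L, 0L, 4L))

  set.seed(67)
  for (i in 1:50) {
    a <- matrix(rpois(16, 3), 4, 4, dimnames = list(states4, states4))
    cts <- structure(list(scenario = "IMPACT", a = a, n_transitions = sum(a)),
                     class = "transition_counts")
    tm <- transition_probabilities(cts)
    for (r in seq_len(4)) {
      if (sum(a[r, ]) == 0) {
        expect_true(all(is.na(tm$p[r, ])))
      } else {
        expect_equal(tm$p[r, ], a[r, ] / sum(a[r, ]))
        expect_equal(sum(tm$p[r, ]), 1)
      }
    }
  }
})

test_that("chain comparison reports differences and a calibrated permutation null", {
  cfg <- simulation_config(n_sessions = 8, seed = 73)
  ev <- segment_events(make_blocks(generate_survey(cfg)))
  ct <- count_transitions(ev)
  pc <- transition_probabilities(ct$control)
  pim <- transition_probabilities(ct$impact)
  # identical matrices: all differences zero
  same <- compare_chains(pc, pc)
  expect_true(all(same$diff[is.finite(same$diff)] == 0))

  tt <- transition_table(ev)
  cmp <- compare_chains(pc, pim, tt, n_permutations = 99, seed = 4)
  expect_equal(cmp$diff, pim$p - pc$p)
  expect_true(all(cmp$p_values[is.finite(cmp$p_values)] > 0))
  expect_true(all(cmp$p_values[is.finite(cmp$p_values)] <= 1))
  # deterministic under the seed
  cmp2 <- compare_chains(pc, pim, tt, n_permutations = 99, seed = 4)
  expect_identical(cmp$p_values, cmp2$p_values)
  expect_error(compare_chains(pc, pim, n_permutations = 10), "transition_table")
})

test_that("a strong single-cell difference between scenarios is flagged", {
  P_imp <- default_control_matrix()
  P_imp["FEE", "FEE"] <- P_imp["FEE", "FEE"] - 0.3
  P_imp["FEE", "TRA"] <- P_imp["FEE", "TRA"] + 0.3
  cfg <- simulation_config(P_impact = P_imp, n_sessions = 120,
                           sighting_hazard = 0.2, seed = 81)
  ev <- segment_events(make_blocks(generate_survey(cfg)))
  ct <- count_transitions(ev)
  cmp <- compare_chains(transition_probabilities(ct$control),
                        transition_probabilities(ct$impact),
                        transition_table(ev), n_permutations = 199, seed = 5)
  expect_lt(cmp$p_values["FEE", "TRA"], 0.05)
  expect_lt(cmp$p_values["FEE", "FEE"], 0.05)
})

test_that("DOT export enumerates exactly the positive cells", {
  ct <- suppressMessages(count_transitions(segment_events(
    blocks_at(c(0, 5, 10, 15), state = "TRA"))))
  tm <- transition_probabilities(ct$control)
  f <- withr::local_tempfile(fileext = ".dot")
  export_chain_diagram(tm, f)
  txt <- readLines(f)
  expect_equal(sum(grepl("->", txt)), 1)  # only TRA -> TRA
  expect_true(any(grepl("TRA -> TRA \\[label=\"1\\.00\"", txt)))
  expect_true(any(grepl("no data", txt)))  # unsupported rows annotated

  set.seed(19)
  a <- matrix(rpois(16, 2), 4, 4, dimnames = list(states4, states4))
  cts <- structure(list(scenario = "IMPACT", a = a, n_transitions = sum(a)),
                   class = "transition_counts")
  tm2 <- transition_probabilities(cts)
  f2 <- withr::local_tempfile(fileext = ".dot")
  export_chain_diagram(tm2, f2)
  n_edges <- sum(a[rowSums(a) > 0, ] > 0)
  expect_equal(sum(grepl("->", readLines(f2))), n_edges)

  # identity matrix: four self-loops
  idc <- structure(list(scenario = "CONTROL",
                        a = diag(4L) * 2L,
                        n_transitions = 8L), class = "transition_counts")
  dimnames(idc$a) <- list(states4, states4)
  f3 <- withr::local_tempfile(fileext = ".dot")
  export_chain_diagram(transition_probabilities(idc), f3)
  txt3 <- readLines(f3)
  expect_equal(sum(grepl("->", txt3)), 4)
  expect_true(all(grepl("label=\"1\\.00\"", txt3[grepl("->", txt3)])))
})
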