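#' Run the full vessel-disturbance analysis pipeline
#'
#' Orchestrates the complete analysis on a set of observation records:
#' block construction and event segmentation, scenario-split activity
#' budgets with time-in-area summaries and the Mann-Whitney comparison,
#' rare-state exclusion, the reaction-time GEE suite M1-M3 with nested
#' Wald comparisons, and control/impact Markov chains with optional
#' permutation comparison and DOT diagram export. Machine-readable results
#' (JSON/CSV/DOT) and a human-readable Markdown report are written to an
#' output directory; every stochastic step records its seed and row counts
#' are logged at every stage.
#'
#' @param config Either a named list or the path of a YAML file, with
#'   entries:
#'   \describe{
#'     \item{records}{path of a records CSV, or}
#'     \item{simulate}{list of [simulation_config()] arguments used to
#'       generate records instead;}
#'     \item{out_dir}{output directory (required);}
#'     \item{block_minutes, tick_minutes, independence_minutes}{segmentation
#'       settings (defaults 5, 1, 15);}
#'     \item{vessel_rule}{block vessel aggregation, `"any"` (default) or
#'       `"majority"`;}
#'     \item{min_samples}{rare-state threshold (default 12);}
#'     \item{link}{GEE link, `"inverse"` (default) or `"log"`;}
#'     \item{exposure_rule}{transition exposure rule (default
#'       `"preceding"`);}
#'     \item{n_permutations}{chain-comparison permutations (default 0);}
#'     \item{seed}{master seed (default 1).}
#'   }
#' @param quiet Suppress progress logging (default `FALSE`).
#' @return Invisibly, a list with every intermediate and final result
#'   (`records`, `events`, `budgets`, `time_in_area`, `budget_tests`,
#'   `exclusion`, `reactions`, `gee`, `markov`, `files`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  say <- function(...) if (!quiet) message("[vesselwatch] ", ...)
  getd <- function(key, default) if (is.null(config[[key]])) default
                                 else config[[key]]
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name an `out_dir`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(getd("seed", 1L))
  results <- list(seed = seed)
  files <- character(0)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- input ----
  records <- run_stage("input", {
    if (!is.null(config$records)) {
      say("reading records from ", config$records)
      read_records(config$records)
    } else if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- seed
      say("simulating survey (seed ", sim_args$seed, ")")
      generate_survey(do.call(simulation_config, sim_args))
    } else {
      stop("config must provide either `records` or `simulate`")
    }
  })
  say(nrow(records), " tick records in ",
      length(unique(records$session_id)), " session(s)")
  results$records <- records

  # ---- segmentation ----
  ev <- run_stage("segmentation", {
    blocks <- make_blocks(records,
                          block_minutes = getd("block_minutes", 5),
                          tick_minutes = getd("tick_minutes", 1),
                          vessel_rule = getd("vessel_rule", "any"))
    segment_events(blocks, getd("independence_minutes", 15))
  })
  say(nrow(ev$blocks), " blocks in ", nrow(ev$events), " events (",
      sum(ev$events$total_minutes), " observed minutes)")
  stopifnot(sum(ev$blocks$duration_min) == sum(ev$events$total_minutes))
  results$events <- ev
  utils::write.csv(ev$blocks, file.path(out_dir, "blocks.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ev$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c(files, "blocks.csv", "events.csv")

  # ---- budgets ----
  results <- run_stage("budgets", {
    budgets <- list(ALL = activity_budget(ev, "ALL"))
    has_absent <- any(!ev$blocks$vessel_present)
    has_present <- any(ev$blocks$vessel_present)
    if (has_absent) budgets$ABSENT <- activity_budget(ev, "ABSENT")
    if (has_present) budgets$PRESENT <- activity_budget(ev, "PRESENT")
    results$budgets <- budgets
    results$time_in_area <- list(
      ABSENT = if (has_absent) time_in_area_summary(ev, "ABSENT"),
      PRESENT = if (has_present) time_in_area_summary(ev, "PRESENT"))
    if (has_absent && has_present) {
      sa <- tapply(ev$blocks$duration_min[!ev$blocks$vessel_present],
                   ev$blocks$event_id[!ev$blocks$vessel_present], sum)
      sp <- tapply(ev$blocks$duration_min[ev$blocks$vessel_present],
                   ev$blocks$event_id[ev$blocks$vessel_present], sum)
      checks <- if (min(length(sa), length(sp)) >= 3L)
        normality_checks(c(sa, sp), rep(c("ABSENT", "PRESENT"),
                                        c(length(sa), length(sp))))
      results$budget_tests <- list(
        normality = checks,
        time_in_area = compare_budgets(as.numeric(sa), as.numeric(sp)))
      excl <- exclude_rare_states(ev, getd("min_samples", 12))
      results$exclusion <- excl$report
      per_state <- list()
      for (s in excl$report$state[!excl$report$excluded]) {
        bs <- excl$events$blocks[excl$events$blocks$state == s, , drop = FALSE]
        xa <- tapply(bs$duration_min[!bs$vessel_present],
                     bs$event_id[!bs$vessel_present], sum)
        xp <- tapply(bs$duration_min[bs$vessel_present],
                     bs$event_id[bs$vessel_present], sum)
        if (length(xa) > 0L && length(xp) > 0L) {
          per_state[[s]] <- compare_budgets(as.numeric(xa), as.numeric(xp))
        }
      }
      results$budget_tests$per_state <- per_state
    } else {
      say("single-scenario data: budget comparison skipped")
    }
    budget_rows <- do.call(rbind, lapply(budgets, function(b) {
      cbind(scenario = b$scenario, b$table)
    }))
    utils::write.csv(budget_rows, file.path(out_dir, "budgets.csv"),
                     row.names = FALSE, quote = FALSE)
    results
  })
  files <- c(files, "budgets.csv")

  # ---- reactions / GEE ----
  results <- run_stage("reactions_gee", {
    if (!any(ev$blocks$vessel_present)) {
      say("no exposure data: reaction and GEE analysis skipped")
      results["reactions"] <- list(NULL)
      results["gee"] <- list(NULL)
    } else {
    base_ev <- if (!is.null(results$exclusion)) {
      exclude_rare_states(ev, getd("min_samples", 12))$events
    } else ev
    rows <- reaction_time_table(base_ev)
    results$reactions <- list(rows = rows, budget = reaction_budget(rows))
    link <- getd("link", "inverse")
    fits <- list()
    for (mid in c("M1", "M2", "M3")) {
      fits[[mid]] <- tryCatch(fit_gee(rows, mid, link = link),
                              error = function(e) e)
    }
    ok <- vapply(fits, inherits, logical(1), what = "gee_fit")
    comparisons <- list()
    for (pair in list(c("M1", "M2"), c("M1", "M3"), c("M2", "M3"))) {
      if (all(ok[pair])) {
        key <- paste(pair, collapse = "_vs_")
        comparisons[[key]] <- tryCatch(
          compare_models(fits[[pair[1]]], fits[[pair[2]]]),
          error = function(e) e)
      }
    }
    results$gee <- list(fits = fits, comparisons = comparisons, link = link)
    gee_json <- list(link = link)
    for (mid in names(fits)) {
      f <- fits[[mid]]
      gee_json[[mid]] <- if (inherits(f, "gee_fit")) {
        list(coefficients = as.list(f$coefficients),
             robust_se = as.list(f$robust_se),
             alpha = f$alpha, dispersion = f$dispersion,
             n_clusters = f$n_clusters, wald = f$wald)
      } else list(error = conditionMessage(f))
    }
    gee_json$comparisons <- lapply(comparisons, function(cmp) {
      if (inherits(cmp, "model_comparison")) {
        list(pair = cmp$pair, df = cmp$df,
             wald_statistic = cmp$wald_statistic, p_value = cmp$p_value)
      } else list(error = conditionMessage(cmp))
    })
    jsonlite::write_json(gee_json, file.path(out_dir, "gee_results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    results
  })
  if (!is.null(results$gee)) files <- c(files, "gee_results.json")

  # ---- markov ----
  results <- run_stage("markov", {
    rule <- getd("exposure_rule", "preceding")
    counts <- count_transitions(ev, rule)
    tt <- transition_table(ev, rule)
    chains <- list(
      exposure_rule = rule,
      counts = counts,
      control = transition_probabilities(counts$control),
      impact = transition_probabilities(counts$impact))
    if (chains$impact$n_transitions == 0L) {
      say("no exposure data: impact chain has no transitions")
    }
    nperm <- getd("n_permutations", 0)
    chains$comparison <- compare_chains(chains$control, chains$impact,
                                        transitions = tt,
                                        n_permutations = nperm,
                                        seed = seed)
    results$markov <- chains
    export_chain_diagram(chains$control, file.path(out_dir, "control.dot"))
    export_chain_diagram(chains$impact, file.path(out_dir, "impact.dot"))
    mk_json <- list(
      exposure_rule = rule, seed = seed, n_permutations = nperm,
      control = list(counts = chains$counts$control$a,
                     p = chains$control$p,
                     n_transitions = chains$control$n_transitions),
      impact = list(counts = chains$counts$impact$a,
                    p = chains$impact$p,
                    n_transitions = chains$impact$n_transitions),
      difference = chains$comparison$diff)
    if (!is.null(chains$comparison$p_values)) {
      mk_json$permutation_p <- chains$comparison$p_values
    }
    jsonlite::write_json(mk_json, file.path(out_dir, "chains.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results
  })
  files <- c(files, "control.dot", "impact.dot", "chains.json")

  # ---- report ----
  run_stage("report", {
    writeLines(pipeline_report(results), file.path(out_dir, "report.md"))
  })
  files <- c(files, "report.md")
  results$files <- file.path(out_dir, files)
  say("report bundle written to ", out_dir)
  invisible(results)
}

fmt_pct <- function(x) sprintf("%.1f%%", x)

pipeline_report <- function(res) {
  ev <- res$events
  lines <- c("# Vessel-disturbance analysis report", "",
             sprintf("- Seed: %d", res$seed),
             sprintf("- Events: %d; blocks: %d; observed minutes: %s",
                     nrow(ev$events), nrow(ev$blocks),
                     format(sum(ev$events$total_minutes))), "")
  lines <- c(lines, "## Activity budgets", "")
  for (b in res$budgets) {
    lines <- c(lines, sprintf("### Scenario %s (%s min)", b$scenario,
                              format(round(b$total_minutes, 1))),
               "", "| state | minutes | percent | blocks |",
               "|---|---|---|---|",
               sprintf("| %s | %.1f | %s | %d |", b$table$state,
                       b$table$total_min, fmt_pct(b$table$percent),
                       b$table$n_blocks), "")
  }
  if (!is.null(res$budget_tests)) {
    tw <- res$budget_tests$time_in_area
    lines <- c(lines, "## Scenario comparison", "",
               sprintf("- Time in area, absent vs. present: U = %s, p = %.3g (n = %d, %d; %s)",
                       format(tw$statistic), tw$p_value, tw$n1, tw$n2,
                       tw$method))
    for (s in names(res$budget_tests$per_state)) {
      ts <- res$budget_tests$per_state[[s]]
      lines <- c(lines, sprintf("- %s minutes per event: U = %s, p = %.3g",
                                s, format(ts$statistic), ts$p_value))
    }
    if (!is.null(res$exclusion)) {
      excl <- res$exclusion[res$exclusion$excluded, , drop = FALSE]
      lines <- c(lines, "",
                 if (nrow(excl) > 0L)
                   sprintf("- Excluded from hypothesis tests (rare): %s",
                           paste(sprintf("%s (N = %d)", excl$state,
                                         excl$n_blocks), collapse = ", "))
                 else "- No states excluded as rare")
    }
    lines <- c(lines, "")
  }
  if (is.null(res$reactions)) {
    lines <- c(lines, "## Reactions to vessels", "",
               "No exposure data: no vessel-present blocks were observed.", "")
  } else {
    rb <- res$reactions$budget
    lines <- c(lines, "## Reactions to vessels", "",
               sprintf("- Share of vessel-present time: neutral %s, negative %s, positive %s",
                       fmt_pct(rb["NEU"]), fmt_pct(rb["NEG"]),
                       fmt_pct(rb["POS"])), "")
    ok <- vapply(res$gee$fits, inherits, logical(1), what = "gee_fit")
    if (any(ok)) {
      lines <- c(lines, sprintf("### GEE model suite (link = %s)", res$gee$link),
                 "")
      for (mid in names(res$gee$fits)[ok]) {
        f <- res$gee$fits[[mid]]
        lines <- c(lines,
                   sprintf("- %s: alpha = %.4f, dispersion = %.3f, %d clusters",
                           mid, f$alpha, f$dispersion, f$n_clusters))
      }
      lines <- c(lines, "", "| comparison | df | Wald chi-sq | p |",
                 "|---|---|---|---|")
      for (cmp in res$gee$comparisons) {
        if (inherits(cmp, "model_comparison")) {
          lines <- c(lines, sprintf("| %s vs. %s | %d | %.3f | %.3g |",
                                    cmp$pair[1], cmp$pair[2], cmp$df,
                                    cmp$wald_statistic, cmp$p_value))
        }
      }
      lines <- c(lines, "")
    }
  }
  mk <- res$markov
  lines <- c(lines, "## Behavioral transition chains",
             sprintf("(exposure rule: %s)", mk$exposure_rule), "")
  for (side in c("control", "impact")) {
    tm <- mk[[side]]
    lines <- c(lines, sprintf("### %s chain (%d transitions)",
                              toupper(side), tm$n_transitions), "")
    if (tm$n_transitions == 0L) {
      lines <- c(lines, "No exposure data for this scenario.", "")
      next
    }
    header <- paste0("| from \\ to | ", paste(colnames(tm$p), collapse = " | "),
                     " |")
    lines <- c(lines, header,
               paste0(paste(rep("|---", ncol(tm$p) + 1L), collapse = ""), "|"))
    for (i in rownames(tm$p)) {
      cells <- if (tm$row_support[i] == 0) rep("no data", 4)
               else sprintf("%.2f", tm$p[i, ])
      lines <- c(lines, paste0("| ", i, " | ",
                               paste(cells, collapse = " | "), " |"))
    }
    lines <- c(lines, "")
  }
  lines
}
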