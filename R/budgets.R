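#' Activity budget per vessel scenario
#'
#' Sums observed minutes per behavioral state over the blocks matching a
#' vessel scenario, per event and in total. "Time spent" in a block is the
#' block's true duration, so truncated blocks contribute their actual
#' minutes. Percentages are taken over the scenario's total observed time
#' and sum to 100 whenever any time was observed.
#'
#' @param ev An `event_set` from [segment_events()].
#' @param scenario `"ALL"`, `"ABSENT"` (vessel-absent blocks only) or
#'   `"PRESENT"` (vessel-present blocks only).
#' @return A `budget_table`: list with `scenario`, `table` (per state:
#'   `total_min`, `percent`, `n_blocks`), `event_sums` (minutes per
#'   event x state on the scenario's blocks) and `total_minutes`. An empty
#'   selection yields zero totals and is flagged via attribute `"empty"`
#'   and a warning.
#' @export
activity_budget <- function(ev, scenario = c("ALL", "ABSENT", "PRESENT")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(ev, "event_set"))
  blocks <- ev$blocks
  blocks <- switch(scenario,
                   ALL = blocks,
                   ABSENT = blocks[!blocks$vessel_present, , drop = FALSE],
                   PRESENT = blocks[blocks$vessel_present, , drop = FALSE])
  states <- behavior_states()
  empty <- nrow(blocks) == 0L
  if (empty) warning("no blocks match scenario ", scenario)

  total_min <- vapply(states, function(s)
    sum(blocks$duration_min[blocks$state == s]), numeric(1))
  n_blocks <- vapply(states, function(s)
    sum(blocks$state == s), integer(1))
  total <- sum(total_min)
  percent <- if (total > 0) 100 * total_min / total else rep(0, length(states))

  event_sums <- if (empty) {
    data.frame(event_id = character(0), state = character(0),
               minutes = numeric(0), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(duration_min ~ event_id + state, data = blocks,
                            FUN = sum)
    names(agg)[3L] <- "minutes"
    agg <- agg[order(agg$event_id, match(agg$state, states)), , drop = FALSE]
    rownames(agg) <- NULL
    agg
  }
  out <- list(scenario = scenario,
              table = data.frame(state = states, total_min = total_min,
                                 percent = percent, n_blocks = n_blocks,
                                 row.names = NULL, stringsAsFactors = FALSE),
              event_sums = event_sums,
              total_minutes = total)
  attr(out, "empty") <- empty
  class(out) <- "budget_table"
  out
}

#' @export
print.budget_table <- function(x, ...) {
  cat("Activity budget (scenario ", x$scenario, "): ",
      round(x$total_minutes, 1), " min observed\n", sep = "")
  tb <- x$table
  tb$percent <- round(tb$percent, 1)
  tb$total_min <- round(tb$total_min, 1)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Flag and exclude rarely observed states from hypothesis testing
#'
#' States observed in fewer than `min_samples` blocks overall are excluded
#' from the hypothesis-testing block subset (but never from descriptive
#' budgets). The default threshold of 12 blocks excludes a state seen in
#' 11 or fewer blocks.
#'
#' @param ev An `event_set`.
#' @param min_samples Minimum number of blocks for a state to enter
#'   hypothesis tests (default 12; 0 disables exclusion).
#' @return List with `events` (an `event_set` restricted to retained
#'   states) and `report` (per state: `n_blocks`, `excluded`).
#' @export
exclude_rare_states <- function(ev, min_samples = 12) {
  stopifnot(inherits(ev, "event_set"), min_samples >= 0)
  states <- behavior_states()
  n_blocks <- vapply(states, function(s)
    sum(ev$blocks$state == s), integer(1))
  excluded <- n_blocks < min_samples
  report <- data.frame(state = states, n_blocks = n_blocks,
                       excluded = excluded, row.names = NULL,
                       stringsAsFactors = FALSE)
  kept <- ev$blocks[!ev$blocks$state %in% states[excluded], , drop = FALSE]
  rownames(kept) <- NULL
  # event identity is preserved: exclusion filters blocks for testing only,
  # it never re-segments
  filtered <- structure(list(blocks = kept, events = events_summary(kept),
                             independence_minutes = ev$independence_minutes),
                        class = "event_set")
  list(events = filtered, report = report)
}

test_result <- function(statistic_name, statistic, p_value, n1, n2 = NA_integer_,
                        method = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(statistic_name = statistic_name, statistic = statistic,
                 p_value = p_value, n1 = n1, n2 = n2, method = method),
            class = "vw_test")
}

#' @export
print.vw_test <- function(x, ...) {
  cat(x$statistic_name, " = ", signif(x$statistic, 5),
      ", p = ", signif(x$p_value, 3),
      " (n1 = ", x$n1, if (!is.na(x$n2)) paste0(", n2 = ", x$n2), ")",
      if (!is.null(x$method)) paste0(" [", x$method, "]"), "\n", sep = "")
  invisible(x)
}

#' Normality and variance-homogeneity checks for per-event sums
#'
#' Runs a Shapiro-Wilk normality test within each scenario group and a
#' Levene test (Brown-Forsythe median centering, via
#' \code{car::leveneTest}) of variance homogeneity across groups. These
#' checks are diagnostic only: the pipeline proceeds with nonparametric
#' comparisons regardless of the outcome.
#'
#' @param values Numeric vector of per-event summed minutes.
#' @param group Factor/character vector of the same length assigning each
#'   value to a scenario group.
#' @return List with `shapiro` (data frame per group: `W`, `p_value`, `n`)
#'   and `levene` (a test result with the F statistic).
#' @export
normality_checks <- function(values, group) {
  stopifnot(length(values) == length(group))
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups for Levene's test")
  sizes <- table(group)
  if (any(sizes < 3L)) {
    stop("Shapiro-Wilk requires at least 3 observations per group; group '",
         names(sizes)[sizes < 3L][1L], "' has ", min(sizes))
  }
  shapiro <- do.call(rbind, lapply(levels(group), function(g) {
    v <- values[group == g]
    if (stats::sd(v) == 0) {
      # degenerate constant sample: normality test undefined
      return(data.frame(group = g, W = NA_real_, p_value = NA_real_,
                        n = length(v), stringsAsFactors = FALSE))
    }
    sw <- stats::shapiro.test(v)
    data.frame(group = g, W = unname(sw$statistic),
               p_value = sw$p.value, n = length(v),
               stringsAsFactors = FALSE)
  }))
  lv <- car::leveneTest(values ~ group)
  levene <- test_result("Levene F", unname(lv[1, "F value"]),
                        unname(lv[1, "Pr(>F)"]),
                        n1 = length(values), method = "Brown-Forsythe")
  if (is.na(levene$statistic)) levene$statistic <- 0
  list(shapiro = shapiro, levene = levene)
}

# Mann-Whitney U by pairwise counting, with 0.5 for ties
mw_u_statistic <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

#' Mann-Whitney U comparison of activity budgets
#'
#' Two-sided Mann-Whitney U test comparing per-event summed minutes
#' between the vessel-absent and vessel-present scenarios. For combined
#' sample sizes up to `exact_limit` the p-value is computed by exhaustive
#' enumeration of all group assignments (exact even under ties); larger
#' samples use the normal approximation with tie and continuity
#' corrections.
#'
#' @param sums_absent,sums_present Numeric vectors of per-event minutes.
#' @param exact_limit Largest `n1 + n2` for which the exact enumeration is
#'   used (default 12).
#' @return A test result with `statistic` = U for the first sample,
#'   `p_value`, group sizes and the method used.
#' @export
compare_budgets <- function(sums_absent, sums_present, exact_limit = 12) {
  x <- as.numeric(sums_absent); y <- as.numeric(sums_present)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u_obs <- mw_u_statistic(x, y)
  mu <- n1 * n2 / 2

  if (stats::sd(c(x, y)) == 0) {
    warning("all values tied across both groups; p set to 1")
    return(test_result("Mann-Whitney U", u_obs, 1, n1, n2, "degenerate"))
  }

  if (n <= exact_limit) {
    pooled <- c(x, y)
    combos <- utils::combn(n, n1)
    dev_obs <- abs(u_obs - mu)
    dev <- apply(combos, 2L, function(idx) {
      abs(mw_u_statistic(pooled[idx], pooled[-idx]) - mu)
    })
    p <- mean(dev >= dev_obs - 1e-9)
    return(test_result("Mann-Whitney U", u_obs, p, n1, n2,
                       "exact permutation"))
  }

  # normal approximation with tie-corrected variance and continuity correction
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result("Mann-Whitney U", u_obs, p, n1, n2, "normal approximation")
}

#' Time-in-area summary per scenario
#'
#' Mean, standard error, range and count of per-event observed minutes
#' under one vessel scenario. Events with no blocks in the scenario do not
#' contribute. With a single event the standard error is reported as 0 and
#' flagged.
#'
#' @param ev An `event_set`.
#' @param scenario `"ALL"`, `"ABSENT"` or `"PRESENT"`.
#' @return List: `mean`, `se`, `min`, `max`, `n`, `single_event` flag.
#' @export
time_in_area_summary <- function(ev, scenario = c("ALL", "ABSENT", "PRESENT")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(ev, "event_set"))
  blocks <- switch(scenario,
                   ALL = ev$blocks,
                   ABSENT = ev$blocks[!ev$blocks$vessel_present, , drop = FALSE],
                   PRESENT = ev$blocks[ev$blocks$vessel_present, , drop = FALSE])
  if (nrow(blocks) == 0L) {
    return(list(mean = NA_real_, se = NA_real_, min = NA_real_,
                max = NA_real_, n = 0L, single_event = FALSE))
  }
  per_event <- tapply(blocks$duration_min, blocks$event_id, sum)
  n <- length(per_event)
  list(mean = mean(per_event),
       se = if (n > 1L) stats::sd(per_event) / sqrt(n) else 0,
       min = min(per_event), max = max(per_event), n = n,
       single_event = n == 1L)
}
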