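# Independent brute-force oracles and small random-input generators.
# Every oracle recomputes its quantity by a different route than the
# package implementation (index arithmetic, linear scans, explicit
# enumeration) so agreement is evidence, not tautology.

states4 <- c("FEE", "TRA", "SOC", "RES")

# random tick-level record stream: arbitrary gaps, states, vessel flags
random_records <- function(n_groups = 3, max_minutes = 120) {
  out <- list()
  for (g in seq_len(n_groups)) {
    session <- sample(sprintf("D%02d", 1:2), 1)
    t <- sample(0:20, 1)
    n <- sample(3:40, 1)
    ts <- integer(n)
    for (i in seq_len(n)) {
      ts[i] <- t
      # mostly contiguous ticks, occasional gaps of varied length
      t <- t + if (runif(1) < 0.85) 1L else sample(c(2:8, 10, 14:17, 20, 30), 1L)
    }
    vessel <- runif(n) < 0.4
    out[[g]] <- data.frame(
      session_id = session,
      timestamp_min = ts,
      group_id = sprintf("g%02d", g),
      state = sample(states4[1:3], n, replace = TRUE,
                     prob = c(0.4, 0.5, 0.1)),
      vessel_present = vessel,
      reaction = ifelse(vessel, sample(c("POS", "NEU", "NEG"), n,
                                       replace = TRUE), "NONE"),
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  # drop accidental duplicate timestamps within a stream
  rec <- rec[!duplicated(rec[c("session_id", "group_id", "timestamp_min")]), ]
  validate_records(rec)
}

# mode with latest-tick tie-break, recomputed by reverse linear scan
oracle_dominant <- function(states) {
  counts <- vapply(unique(states), function(s) sum(states == s), integer(1))
  best <- max(counts)
  cand <- names(counts)[counts == best]
  for (s in rev(states)) if (s %in% cand) return(s)
}

# block tiling by pure index arithmetic over each continuous run
oracle_blocks <- function(records, block = 5, tick = 1) {
  out <- list()
  run <- 0L
  for (k in unique(paste(records$session_id, records$group_id))) {
    g <- records[paste(records$session_id, records$group_id) == k, ]
    g <- g[order(g$timestamp_min), ]
    run_brk <- c(0, cumsum(diff(g$timestamp_min) > tick))
    for (r in unique(run_brk)) {
      run <- run + 1L
      rg <- g[run_brk == r, ]
      n <- nrow(rg)
      n_blocks <- ceiling(n * tick / block)
      for (b in seq_len(n_blocks)) {
        lo <- (b - 1) * (block / tick) + 1
        hi <- min(n, b * (block / tick))
        ticks <- rg[lo:hi, ]
        vp <- any(ticks$vessel_present)
        reac <- if (!vp) "NONE" else {
          rr <- as.character(ticks$reaction[ticks$reaction != "NONE"])
          cnt <- vapply(c("NEG", "NEU", "POS"), function(x) sum(rr == x),
                        integer(1))
          names(cnt)[cnt == max(cnt)][1]  # NEG > NEU > POS on ties
        }
        out[[length(out) + 1L]] <- data.frame(
          session_id = rg$session_id[1], group_id = rg$group_id[1],
          run_id = run, block_index = b - 1L,
          start_min = rg$timestamp_min[1] + (b - 1L) * block,
          duration_min = (hi - lo + 1) * tick,
          state = oracle_dominant(as.character(ticks$state)),
          vessel_present = vp, reaction = reac, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# event count and totals by a forward linear scan over sorted blocks
oracle_events <- function(blocks, independence = 15) {
  blocks <- blocks[order(blocks$session_id, blocks$group_id,
                         blocks$start_min), ]
  n_events <- 0L
  totals <- numeric(0)
  prev_key <- ""
  prev_end <- -Inf
  for (i in seq_len(nrow(blocks))) {
    key <- paste(blocks$session_id[i], blocks$group_id[i])
    gap <- blocks$start_min[i] - prev_end
    if (key != prev_key || gap >= independence) {
      n_events <- n_events + 1L
      totals[n_events] <- 0
    }
    totals[n_events] <- totals[n_events] + blocks$duration_min[i]
    prev_key <- key
    prev_end <- blocks$start_min[i] + blocks$duration_min[i]
  }
  list(n_events = n_events, totals = totals)
}

# per-state minutes by explicit accumulation
oracle_budget <- function(blocks, scenario) {
  keep <- switch(scenario, ALL = rep(TRUE, nrow(blocks)),
                 ABSENT = !blocks$vessel_present,
                 PRESENT = blocks$vessel_present)
  tot <- setNames(numeric(4), states4)
  for (i in which(keep)) {
    tot[blocks$state[i]] <- tot[blocks$state[i]] + blocks$duration_min[i]
  }
  tot
}

# (event, behavior, reaction) sums by triple loop
oracle_reaction_sums <- function(blocks) {
  vp <- blocks[blocks$vessel_present, ]
  if (nrow(vp) == 0) return(NULL)
  key <- paste(vp$event_id, vp$state, vp$reaction, sep = "|")
  sums <- c(tapply(vp$duration_min, key, sum))
  sums[sums > 0]
}

# transition counts by a per-event pairwise scan
oracle_transitions <- function(ev_blocks, rule = "preceding") {
  a <- list(CONTROL = matrix(0L, 4, 4, dimnames = list(states4, states4)),
            IMPACT = matrix(0L, 4, 4, dimnames = list(states4, states4)))
  for (e in unique(ev_blocks$event_id)) {
    g <- ev_blocks[ev_blocks$event_id == e, ]
    g <- g[order(g$block_index), ]
    if (nrow(g) < 2) next
    for (i in seq_len(nrow(g) - 1)) {
      scen <- switch(rule,
        preceding = if (g$vessel_present[i]) "IMPACT" else "CONTROL",
        succeeding = if (g$vessel_present[i + 1]) "IMPACT" else "CONTROL",
        both = if (g$vessel_present[i] && g$vessel_present[i + 1]) "IMPACT"
               else if (!g$vessel_present[i] && !g$vessel_present[i + 1])
                 "CONTROL" else NA)
      if (is.na(scen)) next
      a[[scen]][g$state[i], g$state[i + 1]] <-
        a[[scen]][g$state[i], g$state[i + 1]] + 1L
    }
  }
  a
}

# exact two-sided Mann-Whitney p by enumerating group assignments,
# computing U from midrank sums (the implementation counts pairs instead)
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  mu <- n1 * n2 / 2
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  devs <- apply(combos, 2, function(idx) abs(u_of(idx) - mu))
  mean(devs >= abs(u_obs - mu) - 1e-9)
}

# tiny deterministic block table builder for hand-written cases
block_row <- function(session = "S1", group = "G1", start = 0, dur = 5,
                      state = "TRA", vessel = FALSE,
                      reaction = if (vessel) "NEU" else "NONE") {
  data.frame(session_id = session, group_id = group, run_id = 1L,
             block_index = 0L, start_min = start, duration_min = dur,
             state = state, vessel_present = vessel, reaction = reaction,
             stringsAsFactors = FALSE)
}

blocks_at <- function(starts, ..., session = "S1", group = "G1") {
  do.call(rbind, lapply(starts, function(s)
    block_row(session = session, group = group, start = s, ...)))
}
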