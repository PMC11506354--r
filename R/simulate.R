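#' Configuration for the synthetic survey generator
#'
#' Bundles and validates all parameters of the scan-sampling survey
#' simulator. Defaults describe a year-round shore-based survey of a small
#' estuarine dolphin population under mixed vessel traffic: 8-hour daily
#' sessions sampled in 5-minute blocks, sighting events lasting roughly 2
#' to 135 minutes, first-order Markov behavioral dynamics that differ
#' between vessel-absent (control) and vessel-present (impact) blocks, and
#' reaction categories drawn conditionally on the behavioral state while a
#' vessel is within the proximity radius.
#'
#' @param P_control,P_impact 4x4 row-stochastic transition matrices over
#'   `behavior_states()` governing block-to-block behavioral transitions
#'   when the earlier block is vessel-absent (`P_control`) or
#'   vessel-present (`P_impact`). Rows must sum to 1 within 1e-12.
#' @param initial_distribution Probability vector over the four states for
#'   the first block of each event.
#' @param vessel_process Either a single per-block Bernoulli probability of
#'   vessel presence, or a length-2 vector `c(p_gain, p_keep)` of a 2-state
#'   persistence chain: `p_gain` = P(present | previously absent),
#'   `p_keep` = P(present | previously present).
#' @param reaction_probs 4x3 matrix (rows = states, columns POS/NEU/NEG) of
#'   reaction probabilities for vessel-present blocks, rows summing to 1.
#' @param session_length Session length in minutes (default 480: a
#'   08:00-16:00 shift).
#' @param n_sessions Number of observation sessions (days).
#' @param sighting_hazard Per-scan (5-min) probability that a new group is
#'   sighted while none is in view.
#' @param duration_blocks Function `n -> integer vector` drawing event
#'   lengths in 5-min blocks; the default negative-binomial draw (mean
#'   about 8.5 blocks, truncated at 27) admits the full 2-135 min range.
#' @param block_minutes Sampling block length in minutes (default 5).
#' @param tick_minutes Within-block record resolution in minutes (default 1).
#' @param p_interrupt Probability, at each within-event block boundary,
#'   that the group is momentarily lost, leaving a 5-14 min gap in the
#'   record stream (shorter than the independence interval, so
#'   segmentation must re-merge the runs into one event).
#' @param tick_noise Probability that an individual tick's recorded state
#'   deviates from the block's latent state, to exercise the
#'   dominant-state rule (default 0: blocks are behaviorally pure).
#' @param seed Integer seed for the generator's private random stream.
#' @return A validated `simulation_config` list.
#' @seealso [generate_survey()]
#' @export
simulation_config <- function(P_control = default_control_matrix(),
                              P_impact = default_impact_matrix(),
                              initial_distribution =
                                c(FEE = 0.36, TRA = 0.62, SOC = 0.02, RES = 0),
                              vessel_process = c(p_gain = 0.16, p_keep = 0.80),
                              reaction_probs = default_reaction_probs(),
                              session_length = 480,
                              n_sessions = 38,
                              sighting_hazard = 0.025,
                              duration_blocks = default_duration_blocks,
                              block_minutes = 5,
                              tick_minutes = 1,
                              p_interrupt = 0.15,
                              tick_noise = 0,
                              seed = 1L) {
  states <- behavior_states()
  check_stochastic <- function(P, what) {
    P <- as.matrix(P)
    if (!all(dim(P) == c(4L, 4L))) stop(what, " must be a 4x4 matrix")
    if (any(P < 0) || any(P > 1)) stop(what, " entries must lie in [0, 1]")
    if (any(abs(rowSums(P) - 1) > 1e-12)) {
      stop(what, " rows must sum to 1 (within 1e-12)")
    }
    dimnames(P) <- list(states, states)
    P
  }
  P_control <- check_stochastic(P_control, "P_control")
  P_impact <- check_stochastic(P_impact, "P_impact")

  if (length(initial_distribution) != 4L || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-12) {
    stop("initial_distribution must be a length-4 probability vector")
  }
  initial_distribution <- stats::setNames(as.numeric(initial_distribution),
                                          states)
  if (!length(vessel_process) %in% c(1L, 2L) ||
      any(vessel_process < 0) || any(vessel_process > 1)) {
    stop("vessel_process must be one Bernoulli probability or c(p_gain, p_keep), all in [0, 1]")
  }
  reaction_probs <- as.matrix(reaction_probs)
  if (!all(dim(reaction_probs) == c(4L, 3L)) || any(reaction_probs < 0) ||
      any(abs(rowSums(reaction_probs) - 1) > 1e-12)) {
    stop("reaction_probs must be a 4x3 matrix with rows summing to 1")
  }
  dimnames(reaction_probs) <- list(states, c("POS", "NEU", "NEG"))
  stopifnot(session_length > 0, n_sessions >= 1,
            sighting_hazard > 0, sighting_hazard <= 1,
            block_minutes > 0, tick_minutes > 0,
            block_minutes %% tick_minutes == 0,
            p_interrupt >= 0, p_interrupt < 1,
            tick_noise >= 0, tick_noise < 1)
  if (!is.function(duration_blocks)) {
    stop("duration_blocks must be a function(n) returning block counts")
  }
  cfg <- list(P_control = P_control, P_impact = P_impact,
              initial_distribution = initial_distribution,
              vessel_process = as.numeric(vessel_process),
              reaction_probs = reaction_probs,
              session_length = as.integer(session_length),
              n_sessions = as.integer(n_sessions),
              sighting_hazard = sighting_hazard,
              duration_blocks = duration_blocks,
              block_minutes = as.integer(block_minutes),
              tick_minutes = as.integer(tick_minutes),
              p_interrupt = p_interrupt,
              tick_noise = tick_noise,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Default control-scenario transition matrix
#'
#' Illustrative vessel-absent behavioral transition matrix. Diagonal
#' persistence is strong for traveling (0.73) and feeding (0.60);
#' socializing most often resolves into traveling (0.60); resting is
#' unreachable from the other states.
#'
#' @return 4x4 row-stochastic matrix over `behavior_states()`.
#' @export
default_control_matrix <- function() {
  matrix(c(
    # FEE   TRA   SOC   RES
    0.60, 0.38, 0.02, 0,   # from FEE
    0.26, 0.73, 0.01, 0,   # from TRA
    0.20, 0.60, 0.20, 0,   # from SOC
    0.00, 0.00, 0.00, 1    # from RES (unreachable)
  ), nrow = 4, byrow = TRUE,
  dimnames = list(behavior_states(), behavior_states()))
}

#' Default impact-scenario transition matrix
#'
#' Illustrative vessel-present counterpart of [default_control_matrix()]:
#' traveling becomes stickier (0.79), feeding groups switch to traveling
#' more often (0.41) and transition to socializing not at all, and
#' traveling groups return to feeding less often (0.18).
#'
#' @return 4x4 row-stochastic matrix over `behavior_states()`.
#' @export
default_impact_matrix <- function() {
  matrix(c(
    # FEE   TRA   SOC   RES
    0.59, 0.41, 0.00, 0,   # from FEE
    0.18, 0.79, 0.03, 0,   # from TRA
    0.20, 0.60, 0.20, 0,   # from SOC
    0.00, 0.00, 0.00, 1    # from RES (unreachable)
  ), nrow = 4, byrow = TRUE,
  dimnames = list(behavior_states(), behavior_states()))
}

#' Default reaction probabilities given behavioral state
#'
#' Per-state probabilities of positive, neutral and negative reactions for
#' vessel-present blocks. Neutral dominates in every state; socializing
#' groups never react positively. Under the default impact chain's
#' occupancy these mix to roughly 4% positive, 80% neutral, 16% negative
#' of vessel-present time.
#'
#' @return 4x3 matrix (states x POS/NEU/NEG), rows summing to 1.
#' @export
default_reaction_probs <- function() {
  matrix(c(
    # POS    NEU    NEG
    0.045, 0.780, 0.175,  # FEE
    0.035, 0.820, 0.145,  # TRA
    0.000, 0.600, 0.400,  # SOC
    0.000, 1.000, 0.000   # RES (unreachable)
  ), nrow = 4, byrow = TRUE,
  dimnames = list(behavior_states(), c("POS", "NEU", "NEG")))
}

# Event length in 5-min blocks: 1 + NB, truncated so events stay <= 135 min.
default_duration_blocks <- function(n) {
  pmin(1L + stats::rnbinom(n, size = 1.2, mu = 7.5), 27L)
}

sample_state <- function(prob) {
  sample(behavior_states(), 1L, prob = prob)
}

#' Generate a synthetic scan-sampling survey
#'
#' Simulates shore-based observation sessions and returns per-tick
#' observation records with the statistical structure the downstream
#' analysis assumes: within each sighting event the block-level state
#' sequence is a first-order Markov chain whose transition matrix is
#' `P_impact` when the earlier block is vessel-present and `P_control`
#' otherwise; vessel presence follows the configured per-block process;
#' reactions are drawn from `reaction_probs` conditionally on the block
#' state whenever a vessel is present and are `NONE` otherwise. Events are
#' separated by at least the 15-minute independence interval by
#' construction, while optional within-event interruptions (< 15 min)
#' exercise the event-merging rule. The true block-level labels are
#' attached as `attr(, "truth")` so tests can score recovery exactly.
#'
#' @param config A [simulation_config()].
#' @return A validated `obs_records` data frame (one row per tick) with a
#'   `"truth"` attribute: a data frame of the generator's blocks
#'   (`session_id`, `group_id`, `event_id`, `block_index`, `start_min`,
#'   `duration_min`, `state`, `vessel_present`, `reaction`).
#' @export
#' @examples
#' cfg <- simulation_config(n_sessions = 2, seed = 42)
#' rec <- generate_survey(cfg)
#' head(rec)
generate_survey <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, as.list(config))
  }
  cf <- config
  states <- behavior_states()
  bl <- cf$block_minutes
  tick <- cf$tick_minutes
  ticks_per_block <- bl %/% tick
  gap_min <- 15L  # independence interval between events

  # private stream: no effect on the caller's RNG state
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cf$seed)

  rec_list <- list()
  truth_list <- list()
  ri <- 0L

  for (s in seq_len(cf$n_sessions)) {
    session_id <- sprintf("S%03d", s)
    cursor <- 0L
    group_n <- 0L
    # wait (in whole scans) for the first sighting of the session
    cursor <- cursor + bl * stats::rgeom(1L, cf$sighting_hazard)
    while (cursor < cf$session_length - 1L) {
      n_blocks <- as.integer(cf$duration_blocks(1L))
      if (n_blocks < 1L) n_blocks <- 1L
      # clip the event at session end
      max_blocks <- max(1L, (cf$session_length - cursor) %/% bl)
      n_blocks <- min(n_blocks, max_blocks)
      group_n <- group_n + 1L
      group_id <- sprintf("G%02d", group_n)
      event_id <- paste(session_id, group_id, sep = "_")

      # vessel flags: Bernoulli or persistent 2-state chain, per block
      vp <- logical(n_blocks)
      if (length(cf$vessel_process) == 1L) {
        vp <- stats::runif(n_blocks) < cf$vessel_process
      } else {
        p_gain <- cf$vessel_process[1L]; p_keep <- cf$vessel_process[2L]
        marg <- if (p_gain + (1 - p_keep) > 0)
          p_gain / (p_gain + (1 - p_keep)) else 0
        vp[1L] <- stats::runif(1L) < marg
        if (n_blocks > 1L) for (b in 2L:n_blocks) {
          p <- if (vp[b - 1L]) p_keep else p_gain
          vp[b] <- stats::runif(1L) < p
        }
      }

      # block states: chain driven by the earlier block's exposure
      st <- character(n_blocks)
      st[1L] <- sample_state(cf$initial_distribution)
      if (n_blocks > 1L) for (b in 2L:n_blocks) {
        P <- if (vp[b - 1L]) cf$P_impact else cf$P_control
        st[b] <- sample_state(P[st[b - 1L], ])
      }

      reac <- rep("NONE", n_blocks)
      for (b in which(vp)) {
        reac[b] <- sample(c("POS", "NEU", "NEG"), 1L,
                          prob = cf$reaction_probs[st[b], ])
      }

      # block start times: contiguous except at interruptions (< 15 min)
      starts <- integer(n_blocks)
      starts[1L] <- cursor
      if (n_blocks > 1L) for (b in 2L:n_blocks) {
        pause <- if (stats::runif(1L) < cf$p_interrupt)
          sample(5:14, 1L) else 0L
        starts[b] <- starts[b - 1L] + bl + pause
      }
      durations <- rep(bl, n_blocks)
      durations[n_blocks] <- sample(2:bl, 1L)  # truncated final block
      # drop blocks pushed past the session end by interruptions
      keep <- starts + durations <= cf$session_length
      if (!all(keep)) {
        n_blocks <- sum(keep)
        if (n_blocks == 0L) break
        starts <- starts[keep]; durations <- durations[keep]
        st <- st[keep]; vp <- vp[keep]; reac <- reac[keep]
        durations[n_blocks] <- min(durations[n_blocks], bl)
      }

      # emit per-tick rows for the whole event at once
      n_ticks <- pmax(1L, durations %/% tick)
      t_times <- unlist(lapply(seq_len(n_blocks), function(b)
        starts[b] + tick * (seq_len(n_ticks[b]) - 1L)), use.names = FALSE)
      t_state <- rep(st, n_ticks)
      if (cf$tick_noise > 0) {
        block_of <- rep(seq_len(n_blocks), n_ticks)
        flip <- stats::runif(length(t_state)) < cf$tick_noise
        for (b in seq_len(n_blocks)) {
          fb <- which(flip & block_of == b)
          # never flip a majority, so the latent state stays modal
          cap <- (n_ticks[b] - 1L) %/% 2L
          if (length(fb) > cap) fb <- fb[seq_len(cap)]
          for (k in fb) t_state[k] <- sample(setdiff(states, st[b]), 1L)
        }
      }
      ri <- ri + 1L
      rec_list[[ri]] <- data.frame(
        session_id = session_id, timestamp_min = t_times,
        group_id = group_id, state = t_state,
        vessel_present = rep(vp, n_ticks),
        reaction = rep(reac, n_ticks), stringsAsFactors = FALSE)
      truth_list[[length(truth_list) + 1L]] <- data.frame(
        session_id = session_id, group_id = group_id, event_id = event_id,
        block_index = seq_len(n_blocks) - 1L, start_min = starts,
        duration_min = durations, state = st, vessel_present = vp,
        reaction = reac, stringsAsFactors = FALSE)

      # schedule the next sighting: >= independence interval, then scan wait
      cursor <- starts[n_blocks] + durations[n_blocks] + gap_min +
        bl * (1L + stats::rgeom(1L, cf$sighting_hazard))
    }
  }

  records <- if (ri > 0L) do.call(rbind, rec_list) else
    data.frame(session_id = character(0), timestamp_min = integer(0),
               group_id = character(0), state = character(0),
               vessel_present = logical(0), reaction = character(0),
               stringsAsFactors = FALSE)
  records <- validate_records(records)
  truth <- if (length(truth_list) > 0L) do.call(rbind, truth_list) else NULL
  attr(records, "truth") <- truth
  records
}

#' Generate clustered gamma reaction-time data with known parameters
#'
#' Simulates per-event reaction-time tables from a marginal gamma model
#' with exchangeable within-event correlation, for exercising the GEE
#' fitting machinery by parameter recovery. Rows are (event, behavior,
#' reaction, time) with behavior in FEE/TRA/SOC (reference TRA) and
#' reaction in POS/NEU/NEG (reference NEU). Correlation is induced by a
#' shared event-level gamma multiplier: writing the target squared
#' coefficient of variation as `dispersion` and the target within-event
#' correlation as `alpha`, times are `mu * G_event * E_row` with
#' independent mean-1 gamma factors whose variances solve
#' `var(G) = alpha * dispersion` and
#' `(1 + var(G)) * (1 + var(E)) = 1 + dispersion`, so the marginal mean
#' follows the linear predictor exactly and `cor(Y_ij, Y_ik) = alpha`.
#'
#' @param n_events Number of clusters (>= 2).
#' @param coefficients Named numeric vector on the link scale; names must
#'   be columns of `model.matrix(~ reaction * behavior)` under the
#'   reference coding above (e.g. `"(Intercept)"`, `"reactionNEG"`,
#'   `"behaviorFEE"`, `"reactionPOS:behaviorFEE"`). Unnamed length-1 input
#'   is taken as the intercept.
#' @param alpha Target exchangeable correlation in `[0, 1)`.
#' @param dispersion Target squared coefficient of variation (> 0).
#' @param link `"log"` (default) or `"inverse"`: scale of `coefficients`.
#' @param cluster_sizes Function `n -> integer vector` of rows per event
#'   (default: uniform on 3..6 distinct behavior/reaction combinations).
#' @param seed Integer seed (private stream).
#' @return Data frame `event_id`, `behavior`, `reaction`, `time_min`, with
#'   the true marginal means in column `mu` stripped into
#'   `attr(, "truth")`.
#' @export
generate_gee_dataset <- function(n_events, coefficients, alpha = 0,
                                 dispersion = 0.5, link = c("log", "inverse"),
                                 cluster_sizes = function(n)
                                   sample(3:6, n, replace = TRUE),
                                 seed = 1L) {
  link <- match.arg(link)
  if (n_events < 2L) stop("n_events must be at least 2")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (is.null(names(coefficients))) {
    if (length(coefficients) != 1L) {
      stop("`coefficients` must be named (or a single intercept)")
    }
    names(coefficients) <- "(Intercept)"
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  combos <- expand.grid(
    reaction = factor(c("NEU", "POS", "NEG"), levels = c("NEU", "POS", "NEG")),
    behavior = factor(c("TRA", "FEE", "SOC"), levels = c("TRA", "FEE", "SOC")),
    stringsAsFactors = FALSE)
  sizes <- pmin(pmax(as.integer(cluster_sizes(n_events)), 1L), nrow(combos))

  rows <- do.call(rbind, lapply(seq_len(n_events), function(i) {
    idx <- sample.int(nrow(combos), sizes[i])
    data.frame(event_id = sprintf("E%04d", i), combos[idx, , drop = FALSE],
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL

  X <- stats::model.matrix(~ reaction * behavior, data = rows)
  unknown <- setdiff(names(coefficients), colnames(X))
  if (length(unknown) > 0L) {
    stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "))
  }
  eta <- as.numeric(X[, names(coefficients), drop = FALSE] %*% coefficients)
  mu <- switch(link, log = exp(eta), inverse = 1 / eta)
  if (any(mu <= 0)) stop("coefficients imply non-positive means on the inverse link")

  v_g <- alpha * dispersion
  v_e <- (1 + dispersion) / (1 + v_g) - 1
  g <- if (v_g > 0) stats::rgamma(n_events, shape = 1 / v_g, scale = v_g)
       else rep(1, n_events)
  e <- if (v_e > 0) stats::rgamma(nrow(rows), shape = 1 / v_e, scale = v_e)
       else rep(1, nrow(rows))
  g_row <- g[match(rows$event_id, sprintf("E%04d", seq_len(n_events)))]
  rows$time_min <- mu * g_row * e

  truth <- list(coefficients = coefficients, alpha = alpha,
                dispersion = dispersion, link = link, mu = mu)
  out <- rows[c("event_id", "behavior", "reaction", "time_min")]
  attr(out, "truth") <- truth
  out
}

#' Read a simulation configuration from a YAML file
#'
#' Reads a key-value file whose entries mirror the arguments of
#' [simulation_config()]; matrices are given row-wise as nested lists.
#' Missing keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (m in c("P_control", "P_impact", "reaction_probs")) {
    if (!is.null(raw[[m]])) {
      raw[[m]] <- do.call(rbind, lapply(raw[[m]], as.numeric))
    }
  }
  for (v in c("initial_distribution", "vessel_process")) {
    if (!is.null(raw[[v]])) raw[[v]] <- as.numeric(unlist(raw[[v]]))
  }
  do.call(simulation_config, raw)
}
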