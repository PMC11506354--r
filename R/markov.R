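#' Per-transition table of consecutive block pairs
#'
#' Enumerates every ordered pair of consecutive sampling blocks within an
#' event (transitions never cross event boundaries) together with its
#' scenario label under a chosen exposure rule. Events with fewer than two
#' blocks contribute nothing.
#'
#' @param ev An `event_set`.
#' @param exposure_rule How a transition spanning a vessel arrival or
#'   departure is assigned: `"preceding"` (default; the transition is
#'   IMPACT iff the earlier block is vessel-present - the behavioral
#'   response follows the stimulus), `"succeeding"` (the later block
#'   decides), or `"both"` (IMPACT iff both blocks are vessel-present,
#'   CONTROL iff both are vessel-absent, mixed pairs dropped).
#' @return Data frame `event_id`, `from`, `to`, `scenario`
#'   (CONTROL/IMPACT), with attribute `"n_dropped"` (mixed pairs removed
#'   under `"both"`) and `"exposure_rule"`.
#' @export
transition_table <- function(ev, exposure_rule = c("preceding", "succeeding",
                                                   "both")) {
  exposure_rule <- match.arg(exposure_rule)
  stopifnot(inherits(ev, "event_set"))
  blocks <- ev$blocks[order(ev$blocks$event_id, ev$blocks$block_index), ,
                      drop = FALSE]
  n <- nrow(blocks)
  tt <- if (n >= 2L) {
    i1 <- which(blocks$event_id[-n] == blocks$event_id[-1L])
    i2 <- i1 + 1L
    vp_from <- blocks$vessel_present[i1]
    vp_to <- blocks$vessel_present[i2]
    scen <- switch(exposure_rule,
                   preceding = ifelse(vp_from, "IMPACT", "CONTROL"),
                   succeeding = ifelse(vp_to, "IMPACT", "CONTROL"),
                   both = ifelse(vp_from & vp_to, "IMPACT",
                                 ifelse(!vp_from & !vp_to, "CONTROL", NA)))
    data.frame(event_id = blocks$event_id[i1], from = blocks$state[i1],
               to = blocks$state[i2], scenario = scen,
               stringsAsFactors = FALSE)
  } else {
    data.frame(event_id = character(0), from = character(0),
               to = character(0), scenario = character(0),
               stringsAsFactors = FALSE)
  }
  n_dropped <- sum(is.na(tt$scenario))
  tt <- tt[!is.na(tt$scenario), , drop = FALSE]
  rownames(tt) <- NULL
  attr(tt, "n_dropped") <- n_dropped
  attr(tt, "exposure_rule") <- exposure_rule
  tt
}

counts_from_table <- function(tt, scenario) {
  states <- behavior_states()
  sub <- tt[tt$scenario == scenario, , drop = FALSE]
  a <- table(factor(sub$from, levels = states),
             factor(sub$to, levels = states))
  a <- matrix(as.integer(a), 4, 4, dimnames = list(states, states))
  structure(list(scenario = scenario, a = a, n_transitions = sum(a)),
            class = "transition_counts")
}

#' Count behavioral transitions per vessel scenario
#'
#' Tallies the transition counts \eqn{a_{ij}} between consecutive
#' dominant-state blocks within events, split into the vessel-absent
#' (CONTROL) and vessel-present (IMPACT) scenarios under the chosen
#' exposure rule. Self-transitions are counted.
#'
#' @inheritParams transition_table
#' @return List with `control` and `impact` (each a `transition_counts`:
#'   4x4 integer matrix `a` and `n_transitions`), plus `exposure_rule` and
#'   `n_dropped`.
#' @export
count_transitions <- function(ev, exposure_rule = c("preceding", "succeeding",
                                                    "both")) {
  tt <- transition_table(ev, exposure_rule)
  single <- sum(ev$events$n_blocks < 2L)
  if (single > 0L) {
    message(single, " event(s) with a single block contribute no transitions")
  }
  list(control = counts_from_table(tt, "CONTROL"),
       impact = counts_from_table(tt, "IMPACT"),
       exposure_rule = attr(tt, "exposure_rule"),
       n_dropped = attr(tt, "n_dropped"))
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("Transition counts (", x$scenario, "), n = ", x$n_transitions,
      "\n", sep = "")
  print(x$a)
  invisible(x)
}

#' Row-normalize transition counts into probabilities
#'
#' Converts counts \eqn{a_{ij}} into maximum-likelihood transition
#' probabilities \eqn{p_{ij} = a_{ij} / \sum_j a_{ij}}, row by row over
#' the four-state space. Rows with no observed transitions (zero support)
#' are reported as `NA` - "no data" - rather than fabricated zeros or
#' absorbing states.
#'
#' @param counts A `transition_counts` object.
#' @return A `transition_matrix`: `scenario`, matrix `p` (rows summing to
#'   1 where supported, `NA` rows otherwise), `row_support` (outgoing
#'   transitions per state) and `n_transitions`.
#' @export
transition_probabilities <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  a <- counts$a
  support <- rowSums(a)
  p <- a / ifelse(support > 0, support, NA_real_)
  p[support == 0, ] <- NA_real_
  structure(list(scenario = counts$scenario, p = p, row_support = support,
                 n_transitions = counts$n_transitions),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Transition probabilities (", x$scenario, "), ",
      x$n_transitions, " transitions\n", sep = "")
  print(round(x$p, 2))
  nosup <- names(x$row_support)[x$row_support == 0]
  if (length(nosup) > 0L) {
    cat("  no data for row(s): ", paste(nosup, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Compare control and impact transition chains
#'
#' Per-cell differences between the impact and control transition
#' matrices, optionally with two-sided permutation p-values obtained by
#' shuffling the scenario labels of transitions within each event (the
#' exchangeable null of no vessel effect on transition structure).
#'
#' @param control,impact `transition_matrix` objects for the two scenarios.
#' @param transitions Per-transition table from [transition_table()];
#'   required when `n_permutations > 0`.
#' @param n_permutations Number of label permutations (0 = differences
#'   only).
#' @param seed Integer seed for the permutation stream.
#' @return A `chain_comparison`: `diff` (p_impact - p_control; `NA` where
#'   either row is unsupported), and when permutations were run `p_values`
#'   (per cell, `(1 + #{|d*| >= |d|}) / (B + 1)`), `n_permutations`,
#'   `seed`.
#' @export
compare_chains <- function(control, impact, transitions = NULL,
                           n_permutations = 0, seed = NULL) {
  stopifnot(inherits(control, "transition_matrix"),
            inherits(impact, "transition_matrix"))
  if (!identical(dimnames(control$p), dimnames(impact$p))) {
    stop("chains are defined over different state spaces")
  }
  d_obs <- impact$p - control$p
  out <- list(diff = d_obs, n_permutations = as.integer(n_permutations),
              seed = seed)
  if (n_permutations > 0) {
    if (is.null(transitions)) {
      stop("`transitions` (from transition_table) is required for permutation")
    }
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (is.null(old_seed)) {
          if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old_seed, envir = globalenv())
      })
      set.seed(seed)
    }
    states <- rownames(d_obs)
    cell <- match(transitions$from, states) +
      4L * (match(transitions$to, states) - 1L)
    is_imp <- transitions$scenario == "IMPACT"
    exceed <- matrix(0L, 4, 4, dimnames = dimnames(d_obs))
    defined <- is.finite(d_obs)
    ev_groups <- split(seq_along(is_imp), transitions$event_id)
    ev_groups <- ev_groups[lengths(ev_groups) > 1L]
    for (b in seq_len(n_permutations)) {
      perm <- is_imp
      for (idx in ev_groups) {
        perm[idx] <- perm[idx][sample.int(length(idx))]
      }
      mi <- matrix(tabulate(cell[perm], 16L), 4, 4)
      mc <- matrix(tabulate(cell[!perm], 16L), 4, 4)
      d_perm <- mi / rowSums(mi) - mc / rowSums(mc)
      hit <- is.finite(d_perm) & defined & (abs(d_perm) >= abs(d_obs) - 1e-12)
      exceed <- exceed + hit
    }
    p_values <- (1 + exceed) / (n_permutations + 1)
    p_values[!defined] <- NA_real_
    out$p_values <- p_values
  }
  class(out) <- "chain_comparison"
  out
}

#' @export
print.chain_comparison <- function(x, ...) {
  cat("Impact - control transition differences\n")
  print(round(x$diff, 3))
  if (!is.null(x$p_values)) {
    cat("Two-sided permutation p-values (", x$n_permutations,
        " permutations)\n", sep = "")
    print(round(x$p_values, 3))
  }
  invisible(x)
}

#' Export a transition chain as a DOT graph
#'
#' Writes a Graphviz DOT description of a behavioral transition chain:
#' nodes are the behavioral states, weighted directed edges are the
#' strictly positive transition probabilities, labeled to two decimals.
#' States whose row has no observed transitions are annotated "no data"
#' and carry no out-edges.
#'
#' @param matrix A `transition_matrix`.
#' @param path Output file path (conventionally `.dot`).
#' @return `path`, invisibly.
#' @export
export_chain_diagram <- function(matrix, path) {
  stopifnot(inherits(matrix, "transition_matrix"))
  states <- rownames(matrix$p)
  lines <- c(sprintf("digraph %s {", tolower(matrix$scenario)),
             "  rankdir=LR;",
             "  node [shape=circle, fontsize=12];")
  for (s in states) {
    label <- if (matrix$row_support[s] == 0)
      sprintf("  %s [label=\"%s\\n(no data)\", style=dashed];", s, s)
    else sprintf("  %s;", s)
    lines <- c(lines, label)
  }
  for (i in states) {
    if (matrix$row_support[i] == 0) next
    for (j in states) {
      pij <- matrix$p[i, j]
      if (is.finite(pij) && pij > 0) {
        lines <- c(lines, sprintf(
          "  %s -> %s [label=\"%.2f\", penwidth=%.2f];", i, j, pij,
          0.5 + 3 * pij))
      }
    }
  }
  lines <- c(lines, "}")
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write DOT file '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
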