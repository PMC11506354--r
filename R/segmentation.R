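#' Dominant behavioral state of a sampling block
#'
#' The modal behavioral pattern among the ticks of one sampling block. A
#' tie between states is broken in favor of the tied state that occupies
#' the latest tick in the block, which is deterministic and independent of
#' the label alphabet.
#'
#' @param states Ordered character/factor vector of tick states within one
#'   block (earliest first).
#' @return Single state code.
#' @export
#' @examples
#' dominant_state(c("TRA", "TRA", "TRA", "FEE", "FEE"))
dominant_state <- function(states) {
  states <- as.character(states)
  if (length(states) == 0L) stop("cannot take the dominant state of an empty block")
  bad <- setdiff(unique(states), behavior_states())
  if (length(bad) > 0L) stop("unknown state code: ", bad[1L])
  counts <- table(states)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  # tie: the tied state seen latest in the block wins
  states[max(which(states %in% top))]
}

# modal non-NONE reaction; ties resolved toward the more negative category
# (NEG > NEU > POS), the conservative choice for impact detection
dominant_reaction <- function(reactions) {
  reactions <- as.character(reactions)
  reactions <- reactions[reactions != "NONE"]
  if (length(reactions) == 0L) return("NONE")
  counts <- table(reactions)
  top <- names(counts)[counts == max(counts)]
  severity <- c(NEG = 3L, NEU = 2L, POS = 1L)
  top[which.max(severity[top])]
}

#' Reduce tick records to dominant-state sampling blocks
#'
#' Tiles each continuous sighting run with fixed-length sampling blocks,
#' starting at the run's first tick; the final block of a run may be
#' truncated. Each block carries the dominant (modal) state of its ticks,
#' a vessel flag that is true if any tick in the block has a vessel
#' within the proximity radius, and the modal non-`NONE` reaction (ties
#' toward the more negative category), or `NONE` when no vessel entered
#' the block.
#'
#' A continuous run is a maximal sequence of ticks of one (session, group)
#' stream with no unobserved gap: consecutive ticks at most `tick_minutes`
#' apart.
#'
#' @param records Validated observation records (see [validate_records()]).
#' @param block_minutes Block length in minutes (default 5).
#' @param tick_minutes Tick resolution of the records in minutes (default 1).
#' @param vessel_rule `"any"` (default: a single vessel-present tick flags
#'   the block, the conservative exposure definition) or `"majority"`.
#' @return Data frame of blocks: `session_id`, `group_id`, `run_id`,
#'   `block_index`, `start_min`, `duration_min`, `state`,
#'   `vessel_present`, `reaction`.
#' @seealso [segment_events()]
#' @export
make_blocks <- function(records, block_minutes = 5, tick_minutes = 1,
                        vessel_rule = c("any", "majority")) {
  vessel_rule <- match.arg(vessel_rule)
  records <- validate_records(records)
  if (nrow(records) == 0L) {
    return(data.frame(session_id = character(0), group_id = character(0),
                      run_id = integer(0), block_index = integer(0),
                      start_min = integer(0), duration_min = numeric(0),
                      state = character(0), vessel_present = logical(0),
                      reaction = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(records$session_id, records$group_id, sep = "\r")
  out <- list()
  run_id <- 0L
  st_chr <- as.character(records$state)
  re_chr <- as.character(records$reaction)
  for (k in unique(key)) {
    sel <- which(key == k)
    ts <- records$timestamp_min[sel]
    if (is.unsorted(ts, strictly = TRUE)) stop("records must be sorted")
    run_local <- cumsum(c(TRUE, diff(ts) > tick_minutes))
    for (r in unique(run_local)) {
      run_id <- run_id + 1L
      rsel <- sel[run_local == r]
      rel <- records$timestamp_min[rsel] - records$timestamp_min[rsel[1L]]
      bidx <- rel %/% block_minutes
      sp <- split(rsel, factor(bidx, levels = unique(bidx)))
      vp <- vapply(sp, function(ii) {
        if (vessel_rule == "any") any(records$vessel_present[ii])
        else mean(records$vessel_present[ii]) > 0.5
      }, logical(1))
      out[[length(out) + 1L]] <- data.frame(
        session_id = records$session_id[rsel[1L]],
        group_id = records$group_id[rsel[1L]],
        run_id = run_id,
        block_index = as.integer(names(sp)),
        start_min = records$timestamp_min[rsel[1L]] +
          as.integer(names(sp)) * block_minutes,
        duration_min = lengths(sp) * tick_minutes,
        state = vapply(sp, function(ii) dominant_state(st_chr[ii]),
                       character(1)),
        vessel_present = vp,
        reaction = ifelse(vp, vapply(sp, function(ii)
          dominant_reaction(re_chr[ii]), character(1)), "NONE"),
        stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, out)
  rownames(blocks) <- NULL
  blocks
}

#' Group sampling blocks into independent sighting events
#'
#' Merges consecutive sighting runs of the same (session, group) stream
#' into one event when the unobserved gap between them is shorter than the
#' independence interval; a gap of at least `independence_minutes` starts
#' a new event (the interval itself counts as sufficient separation).
#' Events never span sessions. Block indices are renumbered contiguously
#' from 0 within each event.
#'
#' @param blocks Block table from [make_blocks()], or an existing
#'   `event_set` (in which case segmentation is recomputed; the operation
#'   is idempotent).
#' @param independence_minutes Minimum gap, in minutes, that separates
#'   independent events (default 15).
#' @return An object of class `event_set`: a list with `blocks` (the block
#'   table plus an `event_id` column) and `events` (one row per event:
#'   `event_id`, `session_id`, `group_id`, `n_blocks`, `start_min`,
#'   `end_min`, `total_minutes`).
#' @export
segment_events <- function(blocks, independence_minutes = 15) {
  if (inherits(blocks, "event_set")) blocks <- blocks$blocks
  req <- c("session_id", "group_id", "start_min", "duration_min",
           "state", "vessel_present", "reaction")
  missing_cols <- setdiff(req, names(blocks))
  if (length(missing_cols) > 0L) {
    stop("block table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  blocks <- blocks[order(blocks$session_id, blocks$group_id,
                         blocks$start_min), , drop = FALSE]
  n <- nrow(blocks)
  if (n == 0L) {
    blocks$event_id <- character(0)
    blocks$run_id <- NULL
    return(structure(list(blocks = blocks, events = events_summary(blocks),
                          independence_minutes = independence_minutes),
                     class = "event_set"))
  }
  key <- paste(blocks$session_id, blocks$group_id, sep = "\r")
  key_first <- c(TRUE, key[-1L] != key[-n])
  gap <- c(Inf, blocks$start_min[-1L] -
                (blocks$start_min[-n] + blocks$duration_min[-n]))
  new_event <- key_first | gap >= independence_minutes
  eidx <- cumsum(new_event)
  grp <- cumsum(key_first)
  ev_local <- eidx - eidx[key_first][grp] + 1L
  blocks$event_id <- sprintf("%s_%s_E%02d", blocks$session_id,
                             blocks$group_id, ev_local)
  # renumber blocks contiguously within each event
  blocks$block_index <- sequence(tabulate(eidx)) - 1L
  blocks$run_id <- NULL
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, events = events_summary(blocks),
                 independence_minutes = independence_minutes),
            class = "event_set")
}

# one summary row per event, preserving (session, group, start) order
events_summary <- function(blocks) {
  if (nrow(blocks) == 0L) {
    return(data.frame(event_id = character(0), session_id = character(0),
                      group_id = character(0), n_blocks = integer(0),
                      start_min = numeric(0), end_min = numeric(0),
                      total_minutes = numeric(0), stringsAsFactors = FALSE))
  }
  f <- factor(blocks$event_id, levels = unique(blocks$event_id))
  first <- match(levels(f), blocks$event_id)
  events <- data.frame(
    event_id = levels(f),
    session_id = blocks$session_id[first],
    group_id = blocks$group_id[first],
    n_blocks = as.integer(tabulate(f)),
    start_min = as.numeric(tapply(blocks$start_min, f, min)),
    end_min = as.numeric(tapply(blocks$start_min + blocks$duration_min, f,
                                max)),
    total_minutes = as.numeric(tapply(blocks$duration_min, f, sum)),
    stringsAsFactors = FALSE)
  events <- events[order(events$session_id, events$group_id,
                         events$start_min), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' @export
print.event_set <- function(x, ...) {
  cat("Sighting events:", nrow(x$events), "events,",
      nrow(x$blocks), "sampling blocks,",
      sum(x$events$total_minutes), "observed minutes\n")
  cat("  independence interval:", x$independence_minutes, "min\n")
  invisible(x)
}
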