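#' Behavioral state codes
#'
#' The four-state ethogram used throughout the package: feeding activities
#' (`FEE`), traveling (`TRA`), socializing (`SOC`) and resting (`RES`).
#' `RES` is a legal code even in datasets where resting is never observed.
#'
#' @return Character vector of the four state codes, in canonical order.
#' @export
#' @examples
#' behavior_states()
behavior_states <- function() c("FEE", "TRA", "SOC", "RES")

#' Reaction-to-vessel codes
#'
#' Reactions of a dolphin group to a vessel within the proximity radius:
#' `POS` (active approach / bowriding), `NEU` (behavior maintained),
#' `NEG` (behavior disrupted, formation change, longer dives, tailslaps),
#' and `NONE`, which is used exactly when no vessel is within the radius.
#'
#' @return Character vector of the four reaction codes.
#' @export
reaction_types <- function() c("POS", "NEU", "NEG", "NONE")

# Canonical CSV column order for observation records.
RECORD_COLUMNS <- c("session_id", "timestamp_min", "group_id",
                    "state", "vessel_present", "reaction")

#' Validate a data frame of observation records
#'
#' Checks the structural invariants of per-minute (or coarser) scan-sampling
#' records: required columns, a closed state/reaction vocabulary, strictly
#' increasing timestamps within each (session, group) stream, and the
#' coupling rule that `reaction == "NONE"` exactly when no vessel is present.
#'
#' @param records Data frame with columns `session_id`, `timestamp_min`,
#'   `group_id`, `state`, `vessel_present`, `reaction`.
#' @return The records, sorted by (session, group, timestamp), with `state`
#'   and `reaction` as factors and `vessel_present` as logical. Invisibly
#'   classed as validated via the `"obs_records"` class.
#' @export
validate_records <- function(records) {
  if (!is.data.frame(records)) stop("`records` must be a data frame")
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[RECORD_COLUMNS]
  records$session_id <- as.character(records$session_id)
  records$group_id <- as.character(records$group_id)

  if (nrow(records) == 0L) {
    records$timestamp_min <- integer(0)
    records$state <- factor(character(0), levels = behavior_states())
    records$vessel_present <- logical(0)
    records$reaction <- factor(character(0), levels = reaction_types())
    class(records) <- c("obs_records", "data.frame")
    return(records)
  }

  ts <- records$timestamp_min
  if (!is.numeric(ts) || any(is.na(ts)) || any(ts < 0) || any(ts != floor(ts))) {
    bad <- which(is.na(ts) | ts < 0 | ts != floor(ts))[1L]
    stop("timestamp_min must be a non-negative integer (row ", bad, ")")
  }
  records$timestamp_min <- as.integer(ts)

  state <- as.character(records$state)
  bad_state <- which(!state %in% behavior_states())
  if (length(bad_state) > 0L) {
    stop("unknown behavioral state '", state[bad_state[1L]],
         "' at row ", bad_state[1L],
         " (expected one of ", paste(behavior_states(), collapse = ", "), ")")
  }

  vp <- records$vessel_present
  if (is.numeric(vp)) {
    if (any(!vp %in% c(0, 1))) {
      stop("vessel_present must be 0/1 or logical (row ",
           which(!vp %in% c(0, 1))[1L], ")")
    }
    vp <- vp == 1
  }
  if (!is.logical(vp) || any(is.na(vp))) {
    stop("vessel_present must be 0/1 or logical with no missing values")
  }
  records$vessel_present <- vp

  reaction <- as.character(records$reaction)
  bad_reac <- which(!reaction %in% reaction_types())
  if (length(bad_reac) > 0L) {
    stop("unknown reaction code '", reaction[bad_reac[1L]],
         "' at row ", bad_reac[1L],
         " (expected one of ", paste(reaction_types(), collapse = ", "), ")")
  }
  # NONE <=> vessel absent
  bad_none <- which(!vp & reaction != "NONE")
  if (length(bad_none) > 0L) {
    stop("reaction must be NONE when no vessel is present (row ",
         bad_none[1L], ")")
  }
  bad_some <- which(vp & reaction == "NONE")
  if (length(bad_some) > 0L) {
    stop("reaction NONE recorded with a vessel present (row ",
         bad_some[1L], ")")
  }

  ord <- order(records$session_id, records$group_id, records$timestamp_min)
  records <- records[ord, , drop = FALSE]
  dup <- duplicated(records[c("session_id", "group_id", "timestamp_min")])
  if (any(dup)) {
    stop("timestamps must be strictly increasing within a (session, group) ",
         "stream; duplicate at sorted row ", which(dup)[1L])
  }

  records$state <- factor(state[ord], levels = behavior_states())
  records$reaction <- factor(reaction[ord], levels = reaction_types())
  rownames(records) <- NULL
  class(records) <- c("obs_records", "data.frame")
  records
}

#' Read observation records from CSV
#'
#' Reads scan-sampling observation records from a comma-separated file in
#' the canonical dialect (UTF-8, header row, `.` decimal) and validates
#' them. Columns, in canonical order: `session_id`, `timestamp_min`,
#' `group_id`, `state`, `vessel_present` (0/1), `reaction`
#' (POS/NEU/NEG/NONE).
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(timestamp_min = "minute")`. Unmapped columns keep canonical names.
#' @return A validated `obs_records` data frame sorted by
#'   (session, group, timestamp).
#' @seealso [write_records()], [validate_records()]
#' @export
read_records <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == "")) {
      stop("`schema` must be a named vector: canonical name -> file name")
    }
    for (canon in names(schema)) {
      file_col <- schema[[canon]]
      if (!file_col %in% names(raw)) {
        stop("schema column '", file_col, "' (for '", canon,
             "') not found in ", path)
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  missing_cols <- setdiff(RECORD_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) > 0L) {
    raw$timestamp_min <- suppressWarnings(as.numeric(raw$timestamp_min))
    raw$vessel_present <- suppressWarnings(as.numeric(raw$vessel_present))
  }
  validate_records(raw)
}

#' Write observation records to CSV
#'
#' Writes validated records in the canonical dialect and column order, with
#' deterministic (session, group, timestamp) ordering, so that
#' `write_records(read_records(f))` reproduces a canonicalized `f` exactly.
#'
#' @param records Records accepted by [validate_records()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  out <- data.frame(
    session_id = records$session_id,
    timestamp_min = records$timestamp_min,
    group_id = records$group_id,
    state = as.character(records$state),
    vessel_present = as.integer(records$vessel_present),
    reaction = as.character(records$reaction),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write records to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Fraction of survey effort with dolphins in sight
#'
#' Percentage of total land-based observation effort during which a dolphin
#' group was in sight.
#'
#' @param total_effort_hours Total survey effort in hours (> 0).
#' @param sighted_hours Hours with a group in sight (>= 0, at most the total).
#' @return Percentage (0-100).
#' @export
#' @examples
#' sighting_fraction(942.9, 48.9)
sighting_fraction <- function(total_effort_hours, sighted_hours) {
  if (!is.numeric(total_effort_hours) || length(total_effort_hours) != 1L ||
      is.na(total_effort_hours) || total_effort_hours <= 0) {
    stop("`total_effort_hours` must be a single positive number")
  }
  if (!is.numeric(sighted_hours) || length(sighted_hours) != 1L ||
      is.na(sighted_hours) || sighted_hours < 0) {
    stop("`sighted_hours` must be a single non-negative number")
  }
  if (sighted_hours > total_effort_hours) {
    stop("sighted hours (", sighted_hours, ") exceed total effort (",
         total_effort_hours, ")")
  }
  100 * sighted_hours / total_effort_hours
}
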