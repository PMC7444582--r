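#' Record the annotated events of one ovulation
#'
#' The four timepoints scored during time-lapse processing, as 0-based
#' frame indices: start of oocyte entry, distal neck closure (oocyte fully
#' inside), sp-ut valve opening, and sp-ut valve closure (embryo fully in
#' the uterus). Any may be \code{NA} when the event was not observed.
#'
#' @param entry_start,neck_close,valve_open,valve_close frame indices or NA.
#' @param embryo_exited did the embryo fully exit into the uterus?
#' @param returned_to_gonad did the oocyte reflux back into the gonad arm?
#' @param observation_end last frame of the recording (0-based).
#' @return object of class \code{event_record}.
#' @export
event_record <- function(entry_start = NA, neck_close = NA, valve_open = NA,
                         valve_close = NA, embryo_exited = FALSE,
                         returned_to_gonad = FALSE, observation_end = NA) {
  if (!is.na(valve_close) && is.na(valve_open))
    stop("valve_close requires valve_open")
  if (!is.na(entry_start) && !is.na(observation_end) &&
      entry_start > observation_end)
    stop("entry_start exceeds observation_end")
  structure(list(entry_start = entry_start, neck_close = neck_close,
                 valve_open = valve_open, valve_close = valve_close,
                 embryo_exited = isTRUE(embryo_exited),
                 returned_to_gonad = isTRUE(returned_to_gonad),
                 observation_end = observation_end),
            class = "event_record")
}

#' Transit times from annotated events
#'
#' Entry time runs from the start of oocyte entry to distal neck closure;
#' dwell time from neck closure to sp-ut valve opening (negative when the
#' valve opens before the neck closes); exit time from valve opening to
#' valve closure; total transit from entry start to valve closure. Each is
#' \code{NA} when a required timepoint is absent. Whenever all four
#' timepoints exist, entry + dwell + exit = total.
#'
#' @param events an [event_record()]; \code{entry_start} must be present.
#' @param dt seconds per frame.
#' @return object of class \code{transit_times}: list with
#'   \code{entry_time}, \code{dwell_time}, \code{exit_time},
#'   \code{total_transit}, in seconds.
#' @export
compute_transit_times <- function(events, dt = 1.0) {
  stopifnot(inherits(events, "event_record"))
  if (is.na(events$entry_start))
    stop("entry_start is required to compute transit times")
  tm <- function(a, b) {
    if (is.na(a) || is.na(b)) NA_real_ else (b - a) * dt
  }
  structure(list(
    entry_time = tm(events$entry_start, events$neck_close),
    dwell_time = tm(events$neck_close, events$valve_open),
    exit_time = tm(events$valve_open, events$valve_close),
    total_transit = tm(events$entry_start, events$valve_close)
  ), class = "transit_times")
}

#' @export
print.transit_times <- function(x, ...) {
  cat("<transit_times> entry", x$entry_time, "s | dwell", x$dwell_time,
      "s | exit", x$exit_time, "s | total", x$total_transit, "s\n")
  invisible(x)
}

#' Classify the transit phenotype of one ovulation
#'
#' Exactly one label per ovulation, in this precedence: reflux into the
#' gonad arm wins; else a valve that opened with a completed exit is a
#' successful transit; else an opened valve without exit; else the embryo
#' is trapped. An exit flag without a valve opening is an inconsistent
#' annotation and is rejected.
#'
#' @param events an [event_record()].
#' @return one of \code{"returned_to_gonad_arm"},
#'   \code{"exited_successfully"}, \code{"valve_opens_no_exit"},
#'   \code{"trapped"}.
#' @export
classify_transit <- function(events) {
  stopifnot(inherits(events, "event_record"))
  if (events$embryo_exited && is.na(events$valve_open))
    stop("inconsistent annotation: embryo_exited without valve_open")
  if (events$returned_to_gonad) return("returned_to_gonad_arm")
  if (!is.na(events$valve_open)) {
    if (events$embryo_exited) return("exited_successfully")
    return("valve_opens_no_exit")
  }
  "trapped"
}

POP_CATEGORIES <- c("unoccupied", "occupied", "small_piece_or_liquid", "emo")

#' Tabulate a population occupancy assay
#'
#' Each scored spermatheca carries one category: \code{unoccupied},
#' \code{occupied}, \code{small_piece_or_liquid} (a fragment of an embryo
#' or fluid), or \code{emo} (endomitotic oocytes in the gonad arm). Counts
#' are tabulated per condition, with the occupancy fraction
#' \code{1 - unoccupied/n}.
#'
#' @param records data frame with columns \code{condition} and
#'   \code{category} (one row per spermatheca), or additionally
#'   \code{count} for pre-aggregated rows.
#' @return object of class \code{population_table}: data frame with one
#'   row per condition, one column per category, plus \code{n} and
#'   \code{occupancy_fraction}.
#' @export
score_population <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("condition", "category") %in% names(records)))
  if (nrow(records) == 0) stop("no records to score")
  bad <- setdiff(unique(records$category), POP_CATEGORIES)
  if (length(bad) > 0)
    stop("unknown category label(s): ", paste(bad, collapse = ", "))
  if (!"count" %in% names(records)) records$count <- 1L
  if (any(records$count < 0)) stop("negative counts")
  conds <- unique(records$condition)
  tab <- t(vapply(conds, function(cc) {
    sub <- records[records$condition == cc, ]
    vapply(POP_CATEGORIES, function(cat)
      sum(sub$count[sub$category == cat]), numeric(1))
  }, numeric(length(POP_CATEGORIES))))
  out <- data.frame(condition = conds, tab, row.names = NULL,
                    check.names = FALSE)
  out$n <- rowSums(tab)
  if (any(out$n == 0))
    stop("condition with zero scored spermathecae: ",
         paste(out$condition[out$n == 0], collapse = ", "))
  out$occupancy_fraction <- 1 - out$unoccupied / out$n
  class(out) <- c("population_table", "data.frame")
  out
}

#' Read an events CSV
#'
#' Columns: \code{ovulation_id, entry_start, neck_close, valve_open,
#' valve_close, exited, returned, observation_end}; empty cells mean the
#' event was not observed.
#'
#' @param path CSV path.
#' @return list of [event_record()]s named by ovulation id.
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path)
  need <- c("ovulation_id", "entry_start", "neck_close", "valve_open",
            "valve_close", "exited", "returned", "observation_end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("events CSV missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    event_record(entry_start = df$entry_start[i],
                 neck_close = df$neck_close[i],
                 valve_open = df$valve_open[i],
                 valve_close = df$valve_close[i],
                 embryo_exited = isTRUE(as.logical(df$exited[i])),
                 returned_to_gonad = isTRUE(as.logical(df$returned[i])),
                 observation_end = df$observation_end[i])
  })
  names(out) <- df$ovulation_id
  out
}

#' Summarise a set of annotated ovulations
#'
#' @param events list of [event_record()]s (e.g. from [read_events_csv()]).
#' @param dt seconds per frame.
#' @return data frame with one row per ovulation: the four transit times
#'   and the phenotype label.
#' @export
summarize_transits <- function(events, dt = 1.0) {
  rows <- lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    tt <- compute_transit_times(ev, dt)
    data.frame(ovulation_id = if (!is.null(names(events)))
                 names(events)[i] else as.character(i),
               entry_time = tt$entry_time,
               dwell_time = tt$dwell_time,
               exit_time = tt$exit_time,
               total_transit = tt$total_transit,
               phenotype = classify_transit(ev))
  })
  do.call(rbind, rows)
}
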