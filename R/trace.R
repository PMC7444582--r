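#' Define a rectangular region of interest
#'
#' Coordinates are 0-based and half-open: the ROI covers pixel rows
#' \code{top .. top + height - 1} and columns \code{left .. left + width - 1}.
#' In practice the ROI is drawn to encompass the entire spermatheca.
#'
#' @param top,left 0-based offsets of the ROI's upper-left corner.
#' @param height,width ROI extent in pixels, each >= 1.
#' @return an object of class \code{roi_spec}.
#' @export
roi_spec <- function(top, left, height, width) {
  if (height < 1 || width < 1) stop("ROI height and width must be >= 1")
  if (top < 0 || left < 0) stop("ROI top/left must be >= 0")
  structure(list(top = top, left = left, height = height, width = width),
            class = "roi_spec")
}

check_roi <- function(roi, d) {
  if (roi$top + roi$height > d[2])
    stop("ROI bottom edge ", roi$top + roi$height,
         " exceeds frame height ", d[2])
  if (roi$left + roi$width > d[3])
    stop("ROI right edge ", roi$left + roi$width,
         " exceeds frame width ", d[3])
}

roi_rows <- function(roi) (roi$top + 1):(roi$top + roi$height)
roi_cols <- function(roi) (roi$left + 1):(roi$left + roi$width)

#' Extract the mean-intensity trace of an ROI
#'
#' One value per frame: the arithmetic mean of all ROI pixels.
#'
#' @param stack a [frame_stack()].
#' @param roi a [roi_spec()]; \code{NULL} uses the full frame.
#' @return numeric vector of length T (raw intensity units).
#' @export
extract_trace <- function(stack, roi = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$pixels)
  if (is.null(roi)) roi <- roi_spec(0, 0, d[2], d[3])
  check_roi(roi, d)
  sub <- stack$pixels[, roi_rows(roi), roi_cols(roi), drop = FALSE]
  apply(sub, 1, mean)
}

#' Normalize a raw trace to its pre-entry baseline (F/F0)
#'
#' F0 is the mean of the \code{baseline_len} frames immediately preceding
#' oocyte entry (frames \code{entry_frame - w .. entry_frame - 1}, 0-based).
#' When fewer pre-entry frames exist the window shrinks to what is
#' available, with a warning. The normalized trace over the baseline window
#' averages exactly 1, and scaling all pixels by a positive constant leaves
#' F/F0 unchanged.
#'
#' @param raw numeric vector of per-frame ROI means.
#' @param entry_frame 0-based frame index at which oocyte entry starts;
#'   must be >= 1 (there must be at least one pre-entry frame).
#' @param baseline_len nominal baseline window length in frames
#'   (30 frames at 1 frame/s in the standard protocol).
#' @param dt frame interval, seconds.
#' @param events optional [event_record()] carried along for downstream
#'   metrics; its \code{entry_start} should agree with \code{entry_frame}.
#' @return object of class \code{calcium_trace}: list with \code{t}
#'   (seconds), \code{F_raw}, \code{F_norm}, scalar \code{F0},
#'   \code{entry_frame}, \code{baseline_len_used}, \code{dt}, \code{events}.
#' @export
normalize_trace <- function(raw, entry_frame, baseline_len = 30L, dt = 1.0,
                            events = NULL) {
  if (length(raw) == 0) stop("raw trace is empty")
  if (is.na(entry_frame) || entry_frame < 1)
    stop("entry_frame must be >= 1: no pre-entry frames for the baseline")
  w <- min(baseline_len, entry_frame)
  if (w < baseline_len)
    warning("only ", w, " pre-entry frames available; baseline window ",
            "shrunk from ", baseline_len)
  win <- (entry_frame - w + 1):entry_frame  # 1-based indices of frames
  f0 <- mean(raw[win])
  if (f0 == 0) stop("baseline F0 is zero: non-informative baseline")
  structure(list(t = (seq_along(raw) - 1) * dt,
                 F_raw = raw,
                 F_norm = raw / f0,
                 F0 = f0,
                 entry_frame = entry_frame,
                 baseline_len_used = w,
                 dt = dt,
                 events = events),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat("<calcium_trace>", length(x$F_raw), "frames, dt =", x$dt,
      "s, F0 =", format(x$F0, digits = 6),
      ", entry at frame", x$entry_frame, "\n")
  invisible(x)
}

#' Build a kymogram (space-time image) from a stack
#'
#' Each frame is collapsed to one line by averaging every ROI column over
#' the ROI rows; lines are stacked so row t of the kymogram is frame t.
#' The mean of each kymogram row equals the frame's ROI mean exactly
#' (equal column weights). Raw intensities by default; with
#' \code{normalize = TRUE} the matrix is divided by the trace baseline F0.
#'
#' @param stack a [frame_stack()].
#' @param roi a [roi_spec()]; \code{NULL} uses the full frame.
#' @param normalize divide by the pre-entry baseline F0?
#' @param entry_frame,baseline_len passed to the F0 computation when
#'   \code{normalize = TRUE}.
#' @return object of class \code{kymogram}: list with \code{values}
#'   (T x roi width matrix), \code{dt}, \code{orientation}.
#' @export
build_kymogram <- function(stack, roi = NULL, normalize = FALSE,
                           entry_frame = NULL, baseline_len = 30L) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$pixels)
  if (is.null(roi)) roi <- roi_spec(0, 0, d[2], d[3])
  check_roi(roi, d)
  sub <- stack$pixels[, roi_rows(roi), roi_cols(roi), drop = FALSE]
  vals <- apply(sub, c(1, 3), mean)  # T x W: mean over ROI rows
  if (normalize) {
    if (is.null(entry_frame)) stop("normalize = TRUE requires entry_frame")
    tr <- normalize_trace(rowMeans(vals), entry_frame, baseline_len,
                          dt = stack$dt)
    vals <- vals / tr$F0
  }
  structure(list(values = vals, dt = stack$dt,
                 orientation = "distal_left_valve_right"),
            class = "kymogram")
}

#' @export
print.kymogram <- function(x, ...) {
  cat("<kymogram>", nrow(x$values), "frames x", ncol(x$values),
      "columns, dt =", x$dt, "s,", x$orientation, "\n")
  invisible(x)
}

#' Write / read a trace CSV with metadata header
#'
#' Columns \code{frame,time_s,F_raw,F_norm}; metadata (\code{F0},
#' \code{entry_frame}, \code{dt}, baseline length) as leading \code{#} lines.
#'
#' @param trace a \code{calcium_trace}.
#' @param path output CSV path.
#' @return \code{path} invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "calcium_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# F0=%.17g", trace$F0),
    sprintf("# entry_frame=%d", as.integer(trace$entry_frame)),
    sprintf("# baseline_len=%d", as.integer(trace$baseline_len_used)),
    sprintf("# dt=%.17g", trace$dt)), con)
  df <- data.frame(frame = seq_along(trace$F_raw) - 1L,
                   time_s = trace$t,
                   F_raw = trace$F_raw,
                   F_norm = trace$F_norm)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", m), "=")[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- read.csv(text = lines[!grepl("^#", lines)])
  tr <- normalize_trace(df$F_raw, entry_frame = as.integer(meta$entry_frame),
                        baseline_len = as.integer(meta$baseline_len),
                        dt = meta$dt)
  tr
}

#' Write a kymogram as a CSV matrix
#'
#' @param kym a \code{kymogram}.
#' @param path output CSV path (one row per frame, no header).
#' @return \code{path} invisibly.
#' @export
write_kymogram_csv <- function(kym, path) {
  stopifnot(inherits(kym, "kymogram"))
  utils::write.table(format(kym$values, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
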