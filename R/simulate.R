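#' Simulate a 1-D spatiotemporal calcium field for one spermatheca
#'
#' Produces a T x X matrix of normalized fluorescence: a baseline near 1.0
#' plus a train of distal-to-proximal propagating calcium pulses across the
#' bag columns, a valve compartment following the preset's regime, and
#' i.i.d. Gaussian noise. Space runs distal (column 1) to the sp-ut valve
#' (last columns); the valve occupies the proximal 10% of columns.
#'
#' The deterministic part of the field is
#' \deqn{F(x,t) = B + \sum_i A_0 (1 + r (t_i - t_{entry}))\, g((t - t_i - x/v)/\tau)}
#' over bag positions \eqn{x \in [0,1]} (tissue-lengths), where
#' \eqn{g(u) = 2^{-u^2}} is a unit-peak kernel with half-maximum at
#' \eqn{|u| = \tau}, and pulse onsets are \eqn{t_i = t_{entry} + D + iP}
#' for every \eqn{t_i < duration}. Presets without a transit
#' (\code{entry_frame = NA}) anchor the pulse clock at t = 0.
#'
#' @param preset a [genotype_preset()].
#' @param duration recording length in seconds.
#' @param seed integer seed fixing the noise field exactly; identical
#'   (preset, duration, seed) give bit-identical output.
#' @param n_columns number of spatial columns X (bag + valve).
#' @param dt frame interval in seconds.
#'
#' @return a list with components \code{field} (class \code{ca_field}:
#'   \code{values} T x X matrix, \code{dt}, \code{x_convention},
#'   \code{n_valve_columns}) and \code{truth} (class \code{ca_ground_truth}:
#'   \code{pulse_onsets} in seconds, \code{pulse_count}, \code{event_frames},
#'   \code{phenotype_label}).
#' @export
simulate_field <- function(preset, duration, seed = 1L, n_columns = 50L,
                           dt = 1.0) {
  stopifnot(inherits(preset, "genotype_preset"))
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  if (duration < preset$onset_delay)
    stop("duration must be >= onset_delay (", preset$onset_delay, " s)")
  if (preset$pulse_amplitude > 0 && preset$pulse_period <= 0)
    stop("pulse_period must be > 0 when pulse_amplitude > 0")
  if (n_columns < 2) stop("n_columns must be >= 2")

  n_t <- as.integer(round(duration / dt))
  times <- (seq_len(n_t) - 1) * dt
  n_valve <- max(1L, as.integer(round(0.1 * n_columns)))
  n_bag <- n_columns - n_valve
  x_bag <- seq(0, 1, length.out = n_bag)

  t_entry <- if (is.na(preset$entry_frame)) 0 else preset$entry_frame * dt

  # pulse onsets: entry + delay, then every period, while inside recording
  onsets <- numeric(0)
  if (preset$pulse_amplitude > 0) {
    t0 <- t_entry + preset$onset_delay
    if (t0 < duration) {
      onsets <- t0 + preset$pulse_period *
        (0:ceiling((duration - t0) / preset$pulse_period))
      onsets <- onsets[onsets < duration - 1e-9]
    }
  }

  kern <- function(u) 2^(-u^2)

  field <- matrix(preset$baseline, nrow = n_t, ncol = n_columns)
  add_wave <- function(cols, x_pos) {
    for (j in seq_along(cols)) {
      acc <- numeric(n_t)
      for (ti in onsets) {
        amp <- preset$pulse_amplitude *
          (1 + preset$ramp_rate * (ti - t_entry))
        acc <- acc + amp *
          kern((times - ti - x_pos[j] / preset$wave_speed) / preset$pulse_tau)
      }
      field[, cols[j]] <<- field[, cols[j]] + acc
    }
  }
  add_wave(seq_len(n_bag), x_bag)

  valve_cols <- (n_bag + 1):n_columns
  valve_amp <- 1.0
  if (preset$valve_regime == "entry_spike_then_quiet") {
    spike <- valve_amp * kern((times - t_entry) / preset$pulse_tau)
    field[, valve_cols] <- field[, valve_cols] + spike
  } else if (preset$valve_regime == "sustained_high") {
    step <- valve_amp / (1 + exp(-(times - t_entry) / preset$pulse_tau))
    field[, valve_cols] <- field[, valve_cols] + step
  } else if (preset$valve_regime == "pulsing_with_bag") {
    add_wave(valve_cols, rep(1, n_valve))
  } # suppressed: baseline only

  if (preset$noise_sd > 0) {
    set.seed(as.integer(seed))
    field <- field + matrix(rnorm(n_t * n_columns, 0, preset$noise_sd),
                            nrow = n_t, ncol = n_columns)
  }

  ev <- list(entry_start = preset$entry_frame,
             neck_close = preset$neck_close_frame,
             valve_open = preset$valve_open_frame,
             valve_close = preset$valve_close_frame)

  field_obj <- structure(list(values = field, dt = dt,
                              x_convention = "distal_left_valve_right",
                              n_valve_columns = n_valve),
                         class = "ca_field")
  truth <- structure(list(pulse_onsets = onsets,
                          pulse_count = length(onsets),
                          event_frames = ev,
                          phenotype_label = preset$exit_outcome),
                     class = "ca_ground_truth")
  list(field = field_obj, truth = truth)
}

#' @export
print.ca_field <- function(x, ...) {
  cat("<ca_field>", nrow(x$values), "frames x", ncol(x$values),
      "columns, dt =", x$dt, "s,", x$x_convention,
      sprintf("(%d valve columns)\n", x$n_valve_columns))
  invisible(x)
}

#' @export
print.ca_ground_truth <- function(x, ...) {
  cat("<ca_ground_truth>", x$pulse_count, "pulses;",
      "phenotype:", ifelse(is.na(x$phenotype_label), "-", x$phenotype_label),
      "\n")
  invisible(x)
}

#' Render a spatiotemporal field as a grayscale movie
#'
#' The inverse of kymogram/ROI extraction: each field column is expanded to
#' a block of pixel columns, each frame row is replicated over the image
#' height, and normalized values are mapped to gray levels by the affine
#' map \code{gray = round(value * gain + offset)}. The map is recorded in
#' the returned stack so it is invertible. Block means reproduce the field
#' exactly up to quantization when \code{width} is a multiple of the field's
#' column count.
#'
#' @param field a \code{ca_field} from [simulate_field()].
#' @param height,width frame size in pixels; \code{width} must be at least
#'   the number of field columns.
#' @param bit_depth 8 or 16.
#' @param gain,offset affine intensity map; values mapping outside
#'   \code{[0, 2^bit_depth - 1]} are an error (no silent clipping).
#' @return a [frame_stack()] with attribute \code{intensity_map}.
#' @export
render_movie <- function(field, height = 40L, width = NULL, bit_depth = 8L,
                         gain = 100, offset = 0) {
  stopifnot(inherits(field, "ca_field"))
  n_x <- ncol(field$values)
  if (is.null(width)) width <- 4L * n_x
  if (width < n_x)
    stop("width must be >= number of field columns (", n_x, ")")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  gray <- round(field$values * gain + offset)
  gmax <- 2^bit_depth - 1
  if (max(gray) > gmax || min(gray) < 0)
    stop("intensity map clips at ", bit_depth, "-bit: mapped values span [",
         min(gray), ", ", max(gray), "], allowed [0, ", gmax,
         "]; adjust gain/offset")
  col_of_px <- floor((seq_len(width) - 1) * n_x / width) + 1
  n_t <- nrow(gray)
  pixels <- array(0L, dim = c(n_t, height, width))
  for (t in seq_len(n_t)) {
    row <- gray[t, col_of_px]
    pixels[t, , ] <- matrix(row, nrow = height, ncol = width, byrow = TRUE)
  }
  stk <- frame_stack(pixels, dt = field$dt, bit_depth = bit_depth,
                     provenance = "rendered from simulated field")
  attr(stk, "intensity_map") <- list(gain = gain, offset = offset)
  stk
}
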