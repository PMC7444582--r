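#' Construct a genotype preset for the calcium movie simulator
#'
#' A preset bundles the dynamic regime of one genotype/RNAi condition:
#' baseline fluorescence, pulse-train timing, amplitude ramp, wave speed,
#' the behaviour of the sp-ut valve compartment, and the annotated transit
#' events the simulated ovulation should carry.
#'
#' All times are in seconds; frame indices are 0-based. Amplitudes are in
#' baseline-normalized fluorescence units (a resting trace sits near 1.0).
#'
#' @param name label for the regime (e.g. \code{"kin2_kd"}).
#' @param baseline resting normalized fluorescence, typically 1.0.
#' @param noise_sd standard deviation of the additive Gaussian noise per
#'   (frame, column) sample, in normalized units. Must be >= 0.
#' @param onset_delay delay (s) from oocyte entry to the first calcium pulse.
#' @param pulse_period period (s) between successive pulse onsets. Must be
#'   positive whenever \code{pulse_amplitude > 0}.
#' @param pulse_amplitude amplitude of the first pulse, normalized units.
#'   Zero disables the pulse train.
#' @param ramp_rate fractional amplitude growth per second since entry:
#'   pulse i has amplitude \code{pulse_amplitude * (1 + ramp_rate * (t_i - t_entry))}.
#' @param wave_speed distal-to-proximal propagation speed in
#'   tissue-lengths per second (the bag spans one tissue-length).
#' @param pulse_tau pulse kernel half-duration (s): the unit-peak kernel
#'   falls to one half at \code{+/- pulse_tau} around the pulse centre.
#' @param valve_regime behaviour of the sp-ut valve columns: one of
#'   \code{"entry_spike_then_quiet"} (bright flash on entry, then quiet),
#'   \code{"sustained_high"} (rises at entry and stays high),
#'   \code{"suppressed"} (baseline throughout), or
#'   \code{"pulsing_with_bag"} (continues the propagating bag wave).
#' @param entry_frame,neck_close_frame,valve_open_frame,valve_close_frame
#'   0-based frame indices of the four transit events; \code{NA} when the
#'   event does not occur (e.g. a trapped embryo never opens the valve, an
#'   empty spermatheca has no transit at all).
#' @param exit_outcome transit phenotype the preset emulates: one of
#'   \code{"exited_successfully"}, \code{"trapped"},
#'   \code{"returned_to_gonad_arm"}, \code{"valve_opens_no_exit"}, or
#'   \code{NA} for presets without a transit.
#' @param baseline_window number of pre-entry frames the downstream F0
#'   normalization expects; \code{entry_frame} must be at least this when a
#'   transit is simulated.
#'
#' @return an object of class \code{genotype_preset}.
#' @seealso [simulate_field()], [load_preset()], [list_presets()]
#' @export
genotype_preset <- function(name,
                            baseline = 1.0,
                            noise_sd = 0.02,
                            onset_delay = 0,
                            pulse_period = 30,
                            pulse_amplitude = 0,
                            ramp_rate = 0,
                            wave_speed = 0.1,
                            pulse_tau = 6,
                            valve_regime = c("entry_spike_then_quiet",
                                             "sustained_high",
                                             "suppressed",
                                             "pulsing_with_bag"),
                            entry_frame = NA,
                            neck_close_frame = NA,
                            valve_open_frame = NA,
                            valve_close_frame = NA,
                            exit_outcome = NA,
                            baseline_window = 30) {
  valve_regime <- match.arg(valve_regime)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0")
  if (pulse_amplitude > 0 && (!is.numeric(pulse_period) || pulse_period <= 0))
    stop("pulse_period must be > 0 when pulse_amplitude > 0")
  if (onset_delay < 0)
    stop("onset_delay must be >= 0")
  if (!is.numeric(pulse_tau) || pulse_tau <= 0)
    stop("pulse_tau must be > 0")
  if (!is.numeric(wave_speed) || wave_speed <= 0)
    stop("wave_speed must be > 0")
  if (!is.na(entry_frame) && entry_frame < baseline_window)
    stop("entry_frame must be >= baseline_window (", baseline_window,
         " frames) when a transit is simulated")
  if (!is.na(valve_close_frame) && is.na(valve_open_frame))
    stop("valve_close_frame requires valve_open_frame")
  structure(list(
    name = name,
    baseline = baseline,
    noise_sd = noise_sd,
    onset_delay = onset_delay,
    pulse_period = pulse_period,
    pulse_amplitude = pulse_amplitude,
    ramp_rate = ramp_rate,
    wave_speed = wave_speed,
    pulse_tau = pulse_tau,
    valve_regime = valve_regime,
    entry_frame = entry_frame,
    neck_close_frame = neck_close_frame,
    valve_open_frame = valve_open_frame,
    valve_close_frame = valve_close_frame,
    exit_outcome = exit_outcome,
    baseline_window = baseline_window
  ), class = "genotype_preset")
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat("<genotype_preset>", x$name, "\n")
  cat("  baseline", x$baseline, "| noise_sd", x$noise_sd,
      "| valve:", x$valve_regime, "\n")
  if (x$pulse_amplitude > 0)
    cat("  pulses: A0", x$pulse_amplitude, "every", x$pulse_period,
        "s, delay", x$onset_delay, "s, ramp", x$ramp_rate,
        "/s, tau", x$pulse_tau, "s, speed", x$wave_speed, "lengths/s\n")
  else
    cat("  pulses: none\n")
  ev <- c(entry = x$entry_frame, neck_close = x$neck_close_frame,
          valve_open = x$valve_open_frame, valve_close = x$valve_close_frame)
  cat("  events:", paste(names(ev), ifelse(is.na(ev), "-", ev),
                         sep = "=", collapse = " "),
      "| outcome:", ifelse(is.na(x$exit_outcome), "-", x$exit_outcome), "\n")
  invisible(x)
}

#' List the genotype presets shipped with the package
#'
#' @return character vector of preset names accepted by [load_preset()].
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "calciflow")
  sort(sub("\\.json$", "", list.files(dir, pattern = "\\.json$")))
}

#' Load a shipped genotype preset by name
#'
#' Presets are stored as JSON under \code{inst/extdata/presets}; each file
#' captures the qualitative calcium regime of one condition (wild type,
#' kinase knockdowns, the constitutively active Gs-alpha mutant, the
#' pulsing empty spermatheca).
#'
#' @param name preset name, one of [list_presets()].
#' @return a [genotype_preset()] object.
#' @export
load_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "calciflow")
  if (!nzchar(path))
    stop("unknown preset '", name, "'; available: ",
         paste(list_presets(), collapse = ", "))
  raw <- jsonlite::fromJSON(path)
  raw <- lapply(raw, function(v) if (is.null(v)) NA else v)
  do.call(genotype_preset, raw)
}
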