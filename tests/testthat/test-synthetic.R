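test_that("preset invariants are enforced with named parameters", {
  expect_error(genotype_preset("x", noise_sd = -1), "noise_sd")
  expect_error(genotype_preset("x", pulse_amplitude = 1, pulse_period = 0),
               "pulse_period")
  expect_error(genotype_preset("x", pulse_tau = 0), "pulse_tau")
  expect_error(genotype_preset("x", wave_speed = 0), "wave_speed")
  expect_error(genotype_preset("x", entry_frame = 10), "entry_frame")
})

test_that("all shipped presets load and are valid", {
  names <- list_presets()
  expect_setequal(names, c("wild_type", "gsa1_kd", "kin1_kd", "kin2_kd",
                           "gsa1_gf", "pde6_kd", "empty_pulsing"))
  for (nm in names) {
    p <- load_preset(nm)
    expect_s3_class(p, "genotype_preset")
    expect_identical(p$name, nm)
  }
  expect_error(load_preset("nonexistent"), "unknown preset")
})

test_that("noise-free zero-amplitude preset yields a constant field", {
  p <- genotype_preset("flat", noise_sd = 0, pulse_amplitude = 0,
                       valve_regime = "suppressed")
  sim <- simulate_field(p, duration = 100, seed = 1)
  expect_true(all(sim$field$values == 1.0))
  expect_identical(sim$truth$pulse_count, 0L)
  expect_length(sim$truth$pulse_onsets, 0)
})

test_that("pulse bookkeeping: onsets are entry + delay + i*period", {
  p <- genotype_preset("train", noise_sd = 0, pulse_amplitude = 0.5,
                       pulse_period = 30, onset_delay = 0,
                       valve_regime = "suppressed", entry_frame = NA)
  sim <- simulate_field(p, duration = 600, seed = 1)
  expect_identical(sim$truth$pulse_count, 20L)
  expect_equal(sim$truth$pulse_onsets, seq(0, 570, by = 30))
  expect_identical(sim$truth$pulse_count, length(sim$truth$pulse_onsets))
  expect_true(all(diff(sim$truth$pulse_onsets) > 0))
})

test_that("identical seeds are bit-identical; seeds differ only in noise", {
  p <- load_preset("kin2_kd")
  a <- simulate_field(p, 200, seed = 42)
  b <- simulate_field(p, 200, seed = 42)
  expect_identical(a$field$values, b$field$values)
  expect_identical(a$truth, b$truth)
  c <- simulate_field(p, 200, seed = 43)
  expect_false(identical(a$field$values, c$field$values))
  # the deterministic part is seed-independent
  p0 <- p; p0$noise_sd <- 0
  det1 <- simulate_field(p0, 200, seed = 1)$field$values
  det2 <- simulate_field(p0, 200, seed = 99)$field$values
  expect_identical(det1, det2)
  expect_true(max(abs(a$field$values - det1)) < 6 * p$noise_sd)
})

test_that("simulator rejects bad durations with a named message", {
  p <- load_preset("wild_type")
  expect_error(simulate_field(p, duration = 0), "duration")
  expect_error(simulate_field(p, duration = -5), "duration")
  expect_error(simulate_field(p, duration = 10), "onset_delay")
})

test_that("wave causality: peak time shifts by delta_x / v along the bag", {
  # 50 columns -> 45 bag columns spaced 1/44 tissue-lengths; with
  # v = 1/88 each column's pulse peaks exactly 2 frames after the last
  p <- genotype_preset("wave", noise_sd = 0, pulse_amplitude = 1,
                       pulse_period = 1000, onset_delay = 50,
                       wave_speed = 1 / 88, pulse_tau = 6,
                       valve_regime = "suppressed", entry_frame = NA)
  sim <- simulate_field(p, duration = 200, seed = 1)
  bag <- sim$field$values[, 1:45]
  peak_frame <- apply(bag, 2, which.max)
  expect_equal(diff(peak_frame), rep(2, 44))
  expect_equal(peak_frame[1], 51)  # onset at t = 50, 0-based frame 50
})

test_that("valve regimes shape the proximal columns as specified", {
  base <- list(noise_sd = 0, pulse_amplitude = 0.5, pulse_period = 40,
               onset_delay = 0, entry_frame = NA)
  mk <- function(regime) do.call(genotype_preset,
                                 c(list(name = regime,
                                        valve_regime = regime), base))
  dur <- 200
  f_sup <- simulate_field(mk("suppressed"), dur, 1)$field
  valve <- (ncol(f_sup$values) - f_sup$n_valve_columns + 1):
    ncol(f_sup$values)
  expect_true(all(f_sup$values[, valve] == 1.0))
  f_high <- simulate_field(mk("sustained_high"), dur, 1)$field
  late <- f_high$values[150:200, valve]
  expect_true(all(late > 1.9))  # risen and held high
  f_pulse <- simulate_field(mk("pulsing_with_bag"), dur, 1)$field
  expect_gt(max(f_pulse$values[, valve]) - min(f_pulse$values[, valve]), 0.4)
  f_spike <- simulate_field(mk("entry_spike_then_quiet"), dur, 1)$field
  expect_gt(max(f_spike$values[1:20, valve]), 1.5)   # spike at entry (t=0)
  expect_true(all(abs(f_spike$values[100:200, valve] - 1) < 1e-6))
})

test_that("rendering maps a constant field to the expected gray level", {
  p <- genotype_preset("flat", noise_sd = 0, pulse_amplitude = 0,
                       valve_regime = "suppressed")
  f <- simulate_field(p, 10, 1)$field
  stk <- render_movie(f, height = 8, width = 100, gain = 100)
  expect_true(all(stk$pixels == 100L))
  expect_identical(dim(stk$pixels), c(10L, 8L, 100L))
})

test_that("rendering rejects intensity maps that clip", {
  p <- genotype_preset("hot", noise_sd = 0, pulse_amplitude = 3,
                       pulse_period = 50, valve_regime = "suppressed",
                       entry_frame = NA)
  f <- simulate_field(p, 100, 1)$field
  expect_error(render_movie(f, height = 8, width = 100,
                            bit_depth = 8, gain = 100), "clips")
})

test_that("rendered frame means match the field to within quantization", {
  p <- load_preset("kin2_kd")
  f <- simulate_field(p, 120, seed = 3)$field
  stk <- render_movie(f, height = 10, width = 4 * ncol(f$values),
                      bit_depth = 16, gain = 1000)
  frame_means <- extract_trace(stk)
  field_means <- rowMeans(f$values)
  expect_lt(max(abs(frame_means - (field_means * 1000))), 0.5)
})

test_that("render + extract + normalize round-trips the field time course", {
  set.seed(99)
  for (s in sample.int(10000, 50)) {
    p <- genotype_preset("rt", noise_sd = 0.01,
                         pulse_amplitude = runif(1, 0.2, 0.8),
                         pulse_period = runif(1, 20, 60),
                         onset_delay = runif(1, 0, 20),
                         ramp_rate = runif(1, 0, 0.004),
                         valve_regime = sample(c("suppressed",
                                                 "pulsing_with_bag"), 1),
                         entry_frame = NA)
    f <- simulate_field(p, 150, seed = s)$field
    stk <- render_movie(f, height = 6, width = 4 * ncol(f$values),
                        bit_depth = 16, gain = 5000)
    rec <- extract_trace(stk) / 5000
    expect_lt(max(abs(rec - rowMeans(f$values))), 0.5 / 5000)
  }
})
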