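# Independent oracles and fixture builders used across the suite.

# Brute-force O(n^2) peak finder: candidates from run-length encoding,
# prominence by exhaustive scan over all samples, width by scanning for
# the half-prominence crossings nearest the peak. Deliberately a separate
# code path from calciflow::find_peaks.
oracle_find_peaks <- function(x, min_prominence = 0.1, min_width = 5) {
  n <- length(x)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- NULL
  if (length(r$values) >= 3) {
    for (k in 2:(length(r$values) - 1)) {
      if (r$values[k] > r$values[k - 1] && r$values[k] > r$values[k + 1]) {
        p <- (starts[k] + ends[k]) %/% 2
        v <- x[p]
        higher_left <- which(x[seq_len(p - 1)] > v)
        lb <- if (length(higher_left)) max(higher_left) + 1 else 1
        higher_right <- which(x[(p + 1):n] > v) + p
        rb <- if (length(higher_right)) min(higher_right) - 1 else n
        left_base <- min(x[lb:p])
        right_base <- min(x[p:rb])
        prom <- v - max(left_base, right_base)
        h <- v - prom / 2
        below_left <- which(x[lb:p] < h) + lb - 1
        kl <- max(below_left)
        lpos <- kl + (h - x[kl]) / (x[kl + 1] - x[kl])
        below_right <- which(x[p:rb] < h) + p - 1
        kr <- min(below_right)
        rpos <- kr - (h - x[kr]) / (x[kr - 1] - x[kr])
        out <- rbind(out, c(index = p - 1, value = v, prominence = prom,
                            width = rpos - lpos))
      }
    }
  }
  if (is.null(out)) return(calciflow:::empty_peaks()[
    , c("index", "value", "prominence", "width")])
  out <- as.data.frame(out)
  out <- out[out$prominence >= min_prominence & out$width >= min_width, ]
  rownames(out) <- NULL
  out
}

# pseudorandom test traces: smooth random walks, with occasional rounding
# so plateaus and exact ties actually occur
random_trace <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(20:200, 1)
  x <- cumsum(rnorm(n, 0, 0.3))
  x <- as.numeric(stats::filter(c(x[1], x, x[n]), rep(1 / 3, 3)))[2:(n + 1)]
  if (seed %% 3 == 0) x <- round(x, 1)  # force plateaus/ties
  x
}

# textured scene for registration fixtures: smooth sinusoidal pattern with
# seeded speckle, values well inside 8-bit range
textured_scene <- function(seed, h, w) {
  set.seed(seed)
  base <- outer(seq_len(h), seq_len(w),
                function(a, b) sin(0.37 * a) * cos(0.23 * b) +
                  0.5 * sin(0.11 * a * b / 7))
  sp <- matrix(rnorm(h * w), h, w)
  px <- 120 + 50 * base + 15 * sp
  matrix(pmin(255L, pmax(0L, as.integer(round(px)))), h, w)
}

# stack whose frames are crops of one scene at injected integer offsets;
# frame t satisfies frame[y, x] = frame0[y - dy_t, x - dx_t]
shifted_stack <- function(scene, h, w, margin, shifts, noise_sd = 0) {
  n_t <- nrow(shifts)
  px <- array(0L, dim = c(n_t, h, w))
  for (t in seq_len(n_t)) {
    dy <- shifts$dy[t]; dx <- shifts$dx[t]
    fr <- scene[(margin + 1 - dy):(margin + h - dy),
                (margin + 1 - dx):(margin + w - dx)]
    if (noise_sd > 0)
      fr <- pmin(255L, pmax(0L, as.integer(round(
        fr + rnorm(h * w, 0, noise_sd)))))
    px[t, , ] <- fr
  }
  frame_stack(px, dt = 1, bit_depth = 8L)
}

# event record matching what the simulator's ground truth implies for a
# preset, for phenotype-recovery checks
truth_to_events <- function(truth, n_frames) {
  ev <- truth$event_frames
  event_record(
    entry_start = ev$entry_start,
    neck_close = ev$neck_close,
    valve_open = ev$valve_open,
    valve_close = ev$valve_close,
    embryo_exited = identical(truth$phenotype_label, "exited_successfully"),
    returned_to_gonad = identical(truth$phenotype_label,
                                  "returned_to_gonad_arm"),
    observation_end = n_frames - 1)
}
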