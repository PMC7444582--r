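#' Construct a frame stack (time-lapse grayscale movie)
#'
#' @param pixels T x H x W array of non-negative integer intensities.
#' @param dt frame interval in seconds (recordings here are 1 frame/s).
#' @param bit_depth 8 or 16.
#' @param provenance free-text note on where the stack came from.
#' @return an object of class \code{frame_stack}.
#' @export
frame_stack <- function(pixels, dt = 1.0, bit_depth = 8L, provenance = "") {
  if (length(dim(pixels)) != 3)
    stop("pixels must be a T x H x W array")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (dt <= 0) stop("dt must be > 0")
  if (min(pixels) < 0 || max(pixels) > 2^bit_depth - 1)
    stop("pixel values outside [0, ", 2^bit_depth - 1, "]")
  structure(list(pixels = pixels, dt = dt, bit_depth = as.integer(bit_depth),
                 provenance = provenance),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<frame_stack>", d[1], "frames of", d[2], "x", d[3], "px,",
      x$bit_depth, "bit, dt =", x$dt, "s\n")
  if (nzchar(x$provenance)) cat(" ", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$pixels)

#' Read a multi-page grayscale TIFF as a frame stack
#'
#' @param path TIFF file path.
#' @param dt frame interval in seconds to attach (not stored in TIFF tags).
#' @return a [frame_stack()].
#' @export
read_stack <- function(path, dt = 1.0) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(pages) == 0) stop("no pages in ", path)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2)
      stop("page ", i, " of ", path, " is not grayscale")
  }
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), d1))
      stop("page ", i, " has size ", paste(dim(pages[[i]]), collapse = "x"),
           ", expected ", paste(d1, collapse = "x"))
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- if (max(unlist(pages)) > 255) 16L else 8L
  if (!bits %in% c(8, 16))
    stop("unsupported bit depth ", bits, " in ", path)
  pixels <- array(0L, dim = c(length(pages), d1[1], d1[2]))
  for (i in seq_along(pages)) pixels[i, , ] <- pages[[i]]
  frame_stack(pixels, dt = dt, bit_depth = as.integer(bits),
              provenance = paste("read from", path))
}

#' Write a frame stack as a multi-page grayscale TIFF
#'
#' Writing then reading back reproduces the pixels, dimensions and bit
#' depth exactly.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  gmax <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(dim(stack$pixels)[1]),
                  function(t) stack$pixels[t, , ] / gmax)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  invisible(path)
}

# zero-normalized cross-correlation of frame vs reference under the
# translation model frame[y, x] = ref[y - dy, x - dx], on the overlap
zncc_at <- function(fr, ref, dy, dx) {
  h <- nrow(fr); w <- ncol(fr)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  a <- fr[ys, xs, drop = FALSE]
  b <- ref[ys - dy, xs - dx, drop = FALSE]
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(-Inf)
  cor(as.vector(a), as.vector(b))
}

#' Rigidly register a stack to its first frame
#'
#' For each frame the integer translation (dy, dx) within
#' \code{+/- max_shift} that maximizes the zero-normalized
#' cross-correlation with frame 0 is found; candidates are scanned in order
#' of increasing \code{|dy| + |dx|} (then lexicographically), so exact ties
#' resolve to the smallest shift. The frame is then shifted back, with
#' out-of-frame pixels filled by the frame median. Frames with zero
#' variance get shift (0, 0) with a warning.
#'
#' @param stack a [frame_stack()] of the paralyzed animal.
#' @param max_shift maximum |dy|, |dx| searched, in pixels; must be below
#'   min(H, W)/4.
#' @return list with \code{stack} (registered) and \code{shifts}, a data
#'   frame with columns \code{frame} (0-based), \code{dy}, \code{dx}: the
#'   detected translation of each frame relative to frame 0.
#' @export
register_stack <- function(stack, max_shift = 10L) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$pixels)
  if (max_shift >= min(d[2], d[3]) / 4)
    stop("max_shift must be < min(H, W)/4")
  # candidate order: |dy|+|dx| ascending, then (dy, dx) lexicographic
  grid <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  grid <- grid[order(abs(grid$dy) + abs(grid$dx), grid$dy, grid$dx), ]
  ref <- stack$pixels[1, , ]
  n_t <- d[1]
  shifts <- data.frame(frame = seq_len(n_t) - 1L, dy = 0L, dx = 0L)
  out <- stack$pixels
  for (t in seq_len(n_t)) {
    fr <- stack$pixels[t, , ]
    if (sd(fr) == 0) {
      warning("frame ", t - 1, " has zero variance; shift (0,0) assumed")
      next
    }
    best <- -Inf; bdy <- 0L; bdx <- 0L
    for (k in seq_len(nrow(grid))) {
      v <- zncc_at(fr, ref, grid$dy[k], grid$dx[k])
      # strict improvement beyond FP noise: exact ties keep the earlier
      # (smaller) candidate in the scan order
      if (v > best + 1e-9) { best <- v; bdy <- grid$dy[k]; bdx <- grid$dx[k] }
    }
    shifts$dy[t] <- bdy; shifts$dx[t] <- bdx
    if (bdy != 0 || bdx != 0)
      out[t, , ] <- shift_frame(fr, bdy, bdx)
  }
  reg <- frame_stack(out, dt = stack$dt, bit_depth = stack$bit_depth,
                     provenance = paste0(stack$provenance, " [registered]"))
  list(stack = reg, shifts = shifts)
}

# undo translation (dy, dx): aligned[y, x] = fr[y + dy, x + dx],
# out-of-frame pixels filled with the frame median
shift_frame <- function(fr, dy, dx) {
  h <- nrow(fr); w <- ncol(fr)
  out <- matrix(as.integer(round(median(fr))), h, w)
  ys <- max(1, 1 - dy):min(h, h - dy)
  xs <- max(1, 1 - dx):min(w, w - dx)
  out[ys, xs] <- fr[ys + dy, xs + dx]
  out
}
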