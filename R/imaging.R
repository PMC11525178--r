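#' Time-lapse image stack
#'
#' Frames are stored as a list of numeric matrices indexed `[y, x]`, with
#' image x = mediolateral (the axis along which the folds appose) and
#' y = rostrocaudal. 3D acquisitions are reduced to 2D maximum projections
#' before measurement; [max_project()] is provided for that.
#'
#' @param frames list of ny x nx matrices, or a 3D array with time as the
#'   third dimension.
#' @param pixel_size pixel size in um/px (e.g. 0.59 for the live-imaging
#'   settings the sensors were designed around).
#' @param time_step frame interval in minutes (default 30).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, time_step = 30) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.list(frames) || length(frames) < 1L)
    .err("invalid-input", "frames must be a non-empty list of matrices (T >= 1)")
  if (!all(vapply(frames, is.matrix, TRUE)))
    .err("invalid-input", "each frame must be a numeric matrix")
  if (length(unique(lapply(frames, dim))) != 1L)
    .err("invalid-input", "all frames must share the same dimensions")
  if (any(vapply(frames, function(f) any(!is.finite(f)) || any(f < 0), TRUE)))
    .err("invalid-input", "intensities must be finite and non-negative")
  if (pixel_size <= 0) .err("invalid-input", "pixel_size must be positive")
  structure(list(frames = frames, pixel_size = pixel_size, time_step = time_step),
            class = "image_stack")
}

#' @method print image_stack
#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d frames of %d x %d px, %.3g um/px, dt = %g min\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$time_step))
  invisible(x)
}

#' Maximum projection of a 3D (y, x, z) volume
#'
#' @param volume 3D array with z as the third dimension.
#' @return A 2D matrix of per-pixel maxima.
#' @export
max_project <- function(volume) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  apply(volume, c(1, 2), max)
}

#' Read a multi-page TIFF as an image stack
#'
#' Each page is treated as one (already projected) timepoint; multi-channel
#' pages are reduced to their first channel.
#'
#' @param path TIFF file path.
#' @param pixel_size um/px.
#' @param time_step minutes between frames.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size, time_step = 30) {
  if (!file.exists(path)) .err("unreadable-input", "no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p
  })
  image_stack(frames, pixel_size = pixel_size, time_step = time_step)
}

#' Write an image stack as a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` jointly across frames.
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(vapply(stack$frames, max, numeric(1)), 1e-12)
  tiff::writeTIFF(lapply(stack$frames, function(f) f / mx), path,
                  bits.per.sample = 16L)
  invisible(path)
}

# circular integer shift of a matrix by (dy, dx)
.roll2 <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1,
    drop = FALSE]
}

# cross-correlation offset of frame relative to ref (frame shifted by +off
# aligns with ref); returns c(dy, dx) with subpixel refinement
.cc_offset <- function(ref, frame) {
  cc <- Re(stats::fft(stats::fft(ref) * Conj(stats::fft(frame)), inverse = TRUE))
  p <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  ny <- nrow(ref); nx <- ncol(ref)
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  sub <- function(v, i, n) {
    cm <- v[((i - 2) %% n) + 1]; c0 <- v[i]; cp <- v[(i %% n) + 1]
    den <- cm - 2 * c0 + cp
    if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  dy <- wrap(p[1], ny) + sub(cc[, p[2]], p[1], ny)
  dx <- wrap(p[2], nx) + sub(cc[p[1], ], p[2], nx)
  c(dy = unname(dy), dx = unname(dx))
}

# rotate matrix about its center by `angle` degrees, bilinear interpolation
.rotate2 <- function(m, angle) {
  if (angle == 0) return(m)
  ny <- nrow(m); nx <- ncol(m)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  th <- angle * pi / 180
  yy <- matrix(seq_len(ny), ny, nx) - cy
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  ys <- cy + cos(th) * yy - sin(th) * xx
  xs <- cx + sin(th) * yy + cos(th) * xx
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  gv <- function(yi, xi) {
    ok <- yi >= 1 & yi <= ny & xi >= 1 & xi <= nx
    out <- numeric(length(yi)); out[ok] <- m[cbind(yi[ok], xi[ok])]
    out
  }
  v <- (1 - fy) * (1 - fx) * gv(y0, x0) + (1 - fy) * fx * gv(y0, x0 + 1) +
    fy * (1 - fx) * gv(y0 + 1, x0) + fy * fx * gv(y0 + 1, x0 + 1)
  matrix(v, ny, nx)
}

#' Register a time-lapse stack to its first frame
#'
#' `translation` mode estimates per-frame offsets by FFT cross-correlation
#' with subpixel (parabolic) refinement and applies the rounded integer
#' shift. `rigid` mode adds an in-plane rotation found by a coarse-then-fine
#' search over angles, mirroring rigid-body registration of maximum
#' projections.
#'
#' @param stack an [image_stack()] (T >= 2 for anything to do; a single
#'   frame returns identity with empty offsets).
#' @param mode `"translation"` or `"rigid"`.
#' @param max_rotation rigid-mode search half-range, degrees.
#' @return List with `stack` (registered) and `offsets` (data frame of
#'   per-frame `dy`, `dx` in px and `angle` in degrees).
#' @export
register_stack <- function(stack, mode = c("translation", "rigid"),
                           max_rotation = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "image_stack"))
  frames <- stack$frames
  if (length(frames) == 1L)
    return(list(stack = stack,
                offsets = data.frame(dy = numeric(0), dx = numeric(0),
                                     angle = numeric(0))))
  if (any(vapply(frames, function(f) sd(f) == 0, TRUE)))
    .err("registration-failure", "featureless (zero-variance) frame")
  ref <- frames[[1]]
  out <- frames
  offs <- data.frame(dy = numeric(length(frames)), dx = 0, angle = 0)
  for (i in seq_along(frames)[-1]) {
    fr <- frames[[i]]
    ang <- 0
    if (mode == "rigid") {
      score <- function(a) {
        rot <- .rotate2(fr, a)
        max(Re(stats::fft(stats::fft(ref) * Conj(stats::fft(rot)), inverse = TRUE)))
      }
      coarse <- seq(-max_rotation, max_rotation, by = 1)
      a0 <- coarse[which.max(vapply(coarse, score, numeric(1)))]
      fine <- seq(a0 - 1, a0 + 1, by = 0.2)
      ang <- fine[which.max(vapply(fine, score, numeric(1)))]
      fr <- .rotate2(fr, ang)
    }
    off <- .cc_offset(ref, fr)
    out[[i]] <- .roll2(fr, round(off["dy"]), round(off["dx"]))
    offs[i, ] <- c(off["dy"], off["dx"], ang)
  }
  list(stack = image_stack(out, stack$pixel_size, stack$time_step),
       offsets = offs)
}

#' Segment the sensor in one frame
#'
#' Global threshold (Otsu on the intensity-normalized frame, or a fixed
#' value), morphological closing, hole filling, and selection of the largest
#' connected component. Thresholding on the normalized frame makes the
#' measurement invariant to detector gain.
#'
#' @param frame numeric matrix `[y, x]`.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold threshold on the normalized (0-1) intensity for
#'   `method = "fixed"`.
#' @param brush_size closing structuring-element diameter in px (odd).
#' @return An object of class `sensor_mask` with `mask` (logical matrix) and
#'   `bbox = c(x_min, x_max, y_min, y_max)` in px.
#' @export
segment_sensor <- function(frame, method = c("otsu", "fixed"), threshold = 0.5,
                           brush_size = 5L) {
  method <- match.arg(method)
  stopifnot(is.matrix(frame))
  rng <- range(frame)
  if (diff(rng) == 0) .err("no-detection", "constant frame")
  fr <- (frame - rng[1]) / diff(rng)
  thr <- if (method == "otsu") EBImage::otsu(EBImage::Image(fr)) else threshold
  mask <- fr > thr
  img <- EBImage::Image(mask * 1)
  img <- EBImage::closing(img, EBImage::makeBrush(brush_size, shape = "disc"))
  img <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(img)
  labs <- EBImage::imageData(lab)
  if (max(labs) < 1) .err("no-detection", "empty mask after filtering")
  sizes <- tabulate(labs[labs > 0])
  keep <- which.max(sizes)
  m <- matrix(labs == keep, nrow(frame), ncol(frame))
  xs <- which(colSums(m) > 0); ys <- which(rowSums(m) > 0)
  structure(list(mask = m,
                 bbox = c(x_min = min(xs), x_max = max(xs),
                          y_min = min(ys), y_max = max(ys)),
                 area = sum(m)),
            class = "sensor_mask")
}

#' Mediolateral width of a segmented sensor
#'
#' Bounding-rectangle extent along image x (the mediolateral axis):
#' `(x_max - x_min + 1) * pixel_size`.
#'
#' @param mask a [segment_sensor()] result.
#' @param pixel_size um/px.
#' @return Width in um.
#' @export
measure_width <- function(mask, pixel_size) {
  stopifnot(inherits(mask, "sensor_mask"))
  if (!any(mask$mask)) .err("no-detection", "empty mask")
  unname((mask$bbox["x_max"] - mask$bbox["x_min"] + 1) * pixel_size)
}

#' Width trace from a time-lapse stack
#'
#' Register, segment and measure every frame; frames without a detection
#' become explicit `NA` gaps (flagged with a warning), never interpolated.
#' The printed width `width0` is the frame-0 measurement.
#'
#' @param stack an [image_stack()].
#' @param register register the stack first (default TRUE when T >= 2).
#' @param mode registration mode, see [register_stack()].
#' @param method segmentation method, see [segment_sensor()].
#' @return A [deformation_trace()].
#' @export
extract_trace <- function(stack, register = TRUE,
                          mode = "translation", method = "otsu") {
  stopifnot(inherits(stack, "image_stack"))
  if (register && length(stack$frames) >= 2L)
    stack <- register_stack(stack, mode = mode)$stack
  widths <- vapply(stack$frames, function(fr) {
    tryCatch(measure_width(segment_sensor(fr, method = method),
                           stack$pixel_size),
             error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(widths))
    warning(sprintf("%d frame(s) without detection: gap(s) left as NA",
                    sum(is.na(widths))), call. = FALSE)
  if (is.na(widths[1]))
    .err("no-detection", "no detection in the first frame; width0 unknown")
  times <- (seq_along(widths) - 1) * stack$time_step
  deformation_trace(times, widths, width0 = widths[1])
}
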