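#' Calibrated image stack
#'
#' Container for grayscale imagery with its physical calibration. `data` is a
#' matrix (y, x), a 3D array (frames-or-planes, y, x) or a 4D array
#' (t, z, y, x); the leading axis of a 3D stack is interpreted by the caller
#' (z for fixed tissue, t for time lapse).
#'
#' @param data numeric array (2D, 3D or 4D).
#' @param pixel_size pixel edge length in micrometres per pixel.
#' @param frame_interval frame spacing in minutes (time-lapse only; `NA`
#'   otherwise).
#' @param axes character vector naming the axes, e.g. `c("t","y","x")`.
#' @return an `image_stack` object.
#' @export
image_stack <- function(data, pixel_size, frame_interval = NA_real_,
                        axes = NULL) {
  check_positive(pixel_size, "pixel_size")
  if (!is.na(frame_interval)) check_positive(frame_interval, "frame_interval")
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  nd <- length(dim(data))
  if (!(nd %in% c(3L, 4L))) {
    stop("`data` must be a 2D, 3D or 4D array", call. = FALSE)
  }
  if (is.null(axes)) axes <- if (nd == 3L) c("z", "y", "x") else c("t", "z", "y", "x")
  structure(
    list(data = data, pixel_size = pixel_size,
         frame_interval = frame_interval, axes = axes),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %s [%s], %.3g um/px%s\n",
              paste(dim(x$data), collapse = " x "),
              paste(x$axes, collapse = ","), x$pixel_size,
              if (is.na(x$frame_interval)) ""
              else sprintf(", %.3g min/frame", x$frame_interval)))
  invisible(x)
}

#' Read a single- or multi-page TIFF as a calibrated stack
#'
#' Pages are stacked along the leading axis in file order. Integer samples
#' are read as stored (no rescaling), so write/read round-trips are
#' bit-exact.
#'
#' @param path TIFF file path.
#' @inheritParams image_stack
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size, frame_interval = NA_real_) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1)))) {
    stop("TIFF pages have inconsistent shapes: ", path, call. = FALSE)
  }
  dat <- array(0, c(length(pages), shp))
  for (i in seq_along(pages)) dat[i, , ] <- pages[[i]]
  gq_log("read_stack ", path, ": ", length(pages), " page(s) ",
         shp[1L], "x", shp[2L])
  image_stack(dat, pixel_size, frame_interval)
}

#' Write a stack (or list of frames) to a multi-page TIFF
#'
#' Values must be non-negative integers representable at `bits` bits per
#' sample; they are stored as-is.
#'
#' @param x an [image_stack()], 3D array (frame, y, x), matrix, or list of
#'   matrices.
#' @param path output file.
#' @param bits bits per sample (8 or 16).
#' @export
write_stack <- function(x, path, bits = 16L) {
  if (inherits(x, "image_stack")) x <- x$data
  if (is.matrix(x)) x <- list(x)
  frames <- if (is.list(x)) as_frame_list(x) else as_frame_list(x)
  maxval <- 2^bits - 1
  bad <- vapply(frames, function(f) any(f < 0 | f > maxval | f != round(f)),
                logical(1))
  if (any(bad)) {
    stop(sprintf("frame values must be integers in [0, %d] for %d-bit TIFF",
                 maxval, bits), call. = FALSE)
  }
  tiff::writeTIFF(lapply(frames, function(f) f / maxval), path,
                  bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Maximum-intensity z-projection
#'
#' Collapses a range of planes to a single image by per-pixel maximum, the
#' standard way time-lapse z-stacks are reduced to one projection per time
#' point before thresholding.
#'
#' @param stack an [image_stack()] or 3D array (z, y, x).
#' @param z_range integer plane indices (1-based); default all planes.
#' @return matrix (y, x).
#' @export
max_project <- function(stack, z_range = NULL) {
  dat <- if (inherits(stack, "image_stack")) stack$data else stack
  if (length(dim(dat)) != 3L) stop("`stack` must be 3D (z, y, x)", call. = FALSE)
  if (is.null(z_range)) z_range <- seq_len(dim(dat)[1L])
  if (length(z_range) == 0L) stop("empty z_range", call. = FALSE)
  if (any(z_range < 1L | z_range > dim(dat)[1L])) {
    stop("z_range outside stack depth", call. = FALSE)
  }
  out <- dat[z_range[1L], , ]
  for (z in z_range[-1L]) out <- pmax(out, dat[z, , ])
  out
}

# Integer-pixel FFT cross-correlation between two equally sized matrices
# (mean-subtracted, no spectral whitening: whitened phase correlation is
# brittle when a sizeable fraction of pixels turns over between frames,
# whereas the magnitude-weighted peak stays put). Returns the shift
# (dy, dx) such that `moving` is approximately `reference` rolled by
# (dy, dx), plus a peak-ratio confidence (primary correlation peak over the
# strongest peak outside its 3x3 neighbourhood).
phase_corr_shift <- function(reference, moving) {
  Fr <- stats::fft(reference - mean(reference))
  Fm <- stats::fft(moving - mean(moving))
  Rm <- Fm * Conj(Fr)
  cc <- Re(stats::fft(Rm, inverse = TRUE)) / length(Rm)
  pk <- which.max(cc)
  ij <- arrayInd(pk, dim(cc))
  dy <- ij[1L] - 1L; dx <- ij[2L] - 1L
  if (dy > nrow(cc) / 2) dy <- dy - nrow(cc)
  if (dx > ncol(cc) / 2) dx <- dx - ncol(cc)
  # confidence: mask out the 3x3 neighbourhood (with wrap) around the peak
  cc2 <- cc
  rr <- ((ij[1L] - 2L):(ij[1L])) %% nrow(cc) + 1L
  cs <- ((ij[2L] - 2L):(ij[2L])) %% ncol(cc) + 1L
  cc2[rr, cs] <- -Inf
  second <- max(cc2)
  conf <- if (second <= 0) Inf else cc[pk] / second
  list(shift = c(dy = dy, dx = dx), confidence = conf)
}

#' Translation registration of a frame sequence
#'
#' Estimates the integer-pixel translation between consecutive frames by
#' phase cross-correlation and accumulates the pairwise shifts into each
#' frame's offset from the reference; consecutive pairs differ only by one
#' interval of drift and morphological turnover, which keeps the estimates
#' stable over long sessions. Each frame is then shifted back onto the
#' reference; pixels that fall outside the frame after shifting are
#' zero-filled and excluded from the joint validity mask, which downstream
#' pixel classification uses to avoid border artefacts.
#'
#' @param frames list of matrices or 3D array (t, y, x).
#' @param reference index of the reference frame (default 1).
#' @param min_confidence peak-ratio below which a pairwise estimate is
#'   flagged low-confidence (reported, never silently dropped).
#' @return list with `aligned` (list of matrices), `shifts` (n x 2 matrix of
#'   (dy, dx), the estimated offset of each frame from the reference),
#'   `confidence` (pairwise peak ratios; `Inf` at the first frame),
#'   `low_confidence` (logical), and `validity` (logical matrix of pixels
#'   valid in every aligned frame).
#' @export
register_translation <- function(frames, reference = 1L, min_confidence = 1.5) {
  frames <- as_frame_list(frames)
  n <- length(frames)
  if (reference < 1L || reference > n) stop("bad reference index", call. = FALSE)
  pair <- matrix(0, n, 2L)           # shift of frame i relative to frame i-1
  conf <- rep(Inf, n)
  if (n > 1L) {
    for (i in 2:n) {
      est <- phase_corr_shift(frames[[i - 1L]], frames[[i]])
      pair[i, ] <- est$shift
      conf[i] <- est$confidence
    }
  }
  cum <- apply(pair, 2L, cumsum)
  cum <- matrix(cum, n, 2L)
  shifts <- sweep(cum, 2L, cum[reference, ])   # offset from the reference
  dimnames(shifts) <- list(NULL, c("dy", "dx"))
  aligned <- vector("list", n)
  validity <- matrix(TRUE, nrow(frames[[1L]]), ncol(frames[[1L]]))
  for (i in seq_len(n)) {
    if (all(shifts[i, ] == 0)) { aligned[[i]] <- frames[[i]]; next }
    sh <- shift2(frames[[i]], -shifts[i, 1L], -shifts[i, 2L], fill = 0)
    aligned[[i]] <- sh$image
    validity <- validity & sh$valid
  }
  gq_log("register_translation: max |shift| = ", max(abs(shifts)), " px")
  list(aligned = aligned, shifts = shifts, confidence = conf,
       low_confidence = conf < min_confidence, validity = validity)
}
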