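#' Triangle auto-threshold of an intensity histogram
#'
#' Implements the triangle method: draw the straight line from the histogram
#' peak to the farthest non-empty tail bin, and take the bin whose histogram
#' point lies at maximal perpendicular distance from that line. When the
#' longer tail lies below the peak the construction is mirrored. Ties are
#' broken toward the peak (the lower threshold, giving the more inclusive
#' mask). The threshold is meant to be applied as "strictly greater than".
#'
#' @param counts non-negative histogram counts per bin.
#' @param values intensity value of each bin (defaults to `0:(nbins-1)`);
#'   must be increasing and equally spaced.
#' @return the threshold on the `values` scale, with attributes `bin` (index)
#'   and `side` ("right" tail or mirrored "left").
#' @export
triangle_threshold <- function(counts, values = seq_along(counts) - 1) {
  if (length(counts) != length(values)) {
    stop("`counts` and `values` must have equal length", call. = FALSE)
  }
  nz <- which(counts > 0)
  if (length(nz) < 2L) {
    stop("triangle threshold needs a histogram with >= 2 non-empty bins",
         call. = FALSE)
  }
  peak <- which.max(counts)
  lo <- nz[1L]; hi <- nz[length(nz)]
  # the triangle spans the longer side of the peak
  side <- if ((hi - peak) >= (peak - lo)) "right" else "left"
  tail_bin <- if (side == "right") hi else lo
  cand <- if (side == "right") seq(peak, tail_bin) else seq(tail_bin, peak)
  # perpendicular distance of (x_i, h_i) from the peak--tail line, in bin
  # index / count units; the line is (x0,y0)-(x1,y1)
  x0 <- peak; y0 <- counts[peak]
  x1 <- tail_bin; y1 <- counts[tail_bin]
  num <- abs((y1 - y0) * cand - (x1 - x0) * counts[cand] + x1 * y0 - x0 * y1)
  den <- sqrt((y1 - y0)^2 + (x1 - x0)^2)
  d <- num / den
  best <- max(d)
  ties <- cand[d >= best - 1e-12 * max(best, 1)]
  bin <- ties[which.min(abs(ties - peak))]
  structure(values[bin], bin = bin, side = side)
}

# Otsu threshold on the intensity scale (EBImage's histogram-variance
# implementation, rescaled). Sits mid-valley between two intensity
# populations, which the movie pipelines prefer over the triangle method's
# near-shoulder cut when background noise is strong.
otsu_threshold_image <- function(image, levels = 256L) {
  rng <- range(image)
  if (rng[1L] == rng[2L]) {
    stop("constant image: Otsu threshold undefined", call. = FALSE)
  }
  scaled <- (image - rng[1L]) / (rng[2L] - rng[1L])
  t01 <- EBImage::otsu(scaled, range = c(0, 1), levels = levels)
  rng[1L] + t01 * (rng[2L] - rng[1L])
}

# Histogram an image into `nbins` equal-width bins spanning its range and
# return the triangle threshold on the intensity scale. Integer-valued
# images with a small range are binned at unit width so bin centres are
# exact intensities.
triangle_threshold_image <- function(image, nbins = 256L) {
  v <- as.numeric(image)
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    stop("constant image: triangle threshold undefined", call. = FALSE)
  }
  if (all(v == round(v)) && diff(rng) <= nbins - 1) {
    values <- seq(rng[1L], rng[2L])
    counts <- tabulate(v - rng[1L] + 1L, nbins = length(values))
  } else {
    edges <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
    idx <- pmin(findInterval(v, edges, rightmost.closed = TRUE), nbins)
    counts <- tabulate(idx, nbins = nbins)
    values <- (edges[-1L] + edges[-length(edges)]) / 2
  }
  triangle_threshold(counts, values)
}
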