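# Independent brute-force oracles. These deliberately use explicit loops and
# plain geometry, not the package's vectorized code paths.

# Walk the discrete circle pixel-by-pixel (midpoint rasterization, angular
# order) and count maximal runs of foreground, starting a new run whenever
# the previous circle pixel was background or not 8-adjacent; merge the run
# wrapping the 0/360 degree seam.
oracle_circle_walk <- function(mask, center, radius_px) {
  pts <- gliaquant:::midpoint_circle(radius_px)
  n <- nrow(pts)
  fg <- logical(n)
  for (i in seq_len(n)) {
    r <- pts[i, 1L] + center[1L] + 1L
    c <- pts[i, 2L] + center[2L] + 1L
    fg[i] <- r >= 1L && r <= nrow(mask) && c >= 1L && c <= ncol(mask) &&
      mask[r, c]
  }
  runs <- 0L
  run_start <- rep(NA_integer_, n)   # which run each pixel belongs to
  for (i in seq_len(n)) {
    if (!fg[i]) next
    prev <- if (i == 1L) n else i - 1L
    adjacent <- fg[prev] &&
      max(abs(pts[i, ] - pts[prev, ])) <= 1L
    if (i > 1L && adjacent) {
      run_start[i] <- run_start[prev]
    } else {
      runs <- runs + 1L
      run_start[i] <- runs
    }
  }
  if (runs > 1L && fg[1L] && fg[n] &&
      max(abs(pts[1L, ] - pts[n, ])) <= 1L &&
      run_start[1L] != run_start[n]) {
    runs <- runs - 1L                 # merge the seam-wrapping run
  }
  runs
}

# Point-to-line distance triangle oracle: for every bin between the peak and
# the farthest non-empty tail bin, project the point onto the peak--tail
# line with vector algebra and take the bin of maximal perpendicular
# distance; ties toward the peak.
oracle_triangle <- function(counts, values = seq_along(counts) - 1) {
  nz <- which(counts > 0)
  peak <- which.max(counts)
  lo <- nz[1L]; hi <- nz[length(nz)]
  tail_bin <- if ((hi - peak) >= (peak - lo)) hi else lo
  a <- c(peak, counts[peak])
  b <- c(tail_bin, counts[tail_bin])
  ab <- b - a
  best <- -1; best_bin <- NA_integer_
  rng <- if (tail_bin > peak) peak:tail_bin else tail_bin:peak
  for (x in rng) {
    p <- c(x, counts[x])
    proj <- a + sum((p - a) * ab) / sum(ab^2) * ab
    d <- sqrt(sum((p - proj)^2))
    if (d > best + 1e-12 ||
        (abs(d - best) <= 1e-12 && abs(x - peak) < abs(best_bin - peak))) {
      best <- d; best_bin <- x
    }
  }
  values[best_bin]
}

# Exhaustive per-pixel classification.
oracle_classify_counts <- function(m1, m2, validity = NULL) {
  if (is.null(validity)) validity <- matrix(TRUE, nrow(m1), ncol(m1))
  counts <- c(stable = 0L, extended = 0L, retracted = 0L)
  for (r in seq_len(nrow(m1))) for (c in seq_len(ncol(m1))) {
    if (!validity[r, c]) next
    if (m1[r, c] && m2[r, c]) counts["stable"] <- counts["stable"] + 1L
    else if (!m1[r, c] && m2[r, c]) counts["extended"] <- counts["extended"] + 1L
    else if (m1[r, c] && !m2[r, c]) counts["retracted"] <- counts["retracted"] + 1L
  }
  counts
}

# Grubbs critical value straight from the t-distribution formula.
oracle_grubbs_decision <- function(values, alpha = 0.05) {
  n <- length(values)
  t <- qt(1 - alpha / (2 * n), df = n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
  s <- sd(values)
  if (!is.finite(s) || s == 0) return(list(remove = FALSE, index = NA_integer_))
  dev <- abs(values - mean(values))
  i <- which.max(dev)
  list(remove = dev[i] / s > crit, index = i)
}

# Small Y-shaped arbor: vertical stem from the soma, forking into two
# diagonal branches at a chosen radius. 0-based soma center.
build_y_arbor <- function(side = 65L, fork_um = 12, pixel_size = 1) {
  ctr <- c((side - 1L) %/% 2L, (side - 1L) %/% 2L)
  m <- matrix(FALSE, side, side)
  fork <- c(ctr[1L] - round(fork_um / pixel_size), ctr[2L])
  stem <- gliaquant:::ras_line4(ctr, fork)
  m[stem + 1L] <- TRUE
  for (s in c(-1L, 1L)) {
    tip <- fork + c(-9L, s * 9L)
    br <- gliaquant:::ras_line4(fork, tip)
    m[br + 1L] <- TRUE
  }
  list(mask = m, center = ctr)
}
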