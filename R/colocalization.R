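#' Two-channel engulfment (colocalization) scoring
#'
#' Scores internalized puncta: each channel stack is smoothed (2D Gaussian
#' per plane), triangle-thresholded (one threshold per channel over the
#' whole stack) and binarized; the two binary stacks are multiplied (logical
#' AND); connected components of the product strictly larger than
#' `min_punctum_px` pixels are counted as internalized puncta; and the count
#' is normalized by the total area occupied by the cell channel's
#' foreground. Components span z-planes with 26-connectivity (8 in 2D),
#' since puncta in a 0.5-um-step stack extend across planes.
#'
#' @param cell_channel,puncta_channel matrices (single plane) or 3D arrays
#'   (z, y, x) of equal shape: the cell (microglia) and puncta (receptor
#'   label) channels.
#' @param min_punctum_px components must be strictly larger than this many
#'   pixels to count (default 1, the ">1 pixel" rule).
#' @param pixel_size micrometres per pixel.
#' @param smooth_sigma Gaussian sigma (pixels) for per-plane smoothing; 0
#'   disables.
#' @param area_mode "per-plane" sums the cell foreground across all planes;
#'   "projected" uses the area of the cell mask's 2D projection.
#' @return a `puncta_result`: list with `n_internal_puncta`,
#'   `microglia_area_um2`, `density_per_um2`, `thresholds` (per channel),
#'   `product_mask`.
#' @export
colocalize <- function(cell_channel, puncta_channel, min_punctum_px = 1L,
                       pixel_size = 1, smooth_sigma = 1,
                       area_mode = c("per-plane", "projected")) {
  area_mode <- match.arg(area_mode)
  check_positive(pixel_size, "pixel_size")
  cell <- as_stack3d(cell_channel)
  pun <- as_stack3d(puncta_channel)
  if (!identical(dim(cell), dim(pun))) {
    stop("channel shapes differ", call. = FALSE)
  }
  cell_s <- smooth_stack(cell, smooth_sigma)
  pun_s <- smooth_stack(pun, smooth_sigma)
  thr_cell <- as.numeric(triangle_threshold_image(cell_s))
  thr_pun <- as.numeric(triangle_threshold_image(pun_s))
  cell_mask <- cell_s > thr_cell
  pun_mask <- pun_s > thr_pun
  if (!any(cell_mask)) stop("empty cell-channel mask: area normalizer zero",
                            call. = FALSE)
  product <- cell_mask & pun_mask
  nz <- dim(product)[1L]
  lab <- if (nz == 1L) {
    label_components(product[1L, , ], connectivity = 8L)
  } else {
    label_components(product, connectivity = 26L)
  }
  sizes <- tabulate(lab[lab > 0L])
  n_puncta <- sum(sizes > min_punctum_px)
  area <- if (area_mode == "per-plane") {
    sum(cell_mask) * pixel_size^2
  } else {
    proj <- apply(cell_mask, c(2L, 3L), any)
    sum(proj) * pixel_size^2
  }
  gq_log("colocalize: thresholds ", signif(thr_cell, 4), "/",
         signif(thr_pun, 4), ", ", n_puncta, " puncta, area ",
         signif(area, 5), " um2")
  structure(list(n_internal_puncta = n_puncta,
                 microglia_area_um2 = area,
                 density_per_um2 = n_puncta / area,
                 thresholds = c(cell = thr_cell, puncta = thr_pun),
                 product_mask = product),
            class = "puncta_result")
}

as_stack3d <- function(x) {
  if (inherits(x, "image_stack")) x <- x$data
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  if (length(dim(x)) != 3L) stop("channel must be 2D or 3D", call. = FALSE)
  x
}

smooth_stack <- function(stack, sigma) {
  if (sigma <= 0) return(stack)
  out <- stack
  for (z in seq_len(dim(stack)[1L])) {
    out[z, , ] <- EBImage::gblur(stack[z, , ], sigma = sigma)
  }
  out
}

#' Descriptive comparison of puncta densities between groups
#'
#' @param group_a,group_b lists of [colocalize()] results (one per image or
#'   animal).
#' @return list with per-group mean and s.e.m. of density, the difference of
#'   means (a - b), and their ratio (a / b, `NA` when b's mean is 0).
#' @export
compare_density <- function(group_a, group_b) {
  dens <- function(g) {
    if (length(g) < 1L) stop("each group needs >= 1 result", call. = FALSE)
    vapply(g, function(r) r$density_per_um2, numeric(1))
  }
  a <- dens(group_a); b <- dens(group_b)
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  list(mean_a = mean(a), sem_a = sem(a), n_a = length(a),
       mean_b = mean(b), sem_b = sem(b), n_b = length(b),
       difference = mean(a) - mean(b),
       ratio = if (mean(b) > 0) mean(a) / mean(b) else NA_real_)
}
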