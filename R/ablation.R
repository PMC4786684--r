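#' Ablation annulus geometry
#'
#' Defines the two concentric compartments around a focal laser lesion: the
#' inner disc of radius X (the target compartment processes converge into)
#' and the outer annulus X < r <= Y (the pool they arrive from). A small
#' core around the centre (the lesion itself, saturated or damaged pixels)
#' is excluded from all counts.
#'
#' @param center 0-based (row, col) of the ablation site.
#' @param inner_radius_um inner radius X in micrometres (~40 in the original
#'   protocol).
#' @param outer_radius_um outer radius Y in micrometres (~80).
#' @param core_exclusion_um radius excluded around the centre (default 5).
#' @return an `ablation_geometry` list.
#' @export
ablation_geometry <- function(center, inner_radius_um = 40,
                              outer_radius_um = 80, core_exclusion_um = 5) {
  check_positive(inner_radius_um, "inner_radius_um")
  check_positive(outer_radius_um, "outer_radius_um")
  if (core_exclusion_um < 0) stop("core_exclusion_um must be >= 0", call. = FALSE)
  if (inner_radius_um >= outer_radius_um) {
    stop("need 0 < inner_radius_um < outer_radius_um", call. = FALSE)
  }
  if (core_exclusion_um >= inner_radius_um) {
    stop("core exclusion must be smaller than the inner radius", call. = FALSE)
  }
  structure(list(center = center, inner_radius_um = inner_radius_um,
                 outer_radius_um = outer_radius_um,
                 core_exclusion_um = core_exclusion_um),
            class = "ablation_geometry")
}

#' Laser-ablation chemotaxis response curve
#'
#' Thresholds each projected time point and counts foreground pixels in the
#' inner disc, Rx(t) (core excluded), and in the outer annulus at the first
#' time point, Ry(0). The response is R(t) = (Rx(t) - Rx(0)) / Ry(0), so
#' R(0) = 0 by construction and R grows as process pixels accumulate near
#' the lesion. Distances use centre-of-pixel positions in micrometres.
#'
#' @param frames list of matrices or 3D array (t, y, x).
#' @param geometry an [ablation_geometry()].
#' @param pixel_size micrometres per pixel.
#' @param frame_interval minutes between frames.
#' @param threshold "first-frame" auto-threshold (default), "per-frame", or
#'   "fixed" with `threshold_value`.
#' @param method auto-threshold flavour: "otsu" (default) or "triangle".
#' @param threshold_value threshold for `threshold = "fixed"`.
#' @return an `ablation_response` data frame with columns `time_min`, `Rx`,
#'   `R`, and attribute `Ry0`.
#' @export
ablation_response <- function(frames, geometry, pixel_size = 1,
                              frame_interval = 1,
                              threshold = c("first-frame", "per-frame", "fixed"),
                              method = c("otsu", "triangle"),
                              threshold_value = NULL) {
  threshold <- match.arg(threshold)
  method <- match.arg(method)
  frames <- as_frame_list(frames)
  if (length(frames) < 2L) stop("need >= 2 time points", call. = FALSE)
  check_positive(pixel_size, "pixel_size")
  if (!inherits(geometry, "ablation_geometry")) {
    stop("`geometry` must come from ablation_geometry()", call. = FALSE)
  }
  dims <- dim(frames[[1L]])
  d <- pixel_distances_um(dims, geometry$center, pixel_size)
  r_out_px <- geometry$outer_radius_um / pixel_size
  if (geometry$center[1L] - r_out_px < 0 ||
      geometry$center[1L] + r_out_px > dims[1L] - 1L ||
      geometry$center[2L] - r_out_px < 0 ||
      geometry$center[2L] + r_out_px > dims[2L] - 1L) {
    stop("outer annulus extends beyond the image", call. = FALSE)
  }
  in_disc <- d > geometry$core_exclusion_um & d <= geometry$inner_radius_um
  in_annulus <- d > geometry$inner_radius_um & d <= geometry$outer_radius_um
  auto_thr <- function(f) {
    if (method == "otsu") otsu_threshold_image(f)
    else as.numeric(triangle_threshold_image(f))
  }
  thr_for <- switch(threshold,
    "first-frame" = {
      t0 <- auto_thr(frames[[1L]])
      function(f) t0
    },
    "per-frame" = auto_thr,
    "fixed" = {
      if (is.null(threshold_value)) stop("threshold_value required", call. = FALSE)
      function(f) threshold_value
    }
  )
  masks <- lapply(frames, function(f) f > thr_for(f))
  Rx <- vapply(masks, function(m) sum(m & in_disc), numeric(1))
  Ry0 <- sum(masks[[1L]] & in_annulus)
  if (Ry0 == 0) stop("Ry(0) = 0: response normalizer undefined", call. = FALSE)
  times <- (seq_along(frames) - 1L) * frame_interval
  structure(data.frame(time_min = times, Rx = Rx, R = (Rx - Rx[1L]) / Ry0),
            Ry0 = Ry0, geometry = geometry,
            class = c("ablation_response", "data.frame"))
}

#' Group descriptive statistics of ablation response curves
#'
#' Mean and s.e.m. of R(t) per time point per group. Curves must share one
#' time grid.
#'
#' @param curves list of [ablation_response()] results.
#' @param groups group label per curve.
#' @return data frame with `group`, `time_min`, `mean_R`, `sem_R`, `n`.
#' @export
compare_response_curves <- function(curves, groups) {
  if (length(curves) != length(groups)) {
    stop("one group label per curve required", call. = FALSE)
  }
  tgrid <- curves[[1L]]$time_min
  same <- vapply(curves, function(cv) isTRUE(all.equal(cv$time_min, tgrid)),
                 logical(1))
  if (!all(same)) stop("curves must share a common time grid", call. = FALSE)
  out <- list()
  for (g in unique(groups)) {
    Rs <- vapply(curves[groups == g], function(cv) cv$R, numeric(length(tgrid)))
    Rs <- matrix(Rs, nrow = length(tgrid))
    n <- ncol(Rs)
    mu <- rowMeans(Rs)
    sem <- if (n > 1L) apply(Rs, 1L, stats::sd) / sqrt(n) else rep(0, length(tgrid))
    out[[g]] <- data.frame(group = g, time_min = tgrid, mean_R = mu,
                           sem_R = sem, n = n)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
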