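#' Binarize a grayscale image into a process-arbor mask
#'
#' Thresholds the image (triangle or Otsu auto-threshold, or a fixed value,
#' applied strictly-greater-than) and removes small artefact components
#' below `min_size` pixels (8-connectivity). A constant image under an
#' auto-threshold yields an empty mask with a warning rather than an error,
#' so batch runs survive blank fields of view.
#'
#' @param image numeric matrix.
#' @param method "triangle", "otsu" or "fixed".
#' @param value threshold for `method = "fixed"`.
#' @param min_size artefact filter: smallest component kept (pixels); 0 or 1
#'   disables filtering.
#' @param pixel_size micrometres per pixel, carried on the mask.
#' @return a `binary_mask`: list with `mask` (logical matrix), `pixel_size`,
#'   `method`, `threshold`.
#' @export
binarize <- function(image, method = c("triangle", "otsu", "fixed"),
                     value = NULL, min_size = 4L, pixel_size = 1) {
  method <- match.arg(method)
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  check_positive(pixel_size, "pixel_size")
  if (method == "fixed") {
    if (is.null(value)) stop("`value` required for fixed threshold", call. = FALSE)
    thr <- value
  } else {
    if (length(unique(as.numeric(image))) < 2L) {
      warning("constant image: auto-threshold undefined, returning empty mask")
      return(structure(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                            pixel_size = pixel_size, method = method,
                            threshold = NA_real_),
                       class = "binary_mask"))
    }
    thr <- if (method == "triangle") {
      as.numeric(triangle_threshold_image(image))
    } else {
      otsu_threshold_image(image)
    }
  }
  mask <- image > thr
  mask <- filter_small_components(mask, as.integer(min_size))
  gq_log("binarize: method=", method, " threshold=", signif(thr, 5),
         " fg=", sum(mask), " px")
  structure(list(mask = mask, pixel_size = pixel_size, method = method,
                 threshold = thr),
            class = "binary_mask")
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$mask else mask > 0
}

# Count the maximal 8-connected foreground runs along the discrete circle of
# integer pixel radius R centred (0-based) at `center`. Pixels falling
# outside the image count as background. Runs wrapping the angular seam are
# merged. Returns an integer.
ring_run_crossings <- function(mask, center, radius_px) {
  pts <- midpoint_circle(radius_px)
  rr <- pts[, 1L] + center[1L] + 1L     # to 1-based rows
  cc <- pts[, 2L] + center[2L] + 1L
  inside <- rr >= 1L & rr <= nrow(mask) & cc >= 1L & cc <= ncol(mask)
  fg <- logical(nrow(pts))
  fg[inside] <- mask[cbind(rr[inside], cc[inside])]
  if (!any(fg)) return(0L)
  if (all(fg)) return(1L)
  # number of background -> foreground transitions around the circle;
  # consecutive circle pixels (and the seam pair) are 8-adjacent by
  # construction of the midpoint rasterization
  prev <- c(fg[length(fg)], fg[-length(fg)])
  sum(fg & !prev)
}

#' Sholl ramification profile
#'
#' Counts, for each concentric sampling circle around the soma, the number
#' of distinct process crossings: maximal 8-connected runs of foreground
#' pixels along the discretized (midpoint-rasterized) circle, with runs
#' wrapping the angular seam merged. Profiles are computed on a 2D
#' projection mask.
#'
#' @param mask a `binary_mask` from [binarize()] or a logical matrix.
#' @param soma_center 0-based (row, col) of the soma centre.
#' @param radius_step sampling step in micrometres.
#' @param max_radius largest sampling radius in micrometres.
#' @param pixel_size micrometres per pixel (taken from the mask if it is a
#'   `binary_mask`).
#' @return a `sholl_profile` data frame with columns `radius_um` and
#'   `crossings`, plus attribute `soma_center`.
#' @export
sholl <- function(mask, soma_center, radius_step, max_radius,
                  pixel_size = NULL) {
  if (is.null(pixel_size)) {
    pixel_size <- if (inherits(mask, "binary_mask")) mask$pixel_size else 1
  }
  m <- as_mask_matrix(mask)
  check_positive(radius_step, "radius_step")
  check_positive(max_radius, "max_radius")
  if (soma_center[1L] < 0 || soma_center[1L] > nrow(m) - 1L ||
      soma_center[2L] < 0 || soma_center[2L] > ncol(m) - 1L) {
    stop("soma_center outside the image", call. = FALSE)
  }
  if (!m[soma_center[1L] + 1L, soma_center[2L] + 1L]) {
    warning("soma_center lies on background; profile computed anyway")
  }
  radii <- seq(radius_step, max_radius, by = radius_step)
  crossings <- vapply(radii, function(r_um) {
    r_px <- round(r_um / pixel_size)
    if (r_px < 1L) return(0L)
    as.integer(ring_run_crossings(m, soma_center, r_px))
  }, integer(1))
  structure(data.frame(radius_um = radii, crossings = crossings),
            soma_center = soma_center, pixel_size = pixel_size,
            class = c("sholl_profile", "data.frame"))
}

#' Soma area and background-subtracted intensity
#'
#' Area is the outlined region's pixel count scaled to square micrometres;
#' intensity is the soma's mean minus the mean of a user-chosen background
#' region, and may be negative (not clipped).
#'
#' @param image numeric matrix.
#' @param soma_mask logical matrix outlining the soma.
#' @param background_mask logical matrix of background pixels.
#' @param pixel_size micrometres per pixel.
#' @return list with `area_um2` and `mean_intensity_bg_subtracted`.
#' @export
soma_metrics <- function(image, soma_mask, background_mask, pixel_size) {
  check_positive(pixel_size, "pixel_size")
  soma_mask <- as_mask_matrix(soma_mask)
  background_mask <- as_mask_matrix(background_mask)
  if (!any(soma_mask)) stop("empty soma region", call. = FALSE)
  if (!any(background_mask)) stop("empty background region", call. = FALSE)
  list(
    area_um2 = sum(soma_mask) * pixel_size^2,
    mean_intensity_bg_subtracted =
      mean(image[soma_mask]) - mean(image[background_mask])
  )
}

#' Microglial cell density
#'
#' Number of counted cell bodies divided by the combined area of the
#' analysed sections. Unit-agnostic: densities come out in cells per the
#' unit of `section_areas`.
#'
#' @param body_positions matrix or data frame of counted body coordinates
#'   (one row per cell), or a single count.
#' @param section_areas areas of the analysed planes.
#' @return density (cells per unit area).
#' @export
cell_density <- function(body_positions, section_areas) {
  n <- if (is.numeric(body_positions) && length(body_positions) == 1L) {
    body_positions
  } else {
    nrow(as.data.frame(body_positions))
  }
  if (any(section_areas < 0)) stop("section areas must be non-negative", call. = FALSE)
  total <- sum(section_areas)
  if (total <= 0) stop("zero total section area", call. = FALSE)
  n / total
}

#' Density ratio relative to baseline
#'
#' @param day_n_density density at the later time point.
#' @param day0_density baseline density (must be positive).
#' @return plain quotient.
#' @export
density_ratio <- function(day_n_density, day0_density) {
  check_positive(day0_density, "day0_density")
  day_n_density / day0_density
}
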