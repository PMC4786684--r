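#' Classify pixel changes between two consecutive thresholded frames
#'
#' The RGB-overlay classification: a pixel is *stable* when foreground in
#' both frames, *extended* when foreground only in the second, *retracted*
#' when foreground only in the first, and background otherwise. Pixels
#' outside the validity mask (e.g. invalidated by registration shifts) are
#' excluded from every count.
#'
#' @param mask_t1,mask_t2 `binary_mask` objects or logical matrices of equal
#'   shape (earlier, later frame).
#' @param validity logical matrix of pixels to include; default all.
#' @param interval_index which consecutive frame pair this map describes.
#' @return a `change_map`: list with `labels` (integer matrix: 0 background,
#'   1 stable, 2 extended, 3 retracted), `counts` (named integer vector),
#'   `validity`, `interval_index`.
#' @export
classify_changes <- function(mask_t1, mask_t2, validity = NULL,
                             interval_index = NA_integer_) {
  m1 <- as_mask_matrix(mask_t1)
  m2 <- as_mask_matrix(mask_t2)
  if (!identical(dim(m1), dim(m2))) stop("mask shapes differ", call. = FALSE)
  if (is.null(validity)) validity <- matrix(TRUE, nrow(m1), ncol(m1))
  if (!identical(dim(validity), dim(m1))) {
    stop("validity mask shape differs from the masks", call. = FALSE)
  }
  labels <- matrix(0L, nrow(m1), ncol(m1))
  labels[m1 & m2] <- 1L
  labels[!m1 & m2] <- 2L
  labels[m1 & !m2] <- 3L
  lv <- labels[validity]
  counts <- c(stable = sum(lv == 1L), extended = sum(lv == 2L),
              retracted = sum(lv == 3L))
  structure(list(labels = labels, counts = counts, validity = validity,
                 interval_index = interval_index),
            class = "change_map")
}

#' Motility, extension and retraction indices
#'
#' Per overlay, the motility index is (extended + retracted) / stable, the
#' extension index extended / stable and the retraction index
#' retracted / stable; each is then averaged across all overlays, so the
#' result is a per-interval rate (e.g. change per 4 min at 4-min cadence).
#'
#' @param change_maps list of [classify_changes()] results (consecutive
#'   overlays).
#' @return a `motility_result`: list with `motility_index`,
#'   `extension_index`, `retraction_index`, and `per_interval` (data frame
#'   of the per-overlay values).
#' @export
motility_index <- function(change_maps) {
  if (length(change_maps) < 1L) stop("need at least one change map", call. = FALSE)
  per <- lapply(seq_along(change_maps), function(i) {
    cm <- change_maps[[i]]
    cts <- cm$counts
    if (cts[["stable"]] == 0L) {
      stop(sprintf("interval %s has zero stable pixels: motility index undefined",
                   if (is.na(cm$interval_index)) i else cm$interval_index),
           call. = FALSE)
    }
    data.frame(
      interval = if (is.na(cm$interval_index)) i else cm$interval_index,
      stable = cts[["stable"]], extended = cts[["extended"]],
      retracted = cts[["retracted"]],
      motility = (cts[["extended"]] + cts[["retracted"]]) / cts[["stable"]],
      extension = cts[["extended"]] / cts[["stable"]],
      retraction = cts[["retracted"]] / cts[["stable"]]
    )
  })
  per <- do.call(rbind, per)
  structure(list(motility_index = mean(per$motility),
                 extension_index = mean(per$extension),
                 retraction_index = mean(per$retraction),
                 per_interval = per),
            class = "motility_result")
}

#' Stability index between consecutive overlays
#'
#' Fraction of the pixels newly extended in overlay *k* that are stable in
#' overlay *k*+1. Undefined (returns `NA`) when overlay *k* has no extension
#' pixels.
#'
#' @param overlay_k,overlay_k1 consecutive [classify_changes()] results.
#' @return fraction in \[0, 1\], or `NA_real_` when undefined.
#' @export
stability_index <- function(overlay_k, overlay_k1) {
  check_overlay_pair(overlay_k, overlay_k1)
  valid <- overlay_k$validity & overlay_k1$validity
  ext_k <- overlay_k$labels == 2L & valid
  if (!any(ext_k)) return(NA_real_)
  sum(ext_k & overlay_k1$labels == 1L) / sum(ext_k)
}

#' Instability index between consecutive overlays
#'
#' Fraction of the pixels stable in overlay *k* that are retracted in
#' overlay *k*+1. Undefined (returns `NA`) when overlay *k* has no stable
#' pixels.
#'
#' @inheritParams stability_index
#' @return fraction in \[0, 1\], or `NA_real_` when undefined.
#' @export
instability_index <- function(overlay_k, overlay_k1) {
  check_overlay_pair(overlay_k, overlay_k1)
  valid <- overlay_k$validity & overlay_k1$validity
  st_k <- overlay_k$labels == 1L & valid
  if (!any(st_k)) return(NA_real_)
  sum(st_k & overlay_k1$labels == 3L) / sum(st_k)
}

check_overlay_pair <- function(a, b) {
  if (!inherits(a, "change_map") || !inherits(b, "change_map")) {
    stop("overlays must be change_map objects", call. = FALSE)
  }
  if (!identical(dim(a$labels), dim(b$labels))) {
    stop("overlay geometries differ", call. = FALSE)
  }
  invisible(NULL)
}

#' Stability histogram of newly stabilized pixels
#'
#' Tracks every pixel that turns from extended to stable at some overlay
#' (its first such stabilization) and reports the fraction still
#' continuously stable after 1, 2, ... subsequent overlays. Pixels stable
#' through the entire session (somata, primary processes) are excluded.
#' Offset 0 is 1 by construction and included for reference; at each larger
#' offset only pixels whose stabilization leaves that many overlays of
#' follow-up contribute to the denominator.
#'
#' @param change_maps list of >= 3 consecutive [classify_changes()] results.
#' @return a data frame with `offset`, `n_at_risk`, `fraction_stable`; empty
#'   (0 rows, with a warning) when no pixel newly stabilizes.
#' @export
stability_histogram <- function(change_maps) {
  K <- length(change_maps)
  if (K < 3L) stop("stability histogram needs >= 3 overlays", call. = FALSE)
  for (i in 2:K) check_overlay_pair(change_maps[[i - 1L]], change_maps[[i]])
  valid <- Reduce(`&`, lapply(change_maps, `[[`, "validity"))
  lab <- vapply(change_maps, function(cm) cm$labels[valid], integer(sum(valid)))
  # lab: n_valid_pixels x K label histories
  always_stable <- rowSums(lab == 1L) == K
  newly <- lab[, -1L, drop = FALSE] == 1L & lab[, -K, drop = FALSE] == 2L
  first_stab <- apply(newly, 1L, function(r) if (any(r)) which(r)[1L] + 1L else NA_integer_)
  cohort <- which(!always_stable & !is.na(first_stab))
  if (length(cohort) == 0L) {
    warning("no newly stabilized pixels; stability histogram is empty")
    return(data.frame(offset = integer(0), n_at_risk = integer(0),
                      fraction_stable = numeric(0)))
  }
  k0 <- first_stab[cohort]
  # continuous-stability survival time: overlays stable in a row from k0
  surv <- vapply(seq_along(cohort), function(j) {
    h <- lab[cohort[j], ]
    d <- 0L
    while (k0[j] + d + 1L <= K && h[k0[j] + d + 1L] == 1L) d <- d + 1L
    d
  }, integer(1))
  max_off <- max(K - k0)
  out <- lapply(0:max_off, function(d) {
    at_risk <- k0 + d <= K
    data.frame(offset = d, n_at_risk = sum(at_risk),
               fraction_stable = mean(surv[at_risk] >= d))
  })
  do.call(rbind, out)
}

#' Motility of an individually traced process
#'
#' Mean absolute length change per minute across consecutive time points of
#' one manually traced process.
#'
#' @param lengths process length (micrometres) at each time point.
#' @param interval_min minutes between time points.
#' @return mean rate in micrometres per minute.
#' @export
traced_motility <- function(lengths, interval_min) {
  check_positive(interval_min, "interval_min")
  if (length(lengths) < 2L) stop("need >= 2 time points", call. = FALSE)
  if (any(lengths < 0)) stop("lengths must be non-negative", call. = FALSE)
  mean(abs(diff(lengths))) / interval_min
}

#' Full time-lapse motility pipeline
#'
#' Registers the projected frames (phase cross-correlation), thresholds them
#' (by default one Otsu threshold taken from the first frame and reused for
#' the whole movie, so index differences reflect morphology rather than
#' threshold drift), classifies consecutive pairs, and computes the motility
#' indices, per-pair stability/instability indices, and the stability
#' histogram. Otsu's mid-valley cut is the movie default because it leaves
#' several noise standard deviations between background and threshold at
#' realistic noise levels; the triangle method (which cuts close to the
#' background shoulder) is available as an option.
#'
#' @param frames list of matrices or 3D array (t, y, x): one projection per
#'   time point.
#' @param frame_interval minutes between frames (metadata, carried through).
#' @param threshold "first-frame" (default) or "per-frame" auto-thresholding,
#'   or "fixed" with `threshold_value`.
#' @param method auto-threshold flavour: "otsu" (default) or "triangle".
#' @param threshold_value threshold for `threshold = "fixed"`.
#' @param min_size artefact filter passed to [binarize()].
#' @param register estimate and correct translational drift first.
#' @return list with `indices` ([motility_index()] result), `stability`
#'   (per-pair data frame with stability and instability indices and their
#'   means), `histogram` ([stability_histogram()] when >= 3 overlays),
#'   `change_maps`, `threshold`, `registration`.
#' @export
motility_pipeline <- function(frames, frame_interval = 4,
                              threshold = c("first-frame", "per-frame", "fixed"),
                              method = c("otsu", "triangle"),
                              threshold_value = NULL, min_size = 4L,
                              register = TRUE) {
  threshold <- match.arg(threshold)
  method <- match.arg(method)
  frames <- as_frame_list(frames)
  if (length(frames) < 2L) stop("need >= 2 frames", call. = FALSE)
  reg <- NULL
  validity <- matrix(TRUE, nrow(frames[[1L]]), ncol(frames[[1L]]))
  if (register) {
    reg <- register_translation(frames)
    frames <- reg$aligned
    validity <- reg$validity
  }
  thr_used <- NULL
  masks <- switch(threshold,
    "first-frame" = {
      b1 <- binarize(frames[[1L]], method = method, min_size = min_size)
      thr_used <- b1$threshold
      lapply(frames, function(f)
        binarize(f, method = "fixed", value = thr_used, min_size = min_size))
    },
    "per-frame" = lapply(frames, function(f)
      binarize(f, method = method, min_size = min_size)),
    "fixed" = {
      if (is.null(threshold_value)) stop("threshold_value required", call. = FALSE)
      thr_used <- threshold_value
      lapply(frames, function(f)
        binarize(f, method = "fixed", value = threshold_value, min_size = min_size))
    }
  )
  maps <- lapply(seq_len(length(masks) - 1L), function(i) {
    classify_changes(masks[[i]], masks[[i + 1L]], validity = validity,
                     interval_index = i)
  })
  idx <- motility_index(maps)
  K <- length(maps)
  stab <- if (K >= 2L) {
    data.frame(
      pair = seq_len(K - 1L),
      stability = vapply(seq_len(K - 1L), function(i)
        stability_index(maps[[i]], maps[[i + 1L]]), numeric(1)),
      instability = vapply(seq_len(K - 1L), function(i)
        instability_index(maps[[i]], maps[[i + 1L]]), numeric(1))
    )
  } else NULL
  hist <- if (K >= 3L) stability_histogram(maps) else NULL
  list(indices = idx,
       stability = if (!is.null(stab)) {
         list(per_pair = stab,
              stability_index = mean(stab$stability, na.rm = TRUE),
              instability_index = mean(stab$instability, na.rm = TRUE))
       } else NULL,
       histogram = hist, change_maps = maps,
       threshold = thr_used, frame_interval = frame_interval,
       registration = reg)
}
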