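# Seeded synthetic-data generators. Every generator is a pure function of
# (parameters, seed): it seeds the RNG itself, so the same call reproduces
# the same arrays bit for bit. Generated binary content uses 0 background
# and 255 foreground; grayscale variants add Gaussian noise and clip to
# [0, 255].

# Jittered angular grid with a guaranteed minimum gap, for placing rays so
# that distinct rays never merge into one run on the smallest sampling
# circle (arc separation > 3 px at radius r_min_px).
spread_angles <- function(n, r_min_px) {
  if (n == 0L) return(numeric(0))
  gap <- 2 * pi / n
  if (0.6 * gap * r_min_px < 3) {
    stop(sprintf("too many branches (%d) to keep rays separable at radius %.0f px",
                 n, r_min_px), call. = FALSE)
  }
  start <- stats::runif(1, 0, 2 * pi)
  (start + gap * (seq_len(n) - 1L) +
      stats::runif(n, -0.2, 0.2) * gap) %% (2 * pi)
}

disc_mask <- function(dims, center, radius_px) {
  rows <- matrix(0:(dims[1L] - 1L), dims[1L], dims[2L])
  cols <- matrix(0:(dims[2L] - 1L), dims[1L], dims[2L], byrow = TRUE)
  (rows - center[1L])^2 + (cols - center[2L])^2 <= radius_px^2
}

add_noise_clip <- function(img, noise_sd) {
  if (noise_sd <= 0) return(img)
  pmin(pmax(img + matrix(stats::rnorm(length(img), 0, noise_sd),
                         nrow(img)), 0), 255)
}

# Render a logical mask as a grayscale frame: background level + foreground
# step + optional Gaussian noise, clipped to [0, 255].
render_mask <- function(mask, background_level, foreground_level, noise_sd) {
  add_noise_clip(matrix(background_level +
                          (foreground_level - background_level) * mask,
                        nrow(mask)), noise_sd)
}

# sample() without the length-1 surprise
sample_exact <- function(x, n) x[sample.int(length(x), n)]

#' Synthetic microglial arbor with analytic Sholl ground truth
#'
#' Draws a soma disc plus `n_branches` straight 1-px-wide 4-connected rays
#' at well-separated random angles and random lengths. Because each ray
#' crosses every circle shorter than it exactly once, the crossing count at
#' each requested radius is known analytically and recorded as ground
#' truth. Ray lengths are kept at least 2 px away from every sampling
#' radius so discretization cannot flip a crossing.
#'
#' @param n_branches number of rays (>= 0).
#' @param branch_radii increasing sampling radii (micrometres) at which
#'   ground-truth crossings are recorded; all must clear the soma by 2 px.
#' @param pixel_size micrometres per pixel.
#' @param seed integer seed.
#' @param soma_radius_um soma disc radius (default 2.5).
#' @param noise_sd Gaussian noise s.d. added to the 0/255 image (default 0).
#' @param lengths_um optional fixed ray lengths (micrometres), one per
#'   branch, replacing the random draw; keep them 2 px clear of every
#'   sampling radius.
#' @return a `synthetic_arbor`: list with `image` (numeric matrix), `mask`
#'   (logical), `soma_center` (0-based), `ground_truth_crossings`
#'   (data frame `radius_um`, `crossings`), `pixel_size`, `lengths_um`.
#' @export
generate_arbor <- function(n_branches, branch_radii, pixel_size = 1,
                           seed = 1L, soma_radius_um = 2.5, noise_sd = 0,
                           lengths_um = NULL) {
  check_positive(pixel_size, "pixel_size")
  if (n_branches < 0) stop("n_branches must be >= 0", call. = FALSE)
  if (length(branch_radii) == 0L || any(diff(branch_radii) <= 0) ||
      any(branch_radii <= 0)) {
    stop("branch_radii must be positive and increasing", call. = FALSE)
  }
  if (min(branch_radii) <= soma_radius_um + 2 * pixel_size) {
    stop("smallest sampling radius must clear the soma by at least 2 px",
         call. = FALSE)
  }
  set.seed(seed)
  r_max_um <- max(c(branch_radii, lengths_um)) + 5 * pixel_size
  r_max_px <- ceiling(r_max_um / pixel_size)
  side <- 2L * (r_max_px + 3L) + 1L
  center <- c(r_max_px + 3L, r_max_px + 3L)    # 0-based
  mask <- matrix(FALSE, side, side)
  mask <- mask | disc_mask(c(side, side), center, soma_radius_um / pixel_size)
  if (n_branches == 0L) lengths_um <- numeric(0)
  if (n_branches > 0L) {
    angles <- spread_angles(n_branches, min(branch_radii) / pixel_size)
    if (is.null(lengths_um)) {
      lengths_um <- stats::runif(n_branches,
                                 min(branch_radii) - 3 * pixel_size,
                                 r_max_um - 2 * pixel_size)
      # nudge lengths off the sampling radii so crossings are unambiguous
      for (i in seq_along(lengths_um)) {
        near <- abs(lengths_um[i] - branch_radii) < 2 * pixel_size
        while (any(near)) {
          lengths_um[i] <- lengths_um[i] + 2.5 * pixel_size
          near <- abs(lengths_um[i] - branch_radii) < 2 * pixel_size
        }
      }
    } else if (length(lengths_um) != n_branches || any(lengths_um <= 0)) {
      stop("lengths_um must give one positive length per branch", call. = FALSE)
    }
    for (i in seq_len(n_branches)) {
      L_px <- lengths_um[i] / pixel_size
      tip <- round(center + L_px * c(sin(angles[i]), cos(angles[i])))
      pts <- ras_line4(center, tip)
      mask[pts + 1L] <- TRUE
    }
  }
  crossings <- vapply(branch_radii, function(r)
    sum(lengths_um > r), integer(1))
  image <- add_noise_clip(matrix(255 * mask, side, side), noise_sd)
  structure(list(image = image, mask = mask, soma_center = center,
                 ground_truth_crossings = data.frame(radius_um = branch_radii,
                                                     crossings = crossings),
                 pixel_size = pixel_size, lengths_um = lengths_um,
                 seed = seed),
            class = "synthetic_arbor")
}

# 4-neighbour foreground counts for a logical matrix.
neighbor_count4 <- function(m) {
  n <- matrix(0L, nrow(m), ncol(m))
  n[-1, ] <- n[-1, ] + m[-nrow(m), ]
  n[-nrow(m), ] <- n[-nrow(m), ] + m[-1, ]
  n[, -1] <- n[, -1] + m[, -ncol(m)]
  n[, -ncol(m)] <- n[, -ncol(m)] + m[, -1]
  n
}

#' Synthetic time-lapse movie with planted extension/retraction
#'
#' Evolves a base arbor over `T` frames: each interval adds
#' `extension_fraction` of the current foreground as new pixels sampled
#' uniformly from the background 4-neighbours of the foreground (tip-wise
#' growth) and removes `retraction_fraction` sampled from process tips
#' (foreground pixels with at most one foreground 4-neighbour). The exact
#' added, removed and stable pixel sets of every interval are recorded, so
#' downstream motility indices have an exact oracle.
#'
#' @param base_arbor a [generate_arbor()] result (or any logical mask).
#' @param T number of frames (>= 2); the original protocol used 12 frames
#'   at 4- or 5-min cadence.
#' @param extension_fraction,retraction_fraction per-interval fractions of
#'   the current foreground, in \[0, 1\].
#' @param frame_interval minutes between frames.
#' @param noise_sd Gaussian noise s.d. on the rendered frames.
#' @param background_level,foreground_level rendered gray levels; the
#'   nonzero background emulates the detector offset of real recordings and
#'   keeps additive noise from piling up at 0.
#' @param seed integer seed.
#' @return a `synthetic_timelapse`: list with `frames` (numeric matrices),
#'   `masks` (logical), `planted` (per interval: `added`, `removed` linear
#'   indices, `stable` count), `frame_interval`, `fractions`, `seed`.
#' @export
generate_timelapse <- function(base_arbor, T = 12L, extension_fraction = 0.1,
                               retraction_fraction = 0.1, frame_interval = 4,
                               noise_sd = 0, background_level = 60,
                               foreground_level = 240, seed = 1L) {
  if (T < 2L) stop("T must be >= 2", call. = FALSE)
  check_fraction(extension_fraction, "extension_fraction")
  check_fraction(retraction_fraction, "retraction_fraction")
  mask <- if (inherits(base_arbor, "synthetic_arbor")) base_arbor$mask
          else base_arbor > 0
  if (!any(mask)) stop("base arbor is empty", call. = FALSE)
  set.seed(seed)
  masks <- vector("list", T)
  masks[[1L]] <- mask
  planted <- vector("list", T - 1L)
  cur <- mask
  for (k in seq_len(T - 1L)) {
    nfg <- sum(cur)
    n_ext <- round(extension_fraction * nfg)
    n_ret <- round(retraction_fraction * nfg)
    # retract first from tips, then extend from the surviving foreground's
    # background neighbours, so no added pixel is left isolated (its anchor
    # cannot have been retracted in the same interval)
    nb <- neighbor_count4(cur)
    ret_cand <- which(cur & nb <= 1L)        # process tips
    n_ret <- min(n_ret, length(ret_cand))
    removed <- if (n_ret > 0L) sort(sample_exact(ret_cand, n_ret)) else integer(0)
    kept <- cur
    kept[removed] <- FALSE
    if (!any(kept)) {
      stop("retraction would empty the foreground at interval ", k, call. = FALSE)
    }
    nb2 <- neighbor_count4(kept)
    ext_cand <- setdiff(which(!kept & nb2 >= 1L), removed)
    n_ext <- min(n_ext, length(ext_cand))
    added <- if (n_ext > 0L) sort(sample_exact(ext_cand, n_ext)) else integer(0)
    nxt <- kept
    nxt[added] <- TRUE
    planted[[k]] <- list(added = added, removed = removed,
                         stable = sum(cur & nxt))
    masks[[k + 1L]] <- nxt
    cur <- nxt
  }
  frames <- lapply(masks, function(m)
    render_mask(m, background_level, foreground_level, noise_sd))
  structure(list(frames = frames, masks = masks, planted = planted,
                 frame_interval = frame_interval,
                 fractions = c(extension = extension_fraction,
                               retraction = retraction_fraction),
                 noise_sd = noise_sd,
                 levels = c(background = background_level,
                            foreground = foreground_level),
                 seed = seed),
            class = "synthetic_timelapse")
}

#' Planted motility indices of a synthetic time-lapse
#'
#' The oracle counterpart of [motility_index()]: indices computed directly
#' from the generator's recorded pixel sets.
#'
#' @param tl a [generate_timelapse()] result.
#' @return list with `motility_index`, `extension_index`,
#'   `retraction_index`, `per_interval`.
#' @export
planted_motility <- function(tl) {
  per <- do.call(rbind, lapply(seq_along(tl$planted), function(k) {
    p <- tl$planted[[k]]
    data.frame(interval = k, stable = p$stable,
               extended = length(p$added), retracted = length(p$removed),
               motility = (length(p$added) + length(p$removed)) / p$stable,
               extension = length(p$added) / p$stable,
               retraction = length(p$removed) / p$stable)
  }))
  list(motility_index = mean(per$motility),
       extension_index = mean(per$extension),
       retraction_index = mean(per$retraction),
       per_interval = per)
}

#' Synthetic laser-ablation convergence movie
#'
#' Radial process segments, one per angle, slide toward the ablation centre
#' at `converge_rate` pixels per frame and halt at the excluded core, so
#' total foreground is (approximately) conserved - translocation, not
#' growth. Segments occupy windows of distance-ordered, pairwise-disjoint
#' ray rasters, which makes the inner-disc pixel count exactly
#' non-decreasing for inward-only motion. Ground-truth counts are
#' recomputed from the rendered frames, never from the construction.
#'
#' @param T number of frames (>= 2).
#' @param converge_rate inward speed, pixels per frame (>= 0).
#' @param seed integer seed.
#' @param n_processes number of radial segments.
#' @param pixel_size micrometres per pixel.
#' @param inner_radius_um,outer_radius_um,core_exclusion_um compartment
#'   geometry (defaults X = 40, Y = 80, core = 5).
#' @param segment_len_px segment length along the ray.
#' @param noise_sd Gaussian noise s.d. on the 0/255 frames.
#' @return a `synthetic_ablation`: list with `frames`, `center` (0-based),
#'   `geometry` ([ablation_geometry()]), `pixel_size`, `planted_Rx_counts`,
#'   `planted_Ry0`, `seed`.
#' @export
generate_ablation_movie <- function(T = 8L, converge_rate = 2, seed = 1L,
                                    n_processes = 16L, pixel_size = 1,
                                    inner_radius_um = 40, outer_radius_um = 80,
                                    core_exclusion_um = 5,
                                    segment_len_px = 20L, noise_sd = 0) {
  if (T < 2L) stop("T must be >= 2", call. = FALSE)
  if (converge_rate < 0) stop("converge_rate must be >= 0", call. = FALSE)
  geom_px <- c(inner_radius_um, outer_radius_um, core_exclusion_um) / pixel_size
  set.seed(seed)
  r_edge <- ceiling(geom_px[2L]) + 10L
  side <- 2L * r_edge + 1L
  center <- c(r_edge, r_edge)                 # 0-based
  # evenly spaced jittered angles; rays may share pixels near the centre but
  # pixel ownership is deduplicated below, so counts stay exact
  gap <- 2 * pi / n_processes
  angles <- (stats::runif(1, 0, 2 * pi) + gap * (seq_len(n_processes) - 1L) +
               stats::runif(n_processes, -0.2, 0.2) * gap) %% (2 * pi)
  used <- matrix(FALSE, side, side)
  rays <- vector("list", n_processes)
  for (i in seq_len(n_processes)) {
    tip <- round(center + (geom_px[2L] + 6) * c(sin(angles[i]), cos(angles[i])))
    pts <- ras_line4(center, tip)
    d <- sqrt((pts[, 1L] - center[1L])^2 + (pts[, 2L] - center[2L])^2)
    ord <- order(d)
    pts <- pts[ord, , drop = FALSE]; d <- d[ord]
    lin <- pts[, 1L] + 1L + pts[, 2L] * side
    fresh <- !used[lin]
    used[lin[fresh]] <- TRUE                  # disjoint ownership across rays
    rays[[i]] <- list(lin = lin[fresh], d = d[fresh])
  }
  frames <- vector("list", T)
  fg_t <- vector("list", T)
  for (t in seq_len(T)) fg_t[[t]] <- integer(0)
  for (i in seq_len(n_processes)) {
    ray <- rays[[i]]
    c0 <- which(ray$d > geom_px[3L])[1L]      # first index outside the core
    start_d <- stats::runif(1, geom_px[1L] + 4, geom_px[2L] - 6)
    a0 <- which(ray$d >= start_d)[1L]
    len <- min(segment_len_px, length(ray$lin) - a0 + 1L)
    for (t in seq_len(T)) {
      a <- max(c0, a0 - round(converge_rate * (t - 1L)))
      idx <- a:(a + len - 1L)
      fg_t[[t]] <- c(fg_t[[t]], ray$lin[idx])
    }
  }
  for (t in seq_len(T)) {
    m <- matrix(FALSE, side, side)
    m[fg_t[[t]]] <- TRUE
    frames[[t]] <- add_noise_clip(matrix(255 * m, side, side), noise_sd)
  }
  # ground truth recomputed by brute force from the rendered frames
  d_um <- pixel_distances_um(c(side, side), center, pixel_size)
  in_disc <- d_um > core_exclusion_um & d_um <= inner_radius_um
  in_ann <- d_um > inner_radius_um & d_um <= outer_radius_um
  Rx <- vapply(frames, function(f) sum(f > 0 & in_disc), numeric(1))
  Ry0 <- sum(frames[[1L]] > 0 & in_ann)
  structure(list(frames = frames, center = center,
                 geometry = ablation_geometry(center, inner_radius_um,
                                              outer_radius_um,
                                              core_exclusion_um),
                 pixel_size = pixel_size,
                 planted_Rx_counts = Rx, planted_Ry0 = Ry0, seed = seed),
            class = "synthetic_ablation")
}

# Compact punctum footprint: the first `k` offsets of a fixed spiral around
# the centre pixel, so any size >= 2 is a connected multi-pixel blob.
punctum_offsets <- function(k) {
  spiral <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(0, -1), c(-1, 0),
                  c(-1, 1), c(1, -1), c(-1, -1), c(0, 2), c(2, 0), c(1, 2))
  spiral[seq_len(min(k, nrow(spiral))), , drop = FALSE]
}

#' Synthetic two-channel engulfment image
#'
#' A bright cell-channel disc (the microglia) plus a puncta channel with
#' `n_internal` multi-pixel puncta planted wholly inside the cell and
#' `n_external` wholly outside, all pairwise well separated so they remain
#' distinct components after smoothing. Internal puncta keep a margin from
#' the cell boundary and external puncta a margin from the cell, so
#' downstream smoothing + thresholding cannot move them across the mask
#' edge.
#'
#' @param n_internal,n_external punctum counts (>= 0).
#' @param puncta_size_px pixels per punctum (>= 2, the ">1 pixel" rule floor).
#' @param seed integer seed.
#' @param shape image shape c(rows, cols).
#' @param cell_radius_px cell disc radius (default ~30% of the short side).
#' @param noise_sd Gaussian noise s.d. on both 0/255 channels.
#' @return a `synthetic_puncta`: list with `channel_cell`, `channel_puncta`
#'   (numeric matrices), `cell_mask`, `planted_internal`, `planted_external`,
#'   `puncta_size_px`, `seed`.
#' @export
generate_puncta_image <- function(n_internal, n_external, puncta_size_px = 4L,
                                  seed = 1L, shape = c(128L, 128L),
                                  cell_radius_px = NULL, noise_sd = 0) {
  if (puncta_size_px < 2L) stop("puncta_size_px must be >= 2", call. = FALSE)
  if (n_internal < 0 || n_external < 0) stop("counts must be >= 0", call. = FALSE)
  set.seed(seed)
  if (is.null(cell_radius_px)) cell_radius_px <- round(min(shape) * 0.3)
  center <- (shape - 1) / 2
  cell_mask <- disc_mask(shape, center, cell_radius_px)
  offs <- punctum_offsets(puncta_size_px)
  extent <- max(abs(offs)) + 1L
  sep <- 2L * extent + 8L
  place <- function(n, internal) {
    centers <- matrix(numeric(0), 0L, 2L)
    tries <- 0L
    while (nrow(centers) < n) {
      tries <- tries + 1L
      if (tries > 20000L) stop("could not place puncta; image too crowded",
                               call. = FALSE)
      p <- c(sample(seq(extent + 2L, shape[1L] - extent - 3L), 1L),
             sample(seq(extent + 2L, shape[2L] - extent - 3L), 1L))
      dc <- sqrt(sum((p - center)^2))
      ok <- if (internal) dc <= cell_radius_px - extent - 4 else
        dc >= cell_radius_px + extent + 7
      if (!ok) next
      if (nrow(centers) > 0L &&
          min(sqrt(rowSums(sweep(centers, 2L, p)^2))) < sep) next
      centers <- rbind(centers, p)
    }
    centers
  }
  all_centers <- rbind(place(n_internal, TRUE), place(n_external, FALSE))
  # enforce separation between the internal and external sets too
  if (n_internal > 0L && n_external > 0L) {
    repeat {
      dmat <- as.matrix(stats::dist(all_centers))
      diag(dmat) <- Inf
      if (min(dmat) >= sep) break
      all_centers <- rbind(place(n_internal, TRUE), place(n_external, FALSE))
    }
  }
  pm <- matrix(FALSE, shape[1L], shape[2L])
  if (nrow(all_centers) > 0L) {
    for (i in seq_len(nrow(all_centers))) {
      px <- sweep(offs, 2L, all_centers[i, ], `+`)
      pm[px + 1L] <- TRUE
    }
  }
  structure(list(
    channel_cell = add_noise_clip(matrix(255 * cell_mask, shape[1L]), noise_sd),
    channel_puncta = add_noise_clip(matrix(255 * pm, shape[1L]), noise_sd),
    cell_mask = cell_mask, puncta_mask = pm,
    planted_internal = as.integer(n_internal),
    planted_external = as.integer(n_external),
    puncta_size_px = as.integer(puncta_size_px), seed = seed),
    class = "synthetic_puncta")
}

#' Synthetic intrinsic-optical-signal experiment
#'
#' Generates the four recording sessions of one animal (contra/ipsi eye x
#' up/down stimulus direction). Every pixel's series is
#' DC + A sin(2 pi f t + phi) + Gaussian noise with the planted per-pixel
#' amplitude A of that eye and a random per-pixel phase. The duration must
#' be an integer number of stimulus periods so the stimulus frequency falls
#' on an exact FFT bin.
#'
#' @param amp_contra,amp_ipsi per-pixel amplitude maps (matrices, same
#'   shape).
#' @param stim_frequency stimulus repetition frequency (Hz).
#' @param duration_s recording duration (s); `duration_s * stim_frequency`
#'   must be an integer, and `stim_frequency < sampling_rate / 2`.
#' @param sampling_rate frames per second (Hz).
#' @param noise_sd Gaussian noise s.d.
#' @param dc baseline reflectance level.
#' @param seed integer seed.
#' @return a `synthetic_ios`: list with `sessions` (named list of (t, y, x)
#'   arrays: `contra_up`, `contra_down`, `ipsi_up`, `ipsi_down`), `planted`
#'   (the amplitude maps), `sampling_rate`, `stim_frequency`, `seed`.
#' @export
generate_ios_session <- function(amp_contra, amp_ipsi, stim_frequency,
                                 duration_s, sampling_rate, noise_sd = 0,
                                 dc = 100, seed = 1L) {
  if (!identical(dim(amp_contra), dim(amp_ipsi))) {
    stop("amplitude maps must share one shape", call. = FALSE)
  }
  if (any(amp_contra < 0) || any(amp_ipsi < 0)) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  check_positive(sampling_rate, "sampling_rate")
  if (stim_frequency >= sampling_rate / 2) {
    stop("stim_frequency must be below Nyquist", call. = FALSE)
  }
  cycles <- duration_s * stim_frequency
  if (abs(cycles - round(cycles)) > 1e-9) {
    stop("duration_s must be an integer multiple of the stimulus period",
         call. = FALSE)
  }
  N <- duration_s * sampling_rate
  if (abs(N - round(N)) > 1e-9) {
    stop("duration_s * sampling_rate must be an integer sample count",
         call. = FALSE)
  }
  N <- as.integer(round(N))
  set.seed(seed)
  dims <- dim(amp_contra)
  tt <- (0:(N - 1L)) / sampling_rate
  one_session <- function(amp) {
    phi <- matrix(stats::runif(prod(dims), 0, 2 * pi), dims[1L])
    arr <- array(0, c(N, dims))
    base <- outer(tt, rep(1, prod(dims))) * 2 * pi * stim_frequency +
      rep(as.numeric(phi), each = N)
    sig <- dc + rep(as.numeric(amp), each = N) * sin(base)
    if (noise_sd > 0) sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
    array(sig, c(N, dims))
  }
  sessions <- list(contra_up = one_session(amp_contra),
                   contra_down = one_session(amp_contra),
                   ipsi_up = one_session(amp_ipsi),
                   ipsi_down = one_session(amp_ipsi))
  structure(list(sessions = sessions,
                 planted = list(amp_contra = amp_contra, amp_ipsi = amp_ipsi),
                 sampling_rate = sampling_rate,
                 stim_frequency = stim_frequency,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_ios")
}

#' Synthetic per-process EM event table
#'
#' Draws per-process event counts as Poisson with mean = planted group
#' density x process area, the model the area-normalized statistics assume.
#' Process areas are uniform on `area_range`.
#'
#' @param group_densities named list: group -> named numeric vector of
#'   planted densities (events per um^2) per event category; a plain named
#'   numeric vector is treated as one category named `events`.
#' @param n_animals animals per group.
#' @param n_processes processes per animal (the original material had 50-88).
#' @param area_range c(min, max) process area in um^2.
#' @param seed integer seed.
#' @return a `synthetic_event_table`: list with `table` (data frame:
#'   `animal`, `group`, `process`, `area_um2`, one column per category) and
#'   `planted_densities`.
#' @export
generate_event_table <- function(group_densities, n_animals = 4L,
                                 n_processes = 60L, area_range = c(0.5, 4),
                                 seed = 1L) {
  if (!is.list(group_densities)) {
    group_densities <- lapply(group_densities, function(d) c(events = d))
  }
  if (is.null(names(group_densities))) {
    stop("group_densities must be named by group", call. = FALSE)
  }
  cats <- names(group_densities[[1L]])
  if (is.null(cats)) {
    group_densities <- lapply(group_densities, function(d) stats::setNames(d, paste0("cat", seq_along(d))))
    cats <- names(group_densities[[1L]])
  }
  if (any(unlist(group_densities) < 0)) {
    stop("densities must be >= 0", call. = FALSE)
  }
  set.seed(seed)
  rows <- list()
  for (g in names(group_densities)) {
    dens <- group_densities[[g]]
    for (a in seq_len(n_animals)) {
      area <- stats::runif(n_processes, area_range[1L], area_range[2L])
      df <- data.frame(animal = sprintf("%s_a%02d", g, a), group = g,
                       process = seq_len(n_processes), area_um2 = area)
      for (cat in cats) {
        df[[cat]] <- stats::rpois(n_processes, dens[[cat]] * area)
      }
      rows[[length(rows) + 1L]] <- df
    }
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 planted_densities = group_densities, seed = seed),
            class = "synthetic_event_table")
}

#' Save a synthetic object as TIFF frames plus a JSON ground-truth sidecar
#'
#' Image-bearing synthetic objects are written as one multi-page TIFF
#' (frames rounded to 8-bit) with the recorded ground truth alongside in
#' `<stem>_truth.json`; event tables are written as CSV with a JSON sidecar.
#'
#' @param x a synthetic object from this module.
#' @param stem output path stem (no extension).
#' @return paths written, invisibly.
#' @export
save_synthetic <- function(x, stem) {
  truth_path <- paste0(stem, "_truth.json")
  to8 <- function(frames) lapply(frames, function(f) pmin(pmax(round(f), 0), 255))
  paths <- character(0)
  if (inherits(x, "synthetic_arbor")) {
    img <- paste0(stem, ".tif")
    write_stack(to8(list(x$image)), img, bits = 8L)
    jsonlite::write_json(list(kind = "arbor", soma_center = x$soma_center,
                              pixel_size = x$pixel_size,
                              ground_truth_crossings = x$ground_truth_crossings,
                              seed = x$seed),
                         truth_path, auto_unbox = TRUE, digits = NA)
    paths <- c(img, truth_path)
  } else if (inherits(x, "synthetic_timelapse")) {
    img <- paste0(stem, ".tif")
    write_stack(to8(x$frames), img, bits = 8L)
    per <- lapply(x$planted, function(p)
      list(n_added = length(p$added), n_removed = length(p$removed),
           stable = p$stable))
    jsonlite::write_json(list(kind = "timelapse",
                              frame_interval = x$frame_interval,
                              fractions = as.list(x$fractions),
                              intervals = per, seed = x$seed),
                         truth_path, auto_unbox = TRUE, digits = NA)
    paths <- c(img, truth_path)
  } else if (inherits(x, "synthetic_ablation")) {
    img <- paste0(stem, ".tif")
    write_stack(to8(x$frames), img, bits = 8L)
    jsonlite::write_json(list(kind = "ablation", center = x$center,
                              pixel_size = x$pixel_size,
                              inner_radius_um = x$geometry$inner_radius_um,
                              outer_radius_um = x$geometry$outer_radius_um,
                              core_exclusion_um = x$geometry$core_exclusion_um,
                              planted_Rx_counts = x$planted_Rx_counts,
                              planted_Ry0 = x$planted_Ry0, seed = x$seed),
                         truth_path, auto_unbox = TRUE, digits = NA)
    paths <- c(img, truth_path)
  } else if (inherits(x, "synthetic_puncta")) {
    img_c <- paste0(stem, "_cell.tif"); img_p <- paste0(stem, "_puncta.tif")
    write_stack(to8(list(x$channel_cell)), img_c, bits = 8L)
    write_stack(to8(list(x$channel_puncta)), img_p, bits = 8L)
    jsonlite::write_json(list(kind = "puncta",
                              planted_internal = x$planted_internal,
                              planted_external = x$planted_external,
                              puncta_size_px = x$puncta_size_px, seed = x$seed),
                         truth_path, auto_unbox = TRUE, digits = NA)
    paths <- c(img_c, img_p, truth_path)
  } else if (inherits(x, "synthetic_event_table")) {
    csv <- paste0(stem, ".csv")
    utils::write.csv(x$table, csv, row.names = FALSE)
    jsonlite::write_json(list(kind = "event_table",
                              planted_densities =
                                lapply(x$planted_densities, as.list),
                              seed = x$seed),
                         truth_path, auto_unbox = TRUE, digits = NA)
    paths <- c(csv, truth_path)
  } else {
    stop("unsupported synthetic object", call. = FALSE)
  }
  invisible(paths)
}
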