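#' Stimulus-locked Fourier amplitude map
#'
#' For every pixel's reflectance time series, takes the discrete Fourier
#' component at the bin nearest the stimulus repetition frequency and
#' reports the amplitude normalized as 2|X[k]|/N, so a pure sinusoid of
#' amplitude A returns exactly A. The phase at the same bin is returned as a
#' by-product (retinotopy), and an optional per-pixel linear detrend removes
#' slow hemodynamic drift before the transform.
#'
#' @param pixel_timeseries 3D array (t, y, x) of reflectance samples.
#' @param sampling_rate samples per second (Hz).
#' @param stim_frequency stimulus repetition frequency (Hz); must be below
#'   the Nyquist frequency.
#' @param detrend remove a per-pixel linear trend first (default FALSE).
#' @return an `amplitude_map`: list with `amplitude` (matrix, >= 0), `phase`
#'   (matrix, radians), `stim_frequency`, `bin` (1-based FFT bin used).
#' @export
amplitude_map <- function(pixel_timeseries, sampling_rate, stim_frequency,
                          detrend = FALSE) {
  if (length(dim(pixel_timeseries)) != 3L) {
    stop("`pixel_timeseries` must be (t, y, x)", call. = FALSE)
  }
  check_positive(sampling_rate, "sampling_rate")
  check_positive(stim_frequency, "stim_frequency")
  if (stim_frequency >= sampling_rate / 2) {
    stop("stim_frequency must be below the Nyquist frequency", call. = FALSE)
  }
  N <- dim(pixel_timeseries)[1L]
  ny <- dim(pixel_timeseries)[2L]; nx <- dim(pixel_timeseries)[3L]
  mat <- matrix(pixel_timeseries, nrow = N)
  if (detrend) {
    tt <- seq_len(N)
    tc <- tt - mean(tt)
    slope <- colSums(tc * mat) / sum(tc^2)
    mat <- mat - outer(tc, slope) - rep(colMeans(mat), each = N)
  }
  bin <- round(stim_frequency * N / sampling_rate) + 1L
  X <- stats::mvfft(mat)[bin, ]
  structure(list(amplitude = matrix(2 * Mod(X) / N, ny, nx),
                 phase = matrix(Arg(X), ny, nx),
                 stim_frequency = stim_frequency, bin = bin,
                 sampling_rate = sampling_rate),
            class = "amplitude_map")
}

#' Mean ROI response over both stimulus directions
#'
#' Averages the up- and down-sweep amplitude maps of one eye over a region
#' of interest.
#'
#' @param map_up,map_down [amplitude_map()] results for the two stimulus
#'   directions (same eye, same geometry).
#' @param roi logical matrix selecting the binocular-zone pixels.
#' @return the mean response (scalar).
#' @export
roi_response <- function(map_up, map_down, roi) {
  au <- if (inherits(map_up, "amplitude_map")) map_up$amplitude else map_up
  ad <- if (inherits(map_down, "amplitude_map")) map_down$amplitude else map_down
  if (!identical(dim(au), dim(ad)) || !identical(dim(au), dim(roi))) {
    stop("maps and roi must share one geometry", call. = FALSE)
  }
  roi <- roi > 0
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  mean((au[roi] + ad[roi]) / 2)
}

#' Default binocular-zone ROI from response strength
#'
#' Selects pixels whose mean amplitude (over the supplied maps) exceeds a
#' fraction of the map maximum; a fallback when no anatomical ROI mask is
#' supplied.
#'
#' @param maps list of [amplitude_map()] results.
#' @param fraction of the maximum mean amplitude (default 0.5).
#' @return logical matrix.
#' @export
default_roi <- function(maps, fraction = 0.5) {
  check_fraction(fraction, "fraction")
  amps <- lapply(maps, function(m) if (inherits(m, "amplitude_map")) m$amplitude else m)
  mu <- Reduce(`+`, amps) / length(amps)
  mu >= fraction * max(mu)
}

#' Ocular dominance index
#'
#' ODI = (contra - ipsi) / (contra + ipsi), computed from the two eyes' mean
#' ROI response amplitudes. Positive values indicate contralateral bias; the
#' index lies in \[-1, 1\] for non-negative responses.
#'
#' @param contra_response,ipsi_response mean ROI amplitudes (>= 0, not both
#'   zero).
#' @return the ODI.
#' @export
compute_odi <- function(contra_response, ipsi_response) {
  if (contra_response < 0 || ipsi_response < 0) {
    stop("responses must be non-negative", call. = FALSE)
  }
  s <- contra_response + ipsi_response
  if (s <= 0) stop("contra + ipsi must be positive", call. = FALSE)
  (contra_response - ipsi_response) / s
}

#' End-to-end ODI from four recording sessions
#'
#' Computes amplitude maps for both stimulus directions of both eyes,
#' averages each eye over the ROI and both directions, and returns the ODI.
#'
#' @param sessions list with elements `contra_up`, `contra_down`, `ipsi_up`,
#'   `ipsi_down`, each a 3D array (t, y, x).
#' @param sampling_rate,stim_frequency see [amplitude_map()].
#' @param roi logical matrix; `NULL` selects [default_roi()] over all four
#'   maps.
#' @param detrend per-pixel linear detrend before the FFT.
#' @return an `odi_result`: list with `odi`, `contra_response`,
#'   `ipsi_response`, `maps`, `roi`.
#' @export
odi_pipeline <- function(sessions, sampling_rate, stim_frequency, roi = NULL,
                         detrend = FALSE) {
  need <- c("contra_up", "contra_down", "ipsi_up", "ipsi_down")
  if (!all(need %in% names(sessions))) {
    stop("sessions must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  maps <- lapply(sessions[need], amplitude_map, sampling_rate = sampling_rate,
                 stim_frequency = stim_frequency, detrend = detrend)
  if (is.null(roi)) roi <- default_roi(maps)
  contra <- roi_response(maps$contra_up, maps$contra_down, roi)
  ipsi <- roi_response(maps$ipsi_up, maps$ipsi_down, roi)
  structure(list(odi = compute_odi(contra, ipsi),
                 contra_response = contra, ipsi_response = ipsi,
                 maps = maps, roi = roi),
            class = "odi_result")
}
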