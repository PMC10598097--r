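#' Preprocessing configuration
#'
#' Collects the tunable parameters of the peak-list cleanup stage.
#'
#' @param blank_tol_ppm Symmetric ppm tolerance for matching sample peaks
#'   to blank peaks (default 1.0 ppm).
#' @param blank_intensity_ratio Minimum blank/sample intensity ratio for
#'   a matched peak to be removed. The default 0 removes on an m/z match
#'   alone.
#' @param rel_intensity_min_pct Relative-intensity floor in percent of
#'   the base peak; peaks with less than this normalized intensity are
#'   filtered out (default 1.0).
#' @param snr_min Signal-to-noise multiple below which peaks are removed
#'   (default 3).
#' @param noise_quantile Fraction of the lowest-intensity peaks used to
#'   estimate the noise level (default 0.2).
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(blank_tol_ppm = 1.0,
                              blank_intensity_ratio = 0,
                              rel_intensity_min_pct = 1.0,
                              snr_min = 3,
                              noise_quantile = 0.2) {
  stopifnot(blank_tol_ppm >= 0, blank_intensity_ratio >= 0,
            rel_intensity_min_pct >= 0, snr_min >= 0,
            noise_quantile > 0, noise_quantile < 1)
  structure(
    list(blank_tol_ppm = blank_tol_ppm,
         blank_intensity_ratio = blank_intensity_ratio,
         rel_intensity_min_pct = rel_intensity_min_pct,
         snr_min = snr_min,
         noise_quantile = noise_quantile),
    class = "preprocess_config"
  )
}

#' Subtract a solvent blank from a sample peak list
#'
#' Removes every sample peak that matches a blank peak within
#' `blank_tol_ppm` and whose blank intensity is at least
#' `blank_intensity_ratio` times the sample intensity. This is peak
#' removal, not intensity differencing: blanks flag solvent/contaminant
#' masses, and removal is the conservative, testable interpretation.
#'
#' @param sample,blank Peak tibbles as returned by [read_xy()].
#' @param config A [preprocess_config()].
#' @return The sample tibble restricted to unmatched peaks, with
#'   attribute `n_removed` giving the removal count.
#' @export
subtract_blank <- function(sample, blank, config = preprocess_config()) {
  stopifnot(is.data.frame(sample), is.data.frame(blank))
  if (nrow(blank) == 0L || nrow(sample) == 0L) {
    attr(sample, "n_removed") <- 0L
    return(sample)
  }
  bmz <- sort(blank$mz)
  bint <- blank$intensity[order(blank$mz)]
  tol <- config$blank_tol_ppm * 1e-6
  hit <- vapply(seq_len(nrow(sample)), function(i) {
    m <- sample$mz[i]
    lo <- m * (1 - tol); hi <- m * (1 + tol)
    j <- findInterval(lo, bmz) + 1L
    while (j <= length(bmz) && bmz[j] <= hi) {
      if (bint[j] >= config$blank_intensity_ratio * sample$intensity[i]) {
        return(TRUE)
      }
      j <- j + 1L
    }
    FALSE
  }, logical(1))
  out <- sample[!hit, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("blank subtraction removed every sample peak", call. = FALSE)
  }
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Normalize intensities to percent of the base peak
#'
#' Sets `rel_intensity` to `100 * intensity / max(intensity)`; raw
#' intensities are left untouched and the base peak gets exactly 100.
#'
#' @param peaks Peak tibble.
#' @return Peak tibble with `rel_intensity` filled in.
#' @export
normalize_intensity <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0L) stop("cannot normalize an empty spectrum",
                              call. = FALSE)
  top <- max(peaks$intensity)
  if (top <= 0) stop("cannot normalize all-zero intensities", call. = FALSE)
  dplyr::mutate(peaks, rel_intensity = 100 * .data$intensity / top)
}

#' Filter peaks below a relative-intensity floor
#'
#' Keeps exactly the peaks with `rel_intensity >= min_pct`; a peak at
#' the floor (e.g. 1.0% at the default 1% cutoff) is retained, since the
#' filter drops peaks with *less than* the floor.
#'
#' @param peaks Peak tibble with `rel_intensity` set (see
#'   [normalize_intensity()]).
#' @param min_pct Floor in percent (default 1).
#' @return Filtered peak tibble (a subset of the input, order preserved).
#' @export
filter_rel_intensity <- function(peaks, min_pct = 1.0) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) > 0L && anyNA(peaks$rel_intensity)) {
    stop("rel_intensity not set; run normalize_intensity() first",
         call. = FALSE)
  }
  peaks[peaks$rel_intensity >= min_pct, , drop = FALSE]
}

#' Filter peaks below a signal-to-noise threshold
#'
#' The noise level is estimated as the median raw intensity of the
#' lowest `noise_quantile` fraction of peaks; peaks with intensity below
#' `snr_min` times that level are removed. The estimate is made once, on
#' the spectrum as given, and carried on the result as attribute
#' `noise_level`; re-applying the filter reuses the stored level, so the
#' operation is idempotent rather than iteratively self-referential.
#' Spectra with fewer than 5 peaks are returned unchanged with a warning
#' (the estimate would be meaningless).
#'
#' @param peaks Peak tibble.
#' @param config A [preprocess_config()].
#' @return Filtered peak tibble with attributes `noise_level` and
#'   `n_removed`.
#' @export
filter_snr <- function(peaks, config = preprocess_config()) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) < 5L) {
    warning("fewer than 5 peaks; SNR filter skipped", call. = FALSE)
    attr(peaks, "n_removed") <- 0L
    return(peaks)
  }
  noise <- attr(peaks, "noise_level")
  if (is.null(noise)) {
    k <- max(1L, ceiling(config$noise_quantile * nrow(peaks)))
    noise <- stats::median(sort(peaks$intensity)[seq_len(k)])
  }
  keep <- peaks$intensity >= config$snr_min * noise
  out <- peaks[keep, , drop = FALSE]
  attr(out, "noise_level") <- noise
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Run the full preprocessing chain on one spectrum
#'
#' Applies, in order: blank subtraction (if a blank is supplied), the
#' signal-to-noise filter, base-peak normalization, and the
#' relative-intensity filter. Normalizing after subtraction guarantees
#' the base peak is a sample peak, not a contaminant.
#'
#' @param sample Peak tibble.
#' @param blank Optional paired blank peak tibble.
#' @param config A [preprocess_config()].
#' @return Preprocessed peak tibble with attribute `preprocess_report`, a
#'   named list of per-stage removal counts and the noise estimate.
#' @export
preprocess_spectrum <- function(sample, blank = NULL,
                                config = preprocess_config()) {
  rep <- list(n_in = nrow(sample))
  if (!is.null(blank)) {
    sample <- subtract_blank(sample, blank, config)
    rep$n_blank_removed <- attr(sample, "n_removed")
  } else {
    rep$n_blank_removed <- NA_integer_
  }
  sample <- filter_snr(sample, config)
  rep$noise_level <- attr(sample, "noise_level") %||% NA_real_
  rep$n_snr_removed <- attr(sample, "n_removed")
  if (nrow(sample) > 0L) {
    sample <- normalize_intensity(sample)
    n0 <- nrow(sample)
    sample <- filter_rel_intensity(sample, config$rel_intensity_min_pct)
    rep$n_rel_removed <- n0 - nrow(sample)
  } else {
    rep$n_rel_removed <- 0L
  }
  rep$n_out <- nrow(sample)
  attr(sample, "preprocess_report") <- rep
  sample
}

#' Preprocess every spectrum of a loaded dataset
#'
#' Maps [preprocess_spectrum()] over the rows of a [load_dataset()]
#' tibble, pairing each sample with its matched blank. Blank rows are
#' passed through untouched.
#'
#' @param dataset Tibble from [load_dataset()].
#' @param config A [preprocess_config()].
#' @return The dataset with `peaks` replaced by preprocessed peaks and an
#'   `n_peaks` column updated; per-stage removal counts are added as
#'   columns `n_blank_removed`, `n_snr_removed`, `n_rel_removed`.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  stopifnot(is.data.frame(dataset), "peaks" %in% names(dataset))
  out <- dataset
  out$n_blank_removed <- NA_integer_
  out$n_snr_removed <- NA_integer_
  out$n_rel_removed <- NA_integer_
  for (i in seq_len(nrow(out))) {
    if (isTRUE(out$is_blank[i])) next
    blank <- if (!is.na(out$blank_row[i])) dataset$peaks[[out$blank_row[i]]]
    pk <- preprocess_spectrum(dataset$peaks[[i]], blank, config)
    rep <- attr(pk, "preprocess_report")
    out$peaks[[i]] <- pk
    out$n_blank_removed[i] <- rep$n_blank_removed
    out$n_snr_removed[i] <- rep$n_snr_removed
    out$n_rel_removed[i] <- rep$n_rel_removed
  }
  out$n_peaks <- vapply(out$peaks, nrow, 1L)
  out
}
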