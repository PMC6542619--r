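#' Multichannel signal epoch
#'
#' @param samples numeric matrix, channels in rows, time samples in columns.
#' @param sampling_rate sampling frequency in Hz.
#' @param channels optional channel labels (default row names or `"ch1"...`).
#' @return an object of class `"signal_epoch"`.
#' @export
signal_epoch <- function(samples, sampling_rate, channels = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop("an epoch needs at least 2 channels")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("'sampling_rate' must be a positive frequency in Hz")
  if (is.null(channels)) {
    channels <- rownames(samples)
    if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(samples)))
  }
  rownames(samples) <- channels
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channels = channels),
            class = "signal_epoch")
}

#' Frequency band definition
#'
#' @param name band label.
#' @param low,high inclusive band limits in Hz, `low < high`.
#' @return an object of class `"band_definition"`.
#' @export
band_definition <- function(name, low, high) {
  if (low >= high) stop("band '", name, "': 'low' must be below 'high'")
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Default MEG frequency bands
#'
#' The seven bands used for band-averaged coherence connectivity:
#' delta 2-4, theta 4.5-7.5, alpha1 8-10.5, alpha2 11-13, beta1 13.5-20,
#' beta2 20.5-29.5 and gamma 30-45 Hz (inclusive limits; the small gaps
#' between printed band edges are left unassigned).
#'
#' @return a named list of [band_definition()] objects.
#' @export
meg_bands <- function() {
  defs <- list(
    delta  = c(2, 4),    theta = c(4.5, 7.5), alpha1 = c(8, 10.5),
    alpha2 = c(11, 13),  beta1 = c(13.5, 20), beta2  = c(20.5, 29.5),
    gamma  = c(30, 45))
  out <- lapply(names(defs), function(nm)
    band_definition(nm, defs[[nm]][1L], defs[[nm]][2L]))
  names(out) <- names(defs)
  out
}

#' Welch magnitude-squared coherence spectrum
#'
#' Estimates the channel-by-channel magnitude-squared coherence
#' `|S_xy|^2 / (S_xx * S_yy)` from Hanning-windowed overlapping segments
#' (Welch cross-/auto-spectra averaging). Defaults follow the MEG
#' connectivity settings: 2-s sliding Hanning windows with 25% overlap and
#' an FFT length giving 0.5 Hz resolution (NFFT = 2000 at 1000 Hz;
#' other sampling rates rescale NFFT to keep the 0.5 Hz grid, with a
#' warning). Frequencies from 2 to 45 Hz inclusive are returned.
#'
#' @param epoch a [signal_epoch()] or channels-by-samples numeric matrix.
#' @param sampling_rate required when `epoch` is a bare matrix.
#' @param window_s segment length in seconds.
#' @param overlap fractional segment overlap in `[0, 1)`.
#' @param nfft FFT length (zero-padded); default `2 * sampling_rate`.
#' @param fmin,fmax inclusive frequency range in Hz.
#' @return an object of class `"coherence_stack"`: list with `coh`
#'   (`C x C x n_freq` array, symmetric, unit diagonal, values in [0, 1]),
#'   `freqs` and `channels`.
#' @export
coherence_spectrum <- function(epoch, sampling_rate = NULL, window_s = 2,
                               overlap = 0.25, nfft = NULL,
                               fmin = 2, fmax = 45) {
  if (inherits(epoch, "signal_epoch")) {
    x <- epoch$samples
    fs <- epoch$sampling_rate
    channels <- epoch$channels
  } else {
    x <- as.matrix(epoch)
    if (is.null(sampling_rate))
      stop("'sampling_rate' is required for a bare matrix")
    fs <- sampling_rate
    channels <- rownames(x)
    if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(x)))
  }
  C <- nrow(x)
  nsamp <- ncol(x)
  win <- floor(window_s * fs)
  if (win < 4L) stop("window too short at this sampling rate")
  step <- win - floor(overlap * win)
  nseg <- floor((nsamp - win) / step) + 1L
  if (nsamp < win || nseg < 2L)
    stop("epoch too short: need at least ", (win + step) / fs,
         " s (2 windows of ", window_s, " s at ", overlap * 100,
         "% overlap), got ", nsamp / fs, " s")
  if (is.null(nfft)) {
    nfft <- as.integer(round(2 * fs))  # 0.5 Hz resolution
    if (fs != 1000)
      warning("sampling rate is ", fs,
              " Hz; NFFT rescaled to ", nfft, " to keep 0.5 Hz resolution")
  }
  if (nfft < win) stop("'nfft' must be at least the window length")
  han <- 0.5 - 0.5 * cos(2 * pi * seq(0L, win - 1L) / (win - 1L))
  freqs_all <- (seq_len(nfft) - 1L) * fs / nfft
  freqs <- seq(fmin, fmax, by = 0.5)
  fidx <- vapply(freqs, function(f) {
    i <- which.min(abs(freqs_all - f))
    if (abs(freqs_all[i] - f) > 1e-6)
      stop("frequency ", f, " Hz not on the FFT grid")
    i
  }, integer(1))
  nf <- length(freqs)
  # segment FFTs: nf x nseg per channel
  Fc <- vector("list", C)
  for (ch in seq_len(C)) {
    seg <- matrix(0, nfft, nseg)
    for (s in seq_len(nseg)) {
      i0 <- (s - 1L) * step
      seg[seq_len(win), s] <- x[ch, i0 + seq_len(win)] * han
    }
    Fc[[ch]] <- stats::mvfft(seg)[fidx, , drop = FALSE]
  }
  auto <- vapply(Fc, function(Z) rowMeans(Mod(Z)^2), numeric(nf))
  coh <- array(0, dim = c(C, C, nf),
               dimnames = list(channels, channels, NULL))
  for (i in seq_len(C)) {
    coh[i, i, ] <- 1
    if (i < C) for (j in (i + 1L):C) {
      Sxy <- rowMeans(Fc[[i]] * Conj(Fc[[j]]))
      msc <- Mod(Sxy)^2 / (auto[, i] * auto[, j])
      msc[!is.finite(msc)] <- 0
      msc <- pmin(1, pmax(0, msc))
      coh[i, j, ] <- msc
      coh[j, i, ] <- msc
    }
  }
  structure(list(coh = coh, freqs = freqs, channels = channels,
                 n_segments = nseg),
            class = "coherence_stack")
}

#' Band-average a coherence stack
#'
#' Arithmetic mean of the per-frequency coherence matrices over the bins
#' whose center frequency falls in `[low, high]` (inclusive).
#'
#' @param stack a `"coherence_stack"` object.
#' @param bands a list of [band_definition()]s (default [meg_bands()]).
#' @return a named list of channel-by-channel matrices, one per band.
#' @export
band_average <- function(stack, bands = meg_bands()) {
  stopifnot(inherits(stack, "coherence_stack"))
  if (inherits(bands, "band_definition")) bands <- list(bands)
  out <- vector("list", length(bands))
  nms <- character(length(bands))
  for (b in seq_along(bands)) {
    bd <- bands[[b]]
    stopifnot(inherits(bd, "band_definition"))
    sel <- which(stack$freqs >= bd$low & stack$freqs <= bd$high)
    if (!length(sel))
      stop("band '", bd$name, "' [", bd$low, ", ", bd$high,
           "] contains no frequency bin")
    Wb <- apply(stack$coh[, , sel, drop = FALSE], c(1L, 2L), mean)
    dimnames(Wb) <- list(stack$channels, stack$channels)
    out[[b]] <- Wb
    nms[b] <- bd$name
  }
  names(out) <- nms
  out
}

#' Average band matrices across epochs
#'
#' Elementwise mean of per-band connectivity matrices computed on several
#' epochs of the same recording, for a more robust single-subject estimate.
#'
#' @param epoch_bands a list (one element per epoch) of named band-matrix
#'   lists as returned by [band_average()].
#' @return a named list of averaged matrices.
#' @export
epoch_average <- function(epoch_bands) {
  if (!length(epoch_bands)) stop("no epochs supplied")
  ref <- epoch_bands[[1L]]
  nms <- names(ref)
  chans <- rownames(ref[[1L]])
  for (e in epoch_bands) {
    if (!identical(names(e), nms))
      stop("epochs disagree on band names")
    if (!identical(rownames(e[[1L]]), chans))
      stop("epochs disagree on channel sets")
  }
  out <- lapply(nms, function(b)
    Reduce(`+`, lapply(epoch_bands, `[[`, b)) / length(epoch_bands))
  names(out) <- nms
  out
}
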