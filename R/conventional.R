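#' Welch power spectral density
#'
#' Segment-averaged periodogram: the series is split into
#' `segment_s`-second segments with fractional `overlap`, each segment is
#' mean-removed, tapered, and its one-sided periodogram averaged across
#' segments. Power is normalized so that the sum over bins times the bin
#' width approximates the signal variance.
#'
#' @param x numeric vector (single channel).
#' @param fs sampling rate in Hz.
#' @param segment_s segment length in seconds (default 2).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param taper `"hann"` (default) or `"rect"`.
#' @return list with `freq_hz` and `power` (non-negative, one value per
#'   frequency bin in `[0, fs/2]`).
#' @export
welch_psd <- function(x, fs, segment_s = 2, overlap = 0.5,
                      taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  L <- round(segment_s * fs)
  if (L < 4L) stop("segment too short")
  if (length(x) < L) stop("signal shorter than one segment")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / (L - 1L))
       else rep(1, L)
  u <- sum(w^2)
  nfreq <- floor(L / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (u * fs)
    p <- p[seq_len(nfreq)]
    # fold two-sided power into one-sided (interior bins doubled)
    if (L %% 2 == 0) p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
    else p[2:nfreq] <- 2 * p[2:nfreq]
    acc <- acc + p
  }
  list(freq_hz = (seq_len(nfreq) - 1L) * fs / L, power = acc / length(starts))
}

in_band <- function(freq, band) freq >= band[1] & freq <= band[2]

#' Spectral edge frequency
#'
#' Smallest frequency below which at least `quantile` of the in-band
#' spectral power lies (SEF95 by default).
#'
#' @param x numeric vector (single channel window).
#' @param fs sampling rate in Hz.
#' @param quantile power quantile in (0, 1] (default 0.95).
#' @param band frequency band `[low, high]` in Hz within `[0, fs/2]`.
#' @param ... passed to [welch_psd()].
#' @return frequency in Hz.
#' @export
sef <- function(x, fs, quantile = 0.95, band = c(0, fs / 2), ...) {
  if (band[1] < 0 || band[2] > fs / 2 || band[1] >= band[2])
    stop("band must lie within [0, fs/2]")
  ps <- welch_psd(x, fs, ...)
  sel <- in_band(ps$freq_hz, band)
  p <- ps$power[sel]; f <- ps$freq_hz[sel]
  tot <- sum(p)
  if (tot <= 0) stop("zero in-band power")
  f[which(cumsum(p) >= quantile * tot)[1L]]
}

#' Band-limited spectral entropy
#'
#' Shannon entropy of the normalized in-band power distribution, divided
#' by `ln` of the number of in-band bins so the value lies in `[0, 1]`
#' (1 = flat spectrum, 0 = single-bin tone). The 0.8-47 Hz default band
#' is the conventional EEG depth-of-anesthesia choice.
#'
#' @inheritParams sef
#' @param band frequency band in Hz (default `c(0.8, 47)`).
#' @return spectral entropy in `[0, 1]`.
#' @export
spectral_entropy <- function(x, fs, band = c(0.8, 47), ...) {
  if (band[1] < 0 || band[2] > fs / 2 || band[1] >= band[2])
    stop("band must lie within [0, fs/2]")
  ps <- welch_psd(x, fs, ...)
  p <- ps$power[in_band(ps$freq_hz, band)]
  tot <- sum(p)
  if (tot <= 0) stop("zero in-band power")
  p <- p / tot
  nz <- p > 0
  H <- -sum(p[nz] * log(p[nz]))
  H / log(length(p))
}

# segment-averaged bispectrum on the f1 <= f2 triangle:
# B(f1,f2) = mean_k X_k(f1) X_k(f2) conj(X_k(f1+f2)); returns magnitude and
# the pair/sum frequencies. Rectangular taper, non-overlapping segments.
bispectrum_mag <- function(x, fs, segment_s = 2) {
  L <- round(segment_s * fs)
  if (length(x) < L) stop("window too short for bispectral averaging")
  n_seg <- floor(length(x) / L)
  half <- floor(L / 2)
  acc <- NULL
  for (k in seq_len(n_seg)) {
    seg <- x[((k - 1L) * L + 1L):(k * L)]
    X <- stats::fft(seg - mean(seg))
    if (is.null(acc)) {
      i1 <- rep(1:half, times = half) ; i2 <- rep(1:half, each = half)
      keep <- i1 <= i2 & (i1 + i2) <= half
      i1 <- i1[keep]; i2 <- i2[keep]
      acc <- complex(length(i1))
    }
    acc <- acc + X[i1 + 1L] * X[i2 + 1L] * Conj(X[i1 + i2 + 1L])
  }
  df <- fs / L
  list(f1 = i1 * df, f2 = i2 * df, fsum = (i1 + i2) * df,
       mag = Mod(acc) / n_seg)
}

#' Synch fast slow (SFS)
#'
#' Bispectral depth-of-anesthesia comparator: `log10` of the summed
#' bispectral magnitude over the region whose pair-sum frequency falls in
#' the fast band (40-47 Hz) divided by the sum over the full band
#' (0.5-47 Hz). Scale-invariant (the cubic amplitude factor cancels in the
#' ratio). The bispectrum is estimated by segment-averaged frequency
#' triple products over non-overlapping `segment_s`-second segments.
#'
#' @inheritParams sef
#' @param fast_band numerator band in Hz (default `c(40, 47)`).
#' @param full_band denominator band in Hz (default `c(0.5, 47)`).
#' @param segment_s bispectrum segment length in seconds (default 2);
#'   the window must be at least 4 s for averaging.
#' @return SFS value (log10 ratio, dimensionless; <= 0 when the fast band
#'   is inside the full band).
#' @export
sfs <- function(x, fs, fast_band = c(40, 47), full_band = c(0.5, 47),
                segment_s = 2) {
  if (length(x) / fs < 4) stop("window must be at least 4 s for SFS")
  b <- bispectrum_mag(x, fs, segment_s)
  num <- sum(b$mag[b$fsum >= fast_band[1] & b$fsum <= fast_band[2]])
  den <- sum(b$mag[b$fsum >= full_band[1] & b$fsum <= full_band[2]])
  if (den <= 0) stop("zero bispectral power in the full band")
  log10(num / den)
}
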