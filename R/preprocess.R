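#' Detect active gesture segments by multi-channel energy thresholding
#'
#' Computes the instantaneous multi-channel energy
#' \deqn{S(n) = \sum_c (x_c(n) - \bar x_c)^2}
#' where \eqn{\bar x_c} is the channel's resting mean, smooths it with a
#' short moving average, and returns the maximal runs where the smoothed
#' energy is at least `th_fraction` of its peak. Runs shorter than
#' `min_duration_ms` are discarded as debounce.
#'
#' @param rec A `semg_recording`, or a numeric C x T matrix (then `fs` must
#'   be given).
#' @param baseline_means Numeric vector, one resting-average per channel. If
#'   `NULL`, estimated from the first 0.5 s of the recording.
#' @param th_fraction Threshold as a fraction of the peak smoothed energy
#'   (default 0.15, i.e. 15% of peak energy).
#' @param fs Sampling rate in Hz (taken from `rec` when it is a recording).
#' @param smooth_ms Moving-average length for the energy trace, in ms.
#' @param min_duration_ms Minimum segment duration in ms.
#' @param min_peak_ratio Activity floor: the peak smoothed energy must
#'   exceed `min_peak_ratio` times the mean smoothed energy of the baseline
#'   window (the first 0.5 s, assumed resting), otherwise the record is
#'   considered rest-only and no segments are returned. A fraction-of-peak
#'   threshold alone would mark an arbitrary stretch of a pure-noise record
#'   as active.
#' @return A data.frame with columns `start` (0-based, inclusive), `end`
#'   (exclusive) and `peak_energy` (maximum smoothed energy inside the
#'   segment), sorted and non-overlapping. Zero rows when the energy never
#'   reaches the threshold or is identically zero.
#' @export
detect_active_segments <- function(rec, baseline_means = NULL,
                                   th_fraction = 0.15, fs = NULL,
                                   smooth_ms = 64, min_duration_ms = 100,
                                   min_peak_ratio = 5) {
  x <- if (inherits(rec, "semg_recording")) rec$semg else as.matrix(rec)
  if (inherits(rec, "semg_recording")) fs <- rec$fs
  if (is.null(fs)) stop_config("fs is required when rec is a plain matrix")
  C <- nrow(x); T <- ncol(x)
  if (is.null(baseline_means)) {
    n0 <- max(1L, min(T, as.integer(round(0.5 * fs))))
    baseline_means <- rowMeans(x[, seq_len(n0), drop = FALSE])
  }
  if (length(baseline_means) != C) {
    stop_dim("baseline_means has %d entries but recording has %d channels",
             length(baseline_means), C)
  }
  S <- colSums((x - baseline_means)^2)
  win <- max(1L, as.integer(round(smooth_ms / 1000 * fs)))
  Ssm <- as.numeric(stats::filter(S, rep(1 / win, win), sides = 2))
  # moving average leaves NAs at the edges; extend the nearest smoothed value
  ok <- which(!is.na(Ssm))
  if (length(ok)) {
    Ssm[seq_len(ok[1] - 1L)] <- Ssm[ok[1]]
    n_ok <- ok[length(ok)]
    if (n_ok < T) Ssm[(n_ok + 1L):T] <- Ssm[n_ok]
  } else {
    Ssm <- S
  }
  peak <- max(Ssm)
  empty <- data.frame(start = integer(0), end = integer(0),
                      peak_energy = numeric(0))
  if (peak <= 0) return(empty)
  floor_win <- max(1L, min(T, as.integer(round(0.5 * fs))))
  if (peak < min_peak_ratio * mean(Ssm[seq_len(floor_win)])) return(empty)
  th <- th_fraction * peak
  above <- Ssm >= th
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(empty)
  min_len <- as.integer(round(min_duration_ms / 1000 * fs))
  segs <- data.frame(start = starts[keep] - 1L, end = ends[keep])
  segs <- segs[segs$end - segs$start >= min_len, , drop = FALSE]
  if (!nrow(segs)) return(empty)
  segs$peak_energy <- vapply(seq_len(nrow(segs)), function(i) {
    max(Ssm[(segs$start[i] + 1L):segs$end[i]])
  }, numeric(1))
  rownames(segs) <- NULL
  segs
}

# RBJ biquad notch coefficients at centre frequency f (Hz) and quality Q.
notch_biquad <- function(f, fs, Q) {
  w0 <- 2 * pi * f / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

comb_sections <- function(fs, f0, order, Q) {
  ks <- seq_len(order)
  ks <- ks[f0 * ks < fs / 2]
  lapply(ks, function(k) notch_biquad(f0 * k, fs, Q))
}

#' Power-line comb filter
#'
#' Removes mains interference with a cascade of IIR notch filters at the
#' fundamental `f0` and its integer multiples (up to `order` notches, capped
#' below the Nyquist frequency). Each notch is a biquad of quality factor
#' `Q`, so the passband between notches is essentially untouched.
#'
#' @param x Numeric vector, or C x T matrix filtered row-wise.
#' @param fs Sampling rate in Hz.
#' @param f0 Fundamental notch frequency in Hz (default 50).
#' @param order Number of notch frequencies `f0 * k`, `k = 1..order`
#'   (default 20; notches at or above Nyquist are dropped).
#' @param Q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @return Filtered signal with the same shape as `x`.
#' @export
comb_filter <- function(x, fs, f0 = 50, order = 20, Q = 35) {
  if (f0 >= fs / 2) stop_config("f0 = %g must be below Nyquist %g", f0, fs / 2)
  secs <- comb_sections(fs, f0, order, Q)
  filt1 <- function(v) {
    # reflected warm-up pad absorbs the IIR startup transient (the notch
    # ring-down lasts ~2Q/(2*pi*f0) seconds)
    npad <- min(length(v), as.integer(ceiling(0.5 * fs)))
    vp <- c(rev(v[seq_len(npad)]), v)
    for (s in secs) vp <- as.numeric(signal::filter(s$b, s$a, vp))
    vp[npad + seq_along(v)]
  }
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(as.numeric(x))
}

#' @rdname comb_filter
#' @param freqs Frequencies (Hz) at which to evaluate the filter's magnitude
#'   response.
#' @return `comb_response` returns `|H(f)|` at `freqs`, computed analytically
#'   from the cascade's transfer function.
#' @export
comb_response <- function(freqs, fs, f0 = 50, order = 20, Q = 35) {
  secs <- comb_sections(fs, f0, order, Q)
  z <- exp(-1i * 2 * pi * freqs / fs)
  H <- rep(1 + 0i, length(freqs))
  for (s in secs) {
    H <- H * (s$b[1] + s$b[2] * z + s$b[3] * z^2) /
      (s$a[1] + s$a[2] * z + s$a[3] * z^2)
  }
  Mod(H)
}

# ---------------------------------------------------------------------------
# Orthogonal discrete wavelet transform (periodized) with the coif5 basis.
# The 30-tap coif5 scaling filter; the wavelet filter follows by quadrature
# mirror construction. Frozen to full double precision.
COIF5_DEC_LO <- c(
  -9.604010112767894e-08, -1.6237995172048338e-07, 2.0612203985788783e-06,
  3.7007277113394796e-06, -2.1270221672515614e-05, -4.12198619242655e-05,
  1.4035632812373243e-04, 3.018579416682448e-04, -6.375589261258812e-04,
  -1.6616273039298788e-03, 2.4315754425382886e-03, 6.761520220620417e-03,
  -9.159507338676163e-03, -1.9758391600965465e-02, 3.2674799467057355e-02,
  4.1287530472117834e-02, -1.0556315130733723e-01, -6.203775157498196e-02,
  4.379823066591634e-01, 7.742936228603274e-01, 4.2157126673075435e-01,
  -5.2046670253554764e-02, -9.192158806008609e-02, 2.8169744270532353e-02,
  2.3408322118927783e-02, -1.0131584846900276e-02, -4.15931262757864e-03,
  2.1782943778456947e-03, 3.585777411617577e-04, -2.12081862067494e-04)

wavelet_filters <- function(basis = "coif5") {
  if (!identical(basis, "coif5")) {
    stop_config("unknown wavelet basis '%s' (only 'coif5' is provided)", basis)
  }
  lo <- COIF5_DEC_LO
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  list(lo = lo, hi = hi, len = L)
}

# One periodized analysis step: x (n x C matrix, n even) -> list(a, d),
# each (n/2 x C). Circular convolution with the analysis filters followed by
# dyadic downsampling.
dwt_step <- function(x, filt) {
  n <- nrow(x)
  half <- n / 2
  a <- matrix(0, half, ncol(x))
  d <- matrix(0, half, ncol(x))
  base <- seq(1L, n, by = 2L)
  for (m in seq_len(filt$len)) {
    rows <- ((base - 1L + m - 1L) %% n) + 1L
    xr <- x[rows, , drop = FALSE]
    a <- a + filt$lo[m] * xr
    d <- d + filt$hi[m] * xr
  }
  list(a = a, d = d)
}

# Inverse of dwt_step (exact for the periodized orthogonal transform).
idwt_step <- function(a, d, filt) {
  half <- nrow(a)
  n <- 2L * half
  x <- matrix(0, n, ncol(a))
  base <- seq(1L, n, by = 2L)
  for (m in seq_len(filt$len)) {
    rows <- ((base - 1L + m - 1L) %% n) + 1L
    x[rows, ] <- x[rows, , drop = FALSE] + filt$lo[m] * a + filt$hi[m] * d
  }
  x
}

max_dwt_level <- function(n) max(0L, floor(log2(n)))

#' Periodized multilevel wavelet decomposition and reconstruction
#'
#' Orthogonal DWT with periodic boundary handling: the transform is exactly
#' invertible (machine precision) for signal lengths divisible by
#' `2^level`. Columns of a matrix input are transformed independently.
#'
#' @param x Numeric vector or T x C matrix (signals in columns).
#' @param level Decomposition depth.
#' @param basis Wavelet family name (only `"coif5"` is built in).
#' @return `wavelet_dec` returns a list with `approx` (coarsest
#'   approximation) and `details` (list of detail coefficient matrices,
#'   finest first). `wavelet_rec` inverts it.
#' @export
wavelet_dec <- function(x, level, basis = "coif5") {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  n <- nrow(xm)
  if (level < 1) stop_config("level must be >= 1")
  if (n %% (2^level) != 0) {
    stop_config("signal length %d is not divisible by 2^level = %d",
                n, 2^level)
  }
  filt <- wavelet_filters(basis)
  details <- vector("list", level)
  a <- xm
  for (l in seq_len(level)) {
    st <- dwt_step(a, filt)
    a <- st$a
    details[[l]] <- st$d
  }
  list(approx = a, details = details, level = level, basis = basis,
       vector_input = vec)
}

#' @rdname wavelet_dec
#' @param dec A decomposition returned by `wavelet_dec`.
#' @export
wavelet_rec <- function(dec) {
  filt <- wavelet_filters(dec$basis)
  a <- dec$approx
  for (l in rev(seq_len(dec$level))) {
    a <- idwt_step(a, dec$details[[l]], filt)
  }
  if (isTRUE(dec$vector_input)) as.numeric(a) else a
}

#' Hard threshold kernel
#'
#' Sets coefficients with `|w| < lambda` to zero and keeps the rest
#' unchanged.
#'
#' @param w Numeric vector/matrix of coefficients.
#' @param lambda Threshold (>= 0).
#' @export
hard_threshold <- function(w, lambda) {
  w[abs(w) < lambda] <- 0
  w
}

#' Stein unbiased-risk (SURE) threshold
#'
#' Selects the threshold minimising Stein's unbiased estimate of risk for
#' coefficients `d` with unit noise scale (the `rigrsure` rule). Returns a
#' threshold on the scale of `d`.
#'
#' @param d Numeric coefficient vector, assumed noise standard deviation 1.
#' @export
sure_threshold <- function(d) {
  n <- length(d)
  if (n == 0) return(0)
  s <- sort(d^2)
  ks <- seq_len(n)
  risk <- (n - 2 * ks + cumsum(s) + (n - ks) * s) / n
  sqrt(s[which.min(risk)])
}

#' Wavelet denoising configuration
#'
#' @param basis Wavelet family (default `"coif5"`).
#' @param level Decomposition depth, or `NULL` for `min(5, max admissible)`.
#' @param threshold_rule `"sure"` (Stein unbiased risk) or `"none"`.
#' @param mode Thresholding mode; only `"hard"` is provided.
#' @export
denoise_config <- function(basis = "coif5", level = NULL,
                           threshold_rule = c("sure", "none"),
                           mode = "hard") {
  threshold_rule <- match.arg(threshold_rule)
  if (!identical(mode, "hard")) stop_config("only hard thresholding is provided")
  wavelet_filters(basis)  # validates the basis name
  structure(list(basis = basis, level = level,
                 threshold_rule = threshold_rule, mode = mode),
            class = "semg_denoise_config")
}

#' Wavelet denoising by hard thresholding of detail coefficients
#'
#' Per channel: multilevel periodized DWT with the configured basis, hard
#' thresholding of every detail level at a SURE-selected threshold (noise
#' scale estimated as `MAD(finest details)/0.6745`), then reconstruction.
#' Signals whose length is not divisible by `2^level` are padded at the end
#' by reflection and trimmed after reconstruction.
#'
#' @param x Numeric vector or C x T matrix (channels in rows).
#' @param cfg A [denoise_config()].
#' @return Denoised signal, same shape as `x`.
#' @export
wavelet_denoise <- function(x, cfg = denoise_config()) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  T <- ncol(xm)
  level <- cfg$level %||% min(5L, max(1L, max_dwt_level(T) - 3L))
  if (level < 1) stop_config("signal too short for wavelet denoising")
  block <- 2^level
  pad <- (block - T %% block) %% block
  if (T + pad < block) pad <- block - T
  xp <- if (pad > 0) {
    cbind(xm, xm[, T - seq_len(pad) + 1L, drop = FALSE])
  } else xm
  dec <- wavelet_dec(t(xp), level, cfg$basis)
  if (identical(cfg$threshold_rule, "sure")) {
    d1 <- dec$details[[1]]
    sigma <- apply(d1, 2, function(v) stats::mad(v, constant = 1) / 0.6745)
    sigma[sigma == 0] <- .Machine$double.eps
    for (l in seq_len(level)) {
      for (ch in seq_len(ncol(d1))) {
        d <- dec$details[[l]][, ch]
        lam <- sigma[ch] * sure_threshold(d / sigma[ch])
        dec$details[[l]][, ch] <- hard_threshold(d, lam)
      }
    }
  }
  out <- t(wavelet_rec(dec))[, seq_len(T), drop = FALSE]
  if (vec) as.numeric(out) else out
}

#' Condition a recording: comb filtering then wavelet denoising
#'
#' Convenience wrapper applying [comb_filter()] and [wavelet_denoise()] to
#' the sEMG channels of a recording.
#'
#' @param rec A `semg_recording`.
#' @param f0,order,Q Comb filter parameters, see [comb_filter()].
#' @param denoise A [denoise_config()], or `NULL` to skip denoising.
#' @return The recording with conditioned `semg`.
#' @export
preprocess_recording <- function(rec, f0 = 50, order = 20, Q = 35,
                                 denoise = denoise_config()) {
  stopifnot(inherits(rec, "semg_recording"))
  x <- comb_filter(rec$semg, rec$fs, f0 = f0, order = order, Q = Q)
  if (!is.null(denoise)) x <- wavelet_denoise(x, denoise)
  rec$semg <- x
  rec
}
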