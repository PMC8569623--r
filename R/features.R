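#' Slice a multichannel signal into sliding windows (sEMG images)
#'
#' Converts a C x T signal into a sequence of channel-by-time windows, the
#' "sEMG images" fed to the recognition network. Windows start at
#' `0, stride, 2*stride, ...`; the trailing remainder that does not fill a
#' whole window is dropped.
#'
#' @param x Numeric C x T matrix.
#' @param window_len Window length L in samples.
#' @param stride Step between window starts in samples.
#' @return A list of `emg_image` objects: C x L matrices with attributes
#'   `t0` (0-based start sample), `window_len` and `stride`.
#' @export
window_signal <- function(x, window_len, stride) {
  x <- as.matrix(x)
  T <- ncol(x)
  if (window_len > T) stop_config("window_len %d exceeds signal length %d",
                                  window_len, T)
  if (window_len < 2) stop_config("window_len must be >= 2")
  if (stride < 1) stop_config("stride must be >= 1")
  starts <- seq(0L, T - window_len, by = stride)
  lapply(starts, function(t0) {
    w <- x[, (t0 + 1L):(t0 + window_len), drop = FALSE]
    structure(w, t0 = t0, window_len = window_len, stride = stride,
              class = c("emg_image", "matrix", "array"))
  })
}

#' Time-domain and spectral features of an sEMG window
#'
#' The four per-channel descriptors used to build feature images:
#' mean absolute value (MAV), low/high band power ratio (FR), median
#' frequency (MDF) and mean spectral power (MNP).
#'
#' @param x Numeric vector (one channel of one window).
#' @return `mean_absolute_value`: \eqn{(1/K)\sum_i |x_i|}.
#' @export
mean_absolute_value <- function(x) {
  if (length(x) < 1) stop_config("empty input")
  mean(abs(x))
}

#' One-sided periodogram with Parseval-consistent scaling
#'
#' Power spectrum of a length-K signal on the discrete frequency grid
#' `0, fs/K, ..., fs/2`, scaled so that `sum(P)` equals the time-domain mean
#' square `mean(x^2)`.
#'
#' @param x Numeric vector, length >= 2.
#' @param fs Sampling rate in Hz.
#' @return A list with `freqs` (length `floor(K/2)+1`) and `P` (same length).
#' @export
power_spectrum <- function(x, fs) {
  K <- length(x)
  if (K < 2) stop_config("need at least 2 samples")
  X <- stats::fft(x)
  M <- K %/% 2 + 1L
  P <- Mod(X[seq_len(M)])^2 / K^2
  # double the interior bins (their conjugate halves carry equal power)
  interior <- seq(2L, M - 1L + (K %% 2L))
  if (length(interior)) P[interior] <- 2 * P[interior]
  list(freqs = (seq_len(M) - 1) * fs / K, P = P)
}

#' @rdname mean_absolute_value
#' @param P One-sided power spectrum values.
#' @param freqs Frequencies corresponding to `P`, in Hz.
#' @param LLC,LHC Lower/upper cut-off of the low-frequency band (Hz).
#' @param HLC,HHC Lower/upper cut-off of the high-frequency band (Hz).
#' @return `frequency_ratio`: low-band power over high-band power. When the
#'   high band carries zero power the `+Inf` sentinel is returned with a
#'   warning (never an error, so batch extraction proceeds).
#' @export
frequency_ratio <- function(P, freqs, LLC, LHC, HLC, HHC) {
  if (!(LLC < LHC && LHC <= HLC && HLC < HHC)) {
    stop_config("band edges must satisfy LLC < LHC <= HLC < HHC")
  }
  low <- sum(P[freqs >= LLC & freqs <= LHC])
  high <- sum(P[freqs >= HLC & freqs <= HHC])
  if (high == 0) {
    warning("zero high-band power; frequency ratio is +Inf")
    return(Inf)
  }
  low / high
}

#' @rdname mean_absolute_value
#' @return `median_frequency`: the smallest grid frequency at which the
#'   cumulative power first reaches half the total power.
#' @export
median_frequency <- function(P, freqs) {
  tot <- sum(P)
  if (tot <= 0) stop_config("median frequency undefined for all-zero spectrum")
  freqs[which(cumsum(P) >= tot / 2)[1]]
}

#' @rdname mean_absolute_value
#' @return `mean_power`: the average of the spectral power values.
#' @export
mean_power <- function(P) {
  if (length(P) < 1) stop_config("empty spectrum")
  mean(P)
}

#' Frequency-band configuration for the FR feature
#'
#' Default bands 20--45 Hz (low) and 95--450 Hz (high), skipping the mains
#' notch region around 50 Hz and its first harmonic.
#'
#' @param LLC,LHC,HLC,HHC Band edges in Hz.
#' @export
band_config <- function(LLC = 20, LHC = 45, HLC = 95, HHC = 450) {
  list(LLC = LLC, LHC = LHC, HLC = HLC, HHC = HHC)
}

#' Build a 4 x C feature image from an sEMG window
#'
#' Computes MAV, FR, MDF and MNP per channel (rows in that order). With
#' `norm_stats` (per-feature mean/sd estimated on a training split) the rows
#' are z-normalised; `+Inf` FR sentinels are mapped to the largest finite
#' normalised value in their row.
#'
#' @param window An `emg_image` (C x L matrix).
#' @param fs Sampling rate in Hz.
#' @param band_cfg A [band_config()].
#' @param norm_stats Optional list with `mean` and `sd`, each length 4.
#' @return A 4 x C matrix of class `feature_image` with
#'   `rownames(c("MAV","FR","MDF","MNP"))`.
#' @export
build_feature_image <- function(window, fs, band_cfg = band_config(),
                                norm_stats = NULL) {
  x <- as.matrix(window)
  C <- nrow(x)
  out <- matrix(0, 4, C, dimnames = list(c("MAV", "FR", "MDF", "MNP"), NULL))
  for (c in seq_len(C)) {
    v <- x[c, ]
    ps <- power_spectrum(v, fs)
    out["MAV", c] <- mean_absolute_value(v)
    out["FR", c] <- suppressWarnings(
      frequency_ratio(ps$P, ps$freqs, band_cfg$LLC, band_cfg$LHC,
                      band_cfg$HLC, band_cfg$HHC))
    out["MDF", c] <- median_frequency(ps$P, ps$freqs)
    out["MNP", c] <- mean_power(ps$P)
  }
  if (!is.null(norm_stats)) {
    out <- (out - norm_stats$mean) / norm_stats$sd
  }
  if (any(is.infinite(out["FR", ]))) {
    finite <- out["FR", is.finite(out["FR", ])]
    repl <- if (length(finite)) max(finite) else 0
    out["FR", is.infinite(out["FR", ])] <- repl
  }
  structure(out, class = c("feature_image", "matrix", "array"))
}

#' Decompose an image into equal contiguous patches along time
#'
#' Splits a channels x time image into `n` contiguous equal-width slices
#' along the time axis, the per-stream inputs of the multi-stream network.
#' The patches concatenate back to the source image exactly.
#'
#' @param img Numeric matrix (rows = channels/features, columns = time).
#' @param n Number of patches (streams).
#' @return A list of `n` matrices of identical shape.
#' @export
decompose_patches <- function(img, n) {
  img <- as.matrix(img)
  W <- ncol(img)
  if (n < 1) stop_config("n must be >= 1")
  if (W %% n != 0) {
    stop_dim(paste0("time axis length %d is not divisible by n = %d; ",
                    "pad the image by %d columns"), W, n, n - W %% n)
  }
  w <- W %/% n
  lapply(seq_len(n), function(i) img[, ((i - 1) * w + 1):(i * w), drop = FALSE])
}

# Plug-in mutual information (bits) between a continuous feature and class
# labels, after 16-bin quantile discretisation of the feature.
plugin_mutual_information <- function(x, labels, bins = 16) {
  ux <- unique(x)
  if (length(ux) <= 1) return(0)
  if (length(ux) <= bins) {
    # few distinct values: use them as categories directly (quantile breaks
    # on heavily tied data would merge distinct values)
    xb <- match(x, ux)
  } else {
    qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                          type = 7, names = FALSE)
    qs <- unique(qs)
    if (length(qs) < 2) return(0)
    xb <- cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
  }
  tab <- table(xb, labels)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / (px[row(pxy)[nz]] * py[col(pxy)[nz]])))
}

#' Rank features by mutual information with the gesture label
#'
#' Recursive elimination: the feature with the lowest estimated mutual
#' information against the labels is dropped first, repeatedly, until all
#' features are ordered. MI is estimated by the plug-in entropy of a 16-bin
#' quantile discretisation. A constant column has MI 0 and is eliminated
#' first; ties break by column index.
#'
#' @param features Numeric samples x F matrix.
#' @param labels Class labels, one per row.
#' @param k Number of features to keep in the selected set (default `F`).
#' @param bins Number of quantile bins for the MI estimate.
#' @return A list with `mi` (per-feature MI in bits), `elimination_order`
#'   (column indices, first eliminated first) and `selected` (the k
#'   highest-MI columns, in decreasing MI order).
#' @export
rank_features_mutual_information <- function(features, labels, k = NULL,
                                             bins = 16) {
  features <- as.matrix(features)
  F <- ncol(features)
  if (F < 2) stop_config("need at least 2 features")
  if (length(unique(labels)) < 2) stop_config("need at least 2 classes")
  mi <- vapply(seq_len(F), function(j) {
    plugin_mutual_information(features[, j], labels, bins)
  }, numeric(1))
  remaining <- seq_len(F)
  elim <- integer(0)
  while (length(remaining) > 1) {
    worst <- remaining[which.min(mi[remaining])]  # which.min: lowest index tie-break
    elim <- c(elim, worst)
    remaining <- setdiff(remaining, worst)
  }
  elim <- c(elim, remaining)
  k <- k %||% F
  list(mi = mi, elimination_order = elim,
       selected = rev(elim)[seq_len(min(k, F))])
}
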