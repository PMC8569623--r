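# ---------------------------------------------------------------------------
# From recordings to network inputs: conditioning, active-segment windowing,
# image construction, accelerometer summary features, normalisation.
# ---------------------------------------------------------------------------

acc_summary_features <- function(acc, span) {
  a <- acc[, span, drop = FALSE]
  as.numeric(rbind(rowMeans(a),
                   sqrt(rowMeans(a^2)),
                   apply(a, 1, function(v) diff(range(v)))))
}

#' Convert a labelled dataset into network input tensors
#'
#' For each recording: optional conditioning (comb filter + wavelet
#' denoising), active-segment detection (threshold at 15% of peak energy),
#' extraction of `n_windows` windows evenly spaced over the dominant
#' segment, conversion of each window into a raw sEMG image (signed samples
#' decimated along time by `cfg$raw_decimation`, stored time x channels) or
#' a 4 x C feature image, and accelerometer summary features (mean, RMS,
#' range per axis) over the segment. In both representations the columns
#' index electrodes, so the multi-stream patch decomposition assigns each
#' stream its own electrode group (convolution weights are shared across
#' space, but electrode identity matters in sEMG; per-stream weights break
#' that inappropriate translation invariance). Images are z-normalised
#' with statistics estimated on this set,
#' or with `norm_stats` from a training split (so test data never
#' contributes to normalisation).
#'
#' @param dataset A `semg_dataset`.
#' @param cfg A [model_config()] (supplies `mode`, `streams`, `raw_decimation`).
#' @param window_ms,stride_ms Window length and stride in ms (the stride
#'   sets the spacing cap when the segment is long).
#' @param n_windows Number of windows per recording (the temporal sequence
#'   length seen by the ConvLSTM).
#' @param condition Apply [comb_filter()] + [wavelet_denoise()] first.
#' @param band_cfg FR band edges for feature images, see [band_config()].
#' @param norm_stats Normalisation statistics from a previous call (training
#'   split), or `NULL` to estimate from this dataset.
#' @return A list with `emg` (array H x W x n_windows x N), `acc` (N x 9),
#'   `y` (0-based labels), `n_classes` and `norm_stats`.
#' @export
prepare_model_inputs <- function(dataset, cfg, window_ms = 200,
                                 stride_ms = 100, n_windows = 6,
                                 condition = TRUE,
                                 band_cfg = band_config(),
                                 norm_stats = NULL) {
  stopifnot(inherits(dataset, "semg_dataset"))
  fs <- dataset$fs
  L <- as.integer(round(window_ms / 1000 * fs))
  N <- length(dataset$recordings)
  emg_list <- vector("list", N)
  acc_mat <- matrix(0, N, 9L)
  for (i in seq_len(N)) {
    rec <- dataset$recordings[[i]]
    if (condition) rec <- preprocess_recording(rec)
    segs <- detect_active_segments(rec)
    if (nrow(segs)) {
      seg <- segs[which.max(segs$peak_energy), ]
    } else {
      seg <- data.frame(start = 0L, end = ncol(rec$semg))
    }
    lo <- seg$start; hi <- seg$end
    if (hi - lo < L) {  # segment shorter than one window: widen around it
      lo <- max(0L, hi - L); hi <- max(hi, lo + L)
    }
    starts <- round(seq(lo, hi - L, length.out = n_windows))
    imgs <- lapply(starts, function(t0) {
      w <- rec$semg[, (t0 + 1L):(t0 + L), drop = FALSE]
      if (cfg$mode == "raw") {
        # raw sEMG image: signed samples decimated along time, stored as
        # time x channels so that patch decomposition (along columns)
        # assigns each stream its own electrode group
        t(w[, seq(ceiling(cfg$raw_decimation / 2), L,
                  by = cfg$raw_decimation), drop = FALSE])
      } else {
        unclass(build_feature_image(w, fs, band_cfg))
      }
    })
    emg_list[[i]] <- simplify2array(imgs)  # H x W x n_windows
    span <- (seg$start + 1L):seg$end
    acc_mat[i, ] <- acc_summary_features(rec$acc, span)
  }
  emg <- simplify2array(emg_list)  # H x W x n_windows x N
  if (is.null(norm_stats)) {
    norm_stats <- if (cfg$mode == "feature") {
      m <- apply(emg, 1, mean); s <- apply(emg, 1, stats::sd)
      list(mode = "feature", mean = m, sd = pmax(s, 1e-12),
           acc_mean = colMeans(acc_mat),
           acc_sd = pmax(apply(acc_mat, 2, stats::sd), 1e-12))
    } else {
      list(mode = "raw", mean = mean(emg), sd = max(stats::sd(emg), 1e-12),
           acc_mean = colMeans(acc_mat),
           acc_sd = pmax(apply(acc_mat, 2, stats::sd), 1e-12))
    }
  }
  if (cfg$mode == "feature") {
    emg <- (emg - norm_stats$mean) / norm_stats$sd  # recycles over rows
  } else {
    emg <- (emg - norm_stats$mean) / norm_stats$sd
  }
  acc_mat <- sweep(sweep(acc_mat, 2, norm_stats$acc_mean), 2,
                   norm_stats$acc_sd, `/`)
  list(emg = emg, acc = acc_mat, y = as.integer(dataset$labels),
       n_classes = dataset$n_classes, norm_stats = norm_stats)
}

subset_inputs <- function(inputs, idx) {
  list(emg = inputs$emg[, , , idx, drop = FALSE],
       acc = inputs$acc[idx, , drop = FALSE],
       y = inputs$y[idx], n_classes = inputs$n_classes,
       norm_stats = inputs$norm_stats)
}
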