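#' Noise and acquisition configuration for the synthetic generator
#'
#' Bundles the stochastic-model parameters used by [generate_recording()] and
#' [generate_dataset()]. The generator emulates a rest/action acquisition
#' protocol: bandlimited EMG-like activity whose amplitude is modulated by a
#' per-gesture activation envelope, riding on baseline instrumentation noise,
#' power-line interference at the mains frequency and its harmonics, and a
#' smooth gesture-correlated tri-axial accelerometer trajectory.
#'
#' @param emg_band Numeric length-2, passband (Hz) of the EMG-like noise.
#'   Defaults to 20--450 Hz, the band holding most surface-EMG energy.
#' @param line_freq Mains interference fundamental in Hz.
#' @param line_amp Amplitude of the mains fundamental, relative to
#'   `baseline_rms` (0 disables interference). Harmonics decay as 1/k.
#' @param n_harmonics Number of mains harmonics (including the fundamental).
#' @param baseline_rms Root-mean-square of the rest-state baseline noise, in
#'   the recording's millivolt-scale arbitrary units.
#' @param snr_db Action-to-rest power ratio in dB at the envelope plateau for
#'   a unit-gain channel. `-Inf` suppresses action activity entirely.
#' @param acc_amp Peak accelerometer excursion (g) along the gesture's
#'   movement direction.
#' @param acc_noise_sd Standard deviation (g) of accelerometer sensor noise.
#' @param acc_jitter Per-recording direction jitter: the class movement
#'   direction is perturbed by `acc_jitter * N(0, I)` and renormalised, so
#'   the accelerometer is informative about the gesture but not perfectly so.
#' @param seed Integer master seed; a fixed seed gives bit-identical output.
#' @return An object of class `semg_noise_config`.
#' @export
noise_config <- function(emg_band = c(20, 450), line_freq = 50, line_amp = 2,
                         n_harmonics = 3, baseline_rms = 0.005, snr_db = 15,
                         acc_amp = 0.5, acc_noise_sd = 0.05, acc_jitter = 0.6,
                         seed = 1L) {
  if (length(emg_band) != 2 || emg_band[1] <= 0 || emg_band[2] <= emg_band[1]) {
    stop_config("emg_band must be (low, high) with 0 < low < high")
  }
  if (line_amp < 0) stop_config("line_amp must be >= 0")
  structure(list(emg_band = as.numeric(emg_band), line_freq = line_freq,
                 line_amp = line_amp, n_harmonics = n_harmonics,
                 baseline_rms = baseline_rms, snr_db = snr_db,
                 acc_amp = acc_amp, acc_noise_sd = acc_noise_sd,
                 acc_jitter = acc_jitter, seed = as.integer(seed)),
            class = "semg_noise_config")
}

# Fixed per-class spatial activation pattern: a seeded log-normal gain per
# channel, normalised to unit root-mean-square so snr_db keeps its meaning.
# Seeded by the class id only, so the signature is stable across datasets.
class_gain_vector <- function(gesture, n_channels) {
  with_local_seed(70001L + as.integer(gesture), {
    # moderate spread: the spatial pattern identifies the gesture but does
    # not saturate classification on its own (spectral signatures and the
    # accelerometer carry complementary information)
    g <- exp(stats::rnorm(n_channels, 0, 0.3))
    g / sqrt(mean(g^2))
  })
}

# Fixed per-class movement direction on the unit sphere (accelerometer).
class_acc_direction <- function(gesture) {
  with_local_seed(90001L + as.integer(gesture), {
    d <- stats::rnorm(3)
    d / sqrt(sum(d^2))
  })
}

# Fixed spectral signature of a (class, channel) pair: the centre of the
# narrow sub-band that receives extra energy during action. Different
# muscles emphasise different parts of the EMG spectrum, which is what
# makes spectral features (MDF, FR) informative about the gesture.
class_band_centre <- function(gesture, channel, band) {
  hw <- 0.15 * (band[2] - band[1])
  with_local_seed(50001L + 97L * as.integer(gesture) + as.integer(channel),
                  stats::runif(1, band[1] + hw, band[2] - hw))
}

# White Gaussian noise brick-wall filtered to `band` in the frequency domain
# and rescaled to unit RMS. FFT filtering keeps the generator free of filter
# transients and exactly reproducible.
bandlimited_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided bin frequencies
  X[freqs < band[1] | freqs > band[2]] <- 0 + 0i
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# Activation envelope: 0 during rest, raised-cosine 100 ms ramps into a
# plateau of 1 over the action span [t_on, t_off).
activation_envelope <- function(n, fs, t_on, t_off, ramp_s = 0.1) {
  t <- (seq_len(n) - 1) / fs
  env <- numeric(n)
  ramp <- ramp_s
  up <- t >= t_on & t < t_on + ramp
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - t_on) / ramp))
  env[t >= t_on + ramp & t < t_off - ramp] <- 1
  dn <- t >= t_off - ramp & t < t_off
  env[dn] <- 0.5 * (1 - cos(pi * (t_off - t[dn]) / ramp))
  env
}

#' Generate one synthetic sEMG + accelerometer recording
#'
#' Simulates a single acquisition trial: rest for the first half of
#' `duration_s`, then the labelled dynamic gesture for the second half
#' (matching a 10 s rest / 10 s action protocol at the default duration).
#' Each sEMG channel is baseline noise plus envelope-modulated, bandlimited
#' EMG-like activity scaled by the gesture's fixed channel-gain signature,
#' plus mains interference. The accelerometer follows a smooth oscillatory
#' trajectory along a jittered class-specific direction.
#'
#' @param gesture Integer class id in `0..G-1`, or `"rest"` for a rest-only
#'   recording (zero envelope).
#' @param duration_s Total trial duration in seconds (default 20: 10 s rest +
#'   10 s action, the acquisition protocol emulated).
#' @param fs Sampling rate in Hz (default 1000).
#' @param cfg A [noise_config()].
#' @param n_channels Number of sEMG channels (default 16).
#' @param subject Subject id string stored with the recording.
#' @return An object of class `semg_recording`: a list with `semg` (C x T
#'   matrix), `acc` (3 x T), `fs`, `label`, `subject` and the ground-truth
#'   `envelope` (length T in \[0,1\]).
#' @export
generate_recording <- function(gesture, duration_s = 20, fs = 1000,
                               cfg = noise_config(), n_channels = 16,
                               subject = "synthetic") {
  if (duration_s <= 0) stop_config("duration_s must be > 0")
  if (fs <= 0) stop_config("fs must be > 0")
  if (cfg$emg_band[2] >= fs / 2) {
    stop_config("emg_band upper edge %.1f must be < fs/2 = %.1f",
                cfg$emg_band[2], fs / 2)
  }
  n <- as.integer(round(duration_s * fs))
  rest_only <- identical(gesture, "rest")
  gest_id <- if (rest_only) 0L else as.integer(gesture)

  env <- if (rest_only) numeric(n) else {
    activation_envelope(n, fs, t_on = duration_s / 2, t_off = duration_s)
  }
  act_scale <- if (is.infinite(cfg$snr_db) && cfg$snr_db < 0) 0 else {
    10^(cfg$snr_db / 20)
  }
  gains <- class_gain_vector(gest_id, n_channels)
  dir0 <- class_acc_direction(gest_id)

  with_local_seed(cfg$seed, {
    t <- (seq_len(n) - 1) / fs
    semg <- matrix(0, n_channels, n)
    for (c in seq_len(n_channels)) {
      base <- cfg$baseline_rms * bandlimited_noise(n, fs, cfg$emg_band)
      act <- if (act_scale > 0 && !rest_only) {
        # action activity: half broadband, half a class/channel-specific
        # sub-band, so gestures differ spectrally as well as spatially
        fc <- class_band_centre(gest_id, c, cfg$emg_band)
        hw <- 0.15 * (cfg$emg_band[2] - cfg$emg_band[1])
        narrow <- bandlimited_noise(n, fs, c(fc - hw, fc + hw))
        broad <- bandlimited_noise(n, fs, cfg$emg_band)
        cfg$baseline_rms * act_scale * gains[c] * env *
          sqrt(0.5) * (narrow + broad)
      } else 0
      line <- 0
      if (cfg$line_amp > 0) {
        for (k in seq_len(cfg$n_harmonics)) {
          fk <- cfg$line_freq * k
          if (fk >= fs / 2) break
          line <- line + (cfg$line_amp * cfg$baseline_rms / k) *
            sin(2 * pi * fk * t + stats::runif(1, 0, 2 * pi))
        }
      }
      semg[c, ] <- base + act + line
    }

    djit <- dir0 + cfg$acc_jitter * stats::rnorm(3)
    djit <- djit / sqrt(sum(djit^2))
    fosc <- 0.5 + 0.2 * gest_id
    osc <- 0.6 + 0.4 * sin(2 * pi * fosc * t + stats::runif(1, 0, 2 * pi))
    acc <- outer(djit, cfg$acc_amp * env * osc) +
      matrix(stats::rnorm(3 * n, 0, cfg$acc_noise_sd), 3, n)

    structure(list(semg = semg, acc = acc, fs = fs,
                   label = if (rest_only) "rest" else gest_id,
                   subject = subject, envelope = env),
              class = "semg_recording")
  })
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("<semg_recording> %d channels x %d samples @ %g Hz, label=%s\n",
              nrow(x$semg), ncol(x$semg), x$fs, as.character(x$label)))
  invisible(x)
}

#' Generate class-balanced synthetic train/test collections
#'
#' Produces disjoint, class-balanced train and test sets of labelled
#' recordings. Each recording receives its own seed derived deterministically
#' from `cfg$seed`, so the whole dataset is reproducible while recordings
#' remain mutually independent.
#'
#' @param n_train_per_class,n_test_per_class Recordings per gesture class
#'   (the emulated protocol uses 500 and 60).
#' @param n_classes Number of gesture classes (default 6).
#' @param fs Sampling rate in Hz.
#' @param cfg A [noise_config()]; `cfg$seed` seeds the whole collection.
#' @param duration_s Trial duration in seconds passed to
#'   [generate_recording()].
#' @param n_channels Number of sEMG channels.
#' @return A list with elements `train` and `test`, each of class
#'   `semg_dataset`: a list of `recordings`, integer `labels` (0-based),
#'   `n_classes` and `fs`.
#' @export
generate_dataset <- function(n_train_per_class, n_test_per_class,
                             n_classes = 6, fs = 1000, cfg = noise_config(),
                             duration_s = 20, n_channels = 16) {
  if (n_train_per_class < 1 || n_test_per_class < 1) {
    stop_config("per-class counts must be >= 1")
  }
  if (n_classes < 2) stop_config("n_classes must be >= 2")
  make_split <- function(n_per_class, offset) {
    labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
    recs <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(cfg$seed, offset + i)
      recs[[i]] <- generate_recording(labels[i], duration_s = duration_s,
                                      fs = fs, cfg = cfg_i,
                                      n_channels = n_channels)
    }
    structure(list(recordings = recs, labels = labels,
                   n_classes = as.integer(n_classes), fs = fs),
              class = "semg_dataset")
  }
  train <- make_split(n_train_per_class, 0L)
  test <- make_split(n_test_per_class, n_train_per_class * n_classes * 131L)
  list(train = train, test = test)
}

#' @export
print.semg_dataset <- function(x, ...) {
  cat(sprintf("<semg_dataset> %d recordings, %d classes @ %g Hz\n",
              length(x$recordings), x$n_classes, x$fs))
  invisible(x)
}

#' Write/read a recording as CSV files with a JSON sidecar
#'
#' Stores a recording as plain-text files sharing a path prefix:
#' `<prefix>_semg.csv` (samples x channels), `<prefix>_acc.csv` (samples x 3),
#' `<prefix>_meta.json` (sampling rate, label, subject) and, when present,
#' `<prefix>_envelope.csv`.
#'
#' @param rec A `semg_recording`.
#' @param prefix Path prefix for the output files.
#' @return `write_recording_csv` returns `prefix` invisibly;
#'   `read_recording_csv` returns the reconstructed `semg_recording`.
#' @export
write_recording_csv <- function(rec, prefix) {
  stopifnot(inherits(rec, "semg_recording"))
  semg <- t(rec$semg)
  colnames(semg) <- paste0("ch", seq_len(ncol(semg)))
  utils::write.csv(semg, paste0(prefix, "_semg.csv"), row.names = FALSE)
  acc <- t(rec$acc)
  colnames(acc) <- c("x", "y", "z")
  utils::write.csv(acc, paste0(prefix, "_acc.csv"), row.names = FALSE)
  meta <- list(fs = rec$fs, label = rec$label, subject = rec$subject)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE)
  if (!is.null(rec$envelope)) {
    utils::write.csv(data.frame(envelope = rec$envelope),
                     paste0(prefix, "_envelope.csv"), row.names = FALSE)
  }
  invisible(prefix)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(prefix) {
  semg <- t(as.matrix(utils::read.csv(paste0(prefix, "_semg.csv"))))
  acc <- t(as.matrix(utils::read.csv(paste0(prefix, "_acc.csv"))))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  env_path <- paste0(prefix, "_envelope.csv")
  env <- if (file.exists(env_path)) {
    utils::read.csv(env_path)$envelope
  } else NULL
  label <- if (identical(meta$label, "rest")) "rest" else as.integer(meta$label)
  structure(list(semg = unname(semg), acc = unname(acc), fs = meta$fs,
                 label = label, subject = meta$subject, envelope = env),
            class = "semg_recording")
}
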