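# Independent oracles used to cross-check package computations.

# Spectral power in a frequency band, straight from the FFT periodogram.
oracle_band_power <- function(x, fs = 125, lo = 0.1, hi = 0.7) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1L) * fs / n
  sum(sp[f >= lo & f <= hi])
}

# Dominant (non-DC) periodogram frequency.
oracle_peak_freq <- function(x, fs = 125) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1L) * fs / n
  half <- f > 0 & f <= fs / 2
  f[half][which.max(sp[half])]
}

# Respiratory band-pass via a Butterworth filter (independent of the package,
# which does no filtering).
oracle_bandpass <- function(x, fs = 125, lo = 0.1, hi = 0.7) {
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  # demean first: a DC offset (gravity) excites large shared edge transients
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

# Brute-force per-class counting report.
oracle_report <- function(truth, predicted, classes = EVENT_CLASSES) {
  res <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(class = cl, precision = p, recall = r, f1 = f,
               support = sum(truth == cl), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# AUC as the exhaustive pairwise probability that a positive outscores a
# negative, ties counting one half.
oracle_auc_pairwise <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
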