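# Spectral estimation helpers shared by the pupillometry and HRV modules.

# Welch power spectral density of a uniformly sampled signal.
# Hann window, 50% overlap; returns one-sided density so that
# sum(psd * df) ~ variance of the signal (Parseval).
welch_psd <- function(x, fs, seg_len = NULL) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- n
  seg_len <- min(seg_len, n)
  if (seg_len < 8L) stop("record too short for spectral estimation")
  x <- x - mean(x)
  step <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  U <- sum(w^2)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (fs * U)
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even seg_len)
  dbl <- rep(2, nf); dbl[1L] <- 1
  if (seg_len %% 2 == 0) dbl[nf] <- 1
  psd <- psd * dbl
  freq <- (seq_len(nf) - 1L) * fs / seg_len
  list(freq = freq, psd = psd)
}

# Lomb-Scargle periodogram of an unevenly sampled series, rescaled to a
# one-sided density in units of x^2 per Hz (sum(psd*df) ~ variance).
lomb_psd <- function(t, x, freq = NULL, oversample = 4) {
  n <- length(t)
  stopifnot(n >= 4L, length(x) == n)
  x <- x - mean(x)
  T_span <- t[n] - t[1L]
  if (is.null(freq)) {
    df <- 1 / (oversample * T_span)
    f_max <- n / (2 * T_span)  # pseudo-Nyquist at the mean sampling rate
    freq <- seq(df, f_max, by = df)
  }
  psd <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    p <- 0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
    p
  }, numeric(1))
  # classical periodogram P(f0) ~ N a^2 / 4 for a sinusoid of amplitude a;
  # scale by 2T/N so the integral over the peak (~width 1/T) gives a^2/2
  psd <- psd * 2 * T_span / n
  list(freq = freq, psd = psd)
}

# integrate a sampled PSD over [f_lo, f_hi) by the trapezoidal rule
band_power <- function(freq, psd, f_lo, f_hi) {
  sel <- freq >= f_lo & freq <= f_hi
  if (sum(sel) < 2L) return(0)
  f <- freq[sel]; p <- psd[sel]
  sum(diff(f) * (p[-1L] + p[-length(p)]) / 2)
}
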