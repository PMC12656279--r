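# Independent reference implementations used as oracles. These deliberately
# use plain loops / direct enumeration so they share no code path with the
# package implementations they check.

# Literal direct-form IIR recursion: y[n] = sum b_k x[n-k] - sum a_k y[n-k]
direct_recursion <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_along(b)) {
      if (i - k + 1 >= 1) acc <- acc + b[k] * x[i - k + 1]
    }
    for (k in seq_along(a)[-1]) {
      if (i - k + 1 >= 1) acc <- acc - a[k] * y[i - k + 1]
    }
    y[i] <- acc / a[1]
  }
  y
}

# Step-down Holm adjustment by direct enumeration of the definition
holm_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- (m - i + 1) * p[o[i]]
    running <- max(running, val)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Textbook Passing-Bablok slope: explicit double loop over all pairs,
# shifted median with offset K = #slopes < -1, slopes == -1 discarded.
pbr_slope_bruteforce <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] != x[i]) {
        s <- (y[j] - y[i]) / (x[j] - x[i])
        if (s != -1) slopes <- c(slopes, s)
      }
    }
  }
  S <- sort(slopes)
  N <- length(S)
  K <- sum(S < -1)
  if (N %% 2 == 1) S[(N + 1) / 2 + K] else 0.5 * (S[N / 2 + K] + S[N / 2 + 1 + K])
}

# Construct a tachogram object directly from uniformly sampled values
make_tach <- function(values, fs = 4) {
  structure(list(knot_times = numeric(0), knot_values = numeric(0),
                 resampled = values,
                 times = (seq_along(values) - 1) / fs,
                 duration = length(values) / fs, fs = fs),
            class = "tachogram")
}

# Plain sinusoid test signal
tone <- function(freq, fs, duration, amp = 1, phase = 0) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  hrv_signal(amp * sin(2 * pi * freq * t + phase), fs)
}

# Beat series from known beat times (bypasses detection)
beats_from_times <- function(times, source = "ecg") {
  structure(list(peak_times = times, intervals = diff(times) * 1000,
                 source = source),
            class = "beat_series")
}

# The published Butterworth coefficient table, transcribed verbatim.
printed_butterworth <- list(
  `1000` = list(b = c(0.00334894, 0.00000000, -0.00669788, 0.00000000, 0.00334894),
                a = c(1.00000000, -3.82854718, 5.50034780, -3.51495413, 0.84315388)),
  `500`  = list(b = c(0.00308602, 0.00000000, -0.00617203, 0.00000000, 0.00308602),
                a = c(1.00000000, -3.83439915, 5.51815832, -3.53292690, 0.84916874)),
  `250`  = list(b = c(0.01145082, 0.00000000, -0.02290164, 0.00000000, 0.01145082),
                a = c(1.00000000, -3.66597653, 5.05449352, -3.10959869, 0.72110356)))
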