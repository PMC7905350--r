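# Shared fixtures, all built in code.

# A pure sinusoid recording.
sine_recording <- function(freq, rate, seconds, channels = 1L, amp = 1) {
  t <- seq(0, seconds - 1 / rate, by = 1 / rate)
  data <- matrix(rep(amp * sin(2 * pi * freq * t), channels),
                 nrow = channels, byrow = TRUE)
  recording(data, rate)
}

# Least-squares sinusoid amplitude at a known frequency.
fit_sine_amplitude <- function(x, freq, rate) {
  t <- (seq_along(x) - 1) / rate
  b <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  cf <- stats::lm.fit(b, x)$coefficients
  sqrt(sum(cf^2))
}

# Small labeled FeatureSet of two Gaussian blobs, well separated unless
# `sep` is small.
blob_features <- function(n_per_class, d = 4L, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per_class * d), ncol = d),
             matrix(stats::rnorm(n_per_class * d, mean = sep / sqrt(d)),
                    ncol = d))
  y <- rep(c(0L, 1L), each = n_per_class)
  idx <- sample(2 * n_per_class)
  structure(list(X = X[idx, , drop = FALSE], y = y[idx],
                 variance_ratios = rep(1, 2 * n_per_class),
                 norm_stats = NULL,
                 params = list(channels = NA, n_components = NA)),
            class = "FeatureSet")
}

# Brute-force Gaussian kernel matrix by double loop.
phi_double_loop <- function(X, rho) {
  N <- nrow(X)
  P <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (k in seq_len(N)) {
      P[k, i] <- exp(-sum((X[k, ] - X[i, ])^2) / rho)
    }
  }
  P
}

# AUC by exhaustive pair counting, ties counted one half.
auc_pair_count <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
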