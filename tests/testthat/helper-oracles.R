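# Independent brute-force oracles used to cross-check the feature and
# metric implementations. Deliberately naive: plain formulas, loops and
# O(n^2) transforms, sharing no code with the package internals.

# type-7 quantile: linear interpolation between order statistics
bf_quantile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

bf_sd <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))

bf_moment <- function(v, k) sum((v - mean(v))^k) / length(v)

bf_time_features <- function(x, y, z) {
  vm <- sqrt(x * x + y * y + z * z)
  ang <- numeric(length(x))
  for (i in seq_along(x)) {
    ang[i] <- if (vm[i] == 0) 0 else asin(max(-1, min(1, x[i] / vm[i]))) * 180 / pi
  }
  chans <- list(vm = vm, x = x, y = y, z = z)
  out <- c(mvm = mean(vm), sdvm = bf_sd(vm),
           mangle = mean(ang), sdangle = bf_sd(ang))
  for (a in c("x", "y", "z")) out[paste0("mean_", a)] <- mean(chans[[a]])
  for (a in c("x", "y", "z")) out[paste0("sd_", a)] <- bf_sd(chans[[a]])
  for (a in c("x", "y", "z")) {
    m <- mean(chans[[a]])
    out[paste0("cv_", a)] <- if (abs(m) < 1e-6) 0 else 100 * bf_sd(chans[[a]]) / abs(m)
  }
  for (a in names(chans)) out[paste0("min_", a)] <- min(chans[[a]])
  for (a in names(chans)) out[paste0("max_", a)] <- max(chans[[a]])
  for (a in names(chans)) out[paste0("lower_", a, "_25")] <- bf_quantile(chans[[a]], 0.25)
  for (a in names(chans)) out[paste0("upper_", a, "_75")] <- bf_quantile(chans[[a]], 0.75)
  for (a in names(chans)) out[paste0("third_moment_", a)] <- bf_moment(chans[[a]], 3)
  for (a in names(chans)) out[paste0("fourth_moment_", a)] <- bf_moment(chans[[a]], 4)
  for (a in names(chans)) {
    m2 <- bf_moment(chans[[a]], 2)
    out[paste0("skewness_", a)] <- if (m2 < 1e-12) 0 else bf_moment(chans[[a]], 3) / m2^1.5
  }
  for (a in names(chans)) {
    m2 <- bf_moment(chans[[a]], 2)
    out[paste0("kurtosis_", a)] <- if (m2 < 1e-12) 0 else bf_moment(chans[[a]], 4) / m2^2
  }
  out["cv_vm"] <- if (mean(vm) < 1e-6) 0 else 100 * bf_sd(vm) / mean(vm)
  names(out)[names(out) == "lower_vm_25"] <- "lower_vm_25"
  out
}

# naive discrete Fourier transform modulus at positive-frequency bins
bf_dft_mod <- function(v) {
  n <- length(v)
  ks <- seq_len(floor(n / 2))
  j <- seq_len(n) - 1
  vapply(ks, function(k) Mod(sum(v * exp(-2i * pi * j * k / n))), numeric(1))
}

# AUC by exhaustive enumeration of positive/negative pairs
bf_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
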