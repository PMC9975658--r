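# Independent oracles used across test files. These deliberately use
# brute-force formulations, not the package's own code paths.

# Optimal 1-D 2-means by exhaustive contiguous partition: the optimal
# two-cluster solution in one dimension is a threshold split of the sorted
# values, so trying every split point is exact.
kmeans_1d_oracle <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  best <- NULL
  best_ss <- Inf
  for (k in 1:(n - 1)) {
    lo <- xs[1:k]
    hi <- xs[(k + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- k
    }
  }
  labels_sorted <- rep(c("LOW", "HIGH"), c(best, n - best))
  labels <- character(n)
  labels[ord] <- labels_sorted
  list(labels = labels,
       centers = c(LOW = mean(xs[1:best]), HIGH = mean(xs[(best + 1):n])),
       ss = best_ss)
}

# Benjamini-Hochberg step-up, written from the definition: find the largest
# i with p_(i) <= i*q/m; adjusted p by the textbook cummin recursion.
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, ps[i] * m / i)
    adj_sorted[i] <- prev
  }
  thresh <- which(ps <= (1:m) * q / m)
  reject_sorted <- rep(FALSE, m)
  if (length(thresh) > 0) reject_sorted[1:max(thresh)] <- TRUE
  adj <- numeric(m)
  rej <- logical(m)
  adj[ord] <- adj_sorted
  rej[ord] <- reject_sorted
  list(adjusted = adj, reject = rej)
}

# Order-free intelligibility matching by explicit token pairing.
multiset_match_oracle <- function(ref, resp) {
  matched <- 0
  resp_left <- resp
  for (w in ref) {
    hit <- match(w, resp_left)
    if (!is.na(hit)) {
      matched <- matched + 1
      resp_left <- resp_left[-hit]
    }
  }
  100 * matched / length(ref)
}

# A deterministic synthetic AM signal whose envelope oscillates at mod_hz.
am_noise_audio <- function(mod_hz = 4.5, fs = 8000, dur = 8, depth = 0.8,
                           seed = 1) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- (1 + depth * sin(2 * pi * mod_hz * t)) * rnorm(length(t), sd = 0.2)
  audio_recording(x, fs)
}
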