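# Shared fixtures, built in code.

# Triangular spike: baseline -60 mV, linear rise to 0 mV over 1 ms, linear
# fall back over 1 ms, inside a -1/+2 ms epoch at 20 kHz (peak at offset 20).
triangle_spike_set <- function(fs = 20000) {
  n_pre <- round(fs / 1000)          # 20
  w <- 3L * n_pre                    # 60
  idx <- seq_len(w) - (n_pre + 1L)   # samples from peak
  v <- pmax(-60, -60 + 60 * (1 - abs(idx) / n_pre))
  spike_set(matrix(v, 1L), fs = fs, pre_ms = 1, post_ms = 2)
}

# Two well-separated spherical Gaussian blobs.
two_blobs <- function(n_per = 100, centers = rbind(c(0, 0), c(10, 10)),
                      sd = 0.5, seed = 42) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Independently coded O(N^2) DCT-II oracle (double loop, no shared code
# with dct_ii's matrix formulation).
dct_oracle <- function(u, alpha = "ortho") {
  N <- length(u)
  v <- numeric(N)
  for (k in 0:(N - 1)) {
    acc <- 0
    for (n in 0:(N - 1))
      acc <- acc + u[n + 1] * cos((2 * n + 1) * pi * k / (2 * N))
    a <- if (alpha == "literal") sqrt((k + 1) / N)
         else if (k == 0) sqrt(1 / N) else sqrt(2 / N)
    v[k + 1] <- a * acc
  }
  v
}

# The default synthetic study dataset, generated once per test run.
.fixture_cache <- new.env(parent = emptyenv())
default_spikes <- function() {
  if (is.null(.fixture_cache$spikes)) {
    ds <- make_dataset(preset = "paper3", n_neurons = 5L,
                       spikes_per_neuron = 100L, seed = 1L)
    .fixture_cache$spikes <- extract_dataset(ds)
  }
  .fixture_cache$spikes
}

# A small, fast 3-class dataset for smoke-level checks.
small_spikes <- function() {
  if (is.null(.fixture_cache$small)) {
    ds <- make_dataset(preset = "paper3", n_neurons = 2L,
                       spikes_per_neuron = 30L, seed = 7L)
    .fixture_cache$small <- extract_dataset(ds)
  }
  .fixture_cache$small
}
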