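# Shared fixtures: small synthetic device configurations and fields, built
# in code at test time.

# A compact 3 x 3 trap array (fast to render and reconstruct).
small_config <- function(...) {
  args <- utils::modifyList(
    list(counts_u = 3, counts_v = 3, margin = 25,
         trap_cv = 0, frame_jitter_cv = 0, occupancy_prob = 0,
         frames = 3, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

# Smooth random thickness field, band-limited below Nyquist/4, zero-mean.
smooth_field <- function(n = 64, kmax = n / 8, seed = 1) {
  set.seed(seed)
  spec <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  k <- c(0:(n / 2), (n / 2 - 1):1)[1:n]
  keep <- outer(k, k, function(a, b) pmax(a, b) <= kmax)
  spec[!keep] <- 0
  f <- Re(stats::fft(spec, inverse = TRUE)) / (n * n)
  f <- f - mean(f)
  f / max(abs(f)) * 0.2
}

rel_l2 <- function(est, truth) sqrt(sum((est - truth)^2) / sum(truth^2))
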