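# Shared fixtures and independent oracles used across test files.

wt_times <- seq(0, 22, by = 2)

# Noiseless cosine series on an arbitrary grid.
make_cosine <- function(times, period, A = 1, phase = 0, mesor = 0) {
  mesor + A * cos(2 * pi * (times - phase) / period)
}

# Independent least-squares oracle: lm() on the explicit cosinor design.
lm_cosinor <- function(y, times, period) {
  d <- data.frame(y = y, c = cos(2 * pi * times / period),
                  s = sin(2 * pi * times / period))
  fit <- lm(y ~ c + s, data = d)
  list(mesor = unname(coef(fit)[1]), a = unname(coef(fit)[2]),
       b = unname(coef(fit)[3]), rss = sum(resid(fit)^2))
}

# Independent BIC oracle built on lm() fits.
lm_bic <- function(rss, n, k) n * log(max(rss, 1e-300) / n) + k * log(n)

# Rand index between two 2-group labelings.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Small mixed simulation used by several tests.
small_mixed_config <- function(seed, n_genes = 1000, noise_sd = 0.2,
                               amplitude_sdlog = 0.25) {
  sim_config(n_genes = n_genes, fractions = c(0.17, 0.015, 0.064),
             noise_sd = noise_sd, amplitude_sdlog = amplitude_sdlog,
             seed = seed)
}
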