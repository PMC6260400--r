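# Cosinor harmonic regression primitives.
#
# All fits are ordinary least squares on the design [1, cos(2*pi*t/T),
# sin(2*pi*t/T)] with explicit times, so non-uniform grids work
# throughout.  Derived quantities follow the standard cosinor
# parameterisation: half-amplitude A = sqrt(a^2 + b^2) and acrophase
# phi = (T / 2*pi) * atan2(b, a) mod T (peak time in hours).

#' Candidate periods of the harmonic model family
#'
#' The default model family: a circadian fundamental plus its second and
#' third harmonics (period divided by 2 and 3).  With the 22-hr intrinsic
#' circadian period this is 22, 11 and 7.33 hr; the third harmonic is
#' represented internally as 22/3 exactly.
#'
#' @param circadian_period Fundamental period in hours.
#' @param harmonics Integer divisors of the fundamental to include.
#' @return Numeric vector of candidate periods in hours.
#' @examples
#' default_periods()          # 22 11 7.33
#' @export
default_periods <- function(circadian_period = 22, harmonics = 1:3) {
  circadian_period / harmonics
}

# Pretty period labels: 22, 11, 7.33
format_period <- function(period) {
  ifelse(is.na(period), "none",
         sub("\\.?0+$", "", sprintf("%.2f", period)))
}

# Match periods numerically with tolerance (7.33 vs 22/3 etc.)
match_period <- function(period, period_set, tol = 0.005) {
  vapply(period, function(p) {
    if (is.na(p)) return(NA_integer_)
    i <- which(abs(period_set - p) <= tol)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
}

cosinor_design <- function(times, period) {
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0)
    stop("`period` must be a single positive number")
  w <- 2 * pi * times / period
  X <- cbind(1, cos(w), sin(w))
  # scale-aware rank check: an aliased harmonic column is numerically
  # tiny rounding noise, which column-pivoted QR still counts as a
  # dimension; the smallest singular value exposes it
  sv <- svd(X, nu = 0, nv = 0)$d
  if (min(sv) < max(sv) * 1e-8)
    stop(sprintf(paste0("singular cosinor design at period T = %g h on ",
                        "this time grid (rhythm aliased by the sampling)"),
                 period))
  X
}

# Fit the cosinor at one period to many series at once.
# values: genes x times matrix.  Returns coefficients (3 x G) and RSS (G).
cosinor_fit_multi <- function(values, times, period) {
  X <- cosinor_design(times, period)
  qx <- qr(X)
  B <- qr.coef(qx, t(values))
  resid <- t(values) - X %*% B
  list(coef = B, rss = colSums(resid^2))
}

new_cosinor_fit <- function(period, mesor, a, b, rss, n, k) {
  A <- sqrt(a^2 + b^2)
  phi <- if (A > 0) ((period / (2 * pi)) * atan2(b, a)) %% period else 0
  if (!is.na(phi) && phi >= period) phi <- 0  # fold rounding artefact
  structure(list(period = period, mesor = mesor, coef_cos = a,
                 coef_sin = b, half_amplitude = A, phase = phi,
                 rss = max(rss, 0), n = n, k = k,
                 criterion = bic_from_rss(rss, n, k)),
            class = "cosinor_fit")
}

# BIC on the Gaussian profile likelihood: n*log(RSS/n) + k*log(n).
# RSS is floored to keep a perfect (noiseless) fit finite and still
# strictly better than any positive-RSS competitor.
bic_from_rss <- function(rss, n, k) {
  n * log(pmax(rss, 1e-300) / n) + k * log(n)
}

aicc_from_rss <- function(rss, n, k) {
  n * log(pmax(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / pmax(n - k - 1, 1)
}

criterion_from_rss <- function(rss, n, k, criterion = c("bic", "aicc")) {
  switch(match.arg(criterion),
         bic = bic_from_rss(rss, n, k),
         aicc = aicc_from_rss(rss, n, k))
}

#' Fit a single-period cosinor model to one series
#'
#' Ordinary least squares of `y` on `[1, cos(2*pi*t/T), sin(2*pi*t/T)]`.
#'
#' @param y Numeric series of expression values (log2 scale).
#' @param times Sampling times in hours (same length as `y`).
#' @param period Candidate period T in hours.
#' @return A `cosinor_fit`: list with `period`, `mesor`, `coef_cos` (a),
#'   `coef_sin` (b), `half_amplitude` (`sqrt(a^2+b^2)`), `phase` (peak
#'   time in hours, in `[0, T)`), `rss`, `n`, `k` (3) and `criterion`
#'   (BIC).
#' @examples
#' t <- seq(0, 22, by = 2)
#' fit <- fit_cosinor(5 + 2 * cos(2 * pi * t / 22), t, period = 22)
#' c(fit$mesor, fit$half_amplitude, fit$phase)
#' @export
fit_cosinor <- function(y, times, period) {
  check_series(y, times)
  f <- cosinor_fit_multi(rbind(y), times, period)
  new_cosinor_fit(period, f$coef[1], f$coef[2], f$coef[3], f$rss[1],
                  length(y), 3L)
}

#' Fit the flat (arrhythmic) null model to one series
#'
#' The intercept-only fit used as the null in model selection: mesor is
#' the mean, RSS the total sum of squares about it, `k = 1`.
#'
#' @inheritParams fit_cosinor
#' @return A `cosinor_fit` with `period = NA`, zero amplitude.
#' @export
fit_flat <- function(y, times) {
  check_series(y, times)
  m <- mean(y)
  structure(list(period = NA_real_, mesor = m, coef_cos = 0, coef_sin = 0,
                 half_amplitude = 0, phase = NA_real_,
                 rss = sum((y - m)^2), n = length(y), k = 1L,
                 criterion = bic_from_rss(sum((y - m)^2), length(y), 1L)),
            class = "cosinor_fit")
}

check_series <- function(y, times) {
  if (length(y) != length(times))
    stop("`y` and `times` must have the same length")
  if (length(y) < 4L) stop("need at least 4 time points")
  if (anyNA(y) || any(!is.finite(y)))
    stop("series contains NA or non-finite values")
  invisible(TRUE)
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "cosinor_fit: T = %s h, mesor = %.4g, A = %.4g, phase = %.4g h, RSS = %.4g\n",
    format_period(x$period), x$mesor, x$half_amplitude,
    if (is.na(x$phase)) NA else x$phase, x$rss))
  invisible(x)
}

#' Peak-to-peak fold amplitude and acrophase of a cosinor fit
#'
#' The peak-to-trough difference of the fitted cosine on the log2 scale
#' is twice the half-amplitude, so the fold amplitude is `2^(2*A)`.
#'
#' @param fit A `cosinor_fit` from [fit_cosinor()].
#' @return List with `fold` (peak-to-peak fold amplitude, >= 1) and
#'   `phase` (peak time in hours, in `[0, T)`).
#' @examples
#' t <- seq(0, 22, by = 2)
#' quantify_amplitude_phase(fit_cosinor(sin(2 * pi * t / 22), t, 22))
#' @export
quantify_amplitude_phase <- function(fit) {
  stopifnot(inherits(fit, "cosinor_fit"))
  list(fold = 2^(2 * fit$half_amplitude), phase = fit$phase)
}

#' Scan a continuous period grid with the cosinor criterion
#'
#' Evaluates the cosinor information criterion at every period of a
#' dense grid, the continuous-period analogue of the discrete model
#' selection (useful for period histograms).  Grid periods whose design
#' is aliased by the sampling (rank-deficient) get `NA` and are skipped.
#'
#' @inheritParams fit_cosinor
#' @param period_grid Numeric grid of candidate periods in hours.
#' @param criterion `"bic"` (default) or `"aicc"`.
#' @return List with `best_period` (criterion argmin; `NA` when no
#'   preference), `no_preference` (`TRUE` for e.g. constant series, where
#'   the profile is flat), and `profile` (data.frame of `period`,
#'   `criterion`, `rss`).
#' @export
period_scan <- function(y, times, period_grid = seq(4.2, 30, by = 0.01),
                        criterion = "bic") {
  check_series(y, times)
  if (length(period_grid) == 0L) stop("`period_grid` is empty")
  n <- length(y)
  rss <- vapply(period_grid, function(T) {
    X <- tryCatch(cosinor_design(times, T), error = function(e) NULL)
    if (is.null(X)) return(NA_real_)
    sum(qr.resid(qr(X), y)^2)
  }, numeric(1))
  crit <- criterion_from_rss(rss, n, 3L, criterion)
  tss <- sum((y - mean(y))^2)
  ok <- which(!is.na(crit))
  flat_profile <- length(ok) > 0 &&
    (tss <= 1e-20 * max(1, sum(y^2)) ||
       diff(range(crit[ok])) < 1e-8)
  best <- if (!length(ok) || flat_profile) NA_real_ else
    period_grid[ok[which.min(crit[ok])]]
  list(best_period = best, no_preference = flat_profile,
       profile = data.frame(period = period_grid, criterion = crit,
                            rss = rss))
}

#' Per-gene cosinor F statistics at a fixed period
#'
#' The F statistic of the cosinor fit at `period` against the flat model
#' (2 and n-3 degrees of freedom) for every gene of a matrix.  This is
#' the per-gene statistic fed to [competitive_gene_set_test()] when
#' asking whether a gene set is enriched for a rhythmic component.
#'
#' @param x An [expression_matrix()].
#' @param period Period in hours.
#' @return Named numeric vector of F statistics (one per gene).
#' @export
cosinor_f_statistics <- function(x, period) {
  stopifnot(inherits(x, "expression_matrix"))
  n <- length(x$times)
  m <- rowMeans(x$values)
  rss0 <- rowSums((x$values - m)^2)
  f <- cosinor_fit_multi(x$values, x$times, period)
  fstat <- pmax(rss0 - f$rss, 0) / 2 / (f$rss / (n - 3))
  setNames(fstat, rownames(x$values))
}

#' Subtract a fitted rhythmic component from a series
#'
#' Fits the cosinor at `period` and removes only the rhythmic part
#' (cosine and sine terms); the mesor is retained.  Used to strip an
#' induced circadian component and expose a residual harmonic rhythm.
#'
#' @inheritParams fit_cosinor
#' @return Numeric residual series, same length as `y`.
#' @examples
#' t <- seq(0, 22, by = 2)
#' y <- 8 + cos(2 * pi * t / 22) + 0.5 * cos(2 * pi * t / (22 / 3))
#' r <- subtract_component(y, t, period = 22)   # 7.33-hr part survives
#' @export
subtract_component <- function(y, times, period) {
  check_series(y, times)
  fit <- fit_cosinor(y, times, period)
  w <- 2 * pi * times / period
  as.numeric(y - fit$coef_cos * cos(w) - fit$coef_sin * sin(w))
}
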