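# Model-selection rhythm detection.
#
# Each gene is fit with a flat model (k = 1) and one cosinor per
# candidate period (k = 3); the minimum-information-criterion model is
# selected.  If a rhythmic model wins, significance is the F test of the
# selected model against flat (df 2, n - 3); by default that p-value is
# Bonferroni-multiplied by the number of candidate periods to pay for
# the selection step, which keeps the downstream BH-FDR calls calibrated.
# Genes where flat wins get p = 1 but remain in the BH universe.

# Shared engine: fits all models for all genes, applies the selection
# and significance rules.  Returns one data.frame row per gene.
classify_matrix <- function(values, times, period_set, criterion = "bic",
                            p_adjust_periods = c("bonferroni", "none")) {
  p_adjust_periods <- match.arg(p_adjust_periods)
  if (length(period_set) == 0L) stop("`period_set` is empty")
  if (any(period_set <= 0)) stop("periods must be positive")
  n <- length(times)
  G <- nrow(values)
  mesor <- rowMeans(values)
  rss0 <- rowSums((values - mesor)^2)

  # order candidates longest first so which.min's first-wins rule
  # implements the prefer-longer-period tie-break
  ord <- order(period_set, decreasing = TRUE)
  periods <- period_set[ord]
  fits <- lapply(periods, function(T) cosinor_fit_multi(values, times, T))

  crit_rhy <- matrix(vapply(fits, function(f)
    criterion_from_rss(f$rss, n, 3L, criterion), numeric(G)), nrow = G)
  crit <- cbind(criterion_from_rss(rss0, n, 1L, criterion), crit_rhy)
  # constant series: flat fits perfectly, call it flat outright
  constant <- rss0 <= 1e-20 * pmax(1, rowSums(values^2))
  sel <- max.col(-crit, ties.method = "first")  # 1 = flat
  sel[constant] <- 1L

  out <- data.frame(gene_id = rownames(values),
                    selected_period = NA_real_, p_value = 1,
                    log2_half_amplitude = NA_real_,
                    peak_to_peak_fold = NA_real_, phase_hours = NA_real_,
                    mean_log2 = mesor, stringsAsFactors = FALSE,
                    row.names = NULL)
  rhythmic <- which(sel > 1L)
  if (length(rhythmic)) {
    for (j in seq_along(periods)) {
      idx <- rhythmic[sel[rhythmic] == j + 1L]
      if (!length(idx)) next
      f <- fits[[j]]
      a <- f$coef[2, idx]; b <- f$coef[3, idx]
      A <- sqrt(a^2 + b^2)
      T <- periods[j]
      phi <- ((T / (2 * pi)) * atan2(b, a)) %% T
      phi[phi >= T | A == 0] <- 0
      rss1 <- f$rss[idx]
      fstat <- pmax(rss0[idx] - rss1, 0) / 2 / (rss1 / (n - 3))
      p <- pf(fstat, 2, n - 3, lower.tail = FALSE)
      if (p_adjust_periods == "bonferroni")
        p <- pmin(1, p * length(periods))
      out$selected_period[idx] <- T
      out$p_value[idx] <- p
      out$log2_half_amplitude[idx] <- A
      out$peak_to_peak_fold[idx] <- 2^(2 * A)
      out$phase_hours[idx] <- phi
    }
  }
  out
}

#' Classify one series into a harmonic period class
#'
#' Fits the flat model and one cosinor per candidate period, selects the
#' minimum-criterion model (ties prefer the longer period, and the flat
#' model beats any tied rhythmic model) and, if a rhythmic model wins,
#' computes the selection-adjusted F-test p-value against flat.
#'
#' @inheritParams fit_cosinor
#' @param period_set Candidate periods in hours; default
#'   [default_periods()] = 22, 11, 7.33.
#' @param criterion Information criterion, `"bic"` (default) or
#'   `"aicc"`.
#' @param p_adjust_periods `"bonferroni"` (default) multiplies the
#'   selected model's F-test p-value by the number of candidate periods
#'   to account for the selection; `"none"` reports the raw
#'   post-selection p-value (anti-conservative).
#' @return List with `selected_period` (`NA` when flat wins), `p_value`,
#'   `fit` (the selected `cosinor_fit`, flat fit when arrhythmic) and
#'   `criteria` (named vector of criterion values for every model).
#' @examples
#' t <- seq(0, 22, by = 2)
#' classify_gene(cos(2 * pi * t / (22 / 3)), t)$selected_period  # 7.33
#' @export
classify_gene <- function(y, times, period_set = default_periods(),
                          criterion = "bic",
                          p_adjust_periods = c("bonferroni", "none")) {
  check_series(y, times)
  row <- classify_matrix(rbind(gene = y), times, period_set, criterion,
                         p_adjust_periods)
  fit <- if (is.na(row$selected_period)) fit_flat(y, times) else
    fit_cosinor(y, times, row$selected_period)
  n <- length(y)
  flat <- fit_flat(y, times)
  crits <- c(none = flat$criterion,
             setNames(vapply(period_set, function(T)
               criterion_from_rss(fit_cosinor(y, times, T)$rss, n, 3L,
                                  criterion), numeric(1)),
               format_period(period_set)))
  list(selected_period = row$selected_period, p_value = row$p_value,
       fit = fit, criteria = crits)
}

#' Transcriptome-wide rhythm detection with FDR control
#'
#' Runs the model-selection classifier on every gene, applies
#' Benjamini-Hochberg correction over the full gene universe (flat genes
#' enter with p = 1) and calls a gene rhythmic at its selected period
#' when its q-value is at most `fdr`.
#'
#' @param x An [expression_matrix()] (typically after
#'   [expression_filter()]).
#' @inheritParams classify_gene
#' @param fdr Target false discovery rate for the headline calls.
#' @param fdr_grid Grid of FDR thresholds at which per-period call
#'   counts are additionally reported (for threshold-robustness plots).
#' @return An object of class `rhythm_calls`: list with `results` (one
#'   row per gene: `gene_id`, `selected_period`, `p_value`, `q_value`,
#'   `log2_half_amplitude`, `peak_to_peak_fold`, `phase_hours`,
#'   `mean_log2`, `rhythmic`, `group`), `counts` (named calls per period
#'   at `fdr`), `fdr_grid_counts` (periods x grid matrix), `period_set`,
#'   `fdr`, `n_genes`.
#' @examples
#' sim <- simulate_transcriptome(sim_config(n_genes = 200, seed = 1))
#' calls <- detect_transcriptome(sim$matrix, fdr = 0.1)
#' calls$counts
#' @export
detect_transcriptome <- function(x, period_set = default_periods(),
                                 fdr = 0.1, criterion = "bic",
                                 p_adjust_periods = c("bonferroni", "none"),
                                 fdr_grid = seq(0.01, 0.2, by = 0.01)) {
  stopifnot(inherits(x, "expression_matrix"))
  if (nrow(x$values) == 0L) stop("empty expression matrix")
  if (!is.numeric(fdr) || length(fdr) != 1L || fdr <= 0 || fdr >= 1)
    stop("`fdr` must be in (0, 1)")
  res <- classify_matrix(x$values, x$times, period_set, criterion,
                         p_adjust_periods)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$rhythmic <- !is.na(res$selected_period) & res$q_value <= fdr
  res$group <- NA_integer_
  res <- res[, c("gene_id", "selected_period", "p_value", "q_value",
                 "log2_half_amplitude", "peak_to_peak_fold", "phase_hours",
                 "mean_log2", "rhythmic", "group")]

  labels <- format_period(sort(period_set, decreasing = TRUE))
  sel_lab <- format_period(res$selected_period)
  counts_at <- function(f) {
    called <- !is.na(res$selected_period) & res$q_value <= f
    vapply(labels, function(L) sum(called & sel_lab == L), integer(1))
  }
  grid_counts <- matrix(vapply(fdr_grid, counts_at,
                               integer(length(labels))),
                        nrow = length(labels))
  dimnames(grid_counts) <- list(labels, sprintf("%g", fdr_grid))

  structure(list(results = res, counts = counts_at(fdr),
                 fdr_grid_counts = grid_counts,
                 period_set = sort(period_set, decreasing = TRUE),
                 fdr = fdr, n_genes = nrow(res)),
            class = "rhythm_calls")
}

#' @export
print.rhythm_calls <- function(x, ...) {
  cat(sprintf("rhythm_calls: %d genes, FDR <= %g\n", x$n_genes, x$fdr))
  cat(sprintf("  total rhythmic: %d\n", sum(x$counts)))
  for (L in names(x$counts))
    cat(sprintf("  %s h: %d\n", L, x$counts[[L]]))
  invisible(x)
}

#' @export
as.data.frame.rhythm_calls <- function(x, ...) x$results

#' Permutation null for the number of rhythmic calls at a period
#'
#' Estimates how often a count as large as the observed number of calls
#' at `period_of_interest` arises by chance, by randomly shuffling the
#' time labels and rerunning the full detection.  By default one shared
#' column permutation per round is applied to all genes, preserving the
#' inter-gene correlation structure (the stricter null); set
#' `shared = FALSE` for independent per-gene shuffles.
#'
#' @inheritParams detect_transcriptome
#' @param period_of_interest Period (hours) whose call count is tested.
#' @param k_obs Observed count; when `NULL`, computed from `x` itself.
#' @param n_permutations Number of label shuffles (>= 1).
#' @param seed Integer seed making the permutations reproducible.
#' @param shared Shuffle columns jointly across genes (default) or
#'   per gene.
#' @return A `null_summary`: list with `n_permutations`, `k_obs`,
#'   `permuted_counts`, and the add-one empirical p-value
#'   `(1 + #\{perm >= k_obs\}) / (n_permutations + 1)`.
#' @export
shuffle_null <- function(x, period_of_interest, k_obs = NULL,
                         n_permutations = 199, fdr = 0.1,
                         period_set = default_periods(), seed = NULL,
                         shared = TRUE, ...) {
  stopifnot(inherits(x, "expression_matrix"))
  if (n_permutations < 1L) stop("`n_permutations` must be >= 1")
  pi_idx <- match_period(period_of_interest, sort(period_set,
                                                  decreasing = TRUE))
  if (is.na(pi_idx))
    stop("`period_of_interest` is not in `period_set`")
  lab <- format_period(sort(period_set, decreasing = TRUE))[pi_idx]
  count_at <- function(em) {
    detect_transcriptome(em, period_set = period_set, fdr = fdr,
                         ...)$counts[[lab]]
  }
  if (is.null(k_obs)) k_obs <- count_at(x)
  if (k_obs < 0) stop("`k_obs` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  nt <- length(x$times)
  perm_counts <- vapply(seq_len(n_permutations), function(i) {
    em <- x
    if (shared) {
      em$values <- x$values[, sample.int(nt), drop = FALSE]
    } else {
      em$values <- t(apply(x$values, 1, function(r) r[sample.int(nt)]))
      rownames(em$values) <- rownames(x$values)
    }
    count_at(em)
  }, integer(1))
  structure(list(n_permutations = n_permutations, k_obs = k_obs,
                 period_of_interest = period_of_interest, fdr = fdr,
                 permuted_counts = perm_counts,
                 empirical_p = (1 + sum(perm_counts >= k_obs)) /
                   (n_permutations + 1)),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf(
    "null_summary: %d calls at T = %s h observed; %d shuffles, empirical p = %.4g\n",
    x$k_obs, format_period(x$period_of_interest), x$n_permutations,
    x$empirical_p))
  invisible(x)
}
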