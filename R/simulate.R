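# Synthetic transcriptome time courses.
#
# The generative model is additive cosines on the log2 scale with
# Gaussian noise:
#   y_i(t) = m_i + sum_k A_ik * exp(-lambda * t) * cos(2*pi*(t - phi_ik)/T_k)
#            + eps_t,   eps_t ~ N(0, noise_sd^2)
# Genes rhythmic at each candidate period are split into two anti-phasic
# phase groups whose centers are exactly half a period apart; per-gene
# phases are jittered N(0, 0.5 h) around their group center.

#' Configuration of the synthetic transcriptome generator
#'
#' Defaults emulate the wild-type study design: samples every 2 hr over
#' one 22-hr circadian period in the dark, ~7,212 expressed genes with
#' ~17% circadian, ~1.5% second-harmonic and ~6.4% third-harmonic
#' rhythms, harmonic genes split into two anti-phasic groups with the
#' larger group holding 392/460 of the third-harmonic genes.
#'
#' @param n_genes Number of genes.
#' @param time_start,time_end,time_step Sampling grid in hours.
#' @param circadian_period Fundamental circadian period (hours).
#' @param period_set Candidate rhythm periods (hours).
#' @param fractions Fraction of genes rhythmic at each period, parallel
#'   to `period_set`; must sum to <= 1, remainder is arrhythmic.  Gene
#'   counts per class are `floor(fraction * n_genes)` with the remainder
#'   assigned to the arrhythmic class (deterministic).
#' @param group1_fraction Proportion of each harmonic class assigned to
#'   phase Group 1 (the larger, default 392/460).
#' @param amplitude_meanlog,amplitude_sdlog Lognormal parameters of the
#'   log2 half-amplitude A (defaults: median A = 1, i.e. 4-fold
#'   peak-to-trough).
#' @param baseline_mean,baseline_sd Normal parameters of the mean log2
#'   expression (mesor); default mean 8 = 256 a.u.
#' @param noise_sd Gaussian noise standard deviation in log2 units.
#' @param damping_rate Shared per-hour exponential decay of rhythm
#'   amplitude (`0` = sustained rhythms).
#' @param genotype One of `"WT"`, `"dCSP1"`, `"dMSN1"`, `"none"`; see
#'   [apply_genotype_preset()].
#' @param superimposed_ratio Circadian:harmonic amplitude ratio of the
#'   superimposed component in the `dCSP1` preset.
#' @param phase_jitter_sd Per-gene phase jitter around the group center
#'   phase, in hours.
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 7212,
                       time_start = 0, time_end = 22, time_step = 2,
                       circadian_period = 22,
                       period_set = default_periods(circadian_period),
                       fractions = c(0.17, 0.015, 0.064),
                       group1_fraction = 392 / 460,
                       amplitude_meanlog = 0, amplitude_sdlog = 0.25,
                       baseline_mean = 8, baseline_sd = 1.5,
                       noise_sd = 0.2, damping_rate = 0,
                       genotype = c("WT", "dCSP1", "dMSN1", "none"),
                       superimposed_ratio = 1, phase_jitter_sd = 0.5,
                       seed = 1L) {
  genotype <- match.arg(genotype)
  cfg <- list(n_genes = as.integer(n_genes), time_start = time_start,
              time_end = time_end, time_step = time_step,
              circadian_period = circadian_period, period_set = period_set,
              fractions = fractions, group1_fraction = group1_fraction,
              amplitude_meanlog = amplitude_meanlog,
              amplitude_sdlog = amplitude_sdlog,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, damping_rate = damping_rate,
              genotype = genotype, superimposed_ratio = superimposed_ratio,
              phase_jitter_sd = phase_jitter_sd, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("`n_genes` must be >= 1")
  if (cfg$time_end <= cfg$time_start || cfg$time_step <= 0)
    stop("invalid time grid")
  if (length(cfg$fractions) != length(cfg$period_set))
    stop("`fractions` must be parallel to `period_set`")
  if (any(cfg$fractions < 0) || sum(cfg$fractions) > 1)
    stop("`fractions` must be non-negative and sum to <= 1")
  if (any(cfg$period_set <= 2 * cfg$time_step))
    stop("every period must exceed twice the sampling step ",
         "(fastest rhythm unresolvable)")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (cfg$damping_rate < 0) stop("`damping_rate` must be >= 0")
  if (cfg$group1_fraction < 0 || cfg$group1_fraction > 1)
    stop("`group1_fraction` must be in [0, 1]")
  invisible(cfg)
}

sim_times <- function(cfg) seq(cfg$time_start, cfg$time_end,
                               by = cfg$time_step)

period_class <- function(period, circadian_period) {
  ratio <- circadian_period / period
  if (abs(ratio - 1) < 1e-6) "circadian"
  else if (abs(ratio - 2) < 1e-6) "second_harmonic"
  else if (abs(ratio - 3) < 1e-6) "third_harmonic"
  else sprintf("period_%s", format_period(period))
}

#' Generate a synthetic expression time course with ground truth
#'
#' Draws per-gene parameters (class, group, mesor, amplitude, phase)
#' according to `config`, applies the genotype preset to the truth, and
#' synthesizes the log2 expression matrix from it.  The same config
#' (including seed) always yields a bit-identical matrix and truth.
#'
#' A warning (not an error) is raised when fewer than 4 samples fall in
#' one cycle of the fastest rhythm and noise is present, as period
#' assignment then rests on very few points per cycle.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (an [expression_matrix()]), `truth` (a
#'   data.frame with one row per gene: `gene_id`, `class`, `wt_class`,
#'   `group`, `mesor`, `period_1`, `amplitude_1`, `phase_1`, `period_2`,
#'   `amplitude_2`, `phase_2`; attribute `"group_centers"` records the
#'   per-class group center phases), and `config`.
#' @examples
#' sim <- simulate_transcriptome(sim_config(n_genes = 100, seed = 7))
#' table(sim$truth$class)
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  times <- sim_times(config)
  min_T <- min(config$period_set)
  if (config$noise_sd > 0 &&
      floor(min_T / config$time_step) + 1 < 4)
    warning(sprintf(
      "only %d samples per %s-hr cycle; period assignment will be fragile",
      floor(min_T / config$time_step) + 1L, format_period(min_T)))

  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  counts <- floor(config$fractions * n)
  class_vec <- rep("arrhythmic", n)
  period_vec <- rep(NA_real_, n)
  pos <- 0L
  for (j in seq_along(config$period_set)) {
    if (counts[j] == 0) next
    idx <- pos + seq_len(counts[j])
    class_vec[idx] <- period_class(config$period_set[j],
                                   config$circadian_period)
    period_vec[idx] <- config$period_set[j]
    pos <- pos + counts[j]
  }

  mesor <- rnorm(n, config$baseline_mean, config$baseline_sd)
  group <- rep(NA_integer_, n)
  amp <- rep(NA_real_, n)
  phase <- rep(NA_real_, n)
  centers <- NULL
  for (j in seq_along(config$period_set)) {
    idx <- which(!is.na(period_vec) &
                   abs(period_vec - config$period_set[j]) < 1e-9)
    if (!length(idx)) next
    T <- config$period_set[j]
    k <- length(idx)
    n1 <- round(k * config$group1_fraction)
    group[idx] <- rep(c(1L, 2L), c(n1, k - n1))
    amp[idx] <- rlnorm(k, config$amplitude_meanlog, config$amplitude_sdlog)
    mu1 <- runif(1, 0, T)
    mu2 <- (mu1 + T / 2) %% T
    mu <- ifelse(group[idx] == 1L, mu1, mu2)
    phase[idx] <- (mu + rnorm(k, 0, config$phase_jitter_sd)) %% T
    centers <- rbind(centers,
                     data.frame(class = period_class(T, config$circadian_period),
                                period = T, group1_center = mu1,
                                group2_center = mu2))
  }

  truth <- data.frame(gene_id = ids, class = class_vec,
                      wt_class = class_vec, group = group, mesor = mesor,
                      period_1 = period_vec, amplitude_1 = amp,
                      phase_1 = phase, period_2 = NA_real_,
                      amplitude_2 = NA_real_, phase_2 = NA_real_,
                      stringsAsFactors = FALSE)
  attr(truth, "group_centers") <- centers
  truth <- apply_genotype_preset(truth, config$genotype,
                                 circadian_period = config$circadian_period,
                                 superimposed_ratio = config$superimposed_ratio,
                                 phase_jitter_sd = config$phase_jitter_sd)

  vals <- synthesize_from_truth(truth, times, config$noise_sd,
                                config$damping_rate)
  list(matrix = expression_matrix(vals, times), truth = truth,
       config = config)
}

# Deterministic signal synthesis given a truth table (noise excepted).
synthesize_from_truth <- function(truth, times, noise_sd, damping_rate) {
  n <- nrow(truth)
  env <- exp(-damping_rate * times)
  vals <- matrix(truth$mesor, n, length(times))
  for (comp in c(1L, 2L)) {
    T <- truth[[paste0("period_", comp)]]
    A <- truth[[paste0("amplitude_", comp)]]
    phi <- truth[[paste0("phase_", comp)]]
    has <- which(!is.na(T))
    for (i in has) {
      vals[i, ] <- vals[i, ] +
        A[i] * env * cos(2 * pi * (times - phi[i]) / T[i])
    }
  }
  vals <- vals + matrix(rnorm(n * length(times), 0, noise_sd),
                        n, length(times))
  rownames(vals) <- truth$gene_id
  vals
}

#' Apply a genotype preset to a simulated truth table
#'
#' * `WT` / `none`: identity.
#' * `dCSP1`: every third-harmonic gene becomes `superimposed` — a
#'   circadian (fundamental-period) component is added on top of the
#'   retained harmonic component, with amplitude `superimposed_ratio`
#'   times the harmonic amplitude and a circadian phase drawn around a
#'   per-group center (Group 2 center is half a circadian period from
#'   Group 1).
#' * `dMSN1`: every third-harmonic gene's rhythm switches to the
#'   second-harmonic (11-hr) period; group labels and phases are kept.
#'
#' All other genes are untouched.  The original class is preserved in
#' the `wt_class` column.  `dCSP1` draws random phases, so call
#' `set.seed()` first for reproducibility when using this directly.
#'
#' @param truth A truth data.frame from [simulate_transcriptome()].
#' @param preset `"WT"`, `"none"`, `"dCSP1"` or `"dMSN1"`.
#' @param circadian_period Fundamental period in hours.
#' @param superimposed_ratio Circadian:harmonic amplitude ratio
#'   (`dCSP1`).
#' @param phase_jitter_sd Phase jitter (hours) for the drawn circadian
#'   phases (`dCSP1`).
#' @return The modified truth data.frame.
#' @export
apply_genotype_preset <- function(truth, preset, circadian_period = 22,
                                  superimposed_ratio = 1,
                                  phase_jitter_sd = 0.5) {
  if (!preset %in% c("WT", "none", "dCSP1", "dMSN1"))
    stop("unknown genotype preset: ", preset)
  if (preset %in% c("WT", "none")) return(truth)
  third <- which(truth$class == "third_harmonic")
  if (!length(third)) return(truth)
  if (preset == "dMSN1") {
    truth$period_1[third] <- circadian_period / 2
    truth$class[third] <- "second_harmonic"
    return(truth)
  }
  # dCSP1: superimpose a circadian component; harmonic moves to slot 2
  T <- circadian_period
  mu1 <- runif(1, 0, T)
  mu <- ifelse(truth$group[third] == 1L, mu1, (mu1 + T / 2) %% T)
  truth$period_2[third] <- truth$period_1[third]
  truth$amplitude_2[third] <- truth$amplitude_1[third]
  truth$phase_2[third] <- truth$phase_1[third]
  truth$period_1[third] <- T
  truth$amplitude_1[third] <- superimposed_ratio * truth$amplitude_2[third]
  truth$phase_1[third] <-
    (mu + rnorm(length(third), 0, phase_jitter_sd)) %% T
  truth$class[third] <- "superimposed"
  attr(truth, "circadian_group_centers") <-
    data.frame(group1_center = mu1, group2_center = (mu1 + T / 2) %% T)
  truth
}
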