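# Cross-genotype comparisons and enrichment tests.

#' Pearson correlation of a residual with a reference series
#'
#' Used to ask whether, after subtracting an induced component
#' ([subtract_component()]), the residual rhythm matches a reference
#' profile (e.g. the wild-type harmonic).  Both series are
#' mean-subtracted, so only waveform agreement matters.
#'
#' @param residual,reference Equal-length numeric series on the same
#'   time grid.
#' @return Pearson correlation coefficient.
#' @export
residual_match <- function(residual, reference) {
  if (length(residual) != length(reference))
    stop("series must have equal length")
  if (sd(residual) == 0 || sd(reference) == 0)
    stop("constant series: correlation undefined")
  cor(residual, reference)
}

#' Cross-tabulate selected periods between two detection runs
#'
#' Counts, over a gene set, how genes called at each period in run A are
#' called in run B (including "none"), the bookkeeping behind period
#' reassignment between genotypes.
#'
#' @param calls_a,calls_b `rhythm_calls` objects or results data.frames
#'   for the two conditions.
#' @param gene_set Gene IDs to tabulate; default: all shared genes.
#' @param fdr Calls with `q_value > fdr` count as "none"; `NULL` (the
#'   default) trusts each table's `rhythmic` column.
#' @return A contingency matrix, rows = periods in A, columns = periods
#'   in B; row and column sums both equal the gene-set size.
#' @export
period_reassignment_table <- function(calls_a, calls_b, gene_set = NULL,
                                      fdr = NULL) {
  res_a <- if (inherits(calls_a, "rhythm_calls")) calls_a$results else calls_a
  res_b <- if (inherits(calls_b, "rhythm_calls")) calls_b$results else calls_b
  shared <- intersect(res_a$gene_id, res_b$gene_id)
  if (!length(shared)) stop("the two results tables share no gene IDs")
  if (is.null(gene_set)) gene_set <- shared
  missing <- setdiff(gene_set, shared)
  if (length(missing))
    stop("gene(s) absent from both tables: ",
         paste(head(missing, 5), collapse = ", "))
  lab <- function(res) {
    called <- if (is.null(fdr)) res$rhythmic else
      (!is.na(res$selected_period) & res$q_value <= fdr)
    ifelse(called, format_period(res$selected_period), "none")
  }
  la <- setNames(lab(res_a), res_a$gene_id)[gene_set]
  lb <- setNames(lab(res_b), res_b$gene_id)[gene_set]
  levels <- unique(c(sort(unique(c(la, lb)[c(la, lb) != "none"]),
                          decreasing = TRUE), "none"))
  table(A = factor(la, levels), B = factor(lb, levels))
}

# One-sided rank-sum p-value (enrichment: set values larger).
# Exact via the Wilcoxon distribution when the data are untied and the
# problem is small; otherwise normal approximation with tie correction
# and continuity correction.  All-tied data give p = 1.
ranksum_p <- function(x_set, x_bg, vif = 1, exact_limit = 1000) {
  n1 <- length(x_set); n2 <- length(x_bg)
  all_r <- rank(c(x_set, x_bg))
  W <- sum(all_r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(all_r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= exact_limit && vif == 1) {
    p <- pwilcox(W - 1, n1, n2, lower.tail = FALSE)
    return(list(W = W, p = p, method = "exact"))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(W = W, p = 1, method = "degenerate"))
  z <- (W - mu - 0.5) / sqrt(sigma2 * vif)
  list(W = W, p = pnorm(z, lower.tail = FALSE), method = "normal")
}

#' Competitive gene-set test of rhythmic components
#'
#' Asks whether genes in a set carry larger per-gene statistics (for
#' example cosinor F statistics at a queried period, see
#' [cosinor_f_statistics()]) than genes outside the set — a competitive
#' test in the spirit of camera, implemented as a one-sided Wilcoxon
#' rank-sum with an optional variance-inflation correction for
#' inter-gene correlation.  BH adjustment is applied across all
#' set-by-component tests performed in the one call.
#'
#' @param statistics Named numeric vector (one component) or matrix
#'   (genes x components, named columns) of per-gene statistics covering
#'   the whole gene universe.
#' @param gene_sets Named list of gene-ID vectors (a bare character
#'   vector is treated as one set); each set must be a proper non-empty
#'   subset of the universe.
#' @param inter_gene_cor Optional average pairwise correlation of set
#'   members' profiles (scalar or per-set vector); when supplied, the
#'   rank-sum variance is inflated by `1 + (n_set - 1) * cor`
#'   (camera-style correction) and the normal approximation is used.
#' @return An `enrichment_result` data.frame: one row per set and
#'   component with `set`, `component`, `n_set`, `statistic` (rank-sum
#'   W), `p_value`, `adj_p_value` (BH across all rows), `direction` and
#'   `method`.
#' @examples
#' stats <- setNames(rnorm(100), sprintf("g%03d", 1:100))
#' competitive_gene_set_test(stats, list(top = names(sort(stats,
#'                                       decreasing = TRUE))[1:10]))
#' @export
competitive_gene_set_test <- function(statistics, gene_sets,
                                      inter_gene_cor = NULL) {
  if (is.null(dim(statistics)))
    statistics <- matrix(statistics, ncol = 1,
                         dimnames = list(names(statistics), "statistic"))
  if (is.null(rownames(statistics)))
    stop("`statistics` must be named by gene ID")
  if (is.character(gene_sets)) gene_sets <- list(set = gene_sets)
  if (is.null(names(gene_sets)))
    names(gene_sets) <- sprintf("set%d", seq_along(gene_sets))
  universe <- rownames(statistics)
  rows <- list()
  for (s in names(gene_sets)) {
    members <- gene_sets[[s]]
    bad <- setdiff(members, universe)
    if (length(bad))
      stop("set '", s, "' has gene(s) outside the statistic universe: ",
           paste(head(bad, 5), collapse = ", "))
    if (length(members) == 0L)
      stop("set '", s, "' is empty")
    if (length(members) == length(universe))
      stop("set '", s, "' equals the universe: competitive test undefined")
    vif <- 1
    if (!is.null(inter_gene_cor)) {
      rho <- if (length(inter_gene_cor) > 1) inter_gene_cor[[s]] else
        inter_gene_cor
      vif <- max(1, 1 + (length(members) - 1) * rho)
    }
    for (comp in colnames(statistics)) {
      in_set <- universe %in% members
      rs <- ranksum_p(statistics[in_set, comp], statistics[!in_set, comp],
                      vif = vif,
                      exact_limit = if (is.null(inter_gene_cor)) 1000 else 0)
      rows[[length(rows) + 1L]] <-
        data.frame(set = s, component = comp, n_set = length(members),
                   statistic = rs$W, p_value = rs$p,
                   direction = "enriched", method = rs$method,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p_value <- p.adjust(out$p_value, method = "BH")
  out <- out[, c("set", "component", "n_set", "statistic", "p_value",
                 "adj_p_value", "direction", "method")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' One-sided overlap (Fisher) enrichment of two gene sets
#'
#' Hypergeometric upper-tail probability of observing at least the seen
#' overlap between two sets drawn from a common universe — the one-sided
#' Fisher's exact test on the 2x2 membership table.
#'
#' @param set_a,set_b Character vectors of gene IDs.
#' @param universe Character vector containing both sets.
#' @param alternative `"greater"` (enrichment, default) or
#'   `"two.sided"`.
#' @return An `enrichment_result` data.frame row with the overlap count
#'   as statistic.
#' @export
overlap_enrichment <- function(set_a, set_b, universe,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe)))
    stop("both sets must be subsets of the universe")
  if (!length(universe)) stop("empty universe")
  k <- length(intersect(set_a, set_b))
  m <- length(set_a); nb <- length(set_b); N <- length(universe)
  p <- if (alternative == "greater") {
    phyper(k - 1, m, N - m, nb, lower.tail = FALSE)
  } else {
    fisher.test(matrix(c(k, m - k, nb - k, N - m - nb + k), 2, 2))$p.value
  }
  out <- data.frame(set = "A_vs_B", component = "overlap",
                    n_set = m, statistic = k, p_value = p,
                    adj_p_value = p,
                    direction = if (alternative == "greater") "enriched"
                    else "two.sided",
                    method = "hypergeometric", stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}
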