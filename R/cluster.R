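# Anti-phasic phase-group clustering and circular phase statistics.

# Circular mean of phases living on a cycle of length `period` (hours).
circular_mean_phase <- function(phases, period) {
  ang <- 2 * pi * phases / period
  (period * atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% period
}

# Circular distance between two phases on the cycle, in [0, period/2].
circular_distance <- function(p1, p2, period) {
  d <- abs(p1 - p2) %% period
  min(d, period - d)
}

centered_profiles <- function(x, gene_set) {
  stopifnot(inherits(x, "expression_matrix"))
  missing <- setdiff(gene_set, rownames(x$values))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(head(missing, 5), collapse = ", "))
  sub <- x$values[gene_set, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0))
    stop("constant profile (undefined correlation) for gene(s): ",
         paste(gene_set[sds == 0], collapse = ", "))
  sub - rowMeans(sub)
}

#' Cluster genes into two anti-phasic groups
#'
#' Mean-subtracts each profile, computes the correlation distance
#' `d(i, j) = 1 - Pearson r(i, j)`, builds an average-linkage
#' hierarchical tree and cuts it at two clusters.  Clusters are
#' relabeled so Group 1 is the larger one, matching the convention that
#' the dominant phase group is Group 1.
#'
#' @param x An [expression_matrix()].
#' @param gene_set Character vector of at least two gene IDs to cluster
#'   (e.g. the genes called rhythmic at the third harmonic).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param phases Optional named vector of acrophases (hours) used to
#'   annotate per-group circular mean phases.
#' @param period Cycle length for the circular phase means (required
#'   with `phases`).
#' @return A `cluster_assignment`: list with `groups` (named 1/2
#'   vector), `sizes`, `linkage`, `order` (dendrogram leaf order) and,
#'   when phases were supplied, `group_phase` (circular mean phase per
#'   group, hours).
#' @examples
#' sim <- simulate_transcriptome(sim_config(n_genes = 300, seed = 2))
#' third <- sim$truth$gene_id[sim$truth$class == "third_harmonic"]
#' cl <- cluster_antiphasic(sim$matrix, third)
#' cl$sizes
#' @export
cluster_antiphasic <- function(x, gene_set,
                               linkage = c("average", "complete", "ward.D2"),
                               phases = NULL, period = NULL) {
  linkage <- match.arg(linkage)
  if (length(gene_set) < 2L) stop("need at least 2 genes to cluster")
  cen <- centered_profiles(x, gene_set)
  cc <- cor(t(cen))
  hc <- hclust(as.dist(1 - cc), method = linkage)
  grp <- cutree(hc, k = 2)
  if (sum(grp == 2L) > sum(grp == 1L)) grp <- 3L - grp
  out <- list(groups = grp,
              sizes = c(`1` = sum(grp == 1L), `2` = sum(grp == 2L)),
              linkage = linkage, order = hc$order)
  if (!is.null(phases)) {
    if (is.null(period)) stop("`period` is required with `phases`")
    ph <- phases[names(grp)]
    if (anyNA(ph)) stop("phases missing for some clustered genes")
    out$group_phase <- vapply(1:2, function(g)
      circular_mean_phase(ph[grp == g], period), numeric(1))
    names(out$group_phase) <- c("1", "2")
    out$period <- period
  }
  structure(out, class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s linkage): Group 1 = %d, Group 2 = %d\n",
              x$linkage, x$sizes[["1"]], x$sizes[["2"]]))
  if (!is.null(x$group_phase))
    cat(sprintf("  circular mean phases: %.3g h vs %.3g h (T = %g h)\n",
                x$group_phase[["1"]], x$group_phase[["2"]], x$period))
  invisible(x)
}

#' Circular phase difference between two gene groups
#'
#' Computes the circular mean acrophase of each group on the common
#' period's cycle and returns their circular distance, in hours and in
#' radians (`2*pi*hours/T`).  Two perfectly anti-phasic groups are half
#' a period, i.e. pi radians, apart.
#'
#' @param assignment A `cluster_assignment` from [cluster_antiphasic()].
#' @param calls A `rhythm_calls` object or results data.frame providing
#'   `gene_id`, `selected_period` and `phase_hours`.
#' @return List with `hours`, `radians`, `period` and
#'   `group_mean_phase` (the two circular means, hours).
#' @export
phase_group_difference <- function(assignment, calls) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  res <- if (inherits(calls, "rhythm_calls")) calls$results else calls
  idx <- match(names(assignment$groups), res$gene_id)
  if (anyNA(idx)) stop("clustered gene(s) missing from results table")
  T <- unique(round(res$selected_period[idx], 6))
  if (length(T) != 1L || is.na(T))
    stop("all clustered genes must share one selected period")
  T <- res$selected_period[idx][1]
  ph <- res$phase_hours[idx]
  m1 <- circular_mean_phase(ph[assignment$groups == 1L], T)
  m2 <- circular_mean_phase(ph[assignment$groups == 2L], T)
  h <- circular_distance(m1, m2, T)
  list(hours = h, radians = 2 * pi * h / T, period = T,
       group_mean_phase = c(`1` = m1, `2` = m2))
}

#' Z-score standardized expression profiles
#'
#' Standardizes each gene's profile to mean 0 and unit standard
#' deviation across time; optionally summarizes groups by their
#' pointwise mean trace (the standard way to display co-regulated
#' anti-phasic groups).
#'
#' @param x An [expression_matrix()].
#' @param gene_set Gene IDs to standardize.
#' @param groups Optional named group membership vector (e.g. from
#'   [cluster_antiphasic()]).
#' @return List with `zscores` (genes x times) and, when `groups` is
#'   given, `group_trace` (groups x times pointwise means).
#' @export
zscore_profiles <- function(x, gene_set, groups = NULL) {
  cen <- centered_profiles(x, gene_set)  # errors on zero variance
  z <- cen / apply(cen, 1, sd)
  out <- list(zscores = z)
  if (!is.null(groups)) {
    g <- groups[rownames(z)]
    out$group_trace <- do.call(rbind, lapply(sort(unique(g)), function(k)
      colMeans(z[g == k, , drop = FALSE])))
    rownames(out$group_trace) <- sort(unique(g))
  }
  out
}

#' Pairwise Pearson correlation matrix of expression profiles
#'
#' Correlations of the mean-subtracted profiles, returned in the
#' supplied gene order (e.g. the leaf order of a reference clustering,
#' so the same arrangement can be compared across genotypes).
#'
#' @param x An [expression_matrix()].
#' @param gene_set Gene IDs to correlate.
#' @param gene_order Optional ordering of `gene_set` for the output.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation_matrix <- function(x, gene_set, gene_order = NULL) {
  cen <- centered_profiles(x, gene_set)
  if (!is.null(gene_order)) {
    if (!setequal(gene_order, gene_set))
      stop("`gene_order` must be a permutation of `gene_set`")
    cen <- cen[gene_order, , drop = FALSE]
  }
  cor(t(cen))
}
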