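test_that("subtracting a component removes it completely and only it", {
  # pure circadian input: residual is the flat mesor
  y <- make_cosine(wt_times, 22, A = 1.3, mesor = 6)
  r <- subtract_component(y, wt_times, 22)
  expect_lt(sqrt(mean((r - 6)^2)), 1e-9)

  # refitting at the subtracted period finds no amplitude left
  set.seed(55)
  for (i in 1:10) {
    y <- rnorm(12, 8)
    r <- subtract_component(y, wt_times, 22)
    expect_lt(fit_cosinor(r, wt_times, 22)$half_amplitude, 1e-9)
  }

  # two-component signal: the other harmonic survives intact
  t11 <- seq(0, 20, by = 2)  # endpoint-exclusive: harmonics orthogonal
  y2 <- make_cosine(t11, 22) + make_cosine(t11, 22 / 3, A = 0.7)
  r2 <- subtract_component(y2, t11, 22)
  expect_equal(residual_match(r2, make_cosine(t11, 22 / 3, A = 0.7)), 1,
               tolerance = 1e-9)

  # residual equals series minus the lm oracle fit, elementwise
  set.seed(56)
  y3 <- make_cosine(wt_times, 22) + make_cosine(wt_times, 22 / 3, A = 0.8) +
    rnorm(12, 0, 0.25)
  orc <- lm_cosinor(y3, wt_times, 22)
  expected <- y3 - orc$a * cos(2 * pi * wt_times / 22) -
    orc$b * sin(2 * pi * wt_times / 22)
  expect_equal(subtract_component(y3, wt_times, 22), expected,
               tolerance = 1e-9)
})

test_that("residual_match is the mean-subtracted Pearson correlation", {
  y <- make_cosine(wt_times, 11, mesor = 4)
  expect_equal(residual_match(y, y), 1)
  expect_equal(residual_match(make_cosine(wt_times, 11),
                              make_cosine(wt_times, 11, phase = 5.5)), -1,
               tolerance = 1e-9)
  set.seed(58)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(residual_match(a, b),
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
               tolerance = 1e-12)
  expect_error(residual_match(rep(1, 12), a), "constant")
})

test_that("period reassignment tables count pairs exactly", {
  sim <- simulate_transcriptome(sim_config(n_genes = 200, seed = 19))
  calls <- detect_transcriptome(sim$matrix)
  tab <- period_reassignment_table(calls, calls)
  expect_equal(sum(tab), 200)
  expect_equal(sum(diag(tab)), 200)  # identical calls: diagonal table

  # brute-force pair counting on two different runs
  sim2 <- simulate_transcriptome(sim_config(n_genes = 200, seed = 20,
                                            noise_sd = 0.6))
  calls2 <- detect_transcriptome(sim2$matrix)
  tab2 <- period_reassignment_table(calls, calls2)
  lab <- function(res) ifelse(res$rhythmic,
                              ifelse(abs(res$selected_period - 22) < .01, "22",
                                     ifelse(abs(res$selected_period - 11) < .01,
                                            "11", "7.33")), "none")
  la <- lab(calls$results); lb <- lab(calls2$results)
  for (i in rownames(tab2)) for (j in colnames(tab2)) {
    expect_equal(unname(tab2[i, j]), sum(la == i & lb == j))
  }
  expect_equal(sum(tab2), 200)
})

test_that("dMSN1 simulation shifts the third-harmonic mass to the 11-hr cell", {
  cfg_wt <- sim_config(n_genes = 800, seed = 23)
  cfg_msn <- sim_config(n_genes = 800, seed = 23, genotype = "dMSN1")
  calls_wt <- detect_transcriptome(simulate_transcriptome(cfg_wt)$matrix)
  sim_msn <- simulate_transcriptome(cfg_msn)
  calls_msn <- detect_transcriptome(sim_msn$matrix)
  ex_third <- sim_msn$truth$gene_id[sim_msn$truth$wt_class ==
                                      "third_harmonic"]
  tab <- period_reassignment_table(calls_wt, calls_msn, gene_set = ex_third)
  # the dominant cell is (7.33 in WT) -> (11 in dMSN1)
  expect_gt(tab["7.33", "11"], 0.8 * length(ex_third))
  expect_equal(sum(tab), length(ex_third))
})

test_that("competitive test matches the exact rank-sum tail", {
  # 10 set genes all above 90 background genes: minimal achievable p
  stats <- setNames(c(rnorm(90), rnorm(10) + 50), sprintf("g%03d", 1:100))
  res <- competitive_gene_set_test(stats,
                                   list(top = sprintf("g%03d", 91:100)))
  expect_equal(res$p_value, exp(-lchoose(100, 10)), tolerance = 1e-12)
  expect_equal(res$method, "exact")

  # complete ties are uninformative
  tied <- setNames(rep(1, 50), sprintf("g%03d", 1:50))
  res_t <- competitive_gene_set_test(tied, list(s = sprintf("g%03d", 1:10)))
  expect_equal(res_t$p_value, 1)

  expect_error(competitive_gene_set_test(stats,
                                         list(all = names(stats))),
               "universe")
  expect_error(competitive_gene_set_test(stats, list(none = character(0))),
               "empty")
})

test_that("competitive test is calibrated under an exchangeable null", {
  set.seed(71)
  ids <- sprintf("g%03d", 1:100)
  ps <- vapply(1:50, function(i) {
    stats <- setNames(rnorm(100), ids)
    competitive_gene_set_test(stats, list(s = sample(ids, 15)))$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("BH adjustment spans all set-by-component tests in one call", {
  set.seed(72)
  ids <- sprintf("g%03d", 1:60)
  stats <- matrix(rnorm(120), 60, 2, dimnames = list(ids, c("22", "7.33")))
  stats[1:10, 2] <- stats[1:10, 2] + 3
  res <- competitive_gene_set_test(stats, list(s1 = ids[1:10],
                                               s2 = ids[31:40]))
  expect_equal(nrow(res), 4)
  expect_equal(res$adj_p_value, p.adjust(res$p_value, "BH"))
  expect_true(all(res$adj_p_value >= res$p_value - 1e-15))
  hit <- res$set == "s1" & res$component == "7.33"
  expect_lt(res$adj_p_value[hit], 0.05)
})

test_that("overlap enrichment equals direct hypergeometric summation", {
  # universe 100, |A| = 20, |B| = 30, overlap 12
  uni <- sprintf("g%03d", 1:100)
  A <- uni[1:20]
  B <- uni[c(1:12, 51:68)]
  res <- overlap_enrichment(A, B, uni)
  oracle <- sum(dhyper(12:20, 20, 80, 30))
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  expect_equal(res$statistic, 12)

  # A inside B = universe: overlap is forced, p = 1
  expect_equal(overlap_enrichment(uni[1:5], uni, uni)$p_value, 1)
  # zero overlap: P(X >= 0) = 1
  expect_equal(overlap_enrichment(uni[1:5], uni[6:10], uni)$p_value, 1)
  expect_error(overlap_enrichment(c(A, "zzz"), B, uni), "subsets")
})

test_that("gene-set files parse named sets", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# name: alpha", "g1", "g2", "# name: beta", "g9"), path)
  sets <- read_gene_sets(path)
  expect_equal(sets, list(alpha = c("g1", "g2"), beta = "g9"))
})
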