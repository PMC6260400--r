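test_that("a noiseless cosine gene evaluates the signal model exactly", {
  times <- seq(0, 22, by = 1)
  cfg <- sim_config(n_genes = 1, time_step = 1, fractions = c(1, 0, 0),
                    amplitude_sdlog = 0, baseline_sd = 0, baseline_mean = 8,
                    noise_sd = 0, phase_jitter_sd = 0, seed = 1)
  sim <- simulate_transcriptome(cfg)
  tr <- sim$truth
  expect_equal(tr$class, "circadian")
  y <- sim$matrix$values[1, ]
  expected <- 8 + tr$amplitude_1 *
    cos(2 * pi * (times - tr$phase_1) / 22)
  expect_equal(unname(y), expected, tolerance = 1e-12)
  # with phase 0, amplitude 1, mesor 8: y(0)=9, y(11)=7, y(22)=9
  shifted <- 8 + cos(2 * pi * (times - 0) / 22)
  expect_equal(shifted[times == 0], 9)
  expect_equal(shifted[times == 11], 7)
  expect_equal(shifted[times == 22], 9)
})

test_that("class counts follow the floor-then-remainder rounding rule", {
  cfg <- sim_config(n_genes = 7212, fractions = c(0.17, 0.015, 0.064),
                    seed = 1)
  sim <- simulate_transcriptome(cfg)
  counts <- table(sim$truth$class)
  # independent oracle: floor of each fraction times n
  expect_equal(unname(counts[["circadian"]]), floor(0.17 * 7212))      # 1226
  expect_equal(unname(counts[["second_harmonic"]]), floor(0.015 * 7212)) # 108
  expect_equal(unname(counts[["third_harmonic"]]), floor(0.064 * 7212)) # 461
  expect_equal(unname(counts[["arrhythmic"]]),
               7212 - floor(0.17 * 7212) - floor(0.015 * 7212) -
                 floor(0.064 * 7212))
})

test_that("identical configs give bit-identical matrices and truths", {
  cfg <- sim_config(n_genes = 200, seed = 33, genotype = "dCSP1")
  s1 <- simulate_transcriptome(cfg)
  s2 <- simulate_transcriptome(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)
})

test_that("group phase centers are exactly anti-phasic; genes jitter around them", {
  sim <- simulate_transcriptome(sim_config(n_genes = 500, seed = 2))
  centers <- attr(sim$truth, "group_centers")
  expect_equal(nrow(centers), 3)
  d <- abs(centers$group2_center - centers$group1_center) %% centers$period
  expect_equal(pmin(d, centers$period - d), centers$period / 2,
               tolerance = 1e-12)
  # per-gene phases live on the right cycle and near their center
  third <- sim$truth[sim$truth$class == "third_harmonic", ]
  expect_true(all(third$phase_1 >= 0 & third$phase_1 < third$period_1))
  expect_true(all(third$group %in% 1:2))
})

test_that("noiseless simulated genes are recovered to machine precision", {
  cfg <- sim_config(n_genes = 60, noise_sd = 0, damping_rate = 0, seed = 17)
  sim <- simulate_transcriptome(cfg)
  rhythmic <- which(sim$truth$class != "arrhythmic")[1:10]
  for (i in rhythmic) {
    tr <- sim$truth[i, ]
    fit <- fit_cosinor(sim$matrix$values[i, ], sim$matrix$times,
                       tr$period_1)
    expect_equal(fit$mesor, tr$mesor, tolerance = 1e-9)
    expect_equal(fit$half_amplitude, tr$amplitude_1, tolerance = 1e-9)
    d <- abs(fit$phase - tr$phase_1) %% tr$period_1
    expect_lt(min(d, tr$period_1 - d), 1e-9)
  }
})

test_that("genotype presets rewrite only the harmonic classes", {
  sim <- simulate_transcriptome(sim_config(n_genes = 300, seed = 3))
  truth <- sim$truth

  # WT preset is the identity
  expect_identical(apply_genotype_preset(truth, "WT"), truth)

  # dMSN1 moves third-harmonic genes to the 11-hr period, keeps groups
  msn <- apply_genotype_preset(truth, "dMSN1")
  moved <- truth$class == "third_harmonic"
  expect_true(all(msn$period_1[moved] == 11))
  expect_identical(msn$group[moved], truth$group[moved])
  expect_identical(msn[!moved, ], truth[!moved, ])

  # dCSP1 superimposes a circadian component on third-harmonic genes
  set.seed(1)
  csp <- apply_genotype_preset(truth, "dCSP1")
  expect_true(all(csp$class[moved] == "superimposed"))
  expect_equal(csp$period_1[moved], rep(22, sum(moved)))
  expect_equal(csp$period_2[moved], truth$period_1[moved])
  expect_equal(csp$amplitude_1[moved], csp$amplitude_2[moved])  # 1:1 ratio
  untouched <- csp[!moved, ]
  attr(untouched, "circadian_group_centers") <- NULL
  expect_identical(untouched, truth[!moved, ])

  expect_error(apply_genotype_preset(truth, "dXYZ"), "unknown")
})

test_that("damping applies a shared exponential envelope", {
  cfg <- sim_config(n_genes = 5, time_end = 46, fractions = c(1, 0, 0),
                    noise_sd = 0, damping_rate = 0.05, phase_jitter_sd = 0,
                    amplitude_sdlog = 0, baseline_sd = 0, seed = 5)
  sim <- simulate_transcriptome(cfg)
  tr <- sim$truth[1, ]
  t <- sim$matrix$times
  expected <- tr$mesor + tr$amplitude_1 * exp(-0.05 * t) *
    cos(2 * pi * (t - tr$phase_1) / 22)
  expect_equal(unname(sim$matrix$values[1, ]), expected, tolerance = 1e-12)
})

test_that("invalid configurations are rejected; fragile grids warn", {
  expect_error(sim_config(fractions = c(0.8, 0.2, 0.3)), "sum to <= 1")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(time_step = 4), "twice the sampling step")
  # 3 samples per cycle of the fastest rhythm: warn, not error
  cfg <- sim_config(n_genes = 10, time_step = 3, time_end = 21,
                    period_set = c(22, 8), fractions = c(0.2, 0.2),
                    seed = 1)
  expect_warning(simulate_transcriptome(cfg), "samples per")
})

test_that("truth JSON and config YAML round-trip", {
  sim <- simulate_transcriptome(sim_config(n_genes = 40, seed = 8,
                                           genotype = "dCSP1"))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  back <- read_truth_json(path)
  expect_equal(back$gene_id, sim$truth$gene_id)
  expect_equal(back$period_2, sim$truth$period_2)
  expect_equal(back$phase_1, sim$truth$phase_1, tolerance = 1e-12)

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_genes: 55", "seed: 4", "genotype: dMSN1",
               "noise_sd: 0.3"), yml)
  cfg <- read_sim_config(yml)
  expect_equal(cfg$n_genes, 55L)
  expect_equal(cfg$genotype, "dMSN1")
  writeLines(c("n_genes: 5", "bogus_key: 1"), yml)
  expect_error(read_sim_config(yml), "bogus_key")
})
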