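test_that("simulation config rejects invalid parameters", {
  expect_error(simulation_config(n_eloci = 0), "positive")
  expect_error(simulation_config(frac_differential = 1.2), "frac_differential")
  expect_error(simulation_config(disorder_low = -1), "concentration")
  expect_error(simulation_config(coverage_mean = 0), "coverage")
})

test_that("epiallele simulation is deterministic and honours frac_differential", {
  cfg <- simulation_config(seed = 21, n_patients = 2, regions_per_patient = 2,
                           n_normal = 3, n_eloci = 40, frac_differential = 0.25)
  s1 <- simulate_epiallele_data(cfg)
  s2 <- simulate_epiallele_data(cfg)
  expect_identical(s1, s2)
  expect_equal(sum(s1$truth$differential), 10)

  none <- simulate_epiallele_data(simulation_config(seed = 21, n_patients = 2,
                                                    regions_per_patient = 2,
                                                    n_normal = 3, n_eloci = 40,
                                                    frac_differential = 0))
  expect_equal(sum(none$truth$differential), 0)
  expect_true(all(none$truth$delta_true == 0))
})

test_that("planted ordered and disordered vectors have the expected disorder", {
  cfg <- simulation_config(seed = 22, n_patients = 2, regions_per_patient = 2,
                           n_normal = 2, n_eloci = 200, frac_differential = 0.5)
  sim <- simulate_epiallele_data(cfg)
  tr <- sim$truth[sim$truth$differential, ]
  hi <- pmax(tr$epi_tumour, tr$epi_normal)
  lo <- pmin(tr$epi_tumour, tr$epi_normal)
  # disordered side near the uniform maximum 0.9375, ordered side near a pole
  expect_gt(mean(hi), 0.85)
  expect_lt(mean(lo), 0.15)
  # whenever >= 95% of mass sits on one pattern, epipoly <= 1 - 0.95^2
  pole_mass <- vapply(seq_len(nrow(tr)), function(i) {
    side <- if (tr$epi_tumour[i] < tr$epi_normal[i]) "pA." else "pB."
    max(as.numeric(tr[i, paste0(side, 0:15)]))
  }, numeric(1))
  conc <- pole_mass >= 0.95
  expect_true(any(conc))
  expect_true(all(lo[conc] <= 1 - 0.95^2 + 1e-12))
})

test_that("empirical epipolymorphism converges to the truth value at high coverage", {
  cfg <- simulation_config(seed = 23, n_patients = 1, regions_per_patient = 2,
                           n_normal = 2, n_eloci = 30, frac_differential = 0.3,
                           coverage_mean = 10000, coverage_dispersion = 1e6)
  sim <- simulate_epiallele_data(cfg)
  prof <- elocus_profiles(sim$counts)
  truth_epi <- ifelse(sim$samples$group[match(prof$sample_id, sim$samples$sample_id)] == "tumour",
                      sim$truth$epi_tumour[match(prof$elocus_id, sim$truth$elocus_id)],
                      sim$truth$epi_normal[match(prof$elocus_id, sim$truth$elocus_id)])
  err <- abs(prof$epipolymorphism - truth_epi)
  expect_lt(mean(err), 0.01)
  # multinomial sampling error at depth 1e4 keeps even the worst locus close
  expect_lt(max(err), 0.05)
})

test_that("expression simulation follows the linear model exactly when noiseless", {
  cfg0 <- simulation_config(seed = 24, beta_meth = -2, beta_epi = 0, noise_sd = 0)
  prof <- data.frame(elocus_id = rep(c("e1", "e2"), each = 6),
                     sample_id = rep(paste0("S", 1:6), 2),
                     epipolymorphism = runif(12), avg_methylation = runif(12),
                     depth = 30)
  ex <- simulate_expression(prof, cfg0)
  # beta_epi = 0, noise 0 -> exact affine function of methylation
  for (g in 1:2) {
    meth <- prof$avg_methylation[prof$elocus_id == c("e1", "e2")[g]]
    fit <- lm(ex$expression[g, ] ~ meth)
    expect_lt(sum(residuals(fit)^2), 1e-20)
    expect_equal(unname(coef(fit)[2]), -2)
  }
  # noiseless full model has RSS 0 with beta_epi != 0
  cfg1 <- simulation_config(seed = 24, beta_meth = -2, beta_epi = -3, noise_sd = 0)
  ex1 <- simulate_expression(prof, cfg1)
  rss <- sum(residuals(lm(ex1$expression[1, ] ~ prof$avg_methylation[prof$elocus_id == "e1"] +
                            prof$epipolymorphism[prof$elocus_id == "e1"]))^2)
  expect_lt(rss, 1e-20)
  # determinism
  expect_identical(ex1$expression, simulate_expression(prof, cfg1)$expression)
})

test_that("mixture simulation satisfies its structural invariants", {
  cfg <- simulation_config(seed = 25, k_true = 4)
  mix <- simulate_mixture(cfg, m = 120, n = 15)
  expect_equal(unname(colSums(mix$A0)), rep(1, 15), tolerance = 1e-12)
  expect_true(all(mix$D >= 0 & mix$D <= 1))
  expect_true(all(mix$T0 >= 0 & mix$T0 <= 1))
  # noiseless k = 1: every column of D equals the single component
  cfg1 <- simulation_config(seed = 26, k_true = 1, mixture_noise_sd = 0)
  mix1 <- simulate_mixture(cfg1, m = 50, n = 8)
  expect_equal(unname(mix1$D), unname(mix1$T0[, rep(1, 8)]))
})

test_that("tree simulation yields additive distances and Brownian features", {
  expect_error(simulate_tree_data(2), ">= 3")
  td <- simulate_tree_data(6, seed = 27, n_features = 10)
  expect_equal(td$dist, t(td$dist))
  expect_equal(unname(diag(td$dist)), rep(0, 6))
  expect_identical(ape::write.tree(simulate_tree_data(6, seed = 27)$tree),
                   ape::write.tree(td$tree))
  # four-point condition on every leaf quartet of the additive matrix
  d <- td$dist
  for (q in utils::combn(rownames(d), 4, simplify = FALSE)) {
    s <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                d[q[1], q[3]] + d[q[2], q[4]],
                d[q[1], q[4]] + d[q[2], q[3]]))
    expect_lt(abs(s[2] - s[3]), 1e-9)
  }
  expect_equal(dim(td$features), c(6L, 10L))
})
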