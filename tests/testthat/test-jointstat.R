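# The joint significance statistic and the volcano classification.

test_that("the t-test wrapper matches the textbook pooled formula and handles degeneracy", {
  a <- c(10.1, 9.9, 10.0, 10.2, 9.8)
  b <- c(11.0, 10.8, 11.2)
  expect_equal(t_test_two_sample(a, b), oracle_pooled_t_p(a, b),
               tolerance = 1e-10)
  expect_equal(t_test_two_sample(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_lt(t_test_two_sample(c(1, 2, 3), c(101, 102, 103)), 1e-6)
  expect_equal(t_test_two_sample(c(5, 5, 5), c(5, 5)), 1)   # no variance, no shift
  expect_equal(t_test_two_sample(c(5, 5, 5), c(6, 6)), 0)   # no variance, shift
  expect_error(t_test_two_sample(c(1), c(1, 2)), ">= 2")
})

test_that("the Gaussian tail is exact at 0, symmetric, and quadrature-accurate", {
  expect_identical(gaussian_upper_tail(0), 0.5)
  expect_identical(gaussian_upper_tail(-1.5), gaussian_upper_tail(1.5))
  for (z in c(0.3, 1, 1.96, 3, 5)) {
    expect_equal(gaussian_upper_tail(z), oracle_tail_quadrature(z),
                 tolerance = 1e-7)
  }
  expect_lt(gaussian_upper_tail(30), 1e-100)  # stable far into the tail
  expect_gt(gaussian_upper_tail(30), 0)
  expect_error(gaussian_upper_tail(Inf), "finite")
})

test_that("p_joint equals an independent brute-force computation per feature", {
  sim <- simulate_ko_experiment(sim_config(n_proteins = 60,
                                           sites_per_protein = 2,
                                           seed = 17))
  norm <- normalize_channels(sim$phospho, sim$design, "none")
  ratios <- compute_ratios(norm, sim$design)
  joint <- compute_p_joint(ratios, norm, sim$design)
  ko <- as.matrix(norm[, sim$design$channel[sim$design$group == "KO"]])
  ct <- as.matrix(norm[, sim$design$channel[sim$design$group == "Control"]])
  sigma <- sd(ratios$log2_effect)
  for (i in seq_len(nrow(joint))) {
    p_ref <- oracle_pooled_t_p(ko[i, ], ct[i, ]) *
      oracle_tail_quadrature(ratios$log2_effect[i] / sigma)
    expect_equal(joint$p_joint[i], p_ref, tolerance = 1e-8)
  }
  expect_true(all(joint$p_joint <= pmin(joint$p_t, joint$gaussian_tail)))
})

test_that("a null feature with zero effect gets p_joint about one half", {
  design <- toy_design()
  set.seed(4)
  m <- matrix(rnorm(20 * 8, 20, 0.5), 20, 8)
  m[1, ] <- rep(c(10, 10.001), 4)[1:8]
  m[1, 1:5] <- c(10, 10.001, 10, 10.001, 10)  # tiny spread, zero shift
  m[1, 6:8] <- c(10, 10.001, 10.0005)
  ph <- toy_phospho(m, design)
  norm <- normalize_channels(ph, design, "none")
  ratios <- compute_ratios(norm, design)
  joint <- compute_p_joint(ratios, norm, design)
  expect_equal(joint$gaussian_tail[1], 0.5, tolerance = 1e-2)
})

test_that("sigma_global needs at least two tested features", {
  design <- toy_design()
  ph <- toy_phospho(matrix(20, 2, 8), design)
  for (ch in design$channel[1:4]) ph[[ch]][1:2] <- 0
  norm <- normalize_channels(ph, design, "none")
  ratios <- compute_ratios(norm, design)
  expect_error(compute_p_joint(ratios, norm, design),
               "fewer than 2 tested features")
})

test_that("negating effects swaps up and down but preserves p_joint", {
  sim <- simulate_ko_experiment(sim_config(n_proteins = 50,
                                           sites_per_protein = 2,
                                           frac_protein_shift = 0,
                                           seed = 23))
  design <- sim$design
  norm <- normalize_channels(sim$phospho, design, "none")
  swapped <- ksi_design(design$channel,
                        ifelse(design$group == "KO", "Control", "KO"))
  j1 <- compute_p_joint(compute_ratios(norm, design), norm, design)
  j2 <- compute_p_joint(compute_ratios(norm, swapped), norm, swapped)
  expect_equal(j2$p_joint, j1$p_joint)
  c1 <- classify_sites(j1, alpha_joint = 0.01)
  c2 <- classify_sites(j2, alpha_joint = 0.01)
  expect_equal(sum(c1$status == "up"), sum(c2$status == "down"))
  expect_equal(sum(c1$status == "down"), sum(c2$status == "up"))
})

test_that("classification partitions sites and applies the protein exclusion", {
  sim <- simulate_ko_experiment(sim_config(n_proteins = 80,
                                           sites_per_protein = 3,
                                           frac_protein_shift = 0.1,
                                           seed = 31))
  fit <- ksi_fit(sim$phospho, sim$design, sim$proteins)
  cnt <- attr(fit$sites, "status_counts")
  expect_equal(sum(cnt), nrow(sim$phospho))
  sig_prot <- fit$proteins$id[!is.na(fit$proteins$p_joint) &
                                fit$proteins$p_joint < 5e-4]
  on_sig <- fit$sites$accession %in% sig_prot & !fit$sites$insufficient
  expect_true(all(fit$sites$status[on_sig] == "excluded_protein_change"))
  expect_true(!any(fit$sites$status[!on_sig] == "excluded_protein_change"))
  # a site on an untouched protein with a strong change is called, an
  # excluded one is not, whatever its p_joint
  expect_true(all(fit$sites$status %in%
                    c("up", "down", "not_significant",
                      "excluded_protein_change",
                      "insufficient_replicates")))
})

test_that("null type-I behaviour matches the analytic coupling, not the nominal level", {
  # p_joint <= p_t pointwise, so the product passes a 5e-4 cut far more
  # often than 5e-4 under the null; the t-test p itself stays calibrated.
  sim <- simulate_ko_experiment(sim_config(n_proteins = 600,
                                           sites_per_protein = 5,
                                           frac_direct = 0,
                                           frac_indirect_up = 0,
                                           frac_protein_shift = 0,
                                           seed = 47))
  norm <- normalize_channels(sim$phospho, sim$design, "none")
  joint <- compute_p_joint(compute_ratios(norm, sim$design), norm,
                           sim$design)
  rate_joint <- mean(joint$p_joint < 5e-4)
  rate_t <- mean(joint$p_t < 0.05)
  expect_gte(rate_joint, mean(joint$p_t < 5e-4))
  expect_gt(rate_joint, 0.01)   # empirically ~2.8% under the null
  expect_lt(rate_joint, 0.06)
  expect_equal(rate_t, 0.05, tolerance = 0.25)
})
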