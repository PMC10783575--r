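# Direct-target calling, subset reports, Fisher enrichment, in vitro
# phospho ratios.

test_that("direct calls require direction, magnitude, significance and motif", {
  tab <- data.frame(
    id = c("down_ok", "down_weak", "up_strong", "no_motif", "excluded"),
    sequence_13 = c("AAAKAASAEAAAA", "FIHRIDSTEVIYQ", "AAAKAASAEAAAA",
                    "AAAAAASAAAAAA", "AAAKAASAEAAAA"),
    log2_effect = c(-0.5, -0.275, 0.5, -0.9, -0.9),
    p_joint = c(4e-4, 4e-4, 1e-6, 1e-6, 1e-6),
    status = c("down", "down", "up", "down", "excluded_protein_change"),
    stringsAsFactors = FALSE)
  calls <- call_direct_targets(tab)
  calls <- calls[match(tab$id, calls$id), ]
  expect_equal(calls$is_direct,
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(calls$passes_motif[calls$id == "down_weak"])
  expect_false(calls$passes_significance[calls$id == "down_weak"])
  expect_false(calls$is_direct[calls$id == "up_strong"])  # sign rule
  expect_false(calls$is_direct[calls$id == "excluded"])   # ineligible
})

test_that("table-replication mode admits boundary p values, strict mode does not", {
  tab <- data.frame(id = "Cdk18_S66", sequence_13 = "QNQRRFSMEDLNK",
                    log2_effect = -0.332, p_joint = 5e-4,
                    stringsAsFactors = FALSE)
  expect_false(call_direct_targets(tab, mode = "strict")$is_direct)
  expect_true(call_direct_targets(tab,
                                  mode = "table_replication")$is_direct)
})

test_that("tightening either threshold never increases the call count", {
  sim <- simulate_ko_experiment(sim_config(n_proteins = 300,
                                           sites_per_protein = 3,
                                           frac_direct = 0.05,
                                           seed = 13))
  fit <- ksi_fit(sim$phospho, sim$design, sim$proteins)
  n0 <- sum(fit$direct$is_direct)
  for (alpha in c(1e-4, 1e-5)) {
    n <- sum(call_direct_targets(fit$sites,
                                 alpha_joint = alpha)$is_direct)
    expect_lte(n, n0)
  }
  n_eff <- sum(call_direct_targets(fit$sites,
                                   effect_threshold = 0.6)$is_direct)
  expect_lte(n_eff, n0)
  # row order invariance
  set.seed(99)
  shuffled <- fit$sites[sample(nrow(fit$sites)), ]
  c1 <- call_direct_targets(fit$sites)
  c2 <- call_direct_targets(shuffled)
  expect_equal(sort(c1$id[c1$is_direct]), sort(c2$id[c2$is_direct]))
})

test_that("indirect characterization flags planted proline at +1", {
  sim <- simulate_ko_experiment(sim_config(n_proteins = 200,
                                           sites_per_protein = 5,
                                           frac_direct = 0,
                                           frac_indirect_up = 0.1,
                                           seed = 19))
  up <- sim$phospho$sequence_13[sim$truth$class == "indirect_up"]
  res <- characterize_indirect(up, sim$phospho$sequence_13)
  expect_true(res$proline_plus1_enriched)
  # uniform up set or foreground == background: nothing flagged
  res0 <- characterize_indirect(sim$phospho$sequence_13,
                                sim$phospho$sequence_13)
  expect_false(res0$proline_plus1_enriched)
  expect_equal(characterize_indirect(character(0),
                                     sim$phospho$sequence_13)$n_up, 0L)
})

test_that("subset reports intersect categories and carry the call flags", {
  kin <- camk2d_kinase_sites()
  rep1 <- subset_report(kin, list(kinase = kin$gene),
                        mode = "table_replication")
  expect_equal(nrow(rep1), 19)
  expect_equal(sum(rep1$is_direct), 1)
  expect_equal(rep1$id[rep1$is_direct], "Cdk18_S66")
  rep2 <- subset_report(kin, list(phosphatase = c("Ppp1r2")),
                        mode = "table_replication")
  expect_equal(nrow(rep2), 0)
  expect_equal(nrow(subset_report(kin[0, ], list(kinase = "Cdk18"))), 0)
})

test_that("Fisher enrichment equals the hypergeometric tail and its identities", {
  bg <- sprintf("g%03d", 1:500)
  term <- bg[1:10]
  query <- c(bg[1:4], bg[101:116])  # 4 hits, query of 20
  res <- fisher_enrichment(query, list(T1 = term), bg)
  expect_equal(res$p_value, oracle_hyper_tail(4, 20, 10, 500),
               tolerance = 1e-12)
  expect_equal(res$fold_enrichment, (4 / 20) / (10 / 500))
  # query == background: fold 1, p 1
  res_all <- fisher_enrichment(bg, list(T1 = term), bg)
  expect_equal(res_all$fold_enrichment, 1)
  expect_equal(res_all$p_value, 1)
  # zero hits: fold 0, never significant
  res0 <- fisher_enrichment(bg[400:420], list(T1 = term), bg)
  expect_equal(res0$fold_enrichment, 0)
  expect_false(res0$significant)
  expect_error(fisher_enrichment(c("nope"), list(T1 = term), bg),
               "absent from background")
})

test_that("in vitro phospho ratios and the one-way ANOVA match the F oracle", {
  ratios <- c(0, 0, 0, 0.4, 0.5, 0.45, 0.8, 0.85, 0.9)
  dose <- rep(c("0", "0.75", "3.75"), each = 3)
  res <- invitro_phospho_ratio(phospho = ratios, total = rep(1, 9),
                               dose = dose)
  expect_equal(res$p_anova, oracle_anova_p(ratios, dose),
               tolerance = 1e-10)
  expect_equal(unname(res$group_means["0"]), 0)
  # zero phospho -> ratio 0; zero total -> flagged
  res2 <- invitro_phospho_ratio(c(0, 1, 1, 2, 2, 3), c(1e6, 2, 0, 4, 4, 6),
                                rep(c("a", "b"), each = 3))
  expect_equal(res2$ratios$ratio[1], 0)
  expect_true(res2$ratios$flagged[3])
  # identical ratios everywhere -> p 1 by convention
  res3 <- invitro_phospho_ratio(rep(2, 6), rep(4, 6),
                                rep(c("a", "b"), each = 3))
  expect_equal(res3$p_anova, 1)
  expect_error(invitro_phospho_ratio(1:3, 1:3, c("a", "a", "b")),
               ">= 2")
})
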