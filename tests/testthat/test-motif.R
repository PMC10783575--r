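# Centralized sequences, motif matching, position enrichment.

test_that("centralized windows pad with '_' at the termini", {
  expect_equal(centralize_sequence("MEKSSSCESLGAQRSTV", 6),
               "_MEKSSSCESLGA")
  long <- paste0(strrep("A", 6), "S", strrep("G", 20))
  expect_equal(centralize_sequence(long, 7), "AAAAAASGGGGGG")
  tailseq <- paste0(strrep("A", 11), "T")
  expect_equal(centralize_sequence(tailseq, 12), "AAAAAAT______")
  expect_error(centralize_sequence("AAS", 9), "outside")
  expect_error(centralize_sequence("AAGAA", 3), "not S/T/Y")
})

test_that("motif specs parse, validate and match as constraints", {
  spec <- motif_spec("-3:RK,0:ST,+2:DE")
  expect_equal(spec$constraints[["-3"]], c("R", "K"))
  expect_true(motif_match("VLHKSKSEEAHAE", spec))   # K at -3, E at +2
  expect_false(motif_match("EKIGEGTYGVVYK", spec))  # G at -3, Y centre
  expect_false(motif_match("AAAAAASAAAAAA", spec))
  expect_true(motif_match("AAAAAASAAAAAA", motif_spec("0:ST")))
  # '_' at a constrained position never matches
  expect_false(motif_match("___KSKSE_____", motif_spec("-6:A,0:S")))
  expect_error(motif_spec("0:AG"), "subset of \\{S, T, Y\\}")
  expect_error(motif_spec("-9:RK"), "\\[-6, 6\\]")
  expect_error(motif_spec("-3:R_"), "illegal residue")
  expect_equal(motif_match(character(0), spec), logical(0))
})

test_that("the planted CAMK2 motif holds across the curated direct-target set", {
  t1 <- camk2d_direct_targets()
  expect_equal(nrow(t1), 35)
  expect_true(all(motif_match(t1$sequence_13, camk2d_motif())))
  expect_true(all(substr(t1$sequence_13, 7, 7) %in% c("S", "T")))
})

test_that("identical foreground and background yield no enrichment flags", {
  set.seed(6)
  seqs <- simulate_ko_experiment(sim_config(n_proteins = 50,
                                            sites_per_protein = 2,
                                            seed = 6))$phospho$sequence_13
  enr <- position_enrichment(seqs, seqs)
  expect_true(all(!enr$enriched))
  expect_true(all(enr$chi_square == 0))
})

test_that("a planted residue is flagged against a uniform background, others are not", {
  set.seed(7)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- matrix(sample(aas, 200 * 13, replace = TRUE), 200, 13)
  mat[, 4] <- "K"  # position -3
  fg <- apply(mat, 1, paste, collapse = "")
  enr <- position_enrichment(fg, "uniform")
  kx <- enr[enr$position == -3 & enr$residue == "K", ]
  expect_true(kx$enriched)
  expect_lt(kx$p_value, 1e-10)
  # exact binomial oracle agrees that nothing else is that extreme
  other <- enr[!(enr$position == -3 & enr$residue == "K"), ]
  binom_p <- mapply(function(k, n) binom.test(k, n, 1 / 20)$p.value,
                    other$fg_count, other$fg_total)
  expect_true(all(other$p_value[binom_p > 0.01] > 0.001))
  expect_lte(sum(other$enriched), 2)  # chance flags only
})

test_that("the curated direct-target set shows R/K at -3 and D/E at +2", {
  t1 <- camk2d_direct_targets()
  enr <- position_enrichment(t1$sequence_13, "uniform",
                             groups = list(RK = c("R", "K"),
                                           DE = c("D", "E")))
  rk <- enr[enr$position == -3 & enr$residue == "RK", ]
  de <- enr[enr$position == 2 & enr$residue == "DE", ]
  expect_true(rk$enriched)
  expect_true(de$enriched)
  # independent 2x2 oracle via stats::chisq.test on the same counts
  seq_bg <- simulate_ko_experiment(sim_config(n_proteins = 500,
                                              sites_per_protein = 1,
                                              seed = 8))$phospho$sequence_13
  enr2 <- position_enrichment(t1$sequence_13, seq_bg)
  r <- enr2[enr2$position == -3 & enr2$residue == "R", ]
  bgk <- sum(substr(seq_bg, 4, 4) == "R")
  tab <- matrix(c(r$fg_count, r$fg_total - r$fg_count,
                  bgk, length(seq_bg) - bgk), 2, byrow = TRUE)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(r$chi_square, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("enrichment is invariant to foreground order and logs a logo matrix", {
  t1 <- camk2d_direct_targets()
  set.seed(9)
  e1 <- position_enrichment(t1$sequence_13, "uniform")
  e2 <- position_enrichment(sample(t1$sequence_13), "uniform")
  expect_equal(e1$chi_square, e2$chi_square)
  expect_equal(e1$p_value, e2$p_value)
  logo <- attr(e1, "logo")
  expect_equal(dim(logo), c(13, 20))
  expect_gt(logo["-3", "R"] + logo["-3", "K"], 0)
})

test_that("padded positions drop out of the counts", {
  fg <- c("______SAAAAAA", "AAAAAASAAAAAA")
  enr <- position_enrichment(fg, "uniform")
  expect_equal(unique(enr$fg_total[enr$position == -3]), 1)
  expect_equal(unique(enr$fg_total[enr$position == 3]), 2)
  expect_error(position_enrichment(character(0), "uniform"),
               "empty foreground")
})
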