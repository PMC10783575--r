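# Independent oracles used across the suite. These deliberately avoid
# the code paths they check: textbook closed forms and quadrature only.

# Pooled-variance two-sided t-test p-value, from the textbook formula.
oracle_pooled_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tstat), df = na + nb - 2)
}

# Standard-normal upper tail by quadrature of the density.
oracle_tail_quadrature <- function(z) {
  stats::integrate(stats::dnorm, abs(z), Inf, rel.tol = 1e-12)$value
}

# One-sided hypergeometric tail P(X >= h) by explicit summation:
# term size K, query size n, background size N.
oracle_hyper_tail <- function(h, n, K, N) {
  ks <- h:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Classical one-way fixed-effects ANOVA p from the hand-computed F.
oracle_anova_p <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

# A small deterministic 5 KO + 3 Control design.
toy_design <- function() {
  ksi_design(c(paste0("KO", 1:5), paste0("C", 1:3)),
             rep(c("KO", "Control"), c(5, 3)))
}

# Build a native-schema phosphosite table from a log2-intensity matrix.
toy_phospho <- function(log2_mat, design,
                        seqs = NULL) {
  n <- nrow(log2_mat)
  if (is.null(seqs)) seqs <- rep("AAAAAASAAAAAA", n)
  x <- data.frame(id = sprintf("G%03d_S%d", seq_len(n), seq_len(n)),
                  accession = sprintf("P%03d", seq_len(n)),
                  gene = sprintf("G%03d", seq_len(n)),
                  residue = "S", position = seq_len(n),
                  sequence_13 = seqs, stringsAsFactors = FALSE)
  int <- 2^log2_mat
  colnames(int) <- design$channel
  cbind(x, as.data.frame(int))
}
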