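# The joint significance statistic p_joint = p_t x Gaussian upper tail
# of the globally standardized log2 effect, and the volcano-style
# classification with protein-level exclusion.

#' Two-sample t-test p-value on log2 intensities
#'
#' Two-sided unpaired t-test. Pooled variance by default (the classical
#' equal-variance test); Welch's unequal-variance form via
#' \code{var_equal = FALSE}.
#'
#' Degenerate inputs are resolved by convention rather than error: if
#' both groups have zero variance and equal means the p-value is 1 (no
#' evidence of a difference); zero variance with unequal means gives the
#' limit p = 0.
#'
#' @param a,b Numeric vectors, at least two finite values each.
#' @param var_equal Pooled variance (default \code{TRUE}) or Welch.
#' @return The two-sided p-value.
#' @export
t_test_two_sample <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 finite values per group", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b, var.equal = var_equal)$p.value
}

#' Standard-normal upper-tail probability of |z|
#'
#' The area under the standard Gaussian density from \code{|z|} to
#' positive infinity, i.e. \code{1 - pnorm(|z|)}, computed on the
#' complementary scale so it stays accurate far into the tail.
#'
#' @param z Finite numeric vector.
#' @return Probabilities in \code{(0, 0.5]}; exactly 0.5 at \code{z = 0}.
#' @examples
#' gaussian_upper_tail(0)     # 0.5
#' gaussian_upper_tail(1.96)  # ~0.025
#' @export
gaussian_upper_tail <- function(z) {
  if (any(!is.finite(z)))
    stop("'z' must be finite", call. = FALSE)
  stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Compute the joint significance statistic per feature
#'
#' For every feature that passed the replicate filter, combines two
#' complementary notions of significance: \code{p_t}, the two-sample
#' t-test p-value comparing KO and Control log2 intensities, and the
#' Gaussian upper-tail probability of \code{Z = log2_effect /
#' sigma_global}, where \code{sigma_global} is the sample standard
#' deviation of the log2 effects across all tested features. Their
#' product is \code{p_joint}: small only when the change is both
#' statistically reliable within the experiment and large relative to
#' the spread of all effects.
#'
#' @param ratios Output of [compute_ratios()].
#' @param norm The normalized log2 intensity table the ratios came from.
#' @param design A [ksi_design()] object.
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @param sigma_ids Optional character vector restricting the set of
#'   feature ids over which \code{sigma_global} is computed (for
#'   example, to standardize against sites surviving the protein-level
#'   exclusion). Default: all tested features.
#' @return \code{ratios} augmented with \code{p_t}, \code{z},
#'   \code{gaussian_tail} and \code{p_joint} (all \code{NA} for
#'   insufficient-replicate features), with \code{sigma_global} attached
#'   as an attribute of the same name.
#' @export
compute_p_joint <- function(ratios, norm, design, var_equal = TRUE,
                            sigma_ids = NULL) {
  stopifnot(identical(nrow(ratios), nrow(norm)))
  tested <- !ratios$insufficient
  if (sum(tested) < 2L)
    stop("fewer than 2 tested features: sigma_global undefined",
         call. = FALSE)
  in_sigma <- tested
  if (!is.null(sigma_ids)) in_sigma <- tested & ratios$id %in% sigma_ids
  if (sum(in_sigma) < 2L)
    stop("fewer than 2 features in the sigma_global set", call. = FALSE)
  sigma_global <- stats::sd(ratios$log2_effect[in_sigma])
  if (!is.finite(sigma_global) || sigma_global <= 0)
    stop("sigma_global is not positive; effects are degenerate",
         call. = FALSE)
  ko <- as.matrix(norm[, .channels(design, "KO"), drop = FALSE])
  ctrl <- as.matrix(norm[, .channels(design, "Control"), drop = FALSE])
  n <- nrow(ratios)
  p_t <- rep(NA_real_, n)
  for (i in which(tested)) {
    p_t[i] <- t_test_two_sample(ko[i, ], ctrl[i, ], var_equal = var_equal)
  }
  z <- ifelse(tested, ratios$log2_effect / sigma_global, NA_real_)
  tail <- rep(NA_real_, n)
  tail[tested] <- gaussian_upper_tail(z[tested])
  ratios$p_t <- p_t
  ratios$z <- z
  ratios$gaussian_tail <- tail
  ratios$p_joint <- p_t * tail
  attr(ratios, "sigma_global") <- sigma_global
  ratios
}

#' Classify phosphosites, excluding protein-level changes
#'
#' Assigns each phosphosite one of five statuses:
#' \code{insufficient_replicates} (failed the replicate filter),
#' \code{excluded_protein_change} (the parent protein itself changed
#' significantly in the total proteome, so the apparent phospho change
#' may just track protein abundance), \code{up}, \code{down}, or
#' \code{not_significant} according to \code{p_joint < alpha_joint} and
#' the sign of the log2 effect.
#'
#' @param phospho Phosphosite results from [compute_p_joint()]; must
#'   carry an \code{accession} column naming the parent protein.
#' @param protein Optional protein-level results from
#'   [compute_p_joint()] keyed by \code{id} = accession. \code{NULL}
#'   skips the exclusion step.
#' @param alpha_joint Significance threshold on \code{p_joint}
#'   (default 0.0005).
#' @return \code{phospho} with a \code{status} factor column. The
#'   attribute \code{"status_counts"} is the named count table; sites
#'   whose accession has no protein-table match are simply not excluded.
#' @export
classify_sites <- function(phospho, protein = NULL, alpha_joint = 5e-4) {
  status <- rep("not_significant", nrow(phospho))
  status[phospho$insufficient] <- "insufficient_replicates"
  excl <- rep(FALSE, nrow(phospho))
  if (!is.null(protein)) {
    if (!"accession" %in% names(phospho))
      stop("phosphosite results need an 'accession' column for protein ",
           "exclusion", call. = FALSE)
    sig_prot <- protein$id[!is.na(protein$p_joint) &
                             protein$p_joint < alpha_joint]
    excl <- phospho$accession %in% sig_prot
  }
  tested <- !phospho$insufficient
  status[tested & excl] <- "excluded_protein_change"
  sig <- tested & !excl & !is.na(phospho$p_joint) &
    phospho$p_joint < alpha_joint
  status[sig & phospho$log2_effect > 0] <- "up"
  status[sig & phospho$log2_effect < 0] <- "down"
  phospho$status <- factor(status,
                           levels = c("up", "down", "not_significant",
                                      "excluded_protein_change",
                                      "insufficient_replicates"))
  attr(phospho, "status_counts") <- table(phospho$status)
  phospho
}
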