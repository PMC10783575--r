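# Front end: fit the whole substrate-inference analysis in one call and
# interrogate the result through the usual S3 methods.

#' Fit the knockout-phosphoproteomics substrate-inference analysis
#'
#' Runs the full pipeline on a phosphosite table, an optional
#' protein-group table and a sample design: log2 transform and channel
#' normalization, per-feature log2(KO/Control) effects, the joint
#' significance statistic (t-test p-value times the Gaussian upper-tail
#' probability of the globally standardized effect), protein-level
#' exclusion, volcano classification, and dual-criteria direct-substrate
#' calling against a consensus motif.
#'
#' @param phospho Phosphosite table in the native schema (see
#'   [read_phosphosite_table()] or [simulate_ko_experiment()]).
#' @param design A [ksi_design()].
#' @param proteins Optional protein-group table for the total-proteome
#'   exclusion rule; \code{NULL} skips it.
#' @param normalization \code{"median"} (default) or \code{"none"}.
#' @param min_per_group Replicate filter passed to [compute_ratios()].
#' @param alpha_joint Significance threshold on p_joint (default 0.0005).
#' @param effect_threshold Minimum |log2 effect| for a direct call
#'   (default 0.3).
#' @param motif Consensus [motif_spec()]; default [camk2d_motif()].
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @param mode Threshold comparison mode for [call_direct_targets()].
#' @return An object of class \code{"ksi_fit"}: a list with
#'   \code{sites} (per-site results: effects, p_t, z, gaussian_tail,
#'   p_joint, status), \code{proteins} (protein-level results or
#'   \code{NULL}), \code{direct} (the [call_direct_targets()] table),
#'   \code{sigma_global}, \code{design} and \code{params}. Methods:
#'   \code{print}, \code{summary}, \code{coef} (named log2 effects),
#'   \code{plot} (volcano).
#' @examples
#' sim <- simulate_ko_experiment(sim_config(n_proteins = 150, seed = 42))
#' fit <- ksi_fit(sim$phospho, sim$design, sim$proteins)
#' fit
#' head(direct_targets(fit))
#' @export
ksi_fit <- function(phospho, design, proteins = NULL,
                    normalization = c("median", "none"),
                    min_per_group = 2L, alpha_joint = 5e-4,
                    effect_threshold = 0.3, motif = camk2d_motif(),
                    var_equal = TRUE,
                    mode = c("strict", "table_replication")) {
  normalization <- match.arg(normalization)
  mode <- match.arg(mode)
  norm <- normalize_channels(phospho, design, method = normalization)
  ratios <- compute_ratios(norm, design, min_per_group = min_per_group)
  joint <- compute_p_joint(ratios, norm, design, var_equal = var_equal)

  prot_joint <- NULL
  if (!is.null(proteins)) {
    pnorm_tab <- normalize_channels(proteins, design,
                                    method = normalization)
    pratios <- compute_ratios(pnorm_tab, design,
                              min_per_group = min_per_group)
    prot_joint <- compute_p_joint(pratios, pnorm_tab, design,
                                  var_equal = var_equal)
  }
  sites <- classify_sites(joint, prot_joint, alpha_joint = alpha_joint)
  direct <- call_direct_targets(sites, motif = motif,
                                alpha_joint = alpha_joint,
                                effect_threshold = effect_threshold,
                                mode = mode)
  structure(list(sites = sites, proteins = prot_joint, direct = direct,
                 sigma_global = attr(joint, "sigma_global"),
                 design = design,
                 params = list(normalization = normalization,
                               min_per_group = min_per_group,
                               alpha_joint = alpha_joint,
                               effect_threshold = effect_threshold,
                               motif = motif, var_equal = var_equal,
                               mode = mode)),
            class = "ksi_fit")
}

#' Direct-substrate calls of a fitted analysis
#'
#' @param fit A \code{"ksi_fit"} object.
#' @return The rows of the direct-call table with \code{is_direct ==
#'   TRUE}.
#' @export
direct_targets <- function(fit) {
  stopifnot(inherits(fit, "ksi_fit"))
  fit$direct[fit$direct$is_direct, , drop = FALSE]
}

#' @export
print.ksi_fit <- function(x, ...) {
  cnt <- attr(x$sites, "status_counts")
  cat("Knockout phosphoproteomics substrate inference\n")
  cat("  ", nrow(x$sites), " phosphosites; ",
      sum(x$design$group == "KO"), " KO vs ",
      sum(x$design$group == "Control"), " Control channels\n", sep = "")
  cat("  sigma_global = ", signif(x$sigma_global, 4),
      " (log2 units)\n", sep = "")
  cat("  status: ", paste(names(cnt), as.integer(cnt), sep = "=",
                          collapse = ", "), "\n", sep = "")
  cat("  direct targets called: ", sum(x$direct$is_direct),
      " (p_joint ", if (x$params$mode == "strict") "<" else "<=",
      " ", x$params$alpha_joint, ", |log2 effect| > ",
      x$params$effect_threshold, ", motif ",
      if (is.null(x$params$motif$name)) "matched"
      else x$params$motif$name, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.ksi_fit <- function(object, ...) {
  out <- list(n_sites = nrow(object$sites),
              status_counts = attr(object$sites, "status_counts"),
              sigma_global = object$sigma_global,
              n_direct = sum(object$direct$is_direct),
              direct = direct_targets(object),
              params = object$params)
  class(out) <- "summary.ksi_fit"
  out
}

#' @export
print.summary.ksi_fit <- function(x, ...) {
  cat("Substrate-inference summary\n")
  cat("  phosphosites tested:",
      x$n_sites - as.integer(x$status_counts["insufficient_replicates"]),
      "of", x$n_sites, "\n")
  print(x$status_counts)
  cat("  sigma_global:", signif(x$sigma_global, 4), "\n")
  cat("  direct targets (", x$n_direct, "):\n", sep = "")
  if (x$n_direct > 0) {
    show <- utils::head(x$direct[, c("id", "log2_effect", "p_joint")], 10)
    print(show, row.names = FALSE)
    if (x$n_direct > 10) cat("  ...\n")
  }
  invisible(x)
}

#' @export
coef.ksi_fit <- function(object, ...) {
  stats::setNames(object$sites$log2_effect, object$sites$id)
}

#' Volcano plot of a fitted analysis
#'
#' Plots -log10(p_joint) against the log2(KO/Control) effect, marking
#' the significance thresholds and highlighting direct-substrate calls.
#'
#' @param x A \code{"ksi_fit"} object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.ksi_fit <- function(x, ...) {
  s <- x$sites[!is.na(x$sites$p_joint), ]
  lp <- -log10(pmax(s$p_joint, 1e-300))
  col <- rep("grey60", nrow(s))
  col[s$status == "up"] <- "firebrick"
  col[s$status == "down"] <- "steelblue"
  col[s$id %in% x$direct$id[x$direct$is_direct]] <- "black"
  graphics::plot(s$log2_effect, lp,
                 xlab = expression(log[2] * "(KO/Control)"),
                 ylab = expression(-log[10] * " p"["joint"]),
                 pch = 20, col = col, ...)
  graphics::abline(h = -log10(x$params$alpha_joint), lty = 2)
  graphics::abline(v = c(-1, 1) * x$params$effect_threshold, lty = 3)
  invisible(x)
}
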