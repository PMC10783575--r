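# Direct-substrate calling by the dual statistical criteria plus motif
# filter, indirect-site characterization, annotated subset reports,
# Fisher-exact term enrichment, and in vitro phospho-occupancy ratios.

#' Call direct kinase substrates
#'
#' A phosphosite is called a direct substrate when it satisfies the dual
#' statistical criteria \emph{and} carries the kinase consensus motif:
#' \code{p_joint} below \code{alpha_joint}, a negative log2 effect whose
#' magnitude exceeds \code{effect_threshold} (the knockout removes the
#' kinase, so true substrates lose phosphorylation), and a motif match
#' on the centralized sequence.
#'
#' @param results Data frame with columns \code{id},
#'   \code{sequence_13}, \code{log2_effect} and \code{p_joint}
#'   (e.g. from [compute_p_joint()] / [classify_sites()], or a printed
#'   results table being re-evaluated). If a \code{status} column is
#'   present, sites with status \code{excluded_protein_change} or
#'   \code{insufficient_replicates} are ineligible.
#' @param motif A [motif_spec()]; default the CAMK2 consensus
#'   [camk2d_motif()].
#' @param alpha_joint Significance threshold on \code{p_joint}
#'   (default 0.0005).
#' @param effect_threshold Minimum |log2 effect| (default 0.3).
#' @param mode \code{"strict"} compares \code{p_joint < alpha_joint} on
#'   computed values; \code{"table_replication"} uses \code{p_joint <=
#'   alpha_joint}, appropriate when re-evaluating published tables whose
#'   p-values are rounded to 4 decimals (a printed "0.0005" may stand
#'   for any value below the threshold). Both modes use strict
#'   \code{>} on |effect|.
#' @return Data frame sorted by \code{p_joint} then effect:
#'   \code{id}, \code{sequence_13}, \code{log2_effect}, \code{p_joint},
#'   \code{passes_significance}, \code{passes_motif}, \code{is_direct}.
#'   Sites with a missing sequence get \code{passes_motif = NA} and are
#'   never called direct.
#' @export
call_direct_targets <- function(results, motif = camk2d_motif(),
                                alpha_joint = 5e-4,
                                effect_threshold = 0.3,
                                mode = c("strict", "table_replication")) {
  mode <- match.arg(mode)
  req <- c("id", "sequence_13", "log2_effect", "p_joint")
  missing <- setdiff(req, names(results))
  if (length(missing) > 0L)
    stop("results table: missing column ",
         paste(missing, collapse = ", "), call. = FALSE)
  eligible <- rep(TRUE, nrow(results))
  if ("status" %in% names(results)) {
    eligible <- !results$status %in% c("excluded_protein_change",
                                       "insufficient_replicates")
  }
  p_ok <- if (mode == "strict") {
    results$p_joint < alpha_joint
  } else {
    results$p_joint <= alpha_joint
  }
  passes_sig <- eligible & !is.na(results$p_joint) & p_ok &
    !is.na(results$log2_effect) & results$log2_effect < 0 &
    abs(results$log2_effect) > effect_threshold
  has_seq <- !is.na(results$sequence_13) & nzchar(results$sequence_13)
  passes_motif <- rep(NA, nrow(results))
  if (any(has_seq))
    passes_motif[has_seq] <- motif_match(results$sequence_13[has_seq],
                                         motif)
  is_direct <- passes_sig & !is.na(passes_motif) & passes_motif
  out <- data.frame(id = results$id,
                    sequence_13 = results$sequence_13,
                    log2_effect = results$log2_effect,
                    p_joint = results$p_joint,
                    passes_significance = passes_sig,
                    passes_motif = passes_motif,
                    is_direct = is_direct,
                    stringsAsFactors = FALSE)
  extra <- intersect(c("accession", "gene", "status"), names(results))
  for (col in extra) out[[col]] <- results[[col]]
  out <- out[order(out$p_joint, out$log2_effect), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Characterize the up-regulated (indirect) phosphosite set
#'
#' Sites that gain phosphorylation after a kinase knockout are
#' necessarily indirect (downstream kinase activation or phosphatase
#' inhibition). This runs [position_enrichment()] on the up-regulated
#' sequences and summarizes whether proline at +1 — the signature of
#' proline-directed CMGC-family kinases — is flagged.
#'
#' @param up_sequences Centralized sequences of the up-regulated sites;
#'   an empty set yields an empty report, not an error.
#' @param background Background for [position_enrichment()].
#' @param p_threshold Enrichment flag threshold (default 0.001).
#' @return A list with \code{enrichment} (the [position_enrichment()]
#'   table, or \code{NULL} when empty), \code{n_up}, and
#'   \code{proline_plus1_enriched} (logical).
#' @export
characterize_indirect <- function(up_sequences, background,
                                  p_threshold = 0.001) {
  if (length(up_sequences) == 0L) {
    return(list(enrichment = NULL, n_up = 0L,
                proline_plus1_enriched = FALSE))
  }
  enr <- position_enrichment(up_sequences, background,
                             p_threshold = p_threshold)
  hit <- enr$position == 1L & enr$residue == "P" & enr$enriched
  list(enrichment = enr, n_up = length(up_sequences),
       proline_plus1_enriched = any(hit))
}

#' Intersect changed sites with user-supplied gene categories
#'
#' Reports, per annotation category (e.g. protein kinases,
#' phosphatases), the changed phosphosites on genes in that category,
#' with their motif and direct-call flags — the package carries no gene
#' database, so category lists are user inputs.
#'
#' @param sites Data frame of sites with a \code{gene} column plus the
#'   columns required by [call_direct_targets()].
#' @param annotation Either a named list \code{category -> gene vector}
#'   or a data frame with columns \code{gene} and \code{category}.
#' @param ... Passed to [call_direct_targets()] (motif, thresholds,
#'   mode).
#' @return Data frame: the [call_direct_targets()] columns plus
#'   \code{gene} and \code{category}, one row per (site, category) hit;
#'   empty when the annotation or site table is empty.
#' @export
subset_report <- function(sites, annotation, ...) {
  if (is.data.frame(annotation)) {
    stopifnot(all(c("gene", "category") %in% names(annotation)))
    annotation <- split(annotation$gene, annotation$category)
  }
  empty <- call_direct_targets(
    data.frame(id = character(), sequence_13 = character(),
               log2_effect = numeric(), p_joint = numeric(),
               gene = character(), stringsAsFactors = FALSE), ...)
  empty$category <- character(0)
  if (length(annotation) == 0L || nrow(sites) == 0L) return(empty)
  if (!"gene" %in% names(sites))
    stop("'sites' needs a 'gene' column", call. = FALSE)
  calls <- call_direct_targets(sites, ...)
  out <- lapply(names(annotation), function(cat) {
    hit <- calls[calls$gene %in% annotation[[cat]], , drop = FALSE]
    if (nrow(hit) > 0L) hit$category <- cat
    hit
  })
  out <- out[vapply(out, nrow, 1L) > 0L]
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fisher-exact term enrichment over user-supplied annotation maps
#'
#' One-sided Fisher exact test (enrichment direction) on the 2x2 table
#' query / non-query vs in-term / not-in-term, one test per term.
#'
#' @param query Character vector of query genes (must all appear in
#'   \code{background}).
#' @param annotation Named list mapping term identifiers to gene sets;
#'   genes outside the background are ignored.
#' @param background Character vector: the gene universe.
#' @param p_threshold Reporting threshold for the \code{significant}
#'   flag (default 0.05).
#' @return Data frame per term: \code{term}, \code{term_size} (in the
#'   background), \code{hits} (in the query), \code{fold_enrichment}
#'   (\code{(hits / |query|) / (term_size / |background|)}),
#'   \code{p_value}, \code{significant}.
#' @export
fisher_enrichment <- function(query, annotation, background,
                              p_threshold = 0.05) {
  query <- unique(query)
  background <- unique(background)
  outside <- setdiff(query, background)
  if (length(outside) > 0L)
    stop("query genes absent from background: ",
         paste(outside, collapse = ", "), call. = FALSE)
  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(names(annotation), function(term) {
    genes <- intersect(unique(annotation[[term]]), background)
    k <- length(genes)
    h <- length(intersect(genes, query))
    tab <- matrix(c(h, n_q - h, k - h, n_bg - n_q - (k - h)), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    fold <- if (n_q > 0 && k > 0) (h / n_q) / (k / n_bg) else NA_real_
    data.frame(term = term, term_size = k, hits = h,
               fold_enrichment = fold, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < p_threshold &
    out$hits > 0
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Phospho-occupancy ratios across doses with one-way ANOVA
#'
#' For in vitro kinase assays read out by quantitative MS: the
#' phospho-to-total intensity ratio per replicate approximates the
#' phosphorylated fraction of the peptide, compared across enzyme doses
#' by a classical one-way fixed-effects ANOVA.
#'
#' @param phospho Phospho intensity per replicate (non-negative).
#' @param total Total intensity per replicate (phosphorylated plus
#'   unphosphorylated); a zero total makes that replicate's ratio
#'   undefined and flags the row.
#' @param dose Dose-group label per replicate (>= 2 groups with >= 2
#'   replicates each).
#' @return A list: \code{ratios} (data frame \code{dose},
#'   \code{phospho}, \code{total}, \code{ratio}, \code{flagged}),
#'   \code{group_means} (named vector), and \code{p_anova}. With no
#'   between- or within-group variation the ANOVA p-value is 1 by
#'   convention.
#' @export
invitro_phospho_ratio <- function(phospho, total, dose) {
  stopifnot(length(phospho) == length(total),
            length(phospho) == length(dose))
  dose <- factor(dose)
  tab <- table(dose)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 dose groups with >= 2 replicates each", call. = FALSE)
  flagged <- !is.finite(total) | total <= 0
  ratio <- ifelse(flagged, NA_real_, phospho / total)
  ok <- !is.na(ratio)
  grand_var <- stats::var(ratio[ok])
  if (!is.finite(grand_var) || grand_var == 0) {
    p <- 1
  } else {
    p <- stats::oneway.test(ratio[ok] ~ dose[ok],
                            var.equal = TRUE)$p.value
  }
  list(ratios = data.frame(dose = dose, phospho = phospho, total = total,
                           ratio = ratio, flagged = flagged,
                           stringsAsFactors = FALSE),
       group_means = tapply(ratio, dose, mean, na.rm = TRUE),
       p_anova = p)
}
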