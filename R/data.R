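# Bundled reference tables from a published CRISPR-knockout
# phosphoproteomics study of CAMK2D in mouse collecting-duct cells.
# Values are as printed (effects to 2-3 decimals, p_joint to 4), so they
# are typically re-evaluated with call_direct_targets(mode =
# "table_replication").

.ref_table <- function(file) {
  path <- system.file("extdata", file, package = "ksubinfer",
                      mustWork = TRUE)
  x <- .read_tsv(path)
  x$id <- paste0(x$gene, "_", x$site)
  x[, c("id", setdiff(names(x), "id"))]
}

#' Reference set: 35 inferred direct CAMK2D substrate phosphosites
#'
#' The curated list of phosphosites called direct CAMK2D targets in a
#' CRISPR-knockout TMT phosphoproteomics experiment in mouse
#' collecting-duct (mpkCCD) cells: significantly down-regulated in the
#' knockout (p_joint < 0.0005, log2(KO/Control) < -0.3) and carrying
#' the CAMK2 consensus (R/K)-X-X-p(S/T)-X-(D/E).
#'
#' @return Data frame: \code{id}, \code{accession}, \code{gene},
#'   \code{site}, \code{sequence_13}, \code{log2_effect},
#'   \code{p_joint}. Values as printed in the source table (rounded).
#' @export
camk2d_direct_targets <- function() .ref_table("camk2d_direct_targets.tsv")

#' Reference set: protein-kinase phosphosites changed by CAMK2D knockout
#'
#' The 19 phosphosites on protein kinases that changed significantly in
#' the same knockout experiment (both directions). Only one of them —
#' Cdk18 Ser66 — also satisfies the full direct-substrate criteria.
#'
#' @return Data frame with the columns of [camk2d_direct_targets()].
#' @export
camk2d_kinase_sites <- function() .ref_table("camk2d_kinase_sites.tsv")

#' Reference set: phosphatase-related phosphosites changed by CAMK2D knockout
#'
#' The four significantly changed phosphosites on protein phosphatases
#' and phosphatase regulators from the same experiment; none satisfies
#' the direct-substrate criteria.
#'
#' @return Data frame with the columns of [camk2d_direct_targets()].
#' @export
camk2d_phosphatase_sites <- function() .ref_table("camk2d_phosphatase_sites.tsv")
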