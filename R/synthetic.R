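# Synthetic knockout-vs-control TMT phosphoproteomics experiments with
# known ground truth, emulating an 11-plex style design (5 KO + 3
# Control biological replicates by default).

#' Configuration for the synthetic TMT experiment generator
#'
#' The generator plants three site classes: \emph{direct} substrates
#' (negative log2 effect in the knockout, centralized sequence carrying
#' the kinase consensus motif R/K at -3, S/T at 0, D/E at +2),
#' \emph{indirect up} sites (positive effect, proline at +1, the
#' signature of downstream proline-directed kinase activation), and
#' \emph{null} sites. A fraction of proteins additionally receive a
#' total-abundance shift in the knockout, reproducing the confounding
#' that the protein-level exclusion rule is designed to remove.
#'
#' @param n_proteins Number of proteins.
#' @param sites_per_protein Phosphosites per protein.
#' @param n_ko_replicates,n_ctrl_replicates Channels per group
#'   (defaults 5 and 3; each must be >= 2 for the t-test).
#' @param frac_direct,frac_indirect_up Fractions of sites planted as
#'   direct targets / indirect up-sites (sum must be <= 1).
#' @param direct_effect_log2 Planted direct effect, log2 units
#'   (must be negative; default -0.8).
#' @param indirect_effect_log2 Planted indirect effect (positive;
#'   default 0.8).
#' @param noise_sd_log2 SD of the additive Gaussian measurement noise in
#'   log2 space, i.e. log-normal intensity noise (default 0.25).
#' @param frac_protein_shift Fraction of proteins with a planted
#'   total-abundance change.
#' @param protein_effect_log2 Size of that protein-level change
#'   (log2 units).
#' @param base_intensity_log2 Baseline log2 reporter intensity.
#' @param st_ratio Probability that a site's central residue is S rather
#'   than T (default 0.8, i.e. S:T = 4:1).
#' @param residue_freq Optional named frequency vector over the 20 amino
#'   acids for the background sequence composition; default uniform.
#' @param seed Integer root seed; the same seed and configuration give
#'   byte-identical tables.
#' @return A validated list of class \code{"ksi_sim_config"}.
#' @seealso [simulate_ko_experiment()]
#' @export
sim_config <- function(n_proteins = 2000L, sites_per_protein = 5L,
                       n_ko_replicates = 5L, n_ctrl_replicates = 3L,
                       frac_direct = 0.005, frac_indirect_up = 0.01,
                       direct_effect_log2 = -0.8,
                       indirect_effect_log2 = 0.8,
                       noise_sd_log2 = 0.25,
                       frac_protein_shift = 0.02,
                       protein_effect_log2 = -0.9,
                       base_intensity_log2 = 20,
                       st_ratio = 0.8,
                       residue_freq = NULL,
                       seed = 1L) {
  chk_count <- function(x, nm, min = 1L) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
      stop("'", nm, "' must be an integer >= ", min, call. = FALSE)
    as.integer(x)
  }
  chk_frac <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
      stop("'", nm, "' must be a fraction in [0, 1]", call. = FALSE)
    as.numeric(x)
  }
  cfg <- list(
    n_proteins = chk_count(n_proteins, "n_proteins"),
    sites_per_protein = chk_count(sites_per_protein, "sites_per_protein"),
    n_ko_replicates = chk_count(n_ko_replicates, "n_ko_replicates", 2L),
    n_ctrl_replicates = chk_count(n_ctrl_replicates, "n_ctrl_replicates", 2L),
    frac_direct = chk_frac(frac_direct, "frac_direct"),
    frac_indirect_up = chk_frac(frac_indirect_up, "frac_indirect_up"),
    direct_effect_log2 = as.numeric(direct_effect_log2),
    indirect_effect_log2 = as.numeric(indirect_effect_log2),
    noise_sd_log2 = as.numeric(noise_sd_log2),
    frac_protein_shift = chk_frac(frac_protein_shift, "frac_protein_shift"),
    protein_effect_log2 = as.numeric(protein_effect_log2),
    base_intensity_log2 = as.numeric(base_intensity_log2),
    st_ratio = chk_frac(st_ratio, "st_ratio"),
    residue_freq = residue_freq,
    seed = chk_count(seed, "seed", 0L)
  )
  if (cfg$frac_direct + cfg$frac_indirect_up > 1)
    stop("'frac_direct' + 'frac_indirect_up' must be <= 1", call. = FALSE)
  if (cfg$direct_effect_log2 >= 0)
    stop("'direct_effect_log2' must be negative", call. = FALSE)
  if (cfg$indirect_effect_log2 <= 0)
    stop("'indirect_effect_log2' must be positive", call. = FALSE)
  if (cfg$noise_sd_log2 < 0)
    stop("'noise_sd_log2' must be non-negative", call. = FALSE)
  if (!is.null(residue_freq)) {
    if (is.null(names(residue_freq)) ||
        !all(AMINO_ACIDS %in% names(residue_freq)))
      stop("'residue_freq' must be named by all 20 amino acids",
           call. = FALSE)
    cfg$residue_freq <- residue_freq[AMINO_ACIDS] /
      sum(residue_freq[AMINO_ACIDS])
  }
  structure(cfg, class = "ksi_sim_config")
}

# Random centralized 13-mers with the class motif imposed. Position
# indices: centre = 7; -3 -> 4, +1 -> 8, +2 -> 9.
.random_sequences <- function(n, class, st_ratio, residue_freq) {
  freq <- if (is.null(residue_freq)) rep(1 / 20, 20) else residue_freq
  mat <- matrix(sample(AMINO_ACIDS, n * 13L, replace = TRUE, prob = freq),
                nrow = n, ncol = 13L)
  mat[, 7L] <- ifelse(stats::runif(n) < st_ratio, "S", "T")
  dir <- class == "direct"
  if (any(dir)) {
    mat[dir, 4L] <- sample(c("R", "K"), sum(dir), replace = TRUE)
    mat[dir, 9L] <- sample(c("D", "E"), sum(dir), replace = TRUE)
  }
  ind <- class == "indirect_up"
  if (any(ind)) mat[ind, 8L] <- "P"
  apply(mat, 1L, paste, collapse = "")
}

#' Simulate a knockout-vs-control TMT phosphoproteomics experiment
#'
#' Draws reporter intensities per site and channel as
#' \code{2^(base + protein_shift * [KO] + site_effect * [KO] + noise)}
#' with independent Gaussian noise in log2 space, and protein-group
#' intensities as \code{2^(base + protein_shift * [KO] + noise)}.
#' Site classes, effects and sequences follow the configuration; the
#' returned ground truth records every planted value.
#'
#' A single root seed is split deterministically into independent
#' streams for the experiment structure (classes, sequences, protein
#' shifts) and for each intensity table, so the same configuration and
#' seed reproduce identical tables and changing the channel count does
#' not reshuffle the sequences.
#'
#' @param config A [sim_config()] object.
#' @return A list of class \code{"ksi_sim"}:
#'   \describe{
#'     \item{phospho}{Phosphosite table in the native reader schema
#'       (\code{id}, \code{accession}, \code{gene}, \code{residue},
#'       \code{position}, \code{sequence_13}, channel columns).}
#'     \item{proteins}{Protein-group table (\code{id}, \code{accession},
#'       \code{gene}, channel columns).}
#'     \item{design}{The [ksi_design()] mapping channels to groups.}
#'     \item{truth}{Ground truth: \code{id}, \code{class}
#'       (direct / indirect_up / null), \code{site_effect_log2},
#'       \code{protein_shift_log2}, \code{protein_shifted}.}
#'     \item{config}{The configuration used.}
#'   }
#' @examples
#' sim <- simulate_ko_experiment(sim_config(n_proteins = 20, seed = 7))
#' head(sim$truth)
#' @export
simulate_ko_experiment <- function(config) {
  if (!inherits(config, "ksi_sim_config"))
    stop("'config' must come from sim_config()", call. = FALSE)
  cfg <- config
  n_sites <- cfg$n_proteins * cfg$sites_per_protein
  channels <- c(paste0("KO", seq_len(cfg$n_ko_replicates)),
                paste0("Ctrl", seq_len(cfg$n_ctrl_replicates)))
  groups <- rep(c("KO", "Control"),
                c(cfg$n_ko_replicates, cfg$n_ctrl_replicates))
  design <- ksi_design(channels, groups)
  is_ko <- design$group == "KO"

  # Stream 1: experiment structure (classes, sequences, protein shifts).
  set.seed(cfg$seed %% 2147480000L)
  gene <- sprintf("GENE%04d", seq_len(cfg$n_proteins))
  accession <- sprintf("SYNP%04d", seq_len(cfg$n_proteins))
  prot_shifted <- stats::runif(cfg$n_proteins) < cfg$frac_protein_shift
  prot_shift <- ifelse(prot_shifted, cfg$protein_effect_log2, 0)

  n_direct <- round(cfg$frac_direct * n_sites)
  n_indirect <- round(cfg$frac_indirect_up * n_sites)
  class <- rep("null", n_sites)
  planted <- sample.int(n_sites, n_direct + n_indirect)
  class[planted[seq_len(n_direct)]] <- "direct"
  if (n_indirect > 0)
    class[planted[n_direct + seq_len(n_indirect)]] <- "indirect_up"
  site_effect <- rep(0, n_sites)
  site_effect[class == "direct"] <- cfg$direct_effect_log2
  site_effect[class == "indirect_up"] <- cfg$indirect_effect_log2
  seqs <- .random_sequences(n_sites, class, cfg$st_ratio, cfg$residue_freq)

  protein_of <- rep(seq_len(cfg$n_proteins), each = cfg$sites_per_protein)
  position <- 10L * (rep(seq_len(cfg$sites_per_protein),
                         times = cfg$n_proteins)) + 3L
  residue <- substr(seqs, 7L, 7L)
  id <- paste0(gene[protein_of], "_", residue, position)

  # Stream 2: phosphosite intensities.
  set.seed((cfg$seed + 1L) %% 2147480000L)
  n_ch <- nrow(design)
  mu <- cfg$base_intensity_log2 +
    outer(prot_shift[protein_of] + site_effect, as.numeric(is_ko))
  noise <- matrix(stats::rnorm(n_sites * n_ch, sd = cfg$noise_sd_log2),
                  nrow = n_sites)
  phospho_int <- 2^(mu + noise)
  colnames(phospho_int) <- design$channel

  # Stream 3: protein-group intensities (independent noise).
  set.seed((cfg$seed + 2L) %% 2147480000L)
  mu_p <- cfg$base_intensity_log2 +
    outer(prot_shift, as.numeric(is_ko))
  noise_p <- matrix(stats::rnorm(cfg$n_proteins * n_ch,
                                 sd = cfg$noise_sd_log2),
                    nrow = cfg$n_proteins)
  protein_int <- 2^(mu_p + noise_p)
  colnames(protein_int) <- design$channel

  phospho <- data.frame(id = id, accession = accession[protein_of],
                        gene = gene[protein_of], residue = residue,
                        position = position, sequence_13 = seqs,
                        stringsAsFactors = FALSE)
  phospho <- cbind(phospho, as.data.frame(phospho_int))
  proteins <- data.frame(id = accession, accession = accession,
                         gene = gene, stringsAsFactors = FALSE)
  proteins <- cbind(proteins, as.data.frame(protein_int))
  truth <- data.frame(id = id, class = class,
                      site_effect_log2 = site_effect,
                      protein_shift_log2 = prot_shift[protein_of],
                      protein_shifted = prot_shifted[protein_of],
                      stringsAsFactors = FALSE)
  structure(list(phospho = phospho, proteins = proteins, design = design,
                 truth = truth, config = cfg),
            class = "ksi_sim")
}

#' @export
print.ksi_sim <- function(x, ...) {
  cat("Synthetic KO-vs-Control TMT experiment\n",
      "  sites: ", nrow(x$phospho), " on ", nrow(x$proteins),
      " proteins; channels: ", sum(x$design$group == "KO"), " KO + ",
      sum(x$design$group == "Control"), " Control\n",
      "  planted: ", sum(x$truth$class == "direct"), " direct, ",
      sum(x$truth$class == "indirect_up"), " indirect up; ",
      sum(x$truth$protein_shifted & !duplicated(x$phospho$accession)),
      " shifted proteins\n", sep = "")
  invisible(x)
}

#' Write a simulated experiment to TSV fixture files
#'
#' Writes \code{phosphosites.tsv}, \code{proteins.tsv}, \code{design.tsv}
#' and \code{truth.tsv} in the dialects read back by [read_design()],
#' [read_phosphosite_table()] and [read_protein_table()]; the round trip
#' reproduces all intensities to full double precision.
#'
#' @param sim A \code{"ksi_sim"} object from [simulate_ko_experiment()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!inherits(sim, "ksi_sim"))
    stop("'sim' must come from simulate_ko_experiment()", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(phospho = file.path(dir, "phosphosites.tsv"),
             proteins = file.path(dir, "proteins.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"))
  # serialize doubles with 17 significant digits so the read-back value
  # is bit-identical
  fmt_full <- function(x) {
    x[] <- lapply(x, function(col)
      if (is.double(col)) sprintf("%.17g", col) else col)
    x
  }
  write_tsv(fmt_full(sim$phospho[, setdiff(names(sim$phospho), "id")]),
            paths["phospho"])
  write_tsv(fmt_full(sim$proteins[, setdiff(names(sim$proteins), "id")]),
            paths["proteins"])
  write_tsv(as.data.frame(sim$design), paths["design"])
  write_tsv(fmt_full(sim$truth), paths["truth"])
  invisible(paths)
}
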