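# Reporter-channel normalization and per-feature log2(KO/Control)
# effect computation.

# Columns of `x` other than design channels are identifier metadata and
# are carried through unchanged.
.meta_cols <- function(x, design) setdiff(names(x), design$channel)

#' Log2-transform and normalize reporter channels
#'
#' Reporter intensities of exactly 0 mean "not observed" in TMT data and
#' become missing (\code{NA}); positive intensities are log2-transformed.
#' With \code{method = "median"} each channel column is then shifted so
#' that all channel medians equal the grand median (the median of the
#' per-channel medians), removing channel-loading differences that would
#' otherwise masquerade as knockout effects. \code{method = "none"}
#' returns the plain log2 transform.
#'
#' @param x Feature table (data frame) with one intensity column per
#'   design channel; other columns are passed through.
#' @param design A [ksi_design()] object.
#' @param method \code{"median"} (default) or \code{"none"}.
#' @return The table with channel columns replaced by (normalized) log2
#'   intensities; missing entries stay missing.
#' @export
normalize_channels <- function(x, design, method = c("median", "none")) {
  method <- match.arg(method)
  .check_channel_columns(x, design, "intensity table")
  for (ch in design$channel) {
    v <- as.numeric(x[[ch]])
    v[!is.na(v) & v <= 0] <- NA_real_
    x[[ch]] <- log2(v)
  }
  if (method == "median") {
    meds <- vapply(design$channel,
                   function(ch) stats::median(x[[ch]], na.rm = TRUE),
                   numeric(1))
    if (anyNA(meds)) {
      bad <- design$channel[is.na(meds)]
      stop("channel with no observed intensities: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    grand <- stats::median(meds)
    for (i in seq_along(design$channel)) {
      ch <- design$channel[i]
      x[[ch]] <- x[[ch]] - meds[i] + grand
    }
  }
  x
}

#' Per-feature group means and log2(KO/Control) effects
#'
#' The effect is the difference of group means of log2 intensities
#' (KO minus Control), computed over the non-missing channels of each
#' group. Features with fewer than \code{min_per_group} finite values in
#' either group are flagged \code{insufficient} and are skipped by the
#' significance statistics downstream; no imputation is performed.
#'
#' @param norm Normalized log2 intensity table from
#'   [normalize_channels()], with an \code{id} column.
#' @param design A [ksi_design()] object.
#' @param min_per_group Minimum finite replicates required per group
#'   (default 2, the t-test minimum).
#' @return Data frame with the input's metadata columns plus
#'   \code{mean_ko}, \code{mean_ctrl}, \code{log2_effect}
#'   (\code{mean_ko - mean_ctrl}), \code{n_ko}, \code{n_ctrl}, and the
#'   logical flag \code{insufficient}.
#' @export
compute_ratios <- function(norm, design, min_per_group = 2L) {
  if (min_per_group < 2L)
    stop("'min_per_group' must be >= 2", call. = FALSE)
  .check_channel_columns(norm, design, "normalized table")
  ko <- as.matrix(norm[, .channels(design, "KO"), drop = FALSE])
  ctrl <- as.matrix(norm[, .channels(design, "Control"), drop = FALSE])
  n_ko <- rowSums(is.finite(ko))
  n_ctrl <- rowSums(is.finite(ctrl))
  mean_ko <- rowMeans(ko, na.rm = TRUE)
  mean_ctrl <- rowMeans(ctrl, na.rm = TRUE)
  mean_ko[n_ko == 0L] <- NA_real_
  mean_ctrl[n_ctrl == 0L] <- NA_real_
  out <- norm[, .meta_cols(norm, design), drop = FALSE]
  out$mean_ko <- mean_ko
  out$mean_ctrl <- mean_ctrl
  out$log2_effect <- mean_ko - mean_ctrl
  out$n_ko <- as.integer(n_ko)
  out$n_ctrl <- as.integer(n_ctrl)
  out$insufficient <- n_ko < min_per_group | n_ctrl < min_per_group
  rownames(out) <- NULL
  out
}
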