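# Reading and validation of sample designs, phosphosite tables and
# protein-group tables; TSV writers for pipeline outputs.

# Thin TSV helpers: header row, tab-separated, '.' decimal, no quoting.
.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a pipeline table as TSV
#'
#' @param x Data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Construct a TMT channel-to-group sample design
#'
#' @param channel Character vector of unique channel labels (must match
#'   the intensity column names of the quantification tables).
#' @param group Group label per channel; canonicalized case-insensitively
#'   to \code{"KO"} or \code{"Control"} (\code{"ctrl"}/\code{"intact"}
#'   are accepted synonyms for the control group).
#' @param replicate Optional replicate index per channel; defaults to
#'   1..n within each group.
#' @return A data frame of class \code{"ksi_design"} with columns
#'   \code{channel}, \code{group}, \code{replicate}.
#' @details Each group must contain at least two channels: the two-sample
#'   t-test downstream needs at least two replicates per group.
#' @examples
#' ksi_design(c(paste0("KO", 1:5), paste0("C", 1:3)),
#'            rep(c("KO", "Control"), c(5, 3)))
#' @export
ksi_design <- function(channel, group, replicate = NULL) {
  channel <- as.character(channel)
  if (anyDuplicated(channel))
    stop("duplicated channel label: ",
         paste(unique(channel[duplicated(channel)]), collapse = ", "),
         call. = FALSE)
  g <- tolower(as.character(group))
  canon <- ifelse(g %in% c("ko", "knockout"), "KO",
           ifelse(g %in% c("control", "ctrl", "intact"), "Control",
                  NA_character_))
  if (anyNA(canon)) {
    bad <- which(is.na(canon))[1]
    stop("unknown group label '", group[bad], "' in design row ", bad,
         " (expected KO or Control)", call. = FALSE)
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(canon), canon, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  n_ko <- sum(canon == "KO")
  n_ctrl <- sum(canon == "Control")
  if (n_ko < 2L || n_ctrl < 2L)
    stop("design needs >= 2 channels per group (got ", n_ko, " KO, ",
         n_ctrl, " Control)", call. = FALSE)
  d <- data.frame(channel = channel, group = canon,
                  replicate = replicate, stringsAsFactors = FALSE)
  class(d) <- c("ksi_design", "data.frame")
  d
}

#' Read a sample-design TSV
#'
#' Expects columns \code{channel}, \code{group} and optionally
#' \code{replicate}; see [ksi_design()] for validation rules.
#'
#' @param path Path to the design TSV.
#' @return A \code{"ksi_design"} data frame.
#' @export
read_design <- function(path) {
  d <- .read_tsv(path)
  names(d) <- tolower(names(d))
  if (!all(c("channel", "group") %in% names(d)))
    stop("design file must have 'channel' and 'group' columns",
         call. = FALSE)
  ksi_design(d$channel, d$group,
             replicate = if ("replicate" %in% names(d)) d$replicate)
}

# Channel labels of the KO / Control groups.
.channels <- function(design, group) design$channel[design$group == group]

# Validate the presence of design channels as numeric-convertible columns.
.check_channel_columns <- function(x, design, what) {
  missing <- setdiff(design$channel, names(x))
  if (length(missing) > 0L)
    stop(what, ": missing intensity column for channel ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# Rename MaxQuant-style columns onto the native schema. `site_level`
# selects which site-level intensity flavour to use when several are
# present (MaxQuant reports per-multiplicity columns; the '___1' columns
# hold the singly-phosphorylated evidence).
.maxquant_map <- function(x, design, site_level = "___1") {
  ren <- c("Protein" = "accession", "Proteins" = "accession",
           "Gene names" = "gene", "Amino acid" = "residue",
           "Position" = "position", "Sequence window" = "sequence_13")
  for (old in names(ren)) {
    if (old %in% names(x) && !(ren[[old]] %in% names(x)))
      names(x)[names(x) == old] <- ren[[old]]
  }
  # Reporter intensity corrected <i> [...] columns -> design channels, in
  # design order.
  rep_cols <- grep(paste0("^Reporter intensity corrected \\d+.*",
                          gsub("([^A-Za-z0-9])", "\\\\\\1", site_level),
                          "$"),
                   names(x), value = TRUE)
  if (length(rep_cols) == 0L)
    rep_cols <- grep("^Reporter intensity corrected \\d+$", names(x),
                     value = TRUE)
  if (length(rep_cols) >= nrow(design)) {
    ord <- order(as.integer(sub("^Reporter intensity corrected (\\d+).*$",
                                "\\1", rep_cols)))
    rep_cols <- rep_cols[ord][seq_len(nrow(design))]
    names(x)[match(rep_cols, names(x))] <- design$channel
  }
  if ("sequence_13" %in% names(x)) {
    # MaxQuant windows are wider (+/-15); trim to the central 13-mer.
    w <- nchar(x$sequence_13)
    ctr <- (w + 1L) %/% 2L
    x$sequence_13 <- substr(x$sequence_13, ctr - 6L, ctr + 6L)
  }
  x
}

# Shared per-row validation. Returns list(valid = df, rejected = df).
.validate_rows <- function(x, design, require_site) {
  reasons <- character(nrow(x))
  for (ch in design$channel) {
    v <- suppressWarnings(as.numeric(x[[ch]]))
    bad <- (is.na(v) & !is.na(x[[ch]]) & nzchar(trimws(as.character(x[[ch]])))) |
      (!is.na(v) & v < 0)
    reasons[bad & !nzchar(reasons)] <-
      paste0("non-numeric or negative intensity in channel ", ch)
    x[[ch]] <- v
  }
  if (require_site) {
    seq13 <- as.character(x$sequence_13)
    res <- toupper(as.character(x$residue))
    pos <- suppressWarnings(as.integer(x$position))
    bad_len <- nchar(seq13) != 13L
    reasons[bad_len & !nzchar(reasons)] <- "centralized sequence not 13 characters"
    core <- gsub("^_+|_+$", "", seq13)
    bad_pad <- grepl("_", core, fixed = TRUE)
    reasons[!bad_len & bad_pad & !nzchar(reasons)] <-
      "'_' padding not confined to the termini"
    bad_chr <- !grepl("^[ACDEFGHIKLMNPQRSTVWY_]{13}$", seq13)
    reasons[!bad_len & bad_chr & !nzchar(reasons)] <-
      "illegal character in centralized sequence"
    bad_res <- !res %in% c("S", "T", "Y")
    reasons[bad_res & !nzchar(reasons)] <- "residue not S/T/Y"
    centre <- substr(seq13, 7L, 7L)
    bad_ctr <- !bad_len & !bad_res & centre != res
    reasons[bad_ctr & !nzchar(reasons)] <-
      "sequence centre does not match the residue field"
    bad_pos <- is.na(pos) | pos < 1L
    reasons[bad_pos & !nzchar(reasons)] <- "position not a positive integer"
    x$residue <- res
    x$position <- pos
    x$sequence_13 <- seq13
  }
  keep <- !nzchar(reasons)
  rejected <- data.frame(row = which(!keep),
                         reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  list(valid = x[keep, , drop = FALSE], rejected = rejected)
}

#' Read a phosphosite intensity table
#'
#' Reads a monophosphosite quantification table (one row per site) and
#' validates it against the sample design: identifier columns
#' \code{accession}, \code{gene}, \code{residue}, \code{position},
#' \code{sequence_13}, plus one reporter-intensity column per design
#' channel. Rows violating the record invariants (13-character
#' centralized sequence whose centre matches the S/T/Y residue field,
#' \code{"_"} padding only at the termini, numeric non-negative
#' intensities) are dropped and logged.
#'
#' @param path Path to the TSV file.
#' @param design A [ksi_design()] object.
#' @param format \code{"native"} for the package's own column schema or
#'   \code{"maxquant"} to map MaxQuant \code{Phospho (STY)Sites.txt}-style
#'   column names (\code{Sequence window}, \code{Amino acid},
#'   \code{Reporter intensity corrected <i>}) onto it.
#' @param site_level For \code{format = "maxquant"}: which site-level
#'   intensity multiplicity columns to take (default \code{"___1"}, the
#'   singly-phosphorylated evidence).
#' @return Data frame of accepted rows with a leading \code{id} column
#'   (\code{GENE_S123}-style site identifier). The attribute
#'   \code{"rejected"} holds a data frame of dropped input rows with a
#'   per-row reason.
#' @export
read_phosphosite_table <- function(path, design,
                                   format = c("native", "maxquant"),
                                   site_level = "___1") {
  format <- match.arg(format)
  x <- .read_tsv(path)
  if (format == "maxquant") x <- .maxquant_map(x, design, site_level)
  req <- c("accession", "gene", "residue", "position", "sequence_13")
  missing <- setdiff(req, names(x))
  if (length(missing) > 0L)
    stop("phosphosite table: missing required column ",
         paste(missing, collapse = ", "), call. = FALSE)
  .check_channel_columns(x, design, "phosphosite table")
  v <- .validate_rows(x, design, require_site = TRUE)
  out <- v$valid[, c(req, design$channel), drop = FALSE]
  out <- cbind(id = paste0(out$gene, "_", out$residue, out$position), out)
  out$id <- as.character(out$id)
  rownames(out) <- NULL
  attr(out, "rejected") <- v$rejected
  out
}

#' Read a protein-group intensity table
#'
#' @param path Path to the TSV file (columns \code{accession},
#'   \code{gene}, plus one intensity column per design channel).
#' @param design A [ksi_design()] object.
#' @return Data frame of accepted rows with a leading \code{id} column
#'   (the accession); attribute \code{"rejected"} as in
#'   [read_phosphosite_table()].
#' @export
read_protein_table <- function(path, design) {
  x <- .read_tsv(path)
  req <- c("accession", "gene")
  missing <- setdiff(req, names(x))
  if (length(missing) > 0L)
    stop("protein table: missing required column ",
         paste(missing, collapse = ", "), call. = FALSE)
  .check_channel_columns(x, design, "protein table")
  if (anyDuplicated(x$accession))
    stop("protein table: duplicated accession ",
         paste(unique(x$accession[duplicated(x$accession)]),
               collapse = ", "), call. = FALSE)
  v <- .validate_rows(x, design, require_site = FALSE)
  out <- v$valid[, c(req, design$channel), drop = FALSE]
  out <- cbind(id = as.character(out$accession), out)
  rownames(out) <- NULL
  attr(out, "rejected") <- v$rejected
  out
}
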