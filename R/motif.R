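# Centralized-sequence handling, consensus-motif matching and
# position-specific residue enrichment.

#: the 20 standard amino-acid one-letter codes
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Define a position-specific consensus motif
#'
#' A motif is a set of constraints mapping positions relative to the
#' phosphorylated residue (position 0, the centre of a 13-mer window)
#' to the residues allowed there. Unconstrained positions match any
#' residue ("X" in the usual motif notation).
#'
#' @param x Either a specification string such as \code{"-3:RK,0:ST,+2:DE"}
#'   (comma-separated \code{position:residues} pairs) or a list of allowed
#'   residue character vectors named by relative position.
#' @param name Optional display name for the motif.
#' @return An object of class \code{"motif_spec"}: a list with elements
#'   \code{constraints} (named list, names are relative positions) and
#'   \code{name}.
#' @details Relative positions must lie in \code{[-6, 6]} so that they fall
#'   inside the standard 13-residue centralized window. A constraint at
#'   position 0 must be a subset of \code{S}, \code{T}, \code{Y} (the
#'   phosphorylatable residues); the padding character \code{"_"} is never
#'   a legal constraint residue.
#' @examples
#' motif_spec("-3:RK,0:ST,+2:DE", name = "CAMK2")
#' @seealso [camk2d_motif()], [motif_match()]
#' @export
motif_spec <- function(x, name = NULL) {
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(x, ",", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L)
      stop("empty motif specification string", call. = FALSE)
    kv <- strsplit(parts, ":", fixed = TRUE)
    bad <- vapply(kv, length, 1L) != 2L
    if (any(bad))
      stop("malformed motif constraint: ", parts[bad][1], call. = FALSE)
    pos <- vapply(kv, `[`, "", 1L)
    res <- lapply(kv, function(p) strsplit(p[2], "")[[1]])
    constraints <- stats::setNames(res, pos)
  } else if (is.list(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("list motif constraints must be named by relative position",
           call. = FALSE)
    constraints <- lapply(x, function(r) strsplit(paste(r, collapse = ""),
                                                  "")[[1]])
  } else {
    stop("'x' must be a specification string or a named list", call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(names(constraints)))
  if (anyNA(pos) || any(pos < -6L | pos > 6L))
    stop("motif positions must be integers in [-6, 6]", call. = FALSE)
  if (anyDuplicated(pos))
    stop("duplicated motif position", call. = FALSE)
  for (i in seq_along(constraints)) {
    allowed <- unique(toupper(constraints[[i]]))
    if (any(!allowed %in% AMINO_ACIDS))
      stop("illegal residue in motif constraint at position ", pos[i],
           ": ", paste(setdiff(allowed, AMINO_ACIDS), collapse = ""),
           call. = FALSE)
    if (pos[i] == 0L && any(!allowed %in% c("S", "T", "Y")))
      stop("position 0 constraint must be a subset of {S, T, Y}",
           call. = FALSE)
    constraints[[i]] <- allowed
  }
  constraints <- constraints[order(pos)]
  structure(list(constraints = constraints, name = name),
            class = "motif_spec")
}

#' The CAMK2 consensus motif (R/K)-X-X-p(S/T)-X-(D/E)
#'
#' Convenience constructor for the calcium/calmodulin-dependent kinase 2
#' substrate consensus: a basic residue (R or K) three positions before
#' the phosphorylated S/T and an acidic residue (D or E) two positions
#' after it.
#'
#' @return A [motif_spec()] object.
#' @export
camk2d_motif <- function() {
  motif_spec("-3:RK,0:ST,+2:DE", name = "(R/K)-X-X-p(S/T)-X-(D/E)")
}

#' @export
print.motif_spec <- function(x, ...) {
  lab <- if (is.null(x$name)) "motif" else x$name
  cons <- vapply(names(x$constraints), function(p)
    paste0(p, ":", paste(x$constraints[[p]], collapse = "")), "")
  cat("Motif spec:", lab, "\n  constraints:",
      paste(cons, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the centralized sequence window around a phosphosite
#'
#' Returns the 13-residue (for the default \code{half_width = 6}) window
#' centred on a phosphorylated residue, padded with \code{"_"} where the
#' window runs past either protein terminus.
#'
#' @param protein_seq Full protein sequence (one string, one-letter codes).
#' @param position 1-based residue position of the phosphosite.
#' @param half_width Number of residues kept on each side of the site.
#' @return A string of length \code{2 * half_width + 1} whose middle
#'   character is the site residue.
#' @examples
#' centralize_sequence("MEKSSSCESLGAQRSTV", 6)  # "_MEKSSSCESLGA"
#' @export
centralize_sequence <- function(protein_seq, position, half_width = 6L) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L)
  n <- nchar(protein_seq)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > n)
    stop("site position ", position, " outside protein of length ", n,
         call. = FALSE)
  centre <- substr(protein_seq, position, position)
  if (!centre %in% c("S", "T", "Y"))
    stop("residue at position ", position, " is '", centre,
         "', not S/T/Y", call. = FALSE)
  lo <- position - half_width
  hi <- position + half_width
  pad_l <- max(0L, 1L - lo)
  pad_r <- max(0L, hi - n)
  core <- substr(protein_seq, max(1L, lo), min(n, hi))
  paste0(strrep("_", pad_l), core, strrep("_", pad_r))
}

#' Match centralized sequences against a consensus motif
#'
#' @param sequences Character vector of centralized sequences (all the
#'   same odd length; 13 for the standard window).
#' @param spec A [motif_spec()].
#' @return Logical vector: \code{TRUE} where every constrained position
#'   carries an allowed residue. A terminal padding character \code{"_"}
#'   at a constrained position never matches.
#' @examples
#' motif_match("VLHKSKSEEAHAE", camk2d_motif())  # TRUE
#' motif_match("EKIGEGTYGVVYK", camk2d_motif())  # FALSE
#' @export
motif_match <- function(sequences, spec) {
  if (!inherits(spec, "motif_spec"))
    stop("'spec' must be a motif_spec", call. = FALSE)
  if (length(sequences) == 0L) return(logical(0))
  len <- unique(nchar(sequences))
  if (length(len) != 1L || len %% 2L != 1L)
    stop("all sequences must share one odd length; got lengths ",
         paste(len, collapse = ", "), call. = FALSE)
  centre <- (len + 1L) %/% 2L
  ok <- rep(TRUE, length(sequences))
  for (p in names(spec$constraints)) {
    idx <- centre + as.integer(p)
    if (idx < 1L || idx > len) {
      ok[] <- FALSE
      break
    }
    ch <- substr(sequences, idx, idx)
    ok <- ok & ch %in% spec$constraints[[p]]
  }
  ok
}

# Count residues at one relative position across a set of centralized
# sequences; '_' padding contributes nothing.
.position_counts <- function(sequences, idx) {
  ch <- substr(sequences, idx, idx)
  ch <- ch[ch %in% AMINO_ACIDS]
  tab <- table(factor(ch, levels = AMINO_ACIDS))
  as.integer(tab)
}

# 2x2 chi-square with 1 df, Yates correction optional. Returns c(stat, p);
# a zero margin yields stat 0 / p 1 (no information).
.chisq_2x2 <- function(a, b, c, d, yates = FALSE) {
  # double arithmetic: integer counts overflow in the margin product
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(c(stat = 0, p = 1))
  delta <- abs(a * d - b * c)
  if (yates) delta <- max(0, delta - n / 2)
  stat <- n * delta^2 / (r1 * r2 * c1 * c2)
  c(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# One-sample (goodness-of-fit) chi-square of an observed count against a
# background probability p0, collapsed to residue vs not-residue.
.chisq_gof <- function(obs, n, p0) {
  if (n == 0 || p0 <= 0 || p0 >= 1) return(c(stat = 0, p = 1))
  e1 <- n * p0
  e2 <- n * (1 - p0)
  stat <- (obs - e1)^2 / e1 + ((n - obs) - e2)^2 / e2
  c(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Position-specific residue enrichment for a set of phosphosites
#'
#' For every (relative position, residue) pair, tests whether the residue
#' is over- or under-represented in the foreground sequences relative to
#' a background, using a 1-df chi-square test: a 2x2
#' residue-vs-other / foreground-vs-background table when the background
#' is itself a set of sequences, or a goodness-of-fit test against the
#' background frequency when the background is a residue-frequency model.
#' This is the sequence-logo style analysis used to read off kinase
#' consensus preferences from regulated phosphosite sets.
#'
#' @param foreground Character vector of centralized sequences (13-mers by
#'   default conventions); must be non-empty.
#' @param background Either a character vector of centralized sequences
#'   (e.g. all quantified sites in the experiment — the natural null),
#'   the string \code{"uniform"} for a uniform 1/20 residue model, or a
#'   named numeric vector of residue frequencies summing to 1.
#' @param p_threshold Significance threshold for the enrichment flag
#'   (default 0.001).
#' @param groups Optional list of residue classes to test pooled in
#'   addition to single residues, e.g. \code{list(RK = c("R","K"),
#'   DE = c("D","E"))}.
#' @param yates Apply Yates continuity correction in the 2x2 test
#'   (default \code{FALSE}).
#' @return A data frame with one row per (position, residue) combination:
#'   \code{position}, \code{residue}, \code{fg_count}, \code{fg_total},
#'   \code{bg_count}, \code{bg_total}, \code{fg_freq}, \code{bg_freq},
#'   \code{chi_square}, \code{p_value}, and \code{enriched} (p below the
#'   threshold \emph{and} foreground frequency above background). The
#'   attribute \code{"logo"} holds a positions-by-residues matrix of
#'   signed log2 fold enrichment for flagged cells (0 elsewhere),
#'   ready for external logo plotting.
#' @details Padding characters \code{"_"} contribute to neither
#'   foreground nor background counts at a position, so terminal sites
#'   simply carry less weight at the outer positions.
#' @export
position_enrichment <- function(foreground, background,
                                p_threshold = 0.001,
                                groups = NULL, yates = FALSE) {
  if (length(foreground) == 0L)
    stop("empty foreground sequence set", call. = FALSE)
  len <- unique(nchar(foreground))
  if (length(len) != 1L || len %% 2L != 1L)
    stop("foreground sequences must share one odd length", call. = FALSE)
  centre <- (len + 1L) %/% 2L
  positions <- seq_len(len) - centre

  bg_seqs <- NULL
  bg_freq <- NULL
  if (is.character(background) && length(background) == 1L &&
      identical(background, "uniform")) {
    bg_freq <- stats::setNames(rep(1 / 20, 20), AMINO_ACIDS)
  } else if (is.numeric(background)) {
    if (is.null(names(background)) ||
        !all(AMINO_ACIDS %in% names(background)))
      stop("frequency background must be named by all 20 amino acids",
           call. = FALSE)
    bg_freq <- background[AMINO_ACIDS] / sum(background[AMINO_ACIDS])
  } else if (is.character(background)) {
    if (any(nchar(background) != len))
      stop("background sequences must have the foreground length",
           call. = FALSE)
    bg_seqs <- background
    if (length(bg_seqs) < length(foreground))
      warning("background smaller than foreground", call. = FALSE)
  } else {
    stop("'background' must be sequences, \"uniform\", or frequencies",
         call. = FALSE)
  }

  units <- c(as.list(stats::setNames(AMINO_ACIDS, AMINO_ACIDS)), groups)
  out <- vector("list", length(positions))
  for (k in seq_along(positions)) {
    idx <- centre + positions[k]
    fg_counts <- .position_counts(foreground, idx)
    fg_total <- sum(fg_counts)
    names(fg_counts) <- AMINO_ACIDS
    if (!is.null(bg_seqs)) {
      bg_counts <- .position_counts(bg_seqs, idx)
      names(bg_counts) <- AMINO_ACIDS
      bg_total <- sum(bg_counts)
    } else {
      bg_counts <- NULL
      bg_total <- NA_integer_
    }
    rows <- lapply(names(units), function(u) {
      resset <- units[[u]]
      a <- sum(fg_counts[resset])
      if (!is.null(bg_seqs)) {
        cc <- sum(bg_counts[resset])
        ts <- .chisq_2x2(a, fg_total - a, cc, bg_total - cc, yates = yates)
        bgf <- if (bg_total > 0) cc / bg_total else NA_real_
        bgc <- cc
      } else {
        p0 <- sum(bg_freq[resset])
        ts <- .chisq_gof(a, fg_total, p0)
        bgf <- p0
        bgc <- NA_integer_
      }
      fgf <- if (fg_total > 0) a / fg_total else NA_real_
      data.frame(position = positions[k], residue = u,
                 fg_count = a, fg_total = fg_total,
                 bg_count = bgc, bg_total = bg_total,
                 fg_freq = fgf, bg_freq = bgf,
                 chi_square = unname(ts["stat"]),
                 p_value = unname(ts["p"]),
                 stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  res$enriched <- !is.na(res$p_value) & res$p_value < p_threshold &
    !is.na(res$fg_freq) & !is.na(res$bg_freq) & res$fg_freq > res$bg_freq
  rownames(res) <- NULL

  logo <- matrix(0, nrow = length(positions), ncol = 20,
                 dimnames = list(as.character(positions), AMINO_ACIDS))
  single <- res[res$residue %in% AMINO_ACIDS, , drop = FALSE]
  flagged <- !is.na(single$p_value) & single$p_value < p_threshold &
    is.finite(single$fg_freq) & is.finite(single$bg_freq) &
    single$fg_freq > 0 & single$bg_freq > 0
  for (i in which(flagged)) {
    logo[as.character(single$position[i]), single$residue[i]] <-
      log2(single$fg_freq[i] / single$bg_freq[i])
  }
  attr(res, "logo") <- logo
  res
}
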