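# Per-round analysis of in vitro selection read sets: peptide counting,
# abundance ranking, position frequency matrices, information-content logos,
# enrichment trajectories and consensus motifs.

#' Construct a selection-round count table
#'
#' @param counts Named integer vector, peptide sequence -> read count.
#' @param round_id Integer round label.
#' @return A list of class `selection_round` with `round_id`, `counts` and
#'   `total_reads` (= sum of counts).
#' @export
selection_round <- function(counts, round_id = NA_integer_) {
  if (length(counts) > 0L) {
    counts <- counts[order(names(counts))]
    if (any(counts < 1)) stop("all peptide counts must be >= 1")
  } else {
    counts <- stats::setNames(integer(0), character(0))
  }
  structure(list(round_id = as.integer(round_id),
                 counts = counts,
                 total_reads = sum(counts)),
            class = "selection_round")
}

#' @export
print.selection_round <- function(x, ...) {
  cat(sprintf("<selection round %s: %d distinct peptides, %d reads>\n",
              x$round_id, length(x$counts), x$total_reads))
  invisible(x)
}

#' Count peptides in a selection-round read set
#'
#' Each read is scanned for exact matches of the 5' and 3' flanking
#' sequences; the insert between them is excised and translated in frame 0.
#' Reads lacking either flank are discarded, as are translations containing
#' internal stops (one trailing stop is tolerated and stripped). Counts are
#' aggregated per peptide and peptides below `min_count` are dropped.
#'
#' @param reads List of [nt_seq()] records.
#' @param flank5,flank3 Plain-DNA flanking sequences (either may be empty,
#'   matching the read boundary).
#' @param min_count Post-aggregation abundance floor (default 1: no floor).
#' @param round_id Round label stored on the result.
#' @return A [selection_round()]. Empty result (no surviving read) warns.
#' @export
count_peptides <- function(reads, flank5 = "", flank3 = "", min_count = 1L,
                           round_id = NA_integer_) {
  if (grepl("[^ACGT]", flank5) || grepl("[^ACGT]", flank3)) {
    stop("flanks must be plain DNA (A/C/G/T only)")
  }
  peptides <- character(0)
  for (r in reads) {
    s <- r$residues
    ins_start <- 1L
    if (nzchar(flank5)) {
      m <- regexpr(flank5, s, fixed = TRUE)
      if (m == -1L) next
      ins_start <- m + attr(m, "match.length")
    }
    ins_end <- nchar(s)
    if (nzchar(flank3)) {
      m <- regexpr(flank3, substr(s, ins_start, nchar(s)), fixed = TRUE)
      if (m == -1L) next
      ins_end <- ins_start + m - 2L
    }
    if (ins_end - ins_start + 1L < 3L) next
    pep <- translate_dna(nt_seq(substr(s, ins_start, ins_end)), 0L)$residues
    pep <- sub("\\*$", "", pep)          # tolerate a trailing stop
    if (!nzchar(pep) || grepl("\\*", pep)) next
    peptides <- c(peptides, pep)
  }
  if (length(peptides) == 0L) {
    warning("no read survived flank matching and translation filters")
    return(selection_round(integer(0), round_id))
  }
  counts <- table(peptides)
  counts <- counts[counts >= min_count]
  selection_round(stats::setNames(as.integer(counts), names(counts)), round_id)
}

#' Rank peptides by abundance
#'
#' @param tab A [selection_round()].
#' @param n Number of top peptides to return.
#' @return `data.frame` with `peptide`, `count`, `fraction` (of total reads),
#'   sorted by decreasing count with ties broken alphabetically.
#' @export
rank_abundance <- function(tab, n = 100L) {
  stopifnot(inherits(tab, "selection_round"), n >= 1L)
  ord <- order(-tab$counts, names(tab$counts))
  top <- utils::head(ord, n)
  data.frame(peptide = names(tab$counts)[top],
             count = as.integer(tab$counts[top]),
             fraction = as.numeric(tab$counts[top]) / tab$total_reads,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Position frequency matrix and information-content logo
#'
#' Residue frequencies are computed per position over equal-length peptides,
#' optionally weighted. Information content per position is
#' `IC = log2(20) - H` bits, where `H` is the Shannon entropy of the column
#' frequencies (no small-sample correction); a letter's logo height is its
#' frequency times the column IC. Peptides containing `X` are excluded.
#'
#' @param peptides Character vector or list of [aa_seq()]s, all one length.
#' @param weights Optional nonnegative weights (e.g. read counts), recycled
#'   against `peptides`; `NULL` weights every sequence equally.
#' @return List of class `peptide_logo` with `pfm` (residues x positions
#'   frequency matrix), `logo` (same shape, bit heights), `ic` (per-position
#'   information content, bits) and `support` (number of sequences used).
#' @export
peptide_logo <- function(peptides, weights = NULL) {
  seqs <- vapply(peptides, function(p) {
    if (inherits(p, "aa_seq")) p$residues else toupper(as.character(p))
  }, character(1), USE.NAMES = FALSE)
  if (length(seqs) == 0L) stop("no peptides supplied")
  if (is.null(weights)) weights <- rep(1, length(seqs))
  weights <- rep_len(as.numeric(weights), length(seqs))
  keep <- !grepl("X", seqs, fixed = TRUE)
  seqs <- seqs[keep]
  weights <- weights[keep]
  if (length(seqs) == 0L) stop("no peptides left after excluding 'X' residues")
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("peptides must all have equal length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  pfm <- matrix(0, nrow = length(AA_ALPHABET), ncol = len,
                dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(len)) {
    w <- tapply(weights, factor(mat[, j], levels = AA_ALPHABET), sum,
                default = 0)
    pfm[, j] <- w / sum(weights)
  }
  ent <- apply(pfm, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- log2(20) - ent
  logo <- sweep(pfm, 2, ic, `*`)
  structure(list(pfm = pfm, logo = logo, ic = ic, support = length(seqs)),
            class = "peptide_logo")
}

#' @export
print.peptide_logo <- function(x, ...) {
  cat(sprintf("<peptide logo: %d positions, %d sequences, total IC %.2f bits>\n",
              ncol(x$pfm), x$support, sum(x$ic)))
  invisible(x)
}

#' Text-free logo plot (stacked letter heights in bits)
#'
#' @param x A [peptide_logo()].
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.peptide_logo <- function(x, ...) {
  graphics::barplot(x$logo, names.arg = seq_len(ncol(x$logo)),
                    xlab = "position", ylab = "bits",
                    ylim = c(0, log2(20)), border = NA,
                    col = grDevices::hcl.colors(nrow(x$logo), "Spectral"), ...)
  invisible(x)
}

#' Enrichment trajectory of one peptide across selection rounds
#'
#' @param rounds List of [selection_round()]s, in round order.
#' @param peptide Peptide sequence (character or [aa_seq()]).
#' @return `data.frame` with `round_id`, `fraction` (0 when absent) and
#'   `ratio` to the previous round (`NA` for the first round and whenever the
#'   previous fraction is 0).
#' @export
enrichment_trajectory <- function(rounds, peptide) {
  stopifnot(length(rounds) >= 1L)
  if (inherits(peptide, "aa_seq")) peptide <- peptide$residues
  frac <- vapply(rounds, function(r) {
    if (r$total_reads == 0L) return(0)
    cnt <- r$counts[peptide]
    if (is.na(cnt)) 0 else as.numeric(cnt) / r$total_reads
  }, numeric(1))
  ratio <- c(NA_real_, frac[-1] / frac[-length(frac)])
  ratio[c(FALSE, frac[-length(frac)] == 0)] <- NA_real_
  data.frame(round_id = vapply(rounds, `[[`, integer(1), "round_id"),
             fraction = frac, ratio = ratio, row.names = NULL)
}

#' Consensus motif of a position frequency matrix
#'
#' @param pfm A [peptide_logo()] or a residues-by-positions frequency matrix.
#' @param threshold Minimum modal frequency for a position to be called;
#'   positions below it are rendered `x`. Modal ties resolve to the
#'   alphabetically smallest residue.
#' @return Consensus string.
#' @export
consensus_sequence <- function(pfm, threshold = 0.5) {
  if (inherits(pfm, "peptide_logo")) pfm <- pfm$pfm
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  vapply(seq_len(ncol(pfm)), function(j) {
    col <- pfm[, j]
    modal <- sort(names(col)[col == max(col)])[1L]
    if (col[modal] >= threshold) modal else "x"
  }, character(1)) |> paste(collapse = "")
}
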