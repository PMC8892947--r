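# Sequence containers and FASTA/FASTQ I/O shared by all pipeline stages.
# Parsing is delegated to Biostrings; the thin wrappers here normalise the
# records into plain R lists so downstream code has no S4 surface.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

IUPAC_NT <- names(Biostrings::IUPAC_CODE_MAP)  # A C G T M R W S Y K V H D B N

#' Construct a nucleotide sequence record
#'
#' @param residues Character scalar over the IUPAC nucleotide alphabet
#'   (`A`,`C`,`G`,`T` plus ambiguity codes).
#' @param id Record identifier.
#' @param quality Optional per-base quality string (same length as
#'   `residues`), as read from FASTQ.
#' @return An object of class `nt_seq`.
#' @export
nt_seq <- function(residues, id = "", quality = NULL) {
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("nucleotide sequence must be nonempty")
  bad <- which(!strsplit(residues, "")[[1]] %in% IUPAC_NT)
  if (length(bad) > 0L) {
    stop(sprintf("invalid nucleotide character at position %d in '%s'",
                 bad[1L], id))
  }
  if (!is.null(quality) && nchar(quality) != nchar(residues)) {
    stop("quality string length differs from sequence length")
  }
  structure(list(id = as.character(id), residues = residues,
                 quality = quality),
            class = "nt_seq")
}

#' Construct a peptide sequence record
#'
#' @param residues Character scalar over the 20 one-letter amino-acid codes;
#'   `*` marks a stop, `X` an undetermined residue.
#' @param id Record identifier.
#' @return An object of class `aa_seq`.
#' @export
aa_seq <- function(residues, id = "") {
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("peptide sequence must be nonempty")
  bad <- which(!strsplit(residues, "")[[1]] %in% c(AA_ALPHABET, "*", "X", "-"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid amino-acid character at position %d in '%s'",
                 bad[1L], id))
  }
  structure(list(id = as.character(id), residues = residues),
            class = "aa_seq")
}

#' @export
print.nt_seq <- function(x, ...) {
  cat(sprintf("<nt_seq %s: %d nt%s>\n", x$id, nchar(x$residues),
              if (is.null(x$quality)) "" else ", with qualities"))
  invisible(x)
}

#' @export
print.aa_seq <- function(x, ...) {
  cat(sprintf("<aa_seq %s: %d aa>\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Read sequences from FASTA or FASTQ
#'
#' One record per entry, order preserved; FASTQ qualities are retained on the
#' returned records.
#'
#' @param path File path.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by extension, falling
#'   back to first-character sniffing).
#' @return List of [nt_seq()] records. An empty file gives an empty list with
#'   a warning.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) "fastq"
              else if (grepl("\\.(fasta|fa|fna)$", path, ignore.case = TRUE)) "fasta"
              else {
                first <- substr(readLines(path, n = 1L, warn = FALSE)[1], 1, 1)
                if (identical(first, "@")) "fastq" else "fasta"
              }
  }
  if (file.size(path) == 0L) {
    warning(sprintf("empty file: %s", path))
    return(list())
  }
  if (format == "fastq") .read_fastq(path) else .read_fasta(path)
}

.read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop(sprintf(
                    "FASTA parse error in %s: %s", path, conditionMessage(e))))
  if (length(set) == 0L) {
    warning(sprintf("no records in %s", path))
    return(list())
  }
  lapply(seq_along(set), function(i) {
    nt_seq(as.character(set[[i]]), id = names(set)[i])
  })
}

# FASTQ is validated record-by-record so malformed input can be reported with
# a line number (Biostrings' message does not carry one).
.read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  while (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  n <- length(lines)
  if (n == 0L) {
    warning(sprintf("no records in %s", path))
    return(list())
  }
  if (n %% 4L != 0L) {
    stop(sprintf("FASTQ parse error in %s: truncated record starting at line %d",
                 path, 4L * (n %/% 4L) + 1L))
  }
  out <- vector("list", n %/% 4L)
  for (i in seq_len(n %/% 4L)) {
    l <- 4L * (i - 1L)
    if (substr(lines[l + 1L], 1, 1) != "@") {
      stop(sprintf("FASTQ parse error in %s: expected '@' header at line %d",
                   path, l + 1L))
    }
    if (substr(lines[l + 3L], 1, 1) != "+") {
      stop(sprintf("FASTQ parse error in %s: expected '+' separator at line %d",
                   path, l + 3L))
    }
    if (nchar(lines[l + 4L]) != nchar(lines[l + 2L])) {
      stop(sprintf(
        "FASTQ parse error in %s: quality length != sequence length at line %d",
        path, l + 4L))
    }
    out[[i]] <- nt_seq(lines[l + 2L],
                       id = sub("^@", "", strsplit(lines[l + 1L], "[ \t]")[[1]][1]),
                       quality = lines[l + 4L])
  }
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs List of [nt_seq()] records.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`. FASTQ requires qualities on every
#'   record; records lacking them are written with a uniform `I` quality.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    stopifnot(inherits(s, "nt_seq"))
    if (format == "fasta") {
      writeLines(c(paste0(">", s$id), s$residues), con)
    } else {
      q <- if (is.null(s$quality)) strrep("I", nchar(s$residues)) else s$quality
      writeLines(c(paste0("@", s$id), s$residues, "+", q), con)
    }
  }
  invisible(path)
}

# ---- genetic code -----------------------------------------------------------

# Expand one IUPAC degenerate codon into its plain-codon set.
expand_codon <- function(codon) {
  sym <- strsplit(toupper(codon), "")[[1]]
  if (length(sym) != 3L || any(!sym %in% IUPAC_NT)) {
    stop(sprintf("'%s' is not a valid IUPAC codon", codon))
  }
  sets <- lapply(sym, function(s) strsplit(Biostrings::IUPAC_CODE_MAP[[s]], "")[[1]])
  as.vector(outer(outer(sets[[1]], sets[[2]], paste0), sets[[3]], paste0))
}

# Translate a single (possibly degenerate) codon: the common residue of all
# expansions, or 'X' when the expansions disagree.
codon_to_aa <- function(codon) {
  aas <- unique(Biostrings::GENETIC_CODE[expand_codon(codon)])
  if (length(aas) == 1L) aas else "X"
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code; the trailing partial codon is dropped and stops are
#' rendered `*`. IUPAC ambiguity codes translate normally when every expansion
#' of the codon encodes the same residue (e.g. `GGN` -> `G`), and to `X`
#' otherwise.
#'
#' @param seq [nt_seq()] or character scalar.
#' @param frame_offset Reading-frame offset, 0, 1 or 2.
#' @return An [aa_seq()] of length `floor((nchar(seq) - frame_offset) / 3)`.
#' @export
translate_dna <- function(seq, frame_offset = 0L) {
  if (is.character(seq)) seq <- nt_seq(seq)
  stopifnot(inherits(seq, "nt_seq"))
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  s <- seq$residues
  if (nchar(s) < frame_offset + 3L) {
    stop("sequence too short for the requested reading frame")
  }
  n_codon <- (nchar(s) - frame_offset) %/% 3L
  starts <- frame_offset + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(s, starts, starts + 2L)
  plain <- !grepl("[^ACGT]", codons)
  aa <- character(n_codon)
  aa[plain] <- Biostrings::GENETIC_CODE[codons[plain]]
  if (any(!plain)) aa[!plain] <- vapply(codons[!plain], codon_to_aa, character(1))
  aa_seq(paste(aa, collapse = ""), id = seq$id)
}
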