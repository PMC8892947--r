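# Multi-frame structural ensembles of a protein-RNA complex.
#
# The canonical on-disk format is multi-model PDB (self-contained text with
# MODEL/ENDMDL blocks). Reading goes through bio3d; the multi-model writer is
# implemented here because bio3d's write.pdb emits a single model.

PROTEIN_RESNAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                      "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                      "THR", "TRP", "TYR", "VAL")
RNA_RESNAMES   <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU",
                    "ADE", "CYT", "GUA", "URA")
WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "SPC")
ION_RESNAMES   <- c("MG", "K", "NA", "CL", "CA", "ZN", "MN")

AA3TO1 <- stats::setNames(
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  PROTEIN_RESNAMES)

# Polymer classification is total: every residue name maps to exactly one
# class; unknown names fall through to "other" (with a warning at read time).
classify_residue <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- rep("other", length(resname))
  out[resname %in% PROTEIN_RESNAMES] <- "protein"
  out[resname %in% RNA_RESNAMES] <- "rna"
  out[resname %in% WATER_RESNAMES] <- "water"
  out[resname %in% ION_RESNAMES] <- "ion"
  out
}

#' Construct a structural ensemble
#'
#' @param atoms `data.frame` with columns `name` (atom name), `element`,
#'   `resname`, `resno`, `chain`; a `class` column (polymer class, one of
#'   `protein`, `rna`, `water`, `ion`, `other`) is derived from `resname`
#'   when absent.
#' @param coords Numeric array `n_atoms x 3 x n_frames` of coordinates in
#'   Angstrom; a single `n_atoms x 3` matrix is promoted to one frame.
#' @param frame_spacing Optional time per frame, in ns.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(atoms, coords, frame_spacing = NULL) {
  atoms <- as.data.frame(atoms)
  req <- c("name", "element", "resname", "resno", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0L) stop("atoms table lacks column(s): ",
                              paste(miss, collapse = ", "))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(atoms)) {
    stop(sprintf("coordinate array has %d atoms per frame but atom table has %d",
                 dim(coords)[1], nrow(atoms)))
  }
  if (dim(coords)[3] < 1L) stop("an ensemble needs at least one frame")
  if (is.null(atoms$class)) atoms$class <- classify_residue(atoms$resname)
  structure(list(atoms = atoms, coords = coords,
                 frame_spacing = frame_spacing),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cls <- table(x$atoms$class)
  cat(sprintf("<ensemble: %d atoms, %d frame(s)>\n", nrow(x$atoms), n_frames(x)))
  cat("  ", paste(sprintf("%s: %d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens An [ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[3]

#' Default analysis window: the final quarter of the trajectory
#'
#' Interface statistics are normally computed on the equilibrated tail of a
#' trajectory; the default window is the last 25% of frames (at least one).
#'
#' @param ens An [ensemble()].
#' @param fraction Tail fraction to keep.
#' @return Integer vector of frame indices (1-based).
#' @export
tail_frames <- function(ens, fraction = 0.25) {
  nf <- n_frames(ens)
  n_keep <- max(1L, floor(fraction * nf))
  seq.int(nf - n_keep + 1L, nf)
}

.resolve_frames <- function(ens, frames) {
  if (is.null(frames)) frames <- tail_frames(ens)
  frames <- as.integer(frames)
  if (length(frames) == 0L) stop("empty frame range")
  if (any(frames < 1L | frames > n_frames(ens))) stop("frame index out of range")
  frames
}

#' Read a structural ensemble from a multi-model PDB file
#'
#' Every MODEL block becomes one frame; atom metadata is taken from the first
#' model and must be identical across models. Polymer classes are assigned
#' from residue names (standard amino acids -> protein; A/C/G/U ribonucleotides
#' -> RNA; HOH/WAT -> water; MG/K/NA/CL/CA -> ion; anything else -> "other",
#' with a warning).
#'
#' @param path PDB file path.
#' @param frame_spacing Optional time per frame in ns, stored on the result.
#' @return An [ensemble()].
#' @export
read_ensemble <- function(path, frame_spacing = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  element <- toupper(trimws(at$elesy))
  noelem <- is.na(element) | !nzchar(element)
  if (any(noelem)) {
    # fall back on the first alphabetic character of the atom name
    element[noelem] <- substr(gsub("[^A-Za-z].*$", "",
                                   gsub("^[0-9']+", "", at$elety[noelem])), 1, 1)
  }
  atoms <- data.frame(name = trimws(at$elety), element = element,
                      resname = trimws(at$resid), resno = at$resno,
                      chain = ifelse(is.na(at$chain), " ", at$chain),
                      stringsAsFactors = FALSE)
  atoms$class <- classify_residue(atoms$resname)
  if (any(atoms$class == "other")) {
    warning("unclassified residue name(s): ",
            paste(unique(atoms$resname[atoms$class == "other"]), collapse = ", "))
  }
  xyz <- pdb$xyz                       # n_frames x 3*n_atoms
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  na <- nrow(atoms)
  if (ncol(xyz) != 3L * na) {
    stop(sprintf("atom-count mismatch between models in %s", path))
  }
  coords <- array(NA_real_, dim = c(na, 3L, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  ensemble(atoms, coords, frame_spacing = frame_spacing)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens An [ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  at <- ens$atoms
  ishet <- at$class %in% c("water", "ion", "other")
  rec <- ifelse(ishet, "HETATM", "ATOM  ")
  # PDB columns: short atom names are indented one space within the 4-char field
  nm <- ifelse(nchar(at$name) < 4L, paste0(" ", formatC(at$name, width = -3)),
               at$name)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(ens)
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ens$coords[, , f]
    lines <- sprintf("%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, seq_len(nrow(at)), nm, at$resname, at$chain, at$resno,
                     xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element)
    writeLines(lines, con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Define secondary-structure elements
#'
#' @param label Character vector, each `"helix"` or `"sheet"`.
#' @param chain Chain identifier per element.
#' @param from,to Inclusive residue-number range per element.
#' @return A `data.frame` of class `ss_elements`.
#' @export
ss_elements <- function(label, chain, from, to) {
  stopifnot(all(label %in% c("helix", "sheet")), all(from <= to))
  structure(data.frame(label = label, chain = chain, from = from, to = to,
                       stringsAsFactors = FALSE),
            class = c("ss_elements", "data.frame"))
}

# Logical mask of atoms covered by an ss_elements set.
.ss_mask <- function(atoms, ss) {
  mask <- rep(FALSE, nrow(atoms))
  for (i in seq_len(nrow(ss))) {
    mask <- mask | (atoms$chain == ss$chain[i] &
                    atoms$resno >= ss$from[i] & atoms$resno <= ss$to[i])
  }
  mask
}
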