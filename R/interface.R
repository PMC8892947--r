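# Protein-RNA interface characterization across a structural ensemble:
# direct hydrogen bonds, water bridges, metal-ion bridges, volumetric
# occupancy grids, and secondary-structure-restricted backbone RMSD.
#
# Geometry criteria are the common trajectory-analysis defaults: an H-bond is
# a donor-acceptor heavy-atom distance <= 3.0 A with a donor-H-acceptor angle
# >= 135 degrees when explicit hydrogens are available (the distance criterion
# alone otherwise). Ion coordination uses per-element distance cutoffs
# (Mg 3.0 A, K 3.5 A). Occupancy is the fraction of analyzed frames in which
# an interaction is present.

# Heavy-atom H-bond donor/acceptor tables for the 20 amino acids, the 4
# ribonucleotides, and water. Backbone entries use resname "*".
.PROT_DONORS <- list(
  "*" = "N",                       # backbone amide (absent in proline, but a
                                   # PRO N never carries an H so the angle
                                   # test rejects it when hydrogens exist)
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG")
.PROT_ACCEPTORS <- list(
  "*" = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")
.RNA_DONORS <- list(
  "*" = "O2'",
  A = "N6", G = c("N1", "N2"), C = "N4", U = "N3")
.RNA_ACCEPTORS <- list(
  "*" = c("OP1", "OP2", "O1P", "O2P", "O5'", "O3'", "O2'", "O4'"),
  A = c("N1", "N3", "N7"), G = c("O6", "N3", "N7"),
  C = c("O2", "N3"), U = c("O2", "O4"))
.WATER_O <- c("O", "OW", "OH2")

.base_resname <- function(resname) {
  # strip common RNA residue-name prefixes (RA -> A etc.)
  sub("^R", "", toupper(resname))
}

# indices of atoms matching a donor/acceptor table within one polymer class
.polar_atoms <- function(atoms, class, table) {
  idx <- integer(0)
  in_class <- atoms$class == class
  if ("*" %in% names(table)) {
    idx <- c(idx, which(in_class & atoms$name %in% table[["*"]]))
  }
  rn <- if (class == "rna") .base_resname(atoms$resname) else toupper(atoms$resname)
  for (res in setdiff(names(table), "*")) {
    idx <- c(idx, which(in_class & rn == res & atoms$name %in% table[[res]]))
  }
  sort(unique(idx))
}

# hydrogens covalently bound to each donor, resolved on the first analyzed
# frame (bond topology is frame-invariant for fixed-topology ensembles)
.donor_hydrogens <- function(ens, donor_idx, frame) {
  at <- ens$atoms
  h_idx <- which(at$element == "H")
  if (length(h_idx) == 0L) return(NULL)
  xyz <- ens$coords[, , frame]
  lapply(donor_idx, function(d) {
    same_res <- h_idx[at$chain[h_idx] == at$chain[d] &
                      at$resno[h_idx] == at$resno[d]]
    if (length(same_res) == 0L) return(integer(0))
    dd <- sqrt(colSums((t(xyz[same_res, , drop = FALSE]) - xyz[d, ])^2))
    same_res[dd <= 1.3]
  })
}

.pair_dist <- function(xyz, i, j) {
  sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
}

.angle_deg <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

.atom_label <- function(atoms, i) {
  sprintf("%s/%s%d/%s", atoms$chain[i], atoms$resname[i], atoms$resno[i],
          atoms$name[i])
}

#' Detect direct protein-RNA hydrogen bonds across an ensemble
#'
#' Per frame, an H-bond exists between a donor and an acceptor on opposite
#' polymer classes when the heavy-atom distance is at most `dist_cutoff` and,
#' if explicit hydrogens are present, some donor hydrogen gives a
#' donor-H-acceptor angle of at least `angle_cutoff`. Detections are
#' aggregated by (donor atom, acceptor atom); occupancy is the fraction of
#' analyzed frames in which the bond is present.
#'
#' @param ens An [ensemble()].
#' @param frames Frame indices to analyze (default: [tail_frames()], the
#'   final quarter).
#' @param dist_cutoff Donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_cutoff Donor-H-acceptor angle cutoff, degrees.
#' @param min_occupancy Minimum occupancy for a record to be reported.
#' @return `data.frame` of class `hbond_records`: donor and acceptor atom
#'   references, `occupancy`, `donor_side` (`protein`/`rna`), and `via`
#'   (`side chain`/`backbone`, judged from the protein heavy atom).
#' @export
detect_hbonds <- function(ens, frames = NULL, dist_cutoff = 3.0,
                          angle_cutoff = 135, min_occupancy = 0.10) {
  stopifnot(inherits(ens, "ensemble"))
  frames <- .resolve_frames(ens, frames)
  at <- ens$atoms
  donors <- c(.polar_atoms(at, "protein", .PROT_DONORS),
              .polar_atoms(at, "rna", .RNA_DONORS))
  acceptors <- c(.polar_atoms(at, "protein", .PROT_ACCEPTORS),
                 .polar_atoms(at, "rna", .RNA_ACCEPTORS))
  # interface candidates: donor and acceptor on opposite polymer classes
  cand <- expand.grid(d = donors, a = acceptors)
  opposite <- (at$class[cand$d] == "protein" & at$class[cand$a] == "rna") |
              (at$class[cand$d] == "rna" & at$class[cand$a] == "protein")
  cand <- cand[opposite, , drop = FALSE]
  if (nrow(cand) == 0L) return(.empty_hbond_df())
  have_h <- any(at$element == "H")
  if (!have_h) {
    warning("no hydrogens in ensemble: angle criterion skipped")
    dh <- NULL
  } else {
    dh <- .donor_hydrogens(ens, cand$d, frames[1])
  }
  present <- integer(nrow(cand))
  for (f in frames) {
    xyz <- ens$coords[, , f]
    ok <- .pair_dist(xyz, cand$d, cand$a) <= dist_cutoff
    if (have_h) {
      for (k in which(ok)) {
        hs <- dh[[k]]
        if (length(hs) == 0L) {
          ok[k] <- FALSE
          next
        }
        angs <- vapply(hs, function(h) {
          .angle_deg(xyz[cand$d[k], ], xyz[h, ], xyz[cand$a[k], ])
        }, numeric(1))
        ok[k] <- any(angs >= angle_cutoff)
      }
    }
    present <- present + ok
  }
  occ <- present / length(frames)
  keep <- which(occ >= min_occupancy & occ > 0)
  if (length(keep) == 0L) return(.empty_hbond_df())
  d <- cand$d[keep]
  a <- cand$a[keep]
  prot_atom <- ifelse(at$class[d] == "protein", at$name[d], at$name[a])
  out <- data.frame(
    donor = vapply(d, function(i) .atom_label(at, i), character(1)),
    donor_chain = at$chain[d], donor_resname = at$resname[d],
    donor_resno = at$resno[d], donor_atom = at$name[d],
    acceptor = vapply(a, function(i) .atom_label(at, i), character(1)),
    acceptor_chain = at$chain[a], acceptor_resname = at$resname[a],
    acceptor_resno = at$resno[a], acceptor_atom = at$name[a],
    occupancy = occ[keep],
    donor_side = at$class[d],
    via = ifelse(prot_atom %in% c("N", "O", "OXT"), "backbone", "side chain"),
    stringsAsFactors = FALSE)
  out <- out[order(-out$occupancy, out$donor, out$acceptor), ]
  rownames(out) <- NULL
  class(out) <- c("hbond_records", "data.frame")
  out
}

.empty_hbond_df <- function() {
  out <- data.frame(donor = character(0), donor_chain = character(0),
                    donor_resname = character(0), donor_resno = integer(0),
                    donor_atom = character(0), acceptor = character(0),
                    acceptor_chain = character(0),
                    acceptor_resname = character(0),
                    acceptor_resno = integer(0), acceptor_atom = character(0),
                    occupancy = numeric(0), donor_side = character(0),
                    via = character(0), stringsAsFactors = FALSE)
  class(out) <- c("hbond_records", "data.frame")
  out
}

#' Side-chain versus backbone H-bond summary
#'
#' @param records An `hbond_records` data frame from [detect_hbonds()].
#' @return List with `sidechain_fraction` (share of records mediated by a
#'   protein side-chain atom) and `per_residue` (named record counts per
#'   contributing protein residue).
#' @export
sidechain_backbone_summary <- function(records) {
  if (nrow(records) == 0L) stop("no H-bond records to summarize")
  prot_res <- ifelse(records$donor_side == "protein",
                     paste0(records$donor_resname, records$donor_resno),
                     paste0(records$acceptor_resname, records$acceptor_resno))
  list(sidechain_fraction = mean(records$via == "side chain"),
       per_residue = sort(table(prot_res), decreasing = TRUE))
}

#' Detect water-mediated protein-RNA bridges
#'
#' Per frame, a water bridges when its oxygen is simultaneously H-bonded
#' (distance criterion, [detect_hbonds()] defaults) to at least one polar
#' protein atom and one polar RNA atom. With `by = "pair"` (default),
#' detections are aggregated per (protein atom, RNA atom) partner pair across
#' exchanging waters — the conserved-site view; `by = "water"` tallies each
#' water molecule instead.
#'
#' @param ens An [ensemble()].
#' @param frames Frame indices (default: final quarter).
#' @param dist_cutoff Water-oxygen to partner heavy-atom distance cutoff, A.
#' @param min_occupancy Minimum reported occupancy.
#' @param by Aggregation mode, `"pair"` or `"water"`.
#' @return `data.frame` of class `bridge_records` with `bridge_kind`
#'   (`water`), bridging species, partner references and `occupancy`.
#' @export
detect_water_bridges <- function(ens, frames = NULL, dist_cutoff = 3.0,
                                 min_occupancy = 0.10,
                                 by = c("pair", "water")) {
  stopifnot(inherits(ens, "ensemble"))
  by <- match.arg(by)
  frames <- .resolve_frames(ens, frames)
  at <- ens$atoms
  wat <- which(at$class == "water" & at$name %in% .WATER_O)
  if (length(wat) == 0L) {
    warning("no water molecules in ensemble")
    return(.empty_bridge_df())
  }
  prot <- sort(unique(c(.polar_atoms(at, "protein", .PROT_DONORS),
                        .polar_atoms(at, "protein", .PROT_ACCEPTORS))))
  rna <- sort(unique(c(.polar_atoms(at, "rna", .RNA_DONORS),
                       .polar_atoms(at, "rna", .RNA_ACCEPTORS))))
  counts <- new.env(parent = emptyenv())
  for (f in frames) {
    xyz <- ens$coords[, , f]
    frame_keys <- character(0)
    for (w in wat) {
      dp <- sqrt(colSums((t(xyz[prot, , drop = FALSE]) - xyz[w, ])^2))
      pc <- prot[dp <= dist_cutoff]
      if (length(pc) == 0L) next
      dr <- sqrt(colSums((t(xyz[rna, , drop = FALSE]) - xyz[w, ])^2))
      rc <- rna[dr <= dist_cutoff]
      if (length(rc) == 0L) next
      frame_keys <- c(frame_keys,
                      if (by == "pair") as.vector(outer(pc, rc, paste))
                      else paste0("w", w))
    }
    # a key is present at most once per frame, however many waters realize it
    for (k in unique(frame_keys)) counts[[k]] <- (counts[[k]] %||% 0L) + 1L
  }
  keys <- ls(counts)
  if (length(keys) == 0L) return(.empty_bridge_df())
  occ <- vapply(keys, function(k) counts[[k]], numeric(1)) / length(frames)
  keep <- occ >= min_occupancy
  keys <- keys[keep]
  occ <- occ[keep]
  if (length(keys) == 0L) return(.empty_bridge_df())
  if (by == "pair") {
    parts <- do.call(rbind, strsplit(keys, " "))
    p <- as.integer(parts[, 1])
    r <- as.integer(parts[, 2])
    species <- rep("water site", length(keys))
  } else {
    w <- as.integer(sub("^w", "", keys))
    species <- vapply(w, function(i) .atom_label(at, i), character(1))
    p <- rep(NA_integer_, length(keys))
    r <- rep(NA_integer_, length(keys))
  }
  out <- data.frame(
    bridge_kind = "water",
    bridging_species = species,
    protein_partner = ifelse(is.na(p), NA_character_,
                             vapply(p, function(i) if (is.na(i)) NA_character_
                                    else .atom_label(at, i), character(1))),
    rna_partner = ifelse(is.na(r), NA_character_,
                         vapply(r, function(i) if (is.na(i)) NA_character_
                                else .atom_label(at, i), character(1))),
    occupancy = occ, stringsAsFactors = FALSE)
  out <- out[order(-out$occupancy), ]
  rownames(out) <- NULL
  class(out) <- c("bridge_records", "data.frame")
  out
}

.empty_bridge_df <- function() {
  out <- data.frame(bridge_kind = character(0), bridging_species = character(0),
                    protein_partner = character(0), rna_partner = character(0),
                    occupancy = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("bridge_records", "data.frame")
  out
}

#' Detect metal-ion protein-RNA bridges
#'
#' Per frame, an ion bridges when it lies within its element's distance
#' cutoff of at least one protein N/O atom and one RNA N/O atom
#' simultaneously. Records are aggregated per (ion, protein atom, RNA atom)
#' triple; the attribute `"coordination"` carries per-partner coordination
#' occupancies and `"ion_occupancy"` the any-partner bridge occupancy per ion.
#'
#' @param ens An [ensemble()].
#' @param frames Frame indices (default: final quarter).
#' @param cutoffs Named per-element coordination cutoffs in Angstrom
#'   (defaults: Mg 3.0, K 3.5). Every ion element present must have one.
#' @param min_occupancy Minimum reported occupancy.
#' @return `data.frame` of class `bridge_records` (`bridge_kind` = `ion`).
#' @export
detect_ion_bridges <- function(ens, frames = NULL,
                               cutoffs = c(MG = 3.0, K = 3.5),
                               min_occupancy = 0.10) {
  stopifnot(inherits(ens, "ensemble"))
  frames <- .resolve_frames(ens, frames)
  at <- ens$atoms
  names(cutoffs) <- toupper(names(cutoffs))
  ions <- which(at$class == "ion")
  if (length(ions) == 0L) return(.empty_bridge_df())
  elems <- toupper(at$element[ions])
  unknown <- setdiff(unique(elems), names(cutoffs))
  if (length(unknown) > 0L) {
    stop("no coordination cutoff defined for ion element(s): ",
         paste(unknown, collapse = ", "))
  }
  prot <- which(at$class == "protein" & toupper(at$element) %in% c("N", "O"))
  rna <- which(at$class == "rna" & toupper(at$element) %in% c("N", "O"))
  triple_count <- list()
  ion_count <- stats::setNames(numeric(length(ions)), as.character(ions))
  coord_count <- list()
  for (f in frames) {
    xyz <- ens$coords[, , f]
    for (k in seq_along(ions)) {
      ion <- ions[k]
      cut <- cutoffs[[elems[k]]]
      dp <- sqrt(colSums((t(xyz[prot, , drop = FALSE]) - xyz[ion, ])^2))
      pc <- prot[dp <= cut]
      dr <- sqrt(colSums((t(xyz[rna, , drop = FALSE]) - xyz[ion, ])^2))
      rc <- rna[dr <= cut]
      for (p in c(pc, rc)) {
        ck <- paste(ion, p)
        coord_count[[ck]] <- (coord_count[[ck]] %||% 0) + 1
      }
      if (length(pc) == 0L || length(rc) == 0L) next
      ion_count[as.character(ion)] <- ion_count[as.character(ion)] + 1
      for (p in pc) for (r in rc) {
        tk <- paste(ion, p, r)
        triple_count[[tk]] <- (triple_count[[tk]] %||% 0) + 1
      }
    }
  }
  nf <- length(frames)
  keys <- names(triple_count)
  occ <- vapply(triple_count, identity, numeric(1)) / nf
  keep <- occ >= min_occupancy
  keys <- keys[keep]
  occ <- unname(occ[keep])
  if (length(keys) == 0L) {
    out <- .empty_bridge_df()
  } else {
    parts <- do.call(rbind, strsplit(keys, " "))
    ion <- as.integer(parts[, 1])
    p <- as.integer(parts[, 2])
    r <- as.integer(parts[, 3])
    out <- data.frame(
      bridge_kind = "ion",
      bridging_species = vapply(ion, function(i) .atom_label(at, i), character(1)),
      protein_partner = vapply(p, function(i) .atom_label(at, i), character(1)),
      rna_partner = vapply(r, function(i) .atom_label(at, i), character(1)),
      occupancy = occ, stringsAsFactors = FALSE)
    out <- out[order(-out$occupancy), ]
    rownames(out) <- NULL
    class(out) <- c("bridge_records", "data.frame")
  }
  if (length(coord_count) > 0L) {
    ck <- do.call(rbind, strsplit(names(coord_count), " "))
    attr(out, "coordination") <- data.frame(
      ion = vapply(as.integer(ck[, 1]), function(i) .atom_label(at, i), character(1)),
      partner = vapply(as.integer(ck[, 2]), function(i) .atom_label(at, i), character(1)),
      partner_class = at$class[as.integer(ck[, 2])],
      occupancy = unname(vapply(coord_count, identity, numeric(1))) / nf,
      stringsAsFactors = FALSE)
  }
  attr(out, "ion_occupancy") <- stats::setNames(
    unname(ion_count) / nf,
    vapply(ions, function(i) .atom_label(at, i), character(1)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select atom indices of an ensemble
#'
#' @param ens An [ensemble()].
#' @param class,element,name Optional filters (vectors, ANDed together).
#' @return Integer atom indices.
#' @export
select_atoms <- function(ens, class = NULL, element = NULL, name = NULL) {
  at <- ens$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(class)) keep <- keep & at$class %in% class
  if (!is.null(element)) keep <- keep & toupper(at$element) %in% toupper(element)
  if (!is.null(name)) keep <- keep & at$name %in% name
  which(keep)
}

#' Volumetric per-frame occupancy grid
#'
#' Voxelizes the selected atoms over the analyzed frames: each voxel's value
#' is the fraction of frames in which at least one selected atom falls inside
#' it. Frames should be superposed beforehand (see [superpose_rmsd()]) so the
#' grid reports conserved sites rather than rigid-body drift.
#'
#' @param ens An [ensemble()].
#' @param frames Frame indices (default: final quarter).
#' @param species Atom selection: integer indices, or a shorthand string
#'   (`"water"` = water oxygens, `"ion"` = all ions, `"ion:MG"` /
#'   `"ion:K"` = one element).
#' @param voxel_size Voxel edge length, Angstrom.
#' @param padding Extra margin around the selected atoms' bounding box, A.
#' @return List of class `occupancy_grid`: `origin`, `voxel_size`, `dims`,
#'   `values` (3D array of per-voxel occupancies in `[0, 1]`).
#' @export
occupancy_grid <- function(ens, frames = NULL, species = "water",
                           voxel_size = 1.0, padding = 1.0) {
  stopifnot(inherits(ens, "ensemble"), voxel_size > 0)
  frames <- .resolve_frames(ens, frames)
  if (is.character(species)) {
    sel <- if (species == "water") {
      select_atoms(ens, class = "water", name = .WATER_O)
    } else if (species == "ion") {
      select_atoms(ens, class = "ion")
    } else if (grepl("^ion:", species)) {
      select_atoms(ens, class = "ion", element = sub("^ion:", "", species))
    } else {
      stop("unknown species shorthand: ", species)
    }
  } else {
    sel <- as.integer(species)
  }
  if (length(sel) == 0L) stop("empty atom selection for occupancy grid")
  sub <- ens$coords[sel, , frames, drop = FALSE]
  lo <- apply(sub, 2, min) - padding
  hi <- apply(sub, 2, max) + padding
  origin <- floor(lo / voxel_size) * voxel_size
  dims <- pmax(1L, as.integer(ceiling((hi - origin) / voxel_size)))
  counts <- array(0L, dim = dims)
  for (fi in seq_along(frames)) {
    xyz <- matrix(sub[, , fi], ncol = 3L)
    vox <- floor(sweep(xyz, 2, origin) / voxel_size) + 1L
    vox <- pmin(pmax(vox, 1L), matrix(dims, nrow(vox), 3L, byrow = TRUE))
    vox <- unique(vox)
    counts[vox] <- counts[vox] + 1L
  }
  structure(list(origin = origin, voxel_size = voxel_size, dims = dims,
                 values = counts / length(frames),
                 n_frames = length(frames)),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("<occupancy grid %dx%dx%d, voxel %g A, max occupancy %.2f>\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size, max(x$values)))
  invisible(x)
}

#' Write an occupancy grid in OpenDX format
#'
#' The standard format consumed by molecular-graphics isosurface renderers
#' (conserved water sites are typically contoured at 0.25 occupancy, ion
#' sites at 0.2).
#'
#' @param grid An [occupancy_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$voxel_size),
    sprintf("delta 0 %g 0", grid$voxel_size),
    sprintf("delta 0 0 %g", grid$voxel_size),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX data order: z varies fastest, then y, then x
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))
  grp <- ceiling(seq_along(vals) / 3)
  lines <- vapply(split(vals, grp), paste, character(1), collapse = " ")
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

# ---- superposition & RMSD ---------------------------------------------------

# Kabsch: rotation R minimizing ||P %*% R - Q|| for centered row-vector
# coordinate matrices (both n x 3), with reflection guard
.kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Superpose frames and compute backbone RMSD over secondary structure
#'
#' For each frame, the protein backbone atoms (N, CA, C, O) of the residues
#' in `ss` are rigid-body superposed onto the reference by Kabsch's method
#' and the RMSD over those same atoms is recorded.
#'
#' @param ens An [ensemble()].
#' @param reference Reference frame index (default 1) or a single-frame
#'   [ensemble()] with matching backbone atoms.
#' @param ss An [ss_elements()] annotation; `NULL` uses every protein residue.
#' @param frames Frame indices to analyze (default: all frames).
#' @return List of class `rmsd_result` with `per_frame` (A), `mean` (A), and
#'   `n_atoms` used.
#' @export
superpose_rmsd <- function(ens, reference = 1L, ss = NULL, frames = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  frames <- .resolve_frames(ens, frames)
  at <- ens$atoms
  bb <- at$class == "protein" & at$name %in% c("N", "CA", "C", "O")
  if (!is.null(ss)) bb <- bb & .ss_mask(at, ss)
  sel <- which(bb)
  if (length(sel) < 3L) stop("need at least 3 backbone atoms for superposition")
  if (inherits(reference, "ensemble")) {
    rat <- reference$atoms
    key <- function(a, i) paste(a$chain[i], a$resno[i], a$name[i])
    ridx <- match(key(at, sel), key(rat, seq_len(nrow(rat))))
    if (anyNA(ridx)) {
      stop("reference lacks backbone atom(s): ",
           paste(utils::head(key(at, sel)[is.na(ridx)], 5), collapse = ", "))
    }
    ref_xyz <- reference$coords[ridx, , 1L]
  } else {
    ref_xyz <- ens$coords[sel, , as.integer(reference)]
  }
  ref_c <- colMeans(ref_xyz)
  Q <- sweep(ref_xyz, 2, ref_c)
  per <- vapply(frames, function(f) {
    P <- ens$coords[sel, , f]
    pc <- colMeans(P)
    P <- sweep(P, 2, pc)
    R <- .kabsch_rotation(P, Q)
    fitP <- P %*% R
    sqrt(mean(rowSums((fitP - Q)^2)))
  }, numeric(1))
  structure(list(per_frame = per, mean = mean(per), n_atoms = length(sel),
                 frames = frames),
            class = "rmsd_result")
}

#' @export
print.rmsd_result <- function(x, ...) {
  cat(sprintf("<RMSD over %d backbone atoms, %d frames: mean %.3f A>\n",
              x$n_atoms, length(x$per_frame), x$mean))
  invisible(x)
}

#' Superpose every frame of an ensemble onto a reference frame
#'
#' Returns a new ensemble in which each frame has been rigid-body fitted
#' (on the chosen atoms) to the reference; useful before [occupancy_grid()].
#'
#' @param ens An [ensemble()].
#' @param reference Reference frame index.
#' @param fit_atoms Atom indices to fit on; default all protein backbone.
#' @return A superposed [ensemble()].
#' @export
superpose_ensemble <- function(ens, reference = 1L, fit_atoms = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  if (is.null(fit_atoms)) {
    fit_atoms <- which(ens$atoms$class == "protein" &
                         ens$atoms$name %in% c("N", "CA", "C", "O"))
  }
  ref <- ens$coords[fit_atoms, , reference]
  ref_c <- colMeans(ref)
  Q <- sweep(ref, 2, ref_c)
  out <- ens$coords
  for (f in seq_len(n_frames(ens))) {
    P <- ens$coords[fit_atoms, , f]
    pc <- colMeans(P)
    R <- .kabsch_rotation(sweep(P, 2, pc), Q)
    moved <- sweep(ens$coords[, , f], 2, pc) %*% R
    out[, , f] <- sweep(moved, 2, -ref_c)
  }
  ensemble(ens$atoms, out, frame_spacing = ens$frame_spacing)
}
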