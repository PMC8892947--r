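# Synthetic-data generators with known ground truth: degenerate-library
# samples, multi-round selections under a retention-weight fitness model,
# and toy protein-RNA ensembles with planted interactions at set occupancies.
# All randomness flows from one explicit seed per generator call.

#' Sample DNA sequences from a degenerate library scheme
#'
#' Each position's codon is drawn uniformly from its degenerate expansion,
#' emulating mixed-base oligonucleotide synthesis.
#'
#' @param scheme A [library_scheme()].
#' @param n Number of molecules to draw.
#' @param seed RNG seed (deterministic output for a given seed).
#' @return List of `n` [nt_seq()] records of plain (expanded) DNA.
#' @export
sample_library <- function(scheme, n, seed = 1L) {
  stopifnot(inherits(scheme, "library_scheme"), n >= 1L)
  set.seed(seed)
  expansions <- lapply(scheme$codons, expand_codon)
  draws <- vapply(expansions, function(ex) {
    ex[sample.int(length(ex), n, replace = TRUE)]
  }, character(n))
  if (n == 1L) draws <- matrix(draws, nrow = 1L)
  seqs <- apply(draws, 1, paste, collapse = "")
  lapply(seq_len(n), function(i) nt_seq(seqs[i], id = sprintf("lib_%06d", i)))
}

#' Specify a multi-round selection simulation
#'
#' @param scheme A [library_scheme()] defining the naive pool.
#' @param n_reads_per_round Reads sequenced per round.
#' @param n_rounds Number of selection rounds after the naive round.
#' @param fitness Named numeric vector: peptide motif (regular expression,
#'   so motifs can be anchored, e.g. `"^SD"`) -> relative retention weight
#'   (> 0). A peptide's weight is the product of the weights of every motif
#'   it matches (1 when none match).
#' @param flank5,flank3 Plain-DNA flanks added to emitted reads.
#' @param error_rate Optional per-base substitution error applied to emitted
#'   reads (PCR/sequencing noise); 0 disables.
#' @param seed RNG seed.
#' @return A list of class `selection_sim_spec`.
#' @export
selection_sim_spec <- function(scheme, n_reads_per_round = 10000L,
                               n_rounds = 5L, fitness = numeric(0),
                               flank5 = "GGATCC", flank3 = "GAATTC",
                               error_rate = 0, seed = 1L) {
  stopifnot(inherits(scheme, "library_scheme"), n_reads_per_round >= 1L,
            n_rounds >= 1L, all(fitness > 0), error_rate >= 0, error_rate < 1)
  structure(list(scheme = scheme, n_reads_per_round = as.integer(n_reads_per_round),
                 n_rounds = as.integer(n_rounds), fitness = fitness,
                 flank5 = flank5, flank3 = flank3,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "selection_sim_spec")
}

.peptide_weight <- function(peptides, fitness) {
  w <- rep(1, length(peptides))
  for (m in names(fitness)) {
    w <- w * ifelse(grepl(m, peptides), fitness[[m]], 1)
  }
  w
}

#' Simulate multi-round affinity selection
#'
#' Round 0 is a multinomial sample of the naive library (peptides translated
#' from [sample_library()] draws). Each subsequent round resamples peptides
#' with probability proportional to (previous-round frequency x retention
#' weight) — frequency-proportional multinomial selection with static
#' weights. Reads are emitted as flanked DNA so the counting stage can be
#' exercised end-to-end.
#'
#' @param spec A [selection_sim_spec()].
#' @return List with `rounds` (list of [selection_round()], round 0 first),
#'   `reads` (per-round lists of [nt_seq()] flanked reads), and `truth`
#'   (data.frame of per-round true sampling frequencies per peptide).
#' @export
simulate_selection <- function(spec) {
  stopifnot(inherits(spec, "selection_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_reads_per_round
  # naive pool: sample DNA molecules, translate, keep stop-free peptides
  dna <- sample_library(spec$scheme, n, seed = spec$seed + 1L)
  dna_str <- vapply(dna, `[[`, character(1), "residues")
  peps <- vapply(dna_str, function(s) translate_dna(nt_seq(s))$residues,
                 character(1), USE.NAMES = FALSE)
  ok <- !grepl("\\*", peps)
  peps <- peps[ok]
  dna_str <- dna_str[ok]
  # representative coding sequence per peptide (for read emission)
  coding <- tapply(dna_str, peps, `[`, 1L)
  freq <- table(peps) / length(peps)
  pool <- names(freq)
  weights <- .peptide_weight(pool, spec$fitness)
  rounds <- vector("list", spec$n_rounds + 1L)
  reads <- vector("list", spec$n_rounds + 1L)
  truth <- vector("list", spec$n_rounds + 1L)
  cur <- as.numeric(freq)
  for (r in 0:spec$n_rounds) {
    if (r > 0L) {
      p <- cur * weights
      cur <- p / sum(p)
    }
    counts <- stats::rmultinom(1L, n, cur)[, 1L]
    keep <- counts > 0L
    rounds[[r + 1L]] <- selection_round(
      stats::setNames(as.integer(counts[keep]), pool[keep]), round_id = r)
    reads[[r + 1L]] <- .emit_reads(pool[keep], counts[keep], coding,
                                   spec$flank5, spec$flank3, spec$error_rate)
    truth[[r + 1L]] <- data.frame(round_id = r, peptide = pool,
                                  true_frequency = cur,
                                  stringsAsFactors = FALSE)
    cur <- counts / sum(counts)   # next round resamples the observed pool
  }
  list(rounds = rounds, reads = reads, truth = do.call(rbind, truth))
}

.emit_reads <- function(peptides, counts, coding, flank5, flank3, error_rate) {
  seqs <- rep(paste0(flank5, coding[peptides], flank3), counts)
  if (error_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(ch)) < error_rate)
      if (length(hit) > 0L) {
        ch[hit] <- vapply(ch[hit], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1))
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  lapply(seq_along(seqs), function(i) nt_seq(seqs[i], id = sprintf("read_%07d", i)))
}

#' Specify a toy ensemble with planted interface interactions
#'
#' @param n_frames Number of frames.
#' @param jitter_sd Gaussian positional jitter per coordinate, Angstrom.
#' @param hbonds,water_bridges,ion_bridges Target occupancies (each a numeric
#'   vector; one planted interaction per entry). Ion bridges alternate Mg and
#'   K sites.
#' @param seed RNG seed.
#' @return A list of class `planted_ensemble_spec`.
#' @export
planted_ensemble_spec <- function(n_frames = 1000L, jitter_sd = 0.02,
                                  hbonds = numeric(0),
                                  water_bridges = numeric(0),
                                  ion_bridges = numeric(0), seed = 1L) {
  occ <- c(hbonds, water_bridges, ion_bridges)
  stopifnot(n_frames >= 1L, jitter_sd >= 0,
            length(occ) == 0L || all(occ >= 0 & occ <= 1))
  structure(list(n_frames = as.integer(n_frames), jitter_sd = jitter_sd,
                 hbonds = hbonds, water_bridges = water_bridges,
                 ion_bridges = ion_bridges, seed = as.integer(seed)),
            class = "planted_ensemble_spec")
}

# A minimal serine residue (backbone + OG side chain): the OG is both a
# donor and an acceptor, so one residue template serves every planted
# protein-side contact. The side-chain OG sits at local (3.6, -1.3, 0) and
# every planted partner is placed along +x from it; the backbone O points
# away (+y) so it stays outside all cutoffs.
.ser_template <- function(resno, origin) {
  data.frame(name = c("N", "CA", "C", "O", "CB", "OG"),
             element = c("N", "C", "C", "O", "C", "O"),
             resname = "SER", resno = resno, chain = "A",
             x = origin[1] + c(0, 1.5, 2.3, 2.9, 2.2, 3.6),
             y = origin[2] + c(0, 0, 1.2, 2.3, -1.3, -1.3),
             z = origin[3],
             stringsAsFactors = FALSE)
}

# A minimal uridine fragment: phosphate (acceptors) + ribose O2'. OP1 points
# along local -x, toward the planted contact.
.u_template <- function(resno, origin) {
  data.frame(name = c("P", "OP1", "OP2", "O5'", "C5'", "O2'"),
             element = c("P", "O", "O", "O", "C", "O"),
             resname = "U", resno = resno, chain = "C",
             x = origin[1] + c(0, -1.3, 0.6, 0.6, 2.0, 3.0),
             y = origin[2] + c(0, 0, 1.4, -1.4, -1.6, 0.5),
             z = origin[3],
             stringsAsFactors = FALSE)
}

#' Build a toy protein-RNA ensemble with planted interactions
#'
#' Constructs a small serine-rich protein chain (A), a uridine RNA chain (C),
#' plus one water (and one ion) per planted bridge, on a wide lattice so that
#' only the planted contacts can satisfy the detection criteria. For each
#' planted interaction an independent Bernoulli(target occupancy) mask over
#' frames decides, per frame, whether the mobile partner sits at bonded
#' geometry (2.7 A pair distance; 2.2 A for ion coordination) or is displaced
#' well beyond every cutoff (by 6 A). Gaussian jitter is added to every
#' coordinate. The realized per-interaction frame masks are returned so
#' detectors can be scored against exact ground truth.
#'
#' @param spec A [planted_ensemble_spec()].
#' @return List with `ensemble` (an [ensemble()]) and `truth` (data.frame:
#'   kind, partner labels, target and realized occupancy) plus `masks`
#'   (list of logical frame masks).
#' @export
build_planted_ensemble <- function(spec) {
  stopifnot(inherits(spec, "planted_ensemble_spec"))
  set.seed(spec$seed)
  n_hb <- length(spec$hbonds)
  n_wb <- length(spec$water_bridges)
  n_ib <- length(spec$ion_bridges)
  n_sites <- max(1L, n_hb + n_wb + n_ib)
  spacing <- 30                      # lattice pitch, A: isolates the sites
  atoms <- list()
  base_xyz <- list()
  site_info <- list()
  next_wat <- 1L
  next_ion <- 1L
  add_res <- function(df) {
    atoms[[length(atoms) + 1L]] <<- df[, 1:5]
    base_xyz[[length(base_xyz) + 1L]] <<- as.matrix(df[, c("x", "y", "z")])
  }
  kinds <- c(rep("hbond", n_hb), rep("water", n_wb), rep("ion", n_ib))
  occs <- c(spec$hbonds, spec$water_bridges, spec$ion_bridges)
  if (length(kinds) == 0L) {        # null spec: two far-apart residues
    add_res(.ser_template(1L, c(0, 0, 0)))
    add_res(.u_template(1L, c(spacing, 0, 0)))
  }
  for (s in seq_along(kinds)) {
    origin <- c((s - 1L) * spacing, 0, 0)
    prot <- .ser_template(s, origin)
    add_res(prot)
    og <- as.numeric(prot[prot$name == "OG", c("x", "y", "z")])
    kind <- kinds[s]
    if (kind == "hbond") {
      # RNA placed so its OP1 sits 2.7 A along +x from the serine OG
      rna <- .u_template(s, og + c(2.7 + 1.3, 0, 0))
      add_res(rna)
      site_info[[s]] <- list(kind = kind, mobile = length(atoms))
    } else if (kind == "water") {
      # water midway: 2.7 A to OG and 2.7 A to OP1; OG-OP1 distance 5.4 A
      # keeps the direct pair outside the H-bond cutoff
      rna <- .u_template(s, og + c(5.4 + 1.3, 0, 0))
      add_res(rna)
      wdf <- data.frame(name = "O", element = "O", resname = "HOH",
                        resno = 500L + next_wat, chain = "W",
                        x = og[1] + 2.7, y = og[2], z = og[3],
                        stringsAsFactors = FALSE)
      next_wat <- next_wat + 1L
      add_res(wdf)
      site_info[[s]] <- list(kind = kind, mobile = length(atoms))
    } else {
      # ion midway: 2.2 A to OG and 2.2 A to OP1; Mg and K sites alternate
      elem <- if (next_ion %% 2L == 1L) "MG" else "K"
      rna <- .u_template(s, og + c(4.4 + 1.3, 0, 0))
      add_res(rna)
      idf <- data.frame(name = elem, element = elem, resname = elem,
                        resno = 600L + next_ion, chain = "I",
                        x = og[1] + 2.2, y = og[2], z = og[3],
                        stringsAsFactors = FALSE)
      next_ion <- next_ion + 1L
      add_res(idf)
      site_info[[s]] <- list(kind = kind, mobile = length(atoms))
    }
  }
  atom_tab <- do.call(rbind, atoms)
  base <- do.call(rbind, base_xyz)
  # residue block offsets into the atom table
  block_rows <- cumsum(vapply(base_xyz, nrow, integer(1)))
  block_start <- c(1L, utils::head(block_rows, -1L) + 1L)
  # minimum inter-atom distance sanity check on the bonded template
  dmin <- min(stats::dist(base))
  if (dmin < 1.0) stop("planted geometry infeasible: atoms closer than 1 A")
  nf <- spec$n_frames
  coords <- array(NA_real_, dim = c(nrow(atom_tab), 3L, nf))
  masks <- lapply(occs, function(o) stats::runif(nf) < o)
  for (f in seq_len(nf)) {
    xyz <- base
    for (s in seq_along(site_info)) {
      if (!masks[[s]][f]) {
        blk <- site_info[[s]]$mobile
        rows <- block_start[blk]:block_rows[blk]
        # displace the mobile species (water/ion) or, for direct H-bonds,
        # the whole RNA residue, sideways far beyond every cutoff
        xyz[rows, 2] <- xyz[rows, 2] + 6
      }
    }
    if (spec$jitter_sd > 0) {
      xyz <- xyz + stats::rnorm(length(xyz), sd = spec$jitter_sd)
    }
    coords[, , f] <- xyz
  }
  ens <- ensemble(atom_tab, coords)
  truth <- if (length(kinds) == 0L) {
    data.frame(kind = character(0), target_occupancy = numeric(0),
               realized_occupancy = numeric(0))
  } else {
    data.frame(kind = kinds, target_occupancy = occs,
               realized_occupancy = vapply(masks, mean, numeric(1)),
               stringsAsFactors = FALSE)
  }
  list(ensemble = ens, truth = truth, masks = masks)
}
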