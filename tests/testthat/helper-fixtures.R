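# Shared fixtures: built in code at test time, no binary files.

# The ten "early" prebiotically plausible residues used as the default
# reduced design alphabet in tests.
EARLY_ALPHABET <- c("G", "A", "D", "E", "V", "S", "I", "L", "P", "T")

# A small acidic-motif library scheme (6 positions) used by the selection
# tests; relax = TRUE because not every pool has an exact degenerate cover.
toy_scheme <- function() {
  pools <- list(
    position_pool(1, "S", c("S", "A", "G", "T")),
    position_pool(2, "D", c("D", "E", "G")),
    position_pool(3, "E", c("E", "D", "V")),
    position_pool(4, "V", c("V", "I", "L", "A")),
    position_pool(5, "E", c("E", "D", "A")),
    position_pool(6, "V", c("V", "L", "G")))
  library_scheme(pools, name = "toy-acidic", alphabet = EARLY_ALPHABET,
                 relax = TRUE)
}

# Table-1-style rate constants with their measured concentration series
# (three 2-fold dilutions from the top of each published injection range).
KINETIC_CASES <- list(
  CL11   = list(k_on = 1.2e4, k_off = 3.0e-4, concs = c(525, 262.5, 131.25) * 1e-9),
  CL11_M = list(k_on = 1.9e4, k_off = 4.5e-4, concs = c(200, 100, 50) * 1e-9),
  CL11_E = list(k_on = 1.6e3, k_off = 3.6e-6, concs = c(11, 5.5, 2.75) * 1e-6))

simulate_case_curves <- function(case, R_max = 100, noise_sd = 0, seed = NULL,
                                 times = seq(0, 900, by = 1), t_switch = 300) {
  p <- kinetic_params(case$k_on, case$k_off, R_max)
  lapply(seq_along(case$concs), function(i) {
    simulate_sensorgram(p, case$concs[i], times, t_switch,
                        noise_sd = noise_sd,
                        seed = if (is.null(seed)) NULL else seed + i)
  })
}

# Round a fitted quantity to the displayed precision, first stripping
# optimizer-level floating-point noise (well below the fit tolerance).
signif_fitted <- function(x, digits = 2) signif(signif(x, 10), digits)

# ---- independent brute-force degenerate-codon oracle ------------------------
# A deliberately separate enumeration of all 15^3 IUPAC codons (expand.grid +
# per-codon translation), used only to cross-check design_codon.

.oracle_env <- new.env()

oracle_codon_table <- function() {
  if (!is.null(.oracle_env$tab)) return(.oracle_env$tab)
  syms <- names(Biostrings::IUPAC_CODE_MAP)
  grid <- expand.grid(s1 = syms, s2 = syms, s3 = syms,
                      stringsAsFactors = FALSE)
  codon <- paste0(grid$s1, grid$s2, grid$s3)
  species <- vector("list", nrow(grid))
  n_stop <- integer(nrow(grid))
  deg <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    bases <- expand.grid(
      b1 = strsplit(Biostrings::IUPAC_CODE_MAP[[grid$s1[i]]], "")[[1]],
      b2 = strsplit(Biostrings::IUPAC_CODE_MAP[[grid$s2[i]]], "")[[1]],
      b3 = strsplit(Biostrings::IUPAC_CODE_MAP[[grid$s3[i]]], "")[[1]],
      stringsAsFactors = FALSE)
    aa <- Biostrings::GENETIC_CODE[paste0(bases$b1, bases$b2, bases$b3)]
    species[[i]] <- sort(unique(aa[aa != "*"]))
    n_stop[i] <- sum(aa == "*")
    deg[i] <- length(aa)
  }
  .oracle_env$tab <- list(codon = codon, species = species,
                          n_stop = n_stop, deg = deg)
  .oracle_env$tab
}

# Returns the optimal codon string, or NA when no feasible codon exists.
oracle_design <- function(required, allow_offtarget = FALSE,
                          allow_stop = FALSE) {
  tab <- oracle_codon_table()
  n_off <- vapply(tab$species, function(sp) length(setdiff(sp, required)),
                  integer(1))
  covers <- vapply(tab$species, function(sp) all(required %in% sp), logical(1))
  ok <- covers &
    (allow_offtarget | n_off == 0L) &
    (allow_stop | tab$n_stop == 0L)
  if (!any(ok)) return(NA_character_)
  idx <- which(ok)
  idx <- idx[order(n_off[idx], tab$n_stop[idx], tab$deg[idx], tab$codon[idx])]
  tab$codon[idx[1L]]
}
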