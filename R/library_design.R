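# Reduced-alphabet combinatorial library design.
#
# A library scheme is an ordered list of per-position substitution pools, each
# encoded by one degenerate codon. Codon optimization is an exhaustive search
# over all 15^3 = 3,375 IUPAC codons: small enough to enumerate once, cache,
# and query exactly — no heuristics involved.

# Cache of the full degenerate-codon table (built on first use).
.codon_env <- new.env(parent = emptyenv())

# One row per degenerate codon: its IUPAC string, degeneracy, encoded
# amino-acid species, and stop-codon count.
degenerate_codon_table <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  codons <- as.vector(outer(outer(IUPAC_NT, IUPAC_NT, paste0), IUPAC_NT, paste0))
  codons <- sort(codons)
  tab <- lapply(codons, function(cd) {
    exp <- expand_codon(cd)
    aa <- Biostrings::GENETIC_CODE[exp]
    list(codon = cd, degeneracy = length(exp),
         species = sort(unique(aa[aa != "*"])),
         n_stop = sum(aa == "*"))
  })
  .codon_env$tab <- tab
  tab
}

#' Expected amino-acid frequencies of a degenerate codon
#'
#' Frequencies are expansion counts over the degeneracy, so they sum to 1
#' including the stop entry `*`.
#'
#' @param codon IUPAC codon string, e.g. `"GNK"`.
#' @return Named numeric vector of frequencies; residues in decreasing
#'   frequency, with a (possibly zero) `*` entry last.
#' @export
codon_profile <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[expand_codon(codon)]
  freq <- table(aa) / length(aa)
  res <- sort(freq[names(freq) != "*"], decreasing = TRUE)
  stop_f <- if ("*" %in% names(freq)) unname(freq[["*"]]) else 0
  c(stats::setNames(as.numeric(res), names(res)), "*" = stop_f)
}

#' Design the optimal degenerate codon for an amino-acid set
#'
#' Exhaustive search over all 3,375 IUPAC degenerate codons. A codon is
#' feasible when its expansion encodes every required residue, encodes no
#' off-target residue unless `allow_offtarget`, and contains no stop codon
#' unless `allow_stop`. Among feasible codons the optimum minimizes, in
#' priority order: number of off-target amino-acid species, number of stop
#' codons in the expansion, degeneracy, and finally the IUPAC string
#' lexicographically (which makes the result deterministic).
#'
#' @param required Character vector of required one-letter amino-acid codes.
#' @param allow_offtarget Permit encoded residues outside `required`.
#' @param allow_stop Permit stop codons in the expansion.
#' @param relax If no exact cover exists and `allow_offtarget` is `FALSE`,
#'   rerun with off-target residues permitted instead of erroring.
#' @return A list of class `degenerate_codon` with elements `codon`,
#'   `expansion`, `encoded` (amino-acid multiset over the expansion),
#'   `degeneracy`, `off_target`, `n_stop`.
#' @export
design_codon <- function(required, allow_offtarget = FALSE, allow_stop = FALSE,
                         relax = FALSE) {
  required <- unique(toupper(required))
  if (length(required) == 0L) stop("required amino-acid set is empty")
  if (!all(required %in% AA_ALPHABET)) {
    stop("unknown amino-acid code(s): ",
         paste(setdiff(required, AA_ALPHABET), collapse = ", "))
  }
  tab <- degenerate_codon_table()
  best <- NULL
  best_key <- NULL
  near <- NULL       # best infeasible codon by coverage, for the error message
  near_key <- NULL
  for (cd in tab) {
    n_missing <- sum(!required %in% cd$species)
    n_off <- length(setdiff(cd$species, required))
    feasible <- n_missing == 0L &&
      (allow_offtarget || n_off == 0L) &&
      (allow_stop || cd$n_stop == 0L)
    if (feasible) {
      key <- c(n_off, cd$n_stop, cd$degeneracy)
      if (is.null(best) || .lex_lt(key, best_key)) {
        best <- cd
        best_key <- key
      }
    } else if (cd$n_stop == 0L || allow_stop) {
      key <- c(n_missing, n_off, cd$n_stop, cd$degeneracy)
      if (is.null(near) || .lex_lt(key, near_key)) {
        near <- cd
        near_key <- key
      }
    }
  }
  if (is.null(best)) {
    if (relax && !allow_offtarget) {
      return(design_codon(required, allow_offtarget = TRUE,
                          allow_stop = allow_stop, relax = FALSE))
    }
    stop(sprintf(
      "no exact degenerate codon encodes {%s}; best near-miss %s encodes {%s}",
      paste(sort(required), collapse = ","), near$codon,
      paste(near$species, collapse = ",")))
  }
  exp <- expand_codon(best$codon)
  structure(list(codon = best$codon, expansion = exp,
                 encoded = Biostrings::GENETIC_CODE[exp],
                 degeneracy = best$degeneracy,
                 off_target = setdiff(best$species, required),
                 n_stop = best$n_stop),
            class = "degenerate_codon")
}

# Strict lexicographic "<" on equal-length integer keys. Tied keys return
# FALSE, so the first codon encountered in sorted IUPAC order wins ties.
.lex_lt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.degenerate_codon <- function(x, ...) {
  cat(sprintf("<degenerate codon %s: %d expansions, encodes {%s}%s>\n",
              x$codon, x$degeneracy,
              paste(sort(unique(x$encoded[x$encoded != "*"])), collapse = ","),
              if (x$n_stop > 0) sprintf(", %d stop(s)", x$n_stop) else ""))
  invisible(x)
}

#' Construct a per-position substitution pool
#'
#' @param position 1-based position in the wild-type protein.
#' @param wild_type Wild-type residue at this position.
#' @param allowed Character vector of permitted residues.
#' @param fixed `TRUE` for a non-randomized (single-residue) position.
#' @return A list of class `position_pool`.
#' @export
position_pool <- function(position, wild_type, allowed, fixed = length(allowed) == 1L) {
  allowed <- sort(unique(toupper(allowed)))
  if (length(allowed) == 0L) stop("allowed set must be nonempty")
  if (fixed && length(allowed) != 1L) stop("a fixed pool holds exactly one residue")
  structure(list(position = as.integer(position),
                 wild_type = toupper(wild_type),
                 allowed = allowed, fixed = isTRUE(fixed)),
            class = "position_pool")
}

#' Derive substitution pools from a family alignment
#'
#' Per alignment column, the pool is the set of residues whose column
#' frequency (over non-gap characters) reaches `min_column_freq`, intersected
#' with the design alphabet. When that intersection is empty the position is
#' fixed at the alphabet member closest to the wild-type residue under
#' `score_table` (higher score = closer; ties resolved alphabetically).
#'
#' @param wild_type [aa_seq()] or character scalar.
#' @param alignment List of [aa_seq()] (or character) sequences, pre-aligned
#'   to the wild-type length with `-` gaps.
#' @param alphabet Design alphabet (character vector of residues).
#' @param min_column_freq Column-frequency threshold in `[0, 1]`.
#' @param score_table 20x20 substitution score matrix with residue dimnames;
#'   defaults to BLOSUM62.
#' @return List of [position_pool()]s, one per position.
#' @export
pools_from_alignment <- function(wild_type, alignment, alphabet,
                                 min_column_freq = 0.1, score_table = NULL) {
  if (is.character(wild_type)) wild_type <- aa_seq(wild_type)
  wt <- strsplit(wild_type$residues, "")[[1]]
  alphabet <- sort(unique(toupper(alphabet)))
  if (min_column_freq < 0 || min_column_freq > 1) {
    stop("min_column_freq must lie in [0, 1]")
  }
  if (is.null(score_table)) score_table <- .blosum62()
  aln <- lapply(alignment, function(s) {
    if (is.character(s)) s <- aa_seq(s)
    r <- strsplit(s$residues, "")[[1]]
    if (length(r) != length(wt)) {
      stop("alignment sequence length differs from wild-type length")
    }
    r
  })
  if (length(aln) == 0L) {
    warning("empty alignment: every pool fixed at the wild-type residue")
    return(lapply(seq_along(wt), function(i) {
      position_pool(i, wt[i], wt[i], fixed = TRUE)
    }))
  }
  mat <- do.call(rbind, aln)
  lapply(seq_along(wt), function(i) {
    col <- mat[, i]
    col <- col[col != "-"]
    freq <- table(col) / length(col)
    passing <- names(freq)[freq >= min_column_freq]
    allowed <- intersect(passing, alphabet)
    if (length(allowed) == 0L) {
      scores <- score_table[wt[i], alphabet]
      pick <- sort(alphabet[scores == max(scores)])[1L]
      position_pool(i, wt[i], pick, fixed = TRUE)
    } else {
      position_pool(i, wt[i], allowed, fixed = length(allowed) == 1L)
    }
  })
}

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
}

#' Assemble a library scheme from pools
#'
#' @param pools List of [position_pool()]s, in sequence order.
#' @param codons Optional character vector of IUPAC codons, one per pool;
#'   designed with [design_codon()] (exact cover, no stops) when `NULL`.
#' @param name Scheme name.
#' @param alphabet Design alphabet the pools were drawn from.
#' @param relax Passed to [design_codon()] when codons are auto-designed.
#' @return A list of class `library_scheme`.
#' @export
library_scheme <- function(pools, codons = NULL, name = "scheme",
                           alphabet = AA_ALPHABET, relax = FALSE) {
  stopifnot(all(vapply(pools, inherits, logical(1), "position_pool")))
  if (is.null(codons)) {
    codons <- vapply(pools, function(p) {
      design_codon(p$allowed, relax = relax)$codon
    }, character(1))
  }
  if (length(codons) != length(pools)) {
    stop("need exactly one codon per pool")
  }
  for (i in seq_along(pools)) {
    enc <- unique(Biostrings::GENETIC_CODE[expand_codon(codons[i])])
    if (!all(pools[[i]]$allowed %in% enc)) {
      stop(sprintf("codon %s at position %d does not cover its pool {%s}",
                   codons[i], pools[[i]]$position,
                   paste(pools[[i]]$allowed, collapse = ",")))
    }
  }
  structure(list(name = name, pools = pools, codons = codons,
                 alphabet = sort(unique(toupper(alphabet)))),
            class = "library_scheme")
}

#' @export
print.library_scheme <- function(x, ...) {
  d <- library_diversity(x)
  cat(sprintf("<library scheme '%s': %d positions (%d randomized)>\n",
              x$name, length(x$pools),
              sum(!vapply(x$pools, `[[`, logical(1), "fixed"))))
  cat(sprintf("  protein variants %.3g, DNA variants %.3g\n",
              d$protein_variants, d$dna_variants))
  invisible(x)
}

#' Exact diversity accounting for a library scheme
#'
#' @param scheme A [library_scheme()].
#' @return List with `protein_variants` (product over pools of the number of
#'   distinct encoded residues within the pool), `dna_variants` (product of
#'   codon degeneracies), and `randomized_fraction` (share of non-fixed
#'   positions). Products are returned as doubles: combinatorial libraries
#'   routinely exceed integer range.
#' @export
library_diversity <- function(scheme) {
  stopifnot(inherits(scheme, "library_scheme"))
  per_pos <- vapply(seq_along(scheme$pools), function(i) {
    enc <- unique(Biostrings::GENETIC_CODE[expand_codon(scheme$codons[i])])
    length(intersect(enc, scheme$pools[[i]]$allowed))
  }, numeric(1))
  deg <- vapply(scheme$codons, function(cd) length(expand_codon(cd)), numeric(1))
  fixed <- vapply(scheme$pools, `[[`, logical(1), "fixed")
  list(protein_variants = prod(per_pos),
       dna_variants = prod(deg),
       randomized_fraction = sum(!fixed) / length(fixed))
}

#' Write a library scheme to JSON
#' @param scheme A [library_scheme()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  obj <- list(name = scheme$name, alphabet = scheme$alphabet,
              positions = lapply(seq_along(scheme$pools), function(i) {
                p <- scheme$pools[[i]]
                list(position = p$position, wild_type = p$wild_type,
                     allowed = p$allowed, fixed = p$fixed,
                     codon = scheme$codons[i])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a library scheme from JSON
#' @param path JSON path written by [write_scheme()].
#' @return A [library_scheme()].
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pools <- lapply(obj$positions, function(p) {
    position_pool(p$position, p$wild_type, unlist(p$allowed), isTRUE(p$fixed))
  })
  codons <- vapply(obj$positions, function(p) p$codon, character(1))
  library_scheme(pools, codons, name = obj$name, alphabet = unlist(obj$alphabet))
}
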