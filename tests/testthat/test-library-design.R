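test_that("worked degenerate-codon designs match the brute-force optimum", {
  # {D,E}: GAT = Asp, GAG = Glu; degeneracy 2; GAK wins the lexicographic tie
  d <- design_codon(c("D", "E"))
  expect_equal(d$codon, "GAK")
  expect_equal(d$degeneracy, 2L)
  expect_equal(oracle_design(c("D", "E")), "GAK")
  # {A,D,E,G,V}: minimal-degeneracy exact cover, first among GNK/GNM/GNS/GNW
  d <- design_codon(c("A", "D", "E", "G", "V"))
  expect_equal(d$codon, "GNK")
  expect_equal(d$degeneracy, 8L)
  expect_equal(oracle_design(c("A", "D", "E", "G", "V")), "GNK")
  # singleton required set: a plain codon
  expect_equal(design_codon("S")$codon, "AGC")
})

test_that("design_codon equals the independent oracle on random required sets", {
  set.seed(101)
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (i in 1:60) {
    req <- sample(aa20, sample(1:10, 1))
    expected <- oracle_design(req)
    if (is.na(expected)) {
      expect_error(design_codon(req), "no exact degenerate codon")
    } else {
      got <- design_codon(req)
      expect_equal(got$codon, expected)
      # exact covers encode the required set exactly (no stops, no extras)
      expect_setequal(unique(got$encoded), req)
      expect_equal(got$n_stop, 0L)
    }
  }
})

test_that("infeasible sets error with a near-miss unless relaxed", {
  expect_error(design_codon(c("A", "I", "L", "V")), "near-miss")
  relaxed <- design_codon(c("A", "I", "L", "V"), relax = TRUE)
  expect_true(all(c("A", "I", "L", "V") %in% relaxed$encoded))
  expect_gt(length(relaxed$off_target), 0L)
})

test_that("codon profiles are exact expansion frequencies summing to one", {
  expect_equal(codon_profile("GGN"), c(G = 1, "*" = 0))
  # GNK: 8 expansions, A/G/V twice each, D/E once each
  p <- codon_profile("GNK")
  expect_equal(p[c("A", "G", "V", "D", "E")],
               c(A = 0.25, G = 0.25, V = 0.25, D = 0.125, E = 0.125))
  expect_equal(sum(p), 1)
  # the full code: 64 expansions, 3 stops
  p <- codon_profile("NNN")
  expect_equal(unname(p["*"]), 3 / 64)
  expect_equal(sum(p), 1)
})

test_that("alignment columns map to pools by thresholded frequency and alphabet", {
  wt <- "GKD"
  aln <- c("GKD", "GKE", "GRD", "GSD", "GKE",
           "GKD", "GRE", "GSD", "GKD", "GKE")
  # col 1 unanimous G; col 2 K:6/10 R:2/10 S:2/10; col 3 D:6/10 E:4/10
  pools <- pools_from_alignment(wt, as.list(aln), alphabet = EARLY_ALPHABET,
                                min_column_freq = 0.1)
  expect_equal(pools[[1]]$allowed, "G")
  expect_true(pools[[1]]$fixed)
  # K and R are outside the early alphabet; only S survives
  expect_equal(pools[[2]]$allowed, "S")
  expect_equal(pools[[3]]$allowed, c("D", "E"))
  expect_false(pools[[3]]$fixed)
})

test_that("a column where nothing passes falls back to a fixed closest residue", {
  wt <- "K"
  aln <- list("K", "R")   # neither K nor R is in the early alphabet
  pools <- pools_from_alignment(wt, aln, alphabet = EARLY_ALPHABET,
                                min_column_freq = 0.1)
  expect_true(pools[[1]]$fixed)
  expect_length(pools[[1]]$allowed, 1L)
  expect_true(pools[[1]]$allowed %in% EARLY_ALPHABET)
  # threshold excluding every residue triggers the same fallback
  pools <- pools_from_alignment("D", list("D", "E"), alphabet = EARLY_ALPHABET,
                                min_column_freq = 0.6)
  expect_true(pools[[1]]$fixed)
})

test_that("alignment edge cases: length mismatch errors, empty alignment warns", {
  expect_error(pools_from_alignment("GKD", list("GK"), EARLY_ALPHABET),
               "length")
  expect_warning(
    pools <- pools_from_alignment("GAD", list(), EARLY_ALPHABET),
    "empty alignment")
  expect_true(all(vapply(pools, `[[`, logical(1), "fixed")))
  expect_equal(vapply(pools, `[[`, character(1), "allowed"),
               c("G", "A", "D"))
})

test_that("diversity accounting is an exact product and multiplicative", {
  pools <- list(position_pool(1, "A", c("A", "D", "E", "G")),
                position_pool(2, "G", "G"),
                position_pool(3, "V", c("D", "E", "V")))
  sch <- library_scheme(pools, name = "p413")
  d <- library_diversity(sch)
  expect_equal(d$protein_variants, 12)
  expect_equal(d$randomized_fraction, 2 / 3)
  # splitting the scheme multiplies: halves reproduce the whole
  left <- library_scheme(pools[1:2], sch$codons[1:2])
  right <- library_scheme(pools[3], sch$codons[3])
  expect_equal(library_diversity(left)$protein_variants *
                 library_diversity(right)$protein_variants,
               d$protein_variants)
  expect_equal(library_diversity(left)$dna_variants *
                 library_diversity(right)$dna_variants,
               d$dna_variants)
  # all-fixed scheme collapses to the wild type
  fixed <- library_scheme(list(position_pool(1, "G", "G"),
                               position_pool(2, "A", "A")))
  expect_equal(library_diversity(fixed)$protein_variants, 1)
  expect_equal(library_diversity(fixed)$randomized_fraction, 0)
})

test_that("library schemes round-trip through JSON", {
  sch <- toy_scheme()
  f <- withr::local_tempfile(fileext = ".json")
  write_scheme(sch, f)
  back <- read_scheme(f)
  expect_equal(back$codons, sch$codons)
  expect_equal(back$alphabet, sch$alphabet)
  expect_equal(lapply(back$pools, `[[`, "allowed"),
               lapply(sch$pools, `[[`, "allowed"))
})
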