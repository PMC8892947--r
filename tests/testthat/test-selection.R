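test_that("peptide counting excises flanked inserts and filters cleanly", {
  mk <- function(s, id) nt_seq(s, id = id)
  reads <- list(mk("GGATCCATGGCTGAATTC", "r1"),
                mk("GGATCCATGGCTGAATTC", "r2"),
                mk("TTTTGGATCCATGGCTGAATTCAA", "r3"),   # flanks internal
                mk("ATGGCTGAATTC", "r4"),               # missing flank5
                mk("GGATCCATGTAGGCTGAATTC", "r5"))      # internal stop
  tab <- count_peptides(reads, flank5 = "GGATCC", flank3 = "GAATTC")
  expect_equal(unname(tab$counts["MA"]), 3L)
  expect_equal(tab$total_reads, 3L)
  expect_equal(sum(tab$counts), tab$total_reads)
})

test_that("counting on no surviving reads warns and returns an empty table", {
  reads <- list(nt_seq("AAAAAAAA"))
  expect_warning(tab <- count_peptides(reads, "GGATCC", "GAATTC"),
                 "no read survived")
  expect_equal(tab$total_reads, 0L)
})

test_that("empirical peptide fractions track generating proportions", {
  # multinomial reads at known proportions; counting recovers them within 2%
  set.seed(77)
  props <- c(AAGG = 0.55, DDEE = 0.30, VVLL = 0.15)
  coding <- c(AAGG = "GCTGCTGGTGGT", DDEE = "GATGATGAAGAA",
              VVLL = "GTTGTTCTTCTT")
  n <- 10000L
  picks <- sample(names(props), n, replace = TRUE, prob = props)
  reads <- lapply(seq_len(n), function(i) {
    nt_seq(paste0("GGATCC", coding[picks[i]], "GAATTC"))
  })
  tab <- count_peptides(reads, "GGATCC", "GAATTC")
  got <- as.numeric(tab$counts[names(props)]) / tab$total_reads
  expect_true(all(abs(got - props) < 0.02))
})

test_that("abundance ranking orders by count with documented tie-break", {
  tab <- selection_round(c(P1 = 50L, P2 = 30L, P3 = 20L))
  top <- rank_abundance(tab, 1)
  expect_equal(top$peptide, "P1")
  expect_equal(top$fraction, 0.5)
  # ties break alphabetically
  tie <- rank_abundance(selection_round(c(AB = 5L, AA = 5L)), 1)
  expect_equal(tie$peptide, "AA")
  # fractions over all peptides sum to one
  full <- rank_abundance(tab, 10)
  expect_equal(sum(full$fraction), 1)
})

test_that("logo information content matches closed-form entropy", {
  # a single sequence has zero entropy: IC = log2(20) everywhere
  lg <- peptide_logo("SDEV")
  expect_equal(unname(lg$ic), rep(log2(20), 4), tolerance = 1e-12)
  # two sequences differing at one position: that column loses exactly 1 bit
  lg <- peptide_logo(c("SDEV", "SDAV"))
  expect_equal(unname(lg$ic[3]), log2(20) - 1, tolerance = 1e-12)
  expect_equal(unname(lg$ic[-3]), rep(log2(20), 3), tolerance = 1e-12)
  # uniform over all 20 residues: zero information
  lg <- peptide_logo(AA_ALPHABET)
  expect_equal(unname(lg$ic[1]), 0, tolerance = 1e-12)
  # PFM columns always sum to 1; letter heights are freq * IC
  expect_equal(unname(colSums(lg$pfm)), 1)
  expect_true(all(lg$logo >= 0))
  expect_true(all(colSums(lg$logo) <= log2(20) + 1e-9))
})

test_that("logos support count weighting and exclude ambiguous peptides", {
  lg <- peptide_logo(c("AD", "ED"), weights = c(3, 1))
  expect_equal(unname(lg$pfm["A", 1]), 0.75)
  lg <- peptide_logo(c("AD", "XD"))
  expect_equal(lg$support, 1L)
  expect_error(peptide_logo(c("AD", "ADE")), "equal length")
})

test_that("enrichment trajectories report fractions and round-over-round ratios", {
  rounds <- list(selection_round(c(AA = 10L, BB = 10L), 0),
                 selection_round(c(AA = 20L, BB = 20L), 1),
                 selection_round(c(AA = 30L, BB = 30L), 2))
  tr <- enrichment_trajectory(rounds, "AA")
  expect_equal(tr$fraction, rep(0.5, 3))
  expect_equal(tr$ratio, c(NA, 1, 1))
  # absent clone: all-zero fractions, ratios undefined
  tr <- enrichment_trajectory(rounds, "ZZ")
  expect_equal(tr$fraction, rep(0, 3))
  expect_true(all(is.na(tr$ratio)))
})

test_that("consensus calls modal residues above threshold, else x", {
  pfm <- matrix(0, nrow = length(AA_ALPHABET), ncol = 2,
                dimnames = list(AA_ALPHABET, NULL))
  pfm[c("E", "D"), 1] <- c(0.9, 0.1)
  pfm[c("E", "V", "D"), 2] <- c(0.4, 0.4, 0.2)
  expect_equal(consensus_sequence(pfm, 0.5), "Ex")
  # at-threshold modal ties resolve to the alphabetically smallest residue
  expect_equal(consensus_sequence(pfm, 0.4), "EE")
})

test_that("a planted acidic motif region fixes in a simulated selection", {
  # the strongly weighted EVEV region fixes by round 8; the weakly weighted
  # N-terminal region can transiently hitch-hike and is asserted only in
  # direction (full-consensus recovery is checked at larger scale elsewhere)
  sch <- toy_scheme()
  spec <- selection_sim_spec(sch, n_reads_per_round = 10000, n_rounds = 8,
                             fitness = c("^SD" = 3, "EVEV$" = 8), seed = 7)
  sim <- simulate_selection(spec)
  final <- sim$rounds[[length(sim$rounds)]]
  top <- rank_abundance(final, 100)
  consensus <- consensus_sequence(peptide_logo(top$peptide), 0.5)
  expect_equal(substr(consensus, 3, 6), "EVEV")
  # enrichment is in the planted direction for the winning clone
  tr <- enrichment_trajectory(sim$rounds, top$peptide[1])
  expect_gt(tr$fraction[nrow(tr)], tr$fraction[1])
  expect_match(top$peptide[1], "EVEV$")
})
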