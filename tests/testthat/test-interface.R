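# Small hand-built ensembles: one serine (donor OG) on chain A and one
# uridine phosphate (acceptor OP1) on chain C, with full control over the
# OG-OP1 distance per frame.
pair_ensemble <- function(distances, extra_atoms = NULL, extra_xyz = NULL) {
  at <- rbind(
    data.frame(name = c("N", "CA", "CB", "OG"), element = c("N", "C", "C", "O"),
               resname = "SER", resno = 1L, chain = "A"),
    data.frame(name = c("P", "OP1"), element = c("P", "O"),
               resname = "U", resno = 1L, chain = "C"))
  base <- rbind(c(-3, 0, 0), c(-1.5, 0, 0), c(-1.5, 1.4, 0), c(0, 0, 0),
                c(1.4, 0.6, 0), c(0, 0, 0))   # OP1 x set per frame
  if (!is.null(extra_atoms)) {
    at <- rbind(at, extra_atoms)
    base <- rbind(base, extra_xyz)
  }
  coords <- array(NA_real_, dim = c(nrow(at), 3, length(distances)))
  for (f in seq_along(distances)) {
    xyz <- base
    xyz[6, 1] <- distances[f]            # OG at origin; OP1 along +x
    xyz[5, 1] <- distances[f] + 1.4      # keep P bonded to OP1
    coords[, , f] <- xyz
  }
  ensemble(at, coords)
}

test_that("H-bond occupancy counts frames inside the distance criterion", {
  # always bonded at 2.8 A
  ens <- pair_ensemble(rep(2.8, 4))
  hb <- suppressWarnings(detect_hbonds(ens, frames = 1:4))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$occupancy, 1.0)
  expect_equal(hb$via, "side chain")
  expect_equal(hb$donor_side, "protein")
  # inside the cutoff in 3 of 4 frames
  ens <- pair_ensemble(c(2.8, 2.9, 2.7, 3.4))
  hb <- suppressWarnings(detect_hbonds(ens, frames = 1:4))
  expect_equal(hb$occupancy, 0.75)
  # outside the cutoff entirely: nothing reported
  ens <- pair_ensemble(rep(3.4, 4))
  hb <- suppressWarnings(detect_hbonds(ens, frames = 1:4))
  expect_equal(nrow(hb), 0L)
  # missing hydrogens are announced once
  expect_warning(detect_hbonds(pair_ensemble(2.8), frames = 1),
                 "angle criterion skipped")
})

test_that("the donor-H-acceptor angle criterion applies when hydrogens exist", {
  h_lin <- data.frame(name = "HG", element = "H", resname = "SER",
                      resno = 1L, chain = "A")
  # hydrogen on the O-O axis: angle 180 degrees, bond accepted
  ens <- pair_ensemble(2.8, extra_atoms = h_lin, extra_xyz = c(0.97, 0, 0))
  hb <- detect_hbonds(ens, frames = 1)
  expect_equal(nrow(hb), 1L)
  # hydrogen pointing away: angle ~35 degrees, bond rejected
  ens <- pair_ensemble(2.8, extra_atoms = h_lin, extra_xyz = c(-0.8, 0.55, 0))
  hb <- detect_hbonds(ens, frames = 1)
  expect_equal(nrow(hb), 0L)
})

test_that("backbone-mediated H-bonds are labelled via backbone", {
  at <- rbind(
    data.frame(name = c("CA", "O"), element = c("C", "O"),
               resname = "GLY", resno = 1L, chain = "A"),
    data.frame(name = c("C1'", "N3"), element = c("C", "N"),
               resname = "U", resno = 1L, chain = "C"))
  xyz <- rbind(c(-1.5, 0, 0), c(0, 0, 0), c(4.2, 0, 0), c(2.8, 0, 0))
  ens <- ensemble(at, xyz)
  hb <- suppressWarnings(detect_hbonds(ens, frames = 1))
  expect_equal(hb$via, "backbone")
  expect_equal(hb$donor_side, "rna")    # U N3 donates to the backbone O
})

test_that("water bridges require simultaneous two-sided contacts", {
  wat <- data.frame(name = "O", element = "O", resname = "HOH",
                    resno = 9L, chain = "W")
  # OG ... 2.7 ... water ... 2.7 ... OP1 (OG-OP1 = 5.4: no direct bond)
  ens <- pair_ensemble(5.4, extra_atoms = wat, extra_xyz = c(2.7, 0, 0))
  wb <- detect_water_bridges(ens, frames = 1)
  expect_equal(nrow(wb), 1L)
  expect_equal(wb$occupancy, 1.0)
  hb <- suppressWarnings(detect_hbonds(ens, frames = 1))
  expect_equal(nrow(hb), 0L)
  # water close to the protein only: no bridge
  ens <- pair_ensemble(9, extra_atoms = wat, extra_xyz = c(2.7, 0, 0))
  expect_equal(nrow(detect_water_bridges(ens, frames = 1)), 0L)
  # no waters at all warns
  expect_warning(detect_water_bridges(pair_ensemble(2.8), frames = 1),
                 "no water")
})

test_that("ion bridges respect per-element cutoffs", {
  k_ion <- data.frame(name = "K", element = "K", resname = "K",
                      resno = 11L, chain = "I")
  # K at 3.4 A from both partners
  ens <- pair_ensemble(6.8, extra_atoms = k_ion, extra_xyz = c(3.4, 0, 0))
  ib <- detect_ion_bridges(ens, frames = 1)
  expect_equal(nrow(ib), 1L)
  expect_equal(ib$occupancy, 1.0)
  ib <- detect_ion_bridges(ens, frames = 1, cutoffs = c(MG = 3.0, K = 3.0))
  expect_equal(nrow(ib), 0L)
  # an ion element without a cutoff is refused by name
  na_ion <- data.frame(name = "NA", element = "NA", resname = "NA",
                       resno = 12L, chain = "I")
  ens <- pair_ensemble(6.8, extra_atoms = na_ion, extra_xyz = c(3.4, 0, 0))
  expect_error(detect_ion_bridges(ens, frames = 1), "NA")
})

test_that("bridge records imply both component contacts in the same frame", {
  pe <- build_planted_ensemble(
    planted_ensemble_spec(n_frames = 50, jitter_sd = 0.02,
                          water_bridges = 0.5, ion_bridges = 0.5, seed = 21))
  ens <- pe$ensemble
  ib <- detect_ion_bridges(ens, frames = seq_len(50))
  coord <- attr(ib, "coordination")
  for (i in seq_len(nrow(ib))) {
    # each partner's one-sided coordination occupancy bounds the bridge
    occ_p <- coord$occupancy[coord$partner == ib$protein_partner[i]]
    occ_r <- coord$occupancy[coord$partner == ib$rna_partner[i]]
    expect_gte(min(occ_p, occ_r), ib$occupancy[i])
  }
})

test_that("occupancies are invariant to frame order and global rigid motion", {
  spec <- planted_ensemble_spec(n_frames = 60, jitter_sd = 0.02,
                                hbonds = 0.5, ion_bridges = 0.7, seed = 5)
  pe <- build_planted_ensemble(spec)
  ens <- pe$ensemble
  base_hb <- suppressWarnings(detect_hbonds(ens, frames = 1:60))
  # reorder frames
  perm <- sample(60)
  ens_perm <- ensemble(ens$atoms, ens$coords[, , perm])
  hb <- suppressWarnings(detect_hbonds(ens_perm, frames = 1:60))
  expect_equal(hb$occupancy, base_hb$occupancy)
  # rotate + translate every frame by the same rigid motion
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ens$coords
  for (f in 1:60) moved[, , f] <- ens$coords[, , f] %*% R + 5
  hb <- suppressWarnings(detect_hbonds(ensemble(ens$atoms, moved),
                                       frames = 1:60))
  expect_equal(hb$occupancy, base_hb$occupancy)
})

test_that("occupancy grids count voxel visits per frame", {
  at <- data.frame(name = "MG", element = "MG", resname = "MG",
                   resno = 1L, chain = "I")
  # stationary atom: its voxel reaches occupancy 1, everything else 0
  coords <- array(rep(c(0.5, 0.5, 0.5), 4), dim = c(1, 3, 4))
  g <- occupancy_grid(ensemble(at, coords), frames = 1:4, species = "ion",
                      voxel_size = 1)
  expect_equal(max(g$values), 1)
  expect_equal(sum(g$values > 0), 1L)
  # alternating between two voxels: both at 0.5
  coords[1, 1, c(2, 4)] <- 5.5
  g <- occupancy_grid(ensemble(at, coords), frames = 1:4, species = "ion",
                      voxel_size = 1)
  expect_equal(sort(g$values[g$values > 0]), c(0.5, 0.5))
  # counting identity: value * n_frames is integral, values within [0, 1]
  expect_true(all(abs(g$values * 4 - round(g$values * 4)) < 1e-12))
  expect_true(all(g$values >= 0 & g$values <= 1))
})

test_that("occupancy grids export readable OpenDX", {
  pe <- build_planted_ensemble(
    planted_ensemble_spec(n_frames = 10, jitter_sd = 0.02,
                          ion_bridges = 0.6, seed = 2))
  g <- occupancy_grid(pe$ensemble, frames = 1:10, species = "ion",
                      voxel_size = 1)
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, f)
  txt <- readLines(f)
  expect_match(txt[1], "gridpositions counts")
  items <- as.integer(sub(".* items ([0-9]+) .*", "\\1", grep("items", txt, value = TRUE)))
  expect_equal(items, prod(g$dims))
})

test_that("superposed RMSD is zero for identity and pure rigid motion", {
  pe <- build_planted_ensemble(
    planted_ensemble_spec(n_frames = 1, jitter_sd = 0, hbonds = 1, seed = 4))
  ens1 <- pe$ensemble
  # duplicate the frame, then rigidly move the copy
  th <- 0.4
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  coords <- array(NA_real_, dim = c(nrow(ens1$atoms), 3, 3))
  coords[, , 1] <- ens1$coords[, , 1]
  coords[, , 2] <- ens1$coords[, , 1]
  coords[, , 3] <- ens1$coords[, , 1] %*% R + 7
  ens <- ensemble(ens1$atoms, coords)
  ss <- ss_elements("helix", "A", 1, 1)
  r <- superpose_rmsd(ens, reference = 1, ss = ss, frames = 1:3)
  expect_equal(r$per_frame, rep(0, 3), tolerance = 1e-10)
  expect_equal(r$mean, 0, tolerance = 1e-10)
})

test_that("Kabsch superposition matches the bio3d reference on a 12-atom toy", {
  set.seed(13)
  P <- matrix(rnorm(36, sd = 3), 12, 3)
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- P %*% R + matrix(rnorm(36, sd = 0.3), 12, 3)   # rotated + distorted
  at <- data.frame(name = rep(c("N", "CA", "C", "O"), 3), element = "C",
                   resname = "GLY", resno = rep(1:3, each = 4), chain = "A")
  at$element <- substr(at$name, 1, 1)
  coords <- array(NA_real_, dim = c(12, 3, 2))
  coords[, , 1] <- Q
  coords[, , 2] <- P
  ens <- ensemble(at, coords)
  mine <- superpose_rmsd(ens, reference = 1, frames = 2)$per_frame
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P)),
                           fixed.inds = 1:36, mobile.inds = 1:36)
  ref <- sqrt(mean(colSums(matrix((fitted - as.vector(t(Q)))^2, nrow = 3))))
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("RMSD against an external reference structure matches atom keys", {
  pe <- build_planted_ensemble(
    planted_ensemble_spec(n_frames = 2, jitter_sd = 0.1, hbonds = 1, seed = 6))
  ens <- pe$ensemble
  ref <- ensemble(ens$atoms, ens$coords[, , 1])
  r <- superpose_rmsd(ens, reference = ref)
  expect_equal(r$per_frame[1], 0, tolerance = 1e-10)
  # a reference lacking the backbone errors with the missing atoms listed
  bad <- ensemble(ens$atoms[ens$atoms$name != "CA", ],
                  ens$coords[ens$atoms$name != "CA", , 1])
  expect_error(superpose_rmsd(ens, reference = bad), "lacks backbone")
})

test_that("side-chain/backbone H-bond shares are tallied per residue", {
  rec <- suppressWarnings(detect_hbonds(pair_ensemble(rep(2.8, 2)),
                                        frames = 1:2))
  # synthesise a 7 side-chain / 3 backbone record set
  recs <- rec[rep(1, 10), ]
  recs$via <- c(rep("side chain", 7), rep("backbone", 3))
  s <- sidechain_backbone_summary(recs)
  expect_equal(s$sidechain_fraction, 0.7)
  expect_equal(unname(s$per_residue[1]), 10L)
  recs$via <- "backbone"
  expect_equal(sidechain_backbone_summary(recs)$sidechain_fraction, 0)
  expect_error(sidechain_backbone_summary(recs[0, ]), "no H-bond")
})
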