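test_that("Manders overlap has its defining fixed points", {
  v <- c(0.3, -1.2, 4, 0.01)
  expect_equal(moc(v, v), 1)
  expect_equal(moc(v, -v), -1)
  expect_equal(moc(c(1, 0), c(0, 1)), 0)
  expect_equal(moc(v, 3.7 * v), 1)            # positive-scale invariance
  expect_true(is.na(moc(c(0, 0), c(1, 2))))   # all-zero -> missing
  expect_error(moc(1:3, 1:2), class = "cryofit_invalid_parameter")
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(moc(a, b), brute_moc(a, b), tolerance = 1e-12)
    expect_gte(1, abs(moc(a, b)))
  }
})

test_that("segment footprints match brute-force lattice enumeration", {
  g <- density_grid(array(0, c(9, 9, 9)), 1, origin = c(-4, -4, -4))
  # single atom at a voxel centre, radius below half a voxel
  expect_equal(segment_voxels(g, c(0, 0, 0), radius = 0.4),
               brute_footprint(g, matrix(c(0, 0, 0), 1), 0.4))
  expect_length(segment_voxels(g, c(0, 0, 0), radius = 0.4), 1)
  # radius-3 sphere: count equals lattice points in the sphere
  fp3 <- segment_voxels(g, c(0, 0, 0), radius = 3)
  expect_equal(fp3, brute_footprint(g, matrix(c(0, 0, 0), 1), 3))
  expect_length(fp3,
    sum(outer(outer((-4:4)^2, (-4:4)^2, "+"), (-4:4)^2, "+") <= 9))
  # far-apart atoms: footprint sizes add
  xyz <- rbind(c(-3, -3, -3), c(3, 3, 3))
  both <- segment_voxels(g, xyz, radius = 1.2)
  expect_length(both, 2 * length(segment_voxels(g, c(3, 3, 3), 1.2)))
})

test_that("SMOC against a model's own simulated map is 1, negated is -1", {
  m <- make_polymer(25, "helix")
  prm <- sim_params(4, 1)
  emap <- simulate_density(m, prm)
  tr <- smoc(m, emap, window = 11, sim = prm)
  expect_true(all(abs(tr$value - 1) < 1e-6, na.rm = TRUE))
  neg <- emap; neg$data <- -neg$data
  trn <- smoc(m, neg, window = 11, sim = prm)
  expect_true(all(abs(trn$value + 1) < 1e-6, na.rm = TRUE))
})

test_that("SMOC matches a brute-force oracle on noisy toy cases", {
  withr::with_seed(21, {
    for (case in 1:10) {
      n_res <- sample(2:3, 1)
      m <- toy_model(resi = rep(seq_len(n_res), each = 2),
                     atom = rep(c("CA", "CB"), n_res),
                     x = runif(2 * n_res, -2, 2),
                     y = runif(2 * n_res, -2, 2),
                     z = runif(2 * n_res, -2, 2), element = "C")
      emap <- density_grid(array(rnorm(10^3), c(10, 10, 10)), 1,
                           origin = c(-5, -5, -5))
      prm <- sim_params(3, 1)
      tr <- smoc(m, emap, window = 3, sim = prm, radius = 1.4)
      simmap <- simulate_density(m, prm, onto = emap)
      expect_equal(tr$value, brute_smoc(m, emap, simmap, 3, 1.4),
                   tolerance = 1e-12)
    }
  })
})

test_that("windows truncate at termini and short chains are skipped", {
  m <- make_polymer(8, "helix")
  emap <- simulate_density(m, sim_params(4, 1))
  tr <- smoc(m, emap, window = 11, sim = sim_params(4, 1))
  expect_equal(nrow(tr), 8)                       # all residues scored
  expect_true(all(is.finite(tr$value)))
  short <- toy_model(resi = 1:3, atom = "CA", x = c(0, 3.8, 7.6),
                     y = 0, z = 0, element = "C")
  expect_warning(
    expect_error(smoc(short, emap, window = 11, sim = sim_params(4, 1)),
                 "no scorable"),
    "skipped")
  expect_error(smoc(m, emap, window = 10, sim = sim_params(4, 1)),
               class = "cryofit_invalid_parameter")
})

test_that("delta-SMOC of a model against itself is exactly zero", {
  m <- make_polymer(20, "helix")
  emap <- simulate_density(m, sim_params(4, 1))
  d <- delta_smoc(m, m, emap, window = 11, sim = sim_params(4, 1))
  expect_true(all(d$value == 0, na.rm = TRUE))
  expect_true(any(is.finite(d$value)))
})

test_that("delta-SMOC is invariant to a global rigid transform of the prediction", {
  m <- make_polymer(20, "helix")
  emap <- simulate_density(m, sim_params(4, 1))
  withr::with_seed(5, rot <- random_rotation())
  mp <- cryofit:::transform_model(m, rot, c(12, -20, 5))
  d <- delta_smoc(mp, m, emap, window = 11, sim = sim_params(4, 1))
  expect_lt(max(abs(d$value), na.rm = TRUE), 1e-6)
})

test_that("delta-SMOC negates when prediction and target swap roles", {
  # identical coordinates (footprints exactly shared) but one atom carries
  # a different element, so the simulated fragments genuinely differ
  m <- make_polymer(15, "helix")
  mp <- m
  mp$element[mp$resi == 8 & mp$atom == "CB"] <- "S"
  emap <- simulate_density(m, sim_params(4, 1))
  d1 <- delta_smoc(mp, m, emap, window = 5, sim = sim_params(4, 1))
  d2 <- delta_smoc(m, mp, emap, window = 5, sim = sim_params(4, 1))
  expect_gt(max(abs(d1$value), na.rm = TRUE), 1e-4)  # non-trivial scores
  expect_equal(d1$value, -d2$value, tolerance = 1e-12)
})

test_that("a shifted loop in the target is flagged positive by the pristine prediction", {
  m <- make_polymer(30, "helix")
  emap <- simulate_density(m, sim_params(4, 1))
  bad <- make_local_error(m, 13:17, "loop_shift", amplitude = 4, seed = 3)
  d <- delta_smoc(m, bad, emap, window = 11, sim = sim_params(4, 1))
  expect_true(all(d$value[d$resi %in% 13:17] > 0))
  outside <- !(d$resi %in% 8:22)  # windows never touching the region
  expect_lt(max(abs(d$value[outside]), na.rm = TRUE), 0.02)
})

test_that("a flipped sidechain shows in the sidechain track, not the backbone", {
  m <- make_polymer(20, "helix")
  emap <- simulate_density(m, sim_params(4, 1))
  flip <- make_local_error(m, 10, "sidechain_flip", amplitude = 3, seed = 4)
  bs <- backbone_sidechain_smoc(flip, m, emap, window = 5,
                                sim = sim_params(2.5, 1))
  expect_lt(bs$sidechain$value[bs$sidechain$resi == 10], 0)
  expect_lt(max(abs(bs$backbone$value), na.rm = TRUE), 0.02)
})

test_that("glycine has a backbone score but no sidechain score", {
  m <- make_polymer(15, "helix")
  m$resname[m$resi == 8] <- "GLY"
  gly <- atomic_model(as.data.frame(m)[!(m$resi == 8 & m$atom == "CB"), ])
  emap <- simulate_density(gly, sim_params(3, 1))
  bs <- backbone_sidechain_smoc(gly, gly, emap, window = 5,
                                sim = sim_params(3, 1))
  expect_true(is.na(bs$sidechain$value[bs$sidechain$resi == 8]))
  expect_true(is.finite(bs$backbone$value[bs$backbone$resi == 8]))
})

test_that("correspondence falls back to sequence alignment when numbering differs", {
  m <- make_polymer(20, "helix")
  shifted <- m
  shifted$resi <- shifted$resi + 100L
  corr <- residue_correspondence(shifted, m)
  expect_equal(nrow(corr), 20)
  expect_equal(corr$resi_t, corr$resi - 100L)
  emap <- simulate_density(m, sim_params(4, 1))
  d <- delta_smoc(shifted, m, emap, window = 11, sim = sim_params(4, 1))
  expect_true(all(d$value == 0, na.rm = TRUE))
})

test_that("local-resolution exclusion keeps only well-resolved residues", {
  tr <- residue_track("A", 1:4, "", c(0.1, 0.2, 0.3, 0.4), name = "dSMOC")
  lr <- residue_track("A", 1:4, "", c(2.0, 2.4, 2.6, 3.0), name = "LocRes",
                      units = "A")
  kept <- exclude_by_locres(tr, lr, cutoff = 2.5)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$resi, 1:2)
  # all below cutoff: unchanged
  lr2 <- residue_track("A", 1:4, "", rep(2, 4), name = "LocRes", units = "A")
  expect_equal(nrow(exclude_by_locres(tr, lr2)), 4)
  # nothing left: warning, empty
  lr3 <- residue_track("A", 1:4, "", rep(9, 4), name = "LocRes", units = "A")
  expect_warning(empty <- exclude_by_locres(tr, lr3), "no residues")
  expect_equal(nrow(empty), 0)
})
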