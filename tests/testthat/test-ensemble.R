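test_that("Kabsch recovers exact rigid transforms and refuses degeneracy", {
  withr::with_seed(1, {
    p <- matrix(rnorm(30), 10, 3)
    r0 <- random_rotation()
    q <- p %*% r0 + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  })
  tf <- kabsch_superpose(p, q)
  expect_lt(tf$rmsd, 1e-9)
  expect_equal(det(tf$rot), 1, tolerance = 1e-12)
  # identity case
  tf0 <- kabsch_superpose(p, p)
  expect_equal(tf0$rot, diag(3), tolerance = 1e-12)
  expect_equal(tf0$trans, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(tf0$rmsd, 1e-12)
  expect_error(kabsch_superpose(p[1:2, ], q[1:2, ]),
               class = "cryofit_invalid_parameter")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line + 0, line),
               class = "cryofit_invalid_parameter")
})

test_that("mirrored coordinates still yield a proper rotation at the true optimum", {
  withr::with_seed(2, p <- matrix(rnorm(12), 4, 3))
  q <- p %*% diag(c(-1, 1, 1))            # reflection: unreachable exactly
  tf <- kabsch_superpose(p, q)
  expect_equal(det(tf$rot), 1, tolerance = 1e-12)
  # oracle: dense random search over proper rotations (centred problem)
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  withr::with_seed(3, {
    best <- Inf
    for (i in 1:20000) {
      rr <- random_rotation()
      best <- min(best, sqrt(mean(rowSums((pc %*% rr - qc)^2))))
    }
  })
  expect_lte(tf$rmsd, best + 1e-6)
})

test_that("ensemble alignment maps shifted copies back onto model 1", {
  m <- make_polymer(20, "helix")
  ms <- cryofit:::transform_model(m, diag(3), c(5, 0, 0))
  ps <- suppressWarnings(prediction_set(list(m, ms)))
  al <- align_ensemble(ps)
  expect_equal(cryofit:::model_coords(al$models[[2]]),
               cryofit:::model_coords(m), tolerance = 1e-9)
  # identical models come back unchanged (to superposition round-off)
  ps5 <- prediction_set(rep(list(m), 5))
  al5 <- align_ensemble(ps5)
  expect_equal(cryofit:::model_coords(al5$models[[3]]),
               cryofit:::model_coords(m), tolerance = 1e-12)
})

test_that("extra residues ride along with the shared-atom alignment", {
  m <- make_polymer(20, "helix")
  tail5 <- as.data.frame(m)[m$resi <= 5, ]
  tail5$resi <- tail5$resi + 20L
  tail5$z <- tail5$z + 40
  extra <- atomic_model(rbind(as.data.frame(m), tail5), "extra")
  shifted <- cryofit:::transform_model(extra, diag(3), c(4, 4, 4))
  ps <- suppressWarnings(prediction_set(list(m, shifted)))
  al <- align_ensemble(ps)
  m2 <- al$models[[2]]
  expect_equal(m2$x[m2$resi <= 20], m$x, tolerance = 1e-9)
  expect_equal(nrow(m2), nrow(extra))     # residues 21-25 transformed along
  expect_equal(m2$z[m2$resi > 20], tail5$z, tolerance = 1e-9)
})

test_that("RMSF is zero for identical models and matches the hand formula", {
  m <- make_polymer(12, "helix")
  ps <- prediction_set(rep(list(m), 5))
  expect_true(all(rmsf(ps)$value == 0))
  # displace residue 6 by +d and -d in two models
  d <- 1.3
  m_plus <- m; sel <- m$resi == 6
  m_plus$x[sel] <- m_plus$x[sel] + d
  m_minus <- m; m_minus$x[sel] <- m_minus$x[sel] - d
  ps2 <- prediction_set(list(m, m_plus, m_minus, m, m))
  r <- rmsf(ps2)
  expect_equal(r$value[r$resi == 6], d * sqrt(2 / 5), tolerance = 1e-12)
  expect_true(all(r$value[r$resi != 6] == 0))
})

test_that("mean squared RMSF follows the Gaussian closed form", {
  m <- make_polymer(40, "helix")
  sigma <- 0.8
  msqs <- vapply(1:60, function(s) {
    mean(rmsf(make_ensemble(m, sigma, n_models = 5, seed = s))$value^2)
  }, numeric(1))
  expect_equal(mean(msqs), 3 * sigma^2 * 4 / 5, tolerance = 0.1)
})

test_that("RMSF is invariant to a rigid transform of the whole set", {
  m <- make_polymer(15, "helix")
  ens <- make_ensemble(m, 0.5, seed = 9)
  r1 <- rmsf(align_ensemble(ens))
  withr::with_seed(4, rot <- random_rotation())
  moved <- ens
  moved$models <- lapply(moved$models, cryofit:::transform_model,
                         rot = rot, trans = c(30, -10, 2))
  r2 <- rmsf(align_ensemble(moved))
  expect_equal(r1$value, r2$value, tolerance = 1e-9)
})

test_that("lDDT is exactly 1 for self and rigid copies", {
  m <- make_polymer(10, "helix")
  expect_equal(lddt(m, m)$lddt_global, 1)
  withr::with_seed(5, rot <- random_rotation())
  mm <- cryofit:::transform_model(m, rot, c(8, 8, 8))
  l <- lddt(mm, m)
  expect_equal(l$lddt_global, 1)
  expect_true(all(l$lddt_per_residue$value == 1))
})

test_that("lDDT matches brute-force pair enumeration on perturbed toys", {
  withr::with_seed(6, {
    for (case in 1:8) {
      n_res <- sample(3:5, 1)
      ref <- toy_model(resi = rep(seq_len(n_res), each = 2),
                       atom = rep(c("CA", "CB"), n_res),
                       x = cumsum(runif(2 * n_res, 0.5, 2)),
                       y = runif(2 * n_res, 0, 4),
                       z = runif(2 * n_res, 0, 4), element = "C")
      mod <- ref
      k <- sample(nrow(mod), 1)
      mod$x[k] <- mod$x[k] + 1.5
      got <- lddt(mod, ref)
      want <- brute_lddt(mod, ref)
      expect_equal(got$lddt_global, want$global, tolerance = 1e-12)
      pr <- got$lddt_per_residue
      expect_equal(pr$value[match(as.integer(names(want$per_res)), pr$resi)],
                   unname(want$per_res), tolerance = 1e-12)
    }
  })
})

test_that("lDDT decays on average as perturbations grow", {
  m <- make_polymer(20, "helix")
  mean_lddt <- vapply(c(0.2, 0.8, 2), function(s) {
    mean(vapply(1:5, function(seed) {
      ens <- suppressWarnings(make_ensemble(m, s, n_models = 2, seed = seed))
      lddt(ens$models[[2]], m)$lddt_global
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_lddt) < 0))
})

test_that("TM-score is 1 for rigid copies and 0.5 at uniform d0 displacement", {
  m <- make_polymer(30, "helix")
  expect_equal(tm_score(m, m), 1)
  withr::with_seed(7, rot <- random_rotation())
  expect_equal(tm_score(cryofit:::transform_model(m, rot, c(3, 3, 3)), m),
               1, tolerance = 1e-9)
  # ring expanded radially by exactly d0: optimal fit is the identity
  n <- 20
  d0 <- max(0.5, 1.24 * (n - 15)^(1 / 3) - 1.8)
  ref <- ca_ring(n); mod <- ca_ring(n, dr = d0)
  expect_equal(tm_score(mod, ref), 0.5, tolerance = 0.02)
  expect_error(tm_score(ca_ring(10), ca_ring(10)),
               class = "cryofit_invalid_parameter")
})

dimer_fixture <- function() {
  # chain A: 5 residues along x at y=0; chain B: 5 residues at y=4 (contact)
  # except residue 5B placed far away
  a <- toy_model(resi = 1:5, atom = "CA", x = (0:4) * 20, y = 0, z = 0,
                 element = "C")
  b <- toy_model(resi = 1:5, atom = "CA", x = (0:4) * 20,
                 y = c(4, 4, 4, 4, 200), z = 0, chain = "B", element = "C")
  atomic_model(dplyr::bind_rows(as.data.frame(a), as.data.frame(b)),
               model_id = "dimer")
}

test_that("interface similarity is the Jaccard of contact sets", {
  ref <- dimer_fixture()
  expect_equal(ips(ref, ref), 1)
  # model: reproduce contacts 1,2; break 3,4; add spurious contact at 5
  mod <- dimer_fixture()
  mod$y[mod$chain == "B" & mod$resi %in% c(3, 4)] <- 50
  mod$y[mod$chain == "B" & mod$resi == 5] <- 4
  mod$x[mod$chain == "B" & mod$resi == 5] <- 80
  expect_equal(ips(mod, ref), 2 / 5)   # |{1,2}| / |{1,2,3,4,5}|
  # no inter-chain contacts at all
  apart <- dimer_fixture()
  apart$y[apart$chain == "B"] <- 500
  expect_equal(ips(apart, ref), 0)
  expect_error(ips(make_polymer(5, "helix"), ref),
               class = "cryofit_invalid_parameter")
})

test_that("the accuracy gate uses strict inequalities and skips IPS for monomers", {
  m <- make_polymer(20, "helix")
  ps <- prediction_set(rep(list(m), 5))
  # self-comparison scores are exactly 1; x > x must fail
  g_fail <- gate_group(ps, m, lddt_min = 1, tm_min = 0.8)
  expect_false(g_fail$passed)
  g_pass <- gate_group(ps, m, lddt_min = 1 - 1e-9, tm_min = 1 - 1e-9)
  expect_true(g_pass$passed)
  expect_true(all(is.na(g_pass$scores$ips)))     # monomer: IPS unused
  gl <- glance(g_pass)
  expect_true(gl$passed)
  expect_equal(gl$lddt_min_of_models, 1)
  expect_equal(nrow(tidy(g_pass)), 5)
})

test_that("track correlation reproduces the textbook formula and its symmetries", {
  a <- residue_track("A", 1:4, "", c(1, 2, 3, 4))
  b <- residue_track("A", 1:4, "", c(1, 3, 2, 4))
  r <- track_pearson(a, b)
  # brute-force formula
  va <- c(1, 2, 3, 4); vb <- c(1, 3, 2, 4)
  rr <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(r$pcc, rr)
  expect_equal(r$n_residues, 4)
  expect_equal(track_pearson(a, a)$pcc, 1)
  neg <- residue_track("A", 1:4, "", -2 * va + 5)
  expect_equal(track_pearson(a, neg)$pcc, -1)
  expect_equal(track_pearson(a, neg, absolute = TRUE)$pcc, 1)
  # affine invariance / sign flip
  b2 <- residue_track("A", 1:4, "", 10 * vb + 3)
  expect_equal(track_pearson(a, b2)$pcc, rr, tolerance = 1e-12)
  b3 <- residue_track("A", 1:4, "", -10 * vb + 3)
  expect_equal(track_pearson(a, b3)$pcc, -rr, tolerance = 1e-12)
  # degenerate cases are missing with a reason
  flat <- residue_track("A", 1:4, "", rep(2, 4))
  expect_true(is.na(track_pearson(a, flat)$pcc))
  expect_match(track_pearson(a, flat)$note, "zero variance")
  short <- residue_track("A", 1:2, "", c(1, 2))
  expect_match(track_pearson(short, short)$note, "fewer than 3")
})

test_that("the flexibility report gates, correlates and records degenerate groups", {
  b <- synth_bundle(40, pattern = "linear_gradient", seed = 2)
  lr <- local_resolution(b$half1, b$half2)
  tab <- rmsf_locres_report(list(b$ensemble), b$target, lr, gate = FALSE)
  expect_equal(nrow(tab), 1)
  expect_true(tab$passed_gate)
  expect_gt(tab$pcc, 0.3)
  # zero-variance ensemble: correlation missing with a reason
  ps0 <- prediction_set(rep(list(b$target), 5), group_id = "rigid")
  tab0 <- rmsf_locres_report(list(ps0), b$target, lr, gate = FALSE)
  expect_true(is.na(tab0$pcc))
  expect_match(tab0$note, "zero variance")
  # gated run on an accurate group passes and reports a correlation
  tiny <- make_ensemble(b$target, 0.15, seed = 3, group_id = "tight")
  tabg <- rmsf_locres_report(list(tiny), b$target, lr, gate = TRUE)
  expect_true(tabg$passed_gate)
})
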