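#' Synthetic polymers, ensembles and half-maps
#'
#' Everything in the package is testable without external data: this
#' module builds toy poly-alanine structures, perturbs them into
#' prediction-like ensembles with a controlled per-residue flexibility
#' profile, and renders noisy half-map pairs whose local resolution
#' follows a known spatial pattern.  All generators are pure functions of
#' their arguments and `seed`.
#'
#' @name synth
NULL

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Decorate a CA trace with N, C, O, CB at plausible offsets.
decorate_trace <- function(ca, chain = "A", resname = "ALA") {
  n_res <- nrow(ca)
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    prev <- if (i > 1) ca[i - 1, ] else 2 * ca[i, ] - ca[i + 1, ]
    nxt <- if (i < n_res) ca[i + 1, ] else 2 * ca[i, ] - ca[i - 1, ]
    u1 <- unit3(prev - ca[i, ]); u2 <- unit3(nxt - ca[i, ])
    nh <- unit3(cross3(u1, u2))
    if (all(abs(cross3(u1, u2)) < 1e-8)) nh <- unit3(cross3(u1, c(0, 0, 1)))
    npos <- ca[i, ] + 1.46 * unit3(u1 + 0.35 * nh)
    cpos <- ca[i, ] + 1.52 * unit3(u2 + 0.35 * nh)
    opos <- cpos + 1.23 * nh
    cbpos <- ca[i, ] + 1.53 * unit3(-(u1 + u2) + 0.8 * nh)
    atoms <- unname(rbind(npos, ca[i, ], cpos, opos, cbpos))
    rows[[i]] <- tibble::tibble(
      chain = chain, resi = i, icode = "", resname = resname,
      atom = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
      occ = 1, bfield = 0, altloc = "")
  }
  df <- dplyr::bind_rows(rows)
  if (resname == "GLY") df <- df[df$atom != "CB", ]
  df
}

#' Generate a toy poly-alanine polymer
#'
#' `"helix"` places C-alphas on ideal alpha-helix geometry (2.3 A radius,
#' 1.5 A rise, 100 degrees per residue, giving the canonical 3.8 A
#' consecutive C-alpha distance); `"coil"` grows a seeded self-avoiding
#' random walk with 3.8 A steps.  Backbone (N, C, O) and C-beta atoms are
#' added at plausible offsets.  Residues are numbered from 1, chain "A".
#'
#' @param n_res Number of residues (>= 5).
#' @param kind `"helix"` or `"coil"`.
#' @param seed Integer seed (used by `"coil"`).
#' @param model_id Identifier.
#' @return An [atomic_model()].
#' @export
make_polymer <- function(n_res, kind = c("helix", "coil"), seed = 1,
                         model_id = "synthetic-target") {
  kind <- match.arg(kind)
  if (n_res < 5) abort("make_polymer: n_res must be >= 5",
                       class = "cryofit_invalid_parameter")
  ca <- if (kind == "helix") {
    th <- (seq_len(n_res) - 1) * 100 * pi / 180
    cbind(2.3 * cos(th), 2.3 * sin(th), (seq_len(n_res) - 1) * 1.5)
  } else {
    withr::with_seed(seed, {
      pos <- matrix(0, n_res, 3)
      dir <- unit3(stats::rnorm(3))
      for (i in 2:n_res) {
        for (try in 1:100) {
          cand_dir <- unit3(dir + 0.8 * stats::rnorm(3))
          cand <- pos[i - 1, ] + 3.8 * cand_dir
          d2 <- rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE], 2,
                              cand)^2)
          if (all(d2 > 3.5^2) || try == 100) break
        }
        pos[i, ] <- cand; dir <- cand_dir
      }
      pos
    })
  }
  atomic_model(decorate_trace(ca), model_id = model_id,
               provenance = "target")
}

#' Per-residue flexibility profiles
#'
#' Displacement scales (standard deviation per coordinate, Angstroms) for
#' [make_ensemble()]: `"constant"` is flat at `sigma_max`;
#' `"linear_gradient"` ramps from `sigma_min` at residue 1 to `sigma_max`
#' at the last residue; `"two_domain"` gives the first half `sigma_min`
#' and the second half `sigma_max`.
#'
#' @param n_res Number of residues.
#' @param pattern Profile shape.
#' @param sigma_min,sigma_max Angstroms.
#' @return Numeric vector of length `n_res` with attribute `pattern`.
#' @export
flex_profile <- function(n_res, pattern = c("linear_gradient", "constant",
                                            "two_domain"),
                         sigma_min = 0.2, sigma_max = 1.2) {
  pattern <- match.arg(pattern)
  s <- switch(pattern,
    constant = rep(sigma_max, n_res),
    linear_gradient = seq(sigma_min, sigma_max, length.out = n_res),
    two_domain = c(rep(sigma_min, floor(n_res / 2)),
                   rep(sigma_max, n_res - floor(n_res / 2))))
  structure(s, pattern = pattern)
}

#' Perturb a target into a prediction-like ensemble
#'
#' Each model is the target with every residue rigidly displaced by a
#' zero-mean Gaussian offset of per-coordinate standard deviation
#' `sigma[i]` — all atoms of a residue move together, so fragment
#' superposition stays meaningful.  Deterministic under `seed`.
#'
#' @param target An [atomic_model()].
#' @param sigma Per-residue displacement scale (recycled), Angstroms.
#' @param n_models Number of models (default 5).
#' @param seed Integer seed.
#' @param group_id Passed to [prediction_set()].
#' @return A [prediction_set()].
#' @export
make_ensemble <- function(target, sigma, n_models = 5, seed = 1,
                          group_id = "synthetic-group") {
  if (n_models < 2) abort("make_ensemble: n_models must be >= 2",
                          class = "cryofit_invalid_parameter")
  rs <- model_residues(target)
  sigma <- rep_len(sigma, nrow(rs))
  rkey <- res_key(rs$chain, rs$resi, rs$icode)
  akey <- res_key(target$chain, target$resi, target$icode)
  ridx <- match(akey, rkey)
  models <- withr::with_seed(seed, {
    lapply(seq_len(n_models), function(m) {
      disp <- matrix(stats::rnorm(3 * nrow(rs)), ncol = 3) * sigma
      mod <- target
      mod$x <- mod$x + disp[ridx, 1]
      mod$y <- mod$y + disp[ridx, 2]
      mod$z <- mod$z + disp[ridx, 3]
      attr(mod, "model_id") <- paste0("m", m)
      attr(mod, "provenance") <- "prediction"
      mod
    })
  })
  prediction_set(models, group_id = group_id,
                 target_id = attr(target, "model_id") %||% "target")
}

# Gaussian-smoothed zone masks: voxels are assigned to the nearest
# representative atom's zone, then each indicator is blurred with a
# raised-cosine-free Gaussian of ~1.5 voxels so zone boundaries blend over
# about 3 voxels, and the masks are renormalised to sum to 1.
zone_masks <- function(grid, rep_xyz, zone_of_res) {
  d <- dim(grid$data)
  cx <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$voxel[1]
  cy <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$voxel[2]
  cz <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$voxel[3]
  best <- array(Inf, d); zone <- array(1L, d)
  for (i in seq_len(nrow(rep_xyz))) {
    d2 <- outer(outer((cx - rep_xyz[i, 1])^2, (cy - rep_xyz[i, 2])^2, "+"),
                (cz - rep_xyz[i, 3])^2, "+")
    upd <- d2 < best
    best[upd] <- d2[upd]
    zone[upd] <- zone_of_res[i]
  }
  n_zones <- max(zone_of_res)
  # Gaussian blur via FFT, sigma 1.5 voxels
  f1 <- function(n) { k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n; k / n }
  s2 <- outer(outer(f1(d[1])^2, f1(d[2])^2, "+"), f1(d[3])^2, "+")
  kern <- exp(-2 * pi^2 * 1.5^2 * s2)
  masks <- lapply(seq_len(n_zones), function(z) {
    ind <- array(as.numeric(zone == z), d)
    Re(fft(fft(ind) * kern, inverse = TRUE)) / length(ind)
  })
  tot <- Reduce(`+`, masks)
  tot[tot < 1e-9] <- 1
  lapply(masks, function(m) pmax(m, 0) / tot)
}

#' Render noisy half-maps with a known local-resolution pattern
#'
#' A density map is simulated from the target, space is partitioned by
#' nearest residue into zones sharing a pattern resolution, each zone is
#' low-pass filtered at its resolution (soft-edged masks blend the zones),
#' and two half-maps are produced by adding independent seeded white
#' Gaussian noise to the shared signal.  `noise_sigma` is the noise
#' standard deviation as a multiple of the signal's standard deviation
#' (1 means map-wide SNR of about one).
#'
#' @param target An [atomic_model()].
#' @param base_resolution Simulation resolution, Angstroms (finer than any
#'   pattern value).
#' @param locres_pattern Per-residue target resolution, Angstroms
#'   (recycled); every value must be at least `2 * voxel_size`.
#' @param noise_sigma Noise level relative to signal SD.
#' @param voxel_size Angstroms.
#' @param seed Integer seed.
#' @param padding Angstroms around the model bounding box.
#' @param grid_dim Optional fixed grid dimensions (e.g. `c(64, 64, 64)`),
#'   centred on the model.
#' @return List: `half1`, `half2`, `signal` (noise-free map), and
#'   `pattern` (the per-residue [residue_track()] of imposed resolution).
#' @export
make_halfmaps <- function(target, base_resolution = 3, locres_pattern = 8,
                          noise_sigma = 1, voxel_size = 1, seed = 1,
                          padding = 8, grid_dim = NULL) {
  rs <- model_residues(target)
  rs <- rs[rs$usable, ]
  pattern <- rep_len(locres_pattern, nrow(rs))
  if (any(pattern < 2 * voxel_size)) {
    abort("make_halfmaps: pattern finer than Nyquist",
          class = "cryofit_invalid_parameter")
  }
  rep_xyz <- cbind(rs$x, rs$y, rs$z)
  if (is.null(grid_dim)) {
    lo <- apply(rep_xyz, 2, min) - padding
    hi <- apply(rep_xyz, 2, max) + padding
    n <- pmax(8L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  } else {
    n <- rep(as.integer(grid_dim), length.out = 3)
    ctr <- (apply(rep_xyz, 2, min) + apply(rep_xyz, 2, max)) / 2
    lo <- ctr - (n - 1) * voxel_size / 2
  }
  template <- density_grid(array(0, n), voxel = rep(voxel_size, 3),
                           origin = lo)
  sim <- simulate_density(target, sim_params(base_resolution, voxel_size),
                          onto = template)
  # group residues into at most 6 resolution zones
  ur <- sort(unique(round(pattern, 3)))
  if (length(ur) > 6) {
    br <- seq(min(pattern), max(pattern), length.out = 7)
    zone_of_res <- findInterval(pattern, br, rightmost.closed = TRUE)
    zone_res <- vapply(seq_len(6), function(z) {
      if (any(zone_of_res == z)) mean(pattern[zone_of_res == z]) else NA
    }, numeric(1))
    keep <- which(!is.na(zone_res))
    zone_of_res <- match(zone_of_res, keep)
    zone_res <- zone_res[keep]
  } else {
    zone_of_res <- match(round(pattern, 3), ur)
    zone_res <- ur
  }
  signal <- array(0, n)
  if (length(zone_res) == 1L) {
    signal <- lowpass_filter(sim, zone_res[1])$data
  } else {
    masks <- zone_masks(template, rep_xyz, zone_of_res)
    for (z in seq_along(zone_res)) {
      signal <- signal + masks[[z]] * lowpass_filter(sim, zone_res[z])$data
    }
  }
  nsd <- noise_sigma * sd(as.vector(signal))
  halves <- withr::with_seed(seed, {
    list(signal + array(stats::rnorm(length(signal), sd = nsd), n),
         signal + array(stats::rnorm(length(signal), sd = nsd), n))
  })
  list(
    half1 = density_grid(halves[[1]], voxel = rep(voxel_size, 3),
                         origin = lo),
    half2 = density_grid(halves[[2]], voxel = rep(voxel_size, 3),
                         origin = lo),
    signal = density_grid(signal, voxel = rep(voxel_size, 3), origin = lo,
                          label = "simulated"),
    pattern = residue_track(rs$chain, rs$resi, rs$icode, pattern,
                            name = "TrueLocRes", units = "A"))
}

#' Corrupt a local region of a model
#'
#' Constructs the local modelling errors delta-SMOC is designed to
#' detect: `"loop_shift"` displaces all atoms of the region along a
#' seeded random direction with a smooth sine bump peaking at `amplitude`
#' mid-region; `"sidechain_flip"` displaces only sidechain atoms, each
#' residue in its own seeded direction, leaving the backbone untouched.
#'
#' @param target An [atomic_model()].
#' @param region Integer residue numbers to corrupt (chain `chain`).
#' @param mode `"loop_shift"` or `"sidechain_flip"`.
#' @param amplitude Peak displacement, Angstroms.
#' @param seed Integer seed.
#' @param chain Chain to corrupt (default first).
#' @return The corrupted [atomic_model()].
#' @export
make_local_error <- function(target, region, mode = c("loop_shift",
                                                      "sidechain_flip"),
                             amplitude = 4, seed = 1, chain = NULL) {
  mode <- match.arg(mode)
  chain <- chain %||% target$chain[1]
  rs <- model_residues(target)
  rc <- rs[rs$chain == chain, ]
  if (!all(region %in% rc$resi)) {
    abort("make_local_error: region outside target",
          class = "cryofit_invalid_parameter")
  }
  pos <- match(region, rc$resi)
  if (min(pos) <= 1L || max(pos) >= nrow(rc)) {
    abort("make_local_error: region touches a chain terminus",
          class = "cryofit_invalid_parameter")
  }
  region <- sort(region)
  out <- target
  kind <- residue_kind(out$resname)
  withr::with_seed(seed, {
    if (mode == "loop_shift") {
      dirv <- unit3(stats::rnorm(3))
      for (k in seq_along(region)) {
        bump <- amplitude * sin(pi * k / (length(region) + 1))
        sel <- out$chain == chain & out$resi == region[k]
        out$x[sel] <- out$x[sel] + bump * dirv[1]
        out$y[sel] <- out$y[sel] + bump * dirv[2]
        out$z[sel] <- out$z[sel] + bump * dirv[3]
      }
    } else {
      for (k in seq_along(region)) {
        dirv <- unit3(stats::rnorm(3))
        sel <- out$chain == chain & out$resi == region[k] &
          !is_backbone(out$atom, kind) & !is_hydrogen(out$element)
        out$x[sel] <- out$x[sel] + amplitude * dirv[1]
        out$y[sel] <- out$y[sel] + amplitude * dirv[2]
        out$z[sel] <- out$z[sel] + amplitude * dirv[3]
      }
    }
  })
  attr(out, "model_id") <- paste0(attr(target, "model_id") %||% "model",
                                  "-", mode)
  out
}

#' Generate a complete synthetic assessment bundle
#'
#' Target, perturbed 5-model ensemble, and half-maps whose
#' local-resolution pattern is generated from the ensemble's flexibility
#' profile (`locres = locres_base + locres_scale * sigma`), so the
#' flexibility-versus-resolution analysis has a known positive ground
#' truth.  With `shuffle_profile = TRUE` the map pattern is computed from
#' a permuted profile, decoupling the two — the matched negative control.
#'
#' @param n_res Residues in the toy polymer.
#' @param pattern Flexibility pattern (see [flex_profile()]).
#' @param seed Integer seed controlling every random draw.
#' @param sigma_min,sigma_max Flexibility range, Angstroms.
#' @param locres_base,locres_scale Map resolution imposed per residue:
#'   `locres_base + locres_scale * sigma`, Angstroms.
#' @param base_resolution,voxel_size,noise_sigma,padding,grid_dim Passed
#'   to [make_halfmaps()].
#' @param kind Polymer kind.
#' @param shuffle_profile Decouple map pattern from ensemble flexibility.
#' @return List: `target`, `ensemble`, `half1`, `half2`, `signal`,
#'   `true_locres` ([residue_track()]), `profile`, `seed`.
#' @export
synth_bundle <- function(n_res = 60, pattern = "linear_gradient", seed = 1,
                         sigma_min = 0.2, sigma_max = 1.2,
                         locres_base = 3.2, locres_scale = 2.5,
                         base_resolution = 3, voxel_size = 1,
                         noise_sigma = 1, padding = 8, grid_dim = NULL,
                         kind = "helix", shuffle_profile = FALSE) {
  target <- make_polymer(n_res, kind = kind, seed = seed)
  prof <- flex_profile(n_res, pattern, sigma_min, sigma_max)
  map_prof <- if (shuffle_profile) {
    withr::with_seed(seed + 1L, sample(prof))
  } else prof
  locres_pattern <- locres_base + locres_scale * map_prof
  ens <- make_ensemble(target, prof, n_models = 5, seed = seed + 2L)
  hm <- make_halfmaps(target, base_resolution = base_resolution,
                      locres_pattern = locres_pattern,
                      noise_sigma = noise_sigma, voxel_size = voxel_size,
                      seed = seed + 3L, padding = padding,
                      grid_dim = grid_dim)
  list(target = target, ensemble = ens, half1 = hm$half1, half2 = hm$half2,
       signal = hm$signal, true_locres = hm$pattern, profile = prof,
       seed = seed)
}
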