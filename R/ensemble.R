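#' Prediction sets
#'
#' A `prediction_set` wraps the (conventionally five) models a group
#' submits for one target.  Fewer than five are allowed with a warning;
#' at least two are required.
#'
#' @param models List of [atomic_model()]s.
#' @param group_id,target_id Identifiers.
#' @return A `prediction_set`.
#' @export
prediction_set <- function(models, group_id = "group", target_id = "") {
  if (!is.list(models) || length(models) < 2L) {
    abort("prediction_set: need at least 2 models",
          class = "cryofit_invalid_parameter")
  }
  if (length(models) != 5L) {
    warn(sprintf("prediction_set: %d models (5 expected)", length(models)))
  }
  structure(list(models = models, group_id = group_id,
                 target_id = target_id),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set '%s' for '%s': %d models>\n",
              x$group_id, x$target_id, length(x$models)))
  invisible(x)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` via SVD of
#' the covariance matrix, constrained to a proper rotation (det = +1) even
#' when a reflection would fit better.  Points are matched by row.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3,
#'   non-collinear.
#' @return List: `rot` (3 x 3), `trans` (length 3), `rmsd` (Angstroms).
#'   Apply as `xyz %*% rot + trans` (rows transform onto the reference).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || nrow(mobile) < 3L) {
    abort("kabsch_superpose: need >= 3 matched points",
          class = "cryofit_invalid_parameter")
  }
  cm <- colMeans(mobile); cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm); q <- sweep(reference, 2, cr)
  if (svd(q)$d[2] < 1e-8 * max(1, svd(q)$d[1])) {
    abort("kabsch_superpose: degenerate (collinear) reference",
          class = "cryofit_invalid_parameter")
  }
  h <- crossprod(p, q)                      # t(p) %*% q
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- as.numeric(cr - cm %*% rot)
  moved <- sweep(p %*% rot, 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  list(rot = rot, trans = trans, rmsd = rmsd)
}

# Representative-atom coordinates shared by a list of models; returns the
# key vector and one n x 3 matrix per model.
shared_rep_coords <- function(models) {
  reps <- lapply(models, function(m) {
    r <- model_residues(m)
    r[r$usable, c("chain", "resi", "icode", "x", "y", "z")]
  })
  keys <- Reduce(intersect, lapply(reps, function(r)
    res_key(r$chain, r$resi, r$icode)))
  coords <- lapply(reps, function(r) {
    k <- res_key(r$chain, r$resi, r$icode)
    as.matrix(r[match(keys, k), c("x", "y", "z")])
  })
  list(keys = keys, coords = coords)
}

#' Align an ensemble onto its first model
#'
#' Models 2..n are rigidly superposed onto model 1 using the
#' representative atoms (C-alpha / C4') shared by all models; model 1 is
#' untouched.  This mirrors the convention of aligning a group's models
#' 2-5 against model 1 before computing fluctuations.
#'
#' @param pset A [prediction_set()].
#' @return The aligned [prediction_set()].
#' @export
align_ensemble <- function(pset) {
  sh <- shared_rep_coords(pset$models)
  if (length(sh$keys) < 3L) {
    abort("align_ensemble: fewer than 3 shared representative atoms",
          class = "cryofit_invalid_parameter")
  }
  ref <- sh$coords[[1]]
  for (m in seq_along(pset$models)[-1]) {
    tf <- kabsch_superpose(sh$coords[[m]], ref)
    pset$models[[m]] <- transform_model(pset$models[[m]], tf$rot, tf$trans)
  }
  pset
}

#' Per-residue RMSF of an aligned ensemble
#'
#' For each residue present in every model, the root-mean-square
#' fluctuation of its representative atom about the ensemble mean
#' position: `sqrt(mean(|r_m - rbar|^2))` over the m models (population
#' form).  Residues missing from any model are missing.
#'
#' @param pset An aligned [prediction_set()] (see [align_ensemble()]).
#' @return A [residue_track()] named `"RMSF"` (Angstroms).
#' @export
rmsf <- function(pset) {
  sh <- shared_rep_coords(pset$models)
  if (length(sh$keys) == 0L) abort("rmsf: no shared residues")
  arr <- simplify2array(sh$coords)              # n x 3 x m
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- apply((arr - replicate(dim(arr)[3], mean_pos))^2, c(1, 3), sum)
  vals <- sqrt(rowMeans(dev2))
  parts <- strsplit(sh$keys, "|", fixed = TRUE)
  residue_track(chain = vapply(parts, `[`, "", 1),
                resi = as.integer(vapply(parts, `[`, "", 2)),
                icode = vapply(parts, function(p)
                  if (length(p) >= 3) p[3] else "", ""),
                value = vals, name = "RMSF", units = "A")
}

# Matched heavy atoms between model and reference, as two coordinate
# matrices plus the reference residue index of each atom.
matched_atoms <- function(model, reference) {
  am <- scoring_atoms(model); ar <- scoring_atoms(reference)
  corr <- residue_correspondence(model, reference)
  corr$key_p <- res_key(corr$chain, corr$resi, corr$icode)
  corr$key_t <- res_key(corr$chain_t, corr$resi_t, corr$icode_t)
  am$key_t <- corr$key_t[match(res_key(am$chain, am$resi, am$icode),
                               corr$key_p)]
  ar$key <- res_key(ar$chain, ar$resi, ar$icode)
  m <- dplyr::inner_join(
    dplyr::select(am, "key_t", "atom", xm = "x", ym = "y", zm = "z"),
    dplyr::select(ar, key_t = "key", "atom", xr = "x", yr = "y", zr = "z"),
    by = c("key_t", "atom"))
  list(model = cbind(m$xm, m$ym, m$zm),
       ref = cbind(m$xr, m$yr, m$zr),
       res = m$key_t)
}

#' Local Distance Difference Test
#'
#' Superposition-free local agreement score: over all heavy-atom pairs of
#' the reference that come from different residues and lie within
#' `inclusion_radius`, the fraction whose distance is reproduced by the
#' model within `t`, averaged over the tolerance thresholds
#' `t = 0.5, 1, 2, 4` Angstroms.  Reported globally and per residue (each
#' pair counts toward both residues).  No stereochemistry term.
#'
#' @param model,reference [atomic_model()]s.
#' @param inclusion_radius Angstroms (default 15).
#' @param thresholds Tolerance thresholds, Angstroms.
#' @return List: `lddt_global` in [0,1], `lddt_per_residue` (a
#'   [residue_track()]), `n_pairs`.
#' @export
lddt <- function(model, reference, inclusion_radius = 15,
                 thresholds = c(0.5, 1, 2, 4)) {
  ma <- matched_atoms(model, reference)
  n <- nrow(ma$model)
  if (n < 2L) abort("lddt: no matched atom pairs")
  dm <- as.matrix(stats::dist(ma$model))
  dr <- as.matrix(stats::dist(ma$ref))
  same_res <- outer(ma$res, ma$res, "==")
  use <- upper.tri(dr) & !same_res & dr <= inclusion_radius
  if (!any(use)) abort("lddt: no reference pairs within inclusion radius")
  dd <- abs(dm[use] - dr[use])
  pair_scores <- Reduce(`+`, lapply(thresholds, function(t)
    as.numeric(dd < t))) / length(thresholds)
  rows <- row(dr)[use]; cols <- col(dr)[use]
  res_of <- ma$res
  keys <- unique(res_of)
  per_res <- vapply(keys, function(k) {
    sel <- res_of[rows] == k | res_of[cols] == k
    if (!any(sel)) NA_real_ else mean(pair_scores[sel])
  }, numeric(1))
  parts <- strsplit(keys, "|", fixed = TRUE)
  track <- residue_track(
    chain = vapply(parts, `[`, "", 1),
    resi = as.integer(vapply(parts, `[`, "", 2)),
    icode = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
    value = per_res, name = "lDDT", units = "dimensionless")
  list(lddt_global = mean(pair_scores), lddt_per_residue = track,
       n_pairs = sum(use))
}

#' TM-score
#'
#' Length-normalised structural similarity under an optimised rigid
#' superposition: `TM = mean over reference length of 1/(1 + (d_i/d0)^2)`
#' with `d0 = 1.24 (L-15)^(1/3) - 1.8` (floored at 0.5 Angstroms).
#' Residues correspond by sequence (author numbering); the superposition
#' starts from a full-set Kabsch fit and is iteratively refined on the
#' residues currently closer than `d0` until the inlier set repeats
#' (at most 20 iterations); the best score over iterations is returned.
#'
#' @param model,reference [atomic_model()]s with >= 15 corresponding
#'   residues.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, reference) {
  rr <- model_residues(reference)
  l_ref <- sum(rr$usable)
  sh <- shared_rep_coords(list(model, reference))
  n <- length(sh$keys)
  if (n < 15L) abort("tm_score: fewer than 15 corresponding residues",
                     class = "cryofit_invalid_parameter")
  d0 <- max(0.5, 1.24 * (l_ref - 15)^(1 / 3) - 1.8)
  mob <- sh$coords[[1]]; ref <- sh$coords[[2]]
  cutoff <- max(d0, 1.0)
  sel <- seq_len(n)
  best <- 0
  prev <- list()
  for (it in 1:20) {
    tf <- kabsch_superpose(mob[sel, , drop = FALSE],
                           ref[sel, , drop = FALSE])
    d <- sqrt(rowSums((apply_transform(mob, tf$rot, tf$trans) - ref)^2))
    best <- max(best, sum(1 / (1 + (d / d0)^2)) / l_ref)
    new_sel <- which(d < cutoff)
    if (length(new_sel) < 3L) new_sel <- order(d)[1:4]
    if (any(vapply(prev, identical, TRUE, y = new_sel))) break
    prev <- c(prev, list(sel))
    sel <- new_sel
  }
  best
}

# Inter-chain residue contact set of a model, in its own keyspace.
contact_set <- function(model, cutoff) {
  a <- scoring_atoms(model)
  if (length(unique(a$chain)) < 2L) return(character(0))
  xyz <- model_coords(a)
  key <- res_key(a$chain, a$resi, a$icode)
  out <- character(0)
  chains <- unique(a$chain)
  for (i in seq_along(chains)[-length(chains)]) {
    for (j in (i + 1):length(chains)) {
      ai <- which(a$chain == chains[i]); aj <- which(a$chain == chains[j])
      dx <- outer(xyz[ai, 1], xyz[aj, 1], "-")
      dy <- outer(xyz[ai, 2], xyz[aj, 2], "-")
      dz <- outer(xyz[ai, 3], xyz[aj, 3], "-")
      hit <- which(dx * dx + dy * dy + dz * dz < cutoff^2, arr.ind = TRUE)
      if (nrow(hit)) {
        out <- c(out, unique(paste(key[ai][hit[, 1]],
                                   key[aj][hit[, 2]], sep = "--")))
      }
    }
  }
  unique(out)
}

#' Interface patch similarity (contact-set Jaccard)
#'
#' Inter-chain residue contacts are residue pairs from different chains
#' with any heavy-atom distance below `contact_cutoff`.  The score is the
#' Jaccard index between the model's and the reference's contact sets,
#' with model residues mapped into the reference keyspace.
#'
#' @param model,reference [atomic_model()]s with >= 2 chains.
#' @param contact_cutoff Angstroms (default 5).
#' @return Jaccard index in [0, 1], or `NA` if the reference has no
#'   inter-chain contacts.
#' @export
ips <- function(model, reference, contact_cutoff = 5) {
  if (length(unique(model$chain)) < 2L ||
      length(unique(reference$chain)) < 2L) {
    abort("ips: both models need >= 2 chains",
          class = "cryofit_invalid_parameter")
  }
  ref_c <- contact_set(reference, contact_cutoff)
  if (length(ref_c) == 0L) return(NA_real_)
  corr <- residue_correspondence(model, reference)
  map <- setNames(res_key(corr$chain_t, corr$resi_t, corr$icode_t),
                  res_key(corr$chain, corr$resi, corr$icode))
  mod_c <- contact_set(model, contact_cutoff)
  parts <- strsplit(mod_c, "--", fixed = TRUE)
  mod_t <- vapply(parts, function(p) {
    a <- map[p[1]]; b <- map[p[2]]
    if (is.na(a) || is.na(b)) return(NA_character_)
    paste(sort(c(a, b)), collapse = "--")
  }, character(1))
  mod_t <- unique(mod_t[!is.na(mod_t)])
  ref_t <- unique(vapply(strsplit(ref_c, "--", fixed = TRUE), function(p)
    paste(sort(p), collapse = "--"), character(1)))
  length(intersect(mod_t, ref_t)) / length(union(mod_t, ref_t))
}

#' Accuracy gate for a prediction set
#'
#' A group passes only when every model clears all thresholds with strict
#' inequalities: global lDDT > `lddt_min` (0.7), TM-score > `tm_min`
#' (0.8), and — for multimeric targets — interface similarity >
#' `ips_min` (0.8).  For monomers IPS is ignored.
#'
#' @param pset A [prediction_set()].
#' @param target Target [atomic_model()].
#' @param lddt_min,tm_min,ips_min Strict thresholds.
#' @param is_multimer Gate on IPS too?  Default: target has >= 2 chains.
#' @return A `cf_gate` object; see [tidy()] / [glance()] methods.
#' @export
gate_group <- function(pset, target, lddt_min = 0.7, tm_min = 0.8,
                       ips_min = 0.8, is_multimer = NULL) {
  is_multimer <- is_multimer %||% (length(unique(target$chain)) >= 2L)
  rows <- lapply(pset$models, function(m) {
    ld <- lddt(m, target)
    tibble::tibble(
      model_id = attr(m, "model_id") %||% "model",
      lddt_global = ld$lddt_global,
      tm = tm_score(m, target),
      ips = if (is_multimer) ips(m, target) else NA_real_)
  })
  scores <- dplyr::bind_rows(rows)
  ok <- scores$lddt_global > lddt_min & scores$tm > tm_min
  if (is_multimer) ok <- ok & !is.na(scores$ips) & scores$ips > ips_min
  scores$passed <- ok
  structure(list(group_id = pset$group_id, passed = all(ok),
                 scores = scores, is_multimer = is_multimer,
                 thresholds = c(lddt = lddt_min, tm = tm_min,
                                ips = ips_min)),
            class = "cf_gate")
}

#' @export
print.cf_gate <- function(x, ...) {
  cat(sprintf("<cf_gate '%s': %s (lDDT > %.2f, TM > %.2f%s)>\n",
              x$group_id, if (x$passed) "PASSED" else "failed",
              x$thresholds["lddt"], x$thresholds["tm"],
              if (x$is_multimer)
                sprintf(", IPS > %.2f", x$thresholds["ips"]) else ""))
  print(x$scores)
  invisible(x)
}

#' RMSF versus local-resolution report
#'
#' The flexibility analysis end to end: each group is accuracy-gated,
#' aligned onto its first model, reduced to a per-residue RMSF track, and
#' correlated (signed Pearson) with the local resolution projected onto
#' the target.  Groups failing the gate are listed with `passed_gate =
#' FALSE` and no correlation.  Rows are sorted by correlation, descending.
#'
#' @param psets List of [prediction_set()]s.
#' @param target Target [atomic_model()].
#' @param locres Local-resolution [density_grid()].
#' @param lddt_min,tm_min,ips_min Gate thresholds (see [gate_group()]).
#' @param gate Apply the accuracy gate (disable for synthetic ensembles
#'   whose perturbations are deliberately larger than the gate allows).
#' @return Tibble: `group`, `n_models`, `passed_gate`, `n_residues`,
#'   `pcc`, `note`.
#' @export
rmsf_locres_report <- function(psets, target, locres, lddt_min = 0.7,
                               tm_min = 0.8, ips_min = 0.8, gate = TRUE) {
  if (inherits(psets, "prediction_set")) psets <- list(psets)
  lr_track <- project_locres(locres, target, per = "residue")
  rows <- lapply(psets, function(ps) {
    passed <- TRUE
    if (gate) {
      g <- gate_group(ps, target, lddt_min, tm_min, ips_min)
      passed <- g$passed
    }
    if (!passed) {
      return(tibble::tibble(group = ps$group_id,
                            n_models = length(ps$models),
                            passed_gate = FALSE, n_residues = NA_integer_,
                            pcc = NA_real_, note = "failed accuracy gate"))
    }
    tr <- rmsf(align_ensemble(ps))
    pc <- track_pearson(tr, lr_track)
    tibble::tibble(group = ps$group_id, n_models = length(ps$models),
                   passed_gate = TRUE, n_residues = pc$n_residues,
                   pcc = pc$pcc, note = pc$note)
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$pcc))
}
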