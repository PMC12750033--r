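#' Manders' overlap coefficient
#'
#' `sum(a*b) / sqrt(sum(a^2) * sum(b^2))`, the kernel of SMOC scoring.
#' Bounded in [-1, 1]; invariant under positive scaling of either input.
#' If either vector is all zero the overlap is undefined and `NA` is
#' returned (missing, never 0).
#'
#' @param values_a,values_b Equal-length numeric vectors.
#' @return Scalar in [-1, 1], or `NA`.
#' @export
moc <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) == 0L) {
    abort("moc: inputs must have equal nonzero length",
          class = "cryofit_invalid_parameter")
  }
  na2 <- sum(values_a^2); nb2 <- sum(values_b^2)
  if (na2 == 0 || nb2 == 0) return(NA_real_)
  sum(values_a * values_b) / sqrt(na2 * nb2)
}

#' Voxels within a radius of a set of atoms
#'
#' The segment footprint of SMOC: the union of voxels whose centres lie
#' within `radius` of any atom position, as sorted linear indices into the
#' grid array (deterministic ordering).
#'
#' @param grid A [density_grid()].
#' @param xyz n x 3 matrix of atom positions (Angstroms).
#' @param radius Footprint radius, Angstroms.
#' @return Sorted integer vector of linear voxel indices (possibly empty).
#' @export
segment_voxels <- function(grid, xyz, radius = 2.5) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  d <- dim(grid$data)
  frac <- world_to_index(grid, xyz)
  hw <- ceiling(radius / grid$voxel)
  r2 <- radius^2
  out <- vector("list", nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    ci <- nearest_index(frac[i, , drop = FALSE])[1, ]
    i1 <- pmax(ci - hw, 1L); i2 <- pmin(ci + hw, d)
    if (any(i1 > i2)) next
    sx <- seq.int(i1[1], i2[1]); sy <- seq.int(i1[2], i2[2])
    sz <- seq.int(i1[3], i2[3])
    dx2 <- ((sx - frac[i, 1]) * grid$voxel[1])^2
    dy2 <- ((sy - frac[i, 2]) * grid$voxel[2])^2
    dz2 <- ((sz - frac[i, 3]) * grid$voxel[3])^2
    keep <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
    if (!any(keep)) next
    lin <- outer(outer(sx, (sy - 1L) * d[1], "+"),
                 (sz - 1L) * d[1] * d[2], "+")
    out[[i]] <- lin[keep]
  }
  sort(unique(as.integer(unlist(out))))
}

BACKBONE_PROT <- c("N", "CA", "C", "O", "OXT")
BACKBONE_NUC <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                  "C3'", "O3'", "C2'", "C1'")
SUPERPOSE_PROT <- c("N", "CA", "C", "O")
SUPERPOSE_NUC <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

is_backbone <- function(atom, kind) {
  ifelse(kind == "nucleic", atom %in% BACKBONE_NUC, atom %in% BACKBONE_PROT)
}

# Sliding windows over an ordered residue table of one chain: for each
# centre, the window truncates at the termini; centres whose truncated
# window is shorter than ceiling(window/2) are dropped.
chain_windows <- function(n, window) {
  h <- (window - 1L) %/% 2L
  min_len <- as.integer(ceiling(window / 2))
  lapply(seq_len(n), function(ctr) {
    lo <- max(1L, ctr - h); hi <- min(n, ctr + h)
    if (hi - lo + 1L < min_len) NULL else list(ctr = ctr, members = lo:hi)
  })
}

#' SMOC: sliding-window fit-to-density score
#'
#' Density is simulated for the whole model on the experimental grid; for
#' each sliding window of `window` residues per chain, the score is the
#' Manders overlap between experimental and simulated values over the
#' voxels within `radius` of the window's atoms, assigned to the central
#' residue.  Windows truncate at chain ends (minimum half a window) so
#' every residue is scored; chains shorter than half a window are skipped
#' with a warning.
#'
#' @param model An [atomic_model()].
#' @param exp_map Experimental [density_grid()].
#' @param window Odd window length in residues (11 by default).
#' @param sim A [sim_params()]; resolution conventionally the map's
#'   reported global resolution.
#' @param radius Footprint radius around atoms, Angstroms.
#' @return A [residue_track()] named `"SMOC"`.
#' @export
smoc <- function(model, exp_map, window = 11, sim = sim_params(4),
                 radius = 2.5) {
  if (window %% 2 == 0) abort("smoc: window must be odd",
                              class = "cryofit_invalid_parameter")
  atoms <- scoring_atoms(model)
  simmap <- simulate_density(model, sim, onto = exp_map)
  rs <- model_residues(model)
  out <- vector("list", length(unique(rs$chain)))
  names(out) <- unique(rs$chain)
  for (ch in unique(rs$chain)) {
    rc <- rs[rs$chain == ch, ]
    wins <- chain_windows(nrow(rc), window)
    if (all(vapply(wins, is.null, TRUE))) {
      warn(paste0("smoc: chain ", ch, " shorter than half a window; skipped"))
      next
    }
    vals <- rep(NA_real_, nrow(rc))
    akey <- res_key(atoms$chain, atoms$resi, atoms$icode)
    for (w in wins) {
      if (is.null(w)) next
      keys <- res_key(rc$chain[w$members], rc$resi[w$members],
                      rc$icode[w$members])
      sub <- atoms[akey %in% keys, ]
      if (nrow(sub) == 0L) next
      fp <- segment_voxels(exp_map, model_coords(sub), radius)
      if (length(fp) == 0L) next
      vals[w$ctr] <- moc(exp_map$data[fp], simmap$data[fp])
    }
    out[[ch]] <- tibble::tibble(chain = rc$chain, resi = rc$resi,
                                icode = rc$icode, value = vals)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) abort("smoc: no scorable chains")
  as_track(res, name = "SMOC", units = "score")
}

#' Residue correspondence between two models
#'
#' Prediction residues are matched to target residues by author
#' (chain, number, insertion-code) keys when the numbering agrees; for
#' chains with no key overlap, a global sequence alignment (identity
#' scoring, affine gaps, via Biostrings) establishes the mapping.  Chains
#' are paired by identifier, falling back to file order.
#'
#' @param prediction,target [atomic_model()]s.
#' @return Tibble: `chain`, `resi`, `icode` (prediction) and `chain_t`,
#'   `resi_t`, `icode_t` (target).
#' @export
residue_correspondence <- function(prediction, target) {
  rp <- model_residues(prediction)
  rt <- model_residues(target)
  cp <- unique(rp$chain); ct <- unique(rt$chain)
  pairs <- lapply(seq_along(cp), function(i) {
    tc <- if (cp[i] %in% ct) cp[i] else if (i <= length(ct)) ct[i] else NA
    c(cp[i], tc)
  })
  out <- list()
  for (pr in pairs) {
    if (is.na(pr[2])) next
    a <- rp[rp$chain == pr[1], ]
    b <- rt[rt$chain == pr[2], ]
    shared <- merge(a[, c("resi", "icode")], b[, c("resi", "icode")])
    if (nrow(shared) >= 0.5 * min(nrow(a), nrow(b)) && nrow(shared) > 0) {
      bb <- tibble::tibble(chain_t = b$chain, resi_t = b$resi,
                           icode_t = b$icode, resi = b$resi,
                           icode = b$icode)
      m <- dplyr::inner_join(dplyr::select(a, "chain", "resi", "icode"),
                             bb, by = c("resi", "icode"))
      out[[length(out) + 1L]] <- m
    } else {
      out[[length(out) + 1L]] <- align_chain_pair(a, b)
    }
  }
  if (length(out) == 0L) abort("residue_correspondence: no chains matched")
  dplyr::bind_rows(out)
}

one_letter <- function(resname, kind) {
  aa1 <- bio3d::aa321(resname)
  ifelse(kind == "nucleic", substr(resname, nchar(resname), nchar(resname)),
         ifelse(aa1 == "X", "X", aa1))
}

align_chain_pair <- function(a, b) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("residue_correspondence: numbering disagrees and Biostrings is not available")
  }
  sa <- paste(one_letter(a$resname, a$kind), collapse = "")
  sb <- paste(one_letter(b$resname, b$kind), collapse = "")
  alpha <- unique(c(strsplit(sa, "")[[1]], strsplit(sb, "")[[1]]))
  submat <- matrix(-1, length(alpha), length(alpha),
                   dimnames = list(alpha, alpha))
  diag(submat) <- 2                       # identity scoring, affine gaps
  al <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                      substitutionMatrix = submat,
                                      gapOpening = 5, gapExtension = 0.5)
  pa <- as.character(Biostrings::alignedPattern(al))
  pb <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(pa, "")[[1]]; cb <- strsplit(pb, "")[[1]]
  ia <- 0L; ib <- 0L; rows <- list()
  for (k in seq_along(ca)) {
    if (ca[k] != "-") ia <- ia + 1L
    if (cb[k] != "-") ib <- ib + 1L
    if (ca[k] != "-" && cb[k] != "-" && ca[k] == cb[k]) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chain = a$chain[ia], resi = a$resi[ia], icode = a$icode[ia],
        chain_t = b$chain[ib], resi_t = b$resi[ib], icode_t = b$icode[ib])
    }
  }
  dplyr::bind_rows(rows)
}

# Shared engine for fragment-aligned delta-SMOC scoring.  For each
# prediction window the matched fragment is least-squares superposed onto
# the corresponding target residues via matched backbone atoms; both the
# transformed fragment and the target residues are simulated in isolation
# and scored against the experimental map over the requested footprint.
delta_smoc_engine <- function(prediction, target, exp_map, window, sim,
                              radius, footprints) {
  if (window %% 2 == 0) abort("delta_smoc: window must be odd",
                              class = "cryofit_invalid_parameter")
  ap <- scoring_atoms(prediction)
  at <- scoring_atoms(target)
  ap$kind <- residue_kind(ap$resname)
  at$kind <- residue_kind(at$resname)
  ap$key <- res_key(ap$chain, ap$resi, ap$icode)
  at$key <- res_key(at$chain, at$resi, at$icode)
  corr <- residue_correspondence(prediction, target)
  corr$key_p <- res_key(corr$chain, corr$resi, corr$icode)
  corr$key_t <- res_key(corr$chain_t, corr$resi_t, corr$icode_t)
  rp <- model_residues(prediction)
  min_len <- as.integer(ceiling(window / 2))
  results <- lapply(footprints, function(f)
    tibble::tibble(chain = rp$chain, resi = rp$resi, icode = rp$icode,
                   value = NA_real_))
  names(results) <- footprints
  for (ch in unique(rp$chain)) {
    idx_ch <- which(rp$chain == ch)
    rc <- rp[idx_ch, ]
    wins <- chain_windows(nrow(rc), window)
    for (w in wins) {
      if (is.null(w)) next
      keys_p <- res_key(rc$chain[w$members], rc$resi[w$members],
                        rc$icode[w$members])
      mc <- corr[corr$key_p %in% keys_p, ]
      if (nrow(mc) < min_len) next
      frag_p <- ap[ap$key %in% mc$key_p, ]
      frag_t <- at[at$key %in% mc$key_t, ]
      if (nrow(frag_p) == 0L || nrow(frag_t) == 0L) next
      tf <- fragment_superposition(frag_p, frag_t, mc)
      if (is.null(tf)) {
        warn("delta_smoc: degenerate fragment superposition; window skipped")
        next
      }
      frag_m <- frag_p
      xyz <- apply_transform(model_coords(frag_p), tf$rot, tf$trans)
      frag_m$x <- xyz[, 1]; frag_m$y <- xyz[, 2]; frag_m$z <- xyz[, 3]
      sim_p <- simulate_density(restore_model(frag_m, prediction), sim,
                                onto = exp_map)
      sim_t <- simulate_density(restore_model(frag_t, target), sim,
                                onto = exp_map)
      ckey_p <- res_key(rc$chain[w$ctr], rc$resi[w$ctr], rc$icode[w$ctr])
      ckey_t <- mc$key_t[match(ckey_p, mc$key_p)]
      for (f in footprints) {
        sel_p <- footprint_atoms(frag_m, f, ckey_p)
        sel_t <- footprint_atoms(frag_t, f, ckey_t)
        if (nrow(sel_p) == 0L || nrow(sel_t) == 0L) next
        fp_p <- segment_voxels(exp_map, model_coords(sel_p), radius)
        fp_t <- segment_voxels(exp_map, model_coords(sel_t), radius)
        if (length(fp_p) == 0L || length(fp_t) == 0L) next
        s_p <- moc(exp_map$data[fp_p], sim_p$data[fp_p])
        s_t <- moc(exp_map$data[fp_t], sim_t$data[fp_t])
        if (is.na(s_p) || is.na(s_t)) next
        results[[f]]$value[idx_ch[w$ctr]] <- s_p - s_t
      }
    }
  }
  results
}

footprint_atoms <- function(frag, footprint, central_key) {
  if (footprint == "all") return(frag)
  if (is.na(central_key)) return(frag[0, ])
  ctr <- frag[frag$key == central_key, ]
  bb <- is_backbone(ctr$atom, ctr$kind)
  if (footprint == "backbone") ctr[bb, ] else ctr[!bb, ]
}

# Kabsch over matched backbone atoms of a fragment pair; falls back to
# representative atoms when fewer than 3 backbone atoms match.  Exactly
# identical coordinate sets short-circuit to the identity so that a model
# scored against itself gives delta-SMOC of exactly zero.
fragment_superposition <- function(frag_p, frag_t, mc) {
  sup_names <- function(kind) {
    ifelse(kind == "nucleic", list(SUPERPOSE_NUC), list(SUPERPOSE_PROT))[[1]]
  }
  bp <- frag_p[frag_p$atom %in% c(SUPERPOSE_PROT, SUPERPOSE_NUC) &
                 is_backbone(frag_p$atom, frag_p$kind), ]
  bt <- frag_t[frag_t$atom %in% c(SUPERPOSE_PROT, SUPERPOSE_NUC) &
                 is_backbone(frag_t$atom, frag_t$kind), ]
  bp$key_t <- mc$key_t[match(bp$key, mc$key_p)]
  m <- dplyr::inner_join(
    dplyr::select(bp, "key_t", "atom", xp = "x", yp = "y", zp = "z"),
    dplyr::select(bt, key_t = "key", "atom", xt = "x", yt = "y", zt = "z"),
    by = c("key_t", "atom"))
  if (nrow(m) < 3) {
    # representative-atom fallback
    rp <- frag_p[(frag_p$kind == "amino" & frag_p$atom == "CA") |
                   (frag_p$kind == "nucleic" & frag_p$atom == "C4'"), ]
    rt <- frag_t[(frag_t$kind == "amino" & frag_t$atom == "CA") |
                   (frag_t$kind == "nucleic" & frag_t$atom == "C4'"), ]
    rp$key_t <- mc$key_t[match(rp$key, mc$key_p)]
    m <- dplyr::inner_join(
      dplyr::select(rp, "key_t", "atom", xp = "x", yp = "y", zp = "z"),
      dplyr::select(rt, key_t = "key", "atom", xt = "x", yt = "y", zt = "z"),
      by = c("key_t", "atom"))
    if (nrow(m) < 3) return(NULL)
  }
  mob <- cbind(m$xp, m$yp, m$zp); ref <- cbind(m$xt, m$yt, m$zt)
  if (max(abs(mob - ref)) < 1e-9) {
    return(list(rot = diag(3), trans = c(0, 0, 0), rmsd = 0))
  }
  tryCatch(kabsch_superpose(mob, ref), error = function(e) NULL)
}

#' Fragment-aligned delta-SMOC
#'
#' For each sliding window of the prediction, the fragment is superposed
#' onto the corresponding target residues (least-squares over matched
#' backbone atoms), and the difference between the fragment's SMOC and the
#' target residues' SMOC over the window footprint is assigned to the
#' central residue.  Fragment alignment removes global pose error, so the
#' score reflects purely local fit: positive values mean the prediction's
#' fragment explains the experimental density better than the target does.
#' Both fragments are simulated in isolation with the same parameters, so
#' a prediction identical to the target scores exactly zero everywhere.
#'
#' @inheritParams smoc
#' @param prediction,target [atomic_model()]s; residues are matched by
#'   author numbering (sequence-alignment fallback).
#' @return A [residue_track()] named `"dSMOC"` on the prediction's
#'   residues; windows with no resolvable correspondence are missing.
#' @export
delta_smoc <- function(prediction, target, exp_map, window = 11,
                       sim = sim_params(4), radius = 2.5) {
  res <- delta_smoc_engine(prediction, target, exp_map, window, sim,
                           radius, footprints = "all")
  as_track(res$all, name = "dSMOC", units = "score")
}

#' Backbone and sidechain delta-SMOC (high-resolution variant)
#'
#' The 5-residue, fragment-aligned variant used when sidechain density is
#' resolved: after the same fragment superposition as [delta_smoc()], the
#' score footprint is restricted to the central residue's backbone atoms
#' (N, CA, C, O, OXT) for the backbone track and to its remaining heavy
#' atoms (C-beta included) for the sidechain track.  Glycine has no
#' sidechain entry.  Combine with [exclude_by_locres()] to keep only
#' residues resolved better than 2.5 Angstroms.
#'
#' @inheritParams delta_smoc
#' @param window Odd window length; 5 is the high-resolution convention.
#' @return List of two [residue_track()]s: `backbone`, `sidechain`.
#' @export
backbone_sidechain_smoc <- function(prediction, target, exp_map, window = 5,
                                    sim = sim_params(2.5), radius = 2.5) {
  res <- delta_smoc_engine(prediction, target, exp_map, window, sim,
                           radius, footprints = c("backbone", "sidechain"))
  list(backbone = as_track(res$backbone, "backboneSMOC", "score"),
       sidechain = as_track(res$sidechain, "sidechainSMOC", "score"))
}
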