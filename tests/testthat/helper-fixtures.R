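# Fixtures are built in code; oracles here are deliberately independent,
# loop-based implementations of the quantities the package computes with
# vectorised / FFT code paths.

# Minimal model builder: one row per atom.
toy_model <- function(resi, atom, x, y, z, chain = "A", resname = "ALA",
                      element = NULL, bfield = 0, occ = 1, icode = "",
                      altloc = "", model_id = "toy") {
  element <- element %||% substr(atom, 1, 1)
  atomic_model(tibble::tibble(
    chain = chain, resi = as.integer(resi), icode = icode,
    resname = resname, atom = atom, element = element,
    x = x, y = y, z = z, occ = occ, bfield = bfield, altloc = altloc),
    model_id = model_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# CA-only ring model (used for TM-score geometry).
ca_ring <- function(n, radius = 50, dr = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  toy_model(resi = seq_len(n), atom = "CA",
            x = (radius + dr) * cos(th), y = (radius + dr) * sin(th),
            z = rep(0, n), element = "C")
}

# --- independent oracles ----------------------------------------------

# Manders overlap via explicit accumulation loops.
brute_moc <- function(a, b) {
  sab <- 0; saa <- 0; sbb <- 0
  for (i in seq_along(a)) {
    sab <- sab + a[i] * b[i]
    saa <- saa + a[i] * a[i]
    sbb <- sbb + b[i] * b[i]
  }
  if (saa == 0 || sbb == 0) return(NA_real_)
  sab / sqrt(saa * sbb)
}

# Footprint by brute force over every voxel of the grid.
brute_footprint <- function(grid, xyz, radius) {
  d <- dim(grid$data)
  out <- integer(0)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    centre <- grid$origin + (c(i, j, k) - 1) * grid$voxel
    for (a in seq_len(nrow(xyz))) {
      if (sum((centre - xyz[a, ])^2) <= radius^2) {
        out <- c(out, i + (j - 1) * d[1] + (k - 1) * d[1] * d[2])
        break
      }
    }
  }
  sort(unique(out))
}

# Sliding-window SMOC by brute force (single-chain models, residues 1..n).
brute_smoc <- function(model, exp_map, sim_map, window, radius) {
  n <- max(model$resi)
  h <- (window - 1) %/% 2
  min_len <- ceiling(window / 2)
  vals <- rep(NA_real_, n)
  for (ctr in seq_len(n)) {
    lo <- max(1, ctr - h); hi <- min(n, ctr + h)
    if (hi - lo + 1 < min_len) next
    sel <- model$resi >= lo & model$resi <= hi &
      !toupper(model$element) %in% c("H", "D", "T")
    xyz <- cbind(model$x[sel], model$y[sel], model$z[sel])
    fp <- brute_footprint(exp_map, xyz, radius)
    if (length(fp) == 0) next
    vals[ctr] <- brute_moc(exp_map$data[fp], sim_map$data[fp])
  }
  vals
}

# lDDT by explicit pair enumeration (models with identical atom lists).
brute_lddt <- function(model, reference, inclusion_radius = 15,
                       thresholds = c(0.5, 1, 2, 4)) {
  stopifnot(nrow(model) == nrow(reference))
  n <- nrow(model)
  res_scores <- list()
  total <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_res <- model$resi[i] == model$resi[j] &&
      model$chain[i] == model$chain[j] && model$icode[i] == model$icode[j]
    if (same_res) next
    dr <- sqrt(sum((c(reference$x[i], reference$y[i], reference$z[i]) -
                      c(reference$x[j], reference$y[j], reference$z[j]))^2))
    if (dr > inclusion_radius) next
    dm <- sqrt(sum((c(model$x[i], model$y[i], model$z[i]) -
                      c(model$x[j], model$y[j], model$z[j]))^2))
    sc <- mean(abs(dm - dr) < thresholds)
    total <- c(total, sc)
    for (r in unique(c(model$resi[i], model$resi[j]))) {
      res_scores[[as.character(r)]] <-
        c(res_scores[[as.character(r)]], sc)
    }
  }
  list(global = mean(total),
       per_res = vapply(res_scores, mean, numeric(1)))
}

# Uniform random proper rotation from a quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}
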