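#' Per-residue value tracks
#'
#' A `residue_track` is a tibble with one row per residue — columns
#' `chain`, `resi`, `icode`, `value` — plus `name` and `units` attributes.
#' Local resolution, RMSF, SMOC, delta-SMOC and accuracy estimates are all
#' carried this way, so they join and correlate uniformly.  Missing values
#' are kept as `NA` rows (they drop out of correlations); a missing value
#' is never coerced to 0, since 0 is a meaningful delta-SMOC.
#'
#' @param chain,resi,icode,value Parallel vectors (icode defaults empty).
#' @param name Track name, e.g. `"SMOC"`, `"RMSF"`, `"LocRes"`.
#' @param units `"A"`, `"score"`, or `"dimensionless"`.
#' @return A tibble of class `residue_track`.
#' @export
residue_track <- function(chain, resi, icode = "", value,
                          name = "track", units = "dimensionless") {
  tb <- tibble::tibble(chain = as.character(chain), resi = as.integer(resi),
                       icode = as.character(icode), value = as.numeric(value))
  key <- res_key(tb$chain, tb$resi, tb$icode)
  if (anyDuplicated(key)) {
    abort(paste0("residue_track: duplicate residue key(s): ",
                 paste(head(unique(key[duplicated(key)]), 3), collapse = ", ")))
  }
  if (any(is.infinite(tb$value))) {
    abort("residue_track: values must be finite or NA")
  }
  structure(tb, class = c("residue_track", class(tibble::tibble())),
            name = name, units = units)
}

as_track <- function(df, name, units) {
  residue_track(df$chain, df$resi, df$icode, df$value,
                name = name, units = units)
}

#' @export
print.residue_track <- function(x, ...) {
  cat(sprintf("<residue_track '%s' [%s]: %d residues, %d missing>\n",
              attr(x, "name") %||% "?", attr(x, "units") %||% "?",
              nrow(x), sum(is.na(x$value))))
  NextMethod()
}

# Inner-join two tracks on residue keys, keeping rows finite in both.
track_join <- function(a, b, suffixes = c("a", "b")) {
  j <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(a), value_a = "value"),
    dplyr::rename(tibble::as_tibble(b), value_b = "value"),
    by = c("chain", "resi", "icode"))
  dplyr::filter(j, is.finite(.data$value_a), is.finite(.data$value_b))
}

#' Pearson correlation between two residue tracks
#'
#' Computed over the intersection of residue keys with finite values in
#' both tracks.  With fewer than 3 shared residues, or zero variance in
#' either track, the correlation is reported missing with a reason rather
#' than raising.
#'
#' @param a,b [residue_track()]s.
#' @param absolute Return `|r|` (used for accuracy estimates whose
#'   direction varies between predictors).
#' @return One-row tibble: `pcc`, `n_residues`, `note`.
#' @export
track_pearson <- function(a, b, absolute = FALSE) {
  j <- track_join(a, b)
  n <- nrow(j)
  if (n < 3) {
    return(tibble::tibble(pcc = NA_real_, n_residues = n,
                          note = "fewer than 3 shared residues"))
  }
  if (sd(j$value_a) < 1e-12 || sd(j$value_b) < 1e-12) {
    return(tibble::tibble(pcc = NA_real_, n_residues = n,
                          note = "zero variance"))
  }
  r <- cor(j$value_a, j$value_b)
  tibble::tibble(pcc = if (absolute) abs(r) else r, n_residues = n, note = "")
}

#' Drop residues whose local resolution is worse than a cutoff
#'
#' High-resolution fit analyses are restricted to well-resolved residues;
#' entries whose local resolution exceeds `cutoff` (larger = worse) are
#' removed.  The 2.5 Angstrom default is the cutoff used for sidechain-level
#' assessment of high-resolution targets.
#'
#' @param track A score [residue_track()].
#' @param locres_track Local-resolution [residue_track()] (Angstroms).
#' @param cutoff Angstroms; keep residues with locres `<= cutoff`.
#' @return The filtered track.
#' @export
exclude_by_locres <- function(track, locres_track, cutoff = 2.5) {
  keep <- locres_track[!is.na(locres_track$value) &
                         locres_track$value <= cutoff, ]
  out <- dplyr::semi_join(tibble::as_tibble(track),
                          tibble::as_tibble(keep),
                          by = c("chain", "resi", "icode"))
  if (nrow(out) == 0L) warn("exclude_by_locres: no residues retained")
  as_track(out, name = attr(track, "name") %||% "track",
           units = attr(track, "units") %||% "dimensionless")
}
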