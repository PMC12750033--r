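#' Extract local accuracy estimates from a prediction
#'
#' Prediction files carry their per-residue accuracy estimate in the
#' B-factor column (pLDDT by convention; some predictors report a
#' positional error in Angstroms instead, where smaller is better).  The
#' representative atom's value is taken per residue — the same atom the
#' local-resolution projection samples.  The scale is auto-detected:
#' values within [0, 1.001] are unit pLDDT-like scores; within
#' (1.001, 100.5] percent scores, converted to unit; anything larger is
#' treated as a positional error in Angstroms with direction
#' lower-is-better.  Detection can be overridden.
#'
#' An all-zero B-factor column means no estimate was deposited (local
#' accuracy reporting is not mandatory for RNA); this raises a
#' distinguishable `cryofit_lae_absent` condition so pipelines can report
#' "not assessable" rather than a score of 0.
#'
#' @param model An [atomic_model()] with populated `bfield`.
#' @param scale `"auto"`, `"unit"`, `"percent"`, or `"error_angstrom"`.
#' @return A [residue_track()] named `"LAE"` with attributes `scale`
#'   (after conversion: `"unit"` or `"error_angstrom"`) and `direction`.
#' @export
extract_lae <- function(model, scale = c("auto", "unit", "percent",
                                         "error_angstrom")) {
  scale <- match.arg(scale)
  rs <- model_residues(model)
  rs <- rs[rs$usable, ]
  v <- rs$bfield
  if (all(!is.finite(v) | v == 0)) {
    abort("extract_lae: no accuracy estimates present",
          class = "cryofit_lae_absent")
  }
  if (scale == "auto") {
    mx <- max(v, na.rm = TRUE)
    scale <- if (mx <= 1.001) "unit" else if (mx <= 100.5) "percent"
             else "error_angstrom"
  }
  if (scale == "percent") {
    v <- v / 100
    scale <- "unit"
  }
  direction <- if (scale == "error_angstrom") "lower_better" else "higher_better"
  tr <- residue_track(rs$chain, rs$resi, rs$icode, v,
                      name = "LAE",
                      units = if (scale == "unit") "dimensionless" else "A")
  attr(tr, "scale") <- scale
  attr(tr, "direction") <- direction
  tr
}

#' Correlation of accuracy estimates with local resolution
#'
#' Absolute Pearson correlation between a model's local accuracy
#' estimates and the local resolution over shared residues.  The absolute
#' value deals with the opposing directionality of the different estimate
#' conventions (pLDDT: higher is better; positional error: lower is
#' better).
#'
#' @param track An LAE [residue_track()] from [extract_lae()].
#' @param locres_track Local-resolution [residue_track()].
#' @return One-row tibble: `pcc` (= |r|), `n_residues`, `note`.
#' @export
lae_locres_pcc <- function(track, locres_track) {
  track_pearson(track, locres_track, absolute = TRUE)
}
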