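#' Tidy an accuracy gate
#'
#' One row per model with its accuracy scores and pass flag.
#'
#' @param x A `cf_gate` from [gate_group()].
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.cf_gate <- function(x, ...) {
  dplyr::mutate(x$scores, group = x$group_id, .before = 1)
}

#' Glance at an accuracy gate
#'
#' One row per group: the worst score of each kind across the models and
#' whether the group passed.
#'
#' @param x A `cf_gate` from [gate_group()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
#' @exportS3Method generics::glance
glance.cf_gate <- function(x, ...) {
  tibble::tibble(
    group = x$group_id,
    n_models = nrow(x$scores),
    lddt_min_of_models = min(x$scores$lddt_global),
    tm_min_of_models = min(x$scores$tm),
    ips_min_of_models = if (x$is_multimer) min(x$scores$ips) else NA_real_,
    passed = x$passed)
}

#' @rdname tidy.cf_gate
#' @export
#' @exportS3Method generics::tidy
tidy.residue_track <- function(x, ...) tibble::as_tibble(x)
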