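#' Normalize one Ct profile to delta-Ct
#'
#' Converts raw Ct values of a single sample (or pooled group) to
#' delta-Ct = Ct - reference, under one of three strategies:
#'
#' * `global_mean` — reference is the arithmetic mean Ct of every detected
#'   assay in the sample, endogenous controls and spike-in included. This
#'   mean-centric normalization assumes the average expression of the full
#'   panel is constant across samples at equal RNA input; the resulting
#'   delta-Ct values average to zero by construction.
#' * `reference_genes` — reference is the mean Ct of the detected endogenous
#'   controls (snoRNA/snRNA assays); delta-Ct is reported for detected
#'   targets only.
#' * `spike_in` — reference is the Ct of the exogenous spike-in
#'   (cel-miR-39), tracking extraction efficiency; an undetermined spike-in
#'   is an error since it signals extraction failure.
#'
#' Detection requires a determined T with `Ct <= ct_max`; delta-Ct is left
#' undefined (absent) for undetected assays rather than imputed.
#'
#' @param profile named numeric Ct vector (`NA` = undetermined).
#' @param panel a `panel_definition`.
#' @param method normalization strategy.
#' @param ct_max detection cut-off in cycles.
#' @param id sample/group identifier carried into the result.
#' @return object of class `normalized_profile`: list with `id`, `method`,
#'   `reference_value` (the subtracted Ct statistic), `dct` (named vector of
#'   delta-Ct over the assays where it is defined), and `n_detected`.
#' @export
#' @examples
#' pan <- panel_definition(c("A", "B", "C"), "SNORD61", "cel-miR-39", c("A", "B"))
#' normalize_profile(c(A = 20, B = 22, C = 24), pan, "global_mean")
normalize_profile <- function(profile, panel,
                              method = c("global_mean", "reference_genes", "spike_in"),
                              ct_max = 35, id = "sample") {
  method <- match.arg(method)
  stopifnot(inherits(panel, "panel_definition"))
  profile <- profile[intersect(names(profile), panel_assays(panel))]
  detected <- !is.na(profile) & profile <= ct_max
  det <- profile[detected]

  if (method == "global_mean") {
    if (length(det) < 2L) stop("global Ct mean needs at least 2 detected assays")
    ref <- mean(det)
    dct <- det - ref
  } else if (method == "reference_genes") {
    ctrl <- det[intersect(names(det), panel$endogenous_controls)]
    n_missing <- length(panel$endogenous_controls) - length(ctrl)
    if (length(ctrl) == 0L) stop("no endogenous control detected")
    if (n_missing > 0L) {
      warning(n_missing, " endogenous control(s) undetected; reference mean uses ",
              length(ctrl))
    }
    ref <- mean(ctrl)
    dct <- det[intersect(names(det), panel$targets)] - ref
  } else {
    if (!panel$spike_in %in% names(det)) {
      stop("spike-in undetected: extraction failure")
    }
    ref <- unname(det[panel$spike_in])
    dct <- det[intersect(names(det), panel$targets)] - ref
  }

  structure(list(id = id, method = method, reference_value = unname(ref),
                 dct = dct, n_detected = length(det)),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("normalized_profile '%s' (%s): reference Ct %.3f, %d delta-Ct values\n",
              x$id, x$method, x$reference_value, length(x$dct)))
  invisible(x)
}

#' Normalize every column of a Ct matrix
#'
#' @param matrix a [ct_matrix()] (columns = samples or pooled groups).
#' @inheritParams normalize_profile
#' @return named list of [normalize_profile()] results, one per column.
#' @export
normalize_matrix <- function(matrix, panel, method = "global_mean", ct_max = 35) {
  out <- lapply(colnames(matrix), function(s) {
    normalize_profile(matrix[, s], panel, method, ct_max = ct_max, id = s)
  })
  names(out) <- colnames(matrix)
  out
}
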