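#' Hemolysis contamination index of a serum sample
#'
#' Erythrocytes are rich in miR-451a, so hemolysis lowers its Ct relative to
#' the hemolysis-insensitive miR-23a-3p. The index is
#' `Ct(numerator) - Ct(denominator)` over the panel's hemolysis pair
#' (conventionally miR-23a-3p minus miR-451a); a sample passes when the
#' index is strictly below the threshold.
#'
#' @param profile named numeric vector of Ct values for one sample
#'   (`NA` = undetermined).
#' @param panel a `panel_definition` whose `hemolysis_pair` names both assays.
#' @param threshold pass cut-off in cycles; pass iff `delta_ct < threshold`.
#' @return list with `delta_ct` (cycles, `NA` if either Ct undetermined) and
#'   `pass` (FALSE whenever `delta_ct` is not computable).
#' @export
#' @examples
#' pan <- default_serum_panel()
#' hemolysis_index(c("hsa-miR-23a-3p" = 24, "hsa-miR-451a" = 20), pan)
hemolysis_index <- function(profile, panel, threshold = 5) {
  stopifnot(inherits(panel, "panel_definition"))
  pair <- panel$hemolysis_pair
  miss <- setdiff(pair, names(profile))
  if (length(miss)) {
    stop("hemolysis pair assay absent from profile: ", paste(miss, collapse = ", "))
  }
  delta <- unname(profile[pair[1]] - profile[pair[2]])
  list(delta_ct = delta, pass = isTRUE(delta < threshold))
}

#' RNA purity check from spectrophotometric absorbance ratios
#'
#' Accepted ranges (inclusive): A260/280 in \[1.9, 2.1\], A260/230 in
#' \[2.0, 2.2\]. A missing ratio yields `NA` ("unknown"), not failure.
#'
#' @param a260_280,a260_230 absorbance ratios, or `NA` if unmeasured.
#' @return list with logical `pass_260_280`, `pass_260_230` (`NA` = unknown)
#'   and `pass`, the conjunction treating unknown as unknown.
#' @export
purity_check <- function(a260_280 = NA_real_, a260_230 = NA_real_) {
  chk <- function(x, lo, hi) {
    if (is.na(x)) return(NA)
    if (x <= 0) stop("absorbance ratio must be positive")
    x >= lo && x <= hi
  }
  p1 <- chk(a260_280, 1.9, 2.1)
  p2 <- chk(a260_230, 2.0, 2.2)
  overall <- if (isFALSE(p1) || isFALSE(p2)) FALSE else if (is.na(p1) || is.na(p2)) NA else TRUE
  list(pass_260_280 = p1, pass_260_230 = p2, pass = overall)
}

#' Restrict a Ct matrix to detected reactions
#'
#' A cell is detected iff its Ct is determined and `<= ct_max`; reactions
#' with Ct above the cut-off are treated as absent from the profile, per the
#' convention that raw Ct values above 35 are excluded from serum miRNA
#' analysis.
#'
#' @param matrix a [ct_matrix()] (or plain named numeric matrix).
#' @param ct_max detection cut-off in cycles.
#' @return list with `values` (matrix with undetected cells set to `NA`)
#'   and `mask` (logical detection matrix).
#' @export
filter_detected <- function(matrix, ct_max = 35) {
  vals <- unclass(matrix)
  attr(vals, "groups") <- NULL
  mask <- !is.na(vals) & vals <= ct_max
  out <- vals
  out[!mask] <- NA_real_
  list(values = out, mask = mask)
}

#' Expression-tier counts for one profile
#'
#' Tiers over target assays only (controls and spike-in excluded):
#' high `Ct <= 25`; moderate `25 < Ct <= 30`; low `30 < Ct <= 35`;
#' undetected `Ct > 35` or undetermined.
#'
#' @param profile named numeric Ct vector for one sample or pooled group.
#' @param panel a `panel_definition`.
#' @return named integer vector `c(high, moderate, low, undetected)` summing
#'   to the number of panel targets.
#' @export
expression_tiers <- function(profile, panel) {
  stopifnot(inherits(panel, "panel_definition"))
  ct <- profile[panel$targets]          # absent assays become NA
  c(high = sum(!is.na(ct) & ct <= 25),
    moderate = sum(!is.na(ct) & ct > 25 & ct <= 30),
    low = sum(!is.na(ct) & ct > 30 & ct <= 35),
    undetected = sum(is.na(ct) | ct > 35))
}

#' Per-sample quality-control report
#'
#' One row per sample: hemolysis index and pass flag, optional purity
#' ratios, detected-assay count at `ct_max`, and expression-tier counts
#' over the panel targets.
#'
#' @param matrix a [ct_matrix()].
#' @param panel a `panel_definition`.
#' @param ct_max detection cut-off (cycles).
#' @param hemolysis_threshold hemolysis pass cut-off (cycles).
#' @param purity optional data.frame with columns `sample`, `a260_280`,
#'   `a260_230`.
#' @return data.frame of class `qc_report`.
#' @export
qc_report <- function(matrix, panel, ct_max = 35, hemolysis_threshold = 5,
                      purity = NULL) {
  stopifnot(inherits(matrix, "ct_matrix"))
  samples <- colnames(matrix)
  rows <- lapply(samples, function(s) {
    prof <- matrix[, s]
    hem <- hemolysis_index(prof, panel, hemolysis_threshold)
    tiers <- expression_tiers(prof, panel)
    det <- filter_detected(matrix[, s, drop = FALSE], ct_max)
    pr <- c(a260_280 = NA_real_, a260_230 = NA_real_)
    if (!is.null(purity)) {
      i <- match(s, purity$sample)
      if (!is.na(i)) pr <- c(a260_280 = purity$a260_280[i], a260_230 = purity$a260_230[i])
    }
    pc <- purity_check(pr["a260_280"], pr["a260_230"])
    data.frame(sample = s, group = ct_groups(matrix)[s],
               hemolysis_delta_ct = hem$delta_ct, hemolysis_pass = hem$pass,
               purity_260_280 = unname(pr["a260_280"]),
               purity_260_230 = unname(pr["a260_230"]),
               purity_pass = if (is.na(pc$pass)) NA else pc$pass,
               n_detected = sum(det$mask),
               tier_high = tiers[["high"]], tier_moderate = tiers[["moderate"]],
               tier_low = tiers[["low"]], tier_undetected = tiers[["undetected"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qc_report", "data.frame")
  out
}
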