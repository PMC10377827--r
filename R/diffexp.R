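#' Per-assay delta-delta-Ct between two normalized profiles
#'
#' `ddct(m) = dct_test(m) - dct_ref(m)` for assays with a defined delta-Ct in
#' both profiles; assays undetected in either profile are kept with `NA`
#' delta-delta-Ct and are flagged not evaluable downstream.
#'
#' @param test_profile,ref_profile `normalized_profile` objects produced with
#'   the same normalization method.
#' @param assays optional assay universe to report over (default: union of
#'   the two profiles' assays).
#' @return data.frame with columns `mirna`, `ddct`, `evaluable`.
#' @export
delta_delta_ct <- function(test_profile, ref_profile, assays = NULL) {
  stopifnot(inherits(test_profile, "normalized_profile"),
            inherits(ref_profile, "normalized_profile"))
  if (test_profile$method != ref_profile$method) {
    stop("profiles normalized by different methods: ",
         test_profile$method, " vs ", ref_profile$method)
  }
  if (is.null(assays)) {
    assays <- union(names(test_profile$dct), names(ref_profile$dct))
  }
  dt <- test_profile$dct[assays]
  dr <- ref_profile$dct[assays]
  ddct <- unname(dt - dr)
  data.frame(mirna = assays, ddct = ddct, evaluable = !is.na(ddct),
             stringsAsFactors = FALSE)
}

#' Fold change and signed fold regulation from delta-delta-Ct
#'
#' Fold change is `2^(-ddct)`, always positive. Fold regulation rescales
#' down-regulation onto a signed magnitude: `FR = FC` when `FC >= 1`,
#' otherwise `FR = -1/FC`, so `|FR| >= 1` and `FR = +1` at no change.
#'
#' @param ddct numeric vector of delta-delta-Ct values (cycles).
#' @return data.frame with columns `fold_change`, `fold_regulation`.
#' @export
#' @examples
#' fold_regulation(c(-1, 0, 1))   # FR +2, +1, -2
fold_regulation <- function(ddct) {
  fc <- 2^(-ddct)
  fr <- ifelse(fc >= 1, fc, -1 / fc)
  data.frame(fold_change = fc, fold_regulation = fr)
}

#' Classify a contrast's records at a fold-regulation threshold
#'
#' Labels each miRNA `up` when `FR >= up_threshold`, `down` when
#' `FR <= -up_threshold` and `unchanged` otherwise, evaluating fold
#' regulation at printed precision (2 decimals) so that table entries
#' printed exactly at the threshold are included. Records without an
#' evaluable fold regulation propagate as `not_evaluable`.
#'
#' @param records data.frame with a `fold_regulation` column (and optionally
#'   `mirna`, `ddct`, `fold_change`, `evaluable`).
#' @param up_threshold positive threshold on |fold regulation|.
#' @return the records with a `label` factor column
#'   (`up`/`down`/`unchanged`/`not_evaluable`).
#' @export
classify_contrast <- function(records, up_threshold = 2) {
  stopifnot(up_threshold >= 1)
  fr <- round(records$fold_regulation, 2)
  label <- ifelse(is.na(fr), "not_evaluable",
                  ifelse(fr >= up_threshold, "up",
                         ifelse(fr <= -up_threshold, "down", "unchanged")))
  records$label <- factor(label, levels = c("up", "down", "unchanged", "not_evaluable"))
  records
}

#' Full comparison of two normalized profiles
#'
#' Composes [delta_delta_ct()], [fold_regulation()] and [classify_contrast()]
#' over a panel's target assays.
#'
#' @inheritParams delta_delta_ct
#' @param panel a `panel_definition`; comparison is restricted to its targets.
#' @param up_threshold classification threshold on |fold regulation|.
#' @return data.frame of class `mirna_comparison` with columns `mirna`,
#'   `ddct`, `fold_change`, `fold_regulation`, `label`, plus a `contrast`
#'   attribute `"test_vs_ref"`.
#' @export
compare_profiles <- function(test_profile, ref_profile, panel, up_threshold = 2) {
  dd <- delta_delta_ct(test_profile, ref_profile, assays = panel$targets)
  fr <- fold_regulation(dd$ddct)
  rec <- classify_contrast(cbind(dd, fr), up_threshold)
  attr(rec, "contrast") <- paste0(test_profile$id, "_vs_", ref_profile$id)
  class(rec) <- c("mirna_comparison", "data.frame")
  rec
}

#' High-stringency signature: large fold regulation in any contrast
#'
#' Selects miRNAs whose absolute fold regulation reaches `threshold` in at
#' least one of the supplied case-vs-reference contrasts (the "arbitrary
#' cut-off of 10" rule used to call considerably different expression).
#'
#' @param case_contrasts named list of record data.frames (each with
#'   `mirna`, `fold_regulation`), all sharing the reference group.
#' @param threshold cut-off on |fold regulation|.
#' @return object of class `signature_set` with `rule`, `members` (IDs) and
#'   `evidence` (per-contrast fold regulations, wide data.frame).
#' @export
high_stringency_set <- function(case_contrasts, threshold = 10) {
  if (length(case_contrasts) == 0L) stop("at least one contrast is required")
  if (is.null(names(case_contrasts))) {
    names(case_contrasts) <- paste0("contrast", seq_along(case_contrasts))
  }
  ev <- .fr_wide(case_contrasts)
  hit <- apply(abs(ev[-1]) >= threshold, 1, any, na.rm = TRUE)
  signature_set("high_stringency", ev$mirna[hit], ev[hit, , drop = FALSE],
                threshold = threshold)
}

#' Progression signature: strictly increasing fold regulation
#'
#' Selects miRNAs whose fold regulation against the shared control reference
#' increases strictly from the intermediate condition to the overt one,
#' with the overt-condition fold regulation at least `min_fr` — markers of
#' progression (e.g. from impaired fasting glucose to overt diabetes).
#' Both contrasts must be evaluable for a miRNA to qualify.
#'
#' @param ifg_vs_ctrl,t2d_vs_ctrl record data.frames for the intermediate
#'   and overt condition, each against the same control group.
#' @param min_fr floor on the overt-condition fold regulation.
#' @return a `signature_set` (rule `"progression"`).
#' @export
progression_signature <- function(ifg_vs_ctrl, t2d_vs_ctrl, min_fr = 2) {
  ev <- .fr_wide(list(ifg = ifg_vs_ctrl, t2d = t2d_vs_ctrl))
  hit <- !is.na(ev$ifg) & !is.na(ev$t2d) & ev$t2d > ev$ifg & ev$t2d >= min_fr
  signature_set("progression", ev$mirna[hit], ev[hit, , drop = FALSE],
                min_fr = min_fr)
}

#' Condition-specific signature: regulated in one condition only
#'
#' Selects miRNAs differentially regulated (|FR| at or above `threshold`)
#' in the focal condition but not in the other condition
#' (|FR| below `threshold`, or absent/unchanged), with a concordant
#' direction of change when the other condition shows any trend.
#'
#' @param focal_vs_ctrl,other_vs_ctrl record data.frames sharing the control
#'   reference.
#' @param threshold fold-regulation threshold defining "regulated".
#' @return a `signature_set` (rule `"condition_specific"`) whose evidence
#'   carries a `direction` column (`up`/`down` in the focal condition).
#' @export
condition_specific_set <- function(focal_vs_ctrl, other_vs_ctrl, threshold = 2) {
  ev <- .fr_wide(list(focal = focal_vs_ctrl, other = other_vs_ctrl))
  focal_hit <- !is.na(ev$focal) & abs(ev$focal) >= threshold
  other_quiet <- is.na(ev$other) | abs(ev$other) < threshold
  concordant <- is.na(ev$other) | sign(ev$other) == sign(ev$focal)
  hit <- focal_hit & other_quiet & concordant
  ev$direction <- ifelse(ev$focal >= 0, "up", "down")
  signature_set("condition_specific", ev$mirna[hit], ev[hit, , drop = FALSE],
                threshold = threshold)
}

# align fold regulations of several contrasts into one wide frame
.fr_wide <- function(contrasts) {
  ids <- unique(unlist(lapply(contrasts, function(d) d$mirna)))
  out <- data.frame(mirna = ids, stringsAsFactors = FALSE)
  for (nm in names(contrasts)) {
    d <- contrasts[[nm]]
    out[[nm]] <- d$fold_regulation[match(ids, d$mirna)]
  }
  out
}

signature_set <- function(rule, members, evidence, ...) {
  rownames(evidence) <- NULL
  structure(list(rule = rule, members = members, evidence = evidence,
                 params = list(...)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set [%s]: %d miRNA(s)\n", x$rule, length(x$members)))
  if (length(x$members)) print(utils::head(x$evidence, 10))
  invisible(x)
}

#' Concordance between normalization methods
#'
#' For each alternative method, over the miRNAs evaluable under both it and
#' the baseline method: the fraction with identical classification label,
#' the fraction with identical fold-regulation sign, and the count of
#' miRNAs where the baseline |FR| does not exceed the alternative |FR|
#' (mean-centric normalization is expected to be the more conservative).
#'
#' @param results_by_method named list of classified record data.frames for
#'   the same contrast, one per normalization method.
#' @param baseline name of the baseline method (default `"global_mean"`).
#' @return data.frame of class `concordance_report`, one row per method pair.
#' @export
normalization_concordance <- function(results_by_method, baseline = "global_mean") {
  stopifnot(length(results_by_method) >= 2, baseline %in% names(results_by_method))
  base <- results_by_method[[baseline]]
  others <- setdiff(names(results_by_method), baseline)
  rows <- lapply(others, function(nm) {
    oth <- results_by_method[[nm]]
    common <- intersect(base$mirna[!is.na(base$fold_regulation)],
                        oth$mirna[!is.na(oth$fold_regulation)])
    if (length(common) == 0L) stop("no shared evaluable miRNA between methods")
    b <- base[match(common, base$mirna), ]
    o <- oth[match(common, oth$mirna), ]
    data.frame(method_pair = paste(baseline, nm, sep = " vs "),
               n = length(common),
               label_agreement = mean(as.character(b$label) == as.character(o$label)),
               sign_agreement = mean(sign(b$fold_regulation) == sign(o$fold_regulation)),
               n_baseline_not_larger = sum(abs(b$fold_regulation) <= abs(o$fold_regulation)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("concordance_report", "data.frame")
  out
}
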