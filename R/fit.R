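#' Fit a fold-regulation analysis to a Ct cohort
#'
#' The package's central estimator: takes raw per-sample Ct values, runs
#' quality control, pools each group's samples into one profile on the
#' linear scale (mirroring equimolar RNA pooling), normalizes the pooled
#' profiles, and estimates per-miRNA delta-delta-Ct, fold change and signed
#' fold regulation for every group contrast, together with the
#' threshold-based signatures (high-stringency, progression,
#' condition-specific).
#'
#' Contrasts are formed against the `reference` group first and then
#' between case groups, in the order groups appear in the data; for groups
#' `control, IFG, T2D` this yields `IFG vs control`, `T2D vs control` and
#' `T2D vs IFG`. With exactly two case groups the progression signature
#' treats them (in order) as the intermediate and overt condition, and the
#' condition-specific signature is computed for each case group against the
#' other.
#'
#' @param ct a [ct_matrix()] of raw per-sample Ct values. If every group
#'   has a single sample the matrix is taken as already pooled.
#' @param panel a [panel_definition()].
#' @param reference reference group label (default: first group).
#' @param method normalization strategy, see [normalize_profile()].
#' @param ct_max detection cut-off in cycles.
#' @param fr_threshold classification threshold on |fold regulation|.
#' @param stringency_threshold high-stringency signature threshold.
#' @param hemolysis_threshold QC hemolysis pass cut-off in cycles.
#' @param strict_qc error (rather than flag) when a sample fails hemolysis QC.
#' @return object of class `mirct_fit` with elements `qc`, `pooled`
#'   (group-level `ct_matrix`), `profiles` (normalized), `comparisons`
#'   (named list of `mirna_comparison`), `signatures`, and `call`.
#' @seealso [coef.mirct_fit()], [summary.mirct_fit()], [plot.mirct_fit()]
#' @export
mirct_fit <- function(ct, panel, reference = NULL,
                      method = c("global_mean", "reference_genes", "spike_in"),
                      ct_max = 35, fr_threshold = 2, stringency_threshold = 10,
                      hemolysis_threshold = 5, strict_qc = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(ct, "ct_matrix"), inherits(panel, "panel_definition"))
  groups <- unique(ct_groups(ct))
  if (length(groups) < 2) stop("at least two groups are required for a contrast")
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) stop("reference group not present: ", reference)

  qc <- qc_report(ct, panel, ct_max = ct_max,
                  hemolysis_threshold = hemolysis_threshold)
  if (strict_qc && any(!qc$hemolysis_pass)) {
    stop("hemolysis QC failure in sample(s): ",
         paste(qc$sample[!qc$hemolysis_pass], collapse = ", "))
  }

  pooled <- if (all(table(ct_groups(ct)) == 1L)) {
    m <- unclass(ct); colnames(m) <- ct_groups(ct)
    ct_matrix(m, colnames(m), panel = panel)
  } else {
    pool_cohort(ct, panel = panel)
  }

  profiles <- normalize_matrix(pooled, panel, method = method, ct_max = ct_max)

  cases <- setdiff(groups, reference)
  pairs <- rbind(
    if (length(cases)) data.frame(test = cases, ref = reference),
    if (length(cases) > 1) {
      cmb <- utils::combn(cases, 2)
      data.frame(test = cmb[2, ], ref = cmb[1, ])
    }
  )
  comparisons <- lapply(seq_len(nrow(pairs)), function(i) {
    compare_profiles(profiles[[pairs$test[i]]], profiles[[pairs$ref[i]]],
                     panel, up_threshold = fr_threshold)
  })
  names(comparisons) <- paste0(pairs$test, "_vs_", pairs$ref)

  vs_ref <- comparisons[paste0(cases, "_vs_", reference)]
  signatures <- list(high_stringency = high_stringency_set(vs_ref, stringency_threshold))
  if (length(cases) == 2) {
    signatures$progression <- progression_signature(vs_ref[[1]], vs_ref[[2]],
                                                    min_fr = fr_threshold)
    signatures$condition_specific <- stats::setNames(
      list(condition_specific_set(vs_ref[[2]], vs_ref[[1]], fr_threshold),
           condition_specific_set(vs_ref[[1]], vs_ref[[2]], fr_threshold)),
      c(cases[2], cases[1]))
  }

  structure(list(qc = qc, pooled = pooled, profiles = profiles,
                 comparisons = comparisons, signatures = signatures,
                 panel = panel, reference = reference, method = method,
                 thresholds = list(ct_max = ct_max, fr = fr_threshold,
                                   stringency = stringency_threshold,
                                   hemolysis = hemolysis_threshold),
                 call = match.call()),
            class = "mirct_fit")
}

#' @export
print.mirct_fit <- function(x, ...) {
  cat("Fold-regulation analysis of qPCR Ct profiles\n")
  cat(sprintf("  normalization: %s; reference group: %s\n", x$method, x$reference))
  cat(sprintf("  %d target assays, %d contrasts\n",
              length(x$panel$targets), length(x$comparisons)))
  for (nm in names(x$comparisons)) {
    tab <- table(x$comparisons[[nm]]$label)
    cat(sprintf("  %-22s up %3d  down %3d  unchanged %3d  not evaluable %3d\n",
                nm, tab[["up"]], tab[["down"]], tab[["unchanged"]],
                tab[["not_evaluable"]]))
  }
  invisible(x)
}

#' Fold-regulation matrix of a fitted analysis
#'
#' @param object a `mirct_fit`.
#' @param ... unused.
#' @return numeric matrix, target miRNAs x contrasts, of signed fold
#'   regulations (`NA` where not evaluable).
#' @export
coef.mirct_fit <- function(object, ...) {
  sapply(object$comparisons, function(d) {
    stats::setNames(d$fold_regulation, d$mirna)[object$panel$targets]
  })
}

#' Summarize a fitted fold-regulation analysis
#'
#' @param object a `mirct_fit`.
#' @param ... unused.
#' @return list of class `summary.mirct_fit`: per-contrast classification
#'   counts, signature membership counts, and QC failures.
#' @export
summary.mirct_fit <- function(object, ...) {
  counts <- t(sapply(object$comparisons, function(d) table(d$label)))
  sig <- vapply(object$signatures, function(s) {
    if (inherits(s, "signature_set")) length(s$members) else NA_integer_
  }, integer(1))
  out <- list(method = object$method, reference = object$reference,
              classification_counts = counts,
              signature_sizes = sig,
              qc_failed = object$qc$sample[!object$qc$hemolysis_pass],
              thresholds = object$thresholds)
  class(out) <- "summary.mirct_fit"
  out
}

#' @export
print.summary.mirct_fit <- function(x, ...) {
  cat("Classification counts (|FR| threshold", x$thresholds$fr, "):\n")
  print(x$classification_counts)
  cat("\nSignature sizes:\n")
  print(x$signature_sizes)
  if (length(x$qc_failed)) {
    cat("\nHemolysis QC failures:", paste(x$qc_failed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Log-log scatter plot of a contrast
#'
#' Plots linearized expression (`2^-dCt`) of the test group against the
#' reference group, on log axes, coloring up- and down-regulated miRNAs.
#'
#' @param x a `mirct_fit`.
#' @param contrast contrast name (default: first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.mirct_fit <- function(x, contrast = names(x$comparisons)[1], ...) {
  sp <- scatter_data_fit(x, contrast)
  col <- c(up = "firebrick", down = "forestgreen", unchanged = "grey30")[as.character(sp$label)]
  graphics::plot(sp$x, sp$y, log = "xy", pch = 20, col = col,
                 xlab = "reference group 2^-dCt", ylab = "test group 2^-dCt",
                 main = contrast, ...)
  graphics::abline(0, 1, untf = TRUE, lty = 2, col = "grey60")
  invisible(sp)
}
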