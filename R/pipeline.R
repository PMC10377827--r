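#' Scatter-plot data for a contrast
#'
#' One point per evaluable miRNA: linearized expression `2^-dCt` in the
#' reference group (x) and test group (y), with the classification label at
#' the given threshold. Suitable for log-log plotting.
#'
#' @param test_profile,ref_profile `normalized_profile` objects (same method).
#' @param panel a `panel_definition`.
#' @param fr_threshold classification threshold.
#' @return data.frame with columns `mirna`, `x`, `y`, `label`.
#' @export
scatter_data <- function(test_profile, ref_profile, panel, fr_threshold = 2) {
  rec <- compare_profiles(test_profile, ref_profile, panel, fr_threshold)
  rec <- rec[rec$evaluable, ]
  data.frame(mirna = rec$mirna,
             x = 2^(-ref_profile$dct[rec$mirna]),
             y = 2^(-test_profile$dct[rec$mirna]),
             label = rec$label, row.names = NULL)
}

# scatter data from a fitted object's stored profiles
scatter_data_fit <- function(fit, contrast) {
  stopifnot(contrast %in% names(fit$comparisons))
  parts <- strsplit(contrast, "_vs_")[[1]]
  scatter_data(fit$profiles[[parts[1]]], fit$profiles[[parts[2]]],
               fit$panel, fit$thresholds$fr)
}

#' Run the full analysis pipeline from a config
#'
#' Orchestrates the end-to-end run: obtain a cohort (from a Ct CSV or by
#' simulation), QC, pool, normalize, compare all contrasts, derive
#' signatures and concordance across normalization methods, and emit
#' scatter data plus a run manifest. A `fixtures` config instead ingests
#' printed fold-regulation tables directly (no raw Ct needed) and computes
#' classification counts and signatures from them.
#'
#' @param config list (or path to a YAML/JSON file) with fields:
#'   * `panel`: path to a panel config, or `"default"`;
#'   * one of `ct_csv` (+ `layout`), `simulate` (list of [sim_config()]
#'     arguments), or `fixtures` (named list of comparison TSV paths with
#'     entries `ifg_vs_control`, `t2d_vs_control`, `t2d_vs_ifg`, or
#'     `"packaged"` to use the shipped tables);
#'   * optional `reference`, `method`, `methods` (for concordance),
#'     `ct_max`, `fr_threshold`, `stringency_threshold`, `seed`;
#'   * optional `out_dir`: directory to write TSV/JSON artifacts into.
#' @return list (results bundle): `fit` (a [mirct_fit()], unless in fixture
#'   mode), `signatures`, `classification_counts`, `concordance` (when
#'   several methods are configured), `scatter`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
      else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))

  panel <- if (is.null(config$panel) || identical(config$panel, "default")) {
    default_serum_panel()
  } else if (inherits(config$panel, "panel_definition")) config$panel
    else load_panel(config$panel, quiet = TRUE)

  fr_thr <- config$fr_threshold %||% 2
  hs_thr <- config$stringency_threshold %||% 10
  ct_max <- config$ct_max %||% 35
  seed <- config$seed %||% 1

  manifest <- list(package_version = as.character(utils::packageVersion("mirct")),
                   seed = seed, fr_threshold = fr_thr,
                   stringency_threshold = hs_thr, ct_max = ct_max,
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # ---- fixture mode: printed tables in, signatures out -------------------
  if (!is.null(config$fixtures)) {
    fx <- if (identical(config$fixtures, "packaged")) packaged_fixtures()
      else lapply(config$fixtures, read_comparison_fixture)
    fx <- lapply(fx, classify_contrast, up_threshold = fr_thr)
    counts <- t(sapply(fx, function(d) table(d$label)))
    note("fixtures", rows = vapply(fx, nrow, integer(1)))

    vs_ctrl <- fx[intersect(c("ifg_vs_control", "t2d_vs_control"), names(fx))]
    sigs <- list(high_stringency = high_stringency_set(vs_ctrl, hs_thr))
    if (length(vs_ctrl) == 2) {
      sigs$progression <- progression_signature(vs_ctrl[[1]], vs_ctrl[[2]], fr_thr)
      # narrative sub-threshold values refine the "other condition" evidence
      ifg_full <- vs_ctrl[[1]]
      if (!is.null(fx$ifg_vs_control_narrative)) {
        extra <- fx$ifg_vs_control_narrative
        extra <- extra[!extra$mirna %in% ifg_full$mirna, ]
        ifg_full <- rbind(ifg_full[names(extra)], extra)
      }
      sigs$condition_specific <- condition_specific_set(vs_ctrl[[2]], ifg_full, fr_thr)
    }
    bundle <- list(fit = NULL, signatures = sigs,
                   classification_counts = counts, fixtures = fx,
                   manifest = manifest)
    return(.emit_bundle(bundle, config$out_dir))
  }

  # ---- raw-Ct or simulation mode ----------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- NULL
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_cohort(cfg, seed = seed)
    ct <- sim$ct; panel <- sim$panel; truth <- sim$truth
    note("simulate", assays = nrow(ct), samples = ncol(ct))
  } else if (!is.null(config$ct_csv)) {
    ct <- read_ct_table(config$ct_csv, layout = config$layout %||% "long", panel)
    note("read", assays = nrow(ct), samples = ncol(ct))
  } else {
    stop("config must provide one of: ct_csv, simulate, fixtures")
  }

  method <- config[["method"]] %||% "global_mean"
  fit <- mirct_fit(ct, panel, reference = config$reference,
                   method = method, ct_max = ct_max, fr_threshold = fr_thr,
                   stringency_threshold = hs_thr)
  note("fit", contrasts = length(fit$comparisons),
       qc_failures = sum(!fit$qc$hemolysis_pass))

  concordance <- NULL
  methods <- config[["methods"]]
  if (!is.null(methods) && length(methods) > 1) {
    first_contrast <- names(fit$comparisons)[1]
    by_method <- lapply(methods, function(m) {
      f <- mirct_fit(ct, panel, reference = config$reference, method = m,
                     ct_max = ct_max, fr_threshold = fr_thr,
                     stringency_threshold = hs_thr)
      f$comparisons[[first_contrast]]
    })
    names(by_method) <- methods
    concordance <- normalization_concordance(by_method)
  }

  scatter <- lapply(names(fit$comparisons), function(nm) scatter_data_fit(fit, nm))
  names(scatter) <- names(fit$comparisons)

  bundle <- list(fit = fit,
                 signatures = fit$signatures,
                 classification_counts = summary(fit)$classification_counts,
                 concordance = concordance, scatter = scatter,
                 truth = truth, manifest = manifest)
  .emit_bundle(bundle, config$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.emit_bundle <- function(bundle, out_dir) {
  if (is.null(out_dir)) return(bundle)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$fit)) {
    for (nm in names(bundle$fit$comparisons)) {
      write_comparison_table(bundle$fit$comparisons[[nm]],
                             file.path(out_dir, paste0("comparison_", nm, ".tsv")))
    }
    utils::write.table(bundle$fit$qc, file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$scatter)) {
    for (nm in names(bundle$scatter)) {
      utils::write.table(bundle$scatter[[nm]],
                         file.path(out_dir, paste0("scatter_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  counts <- bundle$classification_counts
  jsonlite::write_json(
    list(classification_counts = as.data.frame.matrix(counts),
         signature_members = lapply(
           Filter(function(s) inherits(s, "signature_set"), bundle$signatures),
           function(s) s$members),
         manifest = bundle$manifest),
    file.path(out_dir, "results.json"), auto_unbox = TRUE, pretty = TRUE)
  bundle
}
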