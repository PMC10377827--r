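#' Screen a subject record against the enrollment exclusion criteria
#'
#' Exclusion criteria for a biomarker-discovery cohort free of confounders:
#' ongoing inflammation (CRP > 6 mg/L or ESR > 30 mm/h), obesity
#' (BMI > 30 kg/m^2), poor glycemic control (HbA1c > 8%), moderate-to-severe
#' hypertriglyceridemia (> 175 mg/dL), smoking, alcohol or drug use, and
#' renal impairment (eGFR < 60 mL/min/1.73 m^2 or microalbuminuria).
#' A missing field leaves its criterion unknown rather than violated.
#'
#' @param record list or one-row data.frame with (any of) fields `crp`,
#'   `esr`, `bmi`, `hba1c`, `triglycerides`, `egfr`, `smoking`, `alcohol`,
#'   `drug_use`, `microalbuminuria`.
#' @return list with `eligible` (TRUE/FALSE/NA if any criterion unknown and
#'   none violated), `violations` (character), `unknown` (character).
#' @export
#' @examples
#' screen_eligibility(list(bmi = 29, crp = 3, esr = 9, hba1c = 6.2,
#'                         triglycerides = 120, egfr = 90, smoking = FALSE,
#'                         alcohol = FALSE, drug_use = FALSE,
#'                         microalbuminuria = FALSE))
screen_eligibility <- function(record) {
  record <- as.list(record)
  get <- function(f) if (is.null(record[[f]]) || is.na(record[[f]])) NA else record[[f]]
  criteria <- list(
    "inflammation (CRP > 6 mg/L)"        = function() get("crp") > 6,
    "inflammation (ESR > 30 mm/h)"       = function() get("esr") > 30,
    "obesity (BMI > 30 kg/m2)"           = function() get("bmi") > 30,
    "poor glycemic control (HbA1c > 8%)" = function() get("hba1c") > 8,
    "hypertriglyceridemia (TG > 175 mg/dL)" = function() get("triglycerides") > 175,
    "smoking"                            = function() isTRUE(get("smoking")),
    "alcohol use"                        = function() isTRUE(get("alcohol")),
    "drug use"                           = function() isTRUE(get("drug_use")),
    "renal impairment (eGFR < 60 mL/min/1.73 m2)" = function() get("egfr") < 60,
    "renal impairment (microalbuminuria)" = function() isTRUE(get("microalbuminuria"))
  )
  fields <- c("crp", "esr", "bmi", "hba1c", "triglycerides",
              "smoking", "alcohol", "drug_use", "egfr", "microalbuminuria")
  status <- vapply(seq_along(criteria), function(i) {
    if (i %in% c(6, 7, 8, 10) && is.na(get(fields[i]))) return(NA)   # flags
    v <- criteria[[i]]()
    if (is.na(v)) NA else v
  }, logical(1))
  violations <- names(criteria)[!is.na(status) & status]
  unknown <- names(criteria)[is.na(status)]
  eligible <- if (length(violations)) FALSE else if (length(unknown)) NA else TRUE
  list(eligible = eligible, violations = violations, unknown = unknown)
}

#' Packaged clinical summary fixture
#'
#' The median (IQR) clinical and laboratory characteristics of the
#' three-group dysglycemia cohort the packaged fold-regulation tables come
#' from, as printed — a display fixture for layout comparisons (the
#' underlying subject-level data are not published, so these summaries are
#' not recomputable).
#'
#' @return data.frame with columns `parameter`, `control`, `ifg`, `t2d`,
#'   `p_value` (all character, at printed precision).
#' @export
packaged_clinical_summary <- function() {
  utils::read.delim(
    system.file("extdata", "clinical_summary_table1.tsv", package = "mirct",
                mustWork = TRUE),
    colClasses = "character", check.names = FALSE)
}

#' Median and interquartile range per group
#'
#' Quartiles use the default linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return data.frame with columns `group`, `n`, `median`, `q1`, `q3`.
#' @export
summarize_median_iqr <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  rows <- lapply(unique(groups), function(g) {
    v <- values[groups == g & !is.na(values)]
    if (length(v) == 0L) stop("group has no values: ", g)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis rank test with optional exact permutation p-value
#'
#' The H statistic (with tie correction) and the chi-square approximation
#' come from [stats::kruskal.test()]. For small cohorts the chi-square
#' approximation is poor, so an exact p-value is also computed by
#' enumerating every distinct assignment of the observations to groups of
#' the observed sizes (automatic for total n at most `exact_n_max`).
#'
#' @param groups list of numeric vectors, one per group.
#' @param exact compute the exact permutation p-value (`NA` = automatic).
#' @param exact_n_max largest total n for automatic exact computation.
#' @return list with `statistic` (H), `df`, `p_chisq`, `p_exact`
#'   (`NA` when not computed), `method`.
#' @export
kruskal_wallis <- function(groups, exact = NA, exact_n_max = 10) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  n <- length(x)

  if (length(unique(x)) == 1L) {
    return(list(statistic = 0, df = length(groups) - 1L, p_chisq = 1,
                p_exact = 1, method = "degenerate (all values identical)"))
  }
  kw <- stats::kruskal.test(x, g)
  H <- unname(kw$statistic)

  do_exact <- if (is.na(exact)) n <= exact_n_max else isTRUE(exact)
  p_exact <- NA_real_
  if (do_exact) {
    p_exact <- .kw_exact_p(x, lengths(groups), H)
  }
  list(statistic = H, df = unname(kw$parameter), p_chisq = kw$p.value,
       p_exact = p_exact, method = kw$method)
}

# exact permutation p: enumerate distinct partitions of indices into the
# observed group sizes via nested combinations; P(H_perm >= H_obs)
.kw_exact_p <- function(x, sizes, H_obs) {
  n <- length(x)
  r <- rank(x)
  tie <- table(r)
  tiecorr <- 1 - sum(tie^3 - tie) / (n^3 - n)
  kstat <- function(idx_list) {
    s <- vapply(idx_list, function(i) sum(r[i]), numeric(1))
    H <- 12 / (n * (n + 1)) * sum(s^2 / lengths(idx_list)) - 3 * (n + 1)
    H / tiecorr
  }
  count <- 0L; total <- 0L
  recurse <- function(remaining, sizes, acc) {
    if (length(sizes) == 1L) {
      total <<- total + 1L
      if (kstat(c(acc, list(remaining))) >= H_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes[1], simplify = FALSE)
    for (p in picks) recurse(setdiff(remaining, p), sizes[-1], c(acc, list(p)))
  }
  recurse(seq_len(n), as.integer(sizes), list())
  count / total
}
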