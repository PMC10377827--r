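#' Define a qPCR assay panel
#'
#' A panel describes the assay universe of a miRNA PCR array: the target
#' miRNAs, the endogenous control assays (small nucleolar RNAs), the exogenous
#' spike-in used to monitor extraction efficiency, and the ordered pair of
#' assays whose delta-Ct serves as the hemolysis contamination index.
#'
#' @param targets character vector of target assay IDs (mature miRNA IDs,
#'   e.g. `"hsa-miR-195-5p"`).
#' @param endogenous_controls character vector of endogenous control assay IDs.
#' @param spike_in single assay ID of the exogenous spike-in.
#' @param hemolysis_pair ordered pair of assay IDs `(numerator, denominator)`;
#'   the hemolysis index is `Ct(numerator) - Ct(denominator)`. Both must be
#'   target assays.
#' @param name optional panel name.
#'
#' @return An object of class `panel_definition` with elements `targets`,
#'   `endogenous_controls`, `spike_in`, `hemolysis_pair`, `name`.
#' @export
#' @examples
#' panel_definition(c("hsa-miR-23a-3p", "hsa-miR-451a", "hsa-miR-195-5p"),
#'                  c("SNORD61", "RNU6B"), "cel-miR-39",
#'                  c("hsa-miR-23a-3p", "hsa-miR-451a"))
panel_definition <- function(targets, endogenous_controls, spike_in,
                             hemolysis_pair, name = "panel") {
  targets <- as.character(targets)
  endogenous_controls <- as.character(endogenous_controls)
  spike_in <- as.character(spike_in)
  hemolysis_pair <- as.character(hemolysis_pair)

  if (length(targets) == 0L) stop("panel must list at least one target assay")
  if (length(spike_in) != 1L) stop("exactly one spike-in assay is required")
  all_ids <- c(targets, endogenous_controls, spike_in)
  if (any(!nzchar(all_ids)) || anyNA(all_ids)) {
    stop("assay IDs must be non-empty")
  }
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup)) {
    stop("duplicate assay IDs across panel roles: ", paste(dup, collapse = ", "))
  }
  if (length(hemolysis_pair) != 2L || hemolysis_pair[1] == hemolysis_pair[2]) {
    stop("hemolysis_pair must name two distinct assays")
  }
  missing_pair <- setdiff(hemolysis_pair, targets)
  if (length(missing_pair)) {
    stop("hemolysis_pair assays must be panel targets; missing: ",
         paste(missing_pair, collapse = ", "))
  }
  structure(
    list(targets = targets, endogenous_controls = endogenous_controls,
         spike_in = spike_in, hemolysis_pair = hemolysis_pair, name = name),
    class = "panel_definition"
  )
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("qPCR assay panel:", x$name, "\n")
  cat("  targets:            ", length(x$targets), "\n")
  cat("  endogenous controls:", length(x$endogenous_controls),
      paste0("(", paste(x$endogenous_controls, collapse = ", "), ")"), "\n")
  cat("  spike-in:           ", x$spike_in, "\n")
  cat("  hemolysis pair:     ", paste(x$hemolysis_pair, collapse = " / "), "\n")
  invisible(x)
}

#' All assay IDs of a panel
#'
#' @param panel a `panel_definition`.
#' @return character vector: targets, then controls, then spike-in.
#' @export
panel_assays <- function(panel) {
  stopifnot(inherits(panel, "panel_definition"))
  c(panel$targets, panel$endogenous_controls, panel$spike_in)
}

#' Load a panel definition from a YAML or JSON config file
#'
#' The config must provide `targets`, `endogenous_controls`, `spike_in` and
#' `hemolysis_pair` fields; `name` is optional. Assay IDs are normalized so
#' that a typographic unicode minus reads as an ASCII hyphen.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param quiet suppress the count message.
#' @return a validated [panel_definition()].
#' @export
load_panel <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("panel config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("targets", "endogenous_controls", "spike_in", "hemolysis_pair")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("panel config missing fields: ", paste(miss, collapse = ", "))
  pan <- panel_definition(
    targets = normalize_assay_id(unlist(cfg$targets)),
    endogenous_controls = normalize_assay_id(unlist(cfg$endogenous_controls)),
    spike_in = normalize_assay_id(cfg$spike_in),
    hemolysis_pair = normalize_assay_id(unlist(cfg$hemolysis_pair)),
    name = if (!is.null(cfg$name)) cfg$name else basename(path)
  )
  if (!quiet) {
    message(sprintf("loaded panel '%s': %d targets, %d controls, 1 spike-in",
                    pan$name, length(pan$targets), length(pan$endogenous_controls)))
  }
  pan
}

#' The packaged default serum/plasma panel
#'
#' A 372-target panel emulating a commercial serum & plasma miRNA array:
#' the mature IDs observed in serum profiling plus synthetic placeholder
#' assays (`syn-miR-*`) padding the panel to 372 targets, six snoRNA/snRNA
#' endogenous controls and the cel-miR-39 spike-in.
#'
#' @return a [panel_definition()].
#' @export
default_serum_panel <- function() {
  load_panel(system.file("extdata", "panel_serum_384.yaml", package = "mirct",
                         mustWork = TRUE), quiet = TRUE)
}

# unicode minus (U+2212) appears in some published mature IDs and numbers
normalize_assay_id <- function(x) {
  gsub("−", "-", trimws(as.character(x)))
}
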