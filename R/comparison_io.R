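#' Read a printed comparison table (fold-regulation fixture)
#'
#' Reads a two-column TSV (`mature_id`, `fold_regulation`) transcribed from
#' a published differential-expression table. Unicode minus signs are
#' accepted in both IDs and numbers, as they occur in typeset tables.
#' Under the signed fold-regulation convention every magnitude is at least
#' 1, so |FR| < 1 is rejected as a transcription error.
#'
#' @param path TSV path.
#' @param contrast optional contrast name stored on the result.
#' @return data.frame of class `comparison_fixture` with columns `mirna`,
#'   `fold_regulation`.
#' @export
read_comparison_fixture <- function(path, contrast = basename(path)) {
  df <- utils::read.delim(path, colClasses = "character", strip.white = TRUE,
                          check.names = FALSE)
  need <- c("mature_id", "fold_regulation")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fixture missing columns: ", paste(miss, collapse = ", "))
  mirna <- normalize_assay_id(df$mature_id)
  fr <- suppressWarnings(as.numeric(normalize_assay_id(df$fold_regulation)))
  if (anyNA(fr)) {
    stop("non-numeric fold regulation: '", df$fold_regulation[which(is.na(fr))[1]], "'")
  }
  if (any(abs(fr) < 1)) {
    stop("fold regulation with |FR| < 1 violates the sign convention: ",
         fr[which(abs(fr) < 1)[1]])
  }
  if (anyDuplicated(mirna)) {
    stop("duplicate mature ID in fixture: ", mirna[duplicated(mirna)][1])
  }
  out <- data.frame(mirna = mirna, fold_regulation = fr, stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  class(out) <- c("comparison_fixture", "data.frame")
  out
}

#' Write a comparison table as TSV
#'
#' Rows are sorted by descending fold regulation, ties broken by mature ID
#' ascending; fold regulations are printed at 2 decimals, so the file
#' round-trips through [read_comparison_fixture()] at printed precision.
#'
#' @param records data.frame with `mirna` and `fold_regulation` columns
#'   (rows without an evaluable fold regulation are dropped).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(records, path) {
  rec <- records[!is.na(records$fold_regulation), c("mirna", "fold_regulation")]
  rec <- rec[order(-rec$fold_regulation, rec$mirna), ]
  out <- data.frame(mature_id = rec$mirna,
                    fold_regulation = sprintf("%.2f", rec$fold_regulation))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged fold-regulation fixtures
#'
#' Loads the transcribed differential-expression tables shipped with the
#' package: signed fold regulations for the three contrasts of a serum
#' miRNA profiling study of glucose-tolerance groups (IFG vs control,
#' new-onset T2D vs control, new-onset T2D vs IFG), plus the two
#' narrative-only sub-threshold IFG values for the T2D-specific miRNAs.
#'
#' @return named list of `comparison_fixture` data.frames:
#'   `ifg_vs_control`, `t2d_vs_control`, `t2d_vs_ifg`,
#'   `ifg_vs_control_narrative`.
#' @export
packaged_fixtures <- function() {
  nm <- c("ifg_vs_control", "t2d_vs_control", "t2d_vs_ifg",
          "ifg_vs_control_narrative")
  out <- lapply(nm, function(x) {
    read_comparison_fixture(
      system.file("extdata", paste0("fr_", x, ".tsv"), package = "mirct",
                  mustWork = TRUE),
      contrast = x)
  })
  names(out) <- nm
  out
}
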