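#' Construct a Ct matrix
#'
#' A `ct_matrix` stores one cycle-threshold value per (assay, sample) cell.
#' Undetermined reactions (no amplification before the instrument maximum)
#' are stored as `NA`. Each sample carries a group label.
#'
#' @param values numeric matrix, assays in rows (rownames = assay IDs),
#'   samples in columns (colnames = sample IDs); `NA` marks undetermined.
#' @param groups character vector of group labels, one per sample (recycled
#'   names from `colnames(values)` if unnamed).
#' @param panel optional `panel_definition`; if given, every assay must
#'   belong to the panel.
#'
#' @return an object of class `ct_matrix`: the numeric matrix with a
#'   `groups` attribute.
#' @export
ct_matrix <- function(values, groups, panel = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have assay rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate assay IDs")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  bad <- values[!is.na(values) & (values < 0 | values > 45)]
  if (length(bad)) {
    stop("Ct values outside [0, 45]: ", paste(utils::head(bad, 3), collapse = ", "))
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stop("need one group label per sample")
  }
  names(groups) <- colnames(values)
  if (!is.null(panel)) {
    alien <- setdiff(rownames(values), panel_assays(panel))
    if (length(alien)) {
      stop("assays not in panel: ", paste(utils::head(alien, 5), collapse = ", "))
    }
  }
  structure(values, groups = groups, class = c("ct_matrix", "matrix", "array"))
}

#' @export
print.ct_matrix <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("ct_matrix: %d assays x %d samples (%d groups); %d undetermined cells\n",
              nrow(x), ncol(x), length(unique(g)), sum(is.na(x))))
  cat("groups:", paste(sprintf("%s=%d", names(table(g)), table(g)), collapse = ", "), "\n")
  invisible(x)
}

#' Group labels of a Ct matrix
#' @param x a `ct_matrix`.
#' @return named character vector of group labels per sample.
#' @export
ct_groups <- function(x) attr(x, "groups")

# sentinels recognized as "no amplification" in input tables
.undetermined_tokens <- c("undetermined", "undet", "na", "n/a", "")

parse_ct_value <- function(x, where = "") {
  x <- normalize_assay_id(x)          # also folds unicode minus
  out <- rep(NA_real_, length(x))
  is_missing <- tolower(x) %in% .undetermined_tokens
  num <- suppressWarnings(as.numeric(x))
  bad <- !is_missing & is.na(num)
  if (any(bad)) {
    stop("non-numeric Ct value", where, ": '", x[which(bad)[1]], "'")
  }
  out[!is_missing] <- num[!is_missing]
  oob <- !is.na(out) & (out < 0 | out > 45)
  if (any(oob)) {
    stop("Ct outside [0, 45]", where, ": ", out[which(oob)[1]])
  }
  out
}

#' Read a raw Ct table from CSV
#'
#' Two layouts are supported. `long`: columns `sample`, `group`, `assay`,
#' `ct` (one row per reaction). `wide`: first column `assay`, remaining
#' columns one per sample holding Ct values; group labels are then taken
#' from a `groups` argument or from sample names of the form
#' `"<group>_<replicate>"`. The tokens `"Undetermined"`, `"NA"` and empty
#' cells map to undetermined; unicode minus is accepted in numbers.
#'
#' @param path CSV file path.
#' @param layout `"long"` or `"wide"`.
#' @param panel a `panel_definition`; assays absent from it are an error
#'   when `strict = TRUE`, otherwise dropped with a warning.
#' @param groups for `layout = "wide"`, optional named character vector of
#'   group labels per sample.
#' @param strict reject unknown assays instead of warning.
#' @return a [ct_matrix()].
#' @export
read_ct_table <- function(path, layout = c("long", "wide"), panel,
                          groups = NULL, strict = TRUE) {
  layout <- match.arg(layout)
  stopifnot(inherits(panel, "panel_definition"))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)

  if (layout == "long") {
    need <- c("sample", "group", "assay", "ct")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("long layout missing columns: ", paste(miss, collapse = ", "))
    df$assay <- normalize_assay_id(df$assay)
    key <- paste(df$assay, df$sample, sep = "\r")
    if (anyDuplicated(key)) {
      d <- strsplit(key[duplicated(key)][1], "\r")[[1]]
      stop(sprintf("duplicate (assay, sample) cell: (%s, %s)", d[1], d[2]))
    }
    gmap <- tapply(df$group, df$sample, function(g) unique(g))
    if (any(lengths(gmap) > 1)) {
      stop("inconsistent group label for sample: ",
           names(gmap)[lengths(gmap) > 1][1])
    }
    assays <- unique(df$assay)
    samples <- unique(df$sample)
    vals <- matrix(NA_real_, length(assays), length(samples),
                   dimnames = list(assays, samples))
    vals[cbind(match(df$assay, assays), match(df$sample, samples))] <-
      parse_ct_value(df$ct)
    grp <- unlist(gmap)[samples]
  } else {
    if (names(df)[1] != "assay") stop("wide layout: first column must be 'assay'")
    assays <- normalize_assay_id(df$assay)
    if (anyDuplicated(assays)) {
      stop("duplicate (assay, sample) cell: assay ", assays[duplicated(assays)][1],
           " listed twice")
    }
    samples <- names(df)[-1]
    vals <- sapply(df[-1], parse_ct_value)
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(assays))
    dimnames(vals) <- list(assays, samples)
    if (is.null(groups)) {
      grp <- sub("_[^_]*$", "", samples)
    } else {
      if (is.null(names(groups))) names(groups) <- samples
      grp <- groups[samples]
    }
  }

  alien <- setdiff(rownames(vals), panel_assays(panel))
  if (length(alien)) {
    if (strict) {
      stop("assays not in panel: ", paste(utils::head(alien, 5), collapse = ", "))
    }
    warning("dropping ", length(alien), " assay(s) not in panel")
    vals <- vals[setdiff(rownames(vals), alien), , drop = FALSE]
  }
  ct_matrix(vals, grp, panel = panel)
}

#' Write a Ct matrix as long-format CSV
#'
#' Inverse of `read_ct_table(layout = "long")`; undetermined cells are
#' written as `"Undetermined"`.
#'
#' @param x a `ct_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_matrix"))
  g <- ct_groups(x)
  df <- data.frame(
    sample = rep(colnames(x), each = nrow(x)),
    group = rep(g, each = nrow(x)),
    assay = rep(rownames(x), times = ncol(x)),
    ct = ifelse(is.na(c(unclass(x))), "Undetermined",
                format(c(unclass(x)), trim = TRUE, digits = 10)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
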