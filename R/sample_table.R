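# Core container: a peak-intensity table (cases x features) with per-case
# class labels and m/z feature identifiers, plus delimited-text IO.

#' Construct a peak-intensity sample table
#'
#' Rows are cases (individual spectra; replicate spectra of one patient are
#' separate cases), columns are features identified by m/z value.
#'
#' @param abundances numeric matrix (cases x features) with no missing
#'   values.
#' @param class_labels vector of per-case class labels; at least two
#'   distinct values are required. Levels are coded in first-seen order.
#' @param feature_ids numeric m/z values, one per column, unique and
#'   positive. Defaults to `as.numeric(colnames(abundances))`.
#' @param case_ids optional case identifiers (default `"case_1"`, ...).
#' @param groups optional case-grouping vector (e.g. patient id for
#'   replicate spectra); only used to keep a group's cases in the same
#'   cross-validation fold.
#' @return object of class `sample_table`.
#' @export
sample_table <- function(abundances, class_labels, feature_ids = NULL,
                         case_ids = NULL, groups = NULL) {
  if (!is.matrix(abundances)) abundances <- as.matrix(abundances)
  if (!is.numeric(abundances)) stop("`abundances` must be numeric")
  n <- nrow(abundances)
  p <- ncol(abundances)
  if (anyNA(abundances)) {
    bad <- which(is.na(abundances), arr.ind = TRUE)[1L, ]
    stop("missing abundance at row ", bad[1L], ", column ", bad[2L])
  }
  if (length(class_labels) != n) {
    stop("number of class labels (", length(class_labels),
         ") != number of cases (", n, ")")
  }
  if (length(unique(class_labels)) < 2L) {
    stop("class labels must take at least 2 distinct values")
  }
  if (is.null(feature_ids)) {
    feature_ids <- suppressWarnings(as.numeric(colnames(abundances)))
    if (anyNA(feature_ids)) {
      stop("`feature_ids` not given and column names are not numeric m/z values")
    }
  }
  if (length(feature_ids) != p) {
    stop("number of feature ids (", length(feature_ids),
         ") != number of feature columns (", p, ")")
  }
  if (anyDuplicated(feature_ids)) {
    dup <- feature_ids[duplicated(feature_ids)][1L]
    stop("duplicate feature id: ", dup)
  }
  if (any(feature_ids <= 0)) stop("feature ids (m/z) must be positive")
  if (is.null(case_ids)) case_ids <- paste0("case_", seq_len(n))
  if (!is.null(groups) && length(groups) != n) {
    stop("`groups` must have one entry per case")
  }
  colnames(abundances) <- format_mz(feature_ids)
  rownames(abundances) <- NULL
  structure(list(abundances = abundances,
                 class_labels = as.character(class_labels),
                 class_levels = unique(as.character(class_labels)),
                 feature_ids = feature_ids,
                 case_ids = as.character(case_ids),
                 groups = if (is.null(groups)) NULL else as.character(groups)),
            class = "sample_table")
}

# canonical feature/node name for an m/z value
format_mz <- function(mz) {
  sprintf("%.15g", mz)
}

#' @export
print.sample_table <- function(x, ...) {
  cat("Peak-intensity table: ", nrow(x$abundances), " cases x ",
      ncol(x$abundances), " features\n", sep = "")
  cat("  classes: ",
      paste(sprintf("%s (%d)", x$class_levels,
                    as.vector(table(x$class_labels)[x$class_levels])),
            collapse = ", "), "\n", sep = "")
  cat("  m/z range: ", min(x$feature_ids), " - ", max(x$feature_ids), "\n",
      sep = "")
  if (!is.null(x$groups)) {
    cat("  case groups: ", length(unique(x$groups)), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.sample_table <- function(x) dim(x$abundances)

#' Subset the cases of a sample table
#'
#' @param tbl a [sample_table()].
#' @param idx integer or logical case index.
#' @return a new `sample_table` with the selected cases, row order
#'   preserved.
#' @export
subset_cases <- function(tbl, idx) {
  stopifnot(inherits(tbl, "sample_table"))
  sample_table(tbl$abundances[idx, , drop = FALSE],
               tbl$class_labels[idx],
               feature_ids = tbl$feature_ids,
               case_ids = tbl$case_ids[idx],
               groups = if (is.null(tbl$groups)) NULL else tbl$groups[idx])
}

#' Read a peak-intensity table from delimited text
#'
#' Expects one header row with a label column (name configurable) and the
#' remaining columns headed by numeric m/z values. Every abundance cell
#' must parse as a number; offending cells are reported with their row and
#' column coordinates.
#'
#' @param path file path.
#' @param label_column name of the class-label column (default `"class"`).
#' @param delimiter field delimiter (default `","`).
#' @param group_column optional name of a case-grouping column.
#' @param na_action `"reject"` (default: any missing/non-numeric cell is an
#'   error) or `"drop"` (cases with missing cells are removed with a
#'   warning).
#' @return a [sample_table()].
#' @export
load_sample_table <- function(path, label_column = "class", delimiter = ",",
                              group_column = NULL,
                              na_action = c("reject", "drop")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in ", path,
         " (columns: ", paste(utils::head(names(df), 5), collapse = ", "),
         ", ...)")
  }
  drop_cols <- label_column
  groups <- NULL
  if (!is.null(group_column)) {
    if (!group_column %in% names(df)) {
      stop("group column '", group_column, "' not found in ", path)
    }
    groups <- df[[group_column]]
    drop_cols <- c(drop_cols, group_column)
  }
  labels <- df[[label_column]]
  feat_names <- names(df)[!(names(df) %in% drop_cols)]
  if (length(feat_names) == 0L) stop("no feature columns in ", path)
  mz <- suppressWarnings(as.numeric(feat_names))
  if (anyNA(mz)) {
    stop("non-numeric m/z header(s): ",
         paste(feat_names[is.na(mz)], collapse = ", "))
  }
  if (anyDuplicated(mz)) {
    stop("duplicate feature id in header: ", mz[duplicated(mz)][1L])
  }
  x <- matrix(NA_real_, nrow(df), length(feat_names),
              dimnames = list(NULL, feat_names))
  for (j in seq_along(feat_names)) {
    raw <- df[[feat_names[j]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad) > 0L && na_action == "reject") {
      stop("non-numeric or missing abundance at row ", bad[1L],
           ", column '", feat_names[j], "' (value: '", raw[bad[1L]], "')")
    }
    x[, j] <- val
  }
  keep <- seq_len(nrow(x))
  if (na_action == "drop" && anyNA(x)) {
    keep <- which(stats::complete.cases(x))
    warning("dropped ", nrow(x) - length(keep), " case(s) with missing values")
    x <- x[keep, , drop = FALSE]
  }
  sample_table(x, labels[keep], feature_ids = mz,
               groups = if (is.null(groups)) NULL else groups[keep])
}

#' Write a peak-intensity table as delimited text
#'
#' Values are written with 17 significant digits so that
#' write -> [load_sample_table()] round-trips are bit-identical for double
#' precision data.
#'
#' @param tbl a [sample_table()].
#' @param path output path.
#' @param label_column header for the class column.
#' @param delimiter field delimiter.
#' @param group_column header for the optional group column (written only
#'   if the table has groups).
#' @export
write_sample_table <- function(tbl, path, label_column = "class",
                               delimiter = ",", group_column = "group") {
  stopifnot(inherits(tbl, "sample_table"))
  vals <- apply(tbl$abundances, 2L,
                function(v) formatC(v, format = "g", digits = 17))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = 1L)
  out <- data.frame(tbl$class_labels, vals, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c(label_column, colnames(tbl$abundances))
  if (!is.null(tbl$groups)) {
    out <- cbind(out[1L], stats::setNames(data.frame(tbl$groups), group_column),
                 out[-1L])
  }
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
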