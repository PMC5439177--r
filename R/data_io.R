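#' Identify the gene (expression) columns of a dataset
#'
#' A dataset is a data frame with one row per sample: an optional
#' `sample_id` character column, one label column with exactly two classes,
#' and one numeric column per gene. This helper returns the gene column
#' names, i.e. every numeric column other than the label column.
#'
#' @param data A data frame of samples by genes.
#' @param class_col Name of the label column.
#' @return Character vector of gene column names, in table order.
#' @export
gene_columns <- function(data, class_col = "class") {
  stopifnot(is.data.frame(data))
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  setdiff(num, class_col)
}

# Resolve the two class labels and their orientation. The lexicographically
# larger label is "positive" (tumor) unless `positive` overrides it.
class_info <- function(data, class_col = "class", positive = NULL) {
  if (!class_col %in% names(data)) {
    abort(sprintf("label column '%s' not found in data", class_col))
  }
  labs <- as.character(data[[class_col]])
  u <- sort(unique(labs))
  if (length(u) != 2) {
    abort(sprintf(
      "label column '%s' must have exactly 2 distinct values, found %d: %s",
      class_col, length(u), paste(u, collapse = ", ")
    ))
  }
  if (is.null(positive)) {
    positive <- u[2]
  } else if (!positive %in% u) {
    abort(sprintf("positive label '%s' is not one of: %s",
                  positive, paste(u, collapse = ", ")))
  }
  negative <- setdiff(u, positive)
  is_pos <- labs == positive
  if (sum(is_pos) < 2 || sum(!is_pos) < 2) {
    abort("each class must have at least 2 samples")
  }
  list(positive = positive, negative = negative, is_pos = is_pos,
       n_pos = sum(is_pos), n_neg = sum(!is_pos))
}

#' Read a labeled expression matrix from CSV, TSV, or ARFF
#'
#' Expects one row per sample and one column per gene, plus a label column
#' holding exactly two class values. CSV/TSV files must carry a header row of
#' gene identifiers; ARFF files (the dialect Weka writes) use numeric
#' attributes per gene and one nominal class attribute. An optional
#' `sample_id` column is used as sample identifiers; otherwise identifiers
#' `S1..Sn` are generated.
#'
#' Missing expression values are rejected by default; with
#' `impute_missing = TRUE` each missing cell is replaced by its gene's
#' median over the non-missing samples.
#'
#' @param path Path to the file.
#' @param format One of `"auto"` (by file extension), `"csv"`, `"tsv"`,
#'   `"arff"`.
#' @param label_column Name of the label column. Default `"class"`.
#' @param impute_missing Impute missing expression values by per-gene
#'   median instead of rejecting the file.
#' @return A tibble with columns `sample_id`, the label column, and one
#'   numeric column per gene.
#' @export
read_expression <- function(path, format = c("auto", "csv", "tsv", "arff"),
                            label_column = "class", impute_missing = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     arff = "arff",
                     abort(sprintf("cannot infer format from extension '.%s'", ext)))
  }
  if (format %in% c("csv", "tsv")) {
    header <- strsplit(readLines(path, n = 1L),
                       if (format == "csv") "," else "\t")[[1]]
    header <- gsub('^"|"$', "", trimws(header))
    dup <- unique(header[duplicated(header)])
    if (length(dup) > 0) {
      abort(sprintf("duplicate gene identifier(s) in header: %s",
                    paste(dup, collapse = ", ")))
    }
    reader <- if (format == "csv") readr::read_csv else readr::read_tsv
    df <- suppressWarnings(
      reader(path, show_col_types = FALSE, progress = FALSE,
             name_repair = "minimal")
    )
  } else {
    df <- foreign::read.arff(path)
    dup <- unique(names(df)[duplicated(names(df))])
    if (length(dup) > 0) {
      abort(sprintf("duplicate gene identifier(s): %s", paste(dup, collapse = ", ")))
    }
  }
  df <- as_tibble(df)
  if (!label_column %in% names(df)) {
    abort(sprintf("label column '%s' not found in %s", label_column, path))
  }
  labs <- as.character(df[[label_column]])
  u <- sort(unique(labs))
  if (length(u) != 2) {
    abort(sprintf(
      "label column '%s' must have exactly 2 distinct values; found %d (%s)",
      label_column, length(u), paste(u, collapse = ", ")
    ))
  }
  if ("sample_id" %in% names(df)) {
    sid <- as.character(df$sample_id)
    if (anyDuplicated(sid)) abort("duplicate sample_id values")
    df$sample_id <- NULL
  } else {
    sid <- paste0("S", seq_len(nrow(df)))
  }
  gene_cols <- setdiff(names(df), label_column)
  bad <- gene_cols[!vapply(df[gene_cols], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("non-numeric expression value(s) in column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  na_cols <- gene_cols[vapply(df[gene_cols], anyNA, logical(1))]
  if (length(na_cols) > 0) {
    if (!impute_missing) {
      abort(sprintf(
        "missing expression values in column(s): %s (set impute_missing = TRUE to impute per-gene medians)",
        paste(utils::head(na_cols, 5), collapse = ", ")
      ))
    }
    for (g in na_cols) {
      x <- df[[g]]
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
      df[[g]] <- x
    }
  }
  out <- dplyr::bind_cols(tibble(sample_id = sid), df)
  out <- dplyr::relocate(out, "sample_id", dplyr::all_of(label_column))
  out[[label_column]] <- labs
  out
}

#' Write a labeled expression matrix to CSV, TSV, or ARFF
#'
#' Inverse of [read_expression()]. CSV/TSV writes use full double precision
#' so a save/load round trip reproduces values exactly. ARFF writes numeric
#' attributes per gene and a nominal class attribute (the `sample_id`
#' column is dropped, matching the format's attribute model).
#'
#' @param data Dataset tibble as returned by [read_expression()].
#' @param path Output path.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"arff"`.
#' @param class_col Name of the label column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path, format = c("auto", "csv", "tsv", "arff"),
                             class_col = "class") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", arff = "arff",
                     abort(sprintf("cannot infer format from extension '.%s'", ext)))
  }
  if (format %in% c("csv", "tsv")) {
    writer <- if (format == "csv") readr::write_csv else readr::write_tsv
    writer(data, path, progress = FALSE)
  } else {
    df <- as.data.frame(data[setdiff(names(data), "sample_id")])
    df[[class_col]] <- factor(df[[class_col]])
    foreign::write.arff(df, path)
  }
  invisible(path)
}

#' Z-score standardize every gene column
#'
#' Rescales each gene over all samples pooled (never per class, which would
#' leak labels into the features) to mean 0 and standard deviation 1, using
#' the sample (n-1) standard deviation. Genes that are constant across all
#' samples are mapped to all zeros and flagged: their names are recorded in
#' the `"constant_genes"` attribute of the result (see [constant_genes()]).
#'
#' @param data Dataset tibble.
#' @param class_col Name of the label column (left untouched).
#' @return The dataset with standardized gene columns.
#' @export
zscore_standardize <- function(data, class_col = "class") {
  genes <- gene_columns(data, class_col)
  const <- character(0)
  for (g in genes) {
    x <- data[[g]]
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      data[[g]] <- rep(0, length(x))
      const <- c(const, g)
    } else {
      data[[g]] <- (x - mean(x)) / s
    }
  }
  attr(data, "constant_genes") <- const
  data
}

#' Names of genes flagged constant during standardization
#'
#' @param data Result of [zscore_standardize()].
#' @return Character vector (possibly empty).
#' @export
constant_genes <- function(data) {
  attr(data, "constant_genes") %||% character(0)
}
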