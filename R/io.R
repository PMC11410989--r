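# Delimited-table input and JSON result output. Only numeric analysis columns
# are supported; missing values may be coded "", "NA", "nan" or "NaN" and are
# removed by joint complete-case filtering downstream.

#' Read a delimited phenotype / dosage table
#'
#' Reads a TSV or CSV file (delimiter auto-detected from the extension:
#' `.csv` is comma, anything else tab) with one header row and one row per
#' participant, and returns the selected columns as a numeric matrix.
#'
#' @param path file path.
#' @param columns optional character vector of columns to keep (default all).
#' @return list with `headers` (all column names in the file) and `data`
#'   (numeric matrix of the selected columns).
#' @export
read_table <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) read.csv else read.delim
  df <- reader(path, na.strings = c("", "NA", "nan", "NaN"),
               check.names = FALSE, colClasses = NA)
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  headers <- names(df)
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, headers)
    if (length(missing_cols)) {
      stop("column(s) not found in ", path, ": ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    df <- df[, columns, drop = FALSE]
  }
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]])) {
      suppressWarnings(num <- as.numeric(as.character(df[[cn]])))
      bad <- !is.na(as.character(df[[cn]])) & is.na(num)
      if (any(bad)) {
        stop("non-numeric value(s) in column '", cn, "' of ", path,
             " (first at data row ", which(bad)[1], ")", call. = FALSE)
      }
      df[[cn]] <- num
    }
  }
  list(headers = headers, data = as.matrix(df))
}

#' Read a SNP weight table
#'
#' Reads a delimited file with columns `snp_id`, `effect_allele`, `weight`
#' (per-allele effect of the effect allele on the exposure) and validates it
#' for [build_grs()].
#'
#' @param path file path (TSV or CSV, as in [read_table()]).
#' @return validated data frame with character `snp_id`, `effect_allele` and
#'   numeric `weight`.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) read.csv else read.delim
  df <- reader(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("snp_id", "effect_allele", "weight")
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop("weights file ", path, " is missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$weight)) {
    suppressWarnings(w <- as.numeric(as.character(df$weight)))
    if (anyNA(w)) stop("non-numeric weight in ", path, call. = FALSE)
    df$weight <- w
  }
  validate_weights(df[, need])
}

write_result_json <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  # 17 significant digits: doubles survive the round-trip bit-identically
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

read_result_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
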