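# Cohort file IO: versioned CSV schema with validation that reports the
# offending row/column.

#' Write a cohort to CSV
#'
#' One row per patient-timepoint, columns per [cohort_schema()], UTF-8,
#' '.' decimal separator.
#'
#' @param records cohort data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  validate_records(records)
  utils::write.csv(records[, cohort_schema()$column], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Schema violations (missing columns, negative counts, non-logical flags)
#' are reported with the offending column and row numbers.
#'
#' @param path CSV written by [write_cohort()] (or schema-compatible).
#' @return cohort data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  schema <- cohort_schema()
  missing <- setdiff(schema$column, names(df))
  if (length(missing)) {
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    type <- schema$type[i]
    v <- df[[col]]
    if (type %in% c("numeric", "integer")) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value in column '", col, "' at row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "))
      }
      if (type == "integer") {
        bad <- which(num < 0)
        if (length(bad)) {
          stop("negative count in column '", col, "' at row(s) ",
               paste(utils::head(bad, 5L), collapse = ", "))
        }
        df[[col]] <- as.integer(round(num))
      } else {
        df[[col]] <- num
      }
    } else if (type == "logical") {
      df[[col]] <- as.logical(v)
    } else {
      df[[col]] <- as.character(v)
    }
  }
  validate_records(df)
  df
}

#' Write the truth sidecar accompanying a generated cohort
#'
#' @param truth truth data.frame from the generator.
#' @param path JSON output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
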