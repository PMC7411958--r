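#' Read an analyte table from CSV
#'
#' Expects a header row containing the configured ID column, all configured
#' descriptor columns, and the retention-time column, in any order. Row
#' order is preserved exactly as in the file (elution-order computations
#' rely on stable indexing).
#'
#' @param path CSV file path.
#' @param config a \code{\link{case_study_config}} supplying column names.
#' @return An \code{\link{analyte_table}}.
#' @export
read_analyte_table <- function(path, config) {
  stopifnot(inherits(config, "case_study_config"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(config$id_col, config$descriptor_names, config$tr_col)
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  X <- as.matrix(df[, config$descriptor_names, drop = FALSE])
  storage.mode(X) <- "double"
  lbl <- if ("set_label" %in% names(df)) df$set_label else NULL
  analyte_table(df[[config$id_col]], X, as.numeric(df[[config$tr_col]]),
                set_label = lbl)
}

#' Write an analyte table to CSV
#'
#' Writes a header plus one row per analyte; reading the file back with
#' \code{\link{read_analyte_table}} reproduces the table (IDs bit-exact,
#' numerics to full printed precision). An empty table yields a header-only
#' file.
#'
#' @param table an \code{analyte_table} (or NULL/empty for header-only).
#' @param path destination file path.
#' @param config a \code{case_study_config} supplying column names.
#' @return Invisibly, the path.
#' @export
write_analyte_table <- function(table, path, config) {
  stopifnot(inherits(config, "case_study_config"))
  if (is.null(table)) {
    df <- data.frame(matrix(nrow = 0, ncol = length(config$descriptor_names) + 3))
    names(df) <- c(config$id_col, config$descriptor_names, config$tr_col,
                   "set_label")
  } else {
    stopifnot(inherits(table, "analyte_table"))
    if (!identical(table$descriptor_names, config$descriptor_names))
      stop("table descriptors do not match the configured schema")
    df <- as.data.frame(table)
    names(df) <- c(config$id_col, config$descriptor_names, config$tr_col,
                   "set_label")
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
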