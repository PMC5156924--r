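#' Read and write phase-by-type count tables
#'
#' Count tables are CSV files whose first column holds the phase label
#' (rows in temporal order) and whose remaining columns are named variant
#' types with integer cells.
#'
#' @param path file path.
#' @return `read_count_table()`: an integer matrix with phase row names.
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  m
}

#' @param x phases x types count matrix.
#' @rdname read_count_table
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(phase = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read per-phase house counts
#'
#' A two-column CSV (phase, H).
#'
#' @param path file path.
#' @return named numeric vector of house counts.
#' @export
read_house_counts <- function(path) {
  df <- utils::read.csv(path)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
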