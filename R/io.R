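#' Read and write the tab-separated tables used throughout
#'
#' Thin wrappers fixing the dialect (tab-separated, header, no quoting, no
#' row names) for promoter tables, interaction lists and result tables.
#'
#' @param path File path.
#' @return `read_tsv_table()`: a data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param x Data frame to write.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_tsv_table
#' @param params A [noise_floor_params()] object.
#' @export
write_floor_params <- function(params, path) {
  stopifnot(inherits(params, "noise_floor_params"))
  writeLines(sprintf("%s\t%.10g",
                     c("sigma_ab2", "beta", "n_bg"),
                     c(params$sigma_ab2, params$beta, params$n_bg)),
             path)
  invisible(path)
}

#' @rdname read_tsv_table
#' @export
read_floor_params <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, col.names = c("key", "value"))
  vals <- stats::setNames(kv$value, kv$key)
  noise_floor_params(vals[["sigma_ab2"]], vals[["beta"]], vals[["n_bg"]])
}
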