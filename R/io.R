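#' Read and write quantification tables as TSV
#'
#' Tables are tab-separated with identifier/metadata columns first and one
#' column per sample; missing intensities are encoded as empty cells.
#' Serialization is deterministic: the same table always produces the same
#' bytes, so seeded simulations round-trip byte-identically.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `write_quant_table()` returns `path` invisibly;
#'   `read_quant_table()` returns a data frame.
#' @export
write_quant_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_quant_table
#' @export
read_quant_table <- function(path) {
  read.delim(path, sep = "\t", na.strings = "", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write or read a simulation configuration as YAML
#'
#' @param config A [sim_config()] object.
#' @param path File path.
#' @return `read_sim_config()` returns a validated [sim_config()] object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- unclass(config)
  # named vectors must become maps, or YAML drops the names
  vals$peptides_per_protein <- as.list(vals$peptides_per_protein)
  vals$group_sizes <- as.list(vals$group_sizes)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$group_sizes <- unlist(vals$group_sizes)
  vals$peptides_per_protein <- unlist(vals$peptides_per_protein)
  vals$bio_cv_range <- unlist(vals$bio_cv_range)
  do.call(sim_config, vals)
}
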