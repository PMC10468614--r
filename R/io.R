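#' Write a table as TSV with a provenance header
#'
#' Prepends commented header lines (package version, date, and any
#' \code{...} key = value pairs such as seeds and stage parameters) so every
#' output file records how it was produced. [read_trait_matrix()] and plain
#' \code{read.delim(comment.char = "#")} skip the header.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @param ... Named scalar provenance fields (seed, n_perm, ...).
#' @return \code{path}, invisibly.
#' @export
write_tsv_provenance <- function(df, path, ...) {
  stopifnot(is.character(path), length(path) == 1L)
  prov <- list(...)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metacons %s | %s",
                     as.character(utils::packageVersion("metacons")),
                     format(Sys.time(), "%Y-%m-%d")), con)
  for (k in names(prov)) {
    writeLines(sprintf("# %s = %s", k, format(prov[[k]])), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
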