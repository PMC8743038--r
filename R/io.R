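# Readers and writers for the standard tabular formats.  All files are
# UTF-8, tab-separated, '.' decimals, LF line endings; comment-header lines
# (prefixed '#') carry tool version, parameter hash and seed.

#' Read a gene-level divergence record table
#'
#' TSV with the exact header
#' `species_id  pair_id  gene_id  pathway_id  n_diff  n_opp  s_diff  s_opp`
#' (`pathway_id` may be empty when a separate pathway map is supplied).
#' Every row is validated against the record invariants (non-negative
#' integer differences, strictly positive opportunities, differences not
#' exceeding opportunities); offending rows abort the read with their file
#' line numbers.
#'
#' @param path Path to the TSV.
#' @return Validated data frame of records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stopf("read_records: no such file: %s", path)
  head_lines <- readLines(path, n = 100L)
  n_comment <- match(FALSE, startsWith(head_lines, "#")) - 1L
  if (is.na(n_comment)) stopf("read_records: %s has no data", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           colClasses = c(species_id = "character",
                                          pair_id = "character",
                                          gene_id = "character",
                                          pathway_id = "character"),
                           check.names = FALSE)
  miss <- setdiff(RECORD_COLUMNS, names(tab))
  if (length(miss)) stopf("read_records: %s is missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  tab <- tab[, RECORD_COLUMNS]
  bad <- validate_counts(tab, path)
  if (length(bad)) {
    lines <- bad + n_comment + 1L  # +1 for the header line
    stopf("read_records: %s: invalid counts at line(s) %s%s", path,
          paste(utils::head(lines, 10), collapse = ", "),
          if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10) else "")
  }
  tab
}

#' Write a divergence record table
#'
#' Inverse of [read_records()]; numbers are written so that
#' `read_records()` followed by `write_records()` reproduces the file byte
#' for byte (given the same header lines).
#'
#' @param records Record data frame.
#' @param path Output path.
#' @param header Optional comment-header lines (each written as `# <line>`).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, header = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con, sep = "\n")
  writeLines(paste(RECORD_COLUMNS, collapse = "\t"), con, sep = "\n")
  body <- paste(records$species_id, records$pair_id, records$gene_id,
                records$pathway_id,
                format_num(records$n_diff), format_num(records$n_opp),
                format_num(records$s_diff), format_num(records$s_opp),
                sep = "\t")
  writeLines(body, con, sep = "\n")
  invisible(path)
}

# Generic small-table TSV writer (strings written as-is, no quoting).
write_tsv_table <- function(df, path, header = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con, sep = "\n")
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) format_num(col) else as.character(col)
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  invisible(path)
}

# Standard one-line provenance header for outputs.
output_header <- function(params, seed) {
  sprintf("dndscape %s params=%s seed=%s", package_version_string(),
          params_hash(params), format(seed))
}
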