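# Coarse-graining: gene -> pathway aggregation and the species x pathway
# matrix of pooled dN/dS that every downstream analysis consumes.

#' Construct a pathway matrix
#'
#' Container for per-(species, pathway) pooled dN/dS.  `values` holds the
#' ratio with `NA` marking masked cells (no estimate or insufficient
#' support); `support` holds the pooled synonymous-difference count behind
#' each cell.  Rows are species, columns are pathways, both sorted
#' lexicographically (C collation) for determinism.
#'
#' @param values Numeric matrix (species x pathway) with dimnames; `NA` =
#'   masked.
#' @param support Optional integer matrix of pooled synonymous differences,
#'   same shape; defaults to 0 where masked and `NA_integer_`-free.
#' @param unmapped Character vector of gene ids that had no pathway
#'   annotation.
#' @param n_undefined Count of cells excluded because pooled dS was 0.
#' @return An object of class `pathway_matrix`.
#' @export
pathway_matrix <- function(values, support = NULL, unmapped = character(0),
                           n_undefined = 0L) {
  if (!is.matrix(values)) stopf("pathway_matrix: `values` must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("pathway_matrix: `values` needs species rownames and pathway colnames")
  }
  if (any(values < 0, na.rm = TRUE)) stopf("pathway_matrix: values must be >= 0")
  if (is.null(support)) {
    support <- matrix(0L, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  stopifnot(identical(dim(support), dim(values)))
  ord_r <- order(rownames(values), method = "radix")
  ord_c <- order(colnames(values), method = "radix")
  structure(
    list(values = values[ord_r, ord_c, drop = FALSE],
         support = support[ord_r, ord_c, drop = FALSE],
         species_ids = rownames(values)[ord_r],
         pathway_ids = colnames(values)[ord_c],
         unmapped = unmapped,
         n_undefined = as.integer(n_undefined)),
    class = "pathway_matrix"
  )
}

#' @export
print.pathway_matrix <- function(x, ...) {
  cat(sprintf("pathway_matrix: %d species x %d pathways, %d/%d cells present\n",
              length(x$species_ids), length(x$pathway_ids),
              sum(!is.na(x$values)), length(x$values)))
  if (length(x$unmapped)) cat(sprintf("  unmapped genes: %d\n", length(x$unmapped)))
  if (x$n_undefined) cat(sprintf("  cells with undefined ratio (dS = 0): %d\n", x$n_undefined))
  invisible(x)
}

#' Read a gene-to-pathway map
#'
#' TSV with header `gene_id  pathway_id  pathway_name` (the name column is
#' optional).  Each gene must map to at most one pathway; duplicate gene
#' entries are rejected so that no gene can be double-counted in the
#' permutation nulls.
#'
#' @param path Path to a tab-separated map file.
#' @return Data frame with columns `gene_id`, `pathway_id`, `pathway_name`.
#' @export
read_pathway_map <- function(path) {
  map <- utils::read.delim(path, colClasses = "character", comment.char = "#")
  need <- c("gene_id", "pathway_id")
  miss <- setdiff(need, names(map))
  if (length(miss)) stopf("pathway map %s: missing columns: %s", path,
                          paste(miss, collapse = ", "))
  if (!"pathway_name" %in% names(map)) map$pathway_name <- map$pathway_id
  validate_pathway_map(map)
}

validate_pathway_map <- function(map) {
  dup <- unique(map$gene_id[duplicated(map$gene_id)])
  if (length(dup)) stopf("pathway map: genes mapped more than once: %s",
                         paste(utils::head(dup, 5), collapse = ", "))
  if (!nrow(map)) stopf("pathway map: empty")
  map
}

#' Pool gene records into a species x pathway dN/dS matrix
#'
#' For each (species, pathway) all genes of that pathway are pooled across
#' all of that species' lineage pairs ([pool_counts()]), then the ratio of
#' sums is taken ([compute_dnds()]).  Cells whose pooled synonymous
#' difference count falls below `min_support` are masked, as are cells with
#' pooled dS of exactly zero (ratio undefined).  Genes missing from the map
#' are reported, not silently dropped.
#'
#' @param records Record data frame (filtered; see [filter_records()]).
#' @param map Pathway map data frame (see [read_pathway_map()]); if `NULL`
#'   the records' own `pathway_id` column is used.
#' @param min_support Minimum pooled synonymous differences per cell.
#' @param correction Passed to [compute_dnds()].
#' @return A [pathway_matrix()].
#' @export
aggregate_by_pathway <- function(records, map = NULL, min_support = 10,
                                 correction = "none") {
  if (!nrow(records)) stopf("aggregate_by_pathway: no records")
  if (!is.null(map)) {
    map <- validate_pathway_map(map)
    idx <- match(records$gene_id, map$gene_id)
    pathway <- map$pathway_id[idx]
  } else {
    pathway <- records$pathway_id
    pathway[!is.na(pathway) & pathway == ""] <- NA_character_
  }
  unmapped <- sort_c(unique(records$gene_id[is.na(pathway)]))
  keep <- !is.na(pathway)
  rec <- records[keep, , drop = FALSE]
  pathway <- pathway[keep]
  if (!nrow(rec)) stopf("aggregate_by_pathway: no mapped records")

  key <- paste(rec$species_id, pathway, sep = "\r")
  sums <- rowsum(rec[, COUNT_COLUMNS], key)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  sp <- vapply(parts, `[`, character(1), 1L)
  pw <- vapply(parts, `[`, character(1), 2L)

  est <- compute_dnds(sums$n_diff, sums$n_opp, sums$s_diff, sums$s_opp,
                      correction = correction)
  species_ids <- sort_c(unique(sp))
  pathway_ids <- sort_c(unique(pw))
  values <- matrix(NA_real_, length(species_ids), length(pathway_ids),
                   dimnames = list(species_ids, pathway_ids))
  support <- matrix(0L, length(species_ids), length(pathway_ids),
                    dimnames = list(species_ids, pathway_ids))
  i <- cbind(match(sp, species_ids), match(pw, pathway_ids))
  support[i] <- as.integer(sums$s_diff)
  n_undefined <- sum(is.na(est$ratio))
  ok <- !is.na(est$ratio) & sums$s_diff >= min_support
  values[i[ok, , drop = FALSE]] <- est$ratio[ok]
  if (!any(ok)) {
    stopf("aggregate_by_pathway: no cell reaches min_support = %g pooled synonymous differences",
          min_support)
  }
  pathway_matrix(values, support, unmapped = unmapped,
                 n_undefined = n_undefined)
}

#' Row and column summaries of a pathway matrix
#'
#' Per pathway (column): mean, unbiased variance and coefficient of
#' variation (`sd / mean`) of dN/dS over the species where the pathway has
#' an estimate.  Per species (row): mean over its pathways.  Pathways
#' present in fewer than `min_species` species are omitted.
#'
#' @param pm A [pathway_matrix()].
#' @param min_species Presence threshold for a pathway to be summarized.
#' @return List with data frames `pathways` (`pathway_id`, `n_species`,
#'   `mean`, `variance`, `cv`) and `species` (`species_id`, `n_pathways`,
#'   `mean`).  `cv` is `NA` where the mean is zero.
#' @export
matrix_summaries <- function(pm, min_species = 3) {
  stopifnot(inherits(pm, "pathway_matrix"))
  v <- pm$values
  n_sp <- colSums(!is.na(v))
  keep <- n_sp >= min_species
  if (any(!keep)) {
    message(sprintf("matrix_summaries: omitting %d pathway(s) present in < %d species",
                    sum(!keep), min_species))
  }
  mu <- apply(v[, keep, drop = FALSE], 2, mean, na.rm = TRUE)
  va <- apply(v[, keep, drop = FALSE], 2, stats::var, na.rm = TRUE)
  cv <- ifelse(mu > 0, sqrt(va) / mu, NA_real_)
  pathways <- data.frame(
    pathway_id = colnames(v)[keep], n_species = n_sp[keep],
    mean = mu, variance = va, cv = cv, row.names = NULL
  )
  species <- data.frame(
    species_id = rownames(v),
    n_pathways = rowSums(!is.na(v)),
    mean = rowMeans(v, na.rm = TRUE),
    row.names = NULL
  )
  list(pathways = pathways, species = species)
}

#' Write / read a pathway matrix as TSV
#'
#' Species rows by pathway columns; masked cells are written as empty
#' fields.  Support counts travel in a sidecar JSON file next to the matrix.
#'
#' @param pm A [pathway_matrix()].
#' @param path Output TSV path; the sidecar is `<path>.support.json`.
#' @param header Optional comment-header lines (each prefixed `# `).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(pm, path, header = NULL) {
  stopifnot(inherits(pm, "pathway_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con, sep = "\n")
  writeLines(paste(c("species_id", pm$pathway_ids), collapse = "\t"), con, sep = "\n")
  for (i in seq_along(pm$species_ids)) {
    row <- format_num(pm$values[i, ])
    writeLines(paste(c(pm$species_ids[i], row), collapse = "\t"), con, sep = "\n")
  }
  sidecar <- paste0(path, ".support.json")
  jsonlite::write_json(
    list(species_ids = pm$species_ids, pathway_ids = pm$pathway_ids,
         support = pm$support, unmapped = pm$unmapped,
         n_undefined = pm$n_undefined),
    sidecar, digits = NA
  )
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           colClasses = NA)
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- tab[[1]]
  sidecar <- paste0(path, ".support.json")
  support <- NULL
  unmapped <- character(0)
  n_undefined <- 0L
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    support <- matrix(as.integer(meta$support), nrow(values), ncol(values),
                      dimnames = dimnames(values))
    unmapped <- as.character(meta$unmapped %||% character(0))
    n_undefined <- as.integer(meta$n_undefined %||% 0L)
  }
  pathway_matrix(values, support, unmapped = unmapped, n_undefined = n_undefined)
}
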