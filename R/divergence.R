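# Gene-level divergence: dN, dS and their ratio from substitution counts.
#
# A divergence record holds, for one gene of one species compared between a
# pair of host-resident lineages, the number of nonsynonymous differences
# (n_diff) out of n_opp nonsynonymous opportunities (sites) and the number of
# synonymous differences (s_diff) out of s_opp synonymous opportunities.

RECORD_COLUMNS <- c("species_id", "pair_id", "gene_id", "pathway_id",
                    "n_diff", "n_opp", "s_diff", "s_opp")
COUNT_COLUMNS <- c("n_diff", "n_opp", "s_diff", "s_opp")

validate_counts <- function(records, where = "records") {
  miss <- setdiff(COUNT_COLUMNS, names(records))
  if (length(miss)) stopf("%s: missing columns: %s", where, paste(miss, collapse = ", "))
  bad <- which(
    !is.finite(records$n_diff) | !is.finite(records$s_diff) |
      !is.finite(records$n_opp) | !is.finite(records$s_opp) |
      records$n_diff < 0 | records$s_diff < 0 |
      records$n_opp <= 0 | records$s_opp <= 0 |
      records$n_diff != floor(records$n_diff) |
      records$s_diff != floor(records$s_diff) |
      records$n_diff > records$n_opp | records$s_diff > records$s_opp
  )
  bad
}

#' Compute dN, dS and dN/dS from substitution counts
#'
#' Divergence per site is the raw proportion of differences over
#' opportunities; `dN = n_diff / n_opp`, `dS = s_diff / s_opp` and the ratio
#' is `dN/dS`.  When `dS = 0` the ratio is undefined and returned as `NA`
#' (never 0 or `Inf`); downstream aggregation excludes and counts such cells.
#' An optional Jukes-Cantor multiple-hit correction
#' `d = -(3/4) * log(1 - (4/3) * p)` may be applied to each per-site
#' proportion; it requires every proportion to be below 3/4.
#'
#' All arguments are vectorized and recycled to a common length, so the
#' function serves both per-gene and pooled counts.
#'
#' @param n_diff Nonsynonymous differences (non-negative integers).
#' @param n_opp Nonsynonymous opportunities in sites (positive).
#' @param s_diff Synonymous differences (non-negative integers).
#' @param s_opp Synonymous opportunities in sites (positive).
#' @param correction `"none"` (default) or `"jukes_cantor"`.
#' @param ids Optional record labels used in error messages.
#' @return A data frame with columns `dN`, `dS`, `ratio` and logical
#'   `corrected`.
#' @examples
#' compute_dnds(10, 1000, 10, 250)           # dN = 0.01, dS = 0.04, ratio = 0.25
#' compute_dnds(4, 400, 4, 200)              # pooled counts work the same way
#' @export
compute_dnds <- function(n_diff, n_opp, s_diff, s_opp,
                         correction = c("none", "jukes_cantor"),
                         ids = NULL) {
  correction <- match.arg(correction)
  n <- max(length(n_diff), length(n_opp), length(s_diff), length(s_opp))
  records <- data.frame(
    n_diff = rep_len(n_diff, n), n_opp = rep_len(n_opp, n),
    s_diff = rep_len(s_diff, n), s_opp = rep_len(s_opp, n)
  )
  bad <- validate_counts(records, "compute_dnds")
  if (length(bad)) {
    lab <- if (!is.null(ids)) rep_len(ids, n)[bad] else bad
    stopf("compute_dnds: invalid counts for record(s) %s",
          paste(utils::head(lab, 5), collapse = ", "))
  }
  pn <- records$n_diff / records$n_opp
  ps <- records$s_diff / records$s_opp
  if (correction == "jukes_cantor") {
    sat <- which(pn >= 0.75 | ps >= 0.75)
    if (length(sat)) {
      lab <- if (!is.null(ids)) rep_len(ids, n)[sat] else sat
      stopf("jukes_cantor correction undefined (proportion >= 3/4) for record(s) %s",
            paste(utils::head(lab, 5), collapse = ", "))
    }
    dN <- jc_correct(pn)
    dS <- jc_correct(ps)
  } else {
    dN <- pn
    dS <- ps
  }
  ratio <- ifelse(dS > 0, dN / dS, NA_real_)
  data.frame(dN = dN, dS = dS, ratio = ratio,
             corrected = correction == "jukes_cantor")
}

#' Jukes-Cantor multiple-hit correction of a difference proportion
#'
#' @param p Proportion of differing sites, in `[0, 3/4)`.
#' @return Corrected divergence `-(3/4) * log(1 - (4/3) * p)`.
#' @export
jc_correct <- function(p) {
  if (any(p < 0 | p >= 0.75)) stopf("jc_correct: p must lie in [0, 0.75)")
  -0.75 * log1p(-(4 / 3) * p)
}

#' Pool substitution counts over a set of records
#'
#' Pooled divergence is always the "ratio of sums", never a mean of per-gene
#' ratios: the four count fields are summed field-wise and the sums fed to
#' [compute_dnds()].  This keeps group estimates well-defined when individual
#' genes have few or zero synonymous differences.
#'
#' @param records Data frame with columns `n_diff`, `n_opp`, `s_diff`,
#'   `s_opp` (extra columns ignored).
#' @return One-row data frame of summed counts.
#' @export
pool_counts <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stopf("pool_counts: empty record set")
  }
  bad <- validate_counts(records, "pool_counts")
  if (length(bad)) stopf("pool_counts: invalid counts at rows %s",
                         paste(utils::head(bad, 5), collapse = ", "))
  data.frame(
    n_diff = sum(records$n_diff), n_opp = sum(records$n_opp),
    s_diff = sum(records$s_diff), s_opp = sum(records$s_opp)
  )
}

#' Filter unreliable divergence records
#'
#' Two rules guard the ratio against noise at small synonymous counts:
#' genes with fewer than `min_s_opp` synonymous opportunities are dropped,
#' and entire lineage pairs whose genome-wide pooled dS falls outside
#' `[min_pair_dS, max_pair_dS]` are dropped (too-low dS makes every ratio
#' unstable; too-high dS risks saturation).  Thresholds are configuration,
#' not a claim about how any particular published dataset was filtered.
#'
#' @param records Validated record data frame (see [read_records()]).
#' @param min_s_opp Minimum synonymous opportunities per gene (sites).
#' @param min_pair_dS,max_pair_dS Bounds on each lineage pair's genome-wide
#'   pooled dS (proportions).
#' @return A list with `records` (survivors) and `report` (counts dropped per
#'   rule, totals, thresholds).
#' @export
filter_records <- function(records, min_s_opp = 10, min_pair_dS = 0,
                           max_pair_dS = 0.75) {
  if (min_s_opp < 0 || min_pair_dS < 0 || max_pair_dS < 0) {
    stopf("filter_records: thresholds must be non-negative")
  }
  if (min_pair_dS >= max_pair_dS) {
    stopf("filter_records: min_pair_dS must be < max_pair_dS")
  }
  n_input <- nrow(records)
  keep_gene <- records$s_opp >= min_s_opp
  n_gene_dropped <- sum(!keep_gene)
  rec <- records[keep_gene, , drop = FALSE]

  n_pair_dropped <- 0L
  pairs_dropped <- character(0)
  if (nrow(rec)) {
    key <- paste(rec$species_id, rec$pair_id, sep = "\r")
    s_diff <- rowsum(rec$s_diff, key)
    s_opp <- rowsum(rec$s_opp, key)
    pair_dS <- as.vector(s_diff) / as.vector(s_opp)
    ok_pair <- pair_dS >= min_pair_dS & pair_dS <= max_pair_dS
    bad_keys <- rownames(s_diff)[!ok_pair]
    keep_pair <- !(key %in% bad_keys)
    n_pair_dropped <- sum(!keep_pair)
    pairs_dropped <- sub("\r", "/", bad_keys, fixed = TRUE)
    rec <- rec[keep_pair, , drop = FALSE]
  }
  if (nrow(rec) == 0L) {
    stopf(paste0("filter_records: all %d records removed; review thresholds ",
                 "(min_s_opp=%g, pair dS in [%g, %g])"),
          n_input, min_s_opp, min_pair_dS, max_pair_dS)
  }
  rownames(rec) <- NULL
  list(
    records = rec,
    report = list(
      n_input = n_input,
      n_dropped_low_s_opp = n_gene_dropped,
      n_pairs_dropped = length(pairs_dropped),
      n_dropped_pair_dS = n_pair_dropped,
      pairs_dropped = pairs_dropped,
      n_output = nrow(rec),
      thresholds = list(min_s_opp = min_s_opp, min_pair_dS = min_pair_dS,
                        max_pair_dS = max_pair_dS)
    )
  )
}
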