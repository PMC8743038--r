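# Paired permutation tests on the species x pathway matrix.
#
# Species test: each pathway column's values are shuffled among species,
# giving a null for every species' mean dN/dS that respects both the
# pathway composition and the missingness geometry.  Pathway test: the
# mirror image, shuffling within each species row.  Flags follow the 95%
# percentile interval of the null; empirical p-values (two-sided, deviation
# from the null median, add-one corrected) and BH q-values are reported
# alongside for reuse.

#' Two-sided empirical p-value against a permutation null
#'
#' `p = (1 + #\{null at least as extreme as observed\}) / (B + 1)` where
#' extremeness is absolute deviation from the null median.  The add-one
#' correction keeps p in `[1/(B+1), 1]`.
#'
#' @param observed Observed statistic (scalar).
#' @param null_values Numeric vector of null draws (non-empty).
#' @return The empirical p-value.
#' @export
empirical_pvalue <- function(observed, null_values) {
  if (!length(null_values)) stopf("empirical_pvalue: empty null")
  med <- stats::median(null_values)
  dev <- abs(observed - med)
  (1 + sum(abs(null_values - med) >= dev - 1e-12)) / (length(null_values) + 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Monotone q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stopf("bh_adjust: p-values must be in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Shared engine: permutes within columns of `values`, scores rows.
# `exact = TRUE` enumerates every combination of within-column permutations
# (feasible only for tiny matrices); otherwise B Monte-Carlo draws.
perm_engine <- function(values, B, seed, statistic, exact, unit_label,
                        min_rows, min_cols) {
  stat_fun <- switch(statistic, mean = function(z) mean(z), median = stats::median)
  active <- rowSums(!is.na(values)) > 0
  if (any(!active)) {
    message(sprintf("permutation test: omitting %d fully masked %s(s)",
                    sum(!active), unit_label))
  }
  v <- values[active, , drop = FALSE]
  S <- nrow(v); P <- ncol(v)
  if (S < min_rows || P < min_cols) {
    stopf("permutation test: need a matrix of >= 3 species and >= 2 pathways with data (have %d %ss x %d groups)",
          S, unit_label, P)
  }
  col_rows <- lapply(seq_len(P), function(j) which(!is.na(v[, j])))
  col_vals <- lapply(seq_len(P), function(j) v[col_rows[[j]], j])
  counts <- rowSums(!is.na(v))
  if (statistic == "mean" && !exact) {
    # accumulate the observed statistic with the same arithmetic as the
    # null sums so that exchangeable-and-constant inputs tie exactly
    obs_sums <- numeric(S)
    for (j in seq_len(P)) {
      obs_sums[col_rows[[j]]] <- obs_sums[col_rows[[j]]] + col_vals[[j]]
    }
    observed <- obs_sums / counts
  } else {
    observed <- apply(v, 1, function(z) stat_fun(z[!is.na(z)]))
  }

  if (exact) {
    null_mat <- exact_null(v, col_rows, col_vals, counts, stat_fun)
    B_eff <- ncol(null_mat)
    # The identity assignment is one of the enumerated ones: no add-one.
    p <- vapply(seq_len(S), function(s) {
      med <- stats::median(null_mat[s, ])
      mean(abs(null_mat[s, ] - med) >= abs(observed[s] - med) - 1e-12)
    }, numeric(1))
  } else {
    if (B < 100) warnf("permutation test: B = %d is very small; results will be unstable", B)
    null_mat <- with_seed(seed, {
      sums <- matrix(0, S, B)
      if (statistic == "mean") {
        for (j in seq_len(P)) {
          rows <- col_rows[[j]]; vals <- col_vals[[j]]; n <- length(rows)
          idx <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
          sums[rows, ] <- sums[rows, , drop = FALSE] + matrix(vals[idx], n, B)
        }
        sums / counts
      } else {
        draws <- array(NA_real_, c(S, P, B))
        for (j in seq_len(P)) {
          rows <- col_rows[[j]]; vals <- col_vals[[j]]; n <- length(rows)
          idx <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
          draws[rows, j, ] <- matrix(vals[idx], n, B)
        }
        apply(draws, c(1, 3), function(z) stat_fun(z[!is.na(z)]))
      }
    })
    B_eff <- B
    p <- vapply(seq_len(S), function(s) empirical_pvalue(observed[s], null_mat[s, ]),
                numeric(1))
  }

  lo <- apply(null_mat, 1, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(null_mat, 1, stats::quantile, probs = 0.975, names = FALSE)
  flag <- ifelse(observed < lo, "stronger", ifelse(observed > hi, "weaker", "none"))
  res <- data.frame(
    unit_id = rownames(v), observed = observed, null_lo = lo, null_hi = hi,
    empirical_p = p, q_value = bh_adjust(p), flag = flag,
    n_cells = counts, row.names = NULL
  )
  attr(res, "n_perm") <- B_eff
  attr(res, "seed") <- if (exact) NA_integer_ else seed
  attr(res, "statistic") <- statistic
  attr(res, "exact") <- exact
  class(res) <- c("perm_result", "data.frame")
  res
}

# Enumerate the cartesian product of per-column permutations.
exact_null <- function(v, col_rows, col_vals, counts, stat_fun) {
  sizes <- vapply(col_vals, length, integer(1))
  total <- prod(factorial(sizes))
  if (total > 2e5) stopf("exact permutation test infeasible: %.3g assignments", total)
  perm_sets <- lapply(sizes, all_perms)
  grid <- expand.grid(lapply(perm_sets, seq_along), KEEP.OUT.ATTRS = FALSE)
  S <- nrow(v)
  null_mat <- matrix(NA_real_, S, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    vk <- v
    for (j in seq_along(col_vals)) {
      perm <- perm_sets[[j]][[grid[k, j]]]
      vk[col_rows[[j]], j] <- col_vals[[j]][perm]
    }
    null_mat[, k] <- apply(vk, 1, function(z) stat_fun(z[!is.na(z)]))
  }
  null_mat
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (i in seq_len(n)) {
    for (p in sub) {
      q <- integer(n)
      q[i] <- n
      q[-i] <- p
      out[[k]] <- q
      k <- k + 1L
    }
  }
  out
}

#' Identify species under exceptional constraint
#'
#' The statistic per species is the mean dN/dS over its unmasked pathway
#' cells.  The null shuffles values among species independently within
#' every pathway column (mask geometry fixed), so each species' null mean
#' reflects "a typical species with this pathway repertoire".  A species is
#' flagged `"stronger"` (purifying selection stronger than expected by
#' chance) when its observed mean falls below the null 2.5% quantile, and
#' `"weaker"` above the 97.5% quantile.
#'
#' @param pm A [pathway_matrix()] (or bare matrix with dimnames).
#' @param B Number of permutations.
#' @param seed RNG seed; results are bit-reproducible given
#'   `(matrix, B, seed)`.
#' @param statistic `"mean"` (default) or `"median"`.
#' @param exact Enumerate all within-column permutations instead of
#'   sampling (tiny matrices only); p-values are then exact.
#' @return A `perm_result` data frame: `unit_id`, `observed`, `null_lo`,
#'   `null_hi`, `empirical_p`, `q_value`, `flag`, `n_cells`.
#' @export
test_species <- function(pm, B = 10000, seed = 1,
                         statistic = c("mean", "median"), exact = FALSE) {
  statistic <- match.arg(statistic)
  v <- if (inherits(pm, "pathway_matrix")) pm$values else pm
  perm_engine(v, B, seed, statistic, exact, "species",
              min_rows = 3, min_cols = 2)
}

#' Identify pathways under exceptional constraint
#'
#' Mirror of [test_species()] with rows and columns exchanged: values are
#' shuffled across pathways within each species row, and the statistic per
#' pathway is its mean over species.  By construction
#' `test_pathways(m)` equals `test_species(t(m))` bit-exactly.
#'
#' @inheritParams test_species
#' @return A `perm_result` data frame (one row per pathway).
#' @export
test_pathways <- function(pm, B = 10000, seed = 1,
                          statistic = c("mean", "median"), exact = FALSE) {
  statistic <- match.arg(statistic)
  v <- if (inherits(pm, "pathway_matrix")) pm$values else pm
  perm_engine(t(v), B, seed, statistic, exact, "pathway",
              min_rows = 2, min_cols = 3)
}

#' @export
print.perm_result <- function(x, ...) {
  n_flag <- sum(x$flag != "none")
  cat(sprintf("permutation test (%s, %s permutations): %d/%d unit(s) outside the 95%% null interval\n",
              attr(x, "statistic"),
              if (isTRUE(attr(x, "exact"))) "exact" else format(attr(x, "n_perm")),
              n_flag, nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a permutation-test result table as TSV
#'
#' @param res A `perm_result`.
#' @param path Output path.
#' @param header Optional comment-header lines.
#' @return `path`, invisibly.
#' @export
write_perm_result <- function(res, path, header = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con, sep = "\n")
  writeLines(paste(c("unit_id", "observed", "null_lo", "null_hi",
                     "empirical_p", "q_value", "flag", "n_cells"),
                   collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(res))) {
    writeLines(paste(c(res$unit_id[i],
                       format_num(c(res$observed[i], res$null_lo[i], res$null_hi[i],
                                    res$empirical_p[i], res$q_value[i])),
                       res$flag[i], res$n_cells[i]), collapse = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}
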