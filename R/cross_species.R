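# Cross-species statistics: mean-variance scaling of pathway dN/dS and the
# decay of between-species constraint correlation with phylogenetic
# distance.

#' Taylor's-law regression of pathway variance on pathway mean
#'
#' Across pathways, ordinary least squares of `log10(variance)` on
#' `log10(mean)` of dN/dS over species.  A slope of 2 on these axes is
#' equivalent to a constant coefficient of variation across pathways, so
#' the fit carries a t-test of the slope against 2
#' (`t = (slope - 2) / se`, df = n_pathways - 2) with both the one-sided
#' (upper tail, "variance grows faster than the square of the mean") and
#' two-sided p-values.
#'
#' @param pm A [pathway_matrix()].
#' @param min_species_per_pathway Pathways present in fewer species are
#'   excluded.
#' @return Object of class `scaling_fit`: `slope`, `intercept`, `slope_se`,
#'   `t_vs_2`, `p_one_sided`, `p_two_sided`, `n_pathways`, plus the
#'   per-pathway table used.
#' @export
taylor_regression <- function(pm, min_species_per_pathway = 3) {
  s <- matrix_summaries(pm, min_species = min_species_per_pathway)$pathways
  zero_var <- s$variance <= 0
  if (any(zero_var)) {
    warnf("taylor_regression: excluding %d pathway(s) with zero variance (log undefined)",
          sum(zero_var))
    s <- s[!zero_var, , drop = FALSE]
  }
  if (any(s$mean <= 0)) stopf("taylor_regression: pathway means must be > 0")
  if (nrow(s) < 3) stopf("taylor_regression: need >= 3 usable pathways, got %d", nrow(s))
  fit <- stats::lm(log10(variance) ~ log10(mean), data = s)
  co <- summary(fit)$coefficients
  slope <- co[2, 1]; se <- co[2, 2]
  df <- nrow(s) - 2
  t2 <- (slope - 2) / se
  structure(
    list(slope = slope, intercept = co[1, 1], slope_se = se,
         t_vs_2 = t2,
         p_one_sided = stats::pt(t2, df, lower.tail = FALSE),
         p_two_sided = 2 * stats::pt(abs(t2), df, lower.tail = FALSE),
         n_pathways = nrow(s), df = df, pathways = s),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Taylor's-law fit over %d pathways: slope = %.3f (se %.3f)\n",
              x$n_pathways, x$slope, x$slope_se))
  cat(sprintf("  H0 slope = 2: t = %.3f, one-sided P = %.3f, two-sided P = %.3f\n",
              x$t_vs_2, x$p_one_sided, x$p_two_sided))
  invisible(x)
}

#' Coefficient-of-variation summary of pathway dN/dS
#'
#' Per-pathway CV (sd/mean across species) plus the median CV with a
#' seeded bootstrap percentile CI over pathways.  A median CV of 1 is the
#' Taylor-slope-2 regime where the mean equals the standard deviation.
#'
#' @param pm A [pathway_matrix()].
#' @param min_species Presence threshold per pathway.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @param conf Confidence level.
#' @return List: `pathways` (per-pathway CV table), `median_cv`, `ci_lo`,
#'   `ci_hi`.
#' @export
cv_summary <- function(pm, min_species = 3, n_boot = 1000, seed = 1,
                       conf = 0.95) {
  s <- matrix_summaries(pm, min_species = min_species)$pathways
  cv <- s$cv[!is.na(s$cv)]
  if (!length(cv)) stopf("cv_summary: no pathway with defined CV")
  alpha <- (1 - conf) / 2
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    stats::median(cv[sample.int(length(cv), replace = TRUE)])
  }, numeric(1)))
  list(pathways = s, median_cv = stats::median(cv),
       ci_lo = unname(stats::quantile(boots, alpha)),
       ci_hi = unname(stats::quantile(boots, 1 - alpha)))
}

#' Between-species correlation of pathway constraint profiles
#'
#' For every pair of species sharing at least `min_shared_pathways`
#' unmasked pathways, the Pearson correlation of their `log10` pathway
#' dN/dS vectors over the shared pathways (Spearman available by flag;
#' rank correlation ignores the log).  Pairs with a zero-variance vector
#' are dropped (correlation undefined).
#'
#' @param pm A [pathway_matrix()].
#' @param min_shared_pathways Minimum shared unmasked pathways per pair.
#' @param method `"pearson"` (default, on log10 values) or `"spearman"`.
#' @return Data frame: `species_a`, `species_b`, `r`, `n_shared`.
#' @export
pairwise_pathway_correlation <- function(pm, min_shared_pathways = 5,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(pm, "pathway_matrix"))
  v <- pm$values
  if (method == "pearson") {
    if (any(v <= 0, na.rm = TRUE)) {
      warnf("pairwise_pathway_correlation: masking %d non-positive cell(s) for log scaling",
            sum(v <= 0, na.rm = TRUE))
      v[v <= 0] <- NA_real_
    }
    v <- log10(v)
  }
  sp <- rownames(v)
  S <- length(sp)
  out <- vector("list", S * (S - 1) / 2)
  k <- 0L; dropped <- 0L
  for (i in seq_len(S - 1)) {
    for (j in seq(i + 1, S)) {
      shared <- which(!is.na(v[i, ]) & !is.na(v[j, ]))
      if (length(shared) < min_shared_pathways) { dropped <- dropped + 1L; next }
      a <- v[i, shared]; b <- v[j, shared]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) { dropped <- dropped + 1L; next }
      k <- k + 1L
      out[[k]] <- data.frame(
        species_a = sp[i], species_b = sp[j],
        r = stats::cor(a, b, method = method), n_shared = length(shared)
      )
    }
  }
  if (dropped) message(sprintf(
    "pairwise_pathway_correlation: dropped %d pair(s) (overlap < %d or zero variance)",
    dropped, min_shared_pathways))
  if (!k) stopf("pairwise_pathway_correlation: no species pair with sufficient overlap")
  do.call(rbind, out[seq_len(k)])
}

#' Tip-to-tip phylogenetic distances
#'
#' Cophenetic distances on a phylogeny with branch lengths: the distance
#' between two tips is the sum of branch lengths on the path joining them.
#'
#' @param tree An `ape::phylo` object or path to a newick file.
#' @param species Optional character vector; the tree's tip set must match
#'   it exactly, and the returned matrix is ordered accordingly.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = tips.
#' @export
cophenetic_distances <- function(tree, species = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stopf("cophenetic_distances: tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    stopf("cophenetic_distances: duplicate tip labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(species)) {
    missing_tips <- setdiff(species, rownames(d))
    extra_tips <- setdiff(rownames(d), species)
    if (length(missing_tips) || length(extra_tips)) {
      stopf("cophenetic_distances: tip/species mismatch; missing: [%s]; extra: [%s]",
            paste(missing_tips, collapse = ", "), paste(extra_tips, collapse = ", "))
    }
    d <- d[species, species]
  }
  d
}

#' Decay of pathway-constraint correlation with phylogenetic distance
#'
#' OLS slope (beta) of the between-species correlations on the pairwise
#' phylogenetic distance.  Because pairs share species and are therefore
#' not independent, significance comes from a Mantel-style permutation:
#' species labels of the distance matrix are permuted jointly and the
#' slope recomputed, giving a two-sided permutation p for beta.  The
#' analytic OLS p-value is reported alongside for transparency only.
#'
#' @param correlations Output of [pairwise_pathway_correlation()].
#' @param distances Square distance matrix (see [cophenetic_distances()]),
#'   or path to a square TSV with species ids as header row and first
#'   column.
#' @param n_mantel Number of label permutations.
#' @param seed RNG seed.
#' @param exact Enumerate all label permutations (S <= 8 species).
#' @return Object of class `phylo_signal_fit`: `beta`, `intercept`,
#'   `p_mantel`, `p_ols`, `n_pairs`, `n_species`, `n_mantel`.
#' @export
phylo_distance_regression <- function(correlations, distances,
                                      n_mantel = 999, seed = 1,
                                      exact = FALSE) {
  if (is.character(distances)) distances <- read_distance_tsv(distances)
  if (!isSymmetric(unname(distances)) || any(diag(distances) != 0) ||
      any(distances < 0)) {
    stopf("phylo_distance_regression: distances must be symmetric, non-negative, zero diagonal")
  }
  sp <- sort_c(unique(c(correlations$species_a, correlations$species_b)))
  missing_sp <- setdiff(sp, rownames(distances))
  if (length(missing_sp)) {
    stopf("phylo_distance_regression: no distance for species: %s",
          paste(missing_sp, collapse = ", "))
  }
  ia <- match(correlations$species_a, rownames(distances))
  ib <- match(correlations$species_b, rownames(distances))
  r <- correlations$r
  d_obs <- distances[cbind(ia, ib)]
  if (stats::sd(d_obs) == 0) stopf("phylo_distance_regression: distances are constant; beta undefined")

  slope_of <- function(d) {
    stats::cov(r, d) / stats::var(d)
  }
  beta <- slope_of(d_obs)
  intercept <- mean(r) - beta * mean(d_obs)

  n <- length(r)
  p_ols <- NA_real_
  if (n > 2) {
    ss_res <- sum((r - intercept - beta * d_obs)^2)
    se <- sqrt(ss_res / (n - 2) / sum((d_obs - mean(d_obs))^2))
    p_ols <- 2 * stats::pt(abs(beta / se), n - 2, lower.tail = FALSE)
  }

  S <- nrow(distances)
  if (exact) {
    if (S > 8) stopf("exact Mantel enumeration infeasible for %d species", S)
    perms <- all_perms(S)
    betas <- vapply(perms, function(pp) {
      slope_of(distances[cbind(pp[ia], pp[ib])])
    }, numeric(1))
    p_mantel <- mean(abs(betas) >= abs(beta) - 1e-12)
    n_used <- length(perms)
  } else {
    betas <- with_seed(seed, vapply(seq_len(n_mantel), function(b) {
      pp <- sample.int(S)
      slope_of(distances[cbind(pp[ia], pp[ib])])
    }, numeric(1)))
    p_mantel <- (1 + sum(abs(betas) >= abs(beta) - 1e-12)) / (n_mantel + 1)
    n_used <- n_mantel
  }
  structure(
    list(beta = beta, intercept = intercept, p_mantel = p_mantel,
         p_ols = p_ols, n_pairs = n, n_species = S, n_mantel = n_used,
         exact = exact),
    class = "phylo_signal_fit"
  )
}

#' @export
print.phylo_signal_fit <- function(x, ...) {
  cat(sprintf("correlation-vs-distance regression over %d pairs (%d species):\n",
              x$n_pairs, x$n_species))
  cat(sprintf("  beta = %.4f, Mantel P = %.4g (%s permutations), analytic OLS P = %.3g\n",
              x$beta, x$p_mantel,
              if (isTRUE(x$exact)) "all" else format(x$n_mantel), x$p_ols))
  invisible(x)
}

#' Read / write a square distance matrix TSV
#'
#' Header row and first column carry species ids; the body is numeric.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_distance_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1]]
  m
}

#' @rdname read_distance_tsv
#' @param distances Square matrix with dimnames.
#' @export
write_distance_tsv <- function(distances, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("species_id", colnames(distances)), collapse = "\t"),
             con, sep = "\n")
  for (i in seq_len(nrow(distances))) {
    writeLines(paste(c(rownames(distances)[i], format_num(distances[i, ])),
                     collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}
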