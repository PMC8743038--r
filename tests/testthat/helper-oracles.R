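# Fixtures and independent oracles used across test files.  Oracles are
# deliberately naive (enumeration, nested loops, closed forms) and never
# call the code paths they check.

make_records <- function(n, seed = 1) {
  # Random but valid record table spanning several species/pairs/pathways.
  set.seed(seed)
  data.frame(
    species_id = sprintf("sp%02d", sample(1:4, n, replace = TRUE)),
    pair_id = sprintf("pair%02d", sample(1:3, n, replace = TRUE)),
    gene_id = sprintf("g%03d", seq_len(n)),
    pathway_id = sprintf("P%02d", sample(1:3, n, replace = TRUE)),
    n_diff = rbinom(n, 50, 0.1), n_opp = sample(500:900, n, replace = TRUE),
    s_diff = rbinom(n, 30, 0.2), s_opp = sample(150:350, n, replace = TRUE)
  )
}

# Enumerate all permutations of 1..n (naive recursion, independent of the
# package's enumerator).
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Exhaustive within-column permutation null for a fully observed matrix:
# returns, for each row, the vector of row statistics over every
# combination of per-column permutations.
oracle_column_null <- function(m, stat = mean) {
  S <- nrow(m); P <- ncol(m)
  col_perms <- lapply(seq_len(P), function(j) oracle_perms(S))
  combos <- expand.grid(lapply(col_perms, seq_along))
  null <- matrix(NA_real_, S, nrow(combos))
  for (k in seq_len(nrow(combos))) {
    mk <- m
    for (j in seq_len(P)) mk[, j] <- m[col_perms[[j]][[combos[k, j]]], j]
    null[, k] <- apply(mk, 1, stat)
  }
  null
}

oracle_exact_p <- function(observed, null_row) {
  med <- median(null_row)
  mean(abs(null_row - med) >= abs(observed - med) - 1e-12)
}

# Tip-to-tip path-length oracle: walk both tips up to the root, sum branch
# lengths below the deepest shared ancestor.
oracle_tree_distance <- function(tree, tip_a, tip_b) {
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  path_up <- function(tip) {
    node <- tip; nodes <- node; lens <- numeric(0)
    while (length(p <- parent_of(node))) {
      e <- which(tree$edge[, 2] == node)
      lens <- c(lens, tree$edge.length[e])
      node <- p; nodes <- c(nodes, node)
    }
    list(nodes = nodes, cum = c(0, cumsum(lens)))
  }
  a <- path_up(which(tree$tip.label == tip_a))
  b <- path_up(which(tree$tip.label == tip_b))
  shared <- intersect(a$nodes, b$nodes)
  mrca <- shared[which.min(match(shared, a$nodes))]
  a$cum[match(mrca, a$nodes)] + b$cum[match(mrca, b$nodes)]
}

# Small full pathway matrix from a plain numeric matrix.
pm_from <- function(m, species = sprintf("s%02d", seq_len(nrow(m))),
                    pathways = sprintf("P%02d", seq_len(ncol(m)))) {
  dimnames(m) <- list(species, pathways)
  pathway_matrix(m)
}
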