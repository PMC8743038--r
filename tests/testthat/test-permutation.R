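# Permutation tests for exceptional species and pathways.

test_that("empirical_pvalue follows the add-one deviation-from-median rule", {
  # observed beyond every null value
  expect_equal(empirical_pvalue(10, rnorm(999)), 1 / 1000)
  # observed at the null median
  expect_equal(empirical_pvalue(0.5, c(0.1, 0.3, 0.5, 0.7, 0.9)), 1)
  # hand enumeration on 5 values: median 0.3, |obs-med| = 0.25,
  # deviations (0.2, 0.1, 0, 0.3, 0.6) -> 2 at least as extreme
  expect_equal(empirical_pvalue(0.55, c(0.1, 0.2, 0.3, 0.6, 0.9)), 3 / 6)
  expect_error(empirical_pvalue(1, numeric(0)), "empty")
})

test_that("bh_adjust matches the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(8)
  p <- runif(25)
  q <- bh_adjust(p)
  # oracle: q_i = min over j with p_j >= p_i of m * p_j / rank_j
  # oracle: sort, scale by m/rank, enforce monotonicity from the top
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  q_sorted <- m * ranked / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  expect_equal(q[o], pmin(q_sorted, 1))
  expect_true(all(q >= p))
  expect_error(bh_adjust(c(0, 0.5)), "p-values")
})

test_that("constant matrices flag nothing and give p = 1", {
  pm <- pm_from(matrix(0.1, 4, 3))
  for (res in list(test_species(pm, B = 300, seed = 1),
                   test_pathways(pm, B = 300, seed = 1))) {
    expect_true(all(res$flag == "none"))
    expect_true(all(res$empirical_p == 1))
    expect_true(all(res$null_lo <= res$null_hi))
  }
})

test_that("exact species test matches exhaustive enumeration (3 x 2, 36 assignments)", {
  m <- matrix(c(0.1, 0.1, 0.5,
                0.1, 0.1, 0.5), nrow = 3)
  pm <- pm_from(m, species = c("A", "B", "C"))
  res <- test_species(pm, exact = TRUE)
  null <- oracle_column_null(m)
  expect_equal(ncol(null), 36)
  for (i in 1:3) {
    expect_equal(res$empirical_p[i], oracle_exact_p(mean(m[i, ]), null[i, ]))
  }
  # species C has the largest observed mean and the smallest p
  expect_equal(res$observed[res$unit_id == "C"], 0.5)
})

test_that("exact pathway test matches exhaustive enumeration (2^3 within-row swaps)", {
  m <- matrix(c(0.1, 0.1, 0.1,
                0.2, 0.2, 0.2), nrow = 3)  # pathway Q uniformly half of R
  pm <- pm_from(m, pathways = c("Q", "R"))
  res <- test_pathways(pm, exact = TRUE)
  null <- oracle_column_null(t(m))  # transpose: columns become species rows
  expect_equal(ncol(null), 8)
  for (i in 1:2) {
    expect_equal(res$empirical_p[i], oracle_exact_p(mean(m[, i]), null[i, ]))
  }
  expect_lt(res$observed[res$unit_id == "Q"], res$observed[res$unit_id == "R"])
})

test_that("test_pathways is test_species on the transpose (duality)", {
  set.seed(3)
  m <- matrix(rlnorm(6 * 5, -2, 0.5), 6, 5)
  m[cbind(c(2, 4), c(1, 3))] <- NA
  pm <- pm_from(m)
  a <- test_pathways(pm, B = 400, seed = 9)
  b <- test_species(pm_from(t(m), species = colnames(pm$values),
                            pathways = rownames(pm$values)), B = 400, seed = 9)
  expect_equal(a$observed, b$observed)
  expect_equal(a$empirical_p, b$empirical_p)
  expect_equal(a$null_lo, b$null_lo)
  expect_equal(a$flag, b$flag)
})

test_that("permutations preserve column multisets and respect the mask", {
  # rows whose values are a permutation of the same multiset have invariant
  # row means under within-row permutation
  base <- c(0.1, 0.2, 0.4, 0.8)
  m <- rbind(base, rev(base), base[c(2, 1, 4, 3)])
  pm <- pm_from(m)
  res <- test_pathways(pm, B = 200, seed = 5)
  # every within-row shuffle preserves each species' mean: pathway nulls
  # still vary, but species means are conserved by construction
  sp <- test_species(pm, B = 200, seed = 5)
  expect_equal(sort(unname(sp$observed)), sort(unname(rowMeans(m))))

  # masked cells never receive values: a fully masked species is dropped
  m2 <- matrix(rlnorm(12), 4, 3)
  m2[4, ] <- NA
  expect_message(res2 <- test_species(pm_from(m2), B = 200, seed = 1),
                 "fully masked")
  expect_equal(nrow(res2), 3)
})

test_that("results are bit-reproducible given (matrix, B, seed) and stable at large B", {
  set.seed(10)
  m <- matrix(rlnorm(8 * 5, -2, 0.4), 8, 5)
  m[1, ] <- m[1, ] * 6  # clearly exceptional species
  pm <- pm_from(m)
  r1 <- test_species(pm, B = 2000, seed = 42)
  r2 <- test_species(pm, B = 2000, seed = 42)
  expect_identical(r1, r2)
  r3 <- test_species(pm, B = 2000, seed = 77)
  expect_equal(r1$flag, r3$flag)  # flag set stable across seeds at large B
  expect_equal(r1$flag[1], "weaker")
  expect_true(all(r1$empirical_p >= 1 / 2001))

  expect_warning(test_species(pm, B = 50, seed = 1), "very small")
  expect_error(test_species(pm_from(matrix(1, 2, 4)), B = 200), ">= 3")
})
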