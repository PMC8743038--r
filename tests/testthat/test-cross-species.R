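# Taylor's-law scaling, CV, pairwise correlations and phylogenetic decay.

test_that("taylor_regression recovers slope 2 on a constructed identity", {
  # variance = mean^2 exactly: CV = 1, log-log slope = 2
  means <- c(0.05, 0.1, 0.2, 0.35)
  # 3-species matrix whose column sd equals its column mean exactly
  mat <- sapply(means, function(m) m + c(-1, 0, 1) * m / sd(c(-1, 0, 1)))
  pm <- pm_from(mat)
  s <- matrix_summaries(pm)$pathways
  expect_equal(s$variance, s$mean^2, tolerance = 1e-12)
  fit <- suppressWarnings(taylor_regression(pm))  # "essentially perfect fit"
  # slope is 2 up to the fp noise of the construction; t_vs_2 is a ratio
  # of that same noise to a near-zero se, so only the slope is asserted
  expect_equal(fit$slope, 2, tolerance = 1e-6)
})

test_that("taylor_regression matches closed-form OLS and is scale-invariant", {
  set.seed(4)
  mat <- matrix(rlnorm(5 * 6, -2, 0.6), 5, 6)
  pm <- pm_from(mat)
  fit <- taylor_regression(pm)
  # normal-equations oracle
  x <- log10(apply(mat, 2, mean)); y <- log10(apply(mat, 2, var))
  bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  se <- sqrt(sum((y - mean(y) - bx * (x - mean(x)))^2) / (length(x) - 2) /
               sum((x - mean(x))^2))
  expect_equal(fit$slope, bx, tolerance = 1e-12)
  expect_equal(fit$slope_se, se, tolerance = 1e-12)
  expect_equal(fit$t_vs_2, (bx - 2) / se, tolerance = 1e-12)

  # multiplying all values by k > 0 moves only the intercept
  fit_k <- taylor_regression(pm_from(mat * 3.7))
  expect_equal(fit_k$slope, fit$slope, tolerance = 1e-9)

  # relabeling pathways changes nothing
  mat2 <- mat[, c(3, 1, 2, 6, 5, 4)]
  expect_equal(taylor_regression(pm_from(mat2))$slope, fit$slope,
               tolerance = 1e-12)
})

test_that("zero-variance pathways are excluded with a warning", {
  mat <- cbind(matrix(rlnorm(15, -2, 0.5), 5, 3), rep(0.2, 5))
  expect_warning(fit <- taylor_regression(pm_from(mat)), "zero variance")
  expect_equal(fit$n_pathways, 3)
})

test_that("cv_summary reports CV per pathway and a median with CI", {
  # sd exactly equal to mean in every pathway -> all CV = 1
  mat <- sapply(c(0.05, 0.1, 0.4), function(m) m + c(-1, 0, 1) * m / sd(c(-1, 0, 1)))
  cv <- cv_summary(pm_from(mat), n_boot = 200, seed = 2)
  expect_equal(cv$pathways$cv, rep(1, 3), tolerance = 1e-12)
  expect_equal(cv$median_cv, 1, tolerance = 1e-12)
  # constant rows -> CV 0
  cv0 <- cv_summary(pm_from(matrix(0.2, 4, 3)), n_boot = 50, seed = 1)
  expect_equal(cv0$median_cv, 0)
})

test_that("pairwise correlations behave like Pearson on log values", {
  v <- c(0.02, 0.05, 0.1, 0.3, 0.6)
  # identical vectors -> r = 1; multiplicative scaling -> still r = 1
  mat <- rbind(v, v * 3, v)
  pm <- pm_from(mat)
  cors <- pairwise_pathway_correlation(pm, min_shared_pathways = 5)
  expect_equal(cors$r, rep(1, 3), tolerance = 1e-12)

  # covariance-formula oracle on 4 shared pathways
  a <- c(0.1, 0.2, 0.05, 0.4); b <- c(0.3, 0.1, 0.2, 0.25)
  pm2 <- pm_from(rbind(a, b), species = c("x", "y"),
                 pathways = sprintf("P%02d", 1:4))
  r <- pairwise_pathway_correlation(pm2, min_shared_pathways = 4)$r
  la <- log10(a); lb <- log10(b)
  oracle <- sum((la - mean(la)) * (lb - mean(lb))) /
    sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
  expect_equal(r, oracle, tolerance = 1e-12)

  # insufficient overlap and zero-variance pairs are dropped; only the
  # full-variation pair survives
  m3 <- rbind(v, c(0.02, 0.04, 0.2, 0.3, 0.7),
              c(NA, NA, NA, 0.1, 0.2), rep(0.1, 5))
  expect_message(c3 <- pairwise_pathway_correlation(pm_from(m3),
                                                    min_shared_pathways = 4),
                 "dropped")
  expect_equal(nrow(c3), 1)
  expect_equal(c3$n_shared, 5)
})

test_that("cophenetic distances equal hand-computed path sums", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- cophenetic_distances(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 3), rownames(d)))

  # star tree, all tips at depth h: all distances 2h
  star <- ape::read.tree(text = "(A:1.5,B:1.5,C:1.5,D:1.5);")
  ds <- cophenetic_distances(star)
  expect_true(all(ds[upper.tri(ds)] == 3))

  # random 8-tip tree vs naive path-walk oracle
  tr8 <- simulate_tree(8, seed = 21)
  d8 <- cophenetic_distances(tr8)
  for (pair in list(c("sp01", "sp05"), c("sp02", "sp08"), c("sp03", "sp04"))) {
    expect_equal(d8[pair[1], pair[2]],
                 oracle_tree_distance(tr8, pair[1], pair[2]),
                 tolerance = 1e-12)
  }

  no_bl <- ape::read.tree(text = "((A,B),C);")
  expect_error(cophenetic_distances(no_bl), "branch lengths")
  expect_error(cophenetic_distances(tr, species = c("A", "B", "Z")), "Z")
})

test_that("cophenetic distances satisfy the four-point condition", {
  tr <- simulate_tree(6, seed = 13)
  d <- cophenetic_distances(tr)
  tips <- rownames(d)
  combos <- combn(tips, 4)
  for (k in seq_len(ncol(combos))) {
    q <- combos[, k]
    sums <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                   d[q[1], q[3]] + d[q[2], q[4]],
                   d[q[1], q[4]] + d[q[2], q[3]]))
    expect_lt(abs(sums[2] - sums[3]), 1e-9)
  }
})

test_that("phylo_distance_regression: slopes, exact Mantel, degenerate cases", {
  # constant correlations -> beta = 0
  cors <- data.frame(species_a = c("A", "A", "B"), species_b = c("B", "C", "C"),
                     r = 0.5, n_shared = 5)
  d <- cophenetic_distances(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  fit <- phylo_distance_regression(cors, d, n_mantel = 99, seed = 1)
  expect_equal(fit$beta, 0)

  # two pairs only: exact two-point slope
  cors2 <- data.frame(species_a = c("A", "A"), species_b = c("B", "C"),
                      r = c(0.9, 0.3), n_shared = 5)
  fit2 <- phylo_distance_regression(cors2, d, n_mantel = 99, seed = 1)
  expect_equal(fit2$beta, (0.3 - 0.9) / (4 - 2), tolerance = 1e-12)

  # exact Mantel enumeration on 5 species matches a naive 5! oracle
  tr5 <- simulate_tree(5, seed = 17)
  d5 <- cophenetic_distances(tr5)
  sp <- rownames(d5)
  set.seed(6)
  pairs <- t(combn(sp, 2))
  cors5 <- data.frame(species_a = pairs[, 1], species_b = pairs[, 2],
                      r = runif(nrow(pairs), -0.2, 0.9), n_shared = 5)
  fit5 <- phylo_distance_regression(cors5, d5, exact = TRUE)
  ia <- match(cors5$species_a, sp); ib <- match(cors5$species_b, sp)
  slope_of <- function(dd) cov(cors5$r, dd) / var(dd)
  b_obs <- slope_of(d5[cbind(ia, ib)])
  betas <- sapply(oracle_perms(5), function(pp) slope_of(d5[cbind(pp[ia], pp[ib])]))
  expect_equal(fit5$p_mantel, mean(abs(betas) >= abs(b_obs) - 1e-12))
  expect_equal(fit5$beta, b_obs, tolerance = 1e-12)

  # constant distances -> error
  dc <- matrix(1, 3, 3) - diag(3)
  dimnames(dc) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_error(phylo_distance_regression(cors, dc), "constant")

  # distance matrix TSV round-trip feeds the regression identically
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(d5, path)
  fit5b <- phylo_distance_regression(cors5, path, exact = TRUE)
  expect_equal(fit5b$beta, fit5$beta)
})
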