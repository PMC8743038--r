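# Synthetic-data generator: tree, constraint field, divergence table.

test_that("simulate_tree is deterministic, normalized, and well-formed", {
  tr <- simulate_tree(3, seed = 5)
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)  # two join events for three tips

  a <- ape::write.tree(simulate_tree(12, seed = 9))
  b <- ape::write.tree(simulate_tree(12, seed = 9))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(simulate_tree(12, seed = 10))))

  d <- cophenetic_distances(simulate_tree(40, seed = 3))
  expect_equal(max(d), 1, tolerance = 1e-12)
})

test_that("constraint field: degenerate and white-noise limits", {
  tr <- simulate_tree(10, seed = 2)
  cfg0 <- generator_config(n_species = 10, n_pathways = 6, sigma_OU = 0, seed = 4)
  con0 <- simulate_constraints(tr, cfg0)
  # sigma_OU = 0: every species carries the pathway baseline exactly
  expect_equal(unname(con0$f_sel), matrix(rep(con0$theta, each = 10), 10, 6))

  # lambda -> infinity limit: cross-species correlation ~ 0
  cfg_ws <- generator_config(n_species = 10, n_pathways = 400,
                             lambda_OU = 100, sigma_OU = 0.1,
                             f_sel_range = c(0.7, 0.7), seed = 8)
  con_ws <- simulate_constraints(tr, cfg_ws)
  cors <- cor(t(con_ws$f_sel))
  expect_lt(median(abs(cors[upper.tri(cors)])), 0.12)

  expect_error(generator_config(lambda_OU = 0), "lambda_OU")
})

test_that("OU tip covariance follows the stationary closed form exp(-lambda d)", {
  # 2,000 replicate pathways on a fixed small tree; the empirical
  # correlation between two tips should match exp(-lambda * distance)
  tr <- simulate_tree(6, seed = 31)
  lambda <- 2
  cfg <- generator_config(n_species = 6, n_pathways = 2000, lambda_OU = lambda,
                          sigma_OU = 0.15, f_sel_range = c(0.5, 0.5), seed = 12)
  con <- simulate_constraints(tr, cfg)
  d <- cophenetic_distances(tr)[rownames(con$f_sel), rownames(con$f_sel)]
  emp <- cor(t(con$f_sel))
  theo <- exp(-lambda * d)
  off <- upper.tri(d)
  expect_lt(max(abs(emp[off] - theo[off])), 0.1)  # ~4 Monte-Carlo SEs
})

test_that("divergence table is deterministic and respects record invariants", {
  cfg <- generator_config(n_species = 6, n_pathways = 4, genes_per_pathway = 5,
                          pairs_per_species = 6, seed = 77)
  s1 <- simulate_divergence_table(cfg)
  s2 <- simulate_divergence_table(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$f_sel, s2$truth$f_sel)

  r <- s1$records
  expect_equal(nrow(r), 6 * 4 * 5 * 6)
  expect_true(all(r$n_diff >= 0 & r$n_diff <= r$n_opp))
  expect_true(all(r$s_diff >= 0 & r$s_diff <= r$s_opp))
  expect_equal(sort(unique(r$species_id)), s1$tree$tip.label[order(s1$tree$tip.label)])
  # map covers every emitted gene exactly once
  expect_setequal(unique(r$gene_id), s1$map$gene_id)
  expect_false(anyDuplicated(s1$map$gene_id) > 0)

  # byte-identical TSV for the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "records.tsv"))),
                   unname(tools::md5sum(file.path(d2, "records.tsv"))))
})

test_that("neutral simulation pools to genome-wide dN/dS of 1", {
  cfg <- generator_config(n_species = 8, n_pathways = 5, genes_per_pathway = 40,
                          pairs_per_species = 15,
                          f_sel_range = c(0, 0), sigma_OU = 0, seed = 19)
  sim <- simulate_divergence_table(cfg)
  pooled <- pool_counts(sim$records)
  est <- compute_dnds(pooled$n_diff, pooled$n_opp, pooled$s_diff, pooled$s_opp)
  # Poisson-scale SE of a ratio of large counts
  se <- est$ratio * sqrt(1 / pooled$n_diff + 1 / pooled$s_diff)
  expect_lt(abs(est$ratio - 1), 3 * max(se, 0.01))
})

test_that("fixed dS at d_star reproduces the curve value in pooled counts", {
  # one pathway, many genes, no gene noise, dS pinned at d_star:
  # expected pooled dN/dS = 0.1 + 0.9 (1 - 1/e) = 0.66891
  cfg <- generator_config(n_species = 3, n_pathways = 1,
                          genes_per_pathway = 10000, pairs_per_species = 1,
                          ds_meanlog = log(0.01), ds_sdlog = 1e-9,
                          ds_min = 0.00999999, ds_max = 0.01000001,
                          f_sel_range = c(0.9, 0.9), sigma_OU = 0,
                          sigma_g = 0, d_star = 0.01, seed = 23)
  sim <- simulate_divergence_table(cfg)
  pooled <- pool_counts(sim$records)
  est <- compute_dnds(pooled$n_diff, pooled$n_opp, pooled$s_diff, pooled$s_opp)
  se <- est$ratio * sqrt(1 / pooled$n_diff + 1 / pooled$s_diff)
  expect_lt(abs(est$ratio - 0.668908502945702), 3 * se)
})

test_that("cv_target world enforces its coefficient of variation", {
  cfg <- generator_config(n_species = 40, n_pathways = 12,
                          genes_per_pathway = 10, pairs_per_species = 12,
                          cv_target = 1.2, seed = 41)
  sim <- simulate_divergence_table(cfg)
  # the enforced quantity: per-cell expected dN/dS omega is lognormal with
  # log-sd sqrt(log(1 + cv^2)); the log-scale sd estimator is well-behaved
  # (unlike the raw sample CV of a heavy-tailed lognormal), so assert there
  omega <- sim$truth$omega
  lx <- sweep(log(omega), 2, colMeans(log(omega)))
  expect_equal(sd(as.vector(lx)), sqrt(log(1 + 1.2^2)), tolerance = 0.06)

  # realized cell estimates track omega: the pipeline's median CV matches
  # the sample CV of omega itself (the estimator's small-sample bias for a
  # heavy-tailed lognormal at 40 species is shared by both)
  filt <- filter_records(sim$records)
  pm <- aggregate_by_pathway(filt$records, sim$map, min_support = 5)
  cv <- cv_summary(pm, n_boot = 300, seed = 2)
  cv_omega <- median(apply(omega, 2, function(col) sd(col) / mean(col)))
  expect_equal(cv$median_cv, cv_omega, tolerance = 0.15)
})

test_that("overflowing substitution probabilities are rejected", {
  cfg <- generator_config(n_species = 3, n_pathways = 2, genes_per_pathway = 5,
                          pairs_per_species = 3,
                          ds_meanlog = log(0.9), ds_sdlog = 0.01,
                          ds_min = 0.85, ds_max = 0.95,
                          f_sel_range = c(0, 0), sigma_OU = 0, seed = 2)
  expect_error(simulate_divergence_table(cfg), ">= 3/4")
})
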