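# Pipeline orchestration: filter -> aggregate -> model fit -> permutation
# tests -> scaling -> phylogenetic signal, with a manifest of every
# artifact.  Outputs contain no absolute paths or timestamps, so a rerun
# with the same inputs and seed is byte-identical.

#' Pipeline configuration
#'
#' Collects input locations (or in-memory objects) and every analysis
#' parameter.  Precedence for the command-line interface is flags > config
#' file > these defaults.
#'
#' @param records Path to a records TSV, or a record data frame.
#' @param map Path to a pathway-map TSV, a map data frame, or `NULL` to use
#'   the records' own `pathway_id` column.
#' @param tree Path to a newick tree or an `ape::phylo`; alternatively give
#'   `distances`.
#' @param distances Path to a square distance TSV or a matrix; overrides
#'   `tree`.
#' @param out_dir Output directory.
#' @param min_s_opp,min_pair_dS,max_pair_dS Filtering thresholds
#'   ([filter_records()]).
#' @param min_support Pooled synonymous differences required per matrix
#'   cell ([aggregate_by_pathway()]).
#' @param min_species_per_pathway Presence threshold for summaries and
#'   scaling.
#' @param permutations Permutation count B for both tests.
#' @param n_mantel Mantel permutations for the distance regression.
#' @param min_shared_pathways Overlap threshold for species-pair
#'   correlations.
#' @param statistic Permutation-test statistic, `"mean"` or `"median"`.
#' @param cor_method `"pearson"` or `"spearman"`.
#' @param correction dN/dS multiple-hit correction, `"none"` or
#'   `"jukes_cantor"`.
#' @param seed Seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(records, map = NULL, tree = NULL,
                            distances = NULL, out_dir = "dndscape_out",
                            min_s_opp = 10, min_pair_dS = 0,
                            max_pair_dS = 0.75, min_support = 10,
                            min_species_per_pathway = 3,
                            permutations = 10000, n_mantel = 999,
                            min_shared_pathways = 5,
                            statistic = "mean", cor_method = "pearson",
                            correction = "none", seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# Analysis parameters only (no paths/objects): the hash stamped on outputs.
analysis_params <- function(config) {
  config[c("min_s_opp", "min_pair_dS", "max_pair_dS", "min_support",
           "min_species_per_pathway", "permutations", "n_mantel",
           "min_shared_pathways", "statistic", "cor_method", "correction")]
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Stage order is fixed: read/validate inputs, filter records, aggregate to
#' the species x pathway matrix, fit the purifying-selection curve to
#' per-pair genome-wide points, permutation-test pathways then species,
#' Taylor's-law scaling and CV, species-pair correlations and the
#' phylogenetic-distance regression.  Every artifact is listed in
#' `manifest.json` with its md5 hash; any stage failure aborts with the
#' stage named.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage and
#'   `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  params <- analysis_params(config)
  hdr <- output_header(params, config$seed)

  records <- run_stage("read_records", {
    if (is.character(config$records)) read_records(config$records) else config$records
  })
  map <- run_stage("read_pathway_map", {
    if (is.character(config$map)) read_pathway_map(config$map) else config$map
  })

  filt <- run_stage("filter", filter_records(
    records, min_s_opp = config$min_s_opp,
    min_pair_dS = config$min_pair_dS, max_pair_dS = config$max_pair_dS))
  jsonlite::write_json(
    c(list(meta = list(tool = "dndscape",
                       version = package_version_string(),
                       params = params_hash(params), seed = config$seed)),
      filt$report),
    file.path(out, "filter_report.json"), auto_unbox = TRUE, digits = NA)

  pm <- run_stage("aggregate", aggregate_by_pathway(
    filt$records, map = map, min_support = config$min_support,
    correction = config$correction))
  write_matrix_tsv(pm, file.path(out, "matrix.tsv"), header = hdr)

  fit_bundle <- run_stage("fit_model", {
    key <- paste(filt$records$species_id, filt$records$pair_id, sep = "\r")
    sums <- rowsum(filt$records[, COUNT_COLUMNS], key)
    est <- compute_dnds(sums$n_diff, sums$n_opp, sums$s_diff, sums$s_opp,
                        correction = config$correction)
    parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
    points <- data.frame(
      species_id = vapply(parts, `[`, character(1), 1L),
      pair_id = vapply(parts, `[`, character(1), 2L),
      dS = est$dS, dnds = est$ratio
    )
    usable <- points[!is.na(points$dnds), , drop = FALSE]
    fit <- fit_model(usable$dS, usable$dnds)
    resid <- species_residuals(usable, fit, seed = config$seed)
    list(points = points, fit = fit, residuals = resid)
  })
  jsonlite::write_json(
    list(meta = list(tool = "dndscape", version = package_version_string(),
                     params = params_hash(params), seed = config$seed),
         f_sel = fit_bundle$fit$f_sel, d_star = fit_bundle$fit$d_star,
         loss = fit_bundle$fit$loss, n_points = fit_bundle$fit$n_points,
         d_star_identifiable = fit_bundle$fit$d_star_identifiable),
    file.path(out, "model_fit.json"), auto_unbox = TRUE, digits = NA)
  write_tsv_table(fit_bundle$points, file.path(out, "pair_points.tsv"),
                  header = hdr)
  write_tsv_table(fit_bundle$residuals, file.path(out, "species_residuals.tsv"),
                  header = hdr)

  pw_test <- run_stage("test_pathways", test_pathways(
    pm, B = config$permutations, seed = config$seed,
    statistic = config$statistic))
  write_perm_result(pw_test, file.path(out, "pathway_tests.tsv"), header = hdr)

  sp_test <- run_stage("test_species", test_species(
    pm, B = config$permutations, seed = config$seed,
    statistic = config$statistic))
  write_perm_result(sp_test, file.path(out, "species_tests.tsv"), header = hdr)

  scaling <- run_stage("scaling", {
    tl <- taylor_regression(pm, min_species_per_pathway = config$min_species_per_pathway)
    cv <- cv_summary(pm, min_species = config$min_species_per_pathway,
                     seed = config$seed)
    list(taylor = tl, cv = cv)
  })
  jsonlite::write_json(
    list(meta = list(tool = "dndscape", version = package_version_string(),
                     params = params_hash(params), seed = config$seed),
         slope = scaling$taylor$slope, intercept = scaling$taylor$intercept,
         slope_se = scaling$taylor$slope_se, t_vs_2 = scaling$taylor$t_vs_2,
         p_one_sided = scaling$taylor$p_one_sided,
         p_two_sided = scaling$taylor$p_two_sided,
         n_pathways = scaling$taylor$n_pathways,
         median_cv = scaling$cv$median_cv,
         cv_ci = c(scaling$cv$ci_lo, scaling$cv$ci_hi)),
    file.path(out, "scaling.json"), auto_unbox = TRUE, digits = NA)

  phylo <- run_stage("phylosignal", {
    dist_mat <- if (!is.null(config$distances)) {
      if (is.character(config$distances)) read_distance_tsv(config$distances)
      else config$distances
    } else if (!is.null(config$tree)) {
      cophenetic_distances(config$tree)
    } else {
      stopf("no tree or distance matrix supplied")
    }
    missing_sp <- setdiff(pm$species_ids, rownames(dist_mat))
    extra_sp <- setdiff(rownames(dist_mat), pm$species_ids)
    if (length(missing_sp)) {
      stopf("species in records but not in tree/distances: [%s]; extra in tree: [%s]",
            paste(missing_sp, collapse = ", "),
            paste(extra_sp, collapse = ", "))
    }
    cors <- pairwise_pathway_correlation(
      pm, min_shared_pathways = config$min_shared_pathways,
      method = config$cor_method)
    fit <- phylo_distance_regression(cors, dist_mat,
                                     n_mantel = config$n_mantel,
                                     seed = config$seed)
    list(correlations = cors, fit = fit)
  })
  write_tsv_table(phylo$correlations, file.path(out, "pair_correlations.tsv"),
                  header = hdr)
  jsonlite::write_json(
    list(meta = list(tool = "dndscape", version = package_version_string(),
                     params = params_hash(params), seed = config$seed),
         beta = phylo$fit$beta, intercept = phylo$fit$intercept,
         p_mantel = phylo$fit$p_mantel, p_ols = phylo$fit$p_ols,
         n_pairs = phylo$fit$n_pairs, n_species = phylo$fit$n_species,
         n_mantel = phylo$fit$n_mantel),
    file.path(out, "phylosignal.json"), auto_unbox = TRUE, digits = NA)

  files <- c("filter_report.json", "matrix.tsv", "matrix.tsv.support.json",
             "model_fit.json", "pair_points.tsv", "species_residuals.tsv",
             "pathway_tests.tsv", "species_tests.tsv", "scaling.json",
             "pair_correlations.tsv", "phylosignal.json")
  manifest <- list(
    tool = "dndscape", version = package_version_string(),
    seed = config$seed, params = params,
    params_hash = params_hash(params),
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(filter = filt, matrix = pm, fit = fit_bundle,
                 pathway_tests = pw_test, species_tests = sp_test,
                 scaling = scaling, phylosignal = phylo,
                 manifest = manifest))
}
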