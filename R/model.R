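# Two-parameter effective model of purifying selection.
#
# A fraction f_sel of nonsynonymous sites is deleterious with a single
# effective selection strength; divergence at those sites saturates once
# synonymous divergence passes the scale d_star (mutation-selection
# balance), while the remaining 1 - f_sel of sites drift neutrally.  The
# expected ratio is
#
#   dN/dS(dS) = (1 - f_sel) + f_sel * (1 - exp(-dS/d_star)) / (dS/d_star)
#
# which equals 1 at dS -> 0 (too little time for selection to act) and
# decays monotonically to the asymptote 1 - f_sel.

#' Expected dN/dS under the purifying-selection model
#'
#' @param dS Synonymous divergence (proportion, >= 0); vectorized.
#' @param f_sel Fraction of nonsynonymous sites under selection, in `[0, 1]`.
#' @param d_star Synonymous-divergence scale at which deleterious-site
#'   divergence saturates (> 0).
#' @return Expected dN/dS, in `[1 - f_sel, 1]`; the `dS = 0` limit is
#'   evaluated analytically as 1.
#' @examples
#' model_curve(0, 0.9, 0.01)       # 1: neutral limit
#' model_curve(1e6, 0.9, 0.01)     # ~0.1: asymptote 1 - f_sel
#' @export
model_curve <- function(dS, f_sel, d_star) {
  if (any(dS < 0)) stopf("model_curve: dS must be >= 0")
  if (f_sel < 0 || f_sel > 1) stopf("model_curve: f_sel must be in [0, 1]")
  if (d_star <= 0) stopf("model_curve: d_star must be > 0")
  # written as 1 - f (1 - g) so the dS -> 0 limit is exactly 1
  1 - f_sel * (1 - sat_frac(dS / d_star))
}

# (1 - exp(-x)) / x with the x -> 0 limit handled by series expansion;
# expm1 keeps precision for small x, the series guards x below ~1e-8.
sat_frac <- function(x) {
  out <- numeric(length(x))
  tiny <- x < 1e-8
  out[tiny] <- 1 - x[tiny] / 2 + x[tiny]^2 / 6
  out[!tiny] <- -expm1(-x[!tiny]) / x[!tiny]
  out
}

#' Fit the purifying-selection model to (dS, dN/dS) points
#'
#' Minimizes weighted squared residuals in log(dN/dS) space (the ratio
#' spans orders of magnitude) over a fixed coarse grid of
#' `f_sel` in {0, 0.01, ..., 1} and 50 log-spaced `d_star` knots in
#' `[1e-4, 1e-1]`, then refines the best grid point with bounded
#' quasi-Newton iterations.  Deterministic given the inputs; invariant to
#' point order and to duplicating points with halved weights.
#'
#' @param dS,dnds Numeric vectors of synonymous divergence and observed
#'   dN/dS per point (e.g. one genome-wide point per lineage pair).
#'   Points with `dnds <= 0` cannot enter a log-space fit and are dropped
#'   with a warning.
#' @param weights Optional non-negative per-point weights (default equal).
#' @return An object of class `model_fit`: `f_sel`, `d_star`, `loss`
#'   (weighted residual sum of squares), `n_points`, `residuals`
#'   (per-point log residuals), and `d_star_identifiable` (`FALSE` when the
#'   data are consistent with neutrality, `f_sel = 0`, so the scale cannot
#'   be estimated).
#' @export
fit_model <- function(dS, dnds, weights = NULL) {
  stopifnot(length(dS) == length(dnds))
  if (is.null(weights)) weights <- rep(1, length(dS))
  stopifnot(length(weights) == length(dS), all(weights >= 0))
  ok <- is.finite(dS) & is.finite(dnds) & dS > 0
  pos <- dnds > 0
  if (any(ok & !pos)) {
    warnf("fit_model: dropping %d point(s) with dN/dS <= 0 (log-space fit)",
          sum(ok & !pos))
  }
  ok <- ok & pos
  x <- dS[ok]; y <- log(dnds[ok]); w <- weights[ok]
  if (length(x) < 5) stopf("fit_model: need >= 5 usable points, got %d", length(x))
  if (max(x) / min(x) < 5) {
    stopf("fit_model: dS values span less than a factor of 5 (%.3g-%.3g); d_star is not identifiable",
          min(x), max(x))
  }

  f_grid <- seq(0, 1, by = 0.01)
  d_grid <- 10^seq(log10(1e-4), log10(1e-1), length.out = 50)
  loss_fun <- function(f, d) {
    mu <- log(model_curve(x, f, d))
    sum(w * (y - mu)^2)
  }
  grid_loss <- outer(seq_along(f_grid), seq_along(d_grid),
                     Vectorize(function(i, j) loss_fun(f_grid[i], d_grid[j])))
  best <- arrayInd(which.min(grid_loss), dim(grid_loss))
  f0 <- f_grid[best[1]]; d0 <- d_grid[best[2]]

  obj <- function(par) loss_fun(min(max(par[1], 0), 1), 10^par[2])
  opt <- stats::optim(c(f0, log10(d0)), obj, method = "L-BFGS-B",
                      lower = c(0, -5), upper = c(1, 0),
                      control = list(factr = 1e7))
  f_hat <- min(max(opt$par[1], 0), 1)
  d_hat <- 10^opt$par[2]
  resid <- y - log(model_curve(x, f_hat, d_hat))
  structure(
    list(f_sel = f_hat, d_star = d_hat, loss = opt$value,
         n_points = length(x),
         d_star_identifiable = f_hat > 1e-3,
         residuals = data.frame(dS = x, log_residual = resid, weight = w)),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("purifying-selection fit: f_sel = %.4f, d_star = %.3g (asymptotic dN/dS = %.4f)\n",
              x$f_sel, x$d_star, 1 - x$f_sel))
  cat(sprintf("  loss = %.4g over %d points%s\n", x$loss, x$n_points,
              if (!x$d_star_identifiable) "; d_star not identifiable (near-neutral data)" else ""))
  invisible(x)
}

#' Per-species deviation from the fitted curve
#'
#' For each point the residual is `log(observed dN/dS) - log(expected)`;
#' per species the mean residual and a seeded bootstrap percentile CI are
#' returned.  Positive means the species sits above the curve (weaker
#' constraint than the cross-species trend), negative below it.
#'
#' @param points Data frame with columns `species_id`, `dS`, `dnds`.
#' @param fit A [fit_model()] result computed on the same points.
#' @param n_boot Bootstrap replicates for the CI.
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level.
#' @return Data frame: `species_id`, `n_points`, `mean_residual`, `ci_lo`,
#'   `ci_hi`, `low_support` (fewer than 3 points).
#' @export
species_residuals <- function(points, fit, n_boot = 1000, seed = 1,
                              conf = 0.95) {
  stopifnot(inherits(fit, "model_fit"),
            all(c("species_id", "dS", "dnds") %in% names(points)))
  ok <- is.finite(points$dnds) & points$dnds > 0 & points$dS > 0
  pts <- points[ok, , drop = FALSE]
  resid <- log(pts$dnds) - log(model_curve(pts$dS, fit$f_sel, fit$d_star))
  sp <- sort_c(unique(pts$species_id))
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    rows <- lapply(sp, function(s) {
      r <- resid[pts$species_id == s]
      boots <- vapply(seq_len(n_boot),
                      function(i) mean(r[sample.int(length(r), replace = TRUE)]),
                      numeric(1))
      data.frame(species_id = s, n_points = length(r), mean_residual = mean(r),
                 ci_lo = unname(stats::quantile(boots, alpha)),
                 ci_hi = unname(stats::quantile(boots, 1 - alpha)),
                 low_support = length(r) < 3)
    })
    do.call(rbind, rows)
  })
}
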