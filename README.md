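# dndscape

Comparative population genetics of purifying selection across the many
coexisting species of a host-associated microbial community.

## What it does, and for whom

Given per-gene counts of nonsynonymous and synonymous differences between
pairs of host-resident lineages — the kind of table an upstream
metagenomic SNV-calling pipeline produces for each species across many
hosts — `dndscape` answers the comparative questions that follow:

1. **How does selection scale with divergence?**  Pooled dN/dS declines
   with synonymous divergence dS following a two-parameter model of
   purifying selection,

   dN/dS(dS) = (1 − f_sel) + f_sel · (1 − e^(−dS/d\*)) / (dS/d\*),

   where `f_sel` is the fraction of nonsynonymous sites under selection
   and `d*` the divergence scale at which deleterious-site divergence
   saturates.  The curve equals 1 at dS → 0 and falls to 1 − f_sel.
2. **Which pathways and which species are exceptional?**  Genes are
   coarse-grained into annotated metabolic pathways, giving a species ×
   pathway matrix of pooled dN/dS.  Permuting values across species within
   each pathway (or across pathways within each species) yields 95%
   nonparametric confidence intervals that flag species (or pathways)
   under stronger or weaker purifying selection than expected by chance.
3. **How is constraint dispersed and shared?**  Across pathways, the
   variance of dN/dS scales with its mean (Taylor's law; log–log slope 2
   ⇔ constant coefficient of variation), tested via
   t = (slope − 2)/se.  Between species, the correlation of pathway
   constraint profiles decays with phylogenetic distance; the slope β is
   tested with a Mantel-style label permutation that respects the
   non-independence of species pairs.

A fully seeded synthetic-data generator (binomial substitution counts on
a coalescent species tree, constraint evolving under an
Ornstein–Uhlenbeck process) emits tables, pathway maps, trees and ground
truth for end-to-end validation.  It stands in for the original
human-gut cohort data, which is not deposited.

## Worked example

```r
library(dndscape)

sim  <- simulate_divergence_table(generator_config(
          n_species = 12, n_pathways = 10, genes_per_pathway = 12,
          pairs_per_species = 15, seed = 42))
filt <- filter_records(sim$records)
pm   <- aggregate_by_pathway(filt$records, sim$map)
pm
#> pathway_matrix: 12 species x 10 pathways, 120/120 cells present

# one genome-wide point per lineage pair, then the selection curve
key  <- paste(filt$records$species_id, filt$records$pair_id, sep = "|")
sums <- rowsum(filt$records[, c("n_diff","n_opp","s_diff","s_opp")], key)
est  <- compute_dnds(sums$n_diff, sums$n_opp, sums$s_diff, sums$s_opp)
fit_model(est$dS, est$ratio)
#> purifying-selection fit: f_sel = 0.8040, d_star = 0.00976 (asymptotic dN/dS = 0.1960)
#>   loss = 1.176 over 180 points

sp <- test_species(pm, B = 5000, seed = 1)
sp[sp$flag != "none", ]
#>   unit_id  observed   null_lo   null_hi empirical_p    q_value     flag n_cells
#> 1    sp01 0.6046962 0.4768380 0.5709317  0.00139972 0.00559888   weaker      10
#> 2    sp02 0.3908611 0.4758515 0.5722863  0.00019996 0.00239952 stronger      10
#> 9    sp09 0.6168334 0.4748551 0.5718238  0.00059988 0.00359928   weaker      10

taylor_regression(pm)
#> Taylor's-law fit over 10 pathways: slope = 1.639 (se 1.292)
#>   H0 slope = 2: t = -0.279, one-sided P = 0.606, two-sided P = 0.787

cors <- pairwise_pathway_correlation(pm)
phylo_distance_regression(cors, cophenetic_distances(sim$tree),
                          n_mantel = 999, seed = 1)
#> correlation-vs-distance regression over 66 pairs (12 species):
#>   beta = -0.4356, Mantel P = 0.001 (999 permutations), analytic OLS P = 2.37e-06
```

Reading the numbers: the fitted `f_sel = 0.80` recovers the simulated
mean constraint (0.81) — about 80% of nonsynonymous sites are under
selection, so deeply diverged pairs settle near dN/dS ≈ 0.20.  Species
sp02 sits below its permutation null (stronger purifying selection than a
typical species with the same pathway repertoire); sp01 and sp09 sit
above it.  The Taylor slope is statistically indistinguishable from 2
here (a constant coefficient of variation), and constraint profiles of
closely related species are more similar than distant ones (β < 0,
Mantel P = 0.001).

The same analysis runs end to end with one call — `run_all()` on a
`pipeline_config()` — or from the shell via the installed CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/dndscape.R", package="dndscape"))')
Rscript "$CLI" simulate --out sim/ --seed 1
Rscript "$CLI" run-all --records sim/records.tsv --map sim/pathway_map.tsv \
        --tree sim/tree.nwk --out-dir results/ --seed 1
```

Outputs are TSV/JSON with embedded version, parameter hash and seed;
reruns at a fixed seed are byte-identical.

## Layout

- `R/` — divergence arithmetic and filtering; pathway coarse-graining;
  the selection curve and its fit; the permutation engine; cross-species
  statistics; the synthetic-data generator; I/O, pipeline and CLI.
- `vignettes/constraint-analysis.Rmd` — the model, its assumptions, the
  synthetic world, and the numerical choices.
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles.
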