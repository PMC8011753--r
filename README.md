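# pacseq

Guide detection and power analysis for single-cell CRISPR screens with
directly captured guide RNAs.

## The problem

When polyadenylated gRNAs are captured directly in droplet scRNA-seq, every
cell yields a vector of guide UMI counts contaminated by mapping artefacts
and ambient molecules. Deciding which guide a cell truly carries — and how
many cells per guide are needed to detect the transcriptomic consequence of a
cis-regulatory perturbation — are the two computational problems this package
solves, for people running or planning pooled perturbation screens.

**Guide assignment.** For each guide, cell $i$'s count $k_i$ out of its total
guide-library UMIs $n_i$ is modeled as a two-component binomial mixture

$$k_i \mid z_i \sim \mathrm{Binomial}(n_i, p_{z_i}),\qquad z_i \sim \mathrm{Bernoulli}(\pi),$$

with a noise rate $p_0$ and a signal rate $p_1 > p_0$, fit by EM with
Gaussian-mixture initialization on the count fractions. A guide is present in
a cell when the posterior probability of its count arising from the noise
component is below 0.05; cells carrying exactly one guide are assigned, and
the detection rate is the assigned fraction of high-quality transcriptomes.

**Power analysis.** Given a control population's expression profile and a
guide's expected monoallelic/biallelic loss rates, genes are bucketed by
baseline expression; loss is injected into resampled treatment cells
(biallelic sets expression to 0, monoallelic halves it); Wilcoxon rank-sum
tests against the control, summarized over 100 replicates and
Bonferroni-adjusted (over all genes, and over the independently filtered
family), yield per-bucket p-value curves and the minimum number of treatment
cells required for detection.

The package also provides the supporting stack: FASTQ → guide quantification
via local alignment and UMI collapse, 10x-style MTX IO, knee-rule and 3-MAD
transcriptome QC, log-normalization, Wilcoxon differential expression with a
cross-guide consistency rule, and synthetic-data generators for every stage.

## Worked example

Simulate guide counts for one gRNA across 2000 cells (total guide UMIs ~150
per cell; 30% of cells truly carry the guide), fit the mixture, and call
presence:

```r
library(pacseq)

s <- sim_mixture_counts(2000, total_mean = 150, p_noise = 0.005,
                        p_signal = 0.95, pi_signal = 0.3, seed = 11)
fit <- fit_binomial_mixture(s$k, s$n)
fit
#> Binomial mixture fit (2000 cells)
#>   p_noise = 0.005124, p_signal = 0.9496, pi_signal = 0.323
#>   3 EM iterations, converged = TRUE
mean(call_presence(fit, s$k, s$n) == s$z)
#> [1] 1
```

The fitted noise rate (0.51% of a cell's guide UMIs landing on a guide it
does not carry), signal rate (95% on the guide it does carry) and mixing
weight recover the generating values, and presence calls at the 0.05
noise-probability threshold match the ground-truth labels in every cell.

How many treatment cells would a guide with typical loss rates (25%
monoallelic, 5% biallelic) need for its target's downregulation to survive
Bonferroni correction, as a function of the target's baseline expression?

```r
ctrl <- lognormalize(make_control_matrix(sim_config(seed = 1)))
pg <- power_curve(ctrl, f_mono = 0.25, f_full = 0.05,
                  n_treat_grid = seq(200, 1000, 200), seed = 1)
min_cells_required(pg, alpha = 0.05, which = "filtered")
#>    bucket min_cells
#> 1       1        NA
#> 2       2        NA
#> 3       3        NA
#> 4       4        NA
#> 5       5        NA
#> 6       6       600
#> 7       7       200
#> 8       8       200
#> 9       9       200
#> 10      10      200
```

Buckets are deciles of baseline expression (1 = lowest). Under this loss
profile, targets in the top four deciles are detectable with 200 cells, the
sixth decile needs 600, and below that no grid size up to 1000 cells
suffices (`NA`) — quantifying how sharply power depends on baseline
expression when most perturbed cells retain one functional allele.

A command-line dispatcher over the same functions is installed at
`inst/cli/pacseq.R` (subcommands `simulate`, `quant`, `qc`, `assign`, `de`,
`power`, `run`).

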