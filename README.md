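# glicomix

Quantitative analysis of tumor-organoid co-cultures in which a small number
of glioma stem cells (GSCs) is seeded into human cerebral organoids and the
mixed tissue is profiled over months by droplet single-cell RNA-seq and bulk
whole-exome sequencing. The central question such experiments ask is *how
much of the tissue the tumor genotype has taken over, and what in the
organoid microenvironment let it grow* — which requires assigning every
single cell to its genotype of origin, quantifying the tumor genotype in
bulk DNA, scoring cells for microenvironmental stress programs, staging the
organoid against a developmental reference, and testing for receptor-ligand
crosstalk from organoid cells onto tumor cells.

`glicomix` implements that analysis as reusable R functions, together with
a ground-truthed synthetic-data generator that emulates the statistical
structure of such a co-culture (two germline genotypes sharing most SNPs,
a rare aneuploid tumor genotype, cell-type marker modules, droplet library
size and sequencing-error noise, and an age-graded bulk reference series).
It is aimed at computational biologists who work with organoid or other
two-genotype co-culture models and want the genotype-quantification
machinery without a BAM-level pipeline: all inputs are count matrices,
allele-count tables and VCF callsets.

## The core methods

**Two-genotype demultiplexing.** Cells are assigned to genotypes from
expressed-SNP allele counts with a two-component mixture model. Component
*g* carries a diploid genotype state per site *s*, so its alt-read
probability is restricted to θ<sub>gs</sub> ∈ {ε, ½, 1−ε} with ε the
sequencing error rate. With alt/ref counts a<sub>cs</sub>, r<sub>cs</sub>
for cell *c*,

  log L(c | g) = Σ<sub>s</sub> a<sub>cs</sub> log θ<sub>gs</sub> + r<sub>cs</sub> log(1 − θ<sub>gs</sub>),

and EM alternates cell posteriors (with estimated mixing proportions) with
per-site maximization of the expected complete-data likelihood over the
three states. A cell is labeled when its larger posterior reaches 0.99.
Components are *named* (tumor vs organoid) by inferred CNV: per-gene
reference-centered expression is smoothed along the genome with a moving
average, and the component with the higher median aneuploidy score (mean
squared window score) is the tumor. Cells the mixture leaves unassigned are
rescued by majority vote of their 30 nearest labeled neighbors in PCA
space.

**Germline SNP fingerprints.** From two VCF callsets the package builds
mutually exclusive panels — sites het/hom-alt in one genotype and
confidently hom-ref (explicit 0/0 call with depth) in the other — and reads
out each panel in bulk DNA as the fraction of evaluable sites (depth ≥ 10)
with ≥ 3 alternate reads, giving a per-sample detection fraction per
genotype. A maximum-likelihood mixture-fraction estimator is included as an
optional extra.

**Signature scoring.** Module scores subtract, from the mean expression of
a gene set, the mean of control genes drawn from the same average-expression
bins (24 bins, 100 controls per set gene), so a random set scores 0 in
expectation. Group summaries are z-scaled across groups. Two-group
comparisons use an exact Mann-Whitney rank-sum test (full enumeration for
n ≤ 20, e.g. p = 0.0286 for complete 4-vs-4 separation).

**Developmental staging and cluster identity.** Pseudo-bulk profiles are
correlated (Pearson, over the reference's top variable genes, on
log1p-CPM) with an age-graded reference series and summarized per age
group; cluster identity is compared across datasets through specificity
scores (cluster mean normalized expression ÷ global mean).

**Receptor-ligand crosstalk.** For each ordered cluster pair and
ligand-receptor pair, the observed score is the mean of the ligand's
cluster mean in the sender and the receptor's in the receiver (complexes:
minimum over member genes), gated by a 10% expressed-fraction requirement;
significance comes from shuffling cluster labels (add-one permutation
p-value), interactions are counted per cluster pair, and a directional
filter keeps microenvironment-ligand → tumor-receptor edges.

## Worked example

```r
library(glicomix)

genotypes <- make_genotypes(n_snps = 200, exclusive_fraction = 0.1, seed = 1)
genotypes
#> genotype_pair: 200 biallelic SNP sites
#>   exclusive to A: 20 | exclusive to B: 20 | shared: 160

sim <- simulate_cells(genotypes,
                      sim_config(n_cells = 2000, tumor_fraction = 0.1, seed = 1))
fit <- fit_two_genotype_mixture(sim$allele_counts, error_rate = 1e-3, seed = 1)
fit
#> genotype_mixture: loglik -9836.407 in 5 iterations (converged)
#>   labels: A=123 B=1608 unassigned=269

sce <- normalize_counts(sim$sce)
cnv <- infer_cnv(sce, reference_cells = seq_len(ncol(sce)), window_genes = 51)
fit <- label_components_by_cnv(fit, cnv)   # names A/B as tumor/organoid
fit <- rescue_unassigned(fit, sce)         # kNN vote for the remainder
genotype_fractions(fit, sample_labels = sce$sample)
#>   sample n_cells n_tumor n_organoid n_unassigned tumor_fraction
#> 1   sim1    2000     186       1814            0          0.093

mean(ifelse(fit$assignments$genotype == "tumor", "B", "A") == sim$truth$genotype)
#> [1] 0.998
```

The mixture model separates the two genotypes (here 123 + 1608 cells
unambiguously at posterior ≥ 0.99), CNV labeling identifies the minority
component as the tumor, neighbor rescue labels the remaining cells, and the
recovered per-sample tumor fraction (0.093) matches the simulated ground
truth (186/2000), with 99.8% of cells assigned to the correct genotype.

`run_pipeline()` chains all stages (simulation, QC, demultiplexing,
fingerprints, scoring, staging, crosstalk) on a multi-sample synthetic
cohort and writes a JSON report; see the methods vignette
(`vignettes/glicomix-methods.Rmd`) for the models, parameter choices and
limitations.

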