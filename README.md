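# picnc

Prediction of mutation Impact by Calibrated Nucleotide Conservation.

Deleterious alleles in crop genomes are hard to pin down: genetic mapping
lacks single-base resolution, and direct measures of cross-species
conservation are limited by missing alignments and low discriminatory
power. `picnc` takes the route of *predicting* phylogenetic nucleotide
conservation (PNC) from sequence-derived annotations, then carrying the
predicted conservation into genomic prediction as SNP weights. The package
is aimed at quantitative geneticists who want to prioritize nonsynonymous
variants for cross-population genomic prediction or targeted editing.

The pipeline:

1. **Annotate.** Every candidate nonsynonymous point mutation in the coding
   regions of annotated genes is described by genomic structure (GC content
   in a 100-bp window, mean genome-wide frequency of the covering 13-mers,
   transposon-family membership) and protein structure (mutation type,
   SIFT score and class, a fixed-dimension protein representation, and
   in-silico mutagenesis scores: the per-dimension deviations of the
   representation caused by the mutation plus their Euclidean distance).
2. **Label.** A site is conserved (`w = 1`) when its neutral tree size `N`
   exceeds 5 expected substitutions and its rejected-substitution ratio
   `RS / N` exceeds 0.95 (substitution rate below 0.05); it is unconserved
   (`w = 0`) when absent from the alignment; intermediate sites are left
   unlabeled.
3. **Predict.** A probability random forest `P(w = 1 | annotations)` is
   trained on labeled *monomorphic* sites — sites with no observed
   polymorphism, which avoids survivorship bias — with observations
   weighted by the inverse of their (label x chromosome) class size. SNP
   sites on chromosome *k* are scored by a forest that never saw
   chromosome *k* (leave-one-chromosome-out).
4. **Weight.** Predicted conservation `w_hat` becomes the weight of each
   nonsynonymous SNP in a two-kernel GBLUP,

   y = Q a + u + u_cds + e,  u ~ N(0, G s2_u),  u_cds ~ N(0, G_cds s2_cds),

   with `G` the VanRaden genome-wide relationship matrix and
   `G_cds = X W X' / sum(w_hat)`, `W = diag(w_hat)`, over the coding SNPs.
   Weights below a percentile threshold (0/50/90/99/99.9%) are truncated
   to zero; variance components are estimated by average-information REML
   with an EM fallback; significance of the weights is assessed by 20
   random permutations (significant when the observed accuracy beats all
   of them).

A deterministic synthetic-data generator (`simulate_picnc_data()`) emulates
all inputs — genome, gene models, GERP-style scores, SNP panels with a
planted MAF-conservation coupling, hybrid phenotypes — so the whole
pipeline can be exercised and validated without any downloads. Gene-level
enrichment statistics (expression contrasts, Fisher term enrichment with
Benjamini-Hochberg FDR, Pn/Ps) complete the toolkit.

## Worked example

```r
library(picnc)

bundle <- simulate_picnc_data(sim_config(
  n_chromosomes = 3, genes_per_chromosome = 3, embed_dim = 8,
  n_diverse = 60, n_families = 4, family_size = 10,
  n_background_snps = 150, seed = 42))

w <- label_sites(bundle$annotations$chrom, bundle$annotations$pos,
                 bundle$scores)
loco <- loco_predict(bundle$annotations, w,
                     config = forest_config(n_trees = 60,
                                            min_node_size = 25, seed = 1))
head(loco, 4)
#>   chrom pos ref alt      w_hat
#> 1  chr1 829   C   A 0.19986310
#> 2  chr1 827   C   A 0.15977777
#> 3  chr1 805   C   G 0.49999862
#> 4  chr1 804   G   C 0.09654269
```

Each row is an observed coding SNP with its predicted conservation
probability, scored by a forest trained on the other chromosomes. On this
fixture the predictions track the generator's true conservation
probabilities with a correlation of 0.91. Feeding the truncated weights
into genomic prediction (diversity panel trains, half-sib panel
validates):

```r
snps <- bundle$snps
Xc <- rbind(t(snps$coding_diverse), t(snps$coding_family)); Xc[is.na(Xc)] <- 0
Xb <- rbind(t(snps$background_diverse), t(snps$background_family))
G  <- grm(cbind(Xc, Xb))
Q  <- cbind(1, prcomp(cbind(Xc, Xb))$x[, 1:3])
y  <- c(bundle$phenotypes$y_diverse, bundle$phenotypes$y_family)
tr <- 1:60; va <- 61:100
w_hat <- loco$w_hat[match(paste(snps$sites$chrom, snps$sites$pos, snps$sites$alt),
                          paste(loco$chrom, loco$pos, loco$alt))]
fit <- picnc_gblup(y[tr], Q[tr, ], G[tr, tr],
                   weighted_grm(Xc, truncate_weights(w_hat, 50))[tr, tr])
fit
#> Two-kernel GBLUP
#>   n = 60, REML iterations = 6, logLik = -103.685
#>   variance components:
#>     sigma2_u     5.779
#>     sigma2_u_cds 2.203
#>     sigma2_e     5.372
```

The fitted object carries the REML variance components: here the
conservation-weighted coding kernel explains a genuine share of the
genetic variance next to the genome-wide kernel. Predicting the held-out
panel via the joint kernels (`predict(fit, ...)`) gives a cross-panel
accuracy (Pearson correlation of predicted and observed phenotypes) of
0.315 on this fixture.

A thin command-line wrapper over the same functions is installed at
`inst/cli/picnc.R` with `simulate`, `annotate`, `label`, `loco` and
`gblup` subcommands.

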