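---
title: "Predicting nucleotide conservation and weighting SNPs in genomic prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models, the defaults and why they are what they are, what the synthetic
generator does and does not emulate, and the places where the design was
genuinely open.

## The conservation label

For a genomic site with neutral tree size $N$ (expected substitutions
under a neutral model; a proxy for alignment depth) and rejected
substitutions $RS$, the binary conservation label is

$$w = \begin{cases} 1 & N > 5 \text{ and } RS/N > 0.95\\
0 & \text{site absent from the alignment}\\
\text{missing} & \text{otherwise.} \end{cases}$$

Both thresholds are strict and configurable (`n_min`, `rate_conserved` in
`pnc_label()`). The rationale for dropping intermediate sites rather than
calling them unconserved is contrast: the classifier learns from clearly
conserved sites versus sites in unalignable (hence least conserved)
regions, which maximizes the separation the annotations must explain.
"Absent from the alignment" is encoded as a missing row in the score
table, or equivalently $N = 0$; this convention is asserted by
`label_sites()`.

## Annotations

Each candidate nonsynonymous mutation carries:

* **mutation type** — missense, stop gain, stop loss, from the standard
  nuclear code (selenocysteine is not handled);
* **SIFT score and class** — supplied externally; missing scores are
  imputed to 1 and flagged, class is "constrained" iff score $\le 0.05$;
* **GC content** — count of G/C in the window $[-49, +50]$ around the
  site; at contig ends the window is clipped and the effective length
  recorded, since no edge convention is canonical;
* **k-mer frequency** — the mean genome-wide occurrence count of the (up
  to) 13 windows of length 13 covering the site. Counting is forward
  strand, exact match, case-folded, with ambiguous bases never matching —
  the simplest reproducible dialect; strandedness of k-mer counting has
  no canonical answer and the forward-only choice is documented rather
  than hidden;
* **transposon flags** — four booleans (helitron, TIR, LINE, LTR) from
  labeled interval sets, inclusive coordinates;
* **protein representation and in-silico mutagenesis** — a fixed-dimension
  embedding of the reference protein, plus the signed per-dimension
  deviations (mutant minus reference) and their Euclidean norm. Whether
  deviations should be signed or absolute is not determined; signed is
  the default because it loses no information (the norm is carried
  separately).

The embedder is a contract, not a model: any function mapping a protein
sequence to a fixed-dimension numeric vector can stand behind
`embed_protein()`. The package ships `toy_embedder()`, a deterministic
hashed-composition scheme (1-mer and 2-mer counts hashed into `D` buckets
and divided by sequence length). It is order-sensitive through its 2-mers,
so mutagenesis scores are informative, and it needs no trained weights, so
tests and fixtures are fully reproducible. It does not, of course, encode
real protein structure; conclusions about the usefulness of *learned*
representations do not transfer from it. `D` defaults to 256 to match the
representation size the method was designed around; the fixture bundle
uses `D = 16` to keep forest training at desk scale.

Mutation enumeration walks the representative transcript of each gene —
the one with the longest CDS, ties broken by lexicographically smallest
transcript id so the choice is deterministic. At monomorphic sites,
`per_site` (default 1) alternate alleles are drawn uniformly among the
nonsynonymous options using a site-keyed hash, so the draw for a site
does not depend on the order in which sites are visited; how many
alternates the original procedure drew per site is unknown, hence the
exposed knob. Stop-loss mutations re-translate through the 3' UTR until
the next in-frame stop, bounded by the transcript end (and flagged when
no stop is found).

## The probability forest

`picnc_forest()` estimates $P(w = 1)$ with an ensemble of probability
trees (leaves store class-1 proportions; the forest averages them).
Defaults mirror genome-scale practice: 1000 trees, 50,000 sites per tree
sampled with replacement, at least 100 sites per terminal node, one third
of non-baseline features per tree. Mutation type, SIFT score and SIFT
class are always included as baseline predictors. Sample weights are the
inverse of the (label x chromosome) class size, entering as bootstrap
sampling probabilities — the case-weight semantics of the underlying
`ranger` library — so each class contributes equal total weight; split
impurity on the sampled set is unweighted.

Feature subsetting is per tree by default, with all subset features
available at every split, because that is the stated protocol; a
`per_split` mode (classical mtry) is available since forest libraries
default to it and the two are not equivalent. Neither is asserted to be
"the" original behavior.

Variable importance is the corrected impurity measure: each fitted tree
is paired with a tree grown on the same feature subset plus permuted
shadow copies of every feature, and the importance of a feature is its
impurity reduction minus that of its shadow, accumulated over trees.
Growing the shadow trees separately keeps the *prediction* trees free of
shadow splits, so a depth-1 single-feature tree exactly reproduces the
best Gini threshold — a property the test suite checks against an
exhaustive split search. (The alternative — computing corrected
importance inside the prediction forest — lets shadow variables compete
for splits and perturbs predictions.)

Leave-one-chromosome-out prediction trains one forest per chromosome
carrying SNPs, on the labeled monomorphic sites of all other chromosomes.
Hyperparameter tuning for left-out chromosome $k$ trains on the
chromosomes of parity opposite to $k$ and validates on the remainder
(excluding $k$), over the grid $n_{trees} \in \{100, 250, 500, 1000\}$,
$p_{variables} \in \{1/12, 1/6, 1/3, 2/3\}$; ties prefer more trees, then
a smaller fraction.

Classification accuracy is class-weighted; predicted probabilities round
half *up*, so an exactly uninformative 0.5 calls the conserved class —
an arbitrary but fixed convention.

## Two-kernel GBLUP

The phenotype model is $y = Q\alpha + u + u_{cds} + e$ with
$u \sim N(0, G\sigma^2_u)$, $u_{cds} \sim N(0, G_{cds}\sigma^2_{cds})$,
$e \sim N(0, I\sigma^2_e)$. $Q$ holds an intercept and the top three
principal components of a reference genotype matrix (unscaled scores).
$G$ is the VanRaden cross-product of centered dosages;
$G_{cds} = X_{cds} W X_{cds}^{\top} / \sum_j \hat w_j$ uses *uncentered*
dosages, exactly as the kernel is defined; a `center = TRUE` variant
exists because centering is the more common kernel convention and the
difference is absorbed into the fixed effects only approximately.

Weight truncation uses the nearest-rank convention: the threshold is the
$\lfloor qm/100 \rfloor$-th ascending order statistic and only weights
strictly above it survive. This is the only convention consistent with
all three published prioritized-set sizes (48,345 of 483,448 at 90%;
1,040 and 104 of 103,905 at 99% and 99.9%), which the acceptance suite
reproduces.

REML maximizes the restricted likelihood by a guarded hybrid: at each
iteration the EM update (monotone, non-negative, valid for singular
kernels), an average-information Newton step (with components pinned at
the variance floor of $10^{-10}$ removed from the system and
out-of-bound moves floored), a half Newton step, and boundary candidates
that zero near-vanishing components are all evaluated, and the best
restricted likelihood wins. The boundary candidates matter: when the
optimum sits at $\sigma^2 = 0$, EM approaches it geometrically and never
arrives, while the explicit boundary probe jumps there in one step.
Convergence is declared when the relative likelihood change falls below
`tol` (default $10^{-8}$) or the components stop moving; 200 iterations
without convergence is an error that reports the likelihood trace.

Cross-panel prediction is conditional BLUP on kernels computed jointly
over both panels (shared SNP set and allele frequencies):
$\hat u_{val} = G_{val,train} (G_{train,train} + \varepsilon I)^{-1}
\hat u_{train}$ per kernel, with jitter $\varepsilon = 10^{-8}$; the
mechanics of cross-panel prediction are not otherwise pinned down, and
conditional BLUP is the canonical choice. Leave-one-family-out reports
the pooled correlation over concatenated held-out predictions (with
per-family correlations alongside, since pooling and averaging answer
slightly different questions and the published convention is not
stated).

The permutation test shuffles the SNP weights $B = 20$ times, re-applies
the same truncation, recomputes the full pipeline accuracy, and declares
significance only when the observed accuracy strictly exceeds all $B$
permuted ones. For continuous accuracies this test has exact level
$1/(B+1) \approx 0.048$ under exchangeability. The test suite estimates
the level by Monte-Carlo (200 null replicates) and checks consistency
with a level of at most 0.05 by a one-sided binomial test — at 200
replicates the Monte-Carlo standard error (about 0.015) is of the same
order as the gap between $1/21$ and $0.05$, so a hard cutoff on the raw
estimate would fail a correctly implemented test about a third of the
time.

## Enrichment statistics

Gene prioritization selects genes containing at least one site passing a
percentile rule (same truncation convention) or with observed
conservation 1. Expression contrasts are differences of means on the
$\log(x+1)$ scale with Welch two-sample intervals — the unequal-variance
form, since equal variances across arbitrary gene sets is not a defensible
default. Term enrichment uses two-sided Fisher exact tests (depletions are
as interesting as enrichments) with Benjamini-Hochberg FDR within each
stratum, discarding terms under 20 members; the gene universe defaults to
the genes containing analyzed nonsynonymous SNPs. $P_n/P_s$ ratios are
reported only for genes with $P_s \ge 5$.

## The synthetic generator

`simulate_picnc_data()` plants known structure at desk scale — defaults:
5 chromosomes x 6 genes (CDS 60-140 codons with introns and both UTRs on
both strands), about 7-8 thousand candidate mutations, a 200-line
diversity panel and an 8x25 half-sib hybrid panel (RILs from a recurrent
parent crossed to a common tester), 600 neutral background SNPs, trait
heritability 0.5 with 40 causal SNPs drawn preferentially among
conserved sites. These sizes give the forest and REML enough signal for
minutes-scale validation; they are choices, stated here once, not tuned
quantities.

The generator's true conservation probability is a logistic function of
standardized annotation columns (defaults: strong negative weight on SIFT
score, positive weights on GC content and mutagenesis distance), so
recovery is measurable against ground truth. Emitted $(N, RS)$ rows are
constructed to re-label exactly to the drawn class — conserved sites get
deep trees and near-unit conservation ratios, intermediate sites violate
exactly one threshold, unconserved sites are simply absent. MAF couples
to conservation through a Beta distribution whose second shape grows
with the true conservation probability, reproducing the depletion of
common alleles at constrained sites. Phenotype noise is scaled per panel
so each panel realizes the target heritability despite their different
genetic variances.

What the generator does *not* emulate: linkage disequilibrium and
recombination maps (genotypes are independent across sites given the
family structure), realistic codon usage and splice signals, alignment
error in the conservation scores, and any real relationship between
protein sequence and fitness (the planted logistic stands in for it).
Passing tests therefore demonstrate that the machinery recovers planted
structure of the assumed form — not that the annotations predict
conservation in a real genome.

## Problem sizes in the validation suites

The test and acceptance runs use: REML recovery at $n = 400$ over 20
seeds (true components 1 / 0.5 / 1, mean recovery within 15%); forest
recovery with 5,000 training sites and 19 noise features; permutation
level with 200 null replicates and power over 20 seeds on a 60-line
panel; the end-to-end pipeline on the default generator bundle with
100-tree forests; GBLUP-ridge equivalence on a 50x100 fixture. All sizes
were fixed when the studies were designed.

## Known limitations

* The toy embedder is a plumbing stand-in; swap in a real protein model
  through the embedder contract for scientific use.
* Non-coding mutations are out of scope; so are transposon calling, SIFT
  itself, alignment/score computation, and imputation — all are inputs.
* `G_cds` with uncentered dosages makes the kernel sensitive to allele
  coding; this follows its definition, and the centered variant is one
  flag away.
* Families in the generator share a single recurrent parent and tester;
  more elaborate crossing designs (or LD) require a different simulator.
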