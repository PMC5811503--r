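---
title: "Network-based boosting of GWAS gene scores: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based boosting of GWAS gene scores: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A genome-wide association study (GWAS) tests each SNP for association with
a phenotype and, after multiple-testing correction, typically leaves only a
handful of genome-wide-significant loci. Complex phenotypes are polygenic
and genetically heterogeneous — causal variants are spread over many genes
of the underlying pathways, each carried by only part of the population —
so most truly involved genes sit below the significance threshold.
Because pathway co-membership is visible in co-functional gene networks,
a gene that is only weakly associated on its own but is wired to strongly
associated genes is a good candidate. `gwabnet` formalizes this
guilt-by-association (GBA) rescue for GWAS summary statistics.

## The model

**SNP-to-gene assignment.** Each gene receives the best (minimum) P-value
among SNPs within `window` bases (default 10 kb) of either end of its
span. Internally all coordinates are 0-based half-open; a SNP at 1-based
position $p$ is in the window of gene $[s, e)$ iff
$s - w < p \le e + w$. Ties on P are broken by the smallest position so
output is deterministic. Genes without any SNP in their window stay in
the analysis with neutral evidence: the network may still nominate them.

**Soft guilt-by-association.** Let $p_j$ be the probability that gene $j$
is involved in the phenotype. Each gene $i$ accumulates from its network
neighbours
$$ S_i = \sum_{j \in N(i)} (2p_j - 1)\, l_{ij}, $$
summing only neighbours with $2p_j - 1 > 0$ that pass the *contributor
threshold* (below); $l_{ij} > 0$ is the weight of the edge (for
AraNet-style networks, a log-likelihood score of functional coupling).
A neutral neighbour ($p_j = 1/2$) contributes nothing; only strongly
associated genes donate close to their full edge weight, so $S_i \ge 0$.

**Naive-Bayes combination.** Treating network and GWAS evidence as
conditionally independent given association, the posterior log odds of
association is the sum
$$ \log O(i \in D \mid D_{net}, D_{GWAS}) = S_i + \log O(i \in D \mid D_{GWAS}), $$
which is the final ranking score. The combination is exactly this sum —
no other terms, no iteration: boosting is single-pass over direct
neighbours.

**The contributor threshold.** Hub genes touching many weakly associated
neighbours would accumulate spurious $S_i$. The remedy is to let only
genes whose assigned P-value satisfies $\log_{10} P \le t$ *donate* GBA
score (every gene can still receive). $t$ is scanned over a grid
(default $-6.0, -5.7, \dots, -2.1$; 14 points) and the value maximizing
retrieval performance is selected.

**Evaluation and the null.** Performance is the partial AUC of the ROC
curve restricted to the first 5% of false positives (pAUC(<5% FPR)),
computed against a user-supplied reference set of known
phenotype-associated genes and normalized by the FPR cutoff so a perfect
ranking scores 1 and chance scores 0.025. The boost is called significant
at a threshold when the real network's pAUC exceeds the mean + 2 SD of
the pAUCs obtained from 100 randomized networks run through the identical
pipeline.

## Quantities the data do not define, and what we chose

The evidence terms $p_j$ and $\log O(i \mid D_{GWAS})$ must be derived
from the assigned P-values; no unique recipe follows from the model, so
both are explicit, configurable choices:

* **$p_j$ (default `complement`):** $p_j = 1 - P_j$. This makes the GBA
  weight $2p_j - 1 = 1 - 2P_j$ approach its full value exactly for
  overwhelming association, vanish at $P = 1/2$, and requires no
  reference set inside the GBA sum. A `calibrated` mode instead passes
  the calibrated log odds plus the log prior odds of reference membership
  through the logistic function.
* **GWAS log odds:** genes are sorted by ascending P and cut into rank
  bins of 100; each bin's log-likelihood ratio of reference membership is
  estimated with Jeffreys 0.5 pseudocounts,
  $\mathrm{LLR}_b = \ln \frac{(TP_b + 0.5)/(P_{tot}+1)}{(FP_b + 0.5)/(N_{tot}+1)}$,
  and the bin sequence is projected onto non-increasing sequences by
  weighted pool-adjacent-violators (weights = bin sizes), so calibrated
  evidence never rewards a worse P-value. Genes without an assigned P get
  0 (neutral odds). The pseudocount avoids infinite odds in pure bins;
  bin size 100 trades resolution against counting noise and is exposed
  as `bin_size`.
* **pAUC normalization:** the partial area is divided by the FPR cutoff
  so values live on [0, 1] regardless of the cutoff. Tied scores are
  drawn as a single diagonal ROC segment — equivalent to averaging over
  all orderings of the tied genes and exactly reproducible by vertex
  enumeration (massive ties are common: at strict thresholds most genes
  have $S_i = 0$ and bin-constant log odds).
* **Null model (default `permute`):** gene labels are permuted over
  network positions. Every topological property — degree sequence, weight
  distribution, hubness — is preserved exactly; only the association
  between gene identity and network position is destroyed, which is
  precisely the hypothesis under test ("does the wiring carry phenotype
  information beyond the GWAS scores?"). Degree-preserving double-edge
  swaps (`rewire`, 10×|E| attempted swaps) are available for sensitivity
  analysis; they additionally destroy edge-level structure.
* **Scan mechanics:** the same randomized networks (seeds derived
  deterministically from the master seed and replicate index) are reused
  across all grid points, so differences between thresholds reflect the
  threshold, not permutation noise. The null SD uses the $n-1$
  denominator; the 2-SD rule is the normal-approximation band as
  conventionally drawn. The optimum takes the earliest grid point on
  ties. Contributor-threshold comparison adds a $10^{-9}$ slack so a
  gene with $\log_{10} P$ exactly on a grid value is included despite
  floating-point representation.

Other boundary conventions: P-values of exactly 0 are rejected at parse
time (they break log odds) unless an explicit floor is supplied; gene IDs
are matched case-sensitively with optional, explicit transcript-suffix
stripping; duplicate network edges keep the maximum weight; the
evaluation universe is the union of annotation, network and reference
genes so network-only candidates are ranked and scored.

## What the synthetic generator emulates

`simulate_bundle()` produces the four pipeline inputs with a controlled
planted truth, emulating the statistical structure of a plant GWAS over a
co-functional network at desk scale: 2,000 genes with random
non-overlapping spans on a 30-Mb chromosome and 20,000 uniformly placed
SNPs give roughly one SNP per 1.5 kb — about 15 SNPs per 10-kb-windowed
gene, similar to a genotyping-array study. Null SNP P-values are
Uniform(0, 1]. The network is Barabási–Albert with 4 edges per node
(mean degree ≈ 8, scale-free like real co-functional networks) and
log-normal edge weights (meanlog 0.5, sdlog 0.6; bulk between about 1
and 5, resembling log-likelihood scores).

A 40-gene module plays the phenotype pathway. Genetic heterogeneity is
modelled at the gene level: only `signal_frac` (default 0.4) of module
genes carry association — each gets one SNP inside its span with
$-\log_{10} P = 2 + \mathrm{Exp}(\text{mean} = 5)$, i.e. an exponential
truncated below at 2, so signal P-values are at most $10^{-2}$ and
typically around $10^{-5}$. The reference list is the full module,
including the quiet 60% that GWAS alone cannot find — exactly the genes
boosting should rescue.

**Module wiring is planted by degree-preserving targeted swaps.** Two
existing edges $(m_1, x)$ and $(m_2, y)$ with $m_1, m_2$ in the module
are replaced by $(m_1, m_2)$ and $(x, y)$, each weight travelling with
its donor edge, until 100 intra-module edges exist (about 5 module
partners per module gene). This choice matters: if module edges were
simply *added*, the reference genes would be degree- and
strength-inflated hubs, and the label-permutation null would correctly
flag them even with no association signal planted — the negative control
would be structurally broken by the very hub artifact the contributor
threshold exists to suppress. With swaps, every gene keeps its exact
degree and its expected incident weight, so with `signal_frac = 0` the
planted module is invisible to per-gene network statistics and only the
signal-plus-wiring combination produces a detectable boost.

What the generator does **not** emulate: linkage disequilibrium and
correlated SNPs, multi-chromosome structure (a single chromosome
suffices; the option exists only for layout), mixed-model P-value
artifacts, allele frequencies (MAF filtering belongs upstream), and the
annotation-training circularity of real curated networks. Passing tests
therefore demonstrate correctness of the machinery and recoverability of
a clean planted signal — not performance on any real phenotype.

## Validation strategy and problem sizes

Every numerical component is checked against an independent brute-force
oracle: the sparse-matrix GBA sum against a dense all-pairs double loop
(networks up to 300 nodes), the partial AUC against explicit ROC-vertex
enumeration (500 random rankings with heavy ties, agreement to 1e-12,
plus the closed-form chance value 0.025 and the rank-sum identity for the
full-range AUC), the windowed assignment against an all-pairs SNP × gene
scan, and the pool-adjacent-violators fit against the minimax
characterization of isotonic regression. The end-to-end positive control
runs the default bundle over 20 seeds with 100 randomized networks each;
the boosted pAUC at the optimal threshold exceeds both the GWAS-only
baseline and the null mean + 2 SD in 20 of 20 measured runs, with optimal
thresholds falling between −5.7 and −3.0 — the same range reported for
real phenotypes by this class of method. These sizes keep the full suite
within a few minutes on one core while leaving the planted-module
recovery far from trivial (the quiet module genes are statistically
invisible to GWAS alone).

## Known limitations

* **The 2-SD band is a normal approximation on a skewed statistic.** At
  loose thresholds the null pAUC distribution is strongly right-skewed
  (most permutations give near-chance retrieval; occasionally a permuted
  label set lands on boosted positions), so mean + 2 SD undercovers the
  right tail: a truly null run pokes above the band somewhere along a
  14-point grid more often than the nominal rate suggests. Significance
  calls at a single pre-chosen threshold are better calibrated than
  "anywhere along the curve" readings; an empirical-quantile band would
  fix this but is deliberately not the default, to keep the conventional
  band definition.
* **Clustered reference sets inflate variance further.** When reference
  genes are densely interconnected (as pathway genes are), their boosted
  scores rise and fall together: a single chance contributor inside the
  cluster lifts many positives at once. The permutation null reproduces
  the marginal behaviour but not this correlation, so real-network pAUCs
  have heavier tails than the null SD implies even without true signal.
  This is inherent to evaluating clustered positives with a
  position-randomizing null and is the main caveat when reading marginal
  band excursions.
* **One-hop only.** Boosting does not propagate beyond direct
  neighbours; genes two steps from all signal carry no network evidence.
  Multi-hop diffusion is out of scope by design.
* **The contributor threshold is the only hub control.** No cap or
  damping is applied to individual hub contributions beyond contributor
  selection.

## Reproducing the study conditions

`scripts/acceptance.R --seed <int> --out <path>` regenerates the default
bundle, runs the full scan with 100 randomized networks and writes the
headline metrics (boosted and GWAS-only pAUC, null mean/SD at the
optimum, the selected threshold, significance counts) as JSON. The README
shows a worked example with the numbers a run actually prints.
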