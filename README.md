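# gwabnet

Network-based boosting of GWAS summary statistics for candidate-gene
prioritization.

GWAS of complex phenotypes leave most truly involved genes below the
multiple-testing significance threshold: causal variants are spread over
many pathway genes, each weakly associated on its own. Because pathway
co-membership is visible in co-functional gene networks, a gene that is
subthreshold by itself but wired to strongly associated genes is a strong
candidate. `gwabnet` implements this guilt-by-association rescue for
users who have per-SNP P-values, a gene annotation, a weighted gene
network (e.g. an AraNet-style log-likelihood-score edge list) and a
reference list of known phenotype genes.

## Method

1. **SNP→gene assignment** — each gene gets the best (minimum) P-value
   among SNPs within a window (default 10 kb) of either end of its span.
2. **Soft guilt-by-association** — with p<sub>j</sub> the probability
   that gene *j* is phenotype-involved (default p<sub>j</sub> = 1 −
   P<sub>j</sub>), each gene accumulates from its network neighbours

   *S<sub>i</sub>* = Σ<sub>j</sub> (2p<sub>j</sub> − 1) · l<sub>ij</sub>,

   summing only neighbours with 2p<sub>j</sub> − 1 > 0 whose assigned
   P-value passes a **contributor threshold** log₁₀P ≤ *t* (this
   restriction suppresses hub-gene inflation). l<sub>ij</sub> is the
   edge weight.
3. **Naive-Bayes integration** — the final score is the posterior log
   odds *S<sub>i</sub>* + log O(i ∈ D | D<sub>GWAS</sub>), where the
   GWAS log odds is calibrated from rank bins against the reference set
   (pseudocounted log-likelihood ratios made monotone by isotonic
   regression).
4. **Evaluation and threshold selection** — rankings are scored by the
   partial AUC before 5% false-positive rate against the reference
   genes; the scan repeats the whole procedure over a threshold grid
   (default −6.0, −5.7, …, −2.1) and for 100 label-permuted networks,
   calling the boost significant where the real network exceeds the
   null mean + 2 SD, and selecting the threshold with maximal pAUC.

A synthetic-data module generates full input bundles (network +
annotation + summary statistics + reference list) with a planted,
partially signal-carrying pathway module, so the whole pipeline is
testable without any external download.

## Worked example

```r
library(gwabnet)

# simulate a study: 2,000 genes, 20,000 SNPs, a 40-gene phenotype module
# of which 40% carry association signal; reference list = full module
b <- simulate_bundle("sim", seed = 1)

snps  <- read_summary_stats(b$paths$snps)
genes <- read_gene_models(b$paths$genes)
net   <- load_network(b$paths$network)
ref   <- read_gene_list(b$paths$reference)

assignments <- assign_snps_to_genes(snps, genes, window = 10000)
scores <- score_genes(assignments, reference = ref,
                      extra_genes = union(net$nodes, ref))
scan <- run_scan(net, scores, ref, n_random = 100, seed = 1)
scan
#> threshold scan: 14 grid points in [-6, -2.1], 100 randomized networks (permute null)
#> pAUC(<5% FPR): GWAS-only 0.2128; best boosted 0.5378 at log10(P) <= -4.20
#> null at optimum: 0.0715 +/- 0.0306 (2-SD band); significant at 14/14 thresholds
```

GWAS alone retrieves only the signal-carrying module genes
(pAUC 0.21); boosting over the network more than doubles early
retrieval (pAUC 0.54 at the optimal contributor threshold
log₁₀P ≤ −4.2), far above the randomized-network band. The top of the
final ranking is dominated by *quiet* module members whose own GWAS
evidence is invisible (assigned P ≈ 0.04–0.15) but whose network
neighbourhood vouches for them:

```r
head(scan$final_ranking, 8)
#>   gene_id assigned_pvalue gba_score log_odds_gwas final_score rank is_reference
#> 1  G00550         0.11793     13.95        -0.483       13.47    1         TRUE
#> 2  G00246         0.04192      9.30        -0.483        8.81    2         TRUE
#> 3  G00660         0.14797      9.03        -0.483        8.55    3         TRUE
#> 4  G01284         0.13861      8.63        -0.483        8.15    4         TRUE
#> 5  G00844         0.13717      8.20        -0.483        7.72    5        FALSE
#> 6  G01045         0.04751      7.32        -0.483        6.83    6         TRUE
#> 7  G01578         0.00113      4.65         2.160        6.81    7         TRUE
#> 8  G00672         0.03958      7.17        -0.483        6.69    8         TRUE
```

`write_ranked_table()` / `write_scan_summary()` export these as TSV;
`scan_curves()` returns plot-ready data for the scan figure (boosted
curve, GWAS-only baseline, null band). The same pipeline runs on real
inputs via `run_pipeline()` or the command-line front end
`inst/cli/gwabnet.R` (subcommands `run`, `boost`, `simulate`,
`evaluate`).

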